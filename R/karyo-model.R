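## Block-level karyotype model: the ACK complement, the five rearrangement
## operators, canonical forms, scenario replay and karyotype summaries.

#' Breakpoint specification
#'
#' A breakpoint names a chromosome and a position on it, either a boundary
#' between segments (\code{after} = number of segments preceding the cut;
#' 0 = head terminus, nseg = tail terminus) or a position inside a segment
#' (\code{segment} index plus \code{fraction} of that segment's span, measured
#' along the chromosome reading). A within-segment breakpoint splits that
#' segment into two parts that preserve total block fraction.
#'
#' When the cut falls exactly at the centromere boundary (\code{after} equal to
#' the centromere index) the centromere stays with the tail fragment unless
#' \code{cenToHead = TRUE}.
#'
#' @param chrom Chromosome name.
#' @param after Integer boundary index (mutually exclusive with
#'   \code{segment}).
#' @param segment Integer segment index for a within-segment cut.
#' @param fraction Fraction of the segment span at which to cut, in (0,1).
#'   Defaults to 0.5.
#' @param cenToHead Logical; see Details.
#' @return A list of class \code{"breakpoint"}.
#' @export
#' @examples
#' breakpoint("AK3b", segment = 1)           # split block F into Fa/Fb
#' breakpoint("AK5b+AK7b", after = 1)        # cut at the U|T boundary
breakpoint <- function(chrom, after = NULL, segment = NULL, fraction = 0.5,
                       cenToHead = FALSE) {
  if (is.null(after) == is.null(segment))
    stop("give exactly one of 'after' (a boundary) or 'segment' (a within-segment cut)")
  if (!is.null(segment) && (fraction <= 0 || fraction >= 1))
    stop("'fraction' must lie strictly inside (0,1)")
  structure(list(chrom = chrom,
                 after = if (!is.null(after)) as.integer(after) else NULL,
                 segment = if (!is.null(segment)) as.integer(segment) else NULL,
                 fraction = fraction, cenToHead = isTRUE(cenToHead)),
            class = "breakpoint")
}

bpString <- function(bp) {
  if (!is.null(bp$after)) sprintf("%s:|%d", bp$chrom, bp$after)
  else sprintf("%s:%d@%.3g", bp$chrom, bp$segment, bp$fraction)
}

#' @export
print.breakpoint <- function(x, ...) {
  cat("breakpoint", bpString(x), "\n")
  invisible(x)
}

## coalesce consecutive segments that are contiguous pieces of the same block
## copy read in the same direction (an intact block is indistinguishable from
## two abutting fragments of it); the centromere boundary blocks merging
coalesceSegments <- function(segments, centromere) {
  i <- 1L
  while (i < nrow(segments)) {
    a <- segments[i, ]; b <- segments[i + 1L, ]
    joinable <- a$block == b$block && a$copy == b$copy &&
      a$strand == b$strand && i != centromere &&
      ((a$strand == "+" && abs(a$end - b$start) < 1e-9) ||
       (a$strand == "-" && abs(a$start - b$end) < 1e-9))
    if (joinable) {
      segments$start[i] <- min(a$start, b$start)
      segments$end[i] <- max(a$end, b$end)
      segments <- segments[-(i + 1L), , drop = FALSE]
      if (centromere > i) centromere <- centromere - 1L
    } else i <- i + 1L
  }
  rownames(segments) <- NULL
  list(segments = segments, centromere = centromere)
}

newChromosome <- function(name, segments, centromere, history = character(0)) {
  cs <- coalesceSegments(segments, as.integer(centromere))
  new("Chromosome", name = name, segments = cs$segments,
      centromere = cs$centromere, history = history)
}

segRow <- function(block, start = 0, end = 1, strand = "+", copy = 1L) {
  data.frame(block = block, start = start, end = end, strand = strand,
             copy = as.integer(copy), stringsAsFactors = FALSE)
}

#' Build the Ancestral Crucifer Karyotype (ACK)
#'
#' Constructs the n = 8 gametic complement AK1-AK8 carrying the 22 genomic
#' blocks, one copy each, from a packaged arm/block table (user-overridable).
#' Arm assignments follow the ACK reference layout: AK1 = A,B | C; AK2 = D | E;
#' AK3 = F | G,H; AK4 = I | J; AK5 = (K-L) | (M-N); AK6 = O,P | Q,R;
#' AK7 = S,T | U; AK8 = V | W,X, with the centromere between the two arms.
#'
#' @param file Path to a tab-separated table with columns \code{chromosome},
#'   \code{arm} (\code{upper}/\code{lower}) and \code{blocks} (comma-separated
#'   block labels in reading order). Defaults to the packaged table.
#' @return A \code{\linkS4class{Karyotype}} with 8 chromosomes.
#' @export
#' @examples
#' ack <- buildACK()
#' complementSize(ack)   # 8
#' diploidNumber(ack)    # 16
buildACK <- function(file = system.file("extdata", "ack_karyotype.tsv",
                                        package = "karyoploid")) {
  tab <- tryCatch(read.delim(file, stringsAsFactors = FALSE),
                  error = function(e) stop("configuration error: cannot read ACK table: ",
                                           conditionMessage(e)))
  need <- c("chromosome", "arm", "blocks")
  if (!all(need %in% names(tab)))
    stop("configuration error: ACK table must have columns chromosome, arm, blocks")
  chroms <- list()
  for (nm in unique(tab$chromosome)) {
    sub <- tab[tab$chromosome == nm, , drop = FALSE]
    up <- sub$blocks[sub$arm == "upper"]
    lo <- sub$blocks[sub$arm == "lower"]
    if (length(up) != 1L || length(lo) != 1L)
      stop(sprintf("configuration error: chromosome %s needs one upper and one lower arm", nm))
    upb <- trimws(strsplit(up, ",")[[1]])
    lob <- trimws(strsplit(lo, ",")[[1]])
    segs <- do.call(rbind, lapply(c(upb, lob), segRow))
    chroms[[nm]] <- newChromosome(nm, segs, centromere = length(upb))
  }
  blocks <- unlist(lapply(chroms, function(ch) ch@segments$block))
  if (length(blocks) != 22L || anyDuplicated(blocks) ||
      !setequal(blocks, genomicBlocks()))
    stop("configuration error: ACK table must place each of the 22 genomic blocks exactly once")
  new("Karyotype", chromosomes = unname(chroms), name = "ACK")
}

## ---- fragments: intermediate pieces produced by cutting a chromosome ----
## A fragment is list(segs = data.frame, hasCen = logical, cen = integer) where
## cen is the number of fragment segments preceding the centromere (0..nrow,
## transient values at fragment edges are allowed until fragments are joined).

reverseSegments <- function(segs) {
  if (nrow(segs) == 0L) return(segs)
  out <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  out$strand <- ifelse(out$strand == "+", "-", "+")
  rownames(out) <- NULL
  out
}

reverseFragment <- function(fr) {
  list(segs = reverseSegments(fr$segs), hasCen = fr$hasCen,
       cen = if (fr$hasCen) nrow(fr$segs) - fr$cen else NA_integer_)
}

reverseChromosome <- function(ch) {
  newChromosome(ch@name, reverseSegments(ch@segments),
                nrow(ch@segments) - ch@centromere, ch@history)
}

## Split one segment row at 'fraction' of its span along the reading direction.
splitSegmentRow <- function(row, fraction) {
  w <- row$end - row$start
  if (row$strand == "+") {
    cut <- row$start + fraction * w
    first <- row; first$end <- cut
    second <- row; second$start <- cut
  } else {
    cut <- row$end - fraction * w
    first <- row; first$start <- cut
    second <- row; second$end <- cut
  }
  rbind(first, second)
}

## Resolve a list of breakpoints on one chromosome into refined segments plus
## gap indices (number of refined segments before each cut) and the refined
## centromere gap. Fraction cuts are materialised; boundary cuts are mapped.
resolveCuts <- function(ch, bps) {
  segs <- ch@segments
  n <- nrow(segs)
  fracIdx <- vapply(bps, function(b) if (is.null(b$segment)) NA_integer_ else b$segment,
                    integer(1))
  for (i in seq_along(bps)) {
    b <- bps[[i]]
    if (!is.null(b$after)) {
      if (b$after < 0L || b$after > n)
        stop(sprintf("breakpoint boundary %d out of range on %s", b$after, ch@name))
    } else {
      if (b$segment < 1L || b$segment > n)
        stop(sprintf("breakpoint segment %d out of range on %s", b$segment, ch@name))
    }
  }
  fr <- fracIdx[!is.na(fracIdx)]
  if (anyDuplicated(fr))
    stop("two within-segment breakpoints in the same segment are not supported in one event")
  ord <- order(fracIdx, na.last = NA)  # indices of bps with fraction cuts
  refined <- segs
  # apply fraction splits from the highest segment index down so earlier
  # indices stay valid
  for (i in rev(ord)) {
    b <- bps[[i]]
    refined <- rbind(
      if (b$segment > 1L) refined[seq_len(b$segment - 1L), , drop = FALSE] else NULL,
      splitSegmentRow(refined[b$segment, , drop = FALSE], b$fraction),
      if (b$segment < nrow(refined)) refined[seq(b$segment + 1L, nrow(refined)), , drop = FALSE] else NULL)
  }
  rownames(refined) <- NULL
  shift <- function(origBoundary) {
    # refined index of an original boundary = original + #fraction cuts at or
    # before that boundary
    origBoundary + sum(fr <= origBoundary)
  }
  gaps <- integer(length(bps))
  cenSide <- logical(length(bps))
  for (i in seq_along(bps)) {
    b <- bps[[i]]
    if (!is.null(b$after)) {
      gaps[i] <- shift(b$after)
    } else {
      gaps[i] <- b$segment + sum(fr < b$segment)
    }
    cenSide[i] <- b$cenToHead
  }
  list(segs = refined, gaps = gaps, cen = shift(ch@centromere), cenToHead = cenSide)
}

## Split a chromosome at one breakpoint into head and tail fragments.
splitChromosome <- function(ch, bp) {
  rc <- resolveCuts(ch, list(bp))
  g <- rc$gaps[1]
  cen <- rc$cen
  cenHead <- if (g == cen) rc$cenToHead[1] else g > cen
  n <- nrow(rc$segs)
  headSegs <- if (g >= 1L) rc$segs[seq_len(g), , drop = FALSE] else rc$segs[0, , drop = FALSE]
  tailSegs <- if (g < n) rc$segs[seq(g + 1L, n), , drop = FALSE] else rc$segs[0, , drop = FALSE]
  rownames(headSegs) <- rownames(tailSegs) <- NULL
  list(head = list(segs = headSegs, hasCen = cenHead,
                   cen = if (cenHead) cen else NA_integer_),
       tail = list(segs = tailSegs, hasCen = !cenHead,
                   cen = if (!cenHead) cen - g else NA_integer_))
}

joinFragments <- function(fr1, fr2, name, history = character(0)) {
  if (fr1$hasCen && fr2$hasCen)
    stop(sprintf("dicentric product '%s'", name))
  if (!fr1$hasCen && !fr2$hasCen)
    stop(sprintf("acentric product '%s'", name))
  segs <- rbind(fr1$segs, fr2$segs)
  rownames(segs) <- NULL
  cen <- if (fr1$hasCen) fr1$cen else nrow(fr1$segs) + fr2$cen
  newChromosome(name, segs, cen, history)
}

replaceChromosomes <- function(k, idx, newChroms, drop = integer(0)) {
  ch <- k@chromosomes
  for (i in seq_along(idx)) ch[[idx[i]]] <- newChroms[[i]]
  if (length(drop)) ch <- ch[-drop]
  new("Karyotype", chromosomes = ch, name = k@name)
}

## ---- operators ----

#' Whole-genome duplication
#'
#' Duplicates every chromosome of a monoploid-copy complement; duplicate
#' chromosomes get copy index 2 and name suffix "b" (originals are suffixed
#' "a"). The gametic complement size doubles, so the reported diploid number
#' quadruples relative to the input's n.
#'
#' @param k A \code{\linkS4class{Karyotype}} in which every segment has
#'   copy = 1.
#' @return The duplicated \code{\linkS4class{Karyotype}}.
#' @export
#' @examples
#' k <- applyWGD(buildACK())
#' complementSize(k)  # 16
#' diploidNumber(k)   # 32
applyWGD <- function(k) {
  copies <- unlist(lapply(k@chromosomes, function(ch) ch@segments$copy))
  if (any(copies != 1L))
    stop("input karyotype is already polyploid (segments with copy = 2 present)")
  a <- lapply(k@chromosomes, function(ch) {
    newChromosome(paste0(ch@name, "a"), ch@segments, ch@centromere, ch@history)
  })
  b <- lapply(k@chromosomes, function(ch) {
    segs <- ch@segments
    segs$copy <- 2L
    newChromosome(paste0(ch@name, "b"), segs, ch@centromere, ch@history)
  })
  new("Karyotype", chromosomes = c(a, b), name = k@name)
}

#' End-to-end translocation (EET)
#'
#' Joins two whole chromosomes at the named termini. The first chromosome is
#' oriented so that \code{endA} becomes its tail and the second so that
#' \code{endB} becomes its head; the named ends then abut. The resulting
#' dicentric is resolved by eliminating the centromere of the chromosome not
#' named in \code{keep} (recorded in the fusion chromosome's history). The
#' complement size decreases by one; block content is conserved.
#'
#' @param k A \code{\linkS4class{Karyotype}}.
#' @param chrA,chrB Names of the two chromosomes to fuse (distinct).
#' @param endA,endB \code{"head"} or \code{"tail"}.
#' @param keep Name of the chromosome whose centromere survives (one of
#'   \code{chrA}, \code{chrB}).
#' @param name Name for the fusion chromosome; default
#'   \code{paste0(chrA, "+", chrB)}.
#' @return The karyotype after fusion.
#' @export
applyEET <- function(k, chrA, endA = c("head", "tail"), chrB,
                     endB = c("head", "tail"), keep,
                     name = paste0(chrA, "+", chrB)) {
  endA <- match.arg(endA); endB <- match.arg(endB)
  if (identical(chrA, chrB)) stop("EET requires two distinct chromosomes")
  if (!(keep %in% c(chrA, chrB)))
    stop(sprintf("'keep' must be one of the fused chromosomes ('%s', '%s'), got '%s'",
                 chrA, chrB, keep))
  iA <- match(chrA, chromosomeNames(k)); iB <- match(chrB, chromosomeNames(k))
  if (is.na(iA) || is.na(iB)) stop("EET operands not found in karyotype")
  A <- k@chromosomes[[iA]]; B <- k@chromosomes[[iB]]
  Ao <- if (endA == "head") reverseChromosome(A) else A
  Bo <- if (endB == "tail") reverseChromosome(B) else B
  nA <- nrow(Ao@segments)
  segs <- rbind(Ao@segments, Bo@segments)
  rownames(segs) <- NULL
  cenA <- Ao@centromere
  cenB <- nA + Bo@centromere
  lost <- if (keep == chrA) chrB else chrA
  cen <- if (keep == chrA) cenA else cenB
  hist <- c(A@history, B@history,
            sprintf("centromere of %s eliminated/inactivated", lost))
  fusion <- newChromosome(name, segs, cen, hist)
  replaceChromosomes(k, min(iA, iB), list(fusion), drop = max(iA, iB))
}

## orient an acentric fragment so that its cut end faces the given direction
## ("tail" = cut end last, "head" = cut end first); 'side' says whether the
## fragment came from the head or tail side of its source chromosome.
orientFragment <- function(fr, side = c("head", "tail"),
                           cutEnd = c("tail", "head")) {
  side <- match.arg(side); cutEnd <- match.arg(cutEnd)
  # a head-side fragment has its cut end at its tail; a tail-side fragment has
  # its cut end at its head
  natural <- if (side == "head") "tail" else "head"
  if (natural == cutEnd) fr else reverseFragment(fr)
}

#' Reciprocal translocation
#'
#' Cuts two distinct chromosomes at the given breakpoints and exchanges the
#' fragments distal to the centromeres (the acentric fragments), the unique
#' eucentric rejoining for a breakpoint pair. Within-block breakpoints split
#' blocks; derived sub-block labels (a, b, c) follow ancestral coordinate
#' order (see \code{\link{formatKaryotype}}). Block content is conserved and
#' swapping \code{bp1}/\code{bp2} yields the identical karyotype.
#'
#' @param k A \code{\linkS4class{Karyotype}}.
#' @param bp1,bp2 \code{\link{breakpoint}}s on two distinct chromosomes.
#' @param names Optional length-2 character: names for the products carrying
#'   the centromeres of \code{bp1$chrom} and \code{bp2$chrom} respectively.
#' @return The karyotype after the exchange.
#' @export
applyReciprocalTranslocation <- function(k, bp1, bp2, names = NULL) {
  if (identical(bp1$chrom, bp2$chrom))
    stop("reciprocal translocation requires breakpoints on two distinct chromosomes")
  i1 <- match(bp1$chrom, chromosomeNames(k)); i2 <- match(bp2$chrom, chromosomeNames(k))
  if (is.na(i1) || is.na(i2)) stop("translocation operands not found in karyotype")
  c1 <- k@chromosomes[[i1]]; c2 <- k@chromosomes[[i2]]
  s1 <- splitChromosome(c1, bp1); s2 <- splitChromosome(c2, bp2)
  pick <- function(s) {
    if (s$head$hasCen) list(centric = s$head, centricSide = "head",
                            acentric = s$tail, acentricSide = "tail")
    else list(centric = s$tail, centricSide = "tail",
              acentric = s$head, acentricSide = "head")
  }
  p1 <- pick(s1); p2 <- pick(s2)
  nm <- if (!is.null(names)) names else c(c1@name, c2@name)
  buildProduct <- function(centric, centricSide, acc, accSide, name, history) {
    if (nrow(acc$segs) == 0L) {
      # empty exchanged fragment: chromosome unchanged
      return(joinFragments(centric,
                           list(segs = acc$segs, hasCen = FALSE, cen = NA_integer_),
                           name, history))
    }
    if (centricSide == "head") {
      # open cut end at centric tail: acentric fragment goes after it,
      # cut end first
      joinFragments(centric, orientFragment(acc, accSide, "head"), name, history)
    } else {
      joinFragments(orientFragment(acc, accSide, "tail"), centric, name, history)
    }
  }
  new1 <- buildProduct(p1$centric, p1$centricSide, p2$acentric, p2$acentricSide,
                       nm[1], c1@history)
  new2 <- buildProduct(p2$centric, p2$centricSide, p1$acentric, p1$acentricSide,
                       nm[2], c2@history)
  replaceChromosomes(k, c(i1, i2), list(new1, new2))
}

#' Unequal (reciprocal) translocation
#'
#' A reciprocal exchange in which the second breakpoint lies at a
#' (sub)telomeric terminus of the target chromosome, so the target's exchanged
#' fragment is empty and the donor's acentric fragment is donated whole. The
#' donated fragment's broken end abuts the named target end.
#'
#' @param k A \code{\linkS4class{Karyotype}}.
#' @param bp Interstitial \code{\link{breakpoint}} on the donor chromosome.
#' @param target Name of the receiving chromosome.
#' @param targetEnd \code{"head"} or \code{"tail"}: the target terminus that
#'   receives the fragment.
#' @param names Optional length-2 character: names for the trimmed donor and
#'   the augmented target.
#' @return The karyotype after the donation.
#' @export
applyUnequalTranslocation <- function(k, bp, target,
                                      targetEnd = c("head", "tail"),
                                      names = NULL) {
  targetEnd <- match.arg(targetEnd)
  if (identical(bp$chrom, target))
    stop("unequal translocation requires two distinct chromosomes")
  iD <- match(bp$chrom, chromosomeNames(k)); iT <- match(target, chromosomeNames(k))
  if (is.na(iD) || is.na(iT)) stop("translocation operands not found in karyotype")
  donor <- k@chromosomes[[iD]]; targ <- k@chromosomes[[iT]]
  s <- splitChromosome(donor, bp)
  if (s$head$hasCen) {
    centric <- s$head; centricSide <- "head"; donated <- s$tail; donatedSide <- "tail"
  } else {
    centric <- s$tail; centricSide <- "tail"; donated <- s$head; donatedSide <- "head"
  }
  nm <- if (!is.null(names)) names else c(donor@name, targ@name)
  if (nrow(donated$segs) == 0L) {
    newDonor <- newChromosome(nm[1], centric$segs, centric$cen, donor@history)
    newTarg <- newChromosome(nm[2], targ@segments, targ@centromere, targ@history)
  } else {
    newDonor <- if (centricSide == "head")
      newChromosome(nm[1], centric$segs, centric$cen, donor@history)
    else newChromosome(nm[1], centric$segs, centric$cen, donor@history)
    tFrag <- list(segs = targ@segments, hasCen = TRUE, cen = targ@centromere)
    newTarg <- if (targetEnd == "head")
      joinFragments(orientFragment(donated, donatedSide, "tail"), tFrag,
                    nm[2], targ@history)
    else
      joinFragments(tFrag, orientFragment(donated, donatedSide, "head"),
                    nm[2], targ@history)
  }
  replaceChromosomes(k, c(iD, iT), list(newDonor, newTarg))
}

#' Pericentric inversion
#'
#' Reverses the interval between two breakpoints that flank the centromere
#' (the centromere is carried inside the inverted interval with orientations
#' flipped). Within-block cuts relabel sub-blocks in ancestral coordinate
#' order. Applying the same inversion twice restores the original chromosome
#' up to canonical form.
#'
#' @param k A \code{\linkS4class{Karyotype}}.
#' @param bpL,bpR \code{\link{breakpoint}}s on one chromosome, on opposite
#'   sides of the centromere.
#' @param name Optional new name for the inverted chromosome.
#' @return The karyotype after inversion.
#' @export
applyPericentricInversion <- function(k, bpL, bpR, name = NULL) {
  if (!identical(bpL$chrom, bpR$chrom))
    stop("pericentric inversion requires both breakpoints on one chromosome")
  i <- match(bpL$chrom, chromosomeNames(k))
  if (is.na(i)) stop("inversion operand not found in karyotype")
  ch <- k@chromosomes[[i]]
  rc <- resolveCuts(ch, list(bpL, bpR))
  g <- sort(rc$gaps)
  cen <- rc$cen
  if (!(g[1] < cen && cen < g[2]))
    stop(sprintf("not pericentric: breakpoints on %s do not flank the centromere",
                 ch@name))
  n <- nrow(rc$segs)
  headSegs <- if (g[1] >= 1L) rc$segs[seq_len(g[1]), , drop = FALSE] else rc$segs[0, ]
  midSegs <- rc$segs[seq(g[1] + 1L, g[2]), , drop = FALSE]
  tailSegs <- if (g[2] < n) rc$segs[seq(g[2] + 1L, n), , drop = FALSE] else rc$segs[0, ]
  segs <- rbind(headSegs, reverseSegments(midSegs), tailSegs)
  rownames(segs) <- NULL
  newCen <- g[1] + (g[2] - cen)
  out <- newChromosome(if (is.null(name)) ch@name else name, segs, newCen,
                       ch@history)
  replaceChromosomes(k, i, list(out))
}

## ---- canonical forms, labels, equality ----

fmtFrac <- function(x) formatC(x, digits = 6, format = "fg")

exactTokens <- function(ch, copyAware = TRUE) {
  seg <- ch@segments
  tok <- sprintf("%s:%s-%s:%s%s", seg$block, fmtFrac(seg$start),
                 fmtFrac(seg$end), seg$strand,
                 if (copyAware) paste0("@", seg$copy) else "")
  append(tok, "CEN", after = ch@centromere)
}

flipTokens <- function(tok) {
  out <- rev(tok)
  plus <- grepl("\\+", out, fixed = FALSE)
  # swap strand signs; CEN is untouched
  chartrFlip <- function(x) {
    x2 <- gsub(":\\+", ":@PLUS@", x)
    x2 <- gsub(":-", ":+", x2)
    gsub(":@PLUS@", ":-", x2)
  }
  ifelse(out == "CEN", out, chartrFlip(out))
}

#' Canonical token form of a chromosome
#'
#' Returns the lexicographically smaller of the forward reading and the
#' reversed reading with flipped orientations (centromere position mirrored
#' consistently), so that a chromosome and its full reversal map to the same
#' canonical string.
#'
#' @param ch A \code{\linkS4class{Chromosome}}.
#' @param copyAware Logical; include the homeolog copy index in tokens.
#' @return A single character string.
#' @export
canonicalForm <- function(ch, copyAware = TRUE) {
  fwd <- exactTokens(ch, copyAware)
  rev_ <- flipTokens(fwd)
  f <- paste(fwd, collapse = " ")
  r <- paste(rev_, collapse = " ")
  if (f <= r) f else r
}

chromosomeString <- function(ch) paste(exactTokens(ch), collapse = " ")

#' Sub-block label table for a karyotype
#'
#' Derived display labels (e.g. Fa, Fb, Fc) are a function of the set of cut
#' points observed in each (block, homeolog copy) across the whole karyotype,
#' lettered in ancestral coordinate order, independently per copy. An uncut
#' block copy keeps its plain block label.
#'
#' @param k A \code{\linkS4class{Karyotype}}.
#' @return data.frame with columns block, copy, start, end, label.
#' @export
blockLabelTable <- function(k) {
  segs <- do.call(rbind, lapply(k@chromosomes, function(ch) ch@segments))
  out <- list()
  for (key in unique(paste(segs$block, segs$copy))) {
    parts <- strsplit(key, " ")[[1]]
    b <- parts[1]; cp <- as.integer(parts[2])
    sub <- segs[segs$block == b & segs$copy == cp, , drop = FALSE]
    cuts <- sort(unique(c(sub$start, sub$end)))
    ints <- data.frame(block = b, copy = cp,
                       start = cuts[-length(cuts)], end = cuts[-1],
                       stringsAsFactors = FALSE)
    disp <- if (grepl("-", b)) paste0("(", b, ")") else b
    ints$label <- if (nrow(ints) == 1L) disp
                  else paste0(disp, letters[seq_len(nrow(ints))])
    out[[key]] <- ints
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

labelTokens <- function(ch, labtab, copyAware = FALSE) {
  seg <- ch@segments
  lab <- character(nrow(seg))
  for (i in seq_len(nrow(seg))) {
    hit <- labtab$block == seg$block[i] & labtab$copy == seg$copy[i] &
      abs(labtab$start - seg$start[i]) < 1e-9
    if (!any(hit))
      stop(sprintf("segment %s[%s,%s] copy %d has no label interval",
                   seg$block[i], fmtFrac(seg$start[i]), fmtFrac(seg$end[i]),
                   seg$copy[i]))
    lab[i] <- labtab$label[which(hit)[1]]
  }
  tok <- paste0(lab, seg$strand, if (copyAware) paste0("@", seg$copy) else "")
  append(tok, "CEN", after = ch@centromere)
}

flipLabelTokens <- function(tok) {
  out <- rev(tok)
  sw <- function(x) {
    x2 <- sub("\\+(@[12])?$", "@PLUS@\\1", x)
    x2 <- sub("-(@[12])?$", "+\\1", x2)
    sub("@PLUS@", "-", x2)
  }
  ifelse(out == "CEN", out, vapply(out, sw, character(1), USE.NAMES = FALSE))
}

canonicalLabelString <- function(ch, labtab, copyAware = FALSE) {
  fwd <- labelTokens(ch, labtab, copyAware)
  f <- paste(fwd, collapse = " ")
  r <- paste(flipLabelTokens(fwd), collapse = " ")
  if (f <= r) f else r
}

#' Human-readable block composition of every chromosome
#'
#' Renders each chromosome as its derived sub-block labels with orientations
#' and the centromere position, e.g.
#' \code{"Fa+ T- S- (K-L)+ CEN (M-N)+"} for Cp15.
#'
#' @param k A \code{\linkS4class{Karyotype}}.
#' @param copyAware Logical; append \code{@1}/\code{@2} homeolog suffixes.
#' @return Named character vector (names = chromosome names).
#' @export
formatKaryotype <- function(k, copyAware = FALSE) {
  labtab <- blockLabelTable(k)
  out <- vapply(k@chromosomes,
                function(ch) paste(labelTokens(ch, labtab, copyAware),
                                   collapse = " "),
                character(1))
  names(out) <- chromosomeNames(k)
  out
}

#' Canonical multiset of chromosome strings
#'
#' @param k A \code{\linkS4class{Karyotype}}.
#' @param mode \code{"labels"} (copy-blind, sub-block labels; the comparison
#'   used against painted karyotypes, which cannot phase homeolog copies) or
#'   \code{"exact"} (copy-aware with sub-block fractions).
#' @return Sorted character vector, one canonical string per chromosome.
#' @export
canonicalStrings <- function(k, mode = c("labels", "exact")) {
  mode <- match.arg(mode)
  if (mode == "exact") {
    sort(vapply(k@chromosomes, canonicalForm, character(1)))
  } else {
    labtab <- blockLabelTable(k)
    sort(vapply(k@chromosomes,
                function(ch) canonicalLabelString(ch, labtab), character(1)))
  }
}

#' Karyotype equality
#'
#' Two karyotypes are equal when their multisets of canonical chromosome
#' strings coincide; equality is invariant under reversing any chromosome's
#' stored reading. The default \code{"labels"} mode is copy-blind and compares
#' block-label structure (breakpoint fractions never affect it); \code{"exact"}
#' additionally compares sub-block fractions and homeolog copies.
#'
#' @param k1,k2 \code{\linkS4class{Karyotype}} objects.
#' @param mode \code{"labels"} or \code{"exact"}.
#' @return Logical.
#' @export
karyotypeEqual <- function(k1, k2, mode = c("labels", "exact")) {
  mode <- match.arg(mode)
  identical(canonicalStrings(k1, mode), canonicalStrings(k2, mode))
}

#' Merged ancestral-block coverage of a karyotype
#'
#' Collapses all segments into maximal merged intervals per (block, copy);
#' the multiset of covered intervals is invariant under every operator except
#' WGD, which exactly doubles it.
#'
#' @param k A \code{\linkS4class{Karyotype}}.
#' @return data.frame (block, copy, start, end), sorted.
#' @export
blockCoverage <- function(k) {
  segs <- do.call(rbind, lapply(k@chromosomes, function(ch) ch@segments))
  out <- list()
  for (key in unique(paste(segs$block, segs$copy, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1]]
    b <- parts[1]; cp <- as.integer(parts[2])
    sub <- segs[segs$block == b & segs$copy == cp, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    st <- sub$start[1]; en <- sub$end[1]
    merged <- NULL
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] <= en + 1e-9) en <- max(en, sub$end[i])
      else { merged <- rbind(merged, data.frame(start = st, end = en)); st <- sub$start[i]; en <- sub$end[i] }
    }
    merged <- rbind(merged, data.frame(start = st, end = en))
    out[[key]] <- data.frame(block = b, copy = cp, merged,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$block, res$copy, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## ---- scenario replay ----

rearrangementEvent <- function(kind, params = list(), annotation = character(0)) {
  new("RearrangementEvent", kind = kind, params = params,
      annotation = as.character(annotation))
}

#' Apply one rearrangement event
#'
#' @param k A \code{\linkS4class{Karyotype}}.
#' @param e A \code{\linkS4class{RearrangementEvent}}.
#' @return The karyotype after the event.
#' @export
applyEvent <- function(k, e) {
  p <- e@params
  switch(e@kind,
    WGD = applyWGD(k),
    EET = applyEET(k, p$chrA, p$endA, p$chrB, p$endB, p$keep,
                   name = if (is.null(p$name)) paste0(p$chrA, "+", p$chrB) else p$name),
    RECIP_TRANSLOC = applyReciprocalTranslocation(k, p$bp1, p$bp2, names = p$names),
    UNEQ_TRANSLOC = applyUnequalTranslocation(k, p$bp, p$target, p$targetEnd,
                                              names = p$names),
    PERI_INV = applyPericentricInversion(k, p$bpL, p$bpR, name = p$name),
    stop(sprintf("unknown event kind '%s'", e@kind)))
}

#' Replay a rearrangement scenario
#'
#' Applies the events of a \code{\linkS4class{Scenario}} in order to a start
#' karyotype. Replay is deterministic: two replays of the same scenario yield
#' identical serialized karyotypes. Operator errors are propagated with the
#' failing step index.
#'
#' @param scenario A \code{\linkS4class{Scenario}}.
#' @param start The start \code{\linkS4class{Karyotype}}; defaults to
#'   \code{\link{buildACK}()}.
#' @param snapshots Logical; also return the karyotype after every step.
#' @return If \code{snapshots} is \code{FALSE}, the final karyotype; otherwise
#'   \code{list(final = ..., snapshots = list of per-step karyotypes)}.
#' @export
#' @examples
#' res <- replayScenario(catolobusScenario(), snapshots = TRUE)
#' complementSize(res$final)                   # 15
#' vapply(res$snapshots, complementSize, 1L)   # 16, 15, 15, ...
replayScenario <- function(scenario, start = buildACK(), snapshots = FALSE) {
  k <- start
  snaps <- vector("list", length(scenario@events))
  for (i in seq_along(scenario@events)) {
    k <- tryCatch(applyEvent(k, scenario@events[[i]]),
                  error = function(err)
                    stop(sprintf("scenario step %d (%s): %s", i,
                                 scenario@events[[i]]@kind,
                                 conditionMessage(err)), call. = FALSE))
    snaps[[i]] <- k
  }
  if (snapshots) list(final = k, snapshots = snaps) else k
}

#' The packaged ACK-to-Catolobus rearrangement scenario
#'
#' The six-event scenario that turns the ACK gametic complement into the 15
#' *Catolobus pendulus* chromosomes Cp1-Cp15: a whole-genome duplication
#' (2n = 32); an end-to-end translocation between the AK5 and AK7 homeolog-b
#' copies keeping the AK5 centromere (descending dysploidy to n = 15,
#' 2n = 30); a reciprocal translocation between the fusion chromosome and
#' AK3b producing Cp15 [Fa+T+S+(K-L)+(M-N)] and the U+Fb+G+H product; a
#' pericentric inversion of U+Fb+G+H shaping Cp14 (U+Fb+Ha+G+Fc+Hb); a
#' pericentric inversion of AK1a shaping Cp11 (Aa+Ca+B+Ab+Cb); and an unequal
#' translocation from AK1b to the AK6b upper-arm subtelomere producing Cp12
#' (Ab+B+C) and Cp13 (Aa+O+P+Q+R). Reported Mb sizes and gene-interval
#' breakpoint positions are carried as free-text annotations only.
#'
#' @return A \code{\linkS4class{Scenario}} starting from \code{"ACK"}.
#' @export
#' @examples
#' sc <- catolobusScenario()
#' table(vapply(events(sc), function(e) e@kind, character(1)))
catolobusScenario <- function() {
  ev <- list(
    rearrangementEvent("WGD", annotation = "tetraploid origin, 2n = 4x = 32"),
    rearrangementEvent("EET",
      params = list(chrA = "AK7b", endA = "head", chrB = "AK5b", endB = "head",
                    keep = "AK5b", name = "AK5b+AK7b"),
      annotation = "fusion U+T+S+(K-L)+(M-N); AK7 centromere eliminated/inactivated; n = 16 -> 15"),
    rearrangementEvent("RECIP_TRANSLOC",
      params = list(bp1 = breakpoint("AK3b", segment = 1, fraction = 0.5),
                    bp2 = breakpoint("AK5b+AK7b", after = 1),
                    names = c("preCp14", "Cp15")),
      annotation = "products Cp15 [Fa+T+S+(K-L)+(M-N)] and U+Fb+G+H"),
    rearrangementEvent("PERI_INV",
      params = list(bpL = breakpoint("preCp14", segment = 2, fraction = 0.5),
                    bpR = breakpoint("preCp14", segment = 4, fraction = 0.5),
                    name = "Cp14"),
      annotation = "8.21-Mb pericentric inversion; breakpoints within Fb [AT3G60970 (MRP15) - AT3G14220 (MLE3)] and H [AT2G18900 (F19F24) - AT2G19000 (T20K24)]"),
    rearrangementEvent("PERI_INV",
      params = list(bpL = breakpoint("AK1a", segment = 1, fraction = 0.5),
                    bpR = breakpoint("AK1a", segment = 3, fraction = 0.5),
                    name = "Cp11"),
      annotation = "15.2-Mb pericentric inversion; breakpoints within A [AT1G12180 (T28K15) - AT1G12660 (T12C24)] and C [AT1G52240 (F9I5) - AT1G52450 (F6D8)]"),
    rearrangementEvent("UNEQ_TRANSLOC",
      params = list(bp = breakpoint("AK1b", segment = 1, fraction = 0.5),
                    target = "AK6b", targetEnd = "head",
                    names = c("Cp12", "Cp13")),
      annotation = "breakpoints within A [AT1G13500 (F13B4) - AT1G14220 (F7A19)] and the AK6 upper-arm subtelomere")
  )
  new("Scenario", events = ev, start = "ACK")
}

#' Optional population-20 private inversion
#'
#' The single additional 3.54-Mb pericentric inversion of chromosome Cp13
#' observed in one population, shipped as a one-event scenario to be replayed
#' on top of the canonical karyotype; it is not part of
#' \code{\link{catolobusScenario}}.
#'
#' @return A one-event \code{\linkS4class{Scenario}} starting from
#'   \code{"Catolobus"}.
#' @export
population20Inversion <- function() {
  ev <- list(rearrangementEvent("PERI_INV",
    params = list(bpL = breakpoint("Cp13", segment = 2, fraction = 0.5),
                  bpR = breakpoint("Cp13", segment = 4, fraction = 0.5),
                  name = "Cp13inv"),
    annotation = "3.54-Mb pericentric inversion private to population 20"))
  new("Scenario", events = ev, start = "Catolobus")
}

#' Summarize a karyotype against a reference complement
#'
#' Reports the complement size and diploid number, the per-block homeolog copy
#' numbers, the total number of (block, copy) placements, and -- when a
#' reference karyotype is given -- the number of reference chromosomes whose
#' copy-blind canonical form is absent from the karyotype (multiset
#' difference), i.e. the count of structurally affected reference chromosomes.
#'
#' @param k A \code{\linkS4class{Karyotype}}.
#' @param reference Optional reference \code{\linkS4class{Karyotype}} (e.g.
#'   the post-WGD ACK complement).
#' @return A list of class \code{"karyotypeSummary"} with elements \code{n},
#'   \code{diploidNumber}, \code{blockCopyNumber} (named integer vector),
#'   \code{placements}, \code{blocksAtCopyTwo} and (with a reference)
#'   \code{affected}.
#' @export
#' @examples
#' post <- applyWGD(buildACK())
#' cp <- replayScenario(catolobusScenario())
#' s <- summarizeKaryotype(cp, post)
#' s$affected      # 6 of the 16 ancestral chromosomes
#' s$placements    # 44 block-copy placements
summarizeKaryotype <- function(k, reference = NULL) {
  segs <- do.call(rbind, lapply(k@chromosomes, function(ch) ch@segments))
  pairs <- unique(segs[, c("block", "copy")])
  copyNumber <- vapply(genomicBlocks(),
                       function(b) sum(pairs$block == b), integer(1))
  out <- list(n = complementSize(k), diploidNumber = diploidNumber(k),
              blockCopyNumber = copyNumber,
              placements = nrow(pairs),
              blocksAtCopyTwo = sum(copyNumber == 2L))
  if (!is.null(reference)) {
    cur <- canonicalStrings(k, mode = "labels")
    ref <- canonicalStrings(reference, mode = "labels")
    # multiset difference: reference chromosomes not matched in k
    unmatched <- 0L
    curPool <- cur
    for (s in ref) {
      i <- match(s, curPool)
      if (is.na(i)) unmatched <- unmatched + 1L else curPool <- curPool[-i]
    }
    out$affected <- unmatched
  }
  class(out) <- "karyotypeSummary"
  out
}

#' @export
print.karyotypeSummary <- function(x, ...) {
  cat(sprintf("Karyotype summary: n = %d, 2n = %d\n", x$n, x$diploidNumber))
  cat(sprintf("  block-copy placements: %d (blocks at copy 2: %d)\n",
              x$placements, x$blocksAtCopyTwo))
  if (!is.null(x$affected))
    cat(sprintf("  reference chromosomes structurally affected: %d\n", x$affected))
  invisible(x)
}
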