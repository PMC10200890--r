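## Bounded parsimony search for minimal rearrangement scenarios between two
## block karyotypes. The search runs on a reduced token representation: both
## karyotypes are refined by the target-implied cut set, after which every
## breakpoint is a token boundary. Moves are generated adjacency-guided (each
## event must create at least one block adjacency present in the target and
## currently missing) and pruned with the admissible lower bound
## ceil(missing adjacencies / 2); whole-genome duplication is never searched
## (ploidy change is observed, not inferred).

#' Target-implied breakpoint candidates
#'
#' Collects, per genomic block, the interior cut points (ancestral-coordinate
#' fractions) appearing in any segment of the karyotype. Together with segment
#' boundaries these are the only breakpoints the parsimony search uses: any
#' minimal scenario reaching the target can only cut blocks at positions
#' visible in the target.
#'
#' @param target A \code{\linkS4class{Karyotype}}.
#' @return Named list, block label -> sorted numeric vector of interior cut
#'   fractions (blocks without interior cuts are omitted).
#' @export
#' @examples
#' names(impliedBreakpoints(catolobusKaryotype()))  # "A" "C" "F" "H"
impliedBreakpoints <- function(target) {
  segs <- do.call(rbind, lapply(target@chromosomes, function(ch) ch@segments))
  out <- list()
  for (b in unique(segs$block)) {
    pts <- sort(unique(c(segs$start[segs$block == b], segs$end[segs$block == b])))
    pts <- pts[pts > 1e-12 & pts < 1 - 1e-12]
    if (length(pts)) out[[b]] <- pts
  }
  if (length(out)) out[order(names(out))] else out
}

## ---- token representation ----

flipTok <- function(x) {
  ifelse(x == "^", x,
         paste0(substr(x, 1, nchar(x) - 1L),
                ifelse(substr(x, nchar(x), nchar(x)) == "+", "-", "+")))
}

## tokenize one chromosome under a global per-block cut partition; returns
## list(t = tokens, cen = gap index, map = per-gap model breakpoint info)
tokenizeChromosome <- function(ch, cuts, withMap = FALSE) {
  segs <- ch@segments
  toks <- character(0)
  map <- list()  # map[[g]] for g = 1..(ntok-1): list(after=) or list(segment=, fraction=)
  cenGap <- NA_integer_
  for (s in seq_len(nrow(segs))) {
    b <- segs$block[s]
    part <- sort(unique(c(0, cuts[[b]], 1)))
    disp <- if (grepl("-", b)) paste0("(", b, ")") else b
    inner <- part[part > segs$start[s] + 1e-12 & part < segs$end[s] - 1e-12]
    bounds <- c(segs$start[s], inner, segs$end[s])
    m <- length(bounds) - 1L
    lab <- function(st) {
      i <- which(abs(part - st) < 1e-9)[1]
      if (length(part) == 2L) disp else paste0(disp, letters[i])
    }
    if (segs$strand[s] == "+") {
      pieceStarts <- bounds[-length(bounds)]
      for (t in seq_len(m)) {
        toks <- c(toks, paste0(lab(pieceStarts[t]), "+"))
        if (withMap && t < m) {
          co <- bounds[t + 1L]
          map[[length(toks)]] <- list(segment = s,
            fraction = (co - segs$start[s]) / (segs$end[s] - segs$start[s]))
        }
      }
    } else {
      pieceStarts <- rev(bounds[-length(bounds)])
      for (t in seq_len(m)) {
        toks <- c(toks, paste0(lab(pieceStarts[t]), "-"))
        if (withMap && t < m) {
          co <- pieceStarts[t]
          map[[length(toks)]] <- list(segment = s,
            fraction = (segs$end[s] - co) / (segs$end[s] - segs$start[s]))
        }
      }
    }
    if (withMap) map[[length(toks)]] <- list(after = s)
    if (s == ch@centromere) cenGap <- length(toks)
  }
  out <- list(t = toks, cen = cenGap)
  if (withMap) out$map <- map
  out
}

tokenizeKaryotype <- function(k, cuts) {
  lapply(k@chromosomes, tokenizeChromosome, cuts = cuts)
}

tokChromCanon <- function(tc) {
  fwd <- append(tc$t, "^", after = tc$cen)
  rev_ <- flipTok(rev(fwd))
  f <- paste(fwd, collapse = " ")
  r <- paste(rev_, collapse = " ")
  if (f <= r) f else r
}

tokStateKey <- function(state) {
  paste(sort(vapply(state, tokChromCanon, character(1))), collapse = " / ")
}

## adjacency units: consecutive token pairs; the pair flanking the centromere
## is a single bridging unit "u ^ v" (the centromere has no identity of its
## own, so a plain "u ^" pair would be uninformative)
canonAdj <- function(u, v, bridge = FALSE) {
  mid <- ifelse(bridge, " ^ ", " ")
  a <- paste0(u, mid, v)
  b <- paste0(flipTok(v), mid, flipTok(u))
  ifelse(a <= b, a, b)
}

tokAdjacencies <- function(tc) {
  n <- length(tc$t)
  if (n < 2L) return(character(0))
  canonAdj(tc$t[-n], tc$t[-1], bridge = seq_len(n - 1L) == tc$cen)
}

stateAdjacencies <- function(state) {
  unlist(lapply(state, tokAdjacencies), use.names = FALSE)
}

## multiset difference target - current (returns character vector with
## multiplicity)
missingAdjacencies <- function(targetAdj, currentAdj) {
  tt <- table(targetAdj)
  cc <- table(currentAdj)
  common <- intersect(names(tt), names(cc))
  tt[common] <- pmax(0L, tt[common] - cc[common])
  rep(names(tt), tt)
}

## ---- token-level operators (mirror the model operators exactly) ----

tokSplit <- function(tc, g, cenHead = FALSE) {
  n <- length(tc$t)
  ch <- if (g == tc$cen) cenHead else g > tc$cen
  list(head = list(t = tc$t[seq_len(g)], hasCen = ch,
                   cen = if (ch) tc$cen else NA_integer_),
       tail = list(t = if (g < n) tc$t[seq(g + 1L, n)] else character(0),
                   hasCen = !ch, cen = if (!ch) tc$cen - g else NA_integer_))
}

tokRevFrag <- function(fr) {
  list(t = flipTok(rev(fr$t)), hasCen = fr$hasCen,
       cen = if (fr$hasCen) length(fr$t) - fr$cen else NA_integer_)
}

tokJoin <- function(fr1, fr2) {
  list(t = c(fr1$t, fr2$t),
       cen = if (fr1$hasCen) fr1$cen else length(fr1$t) + fr2$cen)
}

## acentric-exchange reciprocal translocation (terminal gaps give the unequal
## translocation); returns list(a=, b=) products carrying the centromeres of
## the first and second operand respectively
tokRecip <- function(tcA, gA, tcB, gB, cenHeadA = FALSE, cenHeadB = FALSE) {
  sA <- tokSplit(tcA, gA, cenHeadA)
  sB <- tokSplit(tcB, gB, cenHeadB)
  pick <- function(s) if (s$head$hasCen) list(c = s$head, cs = "head", a = s$tail, as_ = "tail")
                      else list(c = s$tail, cs = "tail", a = s$head, as_ = "head")
  pA <- pick(sA); pB <- pick(sB)
  build <- function(cent, cs, acc, accSide) {
    if (!length(acc$t)) return(list(t = cent$t, cen = cent$cen))
    if (cs == "head") {
      fr2 <- if (accSide == "head") tokRevFrag(acc) else acc
      tokJoin(cent, fr2)
    } else {
      fr1 <- if (accSide == "tail") tokRevFrag(acc) else acc
      tokJoin(fr1, cent)
    }
  }
  list(a = build(pA$c, pA$cs, pB$a, pB$as_),
       b = build(pB$c, pB$cs, pA$a, pA$as_))
}

tokEET <- function(tcA, endA, tcB, endB, keep) {
  A <- if (endA == "head") list(t = flipTok(rev(tcA$t)), cen = length(tcA$t) - tcA$cen) else tcA
  B <- if (endB == "tail") list(t = flipTok(rev(tcB$t)), cen = length(tcB$t) - tcB$cen) else tcB
  cen <- if (keep == 1L) A$cen else length(A$t) + B$cen
  list(t = c(A$t, B$t), cen = cen)
}

tokInv <- function(tc, g1, g2) {
  n <- length(tc$t)
  mid <- flipTok(rev(tc$t[seq(g1 + 1L, g2)]))
  list(t = c(if (g1 >= 1L) tc$t[seq_len(g1)], mid,
             if (g2 < n) tc$t[seq(g2 + 1L, n)]),
       cen = g1 + (g2 - tc$cen))
}

## ---- candidate generation (adjacency-guided) ----

## junction adjacency created when the centric piece of (tcC, gC) receives the
## acentric piece of (tcX, gX); NULL when the acentric piece is empty
productJunction <- function(tcC, gC, cenHeadC, tcX, gX, cenHeadX) {
  nX <- length(tcX$t)
  centHeadC <- if (gC == tcC$cen) cenHeadC else gC > tcC$cen
  centHeadX <- if (gX == tcX$cen) cenHeadX else gX > tcX$cen
  accSide <- if (centHeadX) "tail" else "head"   # acentric = other side
  if (accSide == "tail" && gX == nX) return(NULL)
  if (accSide == "head" && gX == 0L) return(NULL)
  bridge <- gC == tcC$cen
  if (centHeadC) {
    u <- tcC$t[gC]
    v <- if (accSide == "tail") tcX$t[gX + 1L] else flipTok(tcX$t[gX])
    canonAdj(u, v, bridge)
  } else {
    v <- tcC$t[gC + 1L]
    u <- if (accSide == "head") tcX$t[gX] else flipTok(tcX$t[gX + 1L])
    canonAdj(u, v, bridge)
  }
}

## junction adjacencies a reciprocal/unequal translocation would create,
## without building the products; used (with invJunctions/eetJunctions) as
## the exhaustive-enumeration oracle the guided generator is tested against
recipJunctions <- function(tcA, gA, tcB, gB, cenHeadA, cenHeadB) {
  c(productJunction(tcA, gA, cenHeadA, tcB, gB, cenHeadB),
    productJunction(tcB, gB, cenHeadB, tcA, gA, cenHeadA))
}

invJunctions <- function(tc, g1, g2) {
  n <- length(tc$t)
  out <- character(0)
  if (g1 >= 1L) out <- c(out, canonAdj(tc$t[g1], flipTok(tc$t[g2])))
  if (g2 < n) out <- c(out, canonAdj(flipTok(tc$t[g1 + 1L]), tc$t[g2 + 1L]))
  out
}

eetJunctions <- function(tcA, endA, tcB, endB, keep) {
  left <- if (endA == "tail") tcA$t[length(tcA$t)] else flipTok(tcA$t[1])
  right <- if (endB == "head") tcB$t[1] else flipTok(tcB$t[length(tcB$t)])
  fusion <- canonAdj(left, right)
  # centromere elimination joins the tokens flanking the lost centromere
  lost <- if (keep == 1L) tcB else tcA
  elim <- canonAdj(lost$t[lost$cen], lost$t[lost$cen + 1L])
  c(fusion, elim)
}

## parse an adjacency unit back into (u, v, bridge)
parseAdj <- function(a) {
  if (grepl(" \\^ ", a)) {
    p <- strsplit(a, " \\^ ")[[1]]
    list(u = p[1], v = p[2], bridge = TRUE)
  } else {
    p <- strsplit(a, " ")[[1]]
    list(u = p[1], v = p[2], bridge = FALSE)
  }
}

## enumerate guided successor events of a token state: for every missing
## target adjacency, locate the token occurrences that could form it and emit
## only the events realising one of them (branching scales with token
## occurrences, not with all breakpoint pairs)
generateMoves <- function(state, missingSet, ops, needEET) {
  nC <- length(state)
  moves <- list()
  seenMv <- new.env(parent = emptyenv())
  doRecip <- "RECIP_TRANSLOC" %in% ops
  doUneq <- "UNEQ_TRANSLOC" %in% ops
  pushTrans <- function(iC, gC, caC, iX, gX, caX) {
    if (iC == iX) return(invisible(NULL))
    nc <- length(state[[iC]]$t)
    term <- gC == 0L || gC == nc   # gX is always interior by construction
    kind <- if (term) "UNEQ_TRANSLOC" else "RECIP_TRANSLOC"
    if ((term && !doUneq) || (!term && !doRecip)) return(invisible(NULL))
    if (iC < iX) key <- paste(iC, gC, caC, iX, gX, caX)
    else key <- paste(iX, gX, caX, iC, gC, caC)
    if (!is.null(seenMv[[key]])) return(invisible(NULL))
    seenMv[[key]] <- TRUE
    moves[[length(moves) + 1L]] <<- list(kind = kind, i = iC, gA = gC,
                                         cenHeadA = caC, j = iX, gB = gX,
                                         cenHeadB = caX)
  }
  pushInv <- function(i, g1, g2) {
    key <- paste("I", i, g1, g2)
    if (!is.null(seenMv[[key]])) return(invisible(NULL))
    seenMv[[key]] <- TRUE
    moves[[length(moves) + 1L]] <<- list(kind = "PERI_INV", i = i,
                                         g1 = g1, g2 = g2)
  }
  pushEET <- function(i, endA, j, endB, keep) {
    if (i > j) {
      tmp <- i; i <- j; j <- tmp
      tmp <- endA; endA <- endB; endB <- tmp
      keep <- 3L - keep
    }
    key <- paste("E", i, endA, j, endB, keep)
    if (!is.null(seenMv[[key]])) return(invisible(NULL))
    seenMv[[key]] <- TRUE
    moves[[length(moves) + 1L]] <<- list(kind = "EET", i = i, endA = endA,
                                         j = j, endB = endB, keep = keep)
  }
  for (a in missingSet) {
    ad <- parseAdj(a)
    readings <- unique(list(c(ad$u, ad$v),
                            c(flipTok(ad$v), flipTok(ad$u))))
    for (rd in readings) {
      u <- rd[1]; v <- rd[2]
      if (doRecip || doUneq) {
        # centric-head side: junction (t_C[gC] == u) + acentric piece of X
        # starting with v; bridge <=> gC == cen_C
        for (iC in seq_len(nC)) {
          tc <- state[[iC]]; n <- length(tc$t); cen <- tc$cen
          gCs <- if (ad$bridge) {
            if (tc$t[cen] == u) list(c(cen, TRUE)) else list()
          } else {
            lapply(which(tc$t == u), function(p)
              if (p > cen) c(p, FALSE) else NULL)
          }
          for (gc in gCs) {
            if (is.null(gc)) next
            for (iX in seq_len(nC)) {
              if (iX == iC) next
              tx <- state[[iX]]; nx <- length(tx$t); cx <- tx$cen
              # acentric = tail of X: t_X[gX+1] == v, gX >= cen_X
              for (q in which(tx$t == v))
                if (q - 1L >= cx)
                  pushTrans(iC, gc[1], gc[2] == 1, iX, q - 1L, q - 1L == cx)
              # acentric = head of X: t_X[gX] == flip(v), gX <= cen_X
              for (p in which(tx$t == flipTok(v)))
                if (p <= cx) pushTrans(iC, gc[1], gc[2] == 1, iX, p, FALSE)
            }
          }
          # centric-tail side: junction (acentric of X ending with u) +
          # (t_C[gC+1] == v); bridge <=> gC == cen_C
          gCs2 <- if (ad$bridge) {
            if (tc$t[cen + 1L] == v) list(cen) else list()
          } else {
            lapply(which(tc$t == v), function(q)
              if (q - 1L < cen) q - 1L else NULL)
          }
          for (gc in gCs2) {
            if (is.null(gc)) next
            for (iX in seq_len(nC)) {
              if (iX == iC) next
              tx <- state[[iX]]; nx <- length(tx$t); cx <- tx$cen
              # acentric = head of X: t_X[gX] == u, gX <= cen_X
              for (p in which(tx$t == u))
                if (p <= cx) pushTrans(iC, gc, FALSE, iX, p, FALSE)
              # acentric = tail of X: t_X[gX+1] == flip(u), gX >= cen_X
              for (q in which(tx$t == flipTok(u)))
                if (q - 1L >= cx)
                  pushTrans(iC, gc, FALSE, iX, q - 1L, q - 1L == cx)
            }
          }
        }
      }
      if ("PERI_INV" %in% ops && !ad$bridge) {
        for (i in seq_len(nC)) {
          tc <- state[[i]]; n <- length(tc$t); cen <- tc$cen
          # junction at the left cut: t[g1] == u, flip(t[g2]) == v
          g1s <- which(tc$t == u); g1s <- g1s[g1s <= cen - 1L]
          g2s <- which(tc$t == flipTok(v)); g2s <- g2s[g2s >= cen + 1L]
          for (g1 in g1s) for (g2 in g2s)
            if (!(g1 == 0L && g2 == n)) pushInv(i, g1, g2)
          # junction at the right cut: flip(t[g1+1]) == u, t[g2+1] == v
          g1s <- which(tc$t == flipTok(u)) - 1L
          g1s <- g1s[g1s >= 0L & g1s <= cen - 1L]
          g2s <- which(tc$t == v) - 1L
          g2s <- g2s[g2s >= cen + 1L & g2s <= n - 1L]
          for (g1 in g1s) for (g2 in g2s)
            if (!(g1 == 0L && g2 == n)) pushInv(i, g1, g2)
        }
      }
      if ("EET" %in% ops && needEET > 0L && nC >= 2L && !ad$bridge) {
        # fusion junction: u at an end of i (read towards the junction),
        # v at an end of j
        for (i in seq_len(nC)) {
          ti <- state[[i]]$t; ni <- length(ti)
          endsA <- c(if (ti[ni] == u) "tail", if (flipTok(ti[1]) == u) "head")
          if (!length(endsA)) next
          for (j in seq_len(nC)) {
            if (j == i) next
            tj <- state[[j]]$t; nj <- length(tj)
            endsB <- c(if (tj[1] == v) "head", if (flipTok(tj[nj]) == v) "tail")
            for (ea in endsA) for (eb in endsB) for (keep in 1:2)
              pushEET(i, ea, j, eb, keep)
          }
        }
        # centromere-elimination junction: u, v flank the centromere of the
        # chromosome whose centromere is lost
        for (l in seq_len(nC)) {
          tl <- state[[l]]
          if (canonAdj(tl$t[tl$cen], tl$t[tl$cen + 1L]) != a) next
          for (m in seq_len(nC)) {
            if (m == l) next
            for (ea in c("head", "tail")) for (eb in c("head", "tail"))
              pushEET(l, ea, m, eb, 2L)  # keep the partner's centromere
          }
        }
      }
    }
  }
  moves
}

## every chromosome must keep its centromere strictly between two tokens
tokStateValid <- function(state) {
  all(vapply(state, function(tc) {
    n <- length(tc$t)
    n >= 2L && length(tc$cen) == 1L && tc$cen >= 1L && tc$cen <= n - 1L
  }, logical(1)))
}

applyTokenMove <- function(state, mv) {
  if (mv$kind %in% c("RECIP_TRANSLOC", "UNEQ_TRANSLOC")) {
    pr <- tokRecip(state[[mv$i]], mv$gA, state[[mv$j]], mv$gB,
                   mv$cenHeadA, mv$cenHeadB)
    state[[mv$i]] <- pr$a
    state[[mv$j]] <- pr$b
  } else if (mv$kind == "PERI_INV") {
    state[[mv$i]] <- tokInv(state[[mv$i]], mv$g1, mv$g2)
  } else if (mv$kind == "EET") {
    fu <- tokEET(state[[mv$i]], mv$endA, state[[mv$j]], mv$endB, mv$keep)
    state[[min(mv$i, mv$j)]] <- fu
    state <- state[-max(mv$i, mv$j)]
  }
  state
}

## canonical serialization of a move for scenario deduplication (operand
## symmetry: operands sorted by canonical chromosome string, gaps mirrored
## when the canonical reading is the reverse one)
moveKey <- function(state, mv) {
  canonGap <- function(tc, g) {
    fwd <- paste(append(tc$t, "^", after = tc$cen), collapse = " ")
    rev_ <- paste(flipTok(rev(append(tc$t, "^", after = tc$cen))), collapse = " ")
    if (fwd <= rev_) g else length(tc$t) - g
  }
  if (mv$kind %in% c("RECIP_TRANSLOC", "UNEQ_TRANSLOC")) {
    a <- sprintf("%s|%d", tokChromCanon(state[[mv$i]]), canonGap(state[[mv$i]], mv$gA))
    b <- sprintf("%s|%d", tokChromCanon(state[[mv$j]]), canonGap(state[[mv$j]], mv$gB))
    paste(mv$kind, paste(sort(c(a, b)), collapse = " x "))
  } else if (mv$kind == "PERI_INV") {
    tc <- state[[mv$i]]
    fwd <- paste(append(tc$t, "^", after = tc$cen), collapse = " ")
    rev_ <- paste(flipTok(rev(append(tc$t, "^", after = tc$cen))), collapse = " ")
    g <- sort(if (fwd <= rev_) c(mv$g1, mv$g2)
              else length(tc$t) - c(mv$g1, mv$g2))
    sprintf("PERI_INV %s|%d-%d", tokChromCanon(tc), g[1], g[2])
  } else {
    kcan <- tokChromCanon(state[[if (mv$keep == 1L) mv$i else mv$j]])
    a <- tokChromCanon(state[[mv$i]])
    b <- tokChromCanon(state[[mv$j]])
    sprintf("EET %s keep %s", paste(sort(c(a, b)), collapse = " x "), kcan)
  }
}

## ---- the search ----

#' Bounded parsimony search between two karyotypes
#'
#' Iterative-deepening search over rearrangement events (EET, reciprocal and
#' unequal translocations, pericentric inversions; whole-genome duplication is
#' never searched) from \code{start} to \code{target}, restricted to
#' target-implied breakpoints (\code{\link{impliedBreakpoints}}). Moves are
#' adjacency-guided: every event must create at least one block adjacency of
#' the target that the current karyotype lacks. States are pruned with the
#' admissible bound ceil(missing adjacencies / 2) and deduplicated by
#' canonical form (a state reached twice at the same depth is expanded once,
#' so returned scenarios are also deduplicated up to the order of events that
#' pass through identical intermediate karyotypes). All minimal-length
#' scenarios found are returned, deduplicated up to operand symmetry and
#' sorted by serialized form; comparisons are copy-blind (painted karyotypes
#' cannot phase homeolog copies).
#'
#' @param start,target \code{\linkS4class{Karyotype}} objects.
#' @param maxDepth Maximum scenario length searched (default 6; values above
#'   6 can be slow).
#' @param ops Character vector of allowed event kinds (subset of
#'   \code{"EET"}, \code{"RECIP_TRANSLOC"}, \code{"UNEQ_TRANSLOC"},
#'   \code{"PERI_INV"}).
#' @param maxNodes Safety cap on node expansions per deepening round.
#' @return List of class \code{"karyoSearchResult"}: \code{found},
#'   \code{distance} (integer, or NA when not found at \code{maxDepth});
#'   \code{scenarios} (list of \code{\linkS4class{Scenario}} objects replaying
#'   start to target), \code{nodesExpanded}.
#' @export
#' @examples
#' ack <- buildACK()
#' searchScenarios(ack, ack, maxDepth = 1)$distance  # 0
searchScenarios <- function(start, target, maxDepth = 6L,
                            ops = c("EET", "RECIP_TRANSLOC",
                                    "UNEQ_TRANSLOC", "PERI_INV"),
                            maxNodes = 5e5) {
  ops <- match.arg(ops, eventKinds(), several.ok = TRUE)
  cuts <- impliedBreakpoints(target)
  cutsS <- impliedBreakpoints(start)
  for (b in names(cutsS))
    cuts[[b]] <- sort(unique(c(cuts[[b]], cutsS[[b]])))
  s0 <- tokenizeKaryotype(start, cuts)
  tState <- tokenizeKaryotype(target, cuts)
  targetAdj <- stateAdjacencies(tState)
  targetKey <- tokStateKey(tState)
  nTarget <- length(tState)
  nodes <- 0L
  solutions <- list()     # list of move-record paths
  solutionKeys <- character(0)

  dfs <- function(state, g, D, path, pathKeys, memo) {
    nodes <<- nodes + 1L
    if (nodes > maxNodes)
      stop(sprintf("search budget exceeded (%d node expansions); not found <= max_depth under this budget", maxNodes))
    key <- tokStateKey(state)
    if (key == targetKey) {
      skey <- paste(pathKeys, collapse = " ;; ")
      if (!(skey %in% solutionKeys)) {
        solutionKeys <<- c(solutionKeys, skey)
        solutions[[length(solutions) + 1L]] <<- path
      }
      return(invisible(NULL))
    }
    if (g >= D) return(invisible(NULL))
    needEET <- length(state) - nTarget
    if (needEET < 0L) return(invisible(NULL))
    missing <- missingAdjacencies(targetAdj, stateAdjacencies(state))
    h <- max(ceiling(length(missing) / 2), needEET)
    if (g + h > D) return(invisible(NULL))
    seen <- memo[[key]]
    if (!is.null(seen) && seen <= g) return(invisible(NULL))
    memo[[key]] <- g
    mvs <- generateMoves(state, unique(missing), ops, needEET)
    for (mv in mvs) {
      st2 <- applyTokenMove(state, mv)
      if (!tokStateValid(st2)) next  # e.g. a centromere pushed onto a terminus
      dfs(st2, g + 1L, D, c(path, list(mv)),
          c(pathKeys, moveKey(state, mv)), memo)
    }
    invisible(NULL)
  }

  distance <- NA_integer_
  for (D in 0:maxDepth) {
    solutions <- list(); solutionKeys <- character(0)
    memo <- new.env(parent = emptyenv())
    dfs(s0, 0L, D, list(), character(0), memo)
    if (length(solutions)) { distance <- D; break }
  }
  found <- !is.na(distance)
  scen <- list()
  if (found) {
    ord <- order(vapply(solutionKeys, identity, character(1)))
    scen <- lapply(solutions[ord], function(p)
      tokenPathToScenario(p, start, cuts))
  }
  structure(list(found = found, distance = distance, scenarios = scen,
                 nodesExpanded = nodes,
                 message = if (found) sprintf("distance %d", distance)
                           else sprintf("not found <= max_depth %d", maxDepth)),
            class = "karyoSearchResult")
}

#' @export
print.karyoSearchResult <- function(x, ...) {
  cat("Parsimony search:", x$message, "\n")
  if (x$found)
    cat(sprintf("  %d minimal scenario(s); %d node expansions\n",
                length(x$scenarios), x$nodesExpanded))
  invisible(x)
}

## convert a token gap on a model chromosome to a model breakpoint
gapToBreakpoint <- function(ch, cuts, g, cenToHead = FALSE) {
  tk <- tokenizeChromosome(ch, cuts, withMap = TRUE)
  if (g < 1L) return(breakpoint(ch@name, after = 0L))
  info <- tk$map[[g]]
  if (!is.null(info$after))
    breakpoint(ch@name, after = info$after, cenToHead = cenToHead)
  else
    breakpoint(ch@name, segment = info$segment, fraction = info$fraction,
               cenToHead = cenToHead)
}

## replay a token move path in lockstep with the model karyotype, emitting
## model RearrangementEvents (chromosome order is kept aligned because the
## token and model operators use identical placement conventions)
tokenPathToScenario <- function(path, start, cuts) {
  k <- start
  evs <- list()
  for (mv in path) {
    nm <- chromosomeNames(k)
    if (mv$kind %in% c("RECIP_TRANSLOC", "UNEQ_TRANSLOC")) {
      chA <- k@chromosomes[[mv$i]]; chB <- k@chromosomes[[mv$j]]
      nA <- length(tokenizeChromosome(chA, cuts)$t)
      nB <- length(tokenizeChromosome(chB, cuts)$t)
      termA <- mv$gA == 0L || mv$gA == nA
      termB <- mv$gB == 0L || mv$gB == nB
      if (termA || termB) {
        if (termB) {
          ev <- rearrangementEvent("UNEQ_TRANSLOC", params = list(
            bp = gapToBreakpoint(chA, cuts, mv$gA, mv$cenHeadA),
            target = chB@name,
            targetEnd = if (mv$gB == 0L) "head" else "tail"))
        } else {
          ev <- rearrangementEvent("UNEQ_TRANSLOC", params = list(
            bp = gapToBreakpoint(chB, cuts, mv$gB, mv$cenHeadB),
            target = chA@name,
            targetEnd = if (mv$gA == 0L) "head" else "tail"))
        }
      } else {
        ev <- rearrangementEvent("RECIP_TRANSLOC", params = list(
          bp1 = gapToBreakpoint(chA, cuts, mv$gA, mv$cenHeadA),
          bp2 = gapToBreakpoint(chB, cuts, mv$gB, mv$cenHeadB)))
      }
    } else if (mv$kind == "PERI_INV") {
      ch <- k@chromosomes[[mv$i]]
      ev <- rearrangementEvent("PERI_INV", params = list(
        bpL = gapToBreakpoint(ch, cuts, mv$g1),
        bpR = gapToBreakpoint(ch, cuts, mv$g2)))
    } else {
      ev <- rearrangementEvent("EET", params = list(
        chrA = nm[mv$i], endA = mv$endA, chrB = nm[mv$j], endB = mv$endB,
        keep = nm[if (mv$keep == 1L) mv$i else mv$j]))
    }
    evs[[length(evs) + 1L]] <- ev
    k <- applyEvent(k, ev)
  }
  new("Scenario", events = evs,
      start = if (is.na(start@name)) "start" else start@name)
}
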