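## Patterson's D-statistic (ABBA-BABA) on four-taxon quartets with
## block-jackknife significance.

#' Quartet specification
#'
#' Four distinct taxa with the topology (((P1, P2), P3), O): P1 and P2 are
#' the closely related ingroup pair, P3 the third ingroup taxon, O the
#' outgroup used to polarise alleles. In frequency mode each slot may name
#' several sample rows (a population).
#'
#' @param P1,P2,P3,O Sample identifiers (character; vectors allowed for
#'   frequency mode).
#' @return A list of class \code{"quartetSpec"}.
#' @export
quartetSpec <- function(P1, P2, P3, O) {
  ids <- c(P1, P2, P3, O)
  if (anyDuplicated(ids)) stop("the four quartet taxa must be distinct samples")
  structure(list(P1 = P1, P2 = P2, P3 = P3, O = O), class = "quartetSpec")
}

#' @export
print.quartetSpec <- function(x, ...) {
  cat(sprintf("(((%s, %s), %s), %s)\n", paste(x$P1, collapse = "+"),
              paste(x$P2, collapse = "+"), paste(x$P3, collapse = "+"),
              paste(x$O, collapse = "+")))
  invisible(x)
}

## per-site ABBA/BABA contributions for a quartet; returns data.frame
## (abba, baba) with one row per usable site, plus skip counts
patternContributions <- function(snpMatrix, quartet, mode = c("binary", "freq")) {
  mode <- match.arg(mode)
  rows <- rownames(snpMatrix)
  for (tx in c("P1", "P2", "P3", "O"))
    if (!all(quartet[[tx]] %in% rows))
      stop(sprintf("quartet taxon %s (%s) not found among matrix rows", tx,
                   paste(setdiff(quartet[[tx]], rows), collapse = ", ")))
  nS <- ncol(snpMatrix)
  freqOf <- function(ids) {
    sub <- snpMatrix[ids, , drop = FALSE]
    colMeans(sub, na.rm = TRUE)
  }
  pO <- freqOf(quartet$O)
  skippedOutgroup <- 0L; skippedMissing <- 0L
  if (mode == "binary") {
    p1 <- freqOf(quartet$P1); p2 <- freqOf(quartet$P2); p3 <- freqOf(quartet$P3)
    usable <- is.finite(p1) & is.finite(p2) & is.finite(p3) & is.finite(pO)
    skippedMissing <- sum(!usable)
    # the outgroup allele defines the ancestral state "A"; a polymorphic
    # outgroup cannot polarise the site
    poly <- usable & pO > 0 & pO < 1
    skippedOutgroup <- sum(poly)
    usable <- usable & !poly
    derived <- function(p, anc) ifelse(anc == 0, p, 1 - p)
    d1 <- derived(p1, pO); d2 <- derived(p2, pO); d3 <- derived(p3, pO)
    abba <- as.numeric(d1 == 0 & d2 == 1 & d3 == 1)
    baba <- as.numeric(d1 == 1 & d2 == 0 & d3 == 1)
  } else {
    p1 <- freqOf(quartet$P1); p2 <- freqOf(quartet$P2); p3 <- freqOf(quartet$P3)
    usable <- is.finite(p1) & is.finite(p2) & is.finite(p3) & is.finite(pO)
    skippedMissing <- sum(!usable)
    amb <- usable & abs(pO - 0.5) < 1e-12
    skippedOutgroup <- sum(amb)
    usable <- usable & !amb
    # polarise by the outgroup major allele
    d1 <- ifelse(pO < 0.5, p1, 1 - p1)
    d2 <- ifelse(pO < 0.5, p2, 1 - p2)
    d3 <- ifelse(pO < 0.5, p3, 1 - p3)
    abba <- (1 - d1) * d2 * d3
    baba <- d1 * (1 - d2) * d3
  }
  abba[!usable] <- NA_real_; baba[!usable] <- NA_real_
  list(abba = abba, baba = baba, usable = usable,
       skippedOutgroup = skippedOutgroup, skippedMissing = skippedMissing)
}

#' Count ABBA and BABA site patterns
#'
#' The outgroup defines the ancestral state "A" per site; the derived allele
#' is "B". A site supports ABBA when the derived allele is shared by P2 and
#' P3, and BABA when it is shared by P1 and P3. In binary mode each site
#' contributes 0 or 1; in frequency mode a site contributes
#' \eqn{(1-p_1) p_2 p_3} to ABBA and \eqn{p_1 (1-p_2) p_3} to BABA, with
#' derived-allele frequencies per taxon. Sites with missing calls, or an
#' outgroup that cannot polarise the site, are skipped and counted.
#'
#' @param snpMatrix Numeric 0/1 (or frequency) matrix, samples in rows
#'   (rownames required), sites in columns; column order is genomic order.
#' @param quartet A \code{\link{quartetSpec}}.
#' @param mode \code{"binary"} (default; one haplotype per taxon, as in a
#'   consensus-supercontig alignment) or \code{"freq"}.
#' @return list(n_abba, n_baba, n_used, n_skipped_outgroup,
#'   n_skipped_missing).
#' @export
countPatterns <- function(snpMatrix, quartet, mode = c("binary", "freq")) {
  pc <- patternContributions(snpMatrix, quartet, mode)
  list(n_abba = sum(pc$abba, na.rm = TRUE),
       n_baba = sum(pc$baba, na.rm = TRUE),
       n_used = sum(pc$usable),
       n_skipped_outgroup = pc$skippedOutgroup,
       n_skipped_missing = pc$skippedMissing)
}

#' Patterson's D statistic
#'
#' \eqn{D = (n_{ABBA} - n_{BABA}) / (n_{ABBA} + n_{BABA})}. Without
#' introgression the two patterns are similarly frequent and D is near zero;
#' gene flow between P2 and P3 inflates ABBA and drives D positive.
#'
#' @param n_abba,n_baba (Weighted) pattern counts.
#' @return D in [-1, 1]; \code{NA} (with a warning-free flag) when the
#'   denominator is zero, so batch callers never stop.
#' @export
#' @examples
#' dStatistic(150, 50)   # 0.5
#' dStatistic(100, 100)  # 0
dStatistic <- function(n_abba, n_baba) {
  tot <- n_abba + n_baba
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  (n_abba - n_baba) / tot
}

#' Block-jackknife significance for D
#'
#' Delete-one jackknife over contiguous site blocks (column order = genomic
#' order, so blocks approximate linkage blocks in target-enrichment data).
#' The standard error comes from the jackknife variance of the delete-one D
#' estimates; Z = D / SE and the p-value is the one-sided upper tail of the
#' standard normal. A constant D across blocks (SE = 0) is flagged as
#' infinite Z rather than an error.
#'
#' @param snpMatrix,quartet,mode As in \code{\link{countPatterns}}.
#' @param blockSize Sites per jackknife block (default 2000).
#' @return Object of class \code{"DResult"}: n_abba, n_baba, D, Z, p,
#'   n_blocks, block_size, significant (p < 0.01 and Z > 3), infiniteZ, plus
#'   skip counts.
#' @export
dJackknife <- function(snpMatrix, quartet, blockSize = 2000L,
                       mode = c("binary", "freq")) {
  mode <- match.arg(mode)
  pc <- patternContributions(snpMatrix, quartet, mode)
  nS <- length(pc$abba)
  blocks <- split(seq_len(nS), ceiling(seq_len(nS) / blockSize))
  bA <- vapply(blocks, function(i) sum(pc$abba[i], na.rm = TRUE), numeric(1))
  bB <- vapply(blocks, function(i) sum(pc$baba[i], na.rm = TRUE), numeric(1))
  nonEmpty <- (bA + bB) > 0
  if (sum(nonEmpty) < 20L)
    stop(sprintf("only %d non-empty jackknife blocks (need >= 20); use a smaller block_size",
                 sum(nonEmpty)))
  totA <- sum(bA); totB <- sum(bB)
  D <- dStatistic(totA, totB)
  bA <- bA[nonEmpty]; bB <- bB[nonEmpty]
  B <- length(bA)
  thetas <- vapply(seq_len(B), function(i)
    dStatistic(totA - bA[i], totB - bB[i]), numeric(1))
  se <- sqrt((B - 1) / B * sum((thetas - mean(thetas))^2))
  infiniteZ <- is.finite(D) && se < 1e-12
  Z <- if (infiniteZ) Inf else D / se
  p <- if (infiniteZ) 0 else pnorm(Z, lower.tail = FALSE)
  out <- list(n_abba = totA, n_baba = totB, D = D, Z = Z, p = p,
              n_blocks = B, block_size = blockSize,
              significant = is.finite(D) && p < 0.01 && Z > 3,
              infiniteZ = infiniteZ,
              n_skipped_outgroup = pc$skippedOutgroup,
              n_skipped_missing = pc$skippedMissing)
  class(out) <- "DResult"
  out
}

#' @export
print.DResult <- function(x, ...) {
  cat(sprintf("ABBA-BABA: nABBA = %.2f, nBABA = %.2f, D = %.4f, Z = %.3f, p = %.3g (%d blocks of %d)\n",
              x$n_abba, x$n_baba, x$D, x$Z, x$p, x$n_blocks, x$block_size))
  cat(sprintf("  significant (p < 0.01 and Z > 3): %s\n", x$significant))
  invisible(x)
}

#' D-statistics for a list of quartets
#'
#' @param snpMatrix As in \code{\link{countPatterns}}.
#' @param quartets List of \code{\link{quartetSpec}}s.
#' @param blockSize,mode Passed to \code{\link{dJackknife}}.
#' @return data.frame with one row per quartet (counts, D, Z, p,
#'   significant).
#' @export
dStatTable <- function(snpMatrix, quartets, blockSize = 2000L,
                       mode = c("binary", "freq")) {
  mode <- match.arg(mode)
  rows <- lapply(quartets, function(q) {
    r <- dJackknife(snpMatrix, q, blockSize, mode)
    data.frame(P1 = paste(q$P1, collapse = "+"), P2 = paste(q$P2, collapse = "+"),
               P3 = paste(q$P3, collapse = "+"), O = paste(q$O, collapse = "+"),
               n_abba = r$n_abba, n_baba = r$n_baba, D = r$D, Z = r$Z,
               p = r$p, significant = r$significant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
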