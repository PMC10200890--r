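## Ploidy inference from biallelic SNP read counts: fixed-mean Gaussian
## mixture model selection (delta log-likelihood), histogram fit statistics
## and the median allele-ratio reference-limit rule.

#' Load per-site biallelic read counts
#'
#' Reads either a 3-column TSV (site_id, ref_reads, alt_reads) or a VCF with
#' per-sample allele depths (AD), keeping biallelic SNP sites only and
#' applying coverage and minor-allele filters. Counts of kept and dropped
#' sites are reported via \code{message()} and attached as the
#' \code{"filterLog"} attribute; no filtering is ever silent.
#'
#' @param file Path to a TSV or VCF file.
#' @param sample Sample name (required for VCF input).
#' @param minCoverage Minimum total read depth per site (default 10).
#' @param minAltReads Minimum minor-allele read count (default 2; this also
#'   removes sites monoallelic in-sample, which carry no frequency signal).
#' @return data.frame with columns site_id, ref_reads, alt_reads, coverage,
#'   alt_frequency; attribute \code{filterLog}.
#' @export
loadSiteCounts <- function(file, sample = NULL, minCoverage = 10,
                           minAltReads = 2) {
  if (grepl("\\.vcf(\\.gz)?$", file, ignore.case = TRUE)) {
    v <- readVcfMinimal(file, requireFields = "AD")
    if (is.null(sample)) stop("'sample' is required for VCF input")
    if (!sample %in% colnames(v$adRef))
      stop(sprintf("sample '%s' not present in VCF", sample))
    tab <- data.frame(site_id = paste0(v$sites$CHROM, ":", v$sites$POS),
                      ref_reads = v$adRef[, sample],
                      alt_reads = v$adAlt[, sample],
                      stringsAsFactors = FALSE)
  } else {
    tab <- read.delim(file, stringsAsFactors = FALSE)
    need <- c("site_id", "ref_reads", "alt_reads")
    if (!all(need %in% names(tab)))
      stop("TSV input must have columns site_id, ref_reads, alt_reads")
  }
  n0 <- nrow(tab)
  tab <- tab[!is.na(tab$ref_reads) & !is.na(tab$alt_reads), , drop = FALSE]
  tab$coverage <- tab$ref_reads + tab$alt_reads
  keepCov <- tab$coverage >= minCoverage
  keepMinor <- pmin(tab$ref_reads, tab$alt_reads) >= minAltReads
  dropped <- c(missing = n0 - nrow(tab),
               low_coverage = sum(!keepCov),
               low_minor_allele = sum(keepCov & !keepMinor))
  tab <- tab[keepCov & keepMinor, , drop = FALSE]
  tab$alt_frequency <- tab$alt_reads / tab$coverage
  rownames(tab) <- NULL
  message(sprintf("loadSiteCounts: kept %d of %d sites (dropped: %d missing, %d low coverage, %d low minor-allele count)",
                  nrow(tab), n0, dropped[1], dropped[2], dropped[3]))
  attr(tab, "filterLog") <- c(kept = nrow(tab), dropped)
  tab
}

#' Allele-ratio distribution and its median
#'
#' The per-site allele ratio divides the read count of the more frequent
#' allele by that of the less frequent allele (always >= 1). Its median
#' separates ploidy classes: a balanced diploid site has expectation near 1,
#' while a tetraploid mixture of 1:3 / 2:2 / 3:1 dosages pushes the median
#' towards 3. Ratios are scale-free: multiplying all read counts by a
#' constant leaves every ratio unchanged.
#'
#' @param counts data.frame with ref_reads and alt_reads columns (e.g. from
#'   \code{\link{loadSiteCounts}}).
#' @return list(median = numeric, ratios = numeric vector).
#' @export
#' @examples
#' alleleRatioStats(data.frame(ref_reads = c(10, 30, 10),
#'                             alt_reads = c(10, 10, 30)))$median  # 3 at the
#' # median of ratios {1, 3, 3}
alleleRatioStats <- function(counts) {
  ok <- pmin(counts$ref_reads, counts$alt_reads) > 0
  if (!any(ok))
    stop("all sites are monoallelic after filtering; allele ratios undefined")
  r <- pmax(counts$ref_reads[ok], counts$alt_reads[ok]) /
       pmin(counts$ref_reads[ok], counts$alt_reads[ok])
  list(median = median(r), ratios = r)
}

ploidyModelMeans <- function(model) {
  switch(model,
         diploid = 1 / 2,
         triploid = c(1 / 3, 2 / 3),
         tetraploid = c(1 / 4, 1 / 2, 3 / 4),
         stop(sprintf("unknown ploidy model '%s'", model)))
}

#' Fit a fixed-mean or free Gaussian mixture to allele frequencies
#'
#' Expectation-maximisation for a one-dimensional Gaussian mixture over
#' alternate-allele frequencies in (0,1). Fixed models represent the ideal
#' expected distribution of a ploidy level: component means pinned at the
#' dosage expectations (diploid \{1/2\}, triploid \{1/3, 2/3\}, tetraploid
#' \{1/4, 1/2, 3/4\}) with uniform dosage-class weights, and only the
#' per-component standard deviations fitted. (Freeing the weights would let
#' a higher-ploidy model collapse onto lower-ploidy data and defeat the
#' delta log-likelihood comparison.) The free model fits means, weights and
#' standard deviations of 3 components.
#' An optional uniform noise component absorbs background sites. The
#' log-likelihood is non-decreasing across iterations; initialisation is
#' deterministic, so the fit is reproducible without any random seed.
#'
#' @param freqs Numeric vector of frequencies strictly inside (0,1); at least
#'   50 sites.
#' @param model One of "diploid", "triploid", "tetraploid", "free".
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param maxIter Maximum EM iterations (default 500).
#' @param sdFloor Lower bound for component standard deviations (default
#'   1e-3).
#' @param noise Logical; include a uniform(0,1) noise component (off by
#'   default).
#' @return list(model, means, weights, sds, noiseWeight, loglik, iterations,
#'   converged, loglikTrace).
#' @export
fitPloidyMixture <- function(freqs, model = c("diploid", "triploid",
                                              "tetraploid", "free"),
                             tol = 1e-8, maxIter = 500L, sdFloor = 1e-3,
                             noise = FALSE) {
  model <- match.arg(model)
  freqs <- freqs[is.finite(freqs) & freqs > 0 & freqs < 1]
  n <- length(freqs)
  if (n < 50L) stop("need >= 50 sites inside (0,1) to fit a mixture")
  free <- model == "free"
  mu <- if (free) c(1 / 4, 1 / 2, 3 / 4) else ploidyModelMeans(model)
  K <- length(mu)
  w <- rep(1 / K, K)
  s <- rep(0.08, K)
  wNoise <- if (noise) 0.05 else 0
  if (noise) w <- w * (1 - wNoise)
  ll <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxIter)) {
    dens <- vapply(seq_len(K), function(k) w[k] * dnorm(freqs, mu[k], s[k]),
                   numeric(n))
    if (noise) dens <- cbind(dens, wNoise * 1)
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    newll <- sum(log(tot))
    trace <- c(trace, newll)
    if (is.finite(ll) && abs(newll - ll) < tol) { converged <- TRUE; ll <- newll; break }
    ll <- newll
    resp <- dens / tot
    nk <- colSums(resp)
    if (free) {
      wAll <- nk / n
      if (noise) { wNoise <- wAll[K + 1L]; wAll <- wAll[seq_len(K)] }
      w <- wAll
    } else if (noise) {
      # fixed models keep uniform dosage-class weights; only the noise share
      # is adapted
      wNoise <- nk[K + 1L] / n
      w <- rep((1 - wNoise) / K, K)
    }
    for (k in seq_len(K)) {
      if (nk[k] < 1e-12) { s[k] <- sdFloor; next }
      if (free) mu[k] <- sum(resp[, k] * freqs) / nk[k]
      s[k] <- sqrt(sum(resp[, k] * (freqs - mu[k])^2) / nk[k])
      if (!is.finite(s[k]) || s[k] < sdFloor) s[k] <- sdFloor
    }
  }
  list(model = model, means = mu, weights = w, sds = s,
       noiseWeight = if (noise) wNoise else 0,
       loglik = ll, iterations = it, converged = converged,
       loglikTrace = trace)
}

#' Ordinary least squares of an empirical histogram on a model histogram
#'
#' The low-level regression behind \code{\link{histoTest}}: empirical bin
#' heights regressed on expected bin heights. A good fit shows a positive
#' slope near 1 with a small standard error, a small sum of squared residuals
#' (SSR) and a large R-squared.
#'
#' @param empirical,expected Numeric vectors of bin heights (same length).
#' @return list(slope, slope_se, intercept, SSR, R2).
#' @export
#' @examples
#' h <- c(1, 4, 6, 4, 1)
#' histoFit(h, h)$slope        # 1
#' histoFit(2 * h, h)$slope    # 2
histoFit <- function(empirical, expected) {
  if (length(empirical) != length(expected))
    stop("empirical and expected histograms must have the same length")
  if (all(empirical == 0) || all(expected == 0))
    stop("empty histogram: no non-zero bins to compare")
  fit <- lm(empirical ~ expected)
  # an exact match is a legitimate input (SSR 0); lm warns about the perfect
  # fit when summarising it
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  list(slope = unname(co["expected", "Estimate"]),
       slope_se = unname(co["expected", "Std. Error"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       SSR = sum(fit$residuals^2),
       R2 = sm$r.squared)
}

expectedBinHeights <- function(fit, breaks) {
  K <- length(fit$means)
  p <- numeric(length(breaks) - 1L)
  for (k in seq_len(K))
    p <- p + fit$weights[k] * (pnorm(breaks[-1], fit$means[k], fit$sds[k]) -
                               pnorm(breaks[-length(breaks)], fit$means[k], fit$sds[k]))
  if (fit$noiseWeight > 0) p <- p + fit$noiseWeight * diff(breaks)
  p / sum(p)
}

#' Histogram fit statistics for one ploidy model
#'
#' Bins the empirical allele-frequency distribution on (0,1), computes the
#' per-bin expectation of the fitted fixed-mean mixture for the given ploidy,
#' and regresses empirical on expected heights
#' (see \code{\link{histoFit}}).
#'
#' @param freqs Numeric vector of alternate-allele frequencies in (0,1).
#' @param ploidy "diploid", "triploid" or "tetraploid".
#' @param bins Number of equal bins on (0,1) (default 30).
#' @param fit Optional pre-computed \code{\link{fitPloidyMixture}} result for
#'   this ploidy.
#' @return list(slope, slope_se, intercept, SSR, R2) as in
#'   \code{\link{histoFit}}.
#' @export
histoTest <- function(freqs, ploidy = c("diploid", "triploid", "tetraploid"),
                      bins = 30L, fit = NULL) {
  ploidy <- match.arg(ploidy)
  freqs <- freqs[is.finite(freqs) & freqs > 0 & freqs < 1]
  breaks <- seq(0, 1, length.out = bins + 1L)
  emp <- tabulate(findInterval(freqs, breaks, rightmost.closed = TRUE),
                  nbins = bins)
  emp <- emp / sum(emp)
  if (is.null(fit)) fit <- fitPloidyMixture(freqs, ploidy)
  expd <- expectedBinHeights(fit, breaks)
  histoFit(emp, expd)
}

#' Full ploidy fit report for one sample
#'
#' Fits the free mixture model plus the three fixed-mean ploidy models,
#' computes the delta log-likelihood (free minus fixed; the generating model
#' nests inside the free model, so the smallest delta identifies the best
#' ploidy), the histogram fit statistics per ploidy, and the median allele
#' ratio.
#'
#' @param counts data.frame of site counts (ref_reads, alt_reads), e.g. from
#'   \code{\link{loadSiteCounts}} or
#'   \code{\link{simulateAlleleCounts}}\code{$counts}.
#' @param knownPloidy Optional known ploidy ("diploid"/"triploid"/
#'   "tetraploid") for reference samples used by \code{\link{callPloidy}}.
#' @param bins Histogram bins for \code{\link{histoTest}}.
#' @param noise Include the uniform noise component in all fits.
#' @param ... Passed to \code{\link{fitPloidyMixture}}.
#' @return Object of class \code{"ploidyFitReport"}: fits, loglik_free,
#'   loglik_fixed, delta_loglik, histotest (per ploidy), median_allele_ratio,
#'   best (ploidy with the smallest delta), knownPloidy.
#' @export
ploidyReport <- function(counts, knownPloidy = NULL, bins = 30L,
                         noise = FALSE, ...) {
  freqs <- counts$alt_reads / (counts$ref_reads + counts$alt_reads)
  freqs <- freqs[is.finite(freqs) & freqs > 0 & freqs < 1]
  ploidies <- c("diploid", "triploid", "tetraploid")
  fits <- lapply(c(ploidies, "free"), function(m)
    fitPloidyMixture(freqs, m, noise = noise, ...))
  names(fits) <- c(ploidies, "free")
  llFree <- fits$free$loglik
  llFixed <- vapply(fits[ploidies], function(f) f$loglik, numeric(1))
  delta <- llFree - llFixed
  ht <- lapply(ploidies, function(p) histoTest(freqs, p, bins, fit = fits[[p]]))
  names(ht) <- ploidies
  ratio <- alleleRatioStats(counts)
  out <- list(fits = fits, loglik_free = llFree, loglik_fixed = llFixed,
              delta_loglik = delta, histotest = ht,
              median_allele_ratio = ratio$median,
              em_iterations = vapply(fits, function(f) f$iterations, numeric(1)),
              converged = vapply(fits, function(f) f$converged, logical(1)),
              best = ploidies[which.min(delta)],
              knownPloidy = knownPloidy,
              n_sites = length(freqs))
  class(out) <- "ploidyFitReport"
  out
}

#' @export
print.ploidyFitReport <- function(x, ...) {
  cat(sprintf("Ploidy fit report (%d sites)\n", x$n_sites))
  for (p in names(x$delta_loglik))
    cat(sprintf("  %-10s delta logL = %10.3f   histotest R2 = %.4f\n",
                p, x$delta_loglik[p], x$histotest[[p]]$R2))
  cat(sprintf("  median allele ratio: %.3f\n", x$median_allele_ratio))
  cat(sprintf("  best model by delta logL: %s\n", x$best))
  if (!is.null(x$knownPloidy))
    cat(sprintf("  known ploidy: %s\n", x$knownPloidy))
  invisible(x)
}

#' Call the ploidy of a query sample against known-ploidy references
#'
#' Applies the four decision criteria: (i) histogram shape (the delta-logL
#' candidate also maximises the histogram R-squared), (ii) the lowest delta
#' log-likelihood, (iii) histogram fit quality of the candidate (positive
#' slope, R-squared above \code{rsqMin}), and (iv) the median allele ratio of
#' the query falling within the reference limits, set to the lowest and
#' highest median allele ratios of samples with known ploidy. The final call
#' is made only when the delta-logL criterion and the median-ratio criterion
#' agree (the query is within limits and the candidate matches the reference
#' ploidy, or the query is outside the limits and the candidate differs);
#' otherwise the call is \code{"ambiguous"}.
#'
#' @param report \code{\link{ploidyReport}} of the query sample.
#' @param referenceReports Non-empty list of \code{\link{ploidyReport}}s with
#'   \code{knownPloidy} set (all the same ploidy).
#' @param rsqMin Minimum histogram R-squared for criterion (iii) (default
#'   0.8).
#' @return Object of class \code{"ploidyCall"}: call, criteria (named logical
#'   vector), reference_limits, candidate.
#' @export
callPloidy <- function(report, referenceReports, rsqMin = 0.8) {
  if (length(referenceReports) == 0L)
    stop("at least one reference report with known ploidy is required")
  refP <- unique(vapply(referenceReports,
                        function(r) as.character(r$knownPloidy), character(1)))
  if (length(refP) != 1L || is.na(refP))
    stop("reference reports must all carry the same known ploidy")
  refMed <- vapply(referenceReports, function(r) r$median_allele_ratio,
                   numeric(1))
  lims <- range(refMed)
  cand <- report$best
  r2 <- vapply(report$histotest, function(h) h$R2, numeric(1))
  within <- report$median_allele_ratio >= lims[1] &&
            report$median_allele_ratio <= lims[2]
  crit <- c(
    histogram_shape = names(which.max(r2)) == cand,
    delta_loglik = which.min(report$delta_loglik) ==
                   which(names(report$delta_loglik) == cand),
    histotest_quality = report$histotest[[cand]]$slope > 0 &&
                        report$histotest[[cand]]$R2 >= rsqMin,
    median_ratio_within_limits = within)
  agree <- (within && cand == refP) || (!within && cand != refP)
  out <- list(call = if (agree) cand else "ambiguous",
              criteria = crit, reference_limits = lims, candidate = cand,
              reference_ploidy = refP)
  class(out) <- "ploidyCall"
  out
}

#' @export
print.ploidyCall <- function(x, ...) {
  cat(sprintf("Ploidy call: %s (candidate %s, reference %s, limits [%.2f, %.2f])\n",
              x$call, x$candidate, x$reference_ploidy,
              x$reference_limits[1], x$reference_limits[2]))
  for (i in seq_along(x$criteria))
    cat(sprintf("  %-28s %s\n", names(x$criteria)[i], x$criteria[i]))
  invisible(x)
}

#' Plot an allele-frequency histogram with fitted mixture curves
#'
#' @param freqs Numeric vector of frequencies in (0,1).
#' @param fit Optional \code{\link{fitPloidyMixture}} result to overlay.
#' @param bins Number of bins (default 30).
#' @param main Plot title.
#' @return Invisibly, the histogram object.
#' @export
plotAlleleFrequencyHistogram <- function(freqs, fit = NULL, bins = 30L,
                                         main = "Allele frequency distribution") {
  freqs <- freqs[is.finite(freqs) & freqs > 0 & freqs < 1]
  h <- graphics::hist(freqs, breaks = seq(0, 1, length.out = bins + 1L),
                      freq = FALSE, xlab = "alternate-allele frequency",
                      main = main, col = "grey85", border = "white")
  if (!is.null(fit)) {
    xs <- seq(0.001, 0.999, length.out = 400)
    dens <- rowSums(vapply(seq_along(fit$means), function(k)
      fit$weights[k] * dnorm(xs, fit$means[k], fit$sds[k]),
      numeric(length(xs))))
    if (fit$noiseWeight > 0) dens <- dens + fit$noiseWeight
    graphics::lines(xs, dens, lwd = 2, col = "firebrick")
  }
  invisible(h)
}
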