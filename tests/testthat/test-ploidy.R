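test_that("site-count loading applies and logs the coverage and minor-allele filters", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("site_id\tref_reads\talt_reads",
               "s1\t5\t3",      # coverage 8 < 10: dropped
               "s2\t20\t1",     # minor allele 1 < 2: dropped
               "s3\t15\t10",
               "s4\t8\t8",
               "s5\t30\t10"), f)
  counts <- suppressMessages(loadSiteCounts(f))
  expect_equal(counts$site_id, c("s3", "s4", "s5"))
  lg <- attr(counts, "filterLog")
  expect_equal(unname(lg["kept"]), 3)
  expect_equal(unname(lg["low_coverage"]), 1)
  expect_equal(unname(lg["low_minor_allele"]), 1)
  # zero thresholds keep everything with positive coverage
  all5 <- suppressMessages(loadSiteCounts(f, minCoverage = 0, minAltReads = 0))
  expect_equal(nrow(all5), 5L)
})

test_that("allele ratios are max/min, scale-free, and their median is as constructed", {
  st <- alleleRatioStats(data.frame(ref_reads = c(10, 30, 10),
                                    alt_reads = c(10, 10, 30)))
  expect_equal(sort(st$ratios), c(1, 3, 3))
  expect_equal(st$median, 3)
  expect_equal(alleleRatioStats(data.frame(ref_reads = 30,
                                           alt_reads = 10))$ratios, 3)
  # scale invariance
  sc <- alleleRatioStats(data.frame(ref_reads = c(100, 300, 100),
                                    alt_reads = c(100, 100, 300)))
  expect_equal(sc$median, st$median)
  expect_error(alleleRatioStats(data.frame(ref_reads = c(10, 0),
                                           alt_reads = c(0, 10))),
               "monoallelic")
})

test_that("EM fits are deterministic, monotone, and the free model dominates fixed fits", {
  sim <- simulateAlleleCounts(nSites = 2000, ploidy = 4, seed = 11)
  freqs <- sim$counts$alt_reads / (sim$counts$ref_reads + sim$counts$alt_reads)
  freqs <- freqs[freqs > 0 & freqs < 1]
  for (m in c("diploid", "triploid", "tetraploid", "free")) {
    fit <- fitPloidyMixture(freqs, m)
    expect_true(all(diff(fit$loglikTrace) > -1e-6),
                label = paste("monotone loglik for", m))
    fit2 <- fitPloidyMixture(freqs, m)
    expect_identical(fit$loglik, fit2$loglik)
  }
  free <- fitPloidyMixture(freqs, "free")$loglik
  for (m in c("diploid", "triploid", "tetraploid"))
    expect_gte(free + 1e-6, fitPloidyMixture(freqs, m)$loglik)
})

test_that("degenerate data concentrate the diploid component at 1/2", {
  freqs <- rep(0.5, 200) + rnorm(200, 0, 1e-4)
  freqs <- pmin(pmax(freqs, 0.01), 0.99)
  fit <- fitPloidyMixture(freqs, "diploid")
  expect_equal(sum(fit$weights), 1, tolerance = 1e-6)
  for (m in c("triploid", "tetraploid"))
    expect_gte(fit$loglik + 1e-6, fitPloidyMixture(freqs, m)$loglik)
})

test_that("histogram regression statistics behave on exact and scaled histograms", {
  h <- c(1, 4, 6, 4, 1, 2, 5, 3)
  exact <- histoFit(h, h)
  expect_equal(exact$slope, 1)
  expect_equal(exact$SSR, 0, tolerance = 1e-12)
  expect_equal(exact$R2, 1)
  doubled <- histoFit(2 * h, h)
  expect_equal(doubled$slope, 2)
  expect_equal(doubled$R2, 1)
  expect_error(histoFit(h, h[-1]), "same length")
  expect_error(histoFit(numeric(8), h), "empty histogram")
})

test_that("triploid data fit the triploid histogram better than the diploid one", {
  sim <- simulateAlleleCounts(nSites = 5000, ploidy = 3, meanDepth = 40,
                              baseError = 0.01, seed = 21)
  freqs <- sim$counts$alt_reads / (sim$counts$ref_reads + sim$counts$alt_reads)
  freqs <- freqs[freqs > 0 & freqs < 1]
  r2Tri <- histoTest(freqs, "triploid")$R2
  r2Dip <- histoTest(freqs, "diploid")$R2
  expect_gt(r2Tri, r2Dip)
})

test_that("the delta log-likelihood criterion recovers the generating ploidy", {
  for (pl in 2:4) {
    sim <- simulateAlleleCounts(nSites = 5000, ploidy = pl, meanDepth = 40,
                                baseError = 0.01, seed = 30 + pl)
    counts <- suppressMessages(
      loadSiteCounts(writeSiteCounts(sim$counts, tempfile(fileext = ".tsv"))))
    rep_ <- ploidyReport(counts)
    expect_equal(rep_$best,
                 c("diploid", "triploid", "tetraploid")[pl - 1L])
    expect_true(all(rep_$delta_loglik > -1e-6))
  }
})

test_that("the median-ratio reference-limit rule reproduces the published band logic", {
  mkRep <- function(med, best = "tetraploid", known = NULL) {
    r2 <- c(diploid = 0.2, triploid = 0.5, tetraploid = 0.95)
    structure(list(
      delta_loglik = c(diploid = 50, triploid = 20, tetraploid = 1),
      histotest = lapply(r2, function(x)
        list(slope = 1, slope_se = 0.05, SSR = 0.01, R2 = x)),
      median_allele_ratio = med, best = best, knownPloidy = known,
      n_sites = 5000), class = "ploidyFitReport")
  }
  refs <- list(mkRep(2.3, known = "tetraploid"),
               mkRep(2.8, known = "tetraploid"))
  # herbarium-specimen medians 2.4-2.7 all fall inside the 2.3-2.8 band
  for (q in c(2.4, 2.5, 2.7)) {
    call <- callPloidy(mkRep(q), refs)
    expect_true(call$criteria[["median_ratio_within_limits"]])
    expect_equal(call$call, "tetraploid")
  }
  expect_equal(callPloidy(mkRep(2.5), refs)$reference_limits, c(2.3, 2.8))
  # a query with median 1.1 fails the criterion
  lowq <- mkRep(1.1)
  expect_false(callPloidy(lowq, refs)$criteria[["median_ratio_within_limits"]])
  expect_error(callPloidy(mkRep(2.5), list()), "reference")
})

test_that("a diploid query against tetraploid references is called diploid, not ambiguous", {
  sim2 <- simulateAlleleCounts(nSites = 5000, ploidy = 2, seed = 41)
  counts2 <- sim2$counts
  counts2 <- counts2[pmin(counts2$ref_reads, counts2$alt_reads) >= 2 &
                     counts2$ref_reads + counts2$alt_reads >= 10, ]
  q <- ploidyReport(counts2)
  refs <- lapply(c(42, 43), function(s) {
    sim <- simulateAlleleCounts(nSites = 5000, ploidy = 4, seed = s)
    cc <- sim$counts
    cc <- cc[pmin(cc$ref_reads, cc$alt_reads) >= 2 &
             cc$ref_reads + cc$alt_reads >= 10, ]
    r <- ploidyReport(cc, knownPloidy = "tetraploid")
    r
  })
  call <- callPloidy(q, refs)
  expect_equal(q$best, "diploid")
  expect_false(call$criteria[["median_ratio_within_limits"]])
  expect_equal(call$call, "diploid")
})

test_that("simulated tetraploid counts yield a median allele ratio in the plausible band", {
  sim <- simulateAlleleCounts(nSites = 5000, ploidy = 4, meanDepth = 40,
                              dosageProbs = c(0.4, 0.2, 0.4), seed = 1)
  counts <- sim$counts
  counts <- counts[pmin(counts$ref_reads, counts$alt_reads) > 0, ]
  med <- alleleRatioStats(counts)$median
  # plausibility band around the observed tetraploid range, not an exact target
  expect_gt(med, 1.8)
  expect_lt(med, 3.5)
})

test_that("the packaged synthetic site-count fixture loads fully at zero thresholds", {
  f <- system.file("extdata", "site_counts_tetraploid_synthetic.tsv",
                   package = "karyoploid")
  counts <- suppressMessages(loadSiteCounts(f, minCoverage = 0,
                                            minAltReads = 0))
  expect_equal(nrow(counts), 1000L)
  expect_true(all(counts$coverage > 0))
})
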