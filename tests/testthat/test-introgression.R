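test_that("pattern counting matches hand enumeration on the toy matrix", {
  M <- toyQuartetMatrix()
  q <- quartetSpec("P1", "P2", "P3", "O")
  pc <- countPatterns(M, q)
  expect_equal(pc$n_abba, 2)
  expect_equal(pc$n_baba, 1)
  # all-identical sites contribute nothing
  M0 <- matrix(0L, 4, 10, dimnames = list(c("P1", "P2", "P3", "O"), NULL))
  pc0 <- countPatterns(M0, q)
  expect_equal(pc0$n_abba + pc0$n_baba, 0)
  # swapping P1 and P2 exchanges the counts
  pcSwap <- countPatterns(M, quartetSpec("P2", "P1", "P3", "O"))
  expect_equal(pcSwap$n_abba, pc$n_baba)
  expect_equal(pcSwap$n_baba, pc$n_abba)
})

test_that("the D statistic is the normalised ABBA/BABA difference", {
  expect_equal(dStatistic(150, 50), 0.5)
  expect_equal(dStatistic(100, 100), 0)
  expect_equal(dStatistic(0, 50), -1)
  expect_true(is.na(dStatistic(0, 0)))
})

test_that("frequency mode matches the closed-form contributions on a hand table", {
  # three sites with fixed per-population derived frequencies
  p1 <- c(0.2, 0.5, 0.0); p2 <- c(0.8, 0.5, 1.0); p3 <- c(1.0, 0.4, 0.5)
  abba <- sum((1 - p1) * p2 * p3)
  baba <- sum(p1 * (1 - p2) * p3)
  M <- rbind(P1 = p1, P2 = p2, P3 = p3, O = c(0, 0, 0))
  pc <- countPatterns(M, quartetSpec("P1", "P2", "P3", "O"), mode = "freq")
  expect_equal(pc$n_abba, abba)
  expect_equal(pc$n_baba, baba)
  expect_equal(dStatistic(pc$n_abba, pc$n_baba),
               (abba - baba) / (abba + baba))
})

test_that("a polymorphic outgroup site is skipped and counted", {
  M <- rbind(P1 = c(0, 0), P2 = c(1, 1), P3 = c(1, 1), O1 = c(0, 0),
             O2 = c(1, 0))
  q <- quartetSpec("P1", "P2", "P3", c("O1", "O2"))
  pc <- countPatterns(M, q, mode = "binary")
  expect_equal(pc$n_skipped_outgroup, 1)
  expect_equal(pc$n_abba, 1)
})

test_that("antisymmetry: exchanging P1 and P2 negates D exactly", {
  sim <- simulateQuartetSnps(nSites = 5000, gamma = 0.2, seed = 7)
  d1 <- dJackknife(sim$matrix, quartetSpec("P1", "P2", "P3", "O"),
                   blockSize = 200)
  d2 <- dJackknife(sim$matrix, quartetSpec("P2", "P1", "P3", "O"),
                   blockSize = 200)
  expect_equal(d1$D, -d2$D)
})

test_that("the jackknife flags degenerate and undersized inputs", {
  sim <- simulateQuartetSnps(nSites = 2000, seed = 3)
  expect_error(dJackknife(sim$matrix, sim$quartet, blockSize = 1000),
               "smaller block_size")
  # constant D across blocks: every site ABBA -> SE 0, infinite Z
  M <- matrix(rep(c(0L, 1L, 1L, 0L), 4000), nrow = 4,
              dimnames = list(c("P1", "P2", "P3", "O"), NULL))
  r <- dJackknife(M, quartetSpec("P1", "P2", "P3", "O"), blockSize = 100)
  expect_true(r$infiniteZ)
  expect_equal(r$D, 1)
  expect_equal(r$Z, Inf)
})

test_that("strong simulated gene flow is detected as significant", {
  sim <- simulateQuartetSnps(nSites = 20000, gamma = 0.3, seed = 4)
  r <- dJackknife(sim$matrix, sim$quartet, blockSize = 500)
  expect_true(r$significant)
  expect_gt(r$D, 0)
  # empirical D within 3 SE of the generator closed form
  se <- r$D / r$Z
  expect_lt(abs(r$D - sim$truth$expectedD), 3 * se)
})

test_that("the jackknife SE shrinks like one over the square root of the site count", {
  se <- vapply(c(5000, 80000), function(n) {
    mean(vapply(1:3, function(s) {
      sim <- simulateQuartetSnps(nSites = n, gamma = 0.2, seed = 9 + s)
      r <- dJackknife(sim$matrix, sim$quartet, blockSize = 250)
      r$D / r$Z
    }, numeric(1)))
  }, numeric(1))
  # a 16-fold increase in sites should shrink the SE about 4-fold
  expect_gt(se[1] / se[2], 2.5)
  expect_lt(se[1] / se[2], 6)
})

test_that("the quartet table reports one row per quartet", {
  sim <- simulateQuartetSnps(nSites = 10000, gamma = 0.25, seed = 5)
  tab <- dStatTable(sim$matrix,
                    list(quartetSpec("P1", "P2", "P3", "O"),
                         quartetSpec("P2", "P1", "P3", "O")),
                    blockSize = 400)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$D[1], -tab$D[2])
  expect_error(quartetSpec("P1", "P1", "P3", "O"), "distinct")
})
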