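test_that("the partition matches hand-computed set algebra on a small table", {
  # 12 samples, 2 clusters, 20 SNPs with known membership
  samples <- c(paste0("I_", 1:6), paste0("II_", 1:6))
  G <- matrix(0L, nrow = 20, ncol = 12,
              dimnames = list(sprintf("m%02d", 1:20), samples))
  G[1:8, c(1, 7)] <- 1L          # shared: one carrier in each cluster
  G[9:12, 1:3] <- 1L             # unique to I (3 carriers)
  G[13:14, 8:9] <- 1L            # unique to II (2 carriers)
  G[15:17, 4] <- 1L              # singletons in I
  G[18:20, c(2, 3)] <- 1L        # unique to I (2 carriers)
  cl <- data.frame(sample = samples, cluster = rep(c("I", "II"), each = 6))
  p <- partitionSnps(G, cl, nPerCluster = 6, seed = 1)
  expect_setequal(p$shared, sprintf("m%02d", 1:8))
  expect_setequal(p$uniquePerCluster$I, sprintf("m%02d", c(9:12, 18:20)))
  expect_setequal(p$uniquePerCluster$II, c("m13", "m14"))
  expect_setequal(p$singletonsRemoved, c("m15", "m16", "m17"))
  expect_length(p$mixed, 0)
  # set algebra: everything accounted for
  expect_equal(length(p$shared) + sum(lengths(p$uniquePerCluster)) +
               length(p$mixed) + length(p$singletonsRemoved) +
               length(p$absentAfterSubsampling), nrow(G))
})

test_that("identical samples share every non-singleton SNP", {
  G <- matrix(1L, nrow = 5, ncol = 4,
              dimnames = list(paste0("s", 1:5), paste0("x", 1:4)))
  cl <- data.frame(sample = paste0("x", 1:4),
                   cluster = rep(c("I", "II"), each = 2))
  p <- partitionSnps(G, cl, nPerCluster = 2, seed = 1)
  expect_length(p$shared, 5)
  expect_true(all(lengths(p$uniquePerCluster) == 0))
})

test_that("subsampling is deterministic and cluster relabeling permutes unique sets", {
  sim <- makeClusterGenotypes(nShared = 30, nUnique = c(I = 8, II = 4),
                              nSingletons = 2, samplesPerCluster = 8,
                              seed = 5)
  p1 <- partitionSnps(sim$genotypes, sim$clusters, nPerCluster = 6, seed = 9)
  p2 <- partitionSnps(sim$genotypes, sim$clusters, nPerCluster = 6, seed = 9)
  expect_identical(p1$subsample, p2$subsample)
  expect_identical(p1$counts, p2$counts)
  # relabel clusters: unique sets permute, shared is unchanged
  relab <- sim$clusters
  relab$cluster <- ifelse(relab$cluster == "I", "II", "I")
  p3 <- partitionSnps(sim$genotypes, relab, nPerCluster = 6, seed = 9)
  expect_setequal(p3$shared, p1$shared)
  expect_setequal(p3$uniquePerCluster$II, p1$uniquePerCluster$I)
  expect_setequal(p3$uniquePerCluster$I, p1$uniquePerCluster$II)
})

test_that("undersized clusters and admixed samples are handled", {
  sim <- makeClusterGenotypes(samplesPerCluster = 4, seed = 2)
  expect_error(partitionSnps(sim$genotypes, sim$clusters, nPerCluster = 6),
               "fewer than")
  cl <- sim$clusters
  cl$admixture <- c(0.5, rep(0, nrow(cl) - 1))
  cl$admixed <- cl$admixture > 0.1
  expect_error(partitionSnps(sim$genotypes, cl, nPerCluster = 4),
               "fewer than")
})

test_that("constructed partitions are recovered exactly from generated genotypes", {
  p <- makeClusterGenotypes(nShared = 50, nUnique = c(I = 10, II = 5),
                            nSingletons = 3, samplesPerCluster = 6, seed = 1)
  res <- partitionSnps(p$genotypes, p$clusters, nPerCluster = 6, seed = 1)
  expect_setequal(res$shared, p$truth$shared)
  expect_setequal(res$uniquePerCluster$I, p$truth$uniquePerCluster$I)
  expect_setequal(res$uniquePerCluster$II, p$truth$uniquePerCluster$II)
  expect_setequal(res$singletonsRemoved, p$truth$singletons)
})

test_that("gene placement follows blocks onto chromosomes with rearrangement flags", {
  cp <- replayScenario(catolobusScenario())
  post <- applyWGD(buildACK())
  tab <- data.frame(gene = c("g1", "g2", "g3"),
                    block = c("D", "U", "B"), stringsAsFactors = FALSE)
  res <- placeOnBlocks(c("g1", "g2", "g3", "g4"), tab, cp, reference = post)
  # block D sits on the two unrearranged AK2 homeologs
  d <- res$placements[res$placements$gene == "g1", ]
  expect_setequal(d$chromosome, c("AK2a", "AK2b"))
  expect_true(all(!d$rearranged))
  # block U sits on AK7a (unrearranged) and Cp14 (rearranged)
  u <- res$placements[res$placements$gene == "g2", ]
  expect_true("Cp14" %in% u$chromosome)
  expect_true(u$rearranged[u$chromosome == "Cp14"])
  expect_false(all(u$rearranged))
  expect_equal(res$unplaced, "g4")
  # empty input gives an empty placement
  empty <- placeOnBlocks(character(0), tab, cp)
  expect_equal(nrow(empty$placements), 0L)
})

test_that("the packaged synthetic gene-block table reads and places genes", {
  f <- system.file("extdata", "gene_blocks_synthetic.tsv",
                   package = "karyoploid")
  tab <- readGeneBlockTable(f)
  expect_setequal(tab$block, genomicBlocks())
  res <- placeOnBlocks("gene011", tab, catolobusKaryotype())
  expect_setequal(res$placements$chromosome, c("Cp6", "Cp15"))
})
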