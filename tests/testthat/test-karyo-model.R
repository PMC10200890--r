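test_that("the ACK complement has 8 chromosomes carrying the 22 blocks once", {
  ack <- buildACK()
  expect_equal(complementSize(ack), 8L)
  expect_equal(diploidNumber(ack), 16L)
  segs <- do.call(rbind, lapply(chromosomes(ack), function(ch) ch@segments))
  expect_setequal(segs$block, genomicBlocks())
  expect_equal(nrow(segs), 22L)
  expect_true(all(segs$copy == 1L))
  # AK5 carries (K-L) and (M-N) on opposite sides of the centromere
  ak5 <- getChromosome(ack, "AK5")
  expect_equal(ak5@segments$block, c("K-L", "M-N"))
  expect_equal(ak5@centromere, 1L)
})

test_that("a malformed ACK table raises a configuration error", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("chromosome\tarm\tblocks", "AK1\tupper\tA,B", "AK1\tlower\tC"),
             bad)
  expect_error(buildACK(bad), "configuration error")
})

test_that("whole-genome duplication doubles the complement and block copies", {
  post <- postWgdAck()
  expect_equal(complementSize(post), 16L)
  expect_equal(diploidNumber(post), 32L)
  segs <- do.call(rbind, lapply(chromosomes(post), function(ch) ch@segments))
  for (b in genomicBlocks())
    expect_equal(sort(segs$copy[segs$block == b]), c(1L, 2L))
  expect_error(applyWGD(post), "polyploid")
  # a duplicated toy gives two chromosomes differing only in copy index
  toy2 <- applyWGD(toyKaryotype())
  a <- getChromosome(toy2, "T1a")@segments
  b <- getChromosome(toy2, "T1b")@segments
  expect_equal(a$block, b$block)
  expect_equal(a$strand, b$strand)
  expect_equal(unique(b$copy), 2L)
})

test_that("the AK5b/AK7b end-to-end translocation reproduces the fusion chromosome", {
  post <- postWgdAck()
  k <- applyEET(post, "AK7b", "head", "AK5b", "head", keep = "AK5b")
  expect_equal(complementSize(k), 15L)
  expect_equal(diploidNumber(k), 30L)
  fus <- formatKaryotype(k)[["AK7b+AK5b"]]
  expect_equal(fus, "U- T- S- (K-L)+ CEN (M-N)+")
  expect_match(getChromosome(k, "AK7b+AK5b")@history,
               "centromere of AK7b eliminated", all = FALSE)
  # content conserved
  expect_equal(blockCoverage(k), blockCoverage(post))
})

test_that("EET is symmetric under operand order with mirrored ends", {
  toy <- toyKaryotype()
  k1 <- applyEET(toy, "T1", "tail", "T2", "head", keep = "T1")
  k2 <- applyEET(toy, "T2", "head", "T1", "tail", keep = "T1")
  expect_true(karyotypeEqual(k1, k2))
  expect_error(applyEET(toy, "T1", "tail", "T2", "head", keep = "T9"),
               "keep")
})

test_that("the reciprocal translocation produces Cp15 and U+Fb+G+H", {
  post <- postWgdAck()
  k <- applyEET(post, "AK7b", "head", "AK5b", "head", keep = "AK5b",
                name = "fus")
  k2 <- applyReciprocalTranslocation(k,
          breakpoint("AK3b", segment = 1, fraction = 0.5),
          breakpoint("fus", after = 1),
          names = c("preCp14", "Cp15"))
  f <- formatKaryotype(k2)
  expect_equal(f[["Cp15"]], "Fa+ T- S- (K-L)+ CEN (M-N)+")
  expect_equal(f[["preCp14"]], "U- Fb+ CEN G+ H+")
  # argument-order symmetry
  k2b <- applyReciprocalTranslocation(k,
           breakpoint("fus", after = 1),
           breakpoint("AK3b", segment = 1, fraction = 0.5))
  expect_true(karyotypeEqual(k2, k2b))
  expect_equal(blockCoverage(k2), blockCoverage(post))
})

test_that("a reciprocal translocation with empty distal fragments is the identity", {
  post <- postWgdAck()
  k <- applyReciprocalTranslocation(post,
         breakpoint("AK2a", after = 0),
         breakpoint("AK4a", after = 0))
  expect_true(karyotypeEqual(k, post, mode = "exact"))
})

test_that("the unequal translocation produces Cp12 and Cp13", {
  post <- postWgdAck()
  k <- applyUnequalTranslocation(post,
         breakpoint("AK1b", segment = 1, fraction = 0.5),
         target = "AK6b", targetEnd = "head",
         names = c("Cp12", "Cp13"))
  f <- formatKaryotype(k)
  expect_equal(f[["Cp12"]], "Ab+ B+ CEN C+")
  expect_equal(f[["Cp13"]], "Aa+ O+ P+ CEN Q+ R+")
  expect_equal(blockCoverage(k), blockCoverage(post))
  # empty donated fragment (breakpoint at the terminus) is the identity
  kid <- applyUnequalTranslocation(post, breakpoint("AK1b", after = 0),
                                   target = "AK6b", targetEnd = "head")
  expect_true(karyotypeEqual(kid, post, mode = "exact"))
})

test_that("donation to head or tail of a palindromic target gives the same canonical product", {
  # palindromic toy target: D | cen | D would need two D blocks; use a target
  # whose canonical form is reversal-symmetric at block-label level
  ack <- buildACK()
  kh <- applyUnequalTranslocation(ack, breakpoint("AK1", segment = 1),
                                  target = "AK4", targetEnd = "head")
  kt <- applyUnequalTranslocation(ack, breakpoint("AK1", segment = 1),
                                  target = "AK4", targetEnd = "tail")
  # AK4 = I | cen | J is not palindromic, so head vs tail differ ...
  expect_false(karyotypeEqual(kh, kt))
  # ... but each product carries the same merged block content
  expect_equal(blockCoverage(kh), blockCoverage(kt))
})

test_that("pericentric inversions reproduce Cp14 and Cp11 and are involutions", {
  post <- postWgdAck()
  k <- applyEET(post, "AK7b", "head", "AK5b", "head", keep = "AK5b",
                name = "fus")
  k <- applyReciprocalTranslocation(k,
         breakpoint("AK3b", segment = 1, fraction = 0.5),
         breakpoint("fus", after = 1), names = c("pre14", "Cp15"))
  k2 <- applyPericentricInversion(k,
          breakpoint("pre14", segment = 2, fraction = 0.5),
          breakpoint("pre14", segment = 4, fraction = 0.5), name = "Cp14")
  expect_equal(formatKaryotype(k2)[["Cp14"]], "U- Fb+ Ha- G- CEN Fc- Hb+")
  # Cp11 from AK1a
  k3 <- applyPericentricInversion(post,
          breakpoint("AK1a", segment = 1, fraction = 0.5),
          breakpoint("AK1a", segment = 3, fraction = 0.5), name = "Cp11")
  expect_equal(formatKaryotype(k3)[["Cp11"]], "Aa+ Ca- CEN B- Ab- Cb+")
  # involution: applying the same cuts again restores the original
  k4 <- applyPericentricInversion(k3,
          breakpoint("Cp11", after = 1),
          breakpoint("Cp11", after = 4), name = "AK1a")
  expect_true(karyotypeEqual(k4, post))
  # breakpoints on one side of the centromere are rejected
  expect_error(applyPericentricInversion(post,
                 breakpoint("AK6a", after = 1), breakpoint("AK6a", after = 2)),
               "not pericentric")
})

test_that("canonical form is reversal-invariant and orientation-sensitive", {
  ack <- buildACK()
  ch <- getChromosome(ack, "AK6")
  rev_ <- karyoploid:::reverseChromosome(ch)
  expect_equal(canonicalForm(ch), canonicalForm(rev_))
  # flipping one internal segment's orientation changes the canonical form
  ch2 <- ch
  ch2@segments$strand[2] <- "-"
  expect_false(canonicalForm(ch2) == canonicalForm(ch))
  # all orientation patterns of a 3-segment toy fall into distinct canonical
  # classes except reversal-symmetric pairs
  pats <- expand.grid(s1 = c("+", "-"), s2 = c("+", "-"), s3 = c("+", "-"),
                      stringsAsFactors = FALSE)
  forms <- apply(pats, 1, function(p) {
    segs <- rbind(segRowT("O", strand = p[1]), segRowT("P", strand = p[2]),
                  segRowT("Q", strand = p[3]))
    canonicalForm(new("Chromosome", name = "t", segments = segs,
                      centromere = 1L, history = character(0)))
  })
  expect_equal(length(unique(forms)), 8L)  # O|PQ layout breaks all symmetry
})

test_that("the full scenario replays to the painted Cp karyotype", {
  post <- postWgdAck()
  sc <- catolobusScenario()
  kinds <- vapply(events(sc), function(e) e@kind, character(1))
  expect_equal(sort(kinds), sort(c("WGD", "EET", "RECIP_TRANSLOC",
                                   "PERI_INV", "PERI_INV", "UNEQ_TRANSLOC")))
  res <- replayScenario(sc, snapshots = TRUE)
  expect_equal(complementSize(res$snapshots[[1]]), 16L)
  expect_equal(complementSize(res$snapshots[[2]]), 15L)
  expect_equal(complementSize(res$final), 15L)
  expect_true(karyotypeEqual(res$final, catolobusKaryotype()))
  f <- formatKaryotype(res$final)
  expect_equal(f[["Cp15"]], "Fa+ T- S- (K-L)+ CEN (M-N)+")
  expect_equal(f[["Cp14"]], "U- Fb+ Ha- G- CEN Fc- Hb+")
  expect_equal(f[["Cp11"]], "Aa+ Ca- CEN B- Ab- Cb+")
  expect_equal(f[["Cp12"]], "Ab+ B+ CEN C+")
  expect_equal(f[["Cp13"]], "Aa+ O+ P+ CEN Q+ R+")
  # replay determinism: byte-identical serialization
  f1 <- tempfile(); f2 <- tempfile()
  writeKaryotype(replayScenario(sc), f1)
  writeKaryotype(replayScenario(sc), f2)
  expect_identical(readLines(f1), readLines(f2))
  # empty scenario returns the start
  empty <- new("Scenario", events = list(), start = "ACK")
  expect_true(karyotypeEqual(replayScenario(empty), buildACK(),
                             mode = "exact"))
  # truncated scenario (WGD + EET only) keeps the unrearranged fusion
  trunc <- new("Scenario", events = events(sc)[1:2], start = "ACK")
  kt <- replayScenario(trunc)
  expect_equal(complementSize(kt), 15L)
  expect_true("U- T- S- (K-L)+ CEN (M-N)+" %in% formatKaryotype(kt))
})

test_that("operator errors propagate with the failing step index", {
  bad <- new("Scenario", events = list(
    karyoploid:::rearrangementEvent("EET", params = list(
      chrA = "nope", endA = "head", chrB = "AK1", endB = "head",
      keep = "AK1"))), start = "ACK")
  expect_error(replayScenario(bad), "step 1")
})

test_that("summarize reports placements, copy numbers and affected chromosomes", {
  post <- postWgdAck()
  cp <- replayScenario(catolobusScenario())
  s <- summarizeKaryotype(cp, post)
  expect_equal(s$n, 15L)
  expect_equal(s$diploidNumber, 30L)
  expect_equal(s$placements, 44L)
  expect_equal(s$blocksAtCopyTwo, 22L)
  expect_equal(unname(s$blockCopyNumber), rep(2L, 22))
  expect_equal(s$affected, 6L)
  expect_equal(summarizeKaryotype(cp, cp)$affected, 0L)
  # ten of the fifteen chromosomes mirror ancestral structure
  refPool <- canonicalStrings(post)
  mirrored <- sum(canonicalStrings(cp) %in% refPool)
  expect_equal(mirrored, 10L)
})

test_that("block content is conserved along the whole scenario (WGD doubles it)", {
  ack <- buildACK()
  cov0 <- blockCoverage(ack)
  res <- replayScenario(catolobusScenario(), snapshots = TRUE)
  covW <- blockCoverage(res$snapshots[[1]])
  expect_equal(nrow(covW), 2L * nrow(cov0))
  for (i in seq(2, length(res$snapshots)))
    expect_equal(blockCoverage(res$snapshots[[i]]), covW)
})

test_that("the population-20 private inversion applies on top of the canonical karyotype", {
  cp <- replayScenario(catolobusScenario())
  cp@name <- "Catolobus"
  k <- replayScenario(population20Inversion(), start = cp)
  expect_equal(complementSize(k), 15L)
  expect_false(karyotypeEqual(k, cp))
  expect_equal(blockCoverage(k), blockCoverage(cp))
})
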