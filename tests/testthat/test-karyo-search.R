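test_that("distance zero holds exactly for copy-blind equal karyotypes", {
  ack <- buildACK()
  r <- searchScenarios(ack, ack, maxDepth = 1)
  expect_equal(r$distance, 0L)
  expect_length(events(r$scenarios[[1]]), 0L)
  # copy-blind: the post-WGD complement equals itself with copies swapped
  post <- applyWGD(ack)
  expect_equal(searchScenarios(post, post, maxDepth = 1)$distance, 0L)
})

test_that("single events of every kind are recovered at distance one", {
  ack <- buildACK()
  cases <- list(
    applyPericentricInversion(ack, breakpoint("AK1", segment = 1),
                              breakpoint("AK1", segment = 3)),
    applyReciprocalTranslocation(ack, breakpoint("AK2", after = 1),
                                 breakpoint("AK4", after = 1)),
    applyEET(ack, "AK7", "head", "AK5", "head", keep = "AK5"),
    applyUnequalTranslocation(ack, breakpoint("AK1", segment = 1),
                              target = "AK6", targetEnd = "head"))
  for (target in cases) {
    r <- searchScenarios(ack, target, maxDepth = 2)
    expect_equal(r$distance, 1L)
    for (s in r$scenarios)
      expect_true(karyotypeEqual(replayScenario(s, ack), target))
  }
})

test_that("an unreachable target within the depth bound is reported, not silent", {
  ack <- buildACK()
  k <- ack
  k <- applyPericentricInversion(k, breakpoint("AK1", segment = 1),
                                 breakpoint("AK1", segment = 3))
  k <- applyPericentricInversion(k, breakpoint("AK3", segment = 1),
                                 breakpoint("AK3", segment = 3))
  r <- searchScenarios(ack, k, maxDepth = 1)
  expect_false(r$found)
  expect_true(is.na(r$distance))
  expect_match(r$message, "not found")
})

test_that("restricting the operator set excludes scenarios using other operators", {
  ack <- buildACK()
  k <- applyEET(ack, "AK7", "head", "AK5", "head", keep = "AK5")
  r <- searchScenarios(ack, k, maxDepth = 1,
                       ops = c("RECIP_TRANSLOC", "PERI_INV"))
  expect_false(r$found)
  r2 <- searchScenarios(ack, k, maxDepth = 1, ops = "EET")
  expect_equal(r2$distance, 1L)
})

test_that("seeded random scenarios of up to three events are recovered at distance <= k", {
  ack <- buildACK()
  for (seed in 1:10) {
    k <- ((seed - 1L) %% 3L) + 1L
    rs <- randomScenario(k = k, start = ack, seed = seed)
    r <- searchScenarios(ack, rs$karyotype, maxDepth = k)
    expect_true(r$found, label = sprintf("seed %d (k = %d) found", seed, k))
    expect_lte(r$distance, k)
    # soundness: every returned scenario replays to the target
    for (s in r$scenarios)
      expect_true(karyotypeEqual(replayScenario(s, ack), rs$karyotype),
                  label = sprintf("seed %d replay", seed))
  }
})

test_that("the targeted move generator matches exhaustive junction enumeration", {
  ## brute-force oracle: enumerate every possible cut pair / inversion / EET,
  ## compute the junction adjacencies it would create, and keep those making
  ## at least one missing target adjacency; the guided scanner must emit
  ## exactly the same move set
  ns <- asNamespace("karyoploid")
  ack <- buildACK()
  targets <- list(
    applyReciprocalTranslocation(
      applyPericentricInversion(ack, breakpoint("AK1", segment = 1),
                                breakpoint("AK1", segment = 3)),
      breakpoint("AK3", after = 1), breakpoint("AK6", after = 1)),
    applyEET(ack, "AK2", "tail", "AK8", "head", keep = "AK8"))
  for (target in targets) {
    cuts <- impliedBreakpoints(target)
    cutsS <- impliedBreakpoints(ack)
    for (b in names(cutsS)) cuts[[b]] <- sort(unique(c(cuts[[b]], cutsS[[b]])))
    state <- ns$tokenizeKaryotype(ack, cuts)
    tgtState <- ns$tokenizeKaryotype(target, cuts)
    missing <- ns$missingAdjacencies(ns$stateAdjacencies(tgtState),
                                     ns$stateAdjacencies(state))
    missingSet <- unique(missing)
    needEET <- length(state) - length(tgtState)
    ops <- c("EET", "RECIP_TRANSLOC", "UNEQ_TRANSLOC", "PERI_INV")
    got <- ns$generateMoves(state, missingSet, ops, needEET)
    keyOf <- function(mv) {
      if (mv$kind %in% c("RECIP_TRANSLOC", "UNEQ_TRANSLOC")) {
        a <- c(mv$i, mv$gA, mv$cenHeadA); b <- c(mv$j, mv$gB, mv$cenHeadB)
        if (mv$i > mv$j) { tmp <- a; a <- b; b <- tmp }
        paste("T", paste(a, collapse = ","), paste(b, collapse = ","))
      } else if (mv$kind == "PERI_INV") paste("I", mv$i, mv$g1, mv$g2)
      else {
        i <- mv$i; j <- mv$j; ea <- mv$endA; eb <- mv$endB; kp <- mv$keep
        if (i > j) { tmp <- i; i <- j; j <- tmp
                     tmp <- ea; ea <- eb; eb <- tmp; kp <- 3L - kp }
        paste("E", i, ea, j, eb, kp)
      }
    }
    want <- character(0)
    nC <- length(state)
    for (i in seq_len(nC - 1L)) for (j in seq(i + 1L, nC)) {
      tcA <- state[[i]]; tcB <- state[[j]]
      for (gA in 0:length(tcA$t)) for (gB in 0:length(tcB$t)) {
        termA <- gA %in% c(0L, length(tcA$t))
        termB <- gB %in% c(0L, length(tcB$t))
        if (termA && termB) next
        for (ca in (if (gA == tcA$cen) c(FALSE, TRUE) else FALSE))
          for (cb in (if (gB == tcB$cen) c(FALSE, TRUE) else FALSE)) {
            jn <- ns$recipJunctions(tcA, gA, tcB, gB, ca, cb)
            if (any(jn %in% missingSet))
              want <- c(want, keyOf(list(kind = "RECIP_TRANSLOC", i = i,
                                         gA = gA, cenHeadA = ca, j = j,
                                         gB = gB, cenHeadB = cb)))
          }
      }
      if (needEET > 0L)
        for (ea in c("head", "tail")) for (eb in c("head", "tail"))
          for (kp in 1:2) {
            jn <- ns$eetJunctions(tcA, ea, tcB, eb, kp)
            if (any(jn %in% missingSet))
              want <- c(want, keyOf(list(kind = "EET", i = i, endA = ea,
                                         j = j, endB = eb, keep = kp)))
          }
    }
    for (i in seq_len(nC)) {
      tc <- state[[i]]
      for (g1 in 0:(tc$cen - 1L)) for (g2 in (tc$cen + 1L):length(tc$t)) {
        if (g1 == 0L && g2 == length(tc$t)) next
        jn <- ns$invJunctions(tc, g1, g2)
        if (length(jn) && any(jn %in% missingSet))
          want <- c(want, keyOf(list(kind = "PERI_INV", i = i,
                                     g1 = g1, g2 = g2)))
      }
    }
    expect_setequal(vapply(got, keyOf, character(1)), unique(want))
  }
})
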