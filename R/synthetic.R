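## Seeded synthetic-data generators emulating the statistical structure each
## pipeline stage assumes: read counts over biallelic sites at a chosen
## ploidy, quartet SNP matrices with a tunable introgression fraction,
## multi-cluster genotype tables with controlled shared/unique/singleton
## counts, and random rearrangement scenarios applied to a karyotype.

#' Simulate biallelic site read counts at a chosen ploidy
#'
#' Per site, an allele dosage d is drawn from \code{dosageProbs} over
#' 1..(ploidy-1), the total depth from a negative binomial (capture data are
#' overdispersed relative to Poisson), and the alternate read count from a
#' binomial with success probability
#' \eqn{p = (d/ploidy)(1-e) + (1 - d/ploidy) e}
#' (the base error shrinks frequencies symmetrically). The truth record
#' stores the generating ploidy and per-site dosages. Output is fully
#' determined by the seed.
#'
#' @param nSites Number of sites (default 5000).
#' @param ploidy 2, 3 or 4.
#' @param dosageProbs Probabilities over dosages 1..(ploidy-1); default
#'   uniform except tetraploid, which uses 0.4/0.2/0.4 for 1:3 / 2:2 / 3:1
#'   (balanced heterozygous dosages are rarer than unbalanced ones in
#'   autotetraploids sampled at random loci).
#' @param meanDepth Mean sequencing depth (default 40).
#' @param dispersion Negative-binomial size parameter (default 5).
#' @param baseError Symmetric base error rate (default 0.01).
#' @param seed Integer seed.
#' @return list(counts = data.frame(site_id, ref_reads, alt_reads),
#'   truth = list(ploidy, dosages, config)).
#' @export
simulateAlleleCounts <- function(nSites = 5000L, ploidy = 4L,
                                 dosageProbs = NULL, meanDepth = 40,
                                 dispersion = 5, baseError = 0.01,
                                 seed = 1L) {
  if (!ploidy %in% 2:4) stop("ploidy must be 2, 3 or 4")
  if (meanDepth <= 0 || dispersion <= 0)
    stop("degenerate depth parameters: meanDepth and dispersion must be positive")
  if (is.null(dosageProbs))
    dosageProbs <- if (ploidy == 4L) c(0.4, 0.2, 0.4)
                   else rep(1 / (ploidy - 1), ploidy - 1)
  if (length(dosageProbs) != ploidy - 1L || any(dosageProbs < 0) ||
      abs(sum(dosageProbs) - 1) > 1e-8)
    stop("dosageProbs must be a probability vector over dosages 1..(ploidy-1)")
  set.seed(seed)
  dos <- sample(seq_len(ploidy - 1L), nSites, replace = TRUE,
                prob = dosageProbs)
  depth <- rnbinom(nSites, size = dispersion, mu = meanDepth)
  depth[depth < 1L] <- 1L
  pRaw <- dos / ploidy
  pEff <- pRaw * (1 - baseError) + (1 - pRaw) * baseError
  alt <- rbinom(nSites, depth, pEff)
  counts <- data.frame(site_id = sprintf("site%05d", seq_len(nSites)),
                       ref_reads = depth - alt, alt_reads = alt,
                       stringsAsFactors = FALSE)
  list(counts = counts,
       truth = list(ploidy = ploidy, dosages = dos,
                    config = list(nSites = nSites, ploidy = ploidy,
                                  dosageProbs = dosageProbs,
                                  meanDepth = meanDepth,
                                  dispersion = dispersion,
                                  baseError = baseError, seed = seed)))
}

#' Write site counts to the TSV format consumed upstream
#'
#' @param counts data.frame(site_id, ref_reads, alt_reads).
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeSiteCounts <- function(counts, path) {
  write.table(counts[, c("site_id", "ref_reads", "alt_reads")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a quartet SNP matrix with tunable introgression
#'
#' A site-pattern multinomial (not a coalescent): with probability g a site
#' is phylogenetically informative for the quartet and is ABBA with
#' probability \eqn{(b + \gamma)/(2b + \gamma)} or BABA with probability
#' \eqn{b/(2b + \gamma)}; the introgression fraction \eqn{\gamma} shifts mass
#' towards ABBA, giving the closed-form expectation
#' \eqn{E[D] = \gamma / (2b + \gamma)}, which is stored in the truth record.
#' Non-informative sites are split between the concordant BBAA pattern and
#' monomorphic sites.
#'
#' @param nSites Number of sites (default 20000).
#' @param b Baseline incomplete-lineage-sorting weight shared by ABBA and
#'   BABA (default 0.1).
#' @param g Fraction of informative (ABBA/BABA) sites (default 0.3).
#' @param gamma Introgression fraction >= 0 (default 0; no gene flow).
#' @param seed Integer seed.
#' @return list(matrix = 4 x nSites 0/1 matrix with rows P1, P2, P3, O;
#'   quartet = \code{\link{quartetSpec}}; truth = list(expectedD, config)).
#' @export
simulateQuartetSnps <- function(nSites = 20000L, b = 0.1, g = 0.3,
                                gamma = 0, seed = 1L) {
  if (b <= 0 || g <= 0 || g > 1 || gamma < 0)
    stop("need b > 0, 0 < g <= 1 and gamma >= 0")
  set.seed(seed)
  pABBA <- g * (b + gamma) / (2 * b + gamma)
  pBABA <- g * b / (2 * b + gamma)
  pBBAA <- (1 - g) * 0.5
  pMono <- 1 - pABBA - pBABA - pBBAA
  cat_ <- sample(c("ABBA", "BABA", "BBAA", "MONO"), nSites, replace = TRUE,
                 prob = c(pABBA, pBABA, pBBAA, pMono))
  M <- matrix(0L, nrow = 4, ncol = nSites,
              dimnames = list(c("P1", "P2", "P3", "O"), NULL))
  M[, cat_ == "ABBA"] <- c(0L, 1L, 1L, 0L)
  M[, cat_ == "BABA"] <- c(1L, 0L, 1L, 0L)
  M[, cat_ == "BBAA"] <- c(1L, 1L, 0L, 0L)
  list(matrix = M,
       quartet = quartetSpec("P1", "P2", "P3", "O"),
       truth = list(expectedD = gamma / (2 * b + gamma),
                    config = list(nSites = nSites, b = b, g = g,
                                  gamma = gamma, seed = seed)))
}

#' Simulate a multi-cluster genotype table with controlled SNP structure
#'
#' Constructs a presence/absence genotype matrix containing exactly the
#' requested numbers of shared SNPs (alternate allele in at least one member
#' of every cluster), cluster-unique SNPs (at least two carriers, all in one
#' cluster, so they survive singleton filtering), and singletons (exactly one
#' carrier overall). The truth record holds the expected partition, which
#' \code{\link{partitionSnps}} recovers exactly when subsampling uses the
#' full clusters.
#'
#' @param nShared Number of shared SNPs (default 50).
#' @param nUnique Named integer vector: unique SNPs per cluster (default
#'   c(I = 10, II = 5)).
#' @param nSingletons Number of singleton SNPs (default 3).
#' @param samplesPerCluster Samples per cluster (default 6; must be >= 2 so
#'   unique SNPs can have two carriers).
#' @param seed Integer seed.
#' @return list(genotypes = SNP x sample 0/1 matrix, clusters = data.frame
#'   (sample, cluster, admixture), truth = list(shared, uniquePerCluster,
#'   singletons)).
#' @export
makeClusterGenotypes <- function(nShared = 50L, nUnique = c(I = 10L, II = 5L),
                                 nSingletons = 3L, samplesPerCluster = 6L,
                                 seed = 1L) {
  if (is.null(names(nUnique)) || any(!nzchar(names(nUnique))))
    stop("nUnique must be a named vector (one entry per cluster)")
  if (length(nUnique) < 2L) stop("at least two clusters are required")
  if (samplesPerCluster < 2L)
    stop("inconsistent request: unique SNPs need >= 2 carriers per cluster")
  labs <- names(nUnique)
  set.seed(seed)
  samples <- unlist(lapply(labs, function(cl)
    sprintf("%s_s%d", cl, seq_len(samplesPerCluster))))
  clusterOf <- rep(labs, each = samplesPerCluster)
  nSnp <- nShared + sum(nUnique) + nSingletons
  ids <- c(if (nShared) sprintf("shared%04d", seq_len(nShared)),
           unlist(lapply(labs, function(cl) {
             n <- nUnique[[cl]]
             if (n) sprintf("unique_%s_%04d", cl, seq_len(n)) else character(0)
           })),
           if (nSingletons) sprintf("singleton%04d", seq_len(nSingletons)))
  G <- matrix(0L, nrow = nSnp, ncol = length(samples),
              dimnames = list(ids, samples))
  for (i in seq_len(nShared)) {
    for (cl in labs) {
      members <- which(clusterOf == cl)
      nCar <- sample(seq_along(members), 1)
      G[i, sample(members, nCar)] <- 1L
    }
  }
  off <- nShared
  for (cl in labs) {
    members <- which(clusterOf == cl)
    for (i in seq_len(nUnique[[cl]])) {
      nCar <- sample(2:length(members), 1)
      G[off + i, sample(members, nCar)] <- 1L
    }
    off <- off + nUnique[[cl]]
  }
  for (i in seq_len(nSingletons))
    G[off + i, sample(length(samples), 1)] <- 1L
  clusters <- data.frame(sample = samples, cluster = clusterOf,
                         admixture = 0, stringsAsFactors = FALSE)
  list(genotypes = G, clusters = clusters,
       truth = list(shared = ids[seq_len(nShared)],
                    uniquePerCluster = stats::setNames(
                      lapply(labs, function(cl)
                        ids[grepl(paste0("^unique_", cl, "_"), ids)]), labs),
                    singletons = ids[grepl("^singleton", ids)],
                    config = list(nShared = nShared, nUnique = nUnique,
                                  nSingletons = nSingletons,
                                  samplesPerCluster = samplesPerCluster,
                                  seed = seed)))
}

#' Apply a random rearrangement scenario to a karyotype
#'
#' Draws k random valid events (rejection-sampling events that would error or
#' leave the karyotype unchanged) and applies them sequentially. Used to test
#' that the parsimony search recovers scenarios of known length.
#'
#' @param k Number of events (>= 0).
#' @param start Start \code{\linkS4class{Karyotype}} (default
#'   \code{\link{buildACK}()}).
#' @param ops Allowed event kinds (WGD excluded).
#' @param seed Integer seed.
#' @param maxReject Rejection budget per event (default 1000).
#' @return list(scenario = \code{\linkS4class{Scenario}},
#'   karyotype = resulting \code{\linkS4class{Karyotype}}).
#' @export
randomScenario <- function(k = 3L, start = buildACK(),
                           ops = c("EET", "RECIP_TRANSLOC",
                                   "UNEQ_TRANSLOC", "PERI_INV"),
                           seed = 1L, maxReject = 1000L) {
  ops <- match.arg(ops, eventKinds(), several.ok = TRUE)
  set.seed(seed)
  cur <- start
  evs <- list()
  randomBp <- function(ch, lo, hi) {
    # a random cut strictly inside gap range [lo, hi]; 30% within-segment
    if (runif(1) < 0.3) {
      segs <- seq.int(max(1L, lo + 1L), min(nrow(ch@segments), hi))
      breakpoint(ch@name, segment = sample(segs, 1),
                 fraction = round(runif(1, 0.2, 0.8), 3))
    } else {
      breakpoint(ch@name, after = sample(seq.int(lo, hi), 1))
    }
  }
  for (i in seq_len(k)) {
    done <- FALSE
    for (try_ in seq_len(maxReject)) {
      kind <- sample(ops, 1)
      nms <- chromosomeNames(cur)
      ev <- tryCatch({
        if (kind == "EET") {
          if (length(nms) < 2L) stop("too few chromosomes")
          pair <- sample(nms, 2)
          rearrangementEvent("EET", params = list(
            chrA = pair[1], endA = sample(c("head", "tail"), 1),
            chrB = pair[2], endB = sample(c("head", "tail"), 1),
            keep = sample(pair, 1)))
        } else if (kind == "RECIP_TRANSLOC") {
          pair <- sample(nms, 2)
          c1 <- getChromosome(cur, pair[1]); c2 <- getChromosome(cur, pair[2])
          rearrangementEvent("RECIP_TRANSLOC", params = list(
            bp1 = randomBp(c1, 1L, nrow(c1@segments) - 1L),
            bp2 = randomBp(c2, 1L, nrow(c2@segments) - 1L)))
        } else if (kind == "UNEQ_TRANSLOC") {
          pair <- sample(nms, 2)
          c1 <- getChromosome(cur, pair[1])
          rearrangementEvent("UNEQ_TRANSLOC", params = list(
            bp = randomBp(c1, 1L, nrow(c1@segments) - 1L),
            target = pair[2], targetEnd = sample(c("head", "tail"), 1)))
        } else {
          nm <- sample(nms, 1)
          ch <- getChromosome(cur, nm)
          rearrangementEvent("PERI_INV", params = list(
            bpL = randomBp(ch, 0L, ch@centromere - 1L),
            bpR = randomBp(ch, ch@centromere + 1L, nrow(ch@segments))))
        }
      }, error = function(e) NULL)
      if (is.null(ev)) next
      nxt <- tryCatch(applyEvent(cur, ev), error = function(e) NULL)
      if (is.null(nxt)) next
      if (karyotypeEqual(nxt, cur)) next  # no-op events are rejected
      cur <- nxt
      evs[[length(evs) + 1L]] <- ev
      done <- TRUE
      break
    }
    if (!done)
      stop(sprintf("could not place a valid event after %d rejections at step %d",
                   maxReject, i))
  }
  list(scenario = new("Scenario", events = evs,
                      start = if (is.na(start@name)) "start" else start@name),
       karyotype = cur)
}
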