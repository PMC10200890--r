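## Formats, configuration and the umbrella pipeline tying the stages together
## in the analysis order: karyotype replay/summary, ploidy inference,
## D-statistics, SNP partitioning.

#' Minimal VCF reader for biallelic SNP records
#'
#' Streams biallelic SNP records (single-base REF and ALT) from a VCF 4.x
#' file (plain or gzipped), preserving contig/position order (relevant for
#' jackknife blocks). Multiallelic and non-SNP records are skipped and
#' counted. Positions are 1-based as in VCF.
#'
#' @param path VCF file path.
#' @param requireFields FORMAT fields the caller needs (e.g. \code{"AD"},
#'   \code{"GT"}); a missing field raises an error naming it.
#' @return list(sites = data.frame(CHROM, POS, ID, REF, ALT),
#'   gt = site x sample genotype matrix (or NULL), adRef/adAlt = site x
#'   sample allele-depth matrices (when AD present),
#'   skippedMultiallelic = count).
#' @export
readVcfMinimal <- function(path, requireFields = character(0)) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(list(sites = data.frame(CHROM = character(0), POS = integer(0),
                                   ID = character(0), REF = character(0),
                                   ALT = character(0)),
                gt = NULL, adRef = NULL, adAlt = NULL,
                skippedMultiallelic = 0L))
  biallelic <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$ALT %in% c("A", "C", "G", "T")
  skipped <- sum(!biallelic)
  if (skipped)
    message(sprintf("readVcfMinimal: skipped %d multiallelic/non-SNP record(s)",
                    skipped))
  fmt <- unique(unlist(strsplit(unname(v@gt[, "FORMAT"]), ":")))
  for (f in requireFields)
    if (!f %in% fmt)
      stop(sprintf("VCF lacks required FORMAT field '%s'", f))
  v2 <- v[biallelic, ]
  fix <- fix[biallelic, , drop = FALSE]
  sites <- data.frame(CHROM = fix$CHROM, POS = as.integer(fix$POS),
                      ID = fix$ID, REF = fix$REF, ALT = fix$ALT,
                      stringsAsFactors = FALSE)
  gt <- if ("GT" %in% fmt) vcfR::extract.gt(v2, element = "GT") else NULL
  adRef <- adAlt <- NULL
  if ("AD" %in% fmt) {
    ad <- vcfR::extract.gt(v2, element = "AD")
    splitAD <- function(i) as.integer(vapply(strsplit(as.vector(ad), ","),
                                             function(x) x[i], character(1)))
    adRef <- matrix(splitAD(1), nrow = nrow(ad), dimnames = dimnames(ad))
    adAlt <- matrix(splitAD(2), nrow = nrow(ad), dimnames = dimnames(ad))
  }
  list(sites = sites, gt = gt, adRef = adRef, adAlt = adAlt,
       skippedMultiallelic = skipped)
}

#' Presence/absence genotype matrix from VCF genotypes
#'
#' Converts GT strings to 0/1 alternate-allele presence per sample (any
#' non-reference allele counts), keeping SNP row names as CHROM:POS.
#'
#' @param vcf Result of \code{\link{readVcfMinimal}} (GT required).
#' @return SNP x sample 0/1 matrix.
#' @export
genotypePresenceMatrix <- function(vcf) {
  if (is.null(vcf$gt)) stop("VCF lacks required FORMAT field 'GT'")
  pres <- ifelse(is.na(vcf$gt), NA_integer_,
                 ifelse(grepl("1", vcf$gt), 1L, 0L))
  rownames(pres) <- paste0(vcf$sites$CHROM, ":", vcf$sites$POS)
  pres
}

#' Derive a per-stage seed from the global run seed
#'
#' One global seed hierarchically derives per-stage seeds by hashing the
#' stage name, so each stage is independently reproducible.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed below 2^31.
#' @export
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((abs(as.numeric(seed)) * 1009 + h) %% 2147483647)
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages with shared logging and hierarchical
#' seeding, writing stage outputs and a manifest (configuration, package
#' version, input checksums, output checksums) into \code{outDir}. All input
#' files are validated before any stage runs; a stage failure aborts the run
#' with the stage name. Outputs are reproducible under a fixed seed.
#'
#' Supported stages and their config blocks:
#' \describe{
#'   \item{replay}{\code{scenario} (path to a scenario JSON; default the
#'     packaged ACK-to-Catolobus scenario); writes the final karyotype and a
#'     summary.}
#'   \item{ploidy}{\code{input} (site-count TSV), optional \code{sample};
#'     writes the fit report and a histogram plot.}
#'   \item{dstat}{\code{input} (site-pattern TSV, samples in rows),
#'     \code{quartets} (TSV with columns P1, P2, P3, O), optional
#'     \code{blockSize}; writes the per-quartet D table.}
#'   \item{snp_partition}{\code{genotypes} (TSV SNP x sample),
#'     \code{clusters} (TSV sample/cluster), optional \code{nPerCluster};
#'     writes the partition counts.}
#' }
#'
#' @param config Named list (or path to a JSON file) with elements
#'   \code{seed}, \code{outDir} and \code{stages} (named list of stage
#'   blocks).
#' @return The manifest, invisibly (also written as manifest.json).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config)
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$outDir)) stop("config$outDir is required")
  stages <- config$stages
  if (is.null(stages) || !length(stages)) stop("config$stages is empty")
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  # validate all referenced input files before running anything
  inputs <- character(0)
  for (st in names(stages))
    for (f in c("scenario", "input", "quartets", "genotypes", "clusters")) {
      p <- stages[[st]][[f]]
      if (!is.null(p)) {
        if (!file.exists(p))
          stop(sprintf("stage '%s': input file '%s' does not exist", st, p))
        inputs[paste(st, f, sep = ".")] <- p
      }
    }
  manifest <- list(package = "karyoploid",
                   version = as.character(utils::packageVersion("karyoploid")),
                   seed = config$seed,
                   stages = as.list(names(stages)),
                   inputs = as.list(tools::md5sum(inputs)))
  outputs <- character(0)
  for (st in names(stages)) {
    blk <- stages[[st]]
    sSeed <- stageSeed(config$seed, st)
    res <- tryCatch(switch(st,
      replay = {
        sc <- if (!is.null(blk$scenario)) readScenario(blk$scenario)
              else catolobusScenario()
        k <- replayScenario(sc, buildACK())
        out <- file.path(config$outDir, "replay_karyotype.json")
        writeKaryotype(k, out)
        sm <- summarizeKaryotype(k, applyWGD(buildACK()))
        out2 <- file.path(config$outDir, "replay_summary.json")
        jsonlite::write_json(list(n = sm$n, diploidNumber = sm$diploidNumber,
                                  placements = sm$placements,
                                  blocksAtCopyTwo = sm$blocksAtCopyTwo,
                                  affected = sm$affected),
                             out2, auto_unbox = TRUE, pretty = TRUE)
        c(out, out2)
      },
      ploidy = {
        counts <- loadSiteCounts(blk$input, sample = blk$sample)
        rep_ <- ploidyReport(counts)
        out <- file.path(config$outDir, "ploidy_report.json")
        jsonlite::write_json(list(
          delta_loglik = as.list(rep_$delta_loglik),
          median_allele_ratio = rep_$median_allele_ratio,
          best = rep_$best,
          histotest = lapply(rep_$histotest, function(h)
            h[c("slope", "slope_se", "SSR", "R2")])),
          out, auto_unbox = TRUE, pretty = TRUE, digits = 10)
        png <- file.path(config$outDir, "ploidy_histogram.png")
        grDevices::png(png, width = 700, height = 500)
        freqs <- counts$alt_reads / counts$coverage
        plotAlleleFrequencyHistogram(freqs, rep_$fits[[rep_$best]])
        grDevices::dev.off()
        c(out, png)
      },
      dstat = {
        M <- as.matrix(read.delim(blk$input, row.names = 1))
        qt <- read.delim(blk$quartets, stringsAsFactors = FALSE)
        quartets <- lapply(seq_len(nrow(qt)), function(i)
          quartetSpec(qt$P1[i], qt$P2[i], qt$P3[i], qt$O[i]))
        bs <- if (is.null(blk$blockSize)) 2000L else blk$blockSize
        tab <- dStatTable(M, quartets, blockSize = bs)
        out <- file.path(config$outDir, "dstat_table.tsv")
        write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
        out
      },
      snp_partition = {
        G <- as.matrix(read.delim(blk$genotypes, row.names = 1))
        cl <- readClusterAssignments(blk$clusters)
        np <- if (is.null(blk$nPerCluster)) 6L else blk$nPerCluster
        part <- partitionSnps(G, cl, nPerCluster = np, seed = sSeed)
        out <- file.path(config$outDir, "snp_partition.json")
        jsonlite::write_json(list(counts = as.list(part$counts),
                                  subsample = part$subsample),
                             out, auto_unbox = TRUE, pretty = TRUE)
        out
      },
      stop(sprintf("unknown stage '%s'", st))),
      error = function(e)
        stop(sprintf("stage '%s' failed: %s", st, conditionMessage(e)),
             call. = FALSE))
    outputs <- c(outputs, res)
  }
  manifest$outputs <- as.list(tools::md5sum(outputs))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
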