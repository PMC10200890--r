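## Cluster-wise SNP partitioning: shared vs cluster-unique SNPs after
## singleton filtering, with optional placement of SNP genes onto block-level
## chromosomes.

#' Read a sample-to-cluster assignment table
#'
#' @param file TSV with columns \code{sample}, \code{cluster} and optionally
#'   \code{admixture} (proportion of the genome assigned to other clusters).
#' @param admixedThreshold Samples whose admixture exceeds this proportion
#'   are marked admixed (default 0.10) and excluded from pure-cluster
#'   analyses.
#' @return data.frame with columns sample, cluster, admixture, admixed.
#' @export
readClusterAssignments <- function(file, admixedThreshold = 0.10) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("sample", "cluster") %in% names(tab)))
    stop("cluster table must have columns 'sample' and 'cluster'")
  if (is.null(tab$admixture)) tab$admixture <- 0
  if (anyDuplicated(tab$sample))
    stop("every sample must have exactly one primary cluster label")
  tab$admixed <- tab$admixture > admixedThreshold
  tab
}

#' Partition SNPs into shared and cluster-unique sets
#'
#' Subsamples an equal number of (non-admixed) samples per cluster (seeded),
#' removes singletons (SNPs whose alternate allele is observed in exactly one
#' sample of the analysis set), then assigns each remaining SNP to the
#' clusters in which at least one subsampled member carries the alternate
#' allele: SNPs present in all clusters are shared, SNPs present in exactly
#' one are unique to it, and SNPs present in more than one but not all
#' clusters (possible with three or more clusters) form a mixed residual
#' category, empty at two clusters.
#'
#' @param genotypes Numeric matrix, SNPs in rows (rownames = SNP ids),
#'   samples in columns; entries > 0 mean the alternate allele is observed
#'   (NA allowed).
#' @param clusters data.frame as from \code{\link{readClusterAssignments}}
#'   (or with columns sample/cluster), or a named character vector
#'   sample -> cluster.
#' @param nPerCluster Samples subsampled per cluster (default 6). Every
#'   cluster must have at least this many non-admixed samples.
#' @param seed Integer seed for the subsampling (identical seed, identical
#'   partition).
#' @return Object of class \code{"clusterSNPPartition"}: shared,
#'   uniquePerCluster (named list), mixed, singletonsRemoved (ids),
#'   absentAfterSubsampling, subsample (named list of samples used), counts.
#' @export
partitionSnps <- function(genotypes, clusters, nPerCluster = 6L, seed = 1L) {
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- paste0("snp", seq_len(nrow(genotypes)))
  if (!is.data.frame(clusters))
    clusters <- data.frame(sample = names(clusters),
                           cluster = unname(clusters),
                           stringsAsFactors = FALSE)
  if (is.null(clusters$admixed)) clusters$admixed <- FALSE
  clusters <- clusters[!clusters$admixed, , drop = FALSE]
  missing <- setdiff(clusters$sample, colnames(genotypes))
  if (length(missing))
    stop(sprintf("samples absent from genotype matrix: %s",
                 paste(missing, collapse = ", ")))
  labs <- sort(unique(clusters$cluster))
  sub <- list()
  for (cl in labs) {
    avail <- sort(clusters$sample[clusters$cluster == cl])
    if (length(avail) < nPerCluster)
      stop(sprintf("cluster %s has %d samples, fewer than nPerCluster = %d",
                   cl, length(avail), nPerCluster))
    # seed each cluster's draw from its member set, not its label, so
    # relabeling clusters permutes the partition without changing it
    set.seed(stageSeed(seed, paste(avail, collapse = ",")))
    sub[[cl]] <- sort(sample(avail, nPerCluster))
  }
  used <- unlist(sub, use.names = FALSE)
  G <- genotypes[, used, drop = FALSE] > 0
  carriers <- rowSums(G, na.rm = TRUE)
  singleton <- carriers == 1L
  absent <- carriers == 0L
  presence <- vapply(labs, function(cl)
    rowSums(G[, sub[[cl]], drop = FALSE], na.rm = TRUE) > 0,
    logical(nrow(G)))
  keep <- !singleton & !absent
  nClusters <- rowSums(presence)
  shared <- rownames(G)[keep & nClusters == length(labs)]
  unique_ <- lapply(seq_along(labs), function(j)
    rownames(G)[keep & nClusters == 1L & presence[, j]])
  names(unique_) <- labs
  mixed <- rownames(G)[keep & nClusters > 1L & nClusters < length(labs)]
  out <- list(shared = shared, uniquePerCluster = unique_, mixed = mixed,
              singletonsRemoved = rownames(G)[singleton],
              absentAfterSubsampling = rownames(G)[absent],
              subsample = sub,
              counts = c(shared = length(shared),
                         stats::setNames(lengths(unique_),
                                         paste0("unique_", labs)),
                         mixed = length(mixed),
                         singletons_removed = sum(singleton)))
  class(out) <- "clusterSNPPartition"
  out
}

#' @export
print.clusterSNPPartition <- function(x, ...) {
  cat("Cluster SNP partition\n")
  for (i in seq_along(x$counts))
    cat(sprintf("  %-20s %d\n", names(x$counts)[i], x$counts[i]))
  invisible(x)
}

#' Read a gene-to-block homeology table
#'
#' @param file TSV with columns \code{gene} and \code{block}; each gene maps
#'   to at most one genomic block.
#' @return data.frame gene/block.
#' @export
readGeneBlockTable <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("gene", "block") %in% names(tab)))
    stop("gene table must have columns 'gene' and 'block'")
  if (anyDuplicated(tab$gene))
    stop("a gene must map to at most one block")
  bad <- setdiff(tab$block, genomicBlocks())
  if (length(bad))
    stop(sprintf("unknown blocks in gene table: %s", paste(bad, collapse = ", ")))
  tab
}

#' Place SNP genes onto block-level chromosomes
#'
#' Each gene is placed through its genomic block onto every chromosome of the
#' karyotype carrying that block (any homeolog copy). When a reference
#' karyotype is given, genes landing on chromosomes that are structurally
#' rearranged relative to it are flagged, supporting the display convention
#' of showing SNPs only on chromosomes without species-specific
#' rearrangements. Genes absent from the table are returned as unplaced.
#'
#' @param genes Character vector of gene identifiers (e.g. genes carrying
#'   cluster-specific SNPs).
#' @param geneTable data.frame gene/block
#'   (see \code{\link{readGeneBlockTable}}).
#' @param karyotype A \code{\linkS4class{Karyotype}} (e.g.
#'   \code{\link{catolobusKaryotype}()}).
#' @param reference Optional reference \code{\linkS4class{Karyotype}} used to
#'   flag rearranged chromosomes (e.g. the post-WGD ACK complement).
#' @return list(placements = data.frame(gene, block, chromosome, rearranged),
#'   unplaced = character vector).
#' @export
placeOnBlocks <- function(genes, geneTable, karyotype, reference = NULL) {
  rearrangedSet <- character(0)
  if (!is.null(reference)) {
    refPool <- canonicalStrings(reference, "labels")
    labtab <- blockLabelTable(karyotype)
    for (ch in karyotype@chromosomes) {
      s <- canonicalLabelString(ch, labtab)
      i <- match(s, refPool)
      if (is.na(i)) rearrangedSet <- c(rearrangedSet, ch@name)
      else refPool <- refPool[-i]
    }
  }
  blockOf <- stats::setNames(geneTable$block, geneTable$gene)
  rows <- list(); unplaced <- character(0)
  for (g in genes) {
    b <- unname(blockOf[g])
    if (is.na(b)) { unplaced <- c(unplaced, g); next }
    onChrom <- chromosomeNames(karyotype)[vapply(karyotype@chromosomes,
      function(ch) b %in% ch@segments$block, logical(1))]
    for (cn in onChrom)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, block = b, chromosome = cn,
        rearranged = cn %in% rearrangedSet, stringsAsFactors = FALSE)
  }
  placements <- if (length(rows)) do.call(rbind, rows)
    else data.frame(gene = character(0), block = character(0),
                    chromosome = character(0), rearranged = logical(0))
  list(placements = placements, unplaced = unplaced)
}
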