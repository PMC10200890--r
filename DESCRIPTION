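Package: karyoploid
Title: Genomic-Block Karyotype Evolution, Ploidy Inference and Introgression
    Statistics for Polyploid Crucifer Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing and replaying block-level karyotype
    rearrangement scenarios in crucifers descending from the Ancestral Crucifer
    Karyotype (ACK, n = 8, 22 genomic blocks): whole-genome duplication,
    end-to-end translocation with centromere elimination, reciprocal and
    unequal translocations, and pericentric inversions, together with a bounded
    parsimony search for minimal scenarios between two karyotypes. Also
    implements ploidy inference from biallelic allele-frequency mixtures
    (fixed-mean Gaussian mixture model selection, histogram fit statistics and
    median allele-ratio limits), Patterson's D-statistic (ABBA-BABA) with
    block-jackknife significance, cluster-wise SNP partitioning after singleton
    filtering, and seeded synthetic-data generators so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, grDevices, tools, jsonlite, vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
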