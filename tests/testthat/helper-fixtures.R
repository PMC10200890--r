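## Shared fixtures built in code.

postWgdAck <- function() applyWGD(buildACK())

## a small two-chromosome toy complement for operator edge cases
toyKaryotype <- function() {
  chr1 <- new("Chromosome", name = "T1",
              segments = rbind(segRowT("A"), segRowT("B")),
              centromere = 1L, history = character(0))
  chr2 <- new("Chromosome", name = "T2",
              segments = rbind(segRowT("D"), segRowT("E")),
              centromere = 1L, history = character(0))
  new("Karyotype", chromosomes = list(chr1, chr2), name = "toy")
}

segRowT <- function(block, start = 0, end = 1, strand = "+", copy = 1L) {
  data.frame(block = block, start = start, end = end, strand = strand,
             copy = as.integer(copy), stringsAsFactors = FALSE)
}

## hand-built 4-sample site-pattern toy: 2 ABBA, 1 BABA, 3 uninformative
toyQuartetMatrix <- function() {
  pats <- cbind(c(0, 1, 1, 0),   # ABBA
                c(1, 0, 1, 0),   # BABA
                c(0, 1, 1, 0),   # ABBA
                c(1, 1, 0, 0),   # BBAA
                c(0, 0, 0, 0),   # monomorphic
                c(1, 1, 1, 0))   # derived in all ingroups
  rownames(pats) <- c("P1", "P2", "P3", "O")
  pats
}
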