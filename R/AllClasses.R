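#' @import methods
#' @importFrom stats median sd dnorm pnorm rbinom rnbinom runif var coef lm
#' @importFrom utils read.delim write.table head tail
#' @importFrom tools md5sum
NULL

#' The 22 genomic blocks of the Ancestral Crucifer Karyotype
#'
#' Block labels A-X used as the coordinate system for karyotype comparison.
#' \code{"K-L"} and \code{"M-N"} are atomic block identities (they are never
#' split into K, L, M, N).
#'
#' @return Character vector of the 22 block labels.
#' @export
#' @examples
#' genomicBlocks()
genomicBlocks <- function() {
  c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K-L", "M-N",
    "O", "P", "Q", "R", "S", "T", "U", "V", "W", "X")
}

## Segments are rows of a data.frame with columns:
##   block  - one of genomicBlocks()
##   start  - fraction in [0,1) within the ancestral block
##   end    - fraction in (0,1], start < end
##   strand - "+" (ancestral reading) or "-"
##   copy   - homeolog index, 1L or 2L
emptySegments <- function() {
  data.frame(block = character(0), start = numeric(0), end = numeric(0),
             strand = character(0), copy = integer(0),
             stringsAsFactors = FALSE)
}

#' Chromosome: an ordered, oriented run of genomic-block segments
#'
#' A chromosome is read head to tail as an ordered list of sub-block segments
#' with exactly one active centromere sitting between two segments
#' (\code{centromere} = number of segments preceding it). A chromosome and its
#' full reversal are the same object up to canonicalization
#' (see \code{\link{canonicalForm}}).
#'
#' @slot name Chromosome name (e.g. "AK1", "Cp15").
#' @slot segments data.frame with columns block, start, end, strand, copy.
#' @slot centromere Integer position: the centromere lies after this many
#'   segments (1 <= centromere <= nrow(segments) - 1).
#' @slot history Character vector of free-text history notes (e.g. eliminated
#'   centromeres, carried Mb annotations).
#' @exportClass Chromosome
setClass("Chromosome",
         representation(name = "character", segments = "data.frame",
                        centromere = "integer", history = "character"),
         prototype(name = NA_character_, segments = emptySegments(),
                   centromere = 1L, history = character(0)))

setValidity("Chromosome", function(object) {
  seg <- object@segments
  need <- c("block", "start", "end", "strand", "copy")
  if (!all(need %in% names(seg)))
    return(sprintf("segments must have columns %s", paste(need, collapse = ", ")))
  if (nrow(seg) < 1L) return("a chromosome needs at least one segment")
  if (!all(seg$block %in% genomicBlocks()))
    return(sprintf("unknown block label(s): %s",
                   paste(setdiff(seg$block, genomicBlocks()), collapse = ", ")))
  if (any(seg$start < 0 | seg$end > 1 | seg$start >= seg$end))
    return("segment fractions must satisfy 0 <= start < end <= 1")
  if (!all(seg$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  if (!all(seg$copy %in% c(1L, 2L))) return("copy must be 1 or 2")
  if (nrow(seg) < 2L)
    return("a chromosome needs >= 2 segments so the centromere lies between two of them")
  if (length(object@centromere) != 1L || is.na(object@centromere) ||
      object@centromere < 1L || object@centromere >= nrow(seg))
    return("centromere index must lie strictly between two segments")
  TRUE
})

#' Karyotype: a gametic chromosome complement
#'
#' Stores the gametic (n) complement; the diploid number reported anywhere in
#' the package is always 2 x complement size (so the tetraploid ACK-derived
#' complement of 16 chromosomes is reported as 2n = 32).
#'
#' @slot chromosomes List of \code{\linkS4class{Chromosome}} objects.
#' @slot name Optional karyotype name.
#' @exportClass Karyotype
setClass("Karyotype",
         representation(chromosomes = "list", name = "character"),
         prototype(chromosomes = list(), name = NA_character_))

setValidity("Karyotype", function(object) {
  ok <- vapply(object@chromosomes, function(x) is(x, "Chromosome"), logical(1))
  if (!all(ok)) return("all elements of @chromosomes must be Chromosome objects")
  for (ch in object@chromosomes) {
    v <- validObject(ch, test = TRUE)
    if (!isTRUE(v)) return(sprintf("chromosome %s: %s", ch@name, v))
  }
  TRUE
})

#' Rearrangement event
#'
#' One step of a \code{\linkS4class{Scenario}}. \code{kind} is one of
#' \code{"WGD"}, \code{"EET"}, \code{"RECIP_TRANSLOC"}, \code{"UNEQ_TRANSLOC"},
#' \code{"PERI_INV"}; \code{params} holds the operand chromosome names,
#' end selectors and \code{\link{breakpoint}} specifications that the
#' corresponding operator consumes; \code{annotation} is free text carried
#' verbatim (Mb sizes, gene-ID breakpoint intervals).
#'
#' @exportClass RearrangementEvent
setClass("RearrangementEvent",
         representation(kind = "character", params = "list",
                        annotation = "character"),
         prototype(kind = NA_character_, params = list(),
                   annotation = character(0)))

eventKinds <- function() c("WGD", "EET", "RECIP_TRANSLOC", "UNEQ_TRANSLOC", "PERI_INV")

setValidity("RearrangementEvent", function(object) {
  if (!(object@kind %in% eventKinds()))
    return(sprintf("kind must be one of %s", paste(eventKinds(), collapse = ", ")))
  TRUE
})

#' Rearrangement scenario
#'
#' An ordered list of \code{\linkS4class{RearrangementEvent}}s replayed
#' deterministically from a start karyotype (see \code{\link{replayScenario}}).
#'
#' @slot events List of RearrangementEvent objects.
#' @slot start Name of the karyotype the scenario starts from.
#' @exportClass Scenario
setClass("Scenario",
         representation(events = "list", start = "character"),
         prototype(events = list(), start = NA_character_))

setValidity("Scenario", function(object) {
  ok <- vapply(object@events, function(x) is(x, "RearrangementEvent"), logical(1))
  if (!all(ok)) return("all elements of @events must be RearrangementEvent objects")
  TRUE
})

## ---- accessors ----

#' @describeIn Karyotype-accessors number of chromosomes in the gametic complement
#' @export
setGeneric("complementSize", function(x) standardGeneric("complementSize"))

#' Karyotype accessors
#'
#' @param x A \code{\linkS4class{Karyotype}}.
#' @name Karyotype-accessors
#' @aliases complementSize diploidNumber chromosomes chromosomeNames
NULL

#' @rdname Karyotype-accessors
#' @export
setMethod("complementSize", "Karyotype", function(x) length(x@chromosomes))

#' @rdname Karyotype-accessors
#' @export
setGeneric("diploidNumber", function(x) standardGeneric("diploidNumber"))

#' @rdname Karyotype-accessors
#' @export
setMethod("diploidNumber", "Karyotype", function(x) 2L * length(x@chromosomes))

#' @rdname Karyotype-accessors
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))

#' @rdname Karyotype-accessors
#' @export
setMethod("chromosomes", "Karyotype", function(x) x@chromosomes)

#' @rdname Karyotype-accessors
#' @export
setGeneric("chromosomeNames", function(x) standardGeneric("chromosomeNames"))

#' @rdname Karyotype-accessors
#' @export
setMethod("chromosomeNames", "Karyotype",
          function(x) vapply(x@chromosomes, function(ch) ch@name, character(1)))

#' @rdname Karyotype-accessors
#' @param name Chromosome name.
#' @export
setGeneric("getChromosome", function(x, name) standardGeneric("getChromosome"))

#' @rdname Karyotype-accessors
#' @export
setMethod("getChromosome", "Karyotype", function(x, name) {
  i <- match(name, chromosomeNames(x))
  if (is.na(i)) stop(sprintf("no chromosome named '%s' in karyotype", name))
  x@chromosomes[[i]]
})

#' @describeIn Scenario-accessors the ordered event list
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' Scenario accessors
#'
#' @param x A \code{\linkS4class{Scenario}}.
#' @name Scenario-accessors
NULL

#' @rdname Scenario-accessors
#' @export
setMethod("events", "Scenario", function(x) x@events)

## ---- show methods ----

setMethod("show", "Chromosome", function(object) {
  cat(sprintf("Chromosome %s: %s\n", object@name,
              chromosomeString(object)))
})

setMethod("show", "Karyotype", function(object) {
  nm <- if (is.na(object@name)) "" else sprintf(" '%s'", object@name)
  cat(sprintf("Karyotype%s: n = %d (2n = %d)\n", nm,
              complementSize(object), diploidNumber(object)))
  for (ch in object@chromosomes)
    cat(sprintf("  %-10s %s\n", ch@name, chromosomeString(ch)))
})

setMethod("show", "RearrangementEvent", function(object) {
  cat(sprintf("<%s> %s\n", object@kind, eventString(object)))
})

setMethod("show", "Scenario", function(object) {
  cat(sprintf("Scenario from '%s' with %d event(s)\n", object@start,
              length(object@events)))
  for (i in seq_along(object@events)) {
    e <- object@events[[i]]
    cat(sprintf("  %d. <%s> %s\n", i, e@kind, eventString(e)))
  }
})

eventString <- function(e) {
  p <- e@params
  s <- switch(e@kind,
    WGD = "duplicate every chromosome",
    EET = sprintf("join %s(%s) to %s(%s), keep centromere of %s",
                  p$chrA, p$endA, p$chrB, p$endB, p$keep),
    RECIP_TRANSLOC = sprintf("exchange distal fragments at %s x %s",
                             bpString(p$bp1), bpString(p$bp2)),
    UNEQ_TRANSLOC = sprintf("donate distal fragment at %s to %s (%s)",
                            bpString(p$bp), p$target, p$targetEnd),
    PERI_INV = sprintf("invert %s between %s and %s", p$chrom,
                       bpString(p$bpL), bpString(p$bpR)),
    "")
  if (length(e@annotation)) s <- paste0(s, " [", paste(e@annotation, collapse = "; "), "]")
  s
}
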