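## Karyotype and scenario file formats: a JSON-structured full-fidelity format
## (round-trips bit-exactly) and a plain token text format for block-label
## karyotype fixtures.

#' Parse a block-label karyotype token file
#'
#' Reads the plain text format used for painted-karyotype fixtures: one
#' chromosome per line, \code{name<TAB>tokens}, tokens like \code{"Fa+"},
#' \code{"(K-L)-"}, \code{"CEN"}, with optional homeolog suffix
#' \code{"@1"}/\code{"@2"}. Exactly one CEN per chromosome. Sub-block letters
#' (a, b, c) are converted to equally spaced ancestral-coordinate intervals
#' per (block, copy), so the parsed object compares equal (in \code{"labels"}
#' mode) to any karyotype with the same block-label structure regardless of
#' actual breakpoint fractions.
#'
#' @param file Path to the token file, or \code{NULL} if \code{lines} given.
#' @param lines Character vector of lines (alternative to \code{file}).
#' @param name Karyotype name.
#' @return A \code{\linkS4class{Karyotype}}.
#' @export
#' @examples
#' cp <- catolobusKaryotype()
#' complementSize(cp)  # 15
parseKaryotypeTokens <- function(file = NULL, lines = NULL, name = NA_character_) {
  if (is.null(lines)) lines <- readLines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parsed <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    list(name = parts[1], tokens = parts[-1])
  })
  tokInfo <- function(tok) {
    copy <- 1L
    m <- regmatches(tok, regexec("@([12])$", tok))[[1]]
    if (length(m)) { copy <- as.integer(m[2]); tok <- sub("@[12]$", "", tok) }
    strand <- substr(tok, nchar(tok), nchar(tok))
    if (!strand %in% c("+", "-"))
      stop(sprintf("token '%s' lacks an orientation sign", tok))
    core <- substr(tok, 1, nchar(tok) - 1L)
    if (startsWith(core, "(")) {
      block <- sub("^\\(([^)]+)\\).*$", "\\1", core)
      sub_ <- sub("^\\([^)]+\\)", "", core)
    } else {
      block <- substr(core, 1, 1)
      sub_ <- substr(core, 2, nchar(core))
    }
    if (!block %in% genomicBlocks())
      stop(sprintf("unknown block in token '%s'", tok))
    list(block = block, sub = sub_, strand = strand, copy = copy)
  }
  infos <- lapply(parsed, function(p)
    lapply(p$tokens[p$tokens != "CEN"], tokInfo))
  # letter sets per (block, copy) across the whole file
  flat <- do.call(rbind, lapply(unlist(infos, recursive = FALSE), function(x)
    data.frame(block = x$block, sub = x$sub, copy = x$copy,
               stringsAsFactors = FALSE)))
  letterMap <- list()
  for (key in unique(paste(flat$block, flat$copy))) {
    parts <- strsplit(key, " ")[[1]]
    subs <- sort(unique(flat$sub[flat$block == parts[1] &
                                 flat$copy == as.integer(parts[2])]))
    if (length(subs) > 1L && "" %in% subs)
      stop(sprintf("block %s copy %s mixes plain and sub-block tokens",
                   parts[1], parts[2]))
    letterMap[[key]] <- subs
  }
  chroms <- lapply(parsed, function(p) {
    cenAt <- which(p$tokens == "CEN")
    if (length(cenAt) != 1L)
      stop(sprintf("chromosome %s must have exactly one CEN token", p$name))
    toks <- p$tokens[p$tokens != "CEN"]
    segs <- do.call(rbind, lapply(toks, function(tk) {
      x <- tokInfo(tk)
      subs <- letterMap[[paste(x$block, x$copy)]]
      m <- length(subs)
      r <- match(x$sub, subs)
      segRow(x$block, (r - 1) / m, r / m, x$strand, x$copy)
    }))
    newChromosome(p$name, segs, centromere = cenAt - 1L)
  })
  new("Karyotype", chromosomes = chroms, name = name)
}

#' The packaged Catolobus pendulus karyotype (Cp1-Cp15)
#'
#' Parses the packaged token fixture transcribing the 44 genomic-block
#' placements on the 15 \emph{Catolobus} chromosomes.
#'
#' @return A \code{\linkS4class{Karyotype}} with 15 chromosomes.
#' @export
catolobusKaryotype <- function() {
  parseKaryotypeTokens(system.file("extdata", "cp_karyotype.txt",
                                   package = "karyoploid"),
                       name = "Catolobus")
}

## ---- JSON karyotype format ----

karyotypeToList <- function(k) {
  list(format = "karyoploid/karyotype", version = 1L,
       name = if (is.na(k@name)) NULL else k@name,
       chromosomes = lapply(k@chromosomes, function(ch) {
         list(name = ch@name, centromere = ch@centromere,
              history = as.list(ch@history),
              segments = lapply(seq_len(nrow(ch@segments)), function(i) {
                s <- ch@segments[i, ]
                list(block = s$block, start = s$start, end = s$end,
                     strand = s$strand, copy = s$copy)
              }))
       }))
}

karyotypeFromList <- function(x) {
  if (!identical(x$format, "karyoploid/karyotype"))
    stop("not a karyoploid karyotype file")
  chroms <- lapply(x$chromosomes, function(c_) {
    segs <- do.call(rbind, lapply(c_$segments, function(s)
      segRow(s$block, s$start, s$end, s$strand, s$copy)))
    newChromosome(c_$name, segs, c_$centromere,
                  history = as.character(unlist(c_$history)))
  })
  new("Karyotype", chromosomes = chroms,
      name = if (is.null(x$name)) NA_character_ else x$name)
}

#' Read and write karyotype files
#'
#' Versioned, JSON-structured text format storing every chromosome as an
#' ordered segment list plus centromere position and history notes. The
#' reader/writer pair round-trips bit-exactly.
#'
#' @param k A \code{\linkS4class{Karyotype}}.
#' @param path File path.
#' @return \code{writeKaryotype} returns \code{path} invisibly;
#'   \code{readKaryotype} returns a \code{\linkS4class{Karyotype}}.
#' @export
writeKaryotype <- function(k, path) {
  jsonlite::write_json(karyotypeToList(k), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname writeKaryotype
#' @export
readKaryotype <- function(path) {
  karyotypeFromList(jsonlite::read_json(path))
}

## ---- JSON scenario format ----

bpToList <- function(bp) {
  list(chrom = bp$chrom, after = bp$after, segment = bp$segment,
       fraction = bp$fraction, cenToHead = bp$cenToHead)
}

bpFromList <- function(x) {
  breakpoint(x$chrom, after = x$after, segment = x$segment,
             fraction = if (is.null(x$fraction)) 0.5 else x$fraction,
             cenToHead = isTRUE(x$cenToHead))
}

eventToList <- function(e) {
  p <- e@params
  pl <- p
  for (f in c("bp", "bp1", "bp2", "bpL", "bpR"))
    if (!is.null(pl[[f]])) pl[[f]] <- bpToList(pl[[f]])
  if (!is.null(pl$names)) pl$names <- as.list(pl$names)
  list(kind = e@kind, params = pl, annotation = as.list(e@annotation))
}

eventFromList <- function(x) {
  p <- x$params
  for (f in c("bp", "bp1", "bp2", "bpL", "bpR"))
    if (!is.null(p[[f]])) p[[f]] <- bpFromList(p[[f]])
  if (!is.null(p$names)) p$names <- as.character(unlist(p$names))
  rearrangementEvent(x$kind, params = p,
                     annotation = as.character(unlist(x$annotation)))
}

#' Read and write scenario files
#'
#' Ordered event records (kind, operands, breakpoints, annotations) in a
#' JSON-structured text format; round-trips bit-exactly.
#'
#' @param scenario A \code{\linkS4class{Scenario}}.
#' @param path File path.
#' @return \code{writeScenario} returns \code{path} invisibly;
#'   \code{readScenario} returns a \code{\linkS4class{Scenario}}.
#' @export
writeScenario <- function(scenario, path) {
  x <- list(format = "karyoploid/scenario", version = 1L,
            start = scenario@start,
            events = lapply(scenario@events, eventToList))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname writeScenario
#' @export
readScenario <- function(path) {
  x <- jsonlite::read_json(path)
  if (!identical(x$format, "karyoploid/scenario"))
    stop("not a karyoploid scenario file")
  new("Scenario", events = lapply(x$events, eventFromList),
      start = if (is.null(x$start)) NA_character_ else x$start)
}
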