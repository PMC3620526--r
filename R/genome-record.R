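#' Annotated genome record
#'
#' A `genome_record` is the unit every analysis stage consumes: a single
#' uppercase nucleotide sequence over `{A,C,G,T,N}`, its topology, and an
#' ordered list of typed annotation features. Coordinates are 0-based
#' half-open internally; all user-facing reports convert to the 1-based
#' inclusive convention of GenBank flat files.
#'
#' @param id Accession or name string.
#' @param sequence Single character string over `A,C,G,T,N` (case-insensitive
#'   on input, stored uppercase). IUPAC ambiguity codes other than `N` are
#'   rejected.
#' @param features List of features built with [feature()].
#' @param circular Logical; circular topology is recorded but features that
#'   wrap the origin must already be split into two intervals.
#' @return An object of class `genome_record`.
#' @examples
#' rec <- genome_record("toy", "ATGAAATAAGGGCCC",
#'   features = list(feature("CDS", "+", cbind(0L, 9L), name = "toyA")))
#' genome_length(rec)
#' @export
genome_record <- function(id, sequence, features = list(), circular = FALSE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 1L) stop("genome sequence must have length >= 1")
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad)) {
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  features <- lapply(features, validate_feature, genome_length = n)
  structure(
    list(id = id, sequence = sequence, circular = isTRUE(circular),
         features = features),
    class = "genome_record"
  )
}

FEATURE_KINDS <- c("CDS", "rRNA", "tRNA", "smallRNA", "pseudogene")

#' Annotation feature
#'
#' @param kind One of `CDS`, `rRNA`, `tRNA`, `smallRNA`, `pseudogene`.
#' @param strand `"+"` or `"-"`.
#' @param intervals Integer matrix with two columns (start, end), 0-based
#'   half-open; several rows for joined locations, given in translation order
#'   on the feature strand.
#' @param name Gene symbol or locus tag.
#' @param qualifiers Named list of free-text qualifier values.
#' @return An object of class `feature`.
#' @export
feature <- function(kind, strand, intervals, name = "", qualifiers = list()) {
  intervals <- matrix(as.integer(intervals), ncol = 2L)
  structure(
    list(kind = kind, strand = strand, intervals = intervals,
         name = name, qualifiers = qualifiers),
    class = "feature"
  )
}

validate_feature <- function(f, genome_length = NULL) {
  if (!inherits(f, "feature")) stop("features must be built with feature()")
  if (!f$kind %in% FEATURE_KINDS) {
    stop("unknown feature kind: ", f$kind)
  }
  if (!f$strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (nrow(f$intervals) < 1L) stop("feature has no intervals")
  if (any(f$intervals[, 1L] >= f$intervals[, 2L])) {
    stop("feature '", f$name, "': interval start must be < end")
  }
  if (!is.null(genome_length)) {
    if (any(f$intervals[, 1L] < 0L) || any(f$intervals[, 2L] > genome_length)) {
      stop("feature '", f$name, "' lies outside [0, ", genome_length, ")")
    }
  }
  if (f$kind == "CDS" && feature_width(f) < 3L) {
    stop("CDS '", f$name, "' shorter than one codon")
  }
  f
}

feature_width <- function(f) sum(f$intervals[, 2L] - f$intervals[, 1L])

#' @export
print.genome_record <- function(x, ...) {
  kinds <- vapply(x$features, function(f) f$kind, character(1))
  cat(sprintf("genome_record '%s': %d bp, %s, %d features\n",
              x$id, nchar(x$sequence),
              if (x$circular) "circular" else "linear",
              length(x$features)))
  if (length(kinds)) print(table(kinds))
  invisible(x)
}

#' Genome length in bp
#' @param record A [genome_record()].
#' @return Integer length.
#' @export
genome_length <- function(record) nchar(record$sequence)

#' Tabulate features as a data frame
#'
#' One row per feature with 1-based inclusive outer coordinates (GenBank
#' convention) for reporting; joined locations keep their full interval set
#' in the underlying record.
#' @param record A [genome_record()].
#' @return data.frame with columns kind, strand, start, end, n_intervals,
#'   width, name.
#' @export
features_table <- function(record) {
  fs <- record$features
  data.frame(
    kind = vapply(fs, function(f) f$kind, character(1)),
    strand = vapply(fs, function(f) f$strand, character(1)),
    start = vapply(fs, function(f) min(f$intervals[, 1L]) + 1L, integer(1)),
    end = vapply(fs, function(f) max(f$intervals[, 2L]), integer(1)),
    n_intervals = vapply(fs, function(f) nrow(f$intervals), integer(1)),
    width = vapply(fs, feature_width, integer(1)),
    name = vapply(fs, function(f) f$name, character(1)),
    stringsAsFactors = FALSE
  )
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

subseq0 <- function(sequence, start0, end0) {
  # 0-based half-open extraction from a plain character sequence
  substr(sequence, start0 + 1L, end0)
}
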