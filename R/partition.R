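#' Exclusive positional partition of a genome
#'
#' Assigns every genome position to exactly one of four classes: `coding`
#' (covered by a CDS), `rna` (rRNA/tRNA/smallRNA), `pseudogene`, or `igr`
#' (intergenic remainder). Overlaps are resolved by the fixed precedence
#' coding > rna > pseudogene, so the partition is independent of feature
#' order. Gene density is the fraction of positions in `coding` or `rna`.
#'
#' @param record A [genome_record()].
#' @return An object of class `genome_partition`: list with `classes`
#'   (integer vector, one value per position, levels
#'   coding/rna/pseudogene/igr), `class_lengths` (named bp totals) and
#'   `gene_density_percent`.
#' @export
build_partition <- function(record) {
  n <- genome_length(record)
  kinds <- vapply(record$features, function(f) f$kind, character(1))
  cover <- function(which_kinds) {
    fs <- record$features[kinds %in% which_kinds]
    if (!length(fs)) return(IRanges::IRanges())
    iv <- do.call(rbind, lapply(fs, function(f) f$intervals))
    IRanges::reduce(IRanges::IRanges(start = iv[, 1L] + 1L, end = iv[, 2L]))
  }
  coding <- cover("CDS")
  rna <- IRanges::setdiff(cover(c("rRNA", "tRNA", "smallRNA")), coding)
  pseudo <- IRanges::setdiff(IRanges::setdiff(cover("pseudogene"), coding), rna)

  classes <- rep.int(4L, n)
  assign_class <- function(classes, ir, value) {
    if (length(ir)) {
      idx <- unlist(mapply(seq.int, IRanges::start(ir), IRanges::end(ir),
                           SIMPLIFY = FALSE), use.names = FALSE)
      classes[idx] <- value
    }
    classes
  }
  classes <- assign_class(classes, coding, 1L)
  classes <- assign_class(classes, rna, 2L)
  classes <- assign_class(classes, pseudo, 3L)

  lens <- c(coding = sum(IRanges::width(coding)),
            rna = sum(IRanges::width(rna)),
            pseudogene = sum(IRanges::width(pseudo)))
  lens <- c(lens, igr = n - sum(lens))
  structure(
    list(classes = classes, class_lengths = lens,
         gene_density_percent = 100 * (lens[["coding"]] + lens[["rna"]]) / n),
    class = "genome_partition"
  )
}

PARTITION_LEVELS <- c("coding", "rna", "pseudogene", "igr")

#' Partition class at given positions
#' @param partition A [build_partition()] result.
#' @param pos0 0-based positions.
#' @return Character vector of class labels.
#' @export
partition_class_at <- function(partition, pos0) {
  PARTITION_LEVELS[partition$classes[pos0 + 1L]]
}

#' @export
print.genome_partition <- function(x, ...) {
  cat("genome_partition:", paste(names(x$class_lengths),
                                 x$class_lengths, sep = "=", collapse = " "),
      sprintf("| gene density %.1f%%\n", x$gene_density_percent))
  invisible(x)
}

#' Extract in-frame coding sequences
#'
#' Returns the nucleotide sequence of every CDS feature in translation
#' order: joined intervals are concatenated on the plus strand and the
#' result reverse-complemented for minus-strand features. Sequences whose
#' length is not a multiple of three, and sequences containing `N`, are
#' flagged rather than silently truncated.
#'
#' @param record A [genome_record()].
#' @param include_pseudogenes Also extract pseudogene features (default
#'   FALSE; profiling uses functional CDS only).
#' @return data.frame with columns `name`, `seq`, `strand`, `frame_ok`
#'   (length divisible by 3) and `n_positions` (comma-separated 1-based
#'   positions of N within the CDS, empty when none).
#' @export
extract_cds <- function(record, include_pseudogenes = FALSE) {
  kinds <- vapply(record$features, function(f) f$kind, character(1))
  keep <- kinds == "CDS"
  if (include_pseudogenes) keep <- keep | kinds == "pseudogene"
  fs <- record$features[keep]
  if (!length(fs)) {
    return(data.frame(name = character(0), seq = character(0),
                      strand = character(0), frame_ok = logical(0),
                      n_positions = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(fs, function(f) {
    iv <- f$intervals
    if (f$strand == "-") {
      # intervals stored in translation order (descending); fetch each on the
      # plus strand, reverse-complement each piece, concatenate in order
      pieces <- vapply(seq_len(nrow(iv)), function(i)
        revcomp(subseq0(record$sequence, iv[i, 1L], iv[i, 2L])), character(1))
    } else {
      pieces <- vapply(seq_len(nrow(iv)), function(i)
        subseq0(record$sequence, iv[i, 1L], iv[i, 2L]), character(1))
    }
    s <- paste(pieces, collapse = "")
    npos <- gregexpr("N", s, fixed = TRUE)[[1]]
    npos <- if (npos[[1]] == -1L) "" else paste(npos, collapse = ",")
    data.frame(name = f$name, seq = s, strand = f$strand,
               frame_ok = nchar(s) %% 3L == 0L, n_positions = npos,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
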