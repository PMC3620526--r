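#' Scan maximal homopolymer runs
#'
#' Finds every maximal single-nucleotide run of at least `min_len` bases on
#' the given strand. Runs are maximal by construction (run-length encoding
#' of the sequence), hence non-overlapping.
#'
#' @param seq Sequence string.
#' @param min_len Minimum run length (default 6, the usual slippage-prone
#'   threshold).
#' @param bases Restrict to runs of these bases (default all four).
#' @return data.frame `base`, `start` (0-based), `length`.
#' @export
scan_homopolymers <- function(seq, min_len = 6L, bases = c("A", "C", "G", "T")) {
  stopifnot(min_len >= 2L)
  r <- rle(strsplit(toupper(seq), "", fixed = TRUE)[[1]])
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_len & r$values %in% bases
  data.frame(base = r$values[keep],
             start = (ends - r$lengths)[keep],
             length = r$lengths[keep],
             stringsAsFactors = FALSE)
}

#' Scan short tandem repeats (microsatellites)
#'
#' Finds maximal tandem tracts of motifs of length `motif_len` (a range),
#' with at least `min_copies` full copies and total tract length at least
#' `min_tract`. A tract reportable under several motif lengths is reported
#' once with the smallest motif; tracts whose motif is itself a
#' single-nucleotide run are left to [scan_homopolymers()].
#'
#' @param seq Sequence string.
#' @param motif_len Integer range of motif sizes (default 2:8).
#' @param min_copies Minimum number of full motif copies (default 2).
#' @param min_tract Minimum tract length in bp (default 6).
#' @return data.frame `motif`, `start` (0-based), `tract_length`, `copies`.
#' @export
scan_microsatellites <- function(seq, motif_len = 2:8, min_copies = 2L,
                                 min_tract = 6L) {
  stopifnot(all(motif_len >= 2L), all(motif_len <= 8L), min_copies >= 2L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- list()
  claimed <- logical(n)  # positions already claimed by a smaller motif
  for (m in sort(motif_len)) {
    if (n < 2L * m) next
    eq <- chars[seq_len(n - m)] == chars[seq_len(n - m) + m]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    for (i in which(r$values & r$lengths + m >= max(min_tract, min_copies * m))) {
      start <- ends[i] - r$lengths[i]          # 0-based tract start
      tract <- r$lengths[i] + m
      motif <- paste(chars[(start + 1L):(start + m)], collapse = "")
      if (smallest_period(motif) < m) next      # reducible motif
      if (length(unique(strsplit(motif, "")[[1]])) == 1L) next  # homopolymer
      copies <- tract %/% m
      if (copies < min_copies) next
      span <- (start + 1L):(start + tract)
      if (any(claimed[span])) next              # already reported, smaller motif
      claimed[span] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        motif = motif, start = start, tract_length = tract, copies = copies,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(motif = character(0), start = integer(0),
                      tract_length = integer(0), copies = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

smallest_period <- function(motif) {
  m <- nchar(motif)
  for (p in seq_len(m - 1L)) {
    if (m %% p == 0L &&
        identical(strrep(substr(motif, 1L, p), m %/% p), motif)) return(p)
  }
  m
}

#' Classify the sequence context of an indel
#'
#' An indel affects a homopolymer iff its inserted/deleted bases consist
#' solely of the run base and its (left-normalized) position lies inside or
#' immediately adjacent to a qualifying run. Failing that, it affects a
#' microsatellite iff the allele is an integer number of copies of a tract's
#' motif (under rotation) and lies inside or adjacent to that tract.
#' Everything else is `other`. Homopolymer takes precedence over
#' microsatellite.
#'
#' @param variant One row of a [call_variants()] table (a left-normalized
#'   insertion or deletion).
#' @param runs [scan_homopolymers()] output for genome A.
#' @param repeats [scan_microsatellites()] output for genome A.
#' @return list(context = "homopolymer"/"microsatellite"/"other",
#'   motif = run base or repeat motif, or NA).
#' @export
classify_indel_context <- function(variant, runs, repeats) {
  if (variant$vtype == "substitution") {
    stop("context classification applies to indels only")
  }
  allele <- if (variant$vtype == "deletion") variant$ref else variant$alt
  pos <- variant$pos
  L <- nchar(allele)
  allele_chars <- unique(strsplit(allele, "", fixed = TRUE)[[1]])

  if (length(allele_chars) == 1L && nrow(runs)) {
    hits <- runs$base == allele_chars &
      pos >= runs$start - 1L & pos <= runs$start + runs$length
    if (any(hits)) {
      return(list(context = "homopolymer", motif = allele_chars))
    }
  }
  if (nrow(repeats)) {
    for (i in seq_len(nrow(repeats))) {
      m <- nchar(repeats$motif[i])
      if (L %% m != 0L) next
      if (!is_motif_multiple(allele, repeats$motif[i])) next
      lo <- repeats$start[i] - m
      hi <- repeats$start[i] + repeats$tract_length[i]
      if (pos >= lo && pos <= hi) {
        return(list(context = "microsatellite", motif = repeats$motif[i]))
      }
    }
  }
  list(context = "other", motif = NA_character_)
}

# allele equals an integer number of copies of motif, up to rotation
is_motif_multiple <- function(allele, motif) {
  m <- nchar(motif)
  rotations <- vapply(seq_len(m) - 1L, function(s) {
    paste0(substr(motif, s + 1L, m), substr(motif, 1L, s))
  }, character(1))
  any(vapply(rotations, function(rot) {
    identical(strrep(rot, nchar(allele) %/% m), allele)
  }, logical(1)))
}

#' Context calls and size statistics for a variant set
#'
#' Applies [classify_indel_context()] to every indel of a classified variant
#' set against genome A's homopolymer and microsatellite tracks, and
#' summarizes contexts and indel sizes.
#'
#' @param summary A [classify_variants()] result (or bare variant table).
#' @param seq Genome A sequence.
#' @param min_run Homopolymer minimum length (default 6).
#' @return list of class `indel_context_summary`: the variants table with
#'   `context`/`context_motif` columns on indel rows, per-context counts,
#'   `homopolymer_percent` (share of indels in homopolymers),
#'   per-run-base counts, and size mean/min/max.
#' @export
summarize_indel_contexts <- function(summary, seq, min_run = 6L) {
  v <- if (inherits(summary, "variant_summary")) summary$variants else as.data.frame(summary)
  runs <- scan_homopolymers(seq, min_len = min_run)
  reps <- scan_microsatellites(seq)
  v$context <- rep(NA_character_, nrow(v))
  v$context_motif <- rep(NA_character_, nrow(v))
  idx <- which(v$vtype != "substitution")
  for (i in idx) {
    cc <- classify_indel_context(v[i, ], runs, reps)
    v$context[i] <- cc$context
    v$context_motif[i] <- cc$motif
  }
  n_indels <- length(idx)
  ctx <- v$context[idx]
  hp <- sum(ctx == "homopolymer")
  sizes <- v$length[idx]
  structure(list(
    variants = v,
    n_indels = n_indels,
    context_counts = table(factor(ctx, levels = c("homopolymer",
                                                  "microsatellite", "other"))),
    homopolymer_percent = if (n_indels) 100 * hp / n_indels else NA_real_,
    homopolymer_base_counts = table(factor(
      v$context_motif[idx][ctx == "homopolymer"], levels = c("A", "C", "G", "T"))),
    size_mean = if (n_indels) mean(sizes) else NA_real_,
    size_min = if (n_indels) min(sizes) else NA_integer_,
    size_max = if (n_indels) max(sizes) else NA_integer_
  ), class = "indel_context_summary")
}

#' @export
print.indel_context_summary <- function(x, ...) {
  cat(sprintf("indel_context_summary: %d indels, %.1f%% in homopolymers (%s), mean size %.1f nt\n",
              x$n_indels, x$homopolymer_percent,
              paste(names(x$context_counts), x$context_counts, sep = "=",
                    collapse = " "),
              x$size_mean))
  invisible(x)
}

#' Write homopolymer / microsatellite tracks as BED
#'
#' 0-based half-open intervals, BED convention.
#' @param track Output of [scan_homopolymers()] or [scan_microsatellites()].
#' @param chrom Chromosome label.
#' @param path Output path.
#' @export
write_track_bed <- function(track, chrom, path) {
  if ("base" %in% names(track)) {
    bed <- data.frame(chrom = chrom, start = track$start,
                      end = track$start + track$length, name = track$base)
  } else {
    bed <- data.frame(chrom = chrom, start = track$start,
                      end = track$start + track$tract_length, name = track$motif)
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bed)
}
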