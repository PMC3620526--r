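#' Call variants from a strain-pair alignment
#'
#' Walks the alignment columns and emits one record per substitution and one
#' per indel event (a maximal run of gap columns in one genome; a mixed run
#' containing gaps in both genomes is split into separate insertion and
#' deletion events at the run boundary). Indels are left-normalized: shifted
#' to the lowest position on genome A that yields the same alternate
#' sequence, the standard variant-normalization convention. Columns
#' containing `N` are excluded from substitution calls.
#'
#' @param map An [align_strain_pair()] result.
#' @param a,b The aligned records or sequences, in the same order.
#' @return data.frame of class `variant_table`: `vtype`
#'   (substitution/insertion/deletion), `pos` (0-based on genome A; for
#'   indels the first deleted base / the base before which the insertion
#'   occurs), `ref`, `alt` (empty string for the absent allele of an
#'   indel), `length`.
#' @export
call_variants <- function(map, a, b) {
  sa <- if (inherits(a, "genome_record")) a$sequence else toupper(a)
  sb <- if (inherits(b, "genome_record")) b$sequence else toupper(b)
  cols <- expand_columns(map$ops)

  m <- cols$op == "M"
  ba <- chars_at(sa, cols$apos[m]); bb <- chars_at(sb, cols$bpos[m])
  sub_idx <- which(ba != bb & ba != "N" & bb != "N")
  subs <- data.frame(vtype = rep("substitution", length(sub_idx)),
                     pos = cols$apos[m][sub_idx],
                     ref = ba[sub_idx], alt = bb[sub_idx],
                     length = rep(1L, length(sub_idx)),
                     stringsAsFactors = FALSE)

  # indel events: runs of I or D
  consumed_a <- cumsum(cols$op != "I")
  r <- rle(cols$op)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  indels <- list()
  for (i in which(r$values != "M")) {
    idx <- starts[i]:ends[i]
    if (r$values[i] == "D") {
      pos <- cols$apos[idx[1]]
      allele <- subseq0(sa, pos, pos + length(idx))
      norm <- normalize_indel(sa, pos, allele)
      indels[[length(indels) + 1L]] <- data.frame(
        vtype = "deletion", pos = norm$pos, ref = norm$allele, alt = "",
        length = length(idx), stringsAsFactors = FALSE)
    } else {
      bpos <- cols$bpos[idx[1]]
      allele <- subseq0(sb, bpos, bpos + length(idx))
      # position on A: number of A bases consumed before this column
      pos <- consumed_a[idx[1]]
      norm <- normalize_indel(sa, pos, allele)
      indels[[length(indels) + 1L]] <- data.frame(
        vtype = "insertion", pos = norm$pos, ref = "", alt = norm$allele,
        length = nchar(allele), stringsAsFactors = FALSE)
    }
  }
  out <- rbind(subs, do.call(rbind, indels))
  if (is.null(out)) {
    out <- data.frame(vtype = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      length = integer(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$pos, out$vtype), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Left-normalize an indel allele
#'
#' Shifts an insertion/deletion to the lowest position on the reference
#' sequence that yields the same alternate sequence: while the base before
#' the event equals the last base of the allele, the event moves one
#' position left and the allele rotates.
#'
#' @param ref_seq Reference (genome A) sequence.
#' @param pos 0-based event position.
#' @param allele Inserted or deleted bases.
#' @return list(pos, allele).
#' @export
normalize_indel <- function(ref_seq, pos, allele) {
  L <- nchar(allele)
  while (pos > 0L && chars_at(ref_seq, pos - 1L) == substr(allele, L, L)) {
    allele <- paste0(chars_at(ref_seq, pos - 1L), substr(allele, 1L, L - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, allele = allele)
}

#' Apply a variant table to a genome sequence
#'
#' Reconstructs genome B from genome A and the called variants; used for the
#' byte-for-byte reconstruction check of the caller.
#' @param seq Genome A sequence.
#' @param variants A [call_variants()] table.
#' @return The derived sequence.
#' @export
apply_variants <- function(seq, variants) {
  subs <- variants[variants$vtype == "substitution", , drop = FALSE]
  if (nrow(subs)) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    chars[subs$pos + 1L] <- subs$alt
    seq <- paste(chars, collapse = "")
  }
  ind <- variants[variants$vtype != "substitution", , drop = FALSE]
  if (nrow(ind)) {
    ind <- ind[order(ind$pos), , drop = FALSE]
    n <- nchar(seq)
    pieces <- character(0)
    cur <- 0L                               # bases of seq consumed so far
    for (i in seq_len(nrow(ind))) {
      p <- ind$pos[i]
      pieces <- c(pieces, substr(seq, cur + 1L, p))
      if (ind$vtype[i] == "deletion") {
        cur <- p + nchar(ind$ref[i])
      } else {
        pieces <- c(pieces, ind$alt[i])
        cur <- p
      }
    }
    pieces <- c(pieces, substr(seq, cur + 1L, n))
    seq <- paste(pieces, collapse = "")
  }
  seq
}

SUB_DIRECTIONS <- c("GCtoAT", "ATtoGC", "AtoT_or_TtoA", "GtoC_or_CtoG")

classify_direction <- function(ref, alt) {
  gc <- c("G", "C")
  ifelse(ref %in% gc & !(alt %in% gc), "GCtoAT",
  ifelse(!(ref %in% gc) & alt %in% gc, "ATtoGC",
  ifelse(ref %in% gc, "GtoC_or_CtoG", "AtoT_or_TtoA")))
}

is_transition <- function(ref, alt) {
  (ref %in% c("A", "G") & alt %in% c("A", "G")) |
    (ref %in% c("C", "T") & alt %in% c("C", "T"))
}

#' Classify called variants
#'
#' Labels every substitution as transition/transversion, assigns its
#' direction class (GC-to-AT gaining, AT-to-GC gaining, A-T or G-C neutral),
#' records which strain carries the A/T allele of a GC/AT-changing site, and
#' maps every variant onto genome A's partition class.
#'
#' @param variants A [call_variants()] table.
#' @param partition_a [build_partition()] of genome A.
#' @return list of class `variant_summary`: the labelled `variants` table
#'   plus summary counts -- totals by type, `ti`/`tv`, direction-class
#'   counts, per-partition counts, per-strain A/T-gain percentages among
#'   GC/AT-changing substitutions, and indel mean size.
#' @export
classify_variants <- function(variants, partition_a) {
  v <- as.data.frame(variants)
  n <- genome_length_from_partition(partition_a)
  v$partition <- partition_class_at(partition_a, pmin(v$pos, n - 1L))
  is_sub <- v$vtype == "substitution"
  v$ti <- rep(NA, nrow(v))
  v$ti[is_sub] <- is_transition(v$ref[is_sub], v$alt[is_sub])
  v$direction <- rep(NA_character_, nrow(v))
  v$direction[is_sub] <- classify_direction(v$ref[is_sub], v$alt[is_sub])
  v$at_gaining_strain <- rep(NA_character_, nrow(v))
  v$at_gaining_strain[is_sub] <-
    c(GCtoAT = "B", ATtoGC = "A", AtoT_or_TtoA = "neither",
      GtoC_or_CtoG = "neither")[v$direction[is_sub]]

  dir_counts <- stats::setNames(
    vapply(SUB_DIRECTIONS, function(d) sum(v$direction[is_sub] == d), integer(1)),
    SUB_DIRECTIONS)
  gcat_total <- dir_counts[["GCtoAT"]] + dir_counts[["ATtoGC"]]
  sizes <- v$length[!is_sub]
  structure(list(
    variants = v,
    n_substitutions = sum(is_sub),
    n_insertions = sum(v$vtype == "insertion"),
    n_deletions = sum(v$vtype == "deletion"),
    ti = sum(v$ti[is_sub]),
    tv = sum(!v$ti[is_sub]),
    ti_percent = if (any(is_sub)) 100 * sum(v$ti[is_sub]) / sum(is_sub) else NA_real_,
    direction_counts = dir_counts,
    gc_at_changing_percent = if (any(is_sub)) 100 * gcat_total / sum(is_sub) else NA_real_,
    at_gain_percent_B = if (gcat_total > 0) 100 * dir_counts[["GCtoAT"]] / gcat_total else NA_real_,
    at_gain_percent_A = if (gcat_total > 0) 100 * dir_counts[["ATtoGC"]] / gcat_total else NA_real_,
    partition_counts = table(factor(v$partition, levels = PARTITION_LEVELS)),
    substitution_partition_counts =
      table(factor(v$partition[is_sub], levels = PARTITION_LEVELS)),
    indel_mean_size = if (length(sizes)) mean(sizes) else NA_real_
  ), class = "variant_summary")
}

genome_length_from_partition <- function(partition) length(partition$classes)

#' @export
print.variant_summary <- function(x, ...) {
  cat(sprintf("variant_summary: %d substitutions (%d ti / %d tv), %d insertions, %d deletions\n",
              x$n_substitutions, x$ti, x$tv, x$n_insertions, x$n_deletions))
  cat("  direction:", paste(names(x$direction_counts), x$direction_counts,
                            sep = "=", collapse = " "), "\n")
  if (!is.na(x$indel_mean_size))
    cat(sprintf("  indel mean size: %.1f nt\n", x$indel_mean_size))
  invisible(x)
}

#' Write variants as a minimal tab-separated variant table
#'
#' VCF-body conventions: CHROM, 1-based POS, REF, ALT and an INFO column
#' carrying the classification labels. Indels are anchored on the preceding
#' reference base as in VCF.
#'
#' @param summary A [classify_variants()] result (or a bare variant table).
#' @param ref_seq Genome A sequence (for indel anchor bases).
#' @param chrom Chromosome/accession label.
#' @param path Output path.
#' @return Invisibly, the written data.frame.
#' @export
write_variant_table <- function(summary, ref_seq, chrom, path) {
  v <- if (inherits(summary, "variant_summary")) summary$variants else as.data.frame(summary)
  rows <- lapply(seq_len(nrow(v)), function(i) {
    pos <- v$pos[i]
    if (v$vtype[i] == "substitution") {
      out <- data.frame(CHROM = chrom, POS = pos + 1L, REF = v$ref[i], ALT = v$alt[i])
    } else if (v$vtype[i] == "deletion") {
      anchor <- if (pos > 0L) chars_at(ref_seq, pos - 1L) else chars_at(ref_seq, pos + nchar(v$ref[i]))
      if (pos > 0L) {
        out <- data.frame(CHROM = chrom, POS = pos, REF = paste0(anchor, v$ref[i]), ALT = anchor)
      } else {
        out <- data.frame(CHROM = chrom, POS = 1L, REF = paste0(v$ref[i], anchor), ALT = anchor)
      }
    } else {
      anchor <- if (pos > 0L) chars_at(ref_seq, pos - 1L) else chars_at(ref_seq, pos)
      if (pos > 0L) {
        out <- data.frame(CHROM = chrom, POS = pos, REF = anchor, ALT = paste0(anchor, v$alt[i]))
      } else {
        out <- data.frame(CHROM = chrom, POS = 1L, REF = anchor, ALT = paste0(v$alt[i], anchor))
      }
    }
    info <- c(sprintf("TYPE=%s", v$vtype[i]))
    if (!is.null(v$ti) && !is.na(v$ti[i])) {
      info <- c(info, sprintf("CLASS=%s", if (v$ti[i]) "ti" else "tv"),
                sprintf("DIR=%s", v$direction[i]))
    }
    if (!is.null(v$partition)) info <- c(info, sprintf("PART=%s", v$partition[i]))
    if (!is.null(v$context) && !is.na(v$context[i])) {
      info <- c(info, sprintf("CONTEXT=%s", v$context[i]))
    }
    out$INFO <- paste(info, collapse = ";")
    out
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(CHROM = character(0), POS = integer(0), REF = character(0),
               ALT = character(0), INFO = character(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
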