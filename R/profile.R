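#' Per-genome summary statistics
#'
#' Computes the usual genome-report quantities for a reduced bacterial
#' genome: size, feature counts, gene density, mean ORF and intergenic
#' lengths, and GC content overall and by partition class. `gc_genes` is
#' computed over positions classed `coding` or `rna`. Positions holding `N`
#' are excluded from both numerator and denominator of every GC figure.
#'
#' @param record A [genome_record()].
#' @param partition The [build_partition()] of `record`.
#' @return An object of class `genome_summary` (a list of named statistics,
#'   percentages kept at full precision).
#' @export
summarize_genome <- function(record, partition) {
  n <- genome_length(record)
  stopifnot(length(partition$classes) == n)
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  is_gc <- chars == "G" | chars == "C"
  is_acgt <- chars != "N"
  gc_of <- function(mask) {
    denom <- sum(is_acgt[mask])
    if (denom == 0) return(NA_real_)
    100 * sum(is_gc[mask]) / denom
  }
  cl <- partition$classes
  kinds <- vapply(record$features, function(f) f$kind, character(1))
  widths <- vapply(record$features, feature_width, integer(1))
  igr_runs <- rle(cl == 4L)
  igr_lens <- igr_runs$lengths[igr_runs$values]
  structure(list(
    id = record$id,
    size = n,
    n_cds = sum(kinds == "CDS"),
    n_rrna = sum(kinds == "rRNA"),
    n_trna = sum(kinds == "tRNA"),
    n_smallrna = sum(kinds == "smallRNA"),
    n_pseudogenes = sum(kinds == "pseudogene"),
    gene_density_percent = partition$gene_density_percent,
    mean_orf_length = if (any(kinds == "CDS")) mean(widths[kinds == "CDS"]) else NA_real_,
    mean_igr_length = if (length(igr_lens)) mean(igr_lens) else NA_real_,
    gc_overall = gc_of(rep(TRUE, n)),
    gc_genes = gc_of(cl <= 2L),
    gc_pseudogenes = gc_of(cl == 3L),
    gc_igr = gc_of(cl == 4L)
  ), class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat(sprintf("genome_summary '%s'\n", x$id))
  for (k in setdiff(names(x), "id")) {
    v <- x[[k]]
    cat(sprintf("  %-22s %s\n", k,
                if (is.numeric(v)) formatC(v, digits = 4, format = "fg") else v))
  }
  invisible(x)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  apply(expand.grid(b, b, b, stringsAsFactors = FALSE)[, 3:1], 1, paste, collapse = "")
}

split_codons <- function(seq) {
  substring(seq, seq(1L, nchar(seq) - 2L, 3L), seq(3L, nchar(seq), 3L))
}

#' Codon usage table
#'
#' Tallies codons over all complete, in-frame, N-free CDS. The final codon
#' of each CDS is tallied among stop codons when it is one (never among the
#' amino-acid codon counts); CDS with an internal stop codon are excluded
#' and reported.
#'
#' @param cds_set data.frame from [extract_cds()], or a character vector of
#'   in-frame CDS sequences.
#' @return Object of class `codon_usage_table`: list with `codon_counts`
#'   (named 64-vector of amino-acid codon tallies), `stop_counts`
#'   (TAA/TAG/TGA), `total_codons`, `excluded_internal_stop` (CDS names),
#'   `skipped_frame_or_n` (CDS names not length-3k or containing N).
#' @export
codon_usage <- function(cds_set) {
  if (is.character(cds_set)) {
    if (!length(cds_set)) cds_set <- data.frame(name = character(0),
      seq = character(0), frame_ok = logical(0), n_positions = character(0),
      stringsAsFactors = FALSE) else
    cds_set <- data.frame(name = paste0("cds", seq_along(cds_set)),
                          seq = cds_set,
                          frame_ok = nchar(cds_set) %% 3L == 0L,
                          n_positions = ifelse(grepl("N", cds_set), "N", ""),
                          stringsAsFactors = FALSE)
  }
  usable <- cds_set$frame_ok & cds_set$n_positions == ""
  skipped <- cds_set$name[!usable]
  counts <- stats::setNames(integer(64), all_codons())
  stop_counts <- stats::setNames(integer(3), STOP_CODONS)
  excluded <- character(0)
  for (i in which(usable)) {
    codons <- split_codons(cds_set$seq[[i]])
    k <- length(codons)
    internal <- codons[seq_len(k - 1L)]
    if (any(internal %in% STOP_CODONS)) {
      excluded <- c(excluded, cds_set$name[[i]])
      next
    }
    last <- codons[[k]]
    if (last %in% STOP_CODONS) {
      stop_counts[[last]] <- stop_counts[[last]] + 1L
      codons <- internal
    }
    tab <- table(codons)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  structure(list(codon_counts = counts, stop_counts = stop_counts,
                 total_codons = sum(counts) + sum(stop_counts),
                 excluded_internal_stop = excluded,
                 skipped_frame_or_n = skipped),
            class = "codon_usage_table")
}

#' Fraction of stop codons that are TAA
#' @param table A [codon_usage()] result.
#' @return Percentage (0-100), NA when no stop codons were tallied.
#' @export
taa_stop_percent <- function(table) {
  tot <- sum(table$stop_counts)
  if (tot == 0) return(NA_real_)
  100 * table$stop_counts[["TAA"]] / tot
}

genetic_code_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(names(gc), gc)
}

#' Within-family codon usage bias test
#'
#' For every amino acid with at least two synonymous codons, tests the
#' observed codon counts against the uniform distribution over the family
#' by Pearson chi-square goodness of fit; when any expected count falls
#' below 5 an exact multinomial test is used instead. Families with zero
#' total count are untestable.
#'
#' @param table A [codon_usage()] result.
#' @param alpha Significance level (default 0.01).
#' @return data.frame with one row per testable amino acid: `aa`,
#'   `n_codons`, `total`, `statistic` (chi-square, NA for exact test),
#'   `p_value`, `method`, `verdict` in biased/unbiased/untestable.
#' @export
codon_bias_test <- function(table, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  fams <- genetic_code_families()
  fams <- fams[vapply(fams, length, integer(1)) >= 2L]
  rows <- lapply(names(fams), function(aa) {
    counts <- table$codon_counts[fams[[aa]]]
    n <- sum(counts)
    if (n == 0) {
      return(data.frame(aa = aa, n_codons = length(counts), total = 0L,
                        statistic = NA_real_, p_value = NA_real_,
                        method = "none", verdict = "untestable",
                        stringsAsFactors = FALSE))
    }
    expected <- n / length(counts)
    if (expected < 5) {
      p <- exact_multinomial_p(as.integer(counts))
      stat <- NA_real_
      method <- "exact multinomial"
    } else {
      ct <- suppressWarnings(stats::chisq.test(counts, p = rep(1 / length(counts),
                                                               length(counts))))
      p <- ct$p.value
      stat <- unname(ct$statistic)
      method <- "chi-square"
    }
    data.frame(aa = aa, n_codons = length(counts), total = n,
               statistic = stat, p_value = p, method = method,
               verdict = if (p < alpha) "biased" else "unbiased",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Exact multinomial goodness-of-fit p-value against the uniform null:
# total probability of outcomes no more probable than the observed one.
exact_multinomial_p <- function(counts) {
  n <- sum(counts)
  k <- length(counts)
  p0 <- rep(1 / k, k)
  obs <- stats::dmultinom(counts, prob = p0)
  acc <- 0
  rec <- function(prefix, remaining, cells_left) {
    if (cells_left == 1L) {
      pr <- stats::dmultinom(c(prefix, remaining), prob = p0)
      if (pr <= obs * (1 + 1e-7)) acc <<- acc + pr
      return(invisible(NULL))
    }
    for (x in 0:remaining) rec(c(prefix, x), remaining - x, cells_left - 1L)
  }
  rec(integer(0), n, k)
  min(acc, 1)
}

#' Amino-acid composition profile ranked by codon GC-richness
#'
#' Translates the CDS set with the standard genetic code (bacterial start
#' codons ATG/GTG/TTG rendered as Met in first position) and returns the
#' per-amino-acid frequency over the proteome, ordered by decreasing mean
#' G+C fraction of each amino acid's synonymous codons (alphabetical
#' tie-break). Stop codons are excluded.
#'
#' @param cds_set As for [codon_usage()].
#' @return Object of class `aa_profile`: list with `freq` (named numeric,
#'   sums to 1, in gc-rank order), `gc_richness` (mean codon GC fraction per
#'   amino acid, same order).
#' @export
aa_profile <- function(cds_set) {
  if (is.character(cds_set)) {
    cds_set <- data.frame(name = paste0("cds", seq_along(cds_set)),
                          seq = cds_set,
                          frame_ok = nchar(cds_set) %% 3L == 0L,
                          n_positions = ifelse(grepl("N", cds_set), "N", ""),
                          stringsAsFactors = FALSE)
  }
  gc_code <- Biostrings::GENETIC_CODE
  aa_counts <- stats::setNames(numeric(length(unique(gc_code[gc_code != "*"]))),
                               sort(unique(gc_code[gc_code != "*"])))
  usable <- which(cds_set$frame_ok & cds_set$n_positions == "")
  for (i in usable) {
    codons <- split_codons(cds_set$seq[[i]])
    aas <- unname(gc_code[codons])
    if (length(aas) && codons[[1]] %in% c("ATG", "GTG", "TTG")) aas[[1]] <- "M"
    aas <- aas[!is.na(aas) & aas != "*"]
    tab <- table(aas)
    aa_counts[names(tab)] <- aa_counts[names(tab)] + as.integer(tab)
  }
  total <- sum(aa_counts)
  freq <- if (total > 0) aa_counts / total else aa_counts
  rank <- aa_gc_richness()
  ord <- names(rank)
  structure(list(freq = freq[ord], gc_richness = rank), class = "aa_profile")
}

#' Mean codon GC fraction per amino acid
#'
#' GC-richness of an amino acid is the mean G+C fraction over its synonymous
#' codons in the standard code; returned in decreasing order with
#' alphabetical tie-break.
#' @return Named numeric vector over the 20 amino acids.
#' @export
aa_gc_richness <- function() {
  fams <- genetic_code_families()
  gc_frac <- vapply(fams, function(codons) {
    mean(vapply(strsplit(codons, ""), function(b) mean(b %in% c("G", "C")),
                numeric(1)))
  }, numeric(1))
  gc_frac[order(-gc_frac, names(gc_frac))]
}
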