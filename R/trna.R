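#' tRNA gene inventory of a genome
#'
#' Counts functional tRNA genes per anticodon. The anticodon is read from
#' the `anticodon` qualifier when present, otherwise parsed from a product
#' string of the form `tRNA-Xxx(NNN)`. Features flagged as pseudogenes are
#' tallied separately and never enter the functional totals; tRNAs whose
#' anticodon cannot be resolved are counted in the total and flagged.
#'
#' @param record A [genome_record()].
#' @return Object of class `trna_inventory`: `anticodon_counts` (named
#'   integer), `total` (functional genes), `n_pseudo`, `n_unresolved`.
#' @export
trna_inventory <- function(record) {
  counts <- integer(0)
  total <- 0L; n_pseudo <- 0L; n_unres <- 0L
  for (f in record$features) {
    is_trna <- f$kind == "tRNA"
    is_pseudo_trna <- f$kind == "pseudogene" &&
      (grepl("^tRNA", f$qualifiers$product %||% "") ||
         !is.null(f$qualifiers$anticodon))
    if (is_pseudo_trna) { n_pseudo <- n_pseudo + 1L; next }
    if (!is_trna) next
    total <- total + 1L
    ac <- resolve_anticodon(f)
    if (is.na(ac)) { n_unres <- n_unres + 1L; next }
    counts[ac] <- (if (ac %in% names(counts)) counts[[ac]] else 0L) + 1L
  }
  structure(list(anticodon_counts = counts, total = total,
                 n_pseudo = n_pseudo, n_unresolved = n_unres),
            class = "trna_inventory")
}

resolve_anticodon <- function(f) {
  q <- f$qualifiers
  ac <- q$anticodon
  if (!is.null(ac)) {
    m <- regmatches(ac, regexpr("[ACGTUacgtu]{3}(?![ACGTUacgtu])", ac, perl = TRUE))
    if (length(m)) return(toupper(gsub("U", "T", toupper(m[[1]]))))
  }
  prod <- q$product %||% ""
  m <- regmatches(prod, regexpr("\\(([ACGTUacgtu]{3})\\)", prod))
  if (length(m)) return(toupper(gsub("U", "T", toupper(gsub("[()]", "", m[[1]])))))
  NA_character_
}

#' Proteome codon demand of a genome
#'
#' Tallies every codon over all functional CDS; stop codons are tallied but
#' excluded from `total_codons`, the genome's translational requirement.
#'
#' @param record A [genome_record()].
#' @return Object of class `codon_demand`: `codon_counts` (named 64-vector
#'   of sense-codon tallies), `stop_counts`, `total_codons`.
#' @export
codon_demand <- function(record) {
  usage <- codon_usage(extract_cds(record))
  structure(list(codon_counts = usage$codon_counts,
                 stop_counts = usage$stop_counts,
                 total_codons = sum(usage$codon_counts)),
            class = "codon_demand")
}

#' Regress tRNA gene count on codon demand across genomes
#'
#' Ordinary least squares of functional tRNA gene count on total sense-codon
#' demand over a panel of genomes; `r_squared` is the squared Pearson
#' correlation.
#'
#' @param panel data.frame with columns `genome`, `total_codons`,
#'   `trna_genes` (or a list of `list(inventory=, demand=, genome=)`).
#' @return Object of class `demand_regression`: `points`, `slope`,
#'   `intercept`, `r_squared`.
#' @export
fit_demand_regression <- function(panel) {
  panel <- as_panel_df(panel)
  if (nrow(panel) < 3L) stop("regression needs at least 3 genomes")
  if (stats::var(panel$total_codons) == 0 || stats::var(panel$trna_genes) == 0) {
    stop("zero variance in tRNA counts or codon demand")
  }
  fit <- stats::lm(trna_genes ~ total_codons, data = panel)
  structure(list(points = panel,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = stats::cor(panel$total_codons, panel$trna_genes)^2),
            class = "demand_regression")
}

as_panel_df <- function(panel) {
  if (is.data.frame(panel)) return(panel)
  do.call(rbind, lapply(seq_along(panel), function(i) {
    p <- panel[[i]]
    data.frame(genome = p$genome %||% paste0("g", i),
               total_codons = p$demand$total_codons,
               trna_genes = p$inventory$total,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.demand_regression <- function(x, ...) {
  cat(sprintf("demand_regression: %d genomes, slope %.3g, intercept %.3g, R^2 = %.3f\n",
              nrow(x$points), x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Leave-one-out overload score for one genome
#'
#' Compares the panel R-squared with and without a focal genome; a positive
#' `delta = r2_without - r2_with` flags the focal genome's tRNA inventory as
#' an outlier (overloaded or depleted) relative to its codon demand.
#'
#' @param panel As for [fit_demand_regression()]; at least 4 genomes.
#' @param focal Genome id present in the panel.
#' @return list(r2_with, r2_without, delta).
#' @export
overload_score <- function(panel, focal) {
  panel <- as_panel_df(panel)
  stopifnot(nrow(panel) >= 4L)
  if (!focal %in% panel$genome) stop("focal genome '", focal, "' not in panel")
  r2_with <- fit_demand_regression(panel)$r_squared
  r2_without <- fit_demand_regression(panel[panel$genome != focal, ])$r_squared
  list(r2_with = r2_with, r2_without = r2_without,
       delta = r2_without - r2_with)
}

#' Sense codons in demand with no cognate tRNA
#'
#' A tRNA is cognate for a codon when its anticodon is the exact
#' reverse-complement (Watson-Crick) match; an optional wobble table
#' (data.frame anticodon, codon) extends decoding. Codons with demand > 0
#' and no cognate are returned in decreasing demand.
#'
#' @param inventory A [trna_inventory()].
#' @param demand A [codon_demand()] from the same genome.
#' @param wobble Optional data.frame with columns `anticodon`, `codon`.
#' @return data.frame `codon`, `demand`.
#' @export
codon_coverage_gaps <- function(inventory, demand, wobble = NULL) {
  acs <- names(inventory$anticodon_counts)[inventory$anticodon_counts > 0L]
  covered <- vapply(acs, revcomp_fast, character(1), USE.NAMES = FALSE)
  if (!is.null(wobble)) {
    covered <- c(covered, wobble$codon[wobble$anticodon %in% acs])
  }
  sense <- demand$codon_counts[!(names(demand$codon_counts) %in% STOP_CODONS)]
  gaps <- sense[sense > 0L & !(names(sense) %in% covered)]
  out <- data.frame(codon = names(gaps), demand = as.integer(gaps),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$demand, out$codon), , drop = FALSE]
  rownames(out) <- NULL
  out
}
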