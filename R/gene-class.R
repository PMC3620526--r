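#' Classify annotated ORFs as functional genes or pseudogenes
#'
#' Applies the two non-exclusionary functional-ORF criteria used for
#' reduced endosymbiont genomes: an ORF is functional iff it conserves at
#' least 80% of the sequence length of its closest ortholog, or its
#' essential functional domains are intact (domain status is an externally
#' supplied flag, e.g. from a Pfam scan run upstream). The 80% boundary is
#' inclusive.
#'
#' @param evidence data.frame with columns `orf_length`, `ortholog_length`
#'   and `essential_domains_intact` (logical; NA = unknown). An optional
#'   `locus` column is carried through.
#' @param length_threshold Conservation threshold (default 0.80).
#' @return The evidence table with a `classification` column
#'   (`functional`/`pseudogene`).
#' @export
classify_orf <- function(evidence, length_threshold = 0.80) {
  ev <- as.data.frame(evidence)
  if (!all(c("orf_length", "ortholog_length") %in% names(ev))) {
    stop("evidence must have orf_length and ortholog_length columns")
  }
  if (is.null(ev$essential_domains_intact)) ev$essential_domains_intact <- NA
  ratio_known <- !is.na(ev$orf_length) & !is.na(ev$ortholog_length)
  domain_known <- !is.na(ev$essential_domains_intact)
  if (any(!ratio_known & !domain_known)) {
    bad <- which(!ratio_known & !domain_known)
    stop("unclassifiable ORF(s) (no ortholog length and no domain flag): row ",
         paste(bad, collapse = ", "))
  }
  if (any(ev$orf_length[ratio_known] <= 0) ||
      any(ev$ortholog_length[ratio_known] <= 0)) {
    stop("lengths must be positive")
  }
  length_ok <- ratio_known & (ev$orf_length / ev$ortholog_length >= length_threshold)
  domain_ok <- domain_known & ev$essential_domains_intact %in% TRUE
  ev$classification <- ifelse(length_ok | domain_ok, "functional", "pseudogene")
  ev
}
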