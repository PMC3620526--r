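#' Pair ortholog coding sequences between two strains
#'
#' Matches CDS by gene name / locus tag. Equal-length pairs are stacked
#' codon on codon; length-mismatched pairs are aligned with the affine-gap
#' aligner and only codon columns where both sequences contribute a full,
#' in-frame, gap-free codon are retained (so frame-preserving indels drop
#' the affected codon columns and frame-shifted tails are discarded).
#'
#' @param cds_a,cds_b [extract_cds()] tables for the two strains.
#' @return list of class `codon_alignment_set`: `alignments` (named list of
#'   two-row codon matrices), `unmatched_a`, `unmatched_b`, `n_pairs`.
#' @export
pair_orthologs <- function(cds_a, cds_b) {
  dup_a <- unique(cds_a$name[duplicated(cds_a$name)])
  dup_b <- unique(cds_b$name[duplicated(cds_b$name)])
  if (length(dup_a) || length(dup_b)) {
    stop("duplicate gene names: ",
         paste(unique(c(dup_a, dup_b)), collapse = ", "))
  }
  shared <- intersect(cds_a$name, cds_b$name)
  alns <- list()
  for (g in shared) {
    sa <- cds_a$seq[cds_a$name == g]
    sb <- cds_b$seq[cds_b$name == g]
    if (grepl("N", sa, fixed = TRUE) || grepl("N", sb, fixed = TRUE)) next
    alns[[g]] <- codon_align_pair(sa, sb)
  }
  structure(list(alignments = alns,
                 unmatched_a = setdiff(cds_a$name, shared),
                 unmatched_b = setdiff(cds_b$name, shared),
                 n_pairs = length(alns)),
            class = "codon_alignment_set")
}

# Two equal-length codon vectors from a possibly length-mismatched CDS pair.
codon_align_pair <- function(sa, sb) {
  if (nchar(sa) == nchar(sb)) {
    return(rbind(split_codons(sa), split_codons(sb)))
  }
  nw <- .nw_align_cpp(sa, sb)
  cols <- expand_columns(data.frame(op = nw$op, len = nw$len))
  m <- cols$op == "M"
  apos <- cols$apos[m]; bpos <- cols$bpos[m]
  # keep codon columns where three consecutive aligned matches cover one
  # full codon in both sequences
  keep <- which(apos %% 3L == 0L)
  codA <- character(0); codB <- character(0)
  mpos <- seq_along(apos)
  for (i in keep) {
    if (i + 2L > length(apos)) next
    if (apos[i + 1L] == apos[i] + 1L && apos[i + 2L] == apos[i] + 2L &&
        bpos[i] %% 3L == 0L &&
        bpos[i + 1L] == bpos[i] + 1L && bpos[i + 2L] == bpos[i] + 2L) {
      codA <- c(codA, subseq0(sa, apos[i], apos[i] + 3L))
      codB <- c(codB, subseq0(sb, bpos[i], bpos[i] + 3L))
    }
  }
  rbind(codA, codB)
}

#' Synonymous and non-synonymous site counts of a codon (NG86)
#'
#' For each of the three positions, the synonymous fraction is the number of
#' single-base changes that are synonymous and do not create a stop codon,
#' divided by the number of non-stop changes at that position. `s` is the
#' sum of fractions, `n = 3 - s`.
#'
#' @param codon 3-letter codon over `{A,C,G,T}`; stop codons are an error.
#' @return c(s = synonymous sites, n = non-synonymous sites).
#' @export
count_sites_ng86 <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[[codon]]
  if (is.na(aa) || aa == "*") stop("stop or invalid codon: ", codon)
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    ref <- substr(codon, p, p)
    syn <- 0L; valid <- 0L
    for (bb in setdiff(bases, ref)) {
      mut <- codon
      substr(mut, p, p) <- bb
      maa <- code[[mut]]
      if (maa == "*") next
      valid <- valid + 1L
      if (maa == aa) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  c(s = s, n = 3 - s)
}

#' Synonymous/non-synonymous differences between two codons (NG86)
#'
#' Codons differing at more than one position are scored by averaging the
#' synonymous/non-synonymous step counts over all minimal mutational
#' pathways that avoid stop codons; pathways through a stop are excluded.
#' When every pathway hits a stop the pair is unscorable.
#'
#' @param c1,c2 Codons over `{A,C,G,T}` (non-stop).
#' @return c(sd, nd), or c(NA, NA) when no stop-free pathway exists.
#' @export
count_diffs_ng86 <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(diff_pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  paths <- perms(diff_pos)
  sd_tot <- 0; nd_tot <- 0; n_valid <- 0L
  for (ord in paths) {
    cur <- c1
    sd <- 0L; nd <- 0L
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[[nxt]] == "*") { ok <- FALSE; break }
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    if (ok) {
      sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0L) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = sd_tot / n_valid, nd = nd_tot / n_valid)
}

perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

jukes_cantor <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) stop("proportion of differences >= 0.75: Jukes-Cantor correction undefined")
  -0.75 * log(1 - 4 * p / 3)
}

#' Estimate dS, dN and omega over ortholog codon alignments (NG86)
#'
#' Concatenates the codon columns of all alignments, counts synonymous and
#' non-synonymous sites (averaged over the two sequences) and differences
#' (pathway-averaged), applies the Jukes-Cantor correction
#' `d = -(3/4) ln(1 - 4p/3)`, and attaches codon-column bootstrap standard
#' errors. Codon pairs containing a stop codon, and pairs with no stop-free
#' mutational pathway, are dropped and counted.
#'
#' @param alignments A [pair_orthologs()] result, a single codon matrix, or
#'   a list of codon matrices.
#' @param bootstrap_reps Bootstrap replicates for standard errors (default
#'   1000; 0 disables).
#' @param seed Bootstrap seed.
#' @return Object of class `selection_summary` with fields `Sd`, `Nd`, `S`,
#'   `N`, `pS`, `pN`, `dS`, `dN`, `dS_se`, `dN_se`, `omega` (NA when dS is
#'   0 or undefined), `n_codons`, `n_skipped`.
#' @export
estimate_dnds <- function(alignments, bootstrap_reps = 1000L, seed = 1L) {
  if (inherits(alignments, "codon_alignment_set")) alignments <- alignments$alignments
  if (is.matrix(alignments)) alignments <- list(alignments)
  codA <- unlist(lapply(alignments, function(m) m[1L, ]), use.names = FALSE)
  codB <- unlist(lapply(alignments, function(m) m[2L, ]), use.names = FALSE)
  stopifnot(length(codA) == length(codB), length(codA) >= 1L)

  code <- Biostrings::GENETIC_CODE
  usable <- code[codA] != "*" & code[codB] != "*" &
    !is.na(code[codA]) & !is.na(code[codB])
  n_skipped <- sum(!usable)
  codA <- codA[usable]; codB <- codB[usable]

  site_cache <- new.env(parent = emptyenv())
  sites_of <- function(codon) {
    v <- site_cache[[codon]]
    if (is.null(v)) {
      v <- count_sites_ng86(codon)
      site_cache[[codon]] <- v
    }
    v
  }
  diff_cache <- new.env(parent = emptyenv())
  diffs_of <- function(a, b) {
    key <- paste0(a, b)
    v <- diff_cache[[key]]
    if (is.null(v)) {
      v <- count_diffs_ng86(a, b)
      diff_cache[[key]] <- v
    }
    v
  }

  per_codon <- vapply(seq_along(codA), function(i) {
    sA <- sites_of(codA[i]); sB <- sites_of(codB[i])
    d <- diffs_of(codA[i], codB[i])
    c(S = (sA[["s"]] + sB[["s"]]) / 2, N = (sA[["n"]] + sB[["n"]]) / 2,
      Sd = d[["sd"]], Nd = d[["nd"]])
  }, numeric(4))

  unscorable <- is.na(per_codon["Sd", ])
  n_skipped <- n_skipped + sum(unscorable)
  per_codon <- per_codon[, !unscorable, drop = FALSE]
  if (!ncol(per_codon)) stop("no scorable codon columns")

  agg <- function(cols) {
    S <- sum(per_codon["S", cols]); N <- sum(per_codon["N", cols])
    Sd <- sum(per_codon["Sd", cols]); Nd <- sum(per_codon["Nd", cols])
    pS <- Sd / S; pN <- Nd / N
    c(dS = jukes_cantor(pS), dN = jukes_cantor(pN))
  }
  S <- sum(per_codon["S", ]); N <- sum(per_codon["N", ])
  Sd <- sum(per_codon["Sd", ]); Nd <- sum(per_codon["Nd", ])
  pS <- Sd / S; pN <- Nd / N
  dS <- jukes_cantor(pS); dN <- jukes_cantor(pN)

  dS_se <- NA_real_; dN_se <- NA_real_
  if (bootstrap_reps > 0L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    nc <- ncol(per_codon)
    boots <- vapply(seq_len(bootstrap_reps), function(r) {
      tryCatch(agg(sample.int(nc, nc, replace = TRUE)),
               error = function(e) c(dS = NA_real_, dN = NA_real_))
    }, numeric(2))
    dS_se <- stats::sd(boots["dS", ], na.rm = TRUE)
    dN_se <- stats::sd(boots["dN", ], na.rm = TRUE)
  }
  structure(list(Sd = Sd, Nd = Nd, S = S, N = N, pS = pS, pN = pN,
                 dS = dS, dN = dN, dS_se = dS_se, dN_se = dN_se,
                 omega = if (is.na(dS) || dS == 0) NA_real_ else dN / dS,
                 n_codons = ncol(per_codon), n_skipped = n_skipped),
            class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  cat(sprintf("selection_summary: %d codons | Sd=%.2f Nd=%.2f S=%.1f N=%.1f\n",
              x$n_codons, x$Sd, x$Nd, x$S, x$N))
  cat(sprintf("  dS = %.4g +/- %.2g, dN = %.4g +/- %.2g, omega = %s\n",
              x$dS, x$dS_se, x$dN, x$dN_se,
              if (is.na(x$omega)) "undefined" else sprintf("%.2f", x$omega)))
  invisible(x)
}
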