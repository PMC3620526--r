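#' Specification for a synthetic annotated genome
#'
#' Defaults emulate the architecture of a reduced, AT-biased endosymbiont
#' genome: ~150 kb, 44% GC, dense but not saturated coding fraction, a small
#' tRNA set, a handful of pseudogenes, homopolymer-enriched intergenic
#' regions, and (optionally) a duplicated rRNA-like block.
#'
#' @param length Genome length in bp.
#' @param gc_content Target GC fraction in (0,1).
#' @param n_cds,n_trna,n_pseudogenes Feature counts.
#' @param cds_len_meanlog,cds_len_sdlog Lognormal parameters of CDS length
#'   in codons.
#' @param duplication `NULL`, or `list(length =, copies =)` for an exactly
#'   duplicated rRNA-like block.
#' @param homopolymer_rate Planted homopolymer runs (length 6-12 of A or T)
#'   per kb of intergenic sequence.
#' @param seed Integer seed; generation is deterministic per seed.
#' @return list of class `genome_spec`.
#' @export
genome_spec <- function(length = 150000L, gc_content = 0.44,
                        n_cds = 110L, n_trna = 10L, n_pseudogenes = 8L,
                        cds_len_meanlog = log(300), cds_len_sdlog = 0.35,
                        duplication = NULL, homopolymer_rate = 1.5,
                        seed = 1L) {
  stopifnot(length >= 1L, gc_content > 0, gc_content < 1)
  structure(as.list(environment()), class = "genome_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

sample_bases <- function(n, gc) {
  sample(c("G", "C", "A", "T"), n, replace = TRUE,
         prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
}

# Base-level GC to use when sampling sense codons so that the realized GC,
# conditional on rejecting stop codons (which are AT-rich), hits the target.
codon_gc_for_target <- function(target) {
  conditional_gc <- function(p) {
    base_p <- c(A = (1 - p) / 2, C = p / 2, G = p / 2, T = (1 - p) / 2)
    codons <- all_codons()
    w <- vapply(strsplit(codons, ""), function(b) prod(base_p[b]), numeric(1))
    gc_frac <- vapply(strsplit(codons, ""), function(b) mean(b %in% c("G", "C")),
                      numeric(1))
    sense <- !(codons %in% STOP_CODONS)
    sum(w[sense] * gc_frac[sense]) / sum(w[sense])
  }
  if (target <= 0.02 || target >= 0.97) return(target)
  stats::uniroot(function(p) conditional_gc(p) - target,
                 lower = 0.01, upper = 0.98, tol = 1e-6)$root
}

sample_sense_codons <- function(n, gc) {
  gc <- codon_gc_for_target(gc)
  mat <- matrix(sample_bases(3L * n, gc), ncol = 3L)
  codons <- paste0(mat[, 1L], mat[, 2L], mat[, 3L])
  bad <- codons %in% STOP_CODONS
  while (any(bad)) {
    m2 <- matrix(sample_bases(3L * sum(bad), gc), ncol = 3L)
    codons[bad] <- paste0(m2[, 1L], m2[, 2L], m2[, 3L])
    bad <- codons %in% STOP_CODONS
  }
  codons
}

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val")

#' Generate a synthetic annotated genome
#'
#' Deterministic for a fixed seed. CDS begin with ATG, end with a stop codon
#' (TAA favoured, as in AT-biased genomes) and contain no internal stop;
#' features never overlap; intergenic blocks carry planted maximal A/T
#' homopolymer runs whose flanking bases are forced to differ from the run
#' base; the optional duplicated block is inserted as two byte-identical
#' rRNA features. Base composition is compensated for the planted AT runs so
#' the realized genome GC tracks the requested value.
#'
#' @param spec A [genome_spec()].
#' @return A [genome_record()].
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    n_dup <- if (is.null(spec$duplication)) 0L else spec$duplication$copies
    dup_len <- if (n_dup) spec$duplication$length else 0L

    cds_codons <- pmax(30L, round(stats::rlnorm(spec$n_cds,
                                                spec$cds_len_meanlog,
                                                spec$cds_len_sdlog)))
    cds_lens <- 3L * (cds_codons + 2L)           # start + body + stop
    trna_lens <- rep(72L, spec$n_trna)
    pseudo_lens <- sample(300:700, spec$n_pseudogenes, replace = TRUE)
    feat_lens <- c(cds_lens, trna_lens, pseudo_lens, rep(dup_len, n_dup))
    feat_kind <- c(rep("CDS", spec$n_cds), rep("tRNA", spec$n_trna),
                   rep("pseudogene", spec$n_pseudogenes), rep("rRNA", n_dup))
    n_feat <- length(feat_lens)
    igr_total <- spec$length - sum(feat_lens)
    if (igr_total < n_feat + 1L) {
      stop("infeasible genome spec: features (", sum(feat_lens),
           " bp) exceed genome length ", spec$length)
    }

    # homopolymer plan and GC compensation for the planted AT runs
    n_runs <- round(spec$homopolymer_rate * igr_total / 1000)
    run_lens <- if (n_runs) sample(6:12, n_runs, replace = TRUE) else integer(0)
    gc_adj <- min(0.98, spec$gc_content * spec$length /
                    max(1, spec$length - sum(run_lens)))

    # feature order and IGR gap sizes (every feature separated by >= 1 bp)
    ord <- sample.int(n_feat)
    feat_lens <- feat_lens[ord]; feat_kind <- feat_kind[ord]
    cuts <- sort(sample.int(igr_total - 1L, n_feat))
    gap_sizes <- diff(c(0L, cuts, igr_total))    # n_feat + 1 gaps, each >= 1

    dup_block <- if (n_dup) paste(sample_bases(dup_len, gc_adj), collapse = "") else NULL
    aa3_pool <- unname(AA3)

    pieces <- character(0)
    feats <- list()
    pos <- 0L
    cds_i <- 0L; trna_i <- 0L; pseudo_i <- 0L; dup_i <- 0L
    add_piece <- function(s) { pieces[[length(pieces) + 1L]] <<- s; pos <<- pos + nchar(s) }

    for (i in seq_len(n_feat)) {
      add_piece(make_igr_block(gap_sizes[i], gc_adj))
      start <- pos
      kind <- feat_kind[i]
      if (kind == "CDS") {
        cds_i <- cds_i + 1L
        body <- paste(sample_sense_codons(feat_lens[i] / 3L - 2L, gc_adj), collapse = "")
        stopc <- sample(STOP_CODONS, 1L, prob = c(0.6, 0.2, 0.2))
        s <- paste0("ATG", body, stopc)
        strand <- sample(c("+", "-"), 1L)
        add_piece(if (strand == "-") revcomp(s) else s)
        feats[[length(feats) + 1L]] <- feature("CDS", strand,
          cbind(start, pos), name = sprintf("g%04d", cds_i),
          qualifiers = list(product = "hypothetical protein"))
      } else if (kind == "tRNA") {
        trna_i <- trna_i + 1L
        aa <- sample(names(AA3), 1L)
        codon <- sample(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa], 1L)
        codon <- gsub("U", "T", codon)
        add_piece(paste(sample_bases(feat_lens[i], gc_adj), collapse = ""))
        feats[[length(feats) + 1L]] <- feature("tRNA", sample(c("+", "-"), 1L),
          cbind(start, pos), name = sprintf("t%04d", trna_i),
          qualifiers = list(product = sprintf("tRNA-%s", AA3[[aa]]),
                            anticodon = revcomp_fast(codon)))
      } else if (kind == "pseudogene") {
        pseudo_i <- pseudo_i + 1L
        add_piece(paste(sample_bases(feat_lens[i], gc_adj), collapse = ""))
        feats[[length(feats) + 1L]] <- feature("pseudogene", sample(c("+", "-"), 1L),
          cbind(start, pos), name = sprintf("ps%03d", pseudo_i),
          qualifiers = list(note = "pseudogene remnant"))
      } else {                                   # duplicated rRNA-like block
        dup_i <- dup_i + 1L
        add_piece(dup_block)
        feats[[length(feats) + 1L]] <- feature("rRNA", "+",
          cbind(start, pos), name = sprintf("rrn_dup%d", dup_i),
          qualifiers = list(product = "ribosomal RNA region (duplicated)"))
      }
    }
    add_piece(make_igr_block(gap_sizes[n_feat + 1L], gc_adj))
    seq <- paste(pieces, collapse = "")

    # plant homopolymer runs inside IGR positions, flanks forced different
    if (n_runs) {
      occupied <- unlist(lapply(feats, function(f)
        seq.int(f$intervals[1L, 1L], f$intervals[1L, 2L] - 1L)), use.names = FALSE)
      igr_mask <- rep(TRUE, spec$length)
      igr_mask[occupied + 1L] <- FALSE
      chars <- strsplit(seq, "", fixed = TRUE)[[1]]
      placed_spans <- integer(0)
      for (rl in run_lens) {
        for (try in 1:100) {
          p <- sample.int(spec$length - rl - 2L, 1L)   # 1-based start of flank
          span <- p:(p + rl + 1L)                       # run + two flanks
          if (!all(igr_mask[span])) next
          if (length(intersect(span, placed_spans))) next
          base <- sample(c("A", "T"), 1L)
          other <- if (base == "A") "G" else "C"
          chars[p] <- other
          chars[(p + 1L):(p + rl)] <- base
          chars[p + rl + 1L] <- other
          placed_spans <- c(placed_spans, span)
          break
        }
      }
      seq <- paste(chars, collapse = "")
    }
    genome_record(sprintf("synthetic_%d", spec$seed), seq,
                  features = feats, circular = TRUE)
  })
}

make_igr_block <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample_bases(n, gc), collapse = "")
}

#' Mutation model for deriving a second strain
#'
#' Defaults reflect the scale of a near-identical endosymbiont strain pair:
#' 23 substitutions with 43.5% transitions, a 45% share of AT-gaining
#' (GC-to-AT) changes, and 5 short indels of 1-2 nt of which 58.3% target
#' homopolymer runs.
#'
#' @param n_substitutions,n_indels Event counts.
#' @param transition_fraction Probability a substitution is a transition
#'   (transitions always change GC/AT content, so `transition_fraction`
#'   cannot exceed `gc_to_at_fraction + at_to_gc_fraction`).
#' @param gc_to_at_fraction Probability a substitution is an AT-gaining
#'   (GC-to-AT) change.
#' @param at_to_gc_fraction Probability a substitution is a GC-gaining
#'   (AT-to-GC) change; the remaining mass goes to the content-neutral A-T
#'   and G-C classes, split by the base composition at the sampled sites.
#' @param indel_size_probs Named numeric: indel sizes and their
#'   probabilities.
#' @param homopolymer_targeting_prob Probability an indel targets a
#'   homopolymer run (expanding/contracting it by whole copies of its base).
#' @param coding_synonymous_fraction `NULL`, or a fraction f: substitutions
#'   are then placed only in CDS interiors and are synonymous with
#'   probability exactly f (stop-creating changes excluded).
#' @param min_spacing Minimum distance in bp between planted events.
#' @param seed Integer seed.
#' @return list of class `mutation_model`.
#' @export
mutation_model <- function(n_substitutions = 23L, transition_fraction = 0.435,
                           gc_to_at_fraction = 0.45, at_to_gc_fraction = 0.45,
                           n_indels = 5L,
                           indel_size_probs = c("1" = 0.8, "2" = 0.2),
                           homopolymer_targeting_prob = 0.583,
                           coding_synonymous_fraction = NULL,
                           min_spacing = 10L, seed = 1L) {
  stopifnot(transition_fraction >= 0, transition_fraction <= 1,
            gc_to_at_fraction >= 0, at_to_gc_fraction >= 0,
            gc_to_at_fraction + at_to_gc_fraction <= 1,
            transition_fraction <= gc_to_at_fraction + at_to_gc_fraction ||
              n_substitutions == 0L,
            homopolymer_targeting_prob >= 0, homopolymer_targeting_prob <= 1)
  structure(as.list(environment()), class = "mutation_model")
}

#' Derive a mutated strain and its truth table
#'
#' Plants the model's substitutions and indels on the ancestor without
#' replacement, respecting the minimum spacing, left-normalizing every indel
#' with the same normalizer the variant caller uses, and recording for each
#' event the labels the pipeline is expected to recover: ti/tv, direction
#' class, AT-gaining strain, partition class, indel sequence context, and
#' synonymous/non-synonymous status for coding substitutions. Deterministic
#' per seed. Feature coordinates are lifted through the planted indels so
#' the derived record is a valid annotated genome.
#'
#' @param ancestor A [genome_record()].
#' @param model A [mutation_model()].
#' @return list(strain = derived [genome_record()], truth = data.frame).
#' @export
derive_strain <- function(ancestor, model) {
  stopifnot(inherits(ancestor, "genome_record"), inherits(model, "mutation_model"))
  seq <- ancestor$sequence
  n <- nchar(seq)
  partition <- build_partition(ancestor)
  runs <- scan_homopolymers(seq, min_len = 6L)
  reps <- scan_microsatellites(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]

  with_seed(model$seed, {
    events <- list()
    blocked <- logical(n)              # genome positions blocked by events
    spacing_ok <- function(lo, hi) {
      idx <- max(1L, lo + 1L):min(n, hi + 1L)
      !any(blocked[idx])
    }
    reserve <- function(lo, hi) {
      idx <- max(1L, lo - model$min_spacing + 1L):min(n, hi + model$min_spacing + 1L)
      blocked[idx] <<- TRUE
    }
    sizes <- as.integer(names(model$indel_size_probs))

    # ---- indels ----
    run_used <- logical(nrow(runs))
    for (e in seq_len(model$n_indels)) {
      placed <- FALSE
      for (try in 1:500) {
        hp <- stats::runif(1) < model$homopolymer_targeting_prob && any(!run_used)
        s <- sample(sizes, 1L, prob = model$indel_size_probs)
        del <- stats::runif(1) < 0.5
        if (hp) {
          cand <- which(!run_used)
          if (!length(cand)) next
          ri <- if (length(cand) == 1L) cand else sample(cand, 1L)
          if (del) s <- min(s, runs$length[ri] - 1L)  # keep the run in place
          pos <- runs$start[ri]
          allele <- strrep(runs$base[ri], s)
          lo <- runs$start[ri] - 1L; hi <- runs$start[ri] + runs$length[ri]
          if (!spacing_ok(lo, hi)) next
          run_used[ri] <- TRUE
          reserve(lo, hi)
        } else {
          pos <- sample.int(n - s - 2L, 1L)
          if (del) {
            allele <- subseq0(seq, pos, pos + s)
          } else {
            allele <- paste(sample(c("A", "C", "G", "T"), s, replace = TRUE),
                            collapse = "")
          }
          norm <- normalize_indel(seq, pos, allele)
          pos <- norm$pos; allele <- norm$allele
          if (!spacing_ok(pos - 1L, pos + s)) next
          reserve(pos - 1L, pos + s)
        }
        v <- data.frame(vtype = if (del) "deletion" else "insertion",
                        pos = pos,
                        ref = if (del) allele else "",
                        alt = if (del) "" else allele,
                        length = s, stringsAsFactors = FALSE)
        ctx <- classify_indel_context(v, runs, reps)
        v$ti <- NA; v$direction <- NA_character_
        v$at_gaining_strain <- NA_character_
        v$partition <- partition_class_at(partition, min(pos, n - 1L))
        v$context <- ctx$context; v$context_motif <- ctx$motif
        v$syn <- NA
        events[[length(events) + 1L]] <- v
        placed <- TRUE
        break
      }
      if (!placed) stop("cannot place indel ", e, " with min_spacing ",
                        model$min_spacing, " after bounded retries")
    }

    # ---- substitutions (vector accumulators: event counts can be large) ----
    ns <- model$n_substitutions
    s_pos <- integer(ns); s_ref <- character(ns); s_alt <- character(ns)
    s_syn <- rep(NA, ns)
    if (!is.null(model$coding_synonymous_fraction)) {
      cds_feats <- Filter(function(f) f$kind == "CDS", ancestor$features)
      if (!length(cds_feats)) stop("coding_synonymous_fraction set but no CDS")
      for (e in seq_len(ns)) {
        want_syn <- stats::runif(1) < model$coding_synonymous_fraction
        placed <- FALSE
        for (try in 1:1000) {
          f <- cds_feats[[sample.int(length(cds_feats), 1L)]]
          cand <- coding_sub_candidate(seq, f, want_syn)
          if (is.null(cand)) next
          if (!spacing_ok(cand$pos, cand$pos)) next
          reserve(cand$pos, cand$pos)
          s_pos[e] <- cand$pos; s_ref[e] <- cand$ref; s_alt[e] <- cand$alt
          s_syn[e] <- want_syn
          placed <- TRUE
          break
        }
        if (!placed) stop("cannot place coding substitution ", e,
                          " after bounded retries")
      }
    } else if (ns > 0L) {
      # direction class drawn explicitly: GCtoAT with prob g, ATtoGC with
      # prob a, content-neutral otherwise; transitions only exist inside the
      # two content-changing classes, so P(ti | changing) = tf / (g + a)
      # keeps the marginal transition fraction at tf exactly.
      g <- model$gc_to_at_fraction; a <- model$at_to_gc_fraction
      gc_pos <- which(chars %in% c("G", "C")) - 1L
      at_pos <- which(chars %in% c("A", "T")) - 1L
      for (e in seq_len(ns)) {
        u <- stats::runif(1)
        cls <- if (u < g) "GCtoAT" else if (u < g + a) "ATtoGC" else "neutral"
        ti <- cls != "neutral" &&
          stats::runif(1) < model$transition_fraction / (g + a)
        placed <- FALSE
        for (try in 1:1000) {
          if (cls == "GCtoAT") {
            pos <- gc_pos[sample.int(length(gc_pos), 1L)]
            ref <- chars[pos + 1L]
            alt <- if (ti) c(G = "A", C = "T")[[ref]]
                   else c(G = "T", C = "A")[[ref]]
          } else if (cls == "ATtoGC") {
            pos <- at_pos[sample.int(length(at_pos), 1L)]
            ref <- chars[pos + 1L]
            alt <- if (ti) c(A = "G", T = "C")[[ref]]
                   else c(A = "C", T = "G")[[ref]]
          } else {
            pos <- sample.int(n, 1L) - 1L
            ref <- chars[pos + 1L]
            if (ref == "N") next
            alt <- c(A = "T", T = "A", G = "C", C = "G")[[ref]]
          }
          if (!spacing_ok(pos, pos)) next
          reserve(pos, pos)
          s_pos[e] <- pos; s_ref[e] <- ref; s_alt[e] <- alt
          placed <- TRUE
          break
        }
        if (!placed) stop("cannot place substitution ", e,
                          " after bounded retries")
      }
    }
    if (ns > 0L) {
      part <- partition_class_at(partition, s_pos)
      if (is.null(model$coding_synonymous_fraction)) {
        in_cds <- part == "coding"
        s_syn[in_cds] <- vapply(which(in_cds), function(i) {
          substitution_is_synonymous(seq, ancestor$features, s_pos[i], s_alt[i])
        }, logical(1))
      }
      dirn <- classify_direction(s_ref, s_alt)
      subs <- data.frame(
        vtype = "substitution", pos = s_pos, ref = s_ref, alt = s_alt,
        length = 1L, ti = is_transition(s_ref, s_alt), direction = dirn,
        at_gaining_strain = unname(c(GCtoAT = "B", ATtoGC = "A",
                                     AtoT_or_TtoA = "neither",
                                     GtoC_or_CtoG = "neither")[dirn]),
        partition = part, context = NA_character_,
        context_motif = NA_character_, syn = s_syn,
        stringsAsFactors = FALSE)
      events[[length(events) + 1L]] <- subs
    }

    truth <- do.call(rbind, events)
    if (is.null(truth)) {
      truth <- data.frame(vtype = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          length = integer(0), ti = logical(0),
                          direction = character(0),
                          at_gaining_strain = character(0),
                          partition = character(0), context = character(0),
                          context_motif = character(0), syn = logical(0),
                          stringsAsFactors = FALSE)
    } else {
      truth <- truth[order(truth$pos), , drop = FALSE]
      rownames(truth) <- NULL
    }
    derived_seq <- apply_variants(seq, truth)
    derived_feats <- lift_features(ancestor$features, truth)
    strain <- genome_record(paste0(ancestor$id, "_derived"), derived_seq,
                            features = derived_feats,
                            circular = ancestor$circular)
    list(strain = strain, truth = truth)
  })
}

# One random candidate substitution inside a CDS with the requested
# synonymy, never creating or destroying a stop codon. Returns
# list(pos, ref, alt) in genome coordinates, or NULL.
coding_sub_candidate <- function(seq, f, want_syn) {
  iv <- f$intervals
  width <- iv[1L, 2L] - iv[1L, 1L]
  n_codons <- width %/% 3L
  if (n_codons < 4L) return(NULL)
  ci <- sample(2:(n_codons - 1L), 1L) - 1L       # internal codon index, 0-based
  code <- Biostrings::GENETIC_CODE
  if (f$strand == "+") {
    g0 <- iv[1L, 1L] + 3L * ci
    codon <- subseq0(seq, g0, g0 + 3L)
  } else {
    g_end <- iv[1L, 2L] - 3L * ci
    codon <- revcomp(subseq0(seq, g_end - 3L, g_end))
  }
  aa <- code[[codon]]
  if (aa == "*") return(NULL)
  cand <- list()
  for (off in 0:2) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, off + 1L, off + 1L))) {
      mut <- codon
      substr(mut, off + 1L, off + 1L) <- b
      if (code[[mut]] == "*") next
      if ((code[[mut]] == aa) != want_syn) next
      if (f$strand == "+") {
        pos <- iv[1L, 1L] + 3L * ci + off
        ref <- substr(codon, off + 1L, off + 1L)
        alt <- b
      } else {
        pos <- iv[1L, 2L] - 3L * ci - 1L - off
        ref <- comp_base(substr(codon, off + 1L, off + 1L))
        alt <- comp_base(b)
      }
      cand[[length(cand) + 1L]] <- list(pos = pos, ref = unname(ref),
                                        alt = unname(alt))
    }
  }
  if (!length(cand)) return(NULL)
  cand[[sample.int(length(cand), 1L)]]
}

# Synonymy of a planted genome-wide substitution that happens to hit a CDS.
substitution_is_synonymous <- function(seq, features, pos, alt) {
  code <- Biostrings::GENETIC_CODE
  for (f in features) {
    if (f$kind != "CDS") next
    iv <- f$intervals
    if (pos < iv[1L, 1L] || pos >= iv[1L, 2L]) next
    if (f$strand == "+") {
      off_in_cds <- pos - iv[1L, 1L]
    } else {
      off_in_cds <- iv[1L, 2L] - 1L - pos
    }
    ci <- off_in_cds %/% 3L
    if (f$strand == "+") {
      g0 <- iv[1L, 1L] + 3L * ci
      codon <- subseq0(seq, g0, g0 + 3L)
      mut <- codon
      substr(mut, off_in_cds %% 3L + 1L, off_in_cds %% 3L + 1L) <- alt
    } else {
      g_end <- iv[1L, 2L] - 3L * ci
      codon <- revcomp(subseq0(seq, g_end - 3L, g_end))
      mut <- codon
      substr(mut, off_in_cds %% 3L + 1L,
             off_in_cds %% 3L + 1L) <- unname(comp_base(alt))
    }
    if (code[[codon]] == "*" || code[[mut]] == "*") return(NA)
    return(code[[codon]] == code[[mut]])
  }
  NA
}

# Lift feature coordinates through the planted indels (ancestor -> strain).
lift_features <- function(features, truth) {
  ind <- truth[truth$vtype != "substitution", , drop = FALSE]
  if (!nrow(ind)) return(features)
  lift <- function(b, is_end) {
    for (i in order(ind$pos, decreasing = TRUE)) {
      p <- ind$pos[i]; L <- ind$length[i]
      if (ind$vtype[i] == "insertion") {
        if ((is_end && b > p) || (!is_end && b >= p)) b <- b + L
      } else {
        b <- b - max(0L, min(L, b - p))
      }
    }
    b
  }
  lapply(features, function(f) {
    iv <- f$intervals
    for (r in seq_len(nrow(iv))) {
      iv[r, 1L] <- lift(iv[r, 1L], FALSE)
      iv[r, 2L] <- lift(iv[r, 2L], TRUE)
    }
    f$intervals <- iv
    f
  })
}

#' Generate a synthetic genome panel for the demand regression
#'
#' tRNA gene counts linear in total codon demand plus Gaussian noise, with
#' one optional genome whose count is multiplied by an overload factor.
#' Deterministic per seed.
#'
#' @param n_genomes Number of genomes (>= 4).
#' @param demand_range Range of total codon demand.
#' @param noise_sd Gaussian noise on the tRNA counts.
#' @param overload_factor `NULL`, or multiplier applied to one genome.
#' @param overload_index Which genome is overloaded (default 1).
#' @param slope,intercept True regression line.
#' @param seed Integer seed.
#' @return data.frame `genome`, `total_codons`, `trna_genes`, `overloaded`.
#' @export
generate_panel <- function(n_genomes = 12L, demand_range = c(1e5, 8e5),
                           noise_sd = 1.5, overload_factor = NULL,
                           overload_index = 1L, slope = 4e-5,
                           intercept = 25, seed = 1L) {
  stopifnot(n_genomes >= 4L)
  with_seed(seed, {
    demand <- round(sort(stats::runif(n_genomes, demand_range[1], demand_range[2])))
    counts <- intercept + slope * demand + stats::rnorm(n_genomes, 0, noise_sd)
    overloaded <- rep(FALSE, n_genomes)
    if (!is.null(overload_factor)) {
      counts[overload_index] <- counts[overload_index] * overload_factor
      overloaded[overload_index] <- TRUE
    }
    # counts left unrounded so the noise model is exactly as stated
    # (a zero-noise panel is exactly collinear)
    data.frame(genome = sprintf("panel%02d", seq_len(n_genomes)),
               total_codons = demand,
               trna_genes = pmax(1, counts),
               overloaded = overloaded,
               stringsAsFactors = FALSE)
  })
}
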