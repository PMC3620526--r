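#' Run one analysis stage and write consolidated reports
#'
#' Orchestrates the package stages behind a single entry point, mirroring
#' how the numbered analysis scripts drive the package. Each subcommand
#' reads annotated genomes (GenBank) or bare sequences (FASTA), runs the
#' corresponding stage, and writes a TSV table plus a JSON report embedding
#' the full parameter set used; messages go to stderr, data to files only.
#' Re-running with the same config and seeds reproduces byte-identical
#' reports.
#'
#' Subcommands: `profile` (genome summary, codon usage, bias tests, amino
#' acid profile), `compare` (alignment, variant calling/classification,
#' indel context, dN/dS over orthologs), `repeats` (exact direct/inverted
#' repeats and IR-flanked regions), `trna` (inventory, demand, panel
#' regression and overload score), `classify` (functional-ORF criterion on
#' an evidence TSV), `simulate` (synthetic ancestor + derived strain +
#' truth table).
#'
#' @param subcommand One of profile, compare, repeats, trna, classify,
#'   simulate.
#' @param config Named list of parameters, or path to a YAML file holding
#'   them. Common fields: `inputs` (character vector of file paths),
#'   `out_dir`; stage fields: `k`, `min_len`, `min_arm`, `alpha`,
#'   `bootstrap_reps`, `seed`, simulation fields passed to [genome_spec()] /
#'   [mutation_model()] as `spec` and `model` sublists.
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(subcommand, config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  handler <- switch(subcommand,
    profile = stage_profile, compare = stage_compare, repeats = stage_repeats,
    trna = stage_trna, classify = stage_classify, simulate = stage_simulate,
    stop("unknown subcommand: '", subcommand,
         "' (expected profile/compare/repeats/trna/classify/simulate)"))
  for (p in config$inputs %||% character(0)) {
    if (!file.exists(p)) stop("unreadable input: ", p)
  }
  message("[symbiodiff] stage '", subcommand, "' -> ", out_dir)
  files <- handler(config, out_dir)
  report <- list(schema_version = "1.0", subcommand = subcommand,
                 parameters = config[setdiff(names(config), "out_dir")],
                 outputs = files)
  report_path <- file.path(out_dir, paste0(subcommand, "_report.json"))
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(files, report = report_path))
}

load_genome <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("fa", "fasta", "fna")) {
    seqs <- read_fasta(path)
    genome_record(names(seqs)[1] %||% basename(path), seqs[[1]])
  } else {
    read_genbank(path)
  }
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stage_profile <- function(config, out_dir) {
  files <- character(0)
  for (p in config$inputs) {
    rec <- load_genome(p)
    part <- build_partition(rec)
    summ <- summarize_genome(rec, part)
    cds <- extract_cds(rec)
    usage <- codon_usage(cds)
    stats_df <- data.frame(statistic = setdiff(names(summ), "id"),
                           value = vapply(setdiff(names(summ), "id"),
                                          function(k) as.numeric(summ[[k]]),
                                          numeric(1)))
    stats_df <- rbind(stats_df,
                      data.frame(statistic = "taa_stop_percent",
                                 value = taa_stop_percent(usage)))
    base <- file.path(out_dir, rec$id)
    files <- c(files,
               summary = write_tsv(stats_df, paste0(base, "_summary.tsv")),
               codon_usage = write_tsv(
                 data.frame(codon = names(usage$codon_counts),
                            count = as.integer(usage$codon_counts)),
                 paste0(base, "_codon_usage.tsv")),
               bias = write_tsv(codon_bias_test(usage,
                                                alpha = config$alpha %||% 0.01),
                                paste0(base, "_codon_bias.tsv")))
    prof <- aa_profile(cds)
    files <- c(files, aa_profile = write_tsv(
      data.frame(aa = names(prof$freq), frequency = as.numeric(prof$freq),
                 gc_richness = as.numeric(prof$gc_richness)),
      paste0(base, "_aa_profile.tsv")))
  }
  files
}

stage_compare <- function(config, out_dir) {
  stopifnot(length(config$inputs) == 2L)
  a <- load_genome(config$inputs[[1]]); b <- load_genome(config$inputs[[2]])
  map <- align_strain_pair(a, b, k = config$k %||% 31L)
  variants <- call_variants(map, a, b)
  part <- build_partition(a)
  summ <- classify_variants(variants, part)
  ctx <- summarize_indel_contexts(summ, a$sequence)
  files <- c(
    variants = {
      p <- file.path(out_dir, "variants.tsv")
      write_variant_table(list(variants = ctx$variants) |>
                            structure(class = "variant_summary"),
                          a$sequence, a$id, p)
      p
    },
    summary = write_tsv(data.frame(
      statistic = c("n_substitutions", "n_insertions", "n_deletions",
                    "ti", "tv", "ti_percent", "gc_at_changing_percent",
                    "at_gain_percent_A", "at_gain_percent_B",
                    "indel_mean_size", "identity_percent",
                    "identical_positions", "length_difference",
                    "homopolymer_indel_percent"),
      value = c(summ$n_substitutions, summ$n_insertions, summ$n_deletions,
                summ$ti, summ$tv, summ$ti_percent, summ$gc_at_changing_percent,
                summ$at_gain_percent_A, summ$at_gain_percent_B,
                summ$indel_mean_size, map$identity_percent,
                map$identical_positions, map$b_len - map$a_len,
                ctx$homopolymer_percent)),
      file.path(out_dir, "compare_summary.tsv")))
  cds_a <- extract_cds(a); cds_b <- extract_cds(b)
  if (nrow(cds_a) && nrow(cds_b) && length(intersect(cds_a$name, cds_b$name))) {
    orth <- pair_orthologs(cds_a, cds_b)
    sel <- estimate_dnds(orth, bootstrap_reps = config$bootstrap_reps %||% 1000L,
                         seed = config$seed %||% 1L)
    files <- c(files, selection = write_tsv(data.frame(
      statistic = c("n_ortholog_pairs", "n_codons", "Sd", "Nd", "S", "N",
                    "pS", "pN", "dS", "dS_se", "dN", "dN_se", "omega"),
      value = c(orth$n_pairs, sel$n_codons, sel$Sd, sel$Nd, sel$S, sel$N,
                sel$pS, sel$pN, sel$dS, sel$dS_se, sel$dN, sel$dN_se,
                sel$omega)),
      file.path(out_dir, "selection.tsv")))
  }
  files
}

stage_repeats <- function(config, out_dir) {
  files <- character(0)
  for (p in config$inputs) {
    rec <- load_genome(p)
    reps <- find_exact_repeats(rec$sequence, min_len = config$min_len %||% 1000L)
    irs <- find_ir_flanked_regions(rec$sequence,
                                   min_arm = config$min_arm %||% 20L,
                                   max_region = config$max_region %||% 50000L)
    base <- file.path(out_dir, rec$id)
    files <- c(files,
               repeats = { write_repeats_tsv(reps, rec$id,
                                             paste0(base, "_repeats.tsv"))
                           paste0(base, "_repeats.tsv") },
               ir_regions = write_tsv(
                 irs[setdiff(names(irs), "arm_seq")],
                 paste0(base, "_ir_regions.tsv")))
  }
  files
}

stage_trna <- function(config, out_dir) {
  rows <- lapply(config$inputs, function(p) {
    rec <- load_genome(p)
    inv <- trna_inventory(rec)
    dem <- codon_demand(rec)
    data.frame(genome = rec$id, total_codons = dem$total_codons,
               trna_genes = inv$total, stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, rows)
  files <- c(points = write_tsv(panel, file.path(out_dir, "trna_panel.tsv")))
  if (nrow(panel) >= 3L) {
    fit <- fit_demand_regression(panel)
    fit_df <- data.frame(statistic = c("slope", "intercept", "r_squared"),
                         value = c(fit$slope, fit$intercept, fit$r_squared))
    if (!is.null(config$focal) && nrow(panel) >= 4L) {
      ov <- overload_score(panel, config$focal)
      fit_df <- rbind(fit_df, data.frame(
        statistic = c("r2_with_focal", "r2_without_focal", "delta_r2"),
        value = c(ov$r2_with, ov$r2_without, ov$delta)))
    }
    files <- c(files, fit = write_tsv(fit_df, file.path(out_dir, "trna_fit.tsv")))
  }
  files
}

stage_classify <- function(config, out_dir) {
  ev <- utils::read.delim(config$inputs[[1]], stringsAsFactors = FALSE)
  out <- classify_orf(ev, length_threshold = config$length_threshold %||% 0.80)
  c(classification = write_tsv(out, file.path(out_dir, "orf_classification.tsv")))
}

stage_simulate <- function(config, out_dir) {
  spec <- do.call(genome_spec, config$spec %||% list())
  model <- do.call(mutation_model, config$model %||% list())
  ancestor <- generate_genome(spec)
  derived <- derive_strain(ancestor, model)
  anc_path <- file.path(out_dir, "ancestor.gbk")
  der_path <- file.path(out_dir, "derived.gbk")
  write_genbank(ancestor, anc_path)
  write_genbank(derived$strain, der_path)
  c(ancestor = anc_path, derived = der_path,
    truth = write_tsv(derived$truth, file.path(out_dir, "truth.tsv")))
}
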