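#!/usr/bin/env Rscript
# Purifying selection on the coding fraction: plant 139 coding substitutions
# with the synonymous share observed between the M. endobia strains (77 of
# 139), pair orthologs by locus name, and estimate dS, dN and omega by the
# Nei-Gojobori pathway method with Jukes-Cantor correction and a seeded
# codon bootstrap for standard errors.

library(symbiodiff)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 20260928L

anc <- read_genbank("results/simulated/ancestor.gbk")
d <- derive_strain(anc, mutation_model(
  n_substitutions = 139L, n_indels = 0L,
  coding_synonymous_fraction = 77 / 139, seed = seed + 5L))

orth <- pair_orthologs(extract_cds(anc), extract_cds(d$strain))
sel <- estimate_dnds(orth, bootstrap_reps = 1000L, seed = seed + 6L)

dir.create("results/selection", recursive = TRUE, showWarnings = FALSE)
write.table(data.frame(statistic = c("n_ortholog_pairs", "n_codons", "Sd", "Nd",
                                     "S", "N", "dS", "dS_se", "dN", "dN_se",
                                     "omega"),
                       value = c(orth$n_pairs, sel$n_codons, sel$Sd, sel$Nd,
                                 sel$S, sel$N, sel$dS, sel$dS_se, sel$dN,
                                 sel$dN_se, sel$omega)),
            "results/selection/dnds.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("%d ortholog pairs, %d codon columns", orth$n_pairs, sel$n_codons))
message(sprintf("%d synonymous and %d non-synonymous differences", sel$Sd, sel$Nd))
message(sprintf("dS = %.4f +/- %.4f, dN = %.4f +/- %.4f, omega = %.2f (omega < 1: purifying selection)",
                sel$dS, sel$dS_se, sel$dN, sel$dN_se, sel$omega))
message("table under results/selection/dnds.tsv")
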