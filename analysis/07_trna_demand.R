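#!/usr/bin/env Rscript
# tRNA inventory versus translational demand: regress functional tRNA gene
# counts on total sense-codon demand over a synthetic genome panel with one
# overloaded genome, score the overload by leave-one-out R^2 change, and
# list sense codons in demand with no cognate (exact anticodon) tRNA for the
# simulated ancestor.

library(symbiodiff)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 20260928L

panel <- generate_panel(n_genomes = 12L, noise_sd = 1.5, overload_factor = 3,
                        overload_index = 1L, seed = seed)
focal <- panel$genome[panel$overloaded]
fit_all <- fit_demand_regression(panel)
ov <- overload_score(panel, focal)

dir.create("results/trna", recursive = TRUE, showWarnings = FALSE)
write.table(panel, "results/trna/panel.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(statistic = c("slope", "intercept", "r2_with_focal",
                                     "r2_without_focal", "delta_r2"),
                       value = c(fit_all$slope, fit_all$intercept,
                                 ov$r2_with, ov$r2_without, ov$delta)),
            "results/trna/fit.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("panel R^2 with the overloaded genome: %.2f; without it: %.2f (delta %.2f)",
                ov$r2_with, ov$r2_without, ov$delta))

anc <- read_genbank("results/simulated/ancestor.gbk")
inv <- trna_inventory(anc)
dem <- codon_demand(anc)
gaps <- codon_coverage_gaps(inv, dem)
write.table(gaps, "results/trna/coverage_gaps.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("ancestor: %d functional tRNA genes, %d total codon demand, %d sense codons without a cognate tRNA (top: %s, demand %d)",
                inv$total, dem$total_codons, nrow(gaps),
                if (nrow(gaps)) gaps$codon[1] else "none",
                if (nrow(gaps)) gaps$demand[1] else 0L))
message("tables under results/trna")
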