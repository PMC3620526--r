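#!/usr/bin/env Rscript
# Simulate the study system: an annotated ancestor genome at the scale of
# the M. endobia chromosome (538 kb, 44% GC, 410 CDS, 41 tRNAs, 25
# pseudogenes, homopolymer-enriched intergenic regions) and a derived strain
# carrying 262 substitutions (43.5% transitions, 45%/45% GC<->AT direction
# classes) and 60 indels with 58.3% homopolymer targeting. Writes both
# genomes as GenBank plus the planted-mutation truth table.
#
# Usage: Rscript analysis/01_simulate_strain_pair.R [seed]

library(symbiodiff)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 20260928L
out <- "results/simulated"

files <- run_pipeline("simulate", list(
  out_dir = out,
  spec = list(length = 538000L, gc_content = 0.44, n_cds = 410L,
              n_trna = 41L, n_pseudogenes = 25L,
              cds_len_meanlog = log(330), seed = seed),
  model = list(n_substitutions = 262L, n_indels = 60L,
               transition_fraction = 0.435, gc_to_at_fraction = 0.45,
               at_to_gc_fraction = 0.45,
               indel_size_probs = stats::setNames(
                 c(.35, .20, .12, .08, .06, .05, .05, .04, .03, .02),
                 c(1, 2, 3, 4, 5, 6, 10, 15, 30, 75)),
               homopolymer_targeting_prob = 0.583, seed = seed + 1L)))

truth <- read.delim(files[["truth"]])
message(sprintf("simulated strain pair under results/simulated: %d substitutions, %d indels planted",
                sum(truth$vtype == "substitution"),
                sum(truth$vtype != "substitution")))
message("ancestor: ", files[["ancestor"]], "  derived: ", files[["derived"]])
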