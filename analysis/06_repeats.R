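#!/usr/bin/env Rscript
# Long exact intragenomic repeats: simulate a genome carrying a duplicated
# rRNA-like block (the concerted-evolution signature of both endosymbiont
# genomes) and a region flanked by inverted-repeat arms, then recover both
# with the repeat finder. Coordinates are reported 1-based inclusive.

library(symbiodiff)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 20260928L

rec <- generate_genome(genome_spec(length = 140000L, gc_content = 0.59,
                                   n_cds = 116L, n_trna = 8L,
                                   n_pseudogenes = 25L,
                                   duplication = list(length = 4023L, copies = 2L),
                                   seed = seed))
# plant a 7 kb region flanked by 71 bp inverted-repeat arms inside an IGR
arm <- substr(rec$sequence, 101, 171)
seq <- rec$sequence
region_start <- 60000L
seqx <- paste0(substr(seq, 1, region_start), arm,
               substr(seq, region_start + 1, region_start + 7032),
               as.character(Biostrings::reverseComplement(Biostrings::DNAString(arm))),
               substr(seq, region_start + 7033, nchar(seq)))

reps <- find_exact_repeats(seqx, min_len = 1000L)
irs <- find_ir_flanked_regions(seqx, min_arm = 20L, max_region = 50000L)

dir.create("results/repeats", recursive = TRUE, showWarnings = FALSE)
write_repeats_tsv(reps, "simulated", "results/repeats/repeat_pairs.tsv")
write.table(irs[setdiff(names(irs), "arm_seq")],
            "results/repeats/ir_flanked_regions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

direct <- reps[reps$orientation == "direct", ][1, ]
message(sprintf("duplicated block: positions %d-%d and %d-%d (%d bp, direct orientation)",
                direct$startA + 1, direct$startA + direct$length,
                direct$startB + 1, direct$startB + direct$length, direct$length))
best_ir <- irs[which.max(irs$arm_length), ]
message(sprintf("inverted-repeat flanked region: %d bp enclosed by %d bp arms at %d and %d",
                best_ir$region_length, best_ir$arm_length,
                best_ir$arm1_start + 1, best_ir$arm2_start + 1))
message("tables under results/repeats")
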