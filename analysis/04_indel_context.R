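#!/usr/bin/env Rscript
# Sequence context of the called indels: maximal homopolymer runs (>= 6 nt)
# and 2-8 nt microsatellite tracts on the ancestor, each indel classified as
# homopolymer / microsatellite / other, with the share of homopolymer indels
# and indel size statistics. Writes BED tracks for both tract types.

library(symbiodiff)

anc <- read_genbank("results/simulated/ancestor.gbk")
der <- read_genbank("results/simulated/derived.gbk")

map <- align_strain_pair(anc, der)
v <- call_variants(map, anc, der)
s <- classify_variants(v, build_partition(anc))
ctx <- summarize_indel_contexts(s, anc$sequence)

dir.create("results/context", recursive = TRUE, showWarnings = FALSE)
runs <- scan_homopolymers(anc$sequence, 6)
at_runs <- runs[runs$base %in% c("A", "T"), ]
write_track_bed(runs, anc$id, "results/context/homopolymers.bed")
write_track_bed(scan_microsatellites(anc$sequence), anc$id,
                "results/context/microsatellites.bed")
write.table(ctx$variants, "results/context/indel_contexts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("%d A/T homopolymer runs >= 6 nt in the ancestor (of %d total runs)",
                nrow(at_runs), nrow(runs)))
message(sprintf("%d/%d indels (%.1f%%) affect homopolymers (A:%d T:%d G:%d C:%d); mean size %.1f nt (range %d-%d)",
                unname(ctx$context_counts["homopolymer"]), ctx$n_indels,
                ctx$homopolymer_percent,
                ctx$homopolymer_base_counts[["A"]], ctx$homopolymer_base_counts[["T"]],
                ctx$homopolymer_base_counts[["G"]], ctx$homopolymer_base_counts[["C"]],
                ctx$size_mean, ctx$size_min, ctx$size_max))
message("tracks and per-indel calls under results/context")
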