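#!/usr/bin/env Rscript
# Reproduction of the published per-genome statistics from the deposited
# accessions. The four GenBank flat files are not redistributable with the
# package; download them (e.g. from NCBI nucleotide: CP002918, CP002244,
# CP003881, CP002243) and place them under inst/extdata/genomes/ as
# <accession>.gbk before running. Computes: genome sizes, GC by partition,
# gene density, tRNA counts; the T. princeps pair's substitutions, indels,
# identical positions and transition fraction; M. endobia's A/T homopolymer
# count, TAA stop incidence, and AAG codon demand; and the T. princeps
# GC-rich amino-acid fraction.

library(symbiodiff)

dir <- "inst/extdata/genomes"
acc <- c(tp_pcval = "CP002918", tp_pcit = "CP002244",
         me_pcval = "CP003881", me_pcit = "CP002243")
paths <- file.path(dir, paste0(acc, ".gbk"))
if (!all(file.exists(paths))) {
  message("deposited GenBank files not found under ", dir, ":")
  message("  expected ", paste(basename(paths), collapse = ", "))
  message("download the four accessions and re-run.")
  quit(status = 1L)
}
recs <- setNames(lapply(paths, read_genbank), names(acc))
dir.create("results/reference", recursive = TRUE, showWarnings = FALSE)

rows <- lapply(names(recs), function(nm) {
  r <- recs[[nm]]
  s <- summarize_genome(r, build_partition(r))
  data.frame(genome = nm, size = s$size, cds = s$n_cds, trna = s$n_trna,
             pseudo = s$n_pseudogenes, density = s$gene_density_percent,
             gc = s$gc_overall, gc_genes = s$gc_genes,
             gc_pseudo = s$gc_pseudogenes, gc_igr = s$gc_igr)
})
tab <- do.call(rbind, rows)
write.table(tab, "results/reference/genome_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(tab)

map <- align_strain_pair(recs$tp_pcval, recs$tp_pcit)
v <- call_variants(map, recs$tp_pcval, recs$tp_pcit)
s <- classify_variants(v, build_partition(recs$tp_pcval))
message(sprintf("T. princeps pair: %d substitutions (%.1f%% transitions), %d indels, %d identical bp (%.2f%%)",
                s$n_substitutions, s$ti_percent,
                s$n_insertions + s$n_deletions,
                map$identical_positions, map$identity_percent))

me <- recs$me_pcval
message(sprintf("M. endobia PCVAL: %d A/T homopolymers >= 6 nt",
                nrow(scan_homopolymers(me$sequence, 6, bases = c("A", "T")))))
message(sprintf("  TAA stop incidence %.2f%%",
                taa_stop_percent(codon_usage(extract_cds(me)))))
dem <- codon_demand(me)
message(sprintf("  AAG codon demand %d; coverage gaps: %s",
                dem$codon_counts[["AAG"]],
                paste(utils::head(codon_coverage_gaps(trna_inventory(me), dem)$codon, 3),
                      collapse = ", ")))
prof <- aa_profile(extract_cds(recs$tp_pcval))
message(sprintf("T. princeps PCVAL GC-rich residues (Ala,Arg,Leu,Gly,Val,Ser): %.2f%% of the proteome",
                100 * sum(prof$freq[c("A", "R", "L", "G", "V", "S")])))
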