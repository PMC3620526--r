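test_that("GC content is computed per partition class", {
  # all-G featureless genome
  rec <- toy_record(seq = strrep("G", 10))
  s <- summarize_genome(rec, build_partition(rec))
  expect_equal(s$gc_overall, 100)
  expect_equal(s$gc_igr, 100)

  # 60 bp: one 30 bp CDS at GC 0.5, IGR at GC 0.2 -> genes 50, igr 20,
  # overall (15 + 6)/60 = 35
  cds_seq <- paste0(strrep("GC", 7), "A", strrep("AT", 7), "C")  # 30 bp, 15 GC
  igr_seq <- paste0(strrep("G", 6), strrep("A", 24))             # 30 bp, 6 GC
  rec2 <- toy_record(seq = paste0(cds_seq, igr_seq), features = list(
    feature("CDS", "+", cbind(0L, 30L), name = "x")))
  s2 <- summarize_genome(rec2, build_partition(rec2))
  expect_equal(s2$gc_genes, 50)
  expect_equal(s2$gc_igr, 20)
  expect_equal(s2$gc_overall, 35)
  expect_equal(s2$mean_orf_length, 30)
  expect_equal(s2$mean_igr_length, 30)
})

test_that("GC mixture identity holds on random annotated genomes", {
  set.seed(11)
  for (rep in 1:5) {
    rec <- generate_genome(genome_spec(length = 8000L, gc_content = runif(1, 0.3, 0.6),
                                       n_cds = 6L, n_trna = 2L, n_pseudogenes = 2L,
                                       seed = rep))
    part <- build_partition(rec)
    s <- summarize_genome(rec, part)
    gcs <- c(s$gc_genes, s$gc_pseudogenes, s$gc_igr)
    lens <- c(part$class_lengths[["coding"]] + part$class_lengths[["rna"]],
              part$class_lengths[["pseudogene"]], part$class_lengths[["igr"]])
    mix <- sum(gcs * lens, na.rm = TRUE) / sum(lens[!is.na(gcs)])
    expect_equal(mix, s$gc_overall, tolerance = 1e-9)
  }
})

test_that("codon usage tallies amino-acid and stop codons separately", {
  u <- codon_usage("ATGAAATAA")
  expect_equal(unname(u$codon_counts[c("ATG", "AAA")]), c(1L, 1L))
  expect_equal(sum(u$codon_counts), 2L)
  expect_equal(unname(u$stop_counts["TAA"]), 1L)
  expect_equal(u$total_codons, 3L)

  # 4 CDS ending TAA,TAA,TAA,TGA -> TAA share of stops 75%
  cds <- paste0("ATGAAA", c("TAA", "TAA", "TAA", "TGA"))
  u2 <- codon_usage(cds)
  expect_equal(taa_stop_percent(u2), 75)

  # internal stop: excluded and reported
  u3 <- codon_usage(data.frame(name = c("ok", "bad"),
                               seq = c("ATGAAATAA", "ATGTAAAAATAA"),
                               frame_ok = TRUE, n_positions = ""))
  expect_equal(u3$excluded_internal_stop, "bad")
  expect_equal(sum(u3$codon_counts), 2L)
})

test_that("codon count conservation holds on simulated CDS sets", {
  set.seed(5)
  rec <- generate_genome(genome_spec(length = 20000L, n_cds = 12L, n_trna = 2L,
                                     n_pseudogenes = 1L, seed = 9L))
  cds <- extract_cds(rec)
  u <- codon_usage(cds)
  total_codons_in <- sum(nchar(cds$seq)) / 3
  expect_equal(sum(u$codon_counts) + sum(u$stop_counts), total_codons_in)
})

test_that("codon bias test matches the hand-computed chi-square and verdicts", {
  u <- codon_usage(character(0))
  # Phe 50/50: exactly uniform
  u$codon_counts[c("TTT", "TTC")] <- c(50L, 50L)
  # overwrite with 90/10 in a second copy: chi-square (90-50)^2/50*2 = 64
  u2 <- u
  u2$codon_counts[c("TTT", "TTC")] <- c(90L, 10L)
  r1 <- codon_bias_test(u, alpha = 0.01)
  r2 <- codon_bias_test(u2, alpha = 0.01)
  expect_equal(r1$verdict[r1$aa == "F"], "unbiased")
  expect_equal(r2$statistic[r2$aa == "F"], 64)
  expect_equal(r2$verdict[r2$aa == "F"], "biased")
  # untouched families are untestable
  expect_equal(r1$verdict[r1$aa == "G"], "untestable")
})

test_that("exact multinomial path engages for small families and is sane", {
  u <- codon_usage(character(0))
  u$codon_counts[c("TAT", "TAC")] <- c(6L, 0L)   # Tyr, n=6, expected 3 < 5
  r <- codon_bias_test(u, alpha = 0.05)
  row <- r[r$aa == "Y", ]
  expect_equal(row$method, "exact multinomial")
  # P(all 6 in one of two cells) = 2 * 0.5^6
  expect_equal(row$p_value, 2 * 0.5^6, tolerance = 1e-12)
})

test_that("amino-acid profile frequencies are hand-countable and sum to 1", {
  prof <- aa_profile("ATGGCTGCAGCGTAA")   # Met + 3x Ala
  expect_equal(sum(prof$freq), 1, tolerance = 1e-9)
  expect_equal(unname(prof$freq[["A"]]), 0.75)
  expect_equal(unname(prof$freq[["M"]]), 0.25)

  # two proteins, residues counted by hand: GTG start is Met
  prof2 <- aa_profile(c("ATGAAATTTTAA", "GTGGGGGGATAA"))
  # proteome: M,K,F + M,G,G = 2 M, 1 K, 1 F, 2 G over 6 residues
  expect_equal(unname(prof2$freq[["M"]]), 2 / 6)
  expect_equal(unname(prof2$freq[["G"]]), 2 / 6)
  expect_equal(unname(prof2$freq[["K"]]), 1 / 6)
  expect_equal(sum(prof2$freq), 1, tolerance = 1e-9)
})

test_that("GC-richness ranking is deterministic with alphabetical tie-break", {
  r <- aa_gc_richness()
  expect_length(r, 20)
  expect_true(all(diff(r) <= 0))
  # ties must be alphabetical
  for (v in unique(r[duplicated(r)])) {
    nm <- names(r)[r == v]
    expect_identical(nm, sort(nm))
  }
  # Ala (GCN, mean 5/6) must outrank Lys (AAA/AAG, mean 1/6)
  expect_lt(which(names(r) == "A"), which(names(r) == "K"))
  expect_equal(unname(r[["A"]]), 5 / 6)
  expect_equal(unname(r[["K"]]), 1 / 6)
})
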