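test_that("NG86 site counts match hand enumeration", {
  # Gly GGA: third position fully synonymous, first position has TGA stop
  # excluded from the denominator
  expect_equal(count_sites_ng86("GGA"), c(s = 1, n = 2))
  # Phe TTT: only TTT->TTC synonymous
  expect_equal(count_sites_ng86("TTT"), c(s = 1 / 3, n = 8 / 3))
  # Met ATG: no synonymous change
  expect_equal(count_sites_ng86("ATG"), c(s = 0, n = 3))
  expect_error(count_sites_ng86("TAA"), "stop")
})

test_that("pathway-averaged difference counts match brute-force enumeration", {
  set.seed(17)
  for (rep in 1:200) {
    c1 <- random_nonstop_codon()
    c2 <- random_nonstop_codon()
    expect_equal(count_diffs_ng86(c1, c2), brute_force_ng86_diffs(c1, c2),
                 info = paste(c1, c2))
  }
})

test_that("dS/dN estimation reproduces the hand-worked Gly example", {
  aln <- rbind(rep("GGA", 10), c(rep("GGA", 9), "GGC"))
  s <- estimate_dnds(aln, bootstrap_reps = 0L)
  expect_equal(s$Sd, 1)
  expect_equal(s$Nd, 0)
  expect_equal(s$S, 10)
  expect_equal(s$N, 20)
  expect_equal(s$pS, 0.1)
  expect_equal(s$dS, -0.75 * log(1 - 0.4 / 3), tolerance = 1e-12)
  expect_equal(round(s$dS, 5), 0.10733)
  expect_equal(s$dN, 0)
  expect_equal(s$omega, 0)

  ident <- rbind(rep("GGA", 5), rep("GGA", 5))
  si <- estimate_dnds(ident, bootstrap_reps = 0L)
  expect_equal(si$Sd + si$Nd, 0)
  expect_equal(si$dS, 0)
  expect_true(is.na(si$omega))
})

test_that("site conservation and symmetry hold on random codon alignments", {
  set.seed(19)
  for (rep in 1:10) {
    n <- 50
    codA <- replicate(n, random_nonstop_codon())
    codB <- codA
    flip <- sample(n, 8)
    for (i in flip) {
      repeat {
        cand <- random_nonstop_codon()
        if (sum(strsplit(cand, "")[[1]] != strsplit(codA[i], "")[[1]]) <= 2) {
          codB[i] <- cand; break
        }
      }
    }
    ab <- estimate_dnds(rbind(codA, codB), bootstrap_reps = 0L)
    ba <- estimate_dnds(rbind(codB, codA), bootstrap_reps = 0L)
    expect_equal(ab$S + ab$N, 3 * ab$n_codons)
    expect_equal(ab$dS, ba$dS)
    expect_equal(ab$dN, ba$dN)
    expect_equal(ab$Sd, ba$Sd)
  }
})

test_that("saturated alignments refuse the Jukes-Cantor correction", {
  # force pN >= 0.75: every codon totally different, nonsynonymous
  aln <- rbind(rep("AAA", 4), rep("TGT", 4))   # Lys vs Cys
  expect_error(estimate_dnds(aln, bootstrap_reps = 0L), "0.75")
})

test_that("ortholog pairing keeps frame-preserving gaps and reports mismatches", {
  cds_a <- data.frame(name = c("g1", "g2"),
                      seq = c("ATGAAACCCGGGTTTTAA", "ATGCATCATTAA"),
                      strand = "+", frame_ok = TRUE, n_positions = "",
                      stringsAsFactors = FALSE)
  cds_b <- cds_a
  # 3-bp deletion in g1 (one codon dropped)
  cds_b$seq[1] <- "ATGAAAGGGTTTTAA"
  orth <- pair_orthologs(cds_a, cds_b)
  expect_equal(orth$n_pairs, 2L)
  m <- orth$alignments$g1
  expect_equal(ncol(m), 5L)           # 6 codons minus the deleted column
  expect_true(all(m[1, ] == m[2, ]))

  dup <- rbind(cds_a, cds_a[1, ])
  expect_error(pair_orthologs(dup, cds_b), "duplicate")

  only_a <- cds_a; only_a$name[2] <- "g9"
  orth2 <- pair_orthologs(only_a, cds_b)
  expect_equal(orth2$unmatched_a, "g9")
  expect_equal(orth2$unmatched_b, "g2")
})

test_that("planted synonymous fraction is recovered through the pipeline", {
  set.seed(23)
  anc <- generate_genome(genome_spec(length = 80000L, n_cds = 60L, n_trna = 2L,
                                     n_pseudogenes = 2L, seed = 29L))
  f <- 0.55
  n_sub <- 150L
  d <- derive_strain(anc, mutation_model(n_substitutions = n_sub, n_indels = 0L,
                                         coding_synonymous_fraction = f,
                                         seed = 37L))
  orth <- pair_orthologs(extract_cds(anc), extract_cds(d$strain))
  s <- estimate_dnds(orth, bootstrap_reps = 0L)
  expect_equal(s$Sd + s$Nd, n_sub)
  expect_equal(s$Sd, sum(d$truth$syn))
  # recovered synonymous share within 3 sigma of the planted fraction
  sigma <- sqrt(f * (1 - f) / n_sub)
  expect_lt(abs(s$Sd / (s$Sd + s$Nd) - f), 3 * sigma)
})

test_that("bootstrap standard errors are seeded and reproducible", {
  set.seed(3)
  codA <- replicate(60, random_nonstop_codon())
  codB <- codA
  codB[1:6] <- vapply(codB[1:6], function(x) {
    repeat {
      y <- random_nonstop_codon()
      if (y != x) return(y)
    }
  }, character(1))
  s1 <- estimate_dnds(rbind(codA, codB), bootstrap_reps = 200L, seed = 7L)
  s2 <- estimate_dnds(rbind(codA, codB), bootstrap_reps = 200L, seed = 7L)
  expect_equal(s1$dS_se, s2$dS_se)
  expect_gt(s1$dS_se + s1$dN_se, 0)
})
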