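test_that("homopolymer scan reports maximal runs only", {
  expect_equal(scan_homopolymers("AAAAAA", 6),
               data.frame(base = "A", start = 0L, length = 6L,
                          stringsAsFactors = FALSE))
  got <- scan_homopolymers("AAAAAATTTTTTTGG", 6)
  expect_equal(got$base, c("A", "T"))
  expect_equal(got$start, c(0L, 6L))
  expect_equal(got$length, c(6L, 7L))
  expect_equal(nrow(scan_homopolymers("ACGTACGT", 6)), 0L)
})

test_that("homopolymer scan matches a regular-expression oracle on random sequences", {
  set.seed(12)
  for (rep in 1:100) {
    s <- random_dna(sample(50:600, 1), gc = runif(1, 0.2, 0.5))
    got <- scan_homopolymers(s, 6)
    for (b in c("A", "C", "G", "T")) {
      m <- gregexpr(paste0(b, "{6,}"), s)[[1]]
      starts <- if (m[1] == -1L) integer(0) else as.integer(m) - 1L
      lens <- if (m[1] == -1L) integer(0) else attr(m, "match.length")
      expect_equal(got$start[got$base == b], starts)
      expect_equal(got$length[got$base == b], lens)
    }
  }
})

test_that("microsatellite scan finds maximal tracts with smallest motif", {
  got <- scan_microsatellites("ATATATAT")
  expect_equal(got$motif, "AT")
  expect_equal(got$copies, 4L)
  expect_equal(got$start, 0L)

  got2 <- scan_microsatellites("ACGACGACGTT")
  expect_equal(got2$motif, "ACG")
  expect_equal(got2$copies, 3L)
  expect_equal(got2$start, 0L)

  # homopolymer tracts are not motif-2 repeats
  expect_equal(nrow(scan_microsatellites("AAAAAA")), 0L)
  # reducible motif "ATAT" must be reported as AT, once
  got3 <- scan_microsatellites("GGATATATATGG")
  expect_equal(got3$motif, "AT")
  expect_equal(nrow(got3), 1L)
})

test_that("indel context classification follows the precedence rules", {
  seq <- paste0("G", strrep("A", 7), "CGCG", strrep("AT", 4), "GCGC")
  runs <- scan_homopolymers(seq, 6)
  reps <- scan_microsatellites(seq)

  del <- data.frame(vtype = "deletion", pos = 1L, ref = "A", alt = "",
                    length = 1L, stringsAsFactors = FALSE)
  got <- classify_indel_context(del, runs, reps)
  expect_equal(got$context, "homopolymer")
  expect_equal(got$motif, "A")

  ins <- data.frame(vtype = "insertion", pos = 12L, ref = "", alt = "AT",
                    length = 2L, stringsAsFactors = FALSE)
  got2 <- classify_indel_context(ins, runs, reps)
  expect_equal(got2$context, "microsatellite")
  expect_equal(got2$motif, "AT")

  other <- data.frame(vtype = "insertion", pos = 10L, ref = "", alt = "GGC",
                      length = 3L, stringsAsFactors = FALSE)
  expect_equal(classify_indel_context(other, runs, reps)$context, "other")

  sub <- data.frame(vtype = "substitution", pos = 2L, ref = "A", alt = "G",
                    length = 1L, stringsAsFactors = FALSE)
  expect_error(classify_indel_context(sub, runs, reps), "indels only")
})

test_that("context calls are invariant under equivalent indel placements", {
  seq <- paste0("GC", strrep("T", 8), "GACGACGAC", strrep("C", 3), "ATATATAT", "G")
  runs <- scan_homopolymers(seq, 6)
  reps <- scan_microsatellites(seq)
  # deleting any T of the run: all equivalent placements normalize to one call
  calls <- lapply(2:9, function(p) {
    norm <- normalize_indel(seq, p, "T")
    v <- data.frame(vtype = "deletion", pos = norm$pos, ref = norm$allele,
                    alt = "", length = 1L, stringsAsFactors = FALSE)
    classify_indel_context(v, runs, reps)
  })
  expect_true(all(vapply(calls, function(x) x$context, character(1)) == "homopolymer"))
  expect_length(unique(vapply(calls, function(x) x$motif, character(1))), 1L)
})

test_that("context summary computes fraction and size statistics from fixtures", {
  set.seed(21)
  anc <- generate_genome(genome_spec(length = 40000L, n_cds = 20L, n_trna = 2L,
                                     n_pseudogenes = 2L, homopolymer_rate = 3,
                                     seed = 13L))
  d <- derive_strain(anc, mutation_model(n_substitutions = 0L, n_indels = 12L,
                                         homopolymer_targeting_prob = 0.5,
                                         seed = 31L))
  v <- call_variants(align_strain_pair(anc, d$strain), anc, d$strain)
  s <- classify_variants(v, build_partition(anc))
  ctx <- summarize_indel_contexts(s, anc$sequence)
  expect_equal(ctx$n_indels, 12L)
  truth_ctx <- d$truth$context[d$truth$vtype != "substitution"]
  called_ctx <- ctx$variants$context[ctx$variants$vtype != "substitution"]
  expect_equal(sort(called_ctx), sort(truth_ctx))
  sizes <- d$truth$length[d$truth$vtype != "substitution"]
  expect_equal(ctx$size_mean, mean(sizes))
  expect_equal(ctx$size_min, min(sizes))
  expect_equal(ctx$size_max, max(sizes))
})
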