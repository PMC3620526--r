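test_that("genome generation is deterministic per seed", {
  g1 <- generate_genome(genome_spec(length = 10000L, gc_content = 0.44, seed = 7L,
                                    n_cds = 6L, n_trna = 2L, n_pseudogenes = 1L))
  g2 <- generate_genome(genome_spec(length = 10000L, gc_content = 0.44, seed = 7L,
                                    n_cds = 6L, n_trna = 2L, n_pseudogenes = 1L))
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(features_table(g1), features_table(g2))
  g3 <- generate_genome(genome_spec(length = 10000L, gc_content = 0.44, seed = 8L,
                                    n_cds = 6L, n_trna = 2L, n_pseudogenes = 1L))
  expect_false(identical(g1$sequence, g3$sequence))
})

test_that("realized GC tracks the requested value on long genomes", {
  g <- generate_genome(genome_spec(length = 200000L, gc_content = 0.59,
                                   n_cds = 100L, n_trna = 10L,
                                   n_pseudogenes = 5L, seed = 11L))
  s <- summarize_genome(g, build_partition(g))
  expect_gte(s$gc_overall, 58)
  expect_lte(s$gc_overall, 60)
})

test_that("generated CDS are well-formed and features never overlap", {
  g <- generate_genome(genome_spec(length = 30000L, n_cds = 20L, n_trna = 3L,
                                   n_pseudogenes = 2L, seed = 13L))
  cds <- extract_cds(g)
  expect_true(all(cds$frame_ok))
  expect_true(all(substr(cds$seq, 1, 3) == "ATG"))
  u <- codon_usage(cds)
  expect_length(u$excluded_internal_stop, 0L)
  expect_equal(sum(u$stop_counts), nrow(cds))
  ft <- features_table(g)
  ft <- ft[order(ft$start), ]
  expect_true(all(ft$start[-1] >= ft$end[-nrow(ft)]))
})

test_that("a planted duplicated block is recovered by the repeat finder", {
  g <- generate_genome(genome_spec(length = 25000L, n_cds = 10L, n_trna = 2L,
                                   n_pseudogenes = 1L,
                                   duplication = list(length = 2000L, copies = 2L),
                                   seed = 17L))
  got <- find_exact_repeats(g$sequence, min_len = 1500)
  direct <- got[got$orientation == "direct", ]
  expect_equal(nrow(direct), 1L)
  expect_gte(direct$length, 2000L)
  # the maximal repeat must cover both planted copies (it may extend by a
  # few chance-matching flanking bases)
  ft <- features_table(g)
  rr <- ft[ft$kind == "rRNA", ]
  expect_lte(direct$startA + 1L, rr$start[1])
  expect_gte(direct$startA + direct$length, rr$end[1])
  expect_lte(direct$startB + 1L, rr$start[2])
  expect_gte(direct$startB + direct$length, rr$end[2])
})

test_that("an empty mutation model returns the ancestor unchanged", {
  anc <- generate_genome(genome_spec(length = 8000L, n_cds = 5L, n_trna = 1L,
                                     n_pseudogenes = 1L, seed = 19L))
  d <- derive_strain(anc, mutation_model(n_substitutions = 0L, n_indels = 0L))
  expect_identical(d$strain$sequence, anc$sequence)
  expect_equal(nrow(d$truth), 0L)
})

test_that("truth table reconstructs the derived strain byte-exactly", {
  for (seed in 1:5) {
    anc <- generate_genome(genome_spec(length = 15000L, n_cds = 10L, n_trna = 2L,
                                       n_pseudogenes = 1L, seed = seed))
    d <- derive_strain(anc, mutation_model(n_substitutions = 15L, n_indels = 5L,
                                           seed = seed + 100L))
    expect_identical(apply_variants(anc$sequence, d$truth), d$strain$sequence)
  }
})

test_that("derived strain generation is deterministic and seeds are independent", {
  anc <- generate_genome(genome_spec(length = 12000L, n_cds = 8L, n_trna = 2L,
                                     n_pseudogenes = 1L, seed = 23L))
  m <- mutation_model(n_substitutions = 12L, n_indels = 3L, seed = 5L)
  d1 <- derive_strain(anc, m)
  d2 <- derive_strain(anc, m)
  expect_identical(d1$strain$sequence, d2$strain$sequence)
  expect_identical(d1$truth, d2$truth)
})

test_that("planted events are recovered with exact positions and classes", {
  anc <- generate_genome(genome_spec(length = 50000L, n_cds = 30L, n_trna = 4L,
                                     n_pseudogenes = 2L, seed = 29L))
  d <- derive_strain(anc, mutation_model(n_substitutions = 23L, n_indels = 5L,
                                         seed = 11L))
  map <- align_strain_pair(anc, d$strain)
  v <- call_variants(map, anc, d$strain)
  expect_equal(sum(v$vtype == "substitution"), 23L)
  expect_equal(sum(v$vtype != "substitution"), 5L)
  truth <- d$truth
  key <- function(x) paste(x$pos, x$vtype, x$ref, x$alt)
  expect_setequal(key(v), key(truth))
  s <- classify_variants(v, build_partition(anc))
  m <- merge(s$variants, truth, by = c("pos", "vtype"))
  expect_equal(nrow(m), 28L)
  expect_equal(m$ti.x, m$ti.y)
  expect_equal(m$direction.x, m$direction.y)
  expect_equal(m$partition.x, m$partition.y)
})

test_that("infeasible specs and unplaceable models raise errors", {
  expect_error(generate_genome(genome_spec(length = 1000L, n_cds = 10L,
                                           n_trna = 0L, n_pseudogenes = 0L,
                                           seed = 1L)),
               "infeasible")
  anc <- generate_genome(genome_spec(length = 3000L, n_cds = 1L, n_trna = 0L,
                                     n_pseudogenes = 0L, seed = 2L))
  expect_error(derive_strain(anc, mutation_model(n_substitutions = 500L,
                                                 n_indels = 0L,
                                                 min_spacing = 50L, seed = 3L)),
               "cannot place")
})

test_that("synthetic panels behave as configured", {
  p1 <- generate_panel(n_genomes = 8L, noise_sd = 0, seed = 41L)
  expect_equal(fit_demand_regression(p1)$r_squared, 1, tolerance = 1e-12)

  p2 <- generate_panel(n_genomes = 8L, noise_sd = 0, overload_factor = 3,
                       overload_index = 2L, seed = 41L)
  focal <- p2$genome[p2$overloaded]
  ov <- overload_score(p2, focal)
  expect_gt(ov$delta, 0.3)
  expect_equal(ov$r2_without, 1, tolerance = 1e-12)
  # the clean genomes all lie on the line: leaving any of them out is neutral
  clean <- p2[p2$genome != focal, ]
  for (g in clean$genome) {
    expect_lt(abs(overload_score(clean, g)$delta), 1e-9)
  }
  expect_identical(generate_panel(n_genomes = 6L, seed = 43L),
                   generate_panel(n_genomes = 6L, seed = 43L))
})
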