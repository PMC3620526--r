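test_that("identical sequences yield no variants", {
  s <- random_dna(400)
  map <- align_strain_pair(s, s, k = 15)
  expect_equal(nrow(call_variants(map, s, s)), 0L)
})

test_that("indels are left-normalized to the lowest equivalent position", {
  # deleting any A of the run in AAAAAG must be reported at position 0
  a <- paste0("AAAAAG", strrep("CGT", 20))
  b <- paste0("AAAAG", strrep("CGT", 20))
  map <- align_strain_pair(a, b, k = 5)
  v <- call_variants(map, a, b)
  expect_equal(nrow(v), 1L)
  expect_equal(v$vtype, "deletion")
  expect_equal(v$pos, 0L)
  expect_equal(v$ref, "A")

  # enumerated equivalent placements agree with the normalizer
  for (p in 0:4) {
    norm <- normalize_indel(a, p, "A")
    expect_equal(norm$pos, 0L)
    expect_equal(norm$allele, "A")
  }
})

test_that("applying called variants reconstructs the derived genome exactly", {
  set.seed(33)
  for (rep in 1:5) {
    anc <- generate_genome(genome_spec(length = 12000L, n_cds = 8L,
                                       n_trna = 2L, n_pseudogenes = 2L,
                                       seed = rep))
    d <- derive_strain(anc, mutation_model(n_substitutions = 8L, n_indels = 3L,
                                           seed = rep + 50L))
    map <- align_strain_pair(anc, d$strain)
    v <- call_variants(map, anc, d$strain)
    expect_identical(apply_variants(anc$sequence, v), d$strain$sequence)
    # length bookkeeping
    ins <- sum(v$length[v$vtype == "insertion"])
    del <- sum(v$length[v$vtype == "deletion"])
    expect_equal(genome_length(d$strain) - genome_length(anc), ins - del)
  }
})

test_that("swapping the pair maps insertions to deletions and keeps totals", {
  set.seed(44)
  anc <- generate_genome(genome_spec(length = 10000L, n_cds = 6L, n_trna = 2L,
                                     n_pseudogenes = 1L, seed = 4L))
  d <- derive_strain(anc, mutation_model(n_substitutions = 10L, n_indels = 4L,
                                         seed = 99L))
  vab <- call_variants(align_strain_pair(anc, d$strain), anc, d$strain)
  vba <- call_variants(align_strain_pair(d$strain, anc), d$strain, anc)
  expect_equal(sum(vab$vtype == "substitution"), sum(vba$vtype == "substitution"))
  expect_equal(sum(vab$vtype == "insertion"), sum(vba$vtype == "deletion"))
  expect_equal(sum(vab$vtype == "deletion"), sum(vba$vtype == "insertion"))
  # direction classes mirror: GCtoAT in one reading is ATtoGC in the other
  pa <- build_partition(anc); pb <- build_partition(d$strain)
  sab <- classify_variants(vab, pa); sba <- classify_variants(vba, pb)
  expect_equal(unname(sab$direction_counts["GCtoAT"]),
               unname(sba$direction_counts["ATtoGC"]))
  expect_equal(sab$ti, sba$ti)
})

test_that("substitution classification follows the direction definitions", {
  part <- build_partition(toy_record(seq = strrep("C", 50)))
  v <- data.frame(vtype = "substitution", pos = 10L, ref = "C", alt = "T",
                  length = 1L, stringsAsFactors = FALSE)
  s <- classify_variants(v, part)
  expect_equal(s$ti, 1L)
  expect_equal(unname(s$direction_counts["GCtoAT"]), 1L)
  expect_equal(s$variants$at_gaining_strain, "B")

  cases <- data.frame(ref = c("A", "G", "A", "C"), alt = c("G", "C", "T", "A"),
                      dir = c("ATtoGC", "GtoC_or_CtoG", "AtoT_or_TtoA", "GCtoAT"),
                      ti = c(TRUE, FALSE, FALSE, FALSE))
  for (i in seq_len(nrow(cases))) {
    vi <- data.frame(vtype = "substitution", pos = 5L, ref = cases$ref[i],
                     alt = cases$alt[i], length = 1L)
    si <- classify_variants(vi, part)
    expect_equal(si$variants$direction, cases$dir[i])
    expect_equal(si$ti, as.integer(cases$ti[i]))
  }
})

test_that("classification summary counts match a planted truth table", {
  set.seed(55)
  anc <- generate_genome(genome_spec(length = 60000L, n_cds = 40L, n_trna = 4L,
                                     n_pseudogenes = 3L, seed = 6L))
  model <- mutation_model(n_substitutions = 100L, transition_fraction = 0.7,
                          n_indels = 0L, seed = 7L)
  d <- derive_strain(anc, model)
  expect_equal(sum(d$truth$ti), 70L, tolerance = 0.15)  # planted Bernoulli draws
  v <- call_variants(align_strain_pair(anc, d$strain), anc, d$strain)
  s <- classify_variants(v, build_partition(anc))
  expect_equal(s$n_substitutions, 100L)
  expect_equal(s$ti, sum(d$truth$ti))
  expect_equal(sum(s$partition_counts), nrow(v))
})

test_that("variant table writer emits VCF-style anchored records", {
  a <- paste0("GAAAAC", strrep("T", 10))
  v <- data.frame(vtype = c("substitution", "deletion"), pos = c(0L, 1L),
                  ref = c("G", "A"), alt = c("T", ""), length = c(1L, 1L),
                  stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- write_variant_table(v, a, "chr", path)
  expect_equal(out$POS, c(1L, 1L))
  expect_equal(out$REF, c("G", "GA"))
  expect_equal(out$ALT, c("T", "G"))
  expect_true(file.exists(path))
})
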