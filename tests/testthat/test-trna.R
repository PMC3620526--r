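trna_feature <- function(start, anticodon, aa = "Lys", pseudo = FALSE) {
  if (pseudo) {
    feature("pseudogene", "+", cbind(start, start + 72L), name = "pst",
            qualifiers = list(product = sprintf("tRNA-%s", aa),
                              anticodon = anticodon))
  } else {
    feature("tRNA", "+", cbind(start, start + 72L), name = "t",
            qualifiers = list(product = sprintf("tRNA-%s", aa),
                              anticodon = anticodon))
  }
}

test_that("tRNA inventory counts anticodons and excludes pseudogenes", {
  rec0 <- toy_record(len = 500)
  inv0 <- trna_inventory(rec0)
  expect_equal(inv0$total, 0L)
  expect_length(inv0$anticodon_counts, 0L)

  rec <- toy_record(len = 500, features = list(
    trna_feature(10L, "CTT"), trna_feature(100L, "CTT"),
    trna_feature(200L, "CTT", pseudo = TRUE)))
  inv <- trna_inventory(rec)
  expect_equal(inv$total, 2L)
  expect_equal(unname(inv$anticodon_counts[["CTT"]]), 2L)
  expect_equal(inv$n_pseudo, 1L)
})

test_that("codon demand tallies sense codons over functional CDS", {
  rec <- toy_record(seq = paste0("ATGAAATAA", strrep("C", 21)), features = list(
    feature("CDS", "+", cbind(0L, 9L), name = "g1")))
  dem <- codon_demand(rec)
  expect_equal(unname(dem$codon_counts[["AAA"]]), 1L)
  expect_equal(dem$total_codons, 2L)

  # 3-CDS hand tally
  seq <- paste0("ATGAAATAA", "ATGCCCGGGTAA", "ATGTTTTTTTAA", strrep("A", 10))
  rec3 <- toy_record(seq = seq, features = list(
    feature("CDS", "+", cbind(0L, 9L), name = "a"),
    feature("CDS", "+", cbind(9L, 21L), name = "b"),
    feature("CDS", "+", cbind(21L, 33L), name = "c")))
  dem3 <- codon_demand(rec3)
  expect_equal(unname(dem3$codon_counts[c("ATG", "AAA", "CCC", "GGG", "TTT")]),
               c(3L, 1L, 1L, 1L, 2L))
  expect_equal(dem3$total_codons, 8L)
  expect_equal(sum(dem3$codon_counts), dem3$total_codons)
})

test_that("demand regression matches closed-form least squares", {
  exact <- data.frame(genome = letters[1:4],
                      total_codons = c(100, 200, 300, 400),
                      trna_genes = c(1, 2, 3, 4))
  expect_equal(fit_demand_regression(exact)$r_squared, 1)

  pts <- data.frame(genome = c("x", "y", "z"),
                    total_codons = c(100, 200, 300),
                    trna_genes = c(30, 32, 40))
  fit <- fit_demand_regression(pts)
  expect_equal(fit$r_squared, 1000^2 / (20000 * 56), tolerance = 1e-12)
  expect_equal(fit$slope, 1000 / 20000)

  # invariances: point order, affine rescaling of the demand axis
  fit2 <- fit_demand_regression(pts[c(3, 1, 2), ])
  expect_equal(fit2$r_squared, fit$r_squared)
  pts3 <- pts; pts3$total_codons <- 5 * pts3$total_codons + 7
  expect_equal(fit_demand_regression(pts3)$r_squared, fit$r_squared)

  flat <- pts; flat$trna_genes <- 5
  expect_error(fit_demand_regression(flat), "variance")
  expect_error(fit_demand_regression(pts[1:2, ]), "3")
})

test_that("overload scoring flags an inflated genome and spares on-line points", {
  line <- data.frame(genome = paste0("g", 1:6),
                     total_codons = c(100, 200, 300, 400, 500, 600),
                     trna_genes = c(10, 20, 30, 40, 50, 60))
  ov <- overload_score(line, "g3")
  expect_equal(ov$delta, 0, tolerance = 1e-9)

  inflated <- line
  inflated$trna_genes[2] <- inflated$trna_genes[2] * 3
  ov2 <- overload_score(inflated, "g2")
  expect_gt(ov2$delta, 0.3)
  expect_equal(ov2$r2_without, 1, tolerance = 1e-12)
  expect_error(overload_score(line, "nope"), "not in panel")
})

test_that("coverage gaps list uncovered codons in decreasing demand", {
  rec <- toy_record(seq = paste0("ATG", "GGG", "GGG", "AAA", "TAA",
                                 strrep("C", 25)),
                    features = list(feature("CDS", "+", cbind(0L, 15L), name = "g")))
  dem <- codon_demand(rec)
  inv <- trna_inventory(toy_record(len = 500, features = list(
    trna_feature(10L, "CAT", "Met"), trna_feature(100L, "TTT", "Lys"))))
  gaps <- codon_coverage_gaps(inv, dem)
  expect_equal(gaps$codon, "GGG")     # ATG covered by CAT, AAA by TTT
  expect_equal(gaps$demand, 2L)

  # wobble table extension removes the gap
  wob <- data.frame(anticodon = "TTT", codon = "GGG")
  expect_equal(nrow(codon_coverage_gaps(inv, dem, wobble = wob)), 0L)

  # full coverage: no gaps
  acs <- unique(vapply(names(dem$codon_counts[dem$codon_counts > 0]),
                       revcomp_manual, character(1)))
  inv_full <- trna_inventory(toy_record(len = 5000, features = lapply(
    seq_along(acs), function(i) trna_feature(10L + 80L * i, acs[i]))))
  expect_equal(nrow(codon_coverage_gaps(inv_full, dem)), 0L)
})
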