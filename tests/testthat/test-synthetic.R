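test_that("generated records are always valid CDSs", {
  specs <- list(
    synthetic_spec(25, model_mutation_only(0.1), seed = 1),
    synthetic_spec(25, model_mutation_only(0.9), length_range = c(101, 110), seed = 2),
    synthetic_spec(25, model_gradient(0.2, 0.8), length_range = c(120, 180), seed = 3),
    synthetic_spec(25, model_coupled(0.37), length_range = c(101, 140), seed = 4),
    synthetic_spec(25, model_weighted(c(GCT = 5, GCC = 1)), cg_suppression = 0.3, seed = 5)
  )
  for (sp in specs) {
    recs <- generate_cds(sp)
    res <- filter_cds(recs)
    expect_equal(res$report$kept, 25L)
    expect_equal(sum(res$report$counts), 0L)
    # sense codon count within the requested range
    L <- nchar(recs) / 3 - 1
    expect_true(all(L >= sp$length_range[1] & L <= sp$length_range[2]))
  }
})

test_that("generation is deterministic in the seed, and sensitive to it", {
  sp <- synthetic_spec(15, model_mutation_only(0.5), seed = 99)
  expect_identical(generate_cds(sp), generate_cds(sp))
  sp2 <- sp
  sp2$seed <- 100L
  expect_false(identical(generate_cds(sp), generate_cds(sp2)))
})

test_that("mutation-only theta controls third-position composition", {
  recs <- generate_cds(synthetic_spec(500, model_mutation_only(0.5),
                                      length_range = c(300, 300), seed = 1))
  pooled <- pool_counts(lapply(unname(recs), count_codons))
  prof <- gc_profile(pooled)
  expect_equal(prof$gc3s, 50, tolerance = 1 / 50)  # percent, +-1

  # 2-fold T/C-ending family: expected RSCU of the C-ending codon is 2*theta
  theta <- 0.3
  recs2 <- generate_cds(synthetic_spec(400, model_mutation_only(theta),
                                       length_range = c(200, 300), seed = 6))
  tab <- rscu(pool_counts(lapply(unname(recs2), count_codons)))
  expect_equal(tab["CAC", "rscu"], 2 * theta, tolerance = 0.05)  # His
  expect_equal(tab["TTC", "rscu"], 2 * theta, tolerance = 0.05)  # Phe
})

test_that("gradient model endpoints shape the positional gradient", {
  # amino acids with a free third position only (see the vignette: Met/Trp
  # always end G and Ile is 3-fold, so they offset realized GC3 from theta)
  code <- standard_genetic_code()
  free_aa <- setdiff(names(code$families)[code$family_size >= 2], c("*", "I"))
  w <- setNames(rep(1, length(free_aa)), free_aa)
  recs <- generate_cds(synthetic_spec(500, model_gradient(0.30, 0.50), aa_weights = w,
                                      length_range = c(300, 400), seed = 8))
  g <- gc3_gradient(recs, n_bins = 100)
  idx <- 2:99
  fit <- lm(g$bins[idx] ~ idx)
  expect_equal(unname(predict(fit, data.frame(idx = 1))), 0.30, tolerance = 0.04)
  expect_equal(unname(predict(fit, data.frame(idx = 100))), 0.50, tolerance = 0.04)
})

test_that("CpG suppression lowers the XCG/XCC ratio in expectation", {
  base <- generate_cds(synthetic_spec(150, model_mutation_only(0.5),
                                      length_range = c(150, 250), seed = 10))
  supp <- generate_cds(synthetic_spec(150, model_mutation_only(0.5),
                                      length_range = c(150, 250),
                                      cg_suppression = 0.5, seed = 10))
  r_base <- xcg_xcc_ratio(rscu(pool_counts(lapply(unname(base), count_codons))))
  r_supp <- xcg_xcc_ratio(rscu(pool_counts(lapply(unname(supp), count_codons))))
  expect_lt(r_supp, r_base)
  expect_lt(r_supp, 1)
})

test_that("amino-acid weights steer amino-acid composition", {
  sp <- synthetic_spec(50, model_mutation_only(0.5),
                       aa_weights = c(K = 10, G = 1), seed = 12)
  recs <- generate_cds(sp)
  pooled <- pool_counts(lapply(unname(recs), count_codons))
  code <- standard_genetic_code()
  aa_counts <- tapply(as.numeric(pooled), code$codon_to_aa[names(pooled)], sum)
  # only K, G (plus the forced start M and stops) appear, in ~10:1 ratio
  expect_equal(sum(aa_counts[setdiff(names(aa_counts), c("K", "G", "M", "*"))]), 0)
  expect_gt(aa_counts[["K"]] / aa_counts[["G"]], 5)
})

test_that("infeasible specs are rejected", {
  expect_error(synthetic_spec(0, model_mutation_only(0.5)), "n_genes")
  expect_error(synthetic_spec(5, model_mutation_only(0.5), length_range = c(50, 60)))
  expect_error(synthetic_spec(5, model_mutation_only(1.2)))
  expect_error(model_weighted(c(XYZ = 1)), "not sense codons")
  expect_error(synthetic_spec(5, model_mutation_only(0.5),
                              aa_weights = c(K = 0)), "all zero")
  # all-zero weights within a needed family
  sp <- synthetic_spec(5, model_weighted(c(AAA = 0, AAG = 0)), seed = 1)
  expect_error(generate_cds(sp), "infeasible")
})

test_that("panels use independent label-salted streams", {
  spec <- synthetic_spec(10, model_mutation_only(0.5), length_range = c(101, 120), seed = 77)
  panel <- generate_panel(list(a = spec, b = spec))
  expect_false(identical(unname(panel$a), unname(panel$b)))

  # removing one label leaves the other unchanged
  solo <- generate_panel(list(b = spec))
  expect_identical(panel$b, solo$b)

  expect_error(generate_panel(setNames(list(spec, spec), c("a", "a"))), "duplicate")
  expect_error(generate_panel(list(spec)), "labeled")
})

test_that("panel species with the same spec share summary statistics", {
  spec <- synthetic_spec(120, model_mutation_only(0.45),
                         length_range = c(200, 300), seed = 55)
  panel <- generate_panel(list(a = spec, b = spec))
  gc3s <- vapply(panel, function(r) {
    gc_profile(pool_counts(lapply(unname(r), count_codons)))$gc3s
  }, numeric(1))
  expect_equal(gc3s[["a"]], gc3s[["b"]], tolerance = 0.03)
})
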