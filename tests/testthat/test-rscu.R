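test_that("RSCU follows the family-normalized formula on hand cases", {
  # 2-fold Lys family {AAA:3, AAG:1}
  counts <- count_codons(make_cds(c(rep("AAA", 3), "AAG")))
  tab <- rscu(counts)
  expect_equal(tab["AAA", "rscu"], 1.5)
  expect_equal(tab["AAG", "rscu"], 0.5)
  expect_equal(tab["AAA", "rel_freq"], 0.75)

  # Arg family concentrated on AGA
  arg <- count_codons(make_cds(rep("AGA", 6)))
  expect_equal(rscu(arg)["AGA", "rscu"], 6)

  # single-codon families are 1 whenever observed
  expect_equal(tab["ATG", "rscu"], 1)
})

test_that("equal within-family usage gives RSCU 1 everywhere", {
  code <- standard_genetic_code()
  counts <- setNames(rep(7L, 64), sort(names(code$codon_to_aa)))
  tab <- rscu(counts)
  expect_true(all(abs(tab$rscu - 1) < 1e-9))
  expect_length(tab$rscu, 64)
  expect_equal(high_frequency_codons(tab), character(0))
})

test_that("family sums conserve family size; unobserved families are NA", {
  recs <- small_panel_records(15, theta = 0.3, seed = 23)
  tab <- rscu(pool_counts(lapply(unname(recs), count_codons)))
  sums <- tapply(tab$rscu, tab$amino_acid, sum)
  sizes <- tapply(tab$family_size, tab$amino_acid, unique)
  observed <- !is.na(sums)
  expect_true(all(abs(sums[observed] - sizes[observed]) < 1e-9))

  lys_only <- count_codons(make_cds(rep("AAA", 10)))
  tab2 <- rscu(lys_only)
  expect_true(is.na(tab2["GGG", "rscu"]))  # Gly never observed -> missing, not 0
})

test_that("RSCU is scale-invariant in the counts", {
  counts <- count_codons(make_cds(c(rep("AAA", 3), "AAG", rep("GGA", 2), "CCC")))
  scaled <- counts * 13L
  expect_equal(rscu(counts)$rscu, rscu(scaled)$rscu)
})

test_that("pooled RSCU equals brute-force recount of the concatenated sequence", {
  recs <- generate_cds(synthetic_spec(100, model_mutation_only(0.42),
                                      length_range = c(101, 200), seed = 5))
  tab <- rscu(pool_counts(lapply(unname(recs), count_codons)))
  oracle <- oracle_rscu_from_seq(paste(recs, collapse = ""))
  expect_equal(setNames(tab$rscu, tab$codon), oracle, tolerance = 1e-12)
})

test_that("pooled sense RSCU agrees with seqinr's independent implementation", {
  recs <- generate_cds(synthetic_spec(40, model_mutation_only(0.55),
                                      length_range = c(101, 150), seed = 9))
  tab <- rscu(pool_counts(lapply(unname(recs), count_codons)))
  chars <- tolower(unlist(strsplit(paste(recs, collapse = ""), "")))
  ref <- seqinr::uco(chars, index = "rscu")
  names(ref) <- toupper(names(ref))
  sense <- setdiff(tab$codon, c("TAA", "TAG", "TGA"))
  expect_equal(setNames(tab$rscu, tab$codon)[sense], ref[sense], tolerance = 1e-9)
})

test_that("high-frequency calls use strict > 1.5 / > 60% rules", {
  # RSCU exactly 1.5 and rel_freq 0.25 -> excluded (4-fold {6,2,4,4})
  counts <- count_codons(make_cds(c(rep("GCT", 6), rep("GCC", 2), rep("GCA", 4), rep("GCG", 4))))
  tab <- rscu(counts)
  expect_equal(tab["GCT", "rscu"], 1.5)
  expect_false("GCT" %in% high_frequency_codons(tab))

  # rel_freq 0.61 in a 2-fold family -> included via the 60% rule (RSCU 1.22)
  counts2 <- count_codons(make_cds(c(rep("AAA", 61), rep("AAG", 39))))
  tab2 <- rscu(counts2)
  expect_equal(tab2["AAA", "rel_freq"], 0.61)
  expect_true("AAA" %in% high_frequency_codons(tab2))

  # RSCU 1.86 (AGA-dominated Arg) -> included; 1-fold families never called
  counts3 <- count_codons(make_cds(c(rep("AGA", 31), rep("AGG", 19), rep("CGT", 25),
                                     rep("CGC", 25), rep("ATG", 50))))
  tab3 <- rscu(counts3)
  expect_equal(tab3["AGA", "rscu"], 1.86)
  hf <- high_frequency_codons(tab3)
  expect_true("AGA" %in% hf)
  expect_false("ATG" %in% hf)
})

test_that("stop-codon RSCU spans the 3-member stop family", {
  counts <- setNames(rep(0L, 64), sort(names(Biostrings::GENETIC_CODE)))
  counts[c("TAA", "TAG", "TGA")] <- c(30L, 26L, 44L)
  expect_equal(stop_codon_rscu(counts),
               c(TAA = 0.90, TAG = 0.78, TGA = 1.32))
  counts[c("TAA", "TAG", "TGA")] <- c(5L, 5L, 5L)
  expect_equal(unname(stop_codon_rscu(counts)), rep(1, 3))
  counts[c("TAA", "TAG", "TGA")] <- c(0L, 0L, 9L)
  expect_equal(unname(stop_codon_rscu(counts)), c(0, 0, 3))
  counts[c("TAA", "TAG", "TGA")] <- 0L
  expect_error(stop_codon_rscu(counts), "no stop codons")
})

test_that("motif_rscu expands wildcard patterns", {
  code <- standard_genetic_code()
  counts <- setNames(rep(2L, 64), sort(names(code$codon_to_aa)))
  tab <- rscu(counts)
  expect_setequal(names(motif_rscu(tab, "NCG")), c("ACG", "CCG", "GCG", "TCG"))
  expect_setequal(names(motif_rscu(tab, "NTA")), c("ATA", "CTA", "GTA", "TTA"))
  expect_equal(unname(motif_rscu(tab, "XCC")), rep(1, 4))
  expect_error(motif_rscu(tab, "NC"), "unknown pattern")
  expect_error(motif_rscu(tab, "NQG"), "unknown pattern")
})

test_that("XCG/XCC ratio detects CpG suppression and handles uniform usage", {
  code <- standard_genetic_code()
  uniform <- rscu(setNames(rep(3L, 64), sort(names(code$codon_to_aa))))
  expect_equal(xcg_xcc_ratio(uniform), 1)

  recs <- generate_cds(synthetic_spec(60, model_mutation_only(0.5),
                                      length_range = c(150, 250),
                                      cg_suppression = 0.5, seed = 31))
  tab <- rscu(pool_counts(lapply(unname(recs), count_codons)))
  expect_lt(xcg_xcc_ratio(tab), 1)

  lys_only <- rscu(count_codons(make_cds(rep("AAA", 10))))
  expect_error(xcg_xcc_ratio(lys_only), "undefined")
})
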