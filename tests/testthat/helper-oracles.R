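# Shared fixtures and independent oracles used across the test files.

# build a CDS string from a vector of sense codons (ATG start and stop added)
make_cds <- function(codons, stop = "TAA") {
  paste0("ATG", paste(codons, collapse = ""), stop)
}

# a valid CDS of n sense codons drawn from one repeated codon
repeat_cds <- function(codon, n, stop = "TAA") {
  make_cds(rep(codon, n), stop = stop)
}

# brute-force RSCU recount from a raw concatenated coding sequence,
# independent of the package's counting/pooling path: chop into codons with
# base string ops, tally with table(), apply the family-normalized formula
# using Biostrings' published code table.
oracle_rscu_from_seq <- function(seq) {
  n <- nchar(seq)
  cods <- substring(seq, seq(1, n - 2, 3), seq(3, n, 3))
  code <- Biostrings::GENETIC_CODE
  all_codons <- sort(names(code))
  tab <- table(factor(cods, levels = all_codons))
  out <- setNames(rep(NA_real_, 64), all_codons)
  for (aa in unique(code)) {
    fam <- all_codons[code[all_codons] == aa]
    tot <- sum(tab[fam])
    if (tot > 0) out[fam] <- length(fam) * as.numeric(tab[fam]) / tot
  }
  out
}

# small deterministic synthetic gene set used by several files
small_panel_records <- function(n_genes = 30, theta = 0.5, seed = 101,
                                length_range = c(101, 160)) {
  generate_cds(synthetic_spec(n_genes, model_mutation_only(theta),
                              length_range = length_range, seed = seed))
}
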