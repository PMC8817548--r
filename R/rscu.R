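# Relative synonymous codon usage (Sharp & Li) and derived statistics:
# high-frequency codons, stop-codon usage, wildcard-motif extraction and
# the XCG/XCC dinucleotide-suppression ratio.

#' Relative synonymous codon usage
#'
#' For each synonymous family `i` of size `n_i` with total count `T_i > 0`,
#' `RSCU_ij = n_i * x_ij / T_i` -- the observed count divided by the count
#' expected under equal use within the family. `rel_freq` is the
#' within-family relative frequency `x_ij / T_i`. Families with zero total
#' count get `NA` (a zero would fake extreme bias). When `include_stops`
#' the three stop codons form one family of size 3.
#'
#' @param counts A 64-entry codon count vector.
#' @param code A `genetic_code`.
#' @param include_stops Include the stop-codon family? Default `TRUE`.
#' @return Data frame of class `rscu_table` with columns `codon`,
#'   `amino_acid`, `family_size`, `count`, `rel_freq`, `rscu`; 64 rows
#'   (or 61 without stops), codons in lexicographic order. The `scope`
#'   attribute of `counts` is carried over.
#' @examples
#' counts <- count_codons("ATGAAAAAAAAAAAGTAA")  # Lys: AAA x3, AAG x1
#' rscu(counts)[c("AAA", "AAG"), "rscu"]      # 1.5, 0.5
#' @export
rscu <- function(counts, code = standard_genetic_code(), include_stops = TRUE) {
  stopifnot(length(counts) == 64L)
  x <- as.numeric(counts[CODONS])
  if (sum(x) <= 0) stop("codon count table is empty")
  aa <- unname(code$codon_to_aa[CODONS])
  fam_total <- tapply(x, aa, sum)[aa]
  n_i <- unname(code$family_size[aa])
  rel_freq <- ifelse(fam_total > 0, x / fam_total, NA_real_)
  rscu_val <- ifelse(fam_total > 0, n_i * x / fam_total, NA_real_)
  out <- data.frame(
    codon = CODONS, amino_acid = aa, family_size = n_i,
    count = x, rel_freq = unname(rel_freq), rscu = unname(rscu_val),
    row.names = CODONS
  )
  if (!include_stops) out <- out[out$amino_acid != "*", ]
  attr(out, "scope") <- attr(counts, "scope")
  class(out) <- c("rscu_table", "data.frame")
  out
}

#' High-frequency codons
#'
#' A codon is high-frequency when its RSCU exceeds `rscu_cutoff` or its
#' within-family relative frequency exceeds `freq_cutoff` (both strict
#' inequalities). Stop codons and single-codon families (Met, Trp) are
#' excluded.
#'
#' @param table An `rscu_table`.
#' @param rscu_cutoff RSCU threshold (default 1.5).
#' @param freq_cutoff Relative-frequency threshold (default 0.60).
#' @return Character vector of codons, lexicographic order.
#' @export
high_frequency_codons <- function(table, rscu_cutoff = 1.5, freq_cutoff = 0.60) {
  stopifnot(inherits(table, "rscu_table"))
  eligible <- table$amino_acid != "*" & table$family_size >= 2L & !is.na(table$rscu)
  hit <- eligible & (table$rscu > rscu_cutoff | table$rel_freq > freq_cutoff)
  table$codon[hit]
}

#' Stop-codon RSCU
#'
#' RSCU over the three-member stop family: `3 * x_s / T_stop`.
#'
#' @param counts A 64-entry codon count vector with at least one stop
#'   codon counted.
#' @return Named numeric vector over TAA, TAG, TGA.
#' @export
stop_codon_rscu <- function(counts) {
  stopifnot(length(counts) == 64L)
  x <- as.numeric(counts[STOP_CODONS])
  names(x) <- STOP_CODONS
  total <- sum(x)
  if (total == 0) stop("no stop codons counted")
  3 * x / total
}

#' RSCU of a wildcard codon motif
#'
#' Expands a three-character pattern in which `N` or `X` matches any base
#' and fixed characters match themselves, and returns the RSCU of the
#' matching codons (e.g. `"NCG"` -> ACG, CCG, GCG, TCG).
#'
#' @param table An `rscu_table`.
#' @param pattern Three-character motif over \{A,C,G,T,N,X\}.
#' @return Named numeric vector of RSCU values for the matching codons.
#' @export
motif_rscu <- function(table, pattern) {
  stopifnot(inherits(table, "rscu_table"), is.character(pattern), length(pattern) == 1L)
  pattern <- toupper(pattern)
  if (nchar(pattern) != 3L || grepl("[^ACGTNX]", pattern)) {
    stop("unknown pattern '", pattern, "': must be 3 characters over {A,C,G,T,N,X}")
  }
  re <- chartr("NX", "..", pattern)
  hits <- table$codon[grepl(paste0("^", re, "$"), table$codon)]
  setNames(table[hits, "rscu"], hits)
}

#' XCG/XCC ratio
#'
#' Sum of the four XCG RSCU values divided by the sum of the four XCC RSCU
#' values (X over A, C, G, T); values below 1 indicate CG dinucleotide
#' suppression at codon positions 2-3.
#'
#' @param table An `rscu_table` in which all eight XCG/XCC codons have
#'   defined RSCU.
#' @return A single numeric ratio.
#' @export
xcg_xcc_ratio <- function(table) {
  xcg <- motif_rscu(table, "XCG")
  xcc <- motif_rscu(table, "XCC")
  if (anyNA(xcg) || anyNA(xcc)) {
    stop("XCG/XCC ratio undefined: some XCG or XCC codons have no observed family")
  }
  denom <- sum(xcc)
  if (denom == 0) stop("XCG/XCC ratio undefined: sum of XCC RSCU is zero")
  sum(xcg) / denom
}

#' Serialize an RSCU table as TSV
#'
#' Columns: codon, amino_acid, count, rel_freq, rscu, is_high_frequency.
#'
#' @param table An `rscu_table`.
#' @param path Output path.
#' @param rscu_cutoff,freq_cutoff High-frequency thresholds, see
#'   [high_frequency_codons()].
#' @return `path`, invisibly.
#' @export
write_rscu_table <- function(table, path, rscu_cutoff = 1.5, freq_cutoff = 0.60) {
  hf <- high_frequency_codons(table, rscu_cutoff, freq_cutoff)
  df <- data.frame(
    codon = table$codon, amino_acid = table$amino_acid, count = table$count,
    rel_freq = table$rel_freq, rscu = table$rscu,
    is_high_frequency = table$codon %in% hf
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
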