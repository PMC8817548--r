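# Codon-pair statistics: adjacent sense-codon pair counts, the 16-category
# junction dinucleotide table, RSCPU and high-frequency pair calls.

#' Count adjacent sense-codon pairs
#'
#' Enumerates overlapping adjacent pairs `(c1,c2), (c2,c3), ...` over each
#' gene's sense codons (the terminal stop codon and any pair involving it
#' are excluded) and pools counts across genes. A gene with `L` sense
#' codons contributes `L - 1` pairs.
#'
#' @param records Named character vector of filtered CDSs.
#' @param code A `genetic_code`.
#' @return Data frame of class `pair_counts` with columns `codon1`,
#'   `codon2`, `count` over all 61 x 61 sense-codon pairs, plus attribute
#'   `total` (total pair count).
#' @export
codon_pair_counts <- function(records, code = standard_genetic_code()) {
  stopifnot(length(records) > 0L)
  sense <- .sense_codons(code)
  pair_strings <- lapply(records, function(s) {
    cods <- .codon_strings(toupper(s))
    L <- length(cods)
    if (L > 0L && cods[L] %in% STOP_CODONS) cods <- cods[-L]
    L <- length(cods)
    if (L < 2L) return(character(0))
    paste(cods[-L], cods[-1L], sep = "|")
  })
  tab <- table(unlist(pair_strings, use.names = FALSE))
  grid <- expand.grid(codon2 = sense, codon1 = sense,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(codon1 = grid$codon1, codon2 = grid$codon2, count = 0)
  key <- paste(out$codon1, out$codon2, sep = "|")
  hit <- match(names(tab), key)
  if (anyNA(hit)) stop("internal error: unexpected stop-containing pair")
  out$count[hit] <- as.numeric(tab)
  attr(out, "total") <- sum(out$count)
  class(out) <- c("pair_counts", "data.frame")
  out
}

#' Junction dinucleotide table
#'
#' Classifies every codon pair by its junction dinucleotide -- the third
#' base of the first codon followed by the first base of the second codon
#' (the XY of nnXYnn) -- and reports the percentage of pairs in each of the
#' 16 categories.
#'
#' @param pairs A `pair_counts` table with at least one pair.
#' @return Data frame with columns `junction` (labels nnAAnn ... nnTTnn)
#'   and `percent`; 16 rows summing to 100.
#' @export
junction_table <- function(pairs) {
  stopifnot(inherits(pairs, "pair_counts"))
  total <- sum(pairs$count)
  if (total == 0) stop("no codon pairs counted")
  xy <- paste0(substr(pairs$codon1, 3L, 3L), substr(pairs$codon2, 1L, 1L))
  levels16 <- as.vector(outer(BASES, BASES, paste0))
  levels16 <- sort(levels16)
  cnt <- tapply(pairs$count, factor(xy, levels = levels16), sum)
  cnt[is.na(cnt)] <- 0
  data.frame(
    junction = paste0("nn", levels16, "nn"),
    percent = 100 * as.numeric(cnt) / total
  )
}

#' Relative synonymous codon pair usage
#'
#' Lifts the RSCU formula to ordered codon pairs: the synonymous family of
#' a pair is the set of all pairs encoding the same ordered amino-acid
#' dipeptide, with size `m = n_i * n_j` (product of the two codon family
#' sizes). Within a family with total observed count `T > 0`,
#' `RSCPU = m * count / T`; `share = count / T` is the within-family share.
#' Families with `T = 0` get `NA`.
#'
#' @param pairs A `pair_counts` table.
#' @param code A `genetic_code`.
#' @return Data frame of class `rscpu_table` with columns `codon1`,
#'   `codon2`, `dipeptide`, `family_size`, `count`, `share`, `rscpu`.
#' @export
rscpu <- function(pairs, code = standard_genetic_code()) {
  stopifnot(inherits(pairs, "pair_counts"))
  if (sum(pairs$count) == 0) stop("no codon pairs counted")
  aa1 <- unname(code$codon_to_aa[pairs$codon1])
  aa2 <- unname(code$codon_to_aa[pairs$codon2])
  dipep <- paste0(aa1, aa2)
  m <- unname(code$family_size[aa1] * code$family_size[aa2])
  fam_total <- stats::ave(pairs$count, dipep, FUN = sum)
  share <- ifelse(fam_total > 0, pairs$count / fam_total, NA_real_)
  val <- ifelse(fam_total > 0, m * pairs$count / fam_total, NA_real_)
  out <- data.frame(
    codon1 = pairs$codon1, codon2 = pairs$codon2, dipeptide = dipep,
    family_size = m, count = pairs$count, share = share, rscpu = val
  )
  class(out) <- c("rscpu_table", "data.frame")
  out
}

#' High-frequency codon pairs
#'
#' A pair is high-frequency when its RSCPU exceeds `rscpu_cutoff` or its
#' within-family share exceeds `share_cutoff` (both strict). Families with
#' fewer than `min_family_size` possible pairs are excluded by default
#' (a single-member family such as Met-Trp offers no synonymous choice),
#' mirroring the exclusion of 1-fold families in the codon-level rule; set
#' `min_family_size = 1` to disable.
#'
#' @param table An `rscpu_table`.
#' @param rscpu_cutoff RSCPU threshold (default 1.5).
#' @param share_cutoff Share threshold (default 0.60).
#' @param min_family_size Minimum synonymous-family size (default 2).
#' @return The qualifying rows of `table` (a data frame).
#' @export
high_frequency_pairs <- function(table, rscpu_cutoff = 1.5, share_cutoff = 0.60,
                                 min_family_size = 2L) {
  stopifnot(inherits(table, "rscpu_table"))
  eligible <- !is.na(table$rscpu) & table$family_size >= min_family_size
  hit <- eligible & (table$rscpu > rscpu_cutoff | table$share > share_cutoff)
  out <- table[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}
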