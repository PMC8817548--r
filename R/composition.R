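# Codon counting and GC-content indices (GC, GC1-GC3, GC3s), plus the
# 5'->3' positional GC3 gradient used for inter-species comparison.

#' Count in-frame codons of one coding sequence
#'
#' Counts every in-frame codon, including the terminal stop codon (which
#' lands in one of the three STOP entries; filtered CDSs contain no other
#' stop). For a filtered gene the sense-codon total is `length/3 - 1`.
#'
#' @param seq A single nucleotide string with length divisible by 3.
#' @param scope Optional label (gene id or pooled-species tag) attached to
#'   the result.
#' @return Named integer vector of length 64 (codon counts, lexicographic
#'   codon order) with attribute `scope`.
#' @export
count_codons <- function(seq, scope = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) %% 3L != 0L || nchar(seq) == 0L) {
    stop("sequence length must be a positive multiple of 3 (got ", nchar(seq), " nt)")
  }
  cods <- .codon_strings(toupper(seq))
  counts <- tabulate(factor(cods, levels = CODONS), nbins = 64L)
  names(counts) <- CODONS
  attr(counts, "scope") <- scope
  counts
}

#' Pool codon count tables elementwise
#'
#' @param tables A non-empty list of 64-entry codon count vectors.
#' @param scope Label for the pooled table (default `"pooled"`).
#' @return A 64-entry codon count vector, the elementwise sum.
#' @export
pool_counts <- function(tables, scope = "pooled") {
  if (!is.list(tables) || length(tables) == 0L) {
    stop("'tables' must be a non-empty list of codon count tables")
  }
  m <- vapply(tables, function(t) {
    stopifnot(length(t) == 64L)
    as.integer(t[CODONS])
  }, integer(64L))
  counts <- as.integer(rowSums(m))
  names(counts) <- CODONS
  attr(counts, "scope") <- scope
  counts
}

#' GC composition indices from a codon count table
#'
#' GC1/GC2/GC3 are the percentage of G or C at codon positions 1/2/3 over
#' all sense codons (stop codons excluded, ATG and TGG included); `gc` is
#' the percentage over all three positions of the same codon set, so
#' `gc = (gc1 + gc2 + gc3)/3` exactly. GC3s restricts the third position to
#' codons of amino acids with two or more synonymous codons (i.e. it also
#' excludes ATG and TGG), the convention used by codonW.
#'
#' @param counts A 64-entry codon count vector ([count_codons()] /
#'   [pool_counts()]).
#' @param code A `genetic_code`.
#' @return List of class `composition_profile` with elements `gc`, `gc1`,
#'   `gc2`, `gc3`, `gc3s` (percent) and `n_codons` (sense codons counted).
#' @examples
#' gc_profile(count_codons("ATGGATTAA"))  # gc1 50, gc2 0, gc3 50, gc3s 0
#' @export
gc_profile <- function(counts, code = standard_genetic_code()) {
  stopifnot(length(counts) == 64L)
  counts <- as.numeric(counts[CODONS])
  sense <- !(CODONS %in% STOP_CODONS)
  n_sense <- sum(counts[sense])
  if (n_sense == 0) {
    stop("cannot compute a GC profile from zero sense codons")
  }
  gc1 <- 100 * sum(counts[sense] * .GC1[sense]) / n_sense
  gc2 <- 100 * sum(counts[sense] * .GC2[sense]) / n_sense
  gc3 <- 100 * sum(counts[sense] * .GC3[sense]) / n_sense
  syn <- sense & code$family_size[code$codon_to_aa[CODONS]] >= 2L
  n_syn <- sum(counts[syn])
  gc3s <- if (n_syn > 0) 100 * sum(counts[syn] * .GC3[syn]) / n_syn else NA_real_
  structure(
    list(gc = (gc1 + gc2 + gc3) / 3, gc1 = gc1, gc2 = gc2, gc3 = gc3,
         gc3s = gc3s, n_codons = as.integer(n_sense)),
    class = "composition_profile"
  )
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("GC %.2f%%  GC1 %.2f%%  GC2 %.2f%%  GC3 %.2f%%  GC3s %.2f%%  (%d sense codons)\n",
              x$gc, x$gc1, x$gc2, x$gc3, x$gc3s, x$n_codons))
  invisible(x)
}

#' Per-gene composition table
#'
#' @param records Named character vector of filtered CDSs.
#' @param code A `genetic_code`.
#' @return Data frame with columns `gene_id`, `n_codons`, `gc`, `gc1`,
#'   `gc2`, `gc3`, `gc3s` (percent), one row per gene.
#' @export
composition_table <- function(records, code = standard_genetic_code()) {
  stopifnot(length(records) > 0L)
  rows <- lapply(seq_along(records), function(i) {
    p <- gc_profile(count_codons(records[[i]]), code)
    data.frame(gene_id = names(records)[i], n_codons = p$n_codons,
               gc = p$gc, gc1 = p$gc1, gc2 = p$gc2, gc3 = p$gc3, gc3s = p$gc3s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# third-position G/C indicator over the sense codons of one gene
# (terminal stop dropped when present)
.gene_gc3_indicators <- function(seq) {
  cods <- .codon_strings(toupper(seq))
  L <- length(cods)
  if (L > 0L && cods[L] %in% STOP_CODONS) cods <- cods[-L]
  substr(cods, 3L, 3L) %in% c("G", "C")
}

#' 5'-to-3' GC3 gradient of a gene set
#'
#' In `positional` mode (the default) each gene's sense codons are split
#' 5'->3' into `n_bins` contiguous, equal-as-possible segments -- segment
#' `b` (0-based) of a gene with `L` codons covers codon indices
#' `floor(b*L/n)` to `floor((b+1)*L/n) - 1` -- and bin `b` of the gradient
#' is the G+C fraction at third codon positions pooled over segment `b` of
#' all genes. Genes with fewer than `n_bins` sense codons cannot fill every
#' segment and are skipped (their number is recorded).
#'
#' In `ranked` mode genes are sorted by gene-level GC3 ascending and split
#' into `n_bins` equal-size groups; each bin is the group mean of gene GC3.
#'
#' @param records Named character vector of filtered CDSs.
#' @param n_bins Number of gradient bins (default 100).
#' @param mode `"positional"` or `"ranked"`.
#' @param species Optional species label carried on the result.
#' @return Object of class `gc3_gradient`: list with `bins` (numeric
#'   `n_bins`-vector of GC3 fractions in \[0, 1\]), `mode`, `n_bins`,
#'   `species`, `n_genes_used`, `n_skipped`.
#' @export
gc3_gradient <- function(records, n_bins = 100L, mode = c("positional", "ranked"),
                         species = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_bins >= 2L)
  if (length(records) == 0L) stop("no records supplied")
  if (mode == "positional") {
    num <- den <- numeric(n_bins)
    skipped <- 0L
    for (s in records) {
      gc <- .gene_gc3_indicators(s)
      L <- length(gc)
      if (L < n_bins) {
        skipped <- skipped + 1L
        next
      }
      bin <- floor((seq_len(L) - 1L) * n_bins / L) + 1L
      num <- num + vapply(split(gc, bin), sum, numeric(1))
      den <- den + tabulate(bin, nbins = n_bins)
    }
    used <- length(records) - skipped
    if (used == 0L) stop("no gene has at least ", n_bins, " sense codons")
    bins <- num / den
  } else {
    gene_gc3 <- vapply(records, function(s) mean(.gene_gc3_indicators(s)), numeric(1))
    N <- length(gene_gc3)
    if (N < n_bins) stop("ranked mode needs at least ", n_bins, " genes (got ", N, ")")
    ord <- sort(gene_gc3)
    grp <- floor((seq_len(N) - 1L) * n_bins / N) + 1L
    bins <- vapply(split(ord, grp), mean, numeric(1))
    used <- N
    skipped <- 0L
  }
  structure(
    list(bins = unname(bins), mode = mode, n_bins = as.integer(n_bins),
         species = species, n_genes_used = used, n_skipped = skipped),
    class = "gc3_gradient"
  )
}

#' @export
print.gc3_gradient <- function(x, ...) {
  cat("GC3 gradient (", x$mode, ", ", x$n_bins, " bins, ",
      x$n_genes_used, " genes",
      if (x$n_skipped > 0) paste0(", ", x$n_skipped, " skipped") else "",
      ")\n", sep = "")
  cat("  range: ", sprintf("%.4f", min(x$bins)), " - ",
      sprintf("%.4f", max(x$bins)), "\n", sep = "")
  invisible(x)
}
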