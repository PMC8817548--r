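# Effective number of codons: Wright's observed estimator, the GC3s
# expected curve, the (ENCexp - ENCobs)/ENCexp deviation histogram, and the
# GC12-GC3 neutrality regression.

# Wright's per-family codon homozygosity estimate; undefined below 2 counts
.wright_fhat <- function(x) {
  n <- sum(x)
  if (n < 2) return(NA_real_)
  p <- x / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Observed effective number of codons (Wright's estimator)
#'
#' For each synonymous family with at least 2 counted codons,
#' `F_hat = (n * sum(p_j^2) - 1) / (n - 1)` with `p_j = x_j / n`. `F_hat`
#' is averaged within each degeneracy class k in \{2, 3, 4, 6\} over
#' families where it is defined, and
#' `ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`. If the 3-fold class (Ile) is
#' missing its average is imputed as `(F2 + F4)/2`, the codonW convention.
#' If any other class average is undefined, or any average is zero or
#' negative, the gene's ENc is undefined and `NA` is returned with a
#' `reason` attribute. The result is capped at `cap` (61: every synonymous
#' codon used equally).
#'
#' @param counts A per-gene 64-entry codon count vector.
#' @param code A `genetic_code`.
#' @param cap Upper saturation cap (default 61).
#' @return ENc value in \[20, cap\], or `NA` with attribute `reason`.
#' @export
enc_observed <- function(counts, code = standard_genetic_code(), cap = 61) {
  stopifnot(length(counts) == 64L)
  counts <- as.numeric(counts[CODONS])
  aa_of <- unname(code$codon_to_aa[CODONS])
  class_weight <- c("2" = 9, "3" = 1, "4" = 5, "6" = 3)
  fbar <- setNames(rep(NA_real_, 4), names(class_weight))
  for (k in names(class_weight)) {
    fams <- code$degeneracy_classes[[k]]
    fh <- vapply(fams, function(a) .wright_fhat(counts[aa_of == a]), numeric(1))
    if (any(!is.na(fh))) fbar[[k]] <- mean(fh, na.rm = TRUE)
  }
  if (is.na(fbar[["3"]]) && !is.na(fbar[["2"]]) && !is.na(fbar[["4"]])) {
    fbar[["3"]] <- (fbar[["2"]] + fbar[["4"]]) / 2
  }
  if (anyNA(fbar)) {
    out <- NA_real_
    attr(out, "reason") <- paste0("undefined_class_", names(fbar)[is.na(fbar)][1])
    return(out)
  }
  if (any(fbar <= 0)) {
    out <- NA_real_
    attr(out, "reason") <- "nonpositive_class_mean"
    return(out)
  }
  min(2 + sum(class_weight / fbar), cap)
}

#' Expected ENc under GC3s-driven mutation alone
#'
#' Evaluates `ENc = 2 + F + 29 / (F^2 + (1 - F)^2)` for `F` the GC3s
#' fraction -- the ENc a gene would show if codon usage were determined
#' only by third-position G+C composition.
#'
#' @param gc3s GC3s as a fraction in \[0, 1\] (vectorized).
#' @return Expected ENc value(s).
#' @examples
#' enc_expected(0.5)  # 60.5
#' @export
enc_expected <- function(gc3s) {
  if (anyNA(gc3s) || any(gc3s < 0 | gc3s > 1)) {
    stop("gc3s must lie in [0, 1]")
  }
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Histogram of the ENc deviation statistic
#'
#' Bins `(ENCexp - ENCobs)/ENCexp` into half-open intervals `[lo, hi)`
#' given by `edges`; values outside the covered range are tallied as
#' out-of-range. Percentages over all bins plus out-of-range sum to 100.
#'
#' @param deviations Numeric vector of deviation values.
#' @param edges Bin edges; default `(-2:5)/10`, i.e. seven bins from -0.2
#'   to 0.5 (integer-ratio form so the edges are the exact doubles of the
#'   written decimals).
#' @return Data frame of class `deviation_histogram` with columns
#'   `bin_lo`, `bin_hi`, `percent`, plus attributes `out_of_range_percent`
#'   and `n`.
#' @export
deviation_histogram <- function(deviations, edges = (-2:5)/10) {
  stopifnot(length(edges) >= 2L, !is.unsorted(edges))
  n <- length(deviations)
  if (n == 0L) stop("no deviations supplied")
  k <- length(edges) - 1L
  idx <- findInterval(deviations, edges, left.open = FALSE)
  in_range <- idx >= 1L & idx <= k & deviations < edges[length(edges)]
  counts <- tabulate(idx[in_range], nbins = k)
  out <- data.frame(
    bin_lo = edges[-length(edges)], bin_hi = edges[-1],
    percent = 100 * counts / n
  )
  attr(out, "out_of_range_percent") <- 100 * sum(!in_range) / n
  attr(out, "n") <- n
  class(out) <- c("deviation_histogram", "data.frame")
  out
}

#' Per-gene ENc table with deviation histogram
#'
#' Computes, for every gene with a defined ENc: observed ENc, GC3s,
#' expected ENc from the GC3s curve, and the deviation
#' `(ENCexp - ENCobs)/ENCexp`. Genes whose ENc is undefined (e.g. a whole
#' degeneracy class absent) are excluded and tallied by reason.
#'
#' @param records Named character vector of filtered CDSs.
#' @param code A `genetic_code`.
#' @param edges Histogram bin edges, see [deviation_histogram()].
#' @return List of class `enc_table` with `genes` (data frame: `gene_id`,
#'   `n_codons`, `gc3s`, `enc_obs`, `enc_exp`, `deviation`), `histogram`
#'   (a `deviation_histogram`), and `excluded` (named integer tally of
#'   exclusion reasons, possibly empty).
#' @export
enc_table <- function(records, code = standard_genetic_code(),
                      edges = (-2:5)/10) {
  stopifnot(length(records) > 0L)
  rows <- vector("list", length(records))
  excluded <- integer(0)
  for (i in seq_along(records)) {
    counts <- count_codons(records[[i]])
    prof <- gc_profile(counts, code)
    obs <- enc_observed(counts, code)
    if (is.na(obs)) {
      reason <- attr(obs, "reason")
      excluded[reason] <- (if (reason %in% names(excluded)) excluded[[reason]] else 0L) + 1L
      next
    }
    f <- prof$gc3s / 100
    ex <- enc_expected(f)
    rows[[i]] <- data.frame(
      gene_id = names(records)[i], n_codons = prof$n_codons,
      gc3s = f, enc_obs = obs, enc_exp = ex, deviation = (ex - obs) / ex
    )
  }
  genes <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(genes) || nrow(genes) == 0L) stop("no gene has a defined ENc")
  rownames(genes) <- NULL
  structure(
    list(genes = genes, histogram = deviation_histogram(genes$deviation, edges),
         excluded = excluded),
    class = "enc_table"
  )
}

#' @export
print.enc_table <- function(x, ...) {
  cat("ENc table:", nrow(x$genes), "genes",
      if (length(x$excluded)) paste0("(", sum(x$excluded), " excluded)") else "", "\n")
  cat(sprintf("  mean ENc_obs %.2f, mean deviation %.4f\n",
              mean(x$genes$enc_obs), mean(x$genes$deviation)))
  invisible(x)
}

#' GC12-GC3 neutrality regression
#'
#' Ordinary least-squares fit of per-gene GC12 (the mean of GC1 and GC2)
#' on GC3, with the Pearson correlation and its two-sided p-value
#' (t-distribution, n - 2 df). A slope near 1 indicates mutation pressure
#' acting alike on all codon positions; a slope near 0 indicates selective
#' constraint on positions 1-2.
#'
#' @param gc12 Per-gene GC12 values (percent or fraction, used as given).
#' @param gc3 Per-gene GC3 values on the same scale.
#' @return List of class `neutrality_fit`: `slope`, `intercept`, `r`,
#'   `r2`, `p_value`, `n_genes`.
#' @export
neutrality_fit <- function(gc12, gc3) {
  stopifnot(length(gc12) == length(gc3))
  ok <- stats::complete.cases(gc12, gc3)
  gc12 <- gc12[ok]
  gc3 <- gc3[ok]
  n <- length(gc3)
  if (n < 3L) stop("neutrality regression needs at least 3 genes")
  if (stats::var(gc3) == 0) stop("slope undefined: GC3 has zero variance")
  fit <- stats::lm(gc12 ~ gc3)
  if (stats::var(gc12) == 0) {
    r <- 0
    p <- 1
  } else {
    ct <- stats::cor.test(gc3, gc12, method = "pearson")
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r = r, r2 = r^2, p_value = p, n_genes = n),
    class = "neutrality_fit"
  )
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf("Neutrality fit (n = %d): GC12 = %.4f + %.4f * GC3;  R2 = %.4f, p = %.3g\n",
              x$n_genes, x$intercept, x$slope, x$r2, x$p_value))
  invisible(x)
}
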