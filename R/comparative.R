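# Cross-species structures: Euclidean distances between GC3 gradients and
# Euclidean/complete-linkage biclustering of the species x 59-codon RSCU
# matrix.

#' Euclidean distance between two numeric vectors
#'
#' `d(p, q) = sqrt(sum((p_i - q_i)^2))`; symmetric, zero iff `p == q`.
#'
#' @param p,q Numeric vectors of equal length.
#' @return A single non-negative number.
#' @export
euclidean_distance <- function(p, q) {
  if (length(p) != length(q)) {
    stop("vectors differ in length (", length(p), " vs ", length(q), ")")
  }
  sqrt(sum((p - q)^2))
}

#' Pairwise Euclidean distances between GC3 gradients
#'
#' @param gradients Named list of `gc3_gradient` objects sharing mode and
#'   bin count (names are species labels; unnamed lists fall back to the
#'   gradients' own `species` fields).
#' @return Symmetric numeric matrix with zero diagonal, species labels as
#'   dimnames.
#' @export
gradient_distance_matrix <- function(gradients) {
  stopifnot(is.list(gradients), length(gradients) >= 2L)
  ok <- vapply(gradients, inherits, logical(1), what = "gc3_gradient")
  if (!all(ok)) stop("all elements must be gc3_gradient objects")
  modes <- vapply(gradients, `[[`, character(1), "mode")
  nb <- vapply(gradients, `[[`, integer(1), "n_bins")
  if (length(unique(modes)) != 1L) stop("gradient mode mismatch: ", paste(unique(modes), collapse = ", "))
  if (length(unique(nb)) != 1L) stop("gradient bin-count mismatch")
  labels <- names(gradients)
  if (is.null(labels) || any(labels == "")) {
    labels <- vapply(gradients, function(g) {
      if (is.null(g$species)) "" else as.character(g$species)
    }, character(1))
  }
  if (any(labels == "") || anyDuplicated(labels)) {
    stop("gradients must carry unique species labels")
  }
  m <- do.call(rbind, lapply(gradients, `[[`, "bins"))
  rownames(m) <- labels
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  dimnames(d) <- list(labels, labels)
  d
}

#' Assemble the species x 59-codon RSCU matrix
#'
#' Rows are species, columns the 59 comparison codons (the 61 sense codons
#' minus the single-codon families ATG and TGG) in fixed lexicographic
#' order. Each species' RSCU must come from pooled genome-wide counts so
#' that every family is observed; a missing (NA) entry is an error naming
#' the species and family.
#'
#' @param tables Named list of `rscu_table` objects, one per species.
#' @return Numeric matrix, species x 59 codons.
#' @export
build_rscu_matrix <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (is.null(names(tables)) || any(names(tables) == "") || anyDuplicated(names(tables))) {
    stop("'tables' must be a list uniquely named by species")
  }
  cods <- .codons59()
  rows <- lapply(names(tables), function(sp) {
    tab <- tables[[sp]]
    stopifnot(inherits(tab, "rscu_table"))
    v <- tab[match(cods, tab$codon), "rscu"]
    if (anyNA(v)) {
      miss <- tab$amino_acid[match(cods[is.na(v)][1], tab$codon)]
      stop("species '", sp, "' has no observed codons for family '", miss,
           "'; species-level RSCU requires pooled counts covering every family")
    }
    v
  })
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(tables), cods)
  m
}

#' Bicluster a species x codon RSCU matrix
#'
#' Agglomerative hierarchical clustering with Euclidean distance and (by
#' default) complete linkage, applied independently to the rows (species)
#' and the columns (codons). Values are used unstandardized: RSCU is
#' already family-normalized.
#'
#' @param m Numeric matrix (e.g. from [build_rscu_matrix()]) with at least
#'   2 rows and 2 columns.
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @return List of class `bicluster`: `row_dendrogram` and
#'   `col_dendrogram` (`hclust` objects), `row_order` and `col_order`
#'   (labels in dendrogram leaf order), and `linkage`.
#' @export
bicluster <- function(m, linkage = "complete") {
  stopifnot(is.matrix(m), nrow(m) >= 2L, ncol(m) >= 2L)
  row_hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = linkage)
  col_hc <- stats::hclust(stats::dist(t(m), method = "euclidean"), method = linkage)
  structure(
    list(row_dendrogram = row_hc, col_dendrogram = col_hc,
         row_order = rownames(m)[row_hc$order],
         col_order = colnames(m)[col_hc$order],
         linkage = linkage),
    class = "bicluster"
  )
}

#' @export
print.bicluster <- function(x, ...) {
  cat("Bicluster (", x$linkage, " linkage): ",
      length(x$row_order), " rows x ", length(x$col_order), " columns\n", sep = "")
  cat("  row order:", paste(x$row_order, collapse = ", "), "\n")
  invisible(x)
}

#' Export a dendrogram as Newick
#'
#' Merge heights become branch lengths via [ape::as.phylo()].
#'
#' @param hc An `hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Export an hclust merge list as TSV
#'
#' Columns `node1`, `node2` (negative = leaf index, positive = earlier
#' merge), `height`, `size` (leaves under the merge).
#'
#' @param hc An `hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_merge_list <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  sizes <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    sz <- function(j) if (j < 0) 1L else sizes[j]
    sizes[i] <- sz(hc$merge[i, 1]) + sz(hc$merge[i, 2])
  }
  df <- data.frame(node1 = hc$merge[, 1], node2 = hc$merge[, 2],
                   height = hc$height, size = sizes)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
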