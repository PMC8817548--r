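# Seeded generator of valid synthetic CDS sets with controlled codon-usage
# structure: third-position GC pressure (mutation-only), arbitrary
# per-family codon weights, 5'->3' GC3 gradients, GC12-GC3 coupling, and
# CpG suppression. Every generated record passes filter_cds().

AA20 <- setdiff(names(standard_genetic_code()$families), "*")

.SENSE <- setdiff(CODONS, STOP_CODONS)
.SENSE_AA <- unname(standard_genetic_code()$codon_to_aa[.SENSE])
.SENSE_GC1 <- substr(.SENSE, 1L, 1L) %in% c("G", "C")
.SENSE_GC2 <- substr(.SENSE, 2L, 2L) %in% c("G", "C")
.SENSE_GC3 <- substr(.SENSE, 3L, 3L) %in% c("G", "C")
.SENSE_NCG <- substr(.SENSE, 2L, 3L) == "CG"

#' Mutation-only codon-choice model
#'
#' Within each synonymous family, codons are chosen by a third-position
#' nucleotide probability restricted to the family: G and C each get weight
#' `theta/2`, A and T each `(1 - theta)/2` (first/second positions are
#' uniform over bases and cancel within a family). Under this model codon
#' usage is driven purely by third-position G+C pressure -- the null that
#' the GC3s-expected ENc curve describes. For a two-fold T/C-ending family
#' the expected RSCU of the C-ending codon is `2 * theta`.
#'
#' @param theta Third-position G+C probability in \[0, 1\].
#' @return A `cds_model` object.
#' @export
model_mutation_only <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) == 1L, theta >= 0, theta <= 1)
  structure(list(type = "mutation_only", theta = theta), class = "cds_model")
}

#' Weighted codon-choice model
#'
#' Codons are chosen within each family proportionally to explicit
#' per-codon weights (unlisted codons default to weight 1).
#'
#' @param weights Named non-negative numeric vector over sense codons.
#' @return A `cds_model` object.
#' @export
model_weighted <- function(weights) {
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  if (any(weights < 0) || anyNA(weights)) stop("weights must be non-negative")
  bad <- setdiff(names(weights), .SENSE)
  if (length(bad)) stop("not sense codons: ", paste(bad, collapse = ", "))
  structure(list(type = "weighted", weights = weights), class = "cds_model")
}

#' Linear 5'-to-3' GC3 gradient model
#'
#' Like [model_mutation_only()], but the third-position G+C probability
#' varies linearly with relative codon position along each gene, from
#' `theta_start` at the 5' end to `theta_end` at the 3' end.
#'
#' @param theta_start,theta_end Third-position G+C probabilities in
#'   \[0, 1\].
#' @return A `cds_model` object.
#' @export
model_gradient <- function(theta_start, theta_end) {
  stopifnot(theta_start >= 0, theta_start <= 1, theta_end >= 0, theta_end <= 1)
  structure(list(type = "gradient", theta_start = theta_start,
                 theta_end = theta_end), class = "cds_model")
}

#' GC12-GC3 coupled model
#'
#' Each gene draws a third-position G+C target `theta_g` uniformly from
#' `theta_range`, then a first/second-position G+C target
#' `g12_g = intercept + slope * (theta_g - gc3_center) + N(0, sigma)`.
#' Codons are sampled from the 61 sense codons with product-form weights
#' `q1(b1) * q2(b2) * q3(b3)` where positions 1-2 use `g12_g` and position
#' 3 uses `theta_g` (G and C split each target equally). Amino-acid
#' composition is emergent in this model; `aa_weights` is ignored. The
#' per-gene targets are attached to the generated records as attribute
#' `params`.
#'
#' @param slope Coupling slope between GC12 and GC3 targets.
#' @param intercept GC12 target at `theta_g = gc3_center` (default 0.45).
#' @param gc3_center Centering constant for the coupling (default 0.42).
#' @param sigma Gaussian noise s.d. on the GC12 target (default 0.01).
#' @param theta_range Range of per-gene GC3 targets
#'   (default `c(0.20, 0.70)`).
#' @return A `cds_model` object.
#' @export
model_coupled <- function(slope, intercept = 0.45, gc3_center = 0.42,
                          sigma = 0.01, theta_range = c(0.20, 0.70)) {
  stopifnot(length(theta_range) == 2L, theta_range[1] >= 0, theta_range[2] <= 1,
            theta_range[1] < theta_range[2], sigma >= 0)
  structure(list(type = "coupled", slope = slope, intercept = intercept,
                 gc3_center = gc3_center, sigma = sigma,
                 theta_range = theta_range), class = "cds_model")
}

#' Specification of a synthetic CDS set
#'
#' @param n_genes Number of genes (>= 1).
#' @param model A `cds_model` (see [model_mutation_only()],
#'   [model_weighted()], [model_gradient()], [model_coupled()]).
#' @param length_range Integer pair: min/max sense codons per gene
#'   (inclusive, start codon included). The minimum must be at least 101
#'   so every gene exceeds the 300-bp filter and fills a 100-bin
#'   positional gradient.
#' @param aa_weights Optional named weights over the 20 amino acids
#'   (default uniform); ignored by the coupled model.
#' @param cg_suppression Multiplier in (0, 1\] applied to the weights of
#'   the four NCG codons before normalization; values below 1 emulate CpG
#'   avoidance at codon positions 2-3.
#' @param stop_weights Optional weights over TAA, TAG, TGA for the
#'   terminal stop (default uniform).
#' @param seed Integer RNG seed; identical specs generate byte-identical
#'   output.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_genes, model, length_range = c(101L, 600L),
                           aa_weights = NULL, cg_suppression = 1,
                           stop_weights = NULL, seed = 1L) {
  stopifnot(inherits(model, "cds_model"),
            is.numeric(n_genes), length(n_genes) == 1L, n_genes >= 1,
            length(length_range) == 2L, length_range[1] >= 101,
            length_range[1] <= length_range[2],
            cg_suppression > 0, cg_suppression <= 1)
  if (!is.null(aa_weights)) {
    stopifnot(!is.null(names(aa_weights)), all(names(aa_weights) %in% AA20),
              all(aa_weights >= 0))
    if (sum(aa_weights) <= 0) stop("infeasible spec: amino-acid weights are all zero")
  }
  if (!is.null(stop_weights)) {
    stopifnot(length(stop_weights) == 3L, all(stop_weights >= 0), sum(stop_weights) > 0)
  }
  structure(
    list(n_genes = as.integer(n_genes), model = model,
         length_range = as.integer(length_range), aa_weights = aa_weights,
         cg_suppression = cg_suppression, stop_weights = stop_weights,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# full amino-acid weight vector over AA20 (uniform default)
.aa_weight_vec <- function(aa_weights) {
  w <- setNames(rep(1, length(AA20)), AA20)
  if (!is.null(aa_weights)) {
    w[] <- 0
    w[names(aa_weights)] <- aa_weights
  }
  w
}

# within-family third-position weights at a constant theta, times the CpG
# multiplier; returns weights over the 61 sense codons (unnormalized)
.third_pos_weights <- function(theta, cg_suppression) {
  w <- ifelse(.SENSE_GC3, theta / 2, (1 - theta) / 2)
  w[.SENSE_NCG] <- w[.SENSE_NCG] * cg_suppression
  w
}

# normalize per-codon weights into overall sense-codon probabilities given
# amino-acid weights; errors if a needed family has zero total weight
.codon_probs <- function(w_codon, aa_w) {
  fam_tot <- tapply(w_codon, .SENSE_AA, sum)[.SENSE_AA]
  need <- aa_w[.SENSE_AA] > 0
  if (any(need & fam_tot == 0)) {
    bad <- unique(.SENSE_AA[need & fam_tot == 0])
    stop("infeasible spec: zero total codon weight for family ",
         paste(bad, collapse = ", "))
  }
  p <- ifelse(fam_tot > 0, (aa_w[.SENSE_AA] / sum(aa_w)) * w_codon / fam_tot, 0)
  unname(p)
}

# inverse-CDF codon sampling where within-family weights vary per position
# (linear in theta); aa_idx and theta have one entry per position
.sample_codons_theta <- function(aa, theta, cg_suppression) {
  out <- character(length(aa))
  for (a in unique(aa)) {
    idx <- which(aa == a)
    fam <- which(.SENSE_AA == a)
    k <- length(fam)
    if (k == 1L) {
      out[idx] <- .SENSE[fam]
      next
    }
    gc3 <- .SENSE_GC3[fam]
    mult <- ifelse(.SENSE_NCG[fam], cg_suppression, 1)
    th <- theta[idx]
    W <- matrix(0, nrow = length(idx), ncol = k)
    for (j in seq_len(k)) {
      W[, j] <- (if (gc3[j]) th / 2 else (1 - th) / 2) * mult[j]
    }
    P <- W / rowSums(W)
    cum <- P
    for (j in 2:k) cum[, j] <- cum[, j - 1] + P[, j]
    u <- stats::runif(length(idx))
    sel <- rep(1L, length(idx))
    for (j in seq_len(k - 1L)) sel <- sel + (u > cum[, j])
    out[idx] <- .SENSE[fam][sel]
  }
  out
}

#' Generate a synthetic CDS set
#'
#' Every record is `ATG` + (L - 1) model-sampled sense codons + one stop
#' codon, where `L` is drawn uniformly from the spec's codon length range;
#' records therefore always pass [filter_cds()]. Identical specs (same
#' seed) produce byte-identical output.
#'
#' @param spec A `synthetic_spec`.
#' @return Named character vector of CDS sequences (`gene00001`, ...).
#'   For the coupled model the per-gene targets are attached as attribute
#'   `params` (data frame with `theta` and `gc12_target`).
#' @export
generate_cds <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  model <- spec$model
  n <- spec$n_genes
  span <- spec$length_range[2] - spec$length_range[1] + 1L
  L <- spec$length_range[1] - 1L + sample.int(span, n, replace = TRUE)
  body_len <- L - 1L
  gene_of <- factor(rep.int(seq_len(n), body_len), levels = seq_len(n))
  total <- sum(body_len)
  aa_w <- .aa_weight_vec(spec$aa_weights)
  params <- NULL

  if (model$type %in% c("mutation_only", "weighted")) {
    w_codon <- if (model$type == "mutation_only") {
      .third_pos_weights(model$theta, spec$cg_suppression)
    } else {
      w <- setNames(rep(1, length(.SENSE)), .SENSE)
      w[names(model$weights)] <- model$weights
      w[.SENSE_NCG] <- w[.SENSE_NCG] * spec$cg_suppression
      unname(w)
    }
    p <- .codon_probs(w_codon, aa_w)
    codons <- sample(.SENSE, total, replace = TRUE, prob = p)
  } else if (model$type == "gradient") {
    pos <- sequence(body_len)
    denom <- rep.int(pmax(body_len - 1L, 1L), body_len)
    t_rel <- (pos - 1L) / denom
    theta <- model$theta_start + (model$theta_end - model$theta_start) * t_rel
    aa <- sample(AA20, total, replace = TRUE, prob = aa_w / sum(aa_w))
    codons <- .sample_codons_theta(aa, theta, spec$cg_suppression)
  } else if (model$type == "coupled") {
    theta_g <- stats::runif(n, model$theta_range[1], model$theta_range[2])
    g12_g <- model$intercept + model$slope * (theta_g - model$gc3_center) +
      stats::rnorm(n, 0, model$sigma)
    g12_g <- pmin(pmax(g12_g, 0.02), 0.98)
    codons_by_gene <- vector("list", n)
    for (g in seq_len(n)) {
      q1 <- ifelse(.SENSE_GC1, g12_g[g] / 2, (1 - g12_g[g]) / 2)
      q2 <- ifelse(.SENSE_GC2, g12_g[g] / 2, (1 - g12_g[g]) / 2)
      q3 <- ifelse(.SENSE_GC3, theta_g[g] / 2, (1 - theta_g[g]) / 2)
      w <- q1 * q2 * q3
      w[.SENSE_NCG] <- w[.SENSE_NCG] * spec$cg_suppression
      codons_by_gene[[g]] <- sample(.SENSE, body_len[g], replace = TRUE, prob = w)
    }
    codons <- unlist(codons_by_gene, use.names = FALSE)
    params <- data.frame(theta = theta_g, gc12_target = g12_g)
  } else {
    stop("unknown model type: ", model$type)
  }

  stops <- sample(STOP_CODONS, n, replace = TRUE,
                  prob = spec$stop_weights)
  bodies <- vapply(split(codons, gene_of), paste, character(1), collapse = "")
  seqs <- paste0("ATG", bodies, stops)
  names(seqs) <- sprintf("gene%05d", seq_len(n))
  if (!is.null(params)) attr(seqs, "params") <- params
  seqs
}

# deterministic per-label seed derived from (seed, label)
.salt_seed <- function(seed, label) {
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 2147483647
  ((seed %% 2147483647) * 48271 + h) %% 2147483647
}

#' Generate a labeled panel of synthetic species
#'
#' Each label gets an independent RNG stream derived from its spec's seed
#' and the label itself, so panels are reproducible and removing one label
#' leaves the others' output unchanged.
#'
#' @param specs Named list of `synthetic_spec` objects; labels must be
#'   unique and non-empty.
#' @return Named list of CDS record vectors (one per label).
#' @export
generate_panel <- function(specs) {
  stopifnot(is.list(specs), length(specs) >= 1L)
  labels <- names(specs)
  if (is.null(labels) || any(labels == "")) stop("all specs must be labeled")
  if (anyDuplicated(labels)) {
    stop("duplicate species label: ", labels[duplicated(labels)][1])
  }
  out <- lapply(labels, function(lab) {
    sp <- specs[[lab]]
    stopifnot(inherits(sp, "synthetic_spec"))
    sp$seed <- .salt_seed(sp$seed, lab)
    generate_cds(sp)
  })
  names(out) <- labels
  out
}
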