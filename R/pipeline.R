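# End-to-end orchestration: filter / profile / simulate over a panel of
# species FASTA files, writing one TSV per module interface plus
# cross-species outputs and a run manifest. All outputs are deterministic
# for fixed inputs; progress goes to messages (stderr).

.ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  invisible(path)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter a panel of species CDS FASTA files
#'
#' Reads each species' FASTA (plain or .gz), applies [filter_cds()], and
#' writes `<label>.filtered.fasta` plus `<label>.filter_report.tsv` into
#' `out_dir`.
#'
#' @param species Named character vector: labels -> FASTA paths.
#' @param out_dir Output directory (created if needed).
#' @param min_len Minimum CDS length in nucleotides (default 300; strictly
#'   longer sequences are kept).
#' @return Named list of `filter_report`s, invisibly.
#' @export
run_filter <- function(species, out_dir, min_len = 300L) {
  stopifnot(is.character(species), length(species) >= 1L,
            !is.null(names(species)), all(names(species) != ""))
  missing <- !file.exists(species)
  if (any(missing)) {
    stop("missing input file for species '", names(species)[missing][1],
         "': ", species[missing][1])
  }
  .ensure_dir(out_dir)
  reports <- lapply(names(species), function(lab) {
    recs <- read_cds_fasta(species[[lab]])
    res <- filter_cds(recs, min_len = min_len)
    if (length(res$kept) > 0L) {
      write_cds_fasta(res$kept, file.path(out_dir, paste0(lab, ".filtered.fasta")))
    }
    write_filter_report(res$report, file.path(out_dir, paste0(lab, ".filter_report.tsv")))
    message("[filter] ", lab, ": kept ", res$report$kept, "/", res$report$total)
    res$report
  })
  names(reports) <- names(species)
  invisible(reports)
}

# all per-species analyses for one filtered record set; writes TSVs under
# dir and returns the pieces needed for cross-species work
.profile_species <- function(lab, records, dir, code, gradient_mode, n_bins,
                             rscu_cutoff, freq_cutoff) {
  .ensure_dir(dir)
  comp <- composition_table(records, code)
  .write_tsv(comp, file.path(dir, "composition.tsv"))

  pooled <- pool_counts(lapply(unname(records), count_codons),
                        scope = paste0("pooled:", lab))
  rt <- rscu(pooled, code)
  write_rscu_table(rt, file.path(dir, "rscu.tsv"), rscu_cutoff, freq_cutoff)

  et <- enc_table(records, code)
  .write_tsv(et$genes, file.path(dir, "enc.tsv"))
  hist_df <- data.frame(et$histogram,
                        check.names = FALSE)
  hist_df$out_of_range_percent <- attr(et$histogram, "out_of_range_percent")
  .write_tsv(hist_df, file.path(dir, "enc_histogram.tsv"))

  fit <- neutrality_fit((comp$gc1 + comp$gc2) / 2, comp$gc3)

  pairs <- codon_pair_counts(records, code)
  .write_tsv(junction_table(pairs), file.path(dir, "junction.tsv"))
  rp <- rscpu(pairs, code)
  hf <- high_frequency_pairs(rp, rscu_cutoff, freq_cutoff)
  rp$is_high_frequency <- paste(rp$codon1, rp$codon2) %in% paste(hf$codon1, hf$codon2)
  .write_tsv(rp, file.path(dir, "rscpu.tsv"))

  grad <- tryCatch(
    gc3_gradient(records, n_bins = n_bins, mode = gradient_mode, species = lab),
    error = function(e) {
      message("[profile] ", lab, ": gradient skipped (", conditionMessage(e), ")")
      NULL
    }
  )
  if (!is.null(grad)) {
    .write_tsv(data.frame(bin = seq_len(grad$n_bins), mean_gc3 = grad$bins),
               file.path(dir, "gradient.tsv"))
  }
  list(rscu = rt, gradient = grad, fit = fit)
}

#' Run the full codon-usage profile over a panel of species
#'
#' For each species: reads and filters the FASTA, then writes per-species
#' TSVs (composition, RSCU, ENc + deviation histogram, junction table,
#' RSCPU, GC3 gradient) under `out_dir/<label>/`. With two or more
#' species it also writes cross-species outputs under `out_dir`: the
#' neutrality-regression table, the GC3-gradient Euclidean distance
#' matrix, the species x 59-codon RSCU matrix, and row/column dendrograms
#' (Newick + merge lists) from Euclidean/complete-linkage biclustering,
#' plus a YAML run manifest.
#'
#' @param species Named character vector: labels -> FASTA paths.
#' @param out_dir Output directory.
#' @param min_len Filter threshold in nucleotides (default 300).
#' @param gradient_mode `"positional"` or `"ranked"`.
#' @param n_bins Gradient bins (default 100).
#' @param rscu_cutoff,freq_cutoff High-frequency thresholds (1.5 / 0.60).
#' @param linkage Clustering linkage (default `"complete"`).
#' @return Invisibly, a list with per-species results (`species`) and the
#'   cross-species objects (`distances`, `rscu_matrix`, `clustering`),
#'   the latter `NULL` for a single-species run.
#' @export
run_profile <- function(species, out_dir, min_len = 300L,
                        gradient_mode = c("positional", "ranked"),
                        n_bins = 100L, rscu_cutoff = 1.5, freq_cutoff = 0.60,
                        linkage = "complete") {
  gradient_mode <- match.arg(gradient_mode)
  stopifnot(is.character(species), length(species) >= 1L,
            !is.null(names(species)), all(names(species) != ""))
  if (anyDuplicated(names(species))) stop("species labels must be unique")
  .ensure_dir(out_dir)
  code <- standard_genetic_code()

  per_species <- lapply(names(species), function(lab) {
    recs <- read_cds_fasta(species[[lab]])
    res <- filter_cds(recs, min_len = min_len)
    if (length(res$kept) == 0L) stop("profile stage: no records pass filtering for '", lab, "'")
    message("[profile] ", lab, ": ", length(res$kept), " genes")
    .profile_species(lab, res$kept, file.path(out_dir, lab), code,
                     gradient_mode, n_bins, rscu_cutoff, freq_cutoff)
  })
  names(per_species) <- names(species)

  fits <- data.frame(
    species = names(species),
    slope = vapply(per_species, function(x) x$fit$slope, numeric(1)),
    intercept = vapply(per_species, function(x) x$fit$intercept, numeric(1)),
    r2 = vapply(per_species, function(x) x$fit$r2, numeric(1)),
    p_value = vapply(per_species, function(x) x$fit$p_value, numeric(1)),
    n_genes = vapply(per_species, function(x) x$fit$n_genes, numeric(1))
  )
  .write_tsv(fits, file.path(out_dir, "neutrality.tsv"))

  distances <- rscu_matrix <- clustering <- NULL
  if (length(species) >= 2L) {
    grads <- lapply(per_species, `[[`, "gradient")
    grads <- grads[!vapply(grads, is.null, logical(1))]
    if (length(grads) >= 2L) {
      distances <- gradient_distance_matrix(grads)
      dm <- data.frame(species = rownames(distances), distances, check.names = FALSE)
      .write_tsv(dm, file.path(out_dir, "gradient_distance.tsv"))
    }
    rscu_matrix <- build_rscu_matrix(lapply(per_species, `[[`, "rscu"))
    .write_tsv(data.frame(species = rownames(rscu_matrix), rscu_matrix,
                          check.names = FALSE),
               file.path(out_dir, "rscu_matrix.tsv"))
    clustering <- bicluster(rscu_matrix, linkage = linkage)
    write_dendrogram_newick(clustering$row_dendrogram,
                            file.path(out_dir, "species_dendrogram.nwk"))
    write_dendrogram_newick(clustering$col_dendrogram,
                            file.path(out_dir, "codon_dendrogram.nwk"))
    write_merge_list(clustering$row_dendrogram,
                     file.path(out_dir, "species_merges.tsv"))
  } else {
    message("[profile] single species: cross-species outputs skipped")
  }

  manifest <- list(
    tool = "cubkit", version = as.character(utils::packageVersion("cubkit")),
    species = as.list(species), min_len = min_len,
    gradient_mode = gradient_mode, n_bins = n_bins,
    rscu_cutoff = rscu_cutoff, freq_cutoff = freq_cutoff, linkage = linkage
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(species = per_species, neutrality = fits,
                 distances = distances, rscu_matrix = rscu_matrix,
                 clustering = clustering))
}

#' Generate a synthetic species panel on disk
#'
#' Writes one FASTA and one YAML metadata sidecar (the spec fields plus the
#' effective seed) per label.
#'
#' @param specs Named list of `synthetic_spec` objects.
#' @param out_dir Output directory.
#' @param seed Optional integer overriding every spec's base seed (each
#'   label still gets its own salted stream).
#' @return Named character vector of FASTA paths, invisibly.
#' @export
run_simulate <- function(specs, out_dir, seed = NULL) {
  stopifnot(is.list(specs), length(specs) >= 1L)
  if (!is.null(seed)) {
    specs <- lapply(specs, function(sp) {
      sp$seed <- as.integer(seed)
      sp
    })
  }
  .ensure_dir(out_dir)
  panel <- generate_panel(specs)
  paths <- vapply(names(panel), function(lab) {
    p <- file.path(out_dir, paste0(lab, ".fasta"))
    write_cds_fasta(panel[[lab]], p)
    sp <- specs[[lab]]
    meta <- list(
      label = lab, n_genes = sp$n_genes, model = unclass(sp$model),
      length_range = sp$length_range, cg_suppression = sp$cg_suppression,
      base_seed = sp$seed, effective_seed = .salt_seed(sp$seed, lab)
    )
    yaml::write_yaml(meta, file.path(out_dir, paste0(lab, ".meta.yaml")))
    message("[simulate] ", lab, ": ", sp$n_genes, " genes -> ", p)
    p
  }, character(1))
  invisible(paths)
}
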