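# CDS FASTA input/output and quality filtering.

FILTER_REASONS <- c("not_triplet", "too_short", "ambiguous_base",
                    "bad_start", "bad_stop", "internal_stop")

#' Read a (possibly gzip-compressed) multi-FASTA CDS file
#'
#' Sequences are uppercased; entry order is preserved. Any single-letter
#' alphabet is accepted at this stage -- classification of ambiguity codes
#' happens in [filter_cds()].
#'
#' @param path Path to a FASTA or FASTA.gz file.
#' @return Named character vector: names are the FASTA headers, values the
#'   uppercased sequences. Zero-length (with a warning) for an empty file.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read FASTA file: '", path, "' does not exist")
  }
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) {
    warning("FASTA file '", path, "' contains no sequences")
    return(setNames(character(0), character(0)))
  }
  setNames(toupper(as.character(x)), names(x))
}

#' Write CDS records to a FASTA file
#'
#' Round-trip safe: `read_cds_fasta(write_cds_fasta(x, f))` reproduces ids
#' and sequences exactly.
#'
#' @param records Named character vector of sequences (ids as names).
#' @param path Output path.
#' @param width Line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(records, path, width = 80L) {
  if (length(records) == 0L) {
    stop("refusing to write an empty record set")
  }
  if (is.null(names(records)) || anyNA(names(records)) || any(names(records) == "")) {
    stop("all records must be named")
  }
  x <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

# in-frame codons of one sequence (length must be a multiple of 3)
.codon_strings <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq.int(1L, n - 2L, by = 3L), seq.int(3L, n, by = 3L))
}

#' Filter coding sequences on structural quality rules
#'
#' Keeps sequences that are in-frame (length divisible by 3), longer than
#' `min_len` nucleotides, composed only of A/C/G/T, start with ATG, end with
#' a stop codon (TAA/TAG/TGA) and contain no internal in-frame stop codon.
#' Each rejected record is attributed to its *first* failing rule in the
#' fixed order: `not_triplet`, `too_short`, `ambiguous_base`, `bad_start`,
#' `bad_stop`, `internal_stop`.
#'
#' The terminal stop codon is retained in kept records; downstream sense
#' statistics exclude it.
#'
#' @param records Named character vector from [read_cds_fasta()].
#' @param min_len Minimum length in nucleotides; records of length
#'   `<= min_len` are rejected (`too_short`). Default 300, so only
#'   sequences strictly longer than 300 bp are kept.
#' @return List with `kept` (named character vector of passing records) and
#'   `report`, a `filter_report`: list with `counts` (named integer per
#'   rejection reason), `kept` and `total`.
#' @export
filter_cds <- function(records, min_len = 300L) {
  n <- length(records)
  len <- nchar(records)
  not_triplet <- len %% 3L != 0L | len == 0L
  too_short <- len <= min_len
  ambiguous <- grepl("[^ACGT]", records)
  bad_start <- substr(records, 1L, 3L) != "ATG"
  bad_stop <- !(substr(records, len - 2L, len) %in% STOP_CODONS)
  internal_stop <- logical(n)
  candidate <- !(not_triplet | too_short | ambiguous | bad_start | bad_stop)
  for (i in which(candidate)) {
    cods <- .codon_strings(records[[i]])
    internal_stop[i] <- any(cods[-length(cods)] %in% STOP_CODONS)
  }
  fails <- cbind(not_triplet, too_short, ambiguous_base = ambiguous,
                 bad_start, bad_stop, internal_stop)
  colnames(fails) <- FILTER_REASONS
  first_fail <- apply(fails, 1L, function(f) {
    w <- which(f)
    if (length(w)) w[1L] else NA_integer_
  })
  if (n == 0L) first_fail <- integer(0)
  rejected <- !is.na(first_fail)
  counts <- vapply(seq_along(FILTER_REASONS),
                   function(k) sum(first_fail == k, na.rm = TRUE), integer(1))
  names(counts) <- FILTER_REASONS
  report <- structure(
    list(counts = counts, kept = sum(!rejected), total = n),
    class = "filter_report"
  )
  list(kept = records[!rejected], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("CDS filter report: kept", x$kept, "of", x$total, "records\n")
  for (r in names(x$counts)) {
    if (x$counts[[r]] > 0) cat("  rejected (", r, "): ", x$counts[[r]], "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a filter report as TSV
#'
#' Writes one row per rejection reason plus a `kept` row; columns `reason`
#' and `count`.
#'
#' @param report A `filter_report` from [filter_cds()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  df <- data.frame(
    reason = c(names(report$counts), "kept"),
    count = c(unname(report$counts), report$kept)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
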