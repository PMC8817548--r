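# Standard nuclear genetic code: codon <-> amino-acid tables, synonymous
# families and degeneracy classes consulted by every other module.
# Codons use the DNA alphabet (T, not U), uppercase.

BASES <- c("A", "C", "G", "T")

#' The 64 codons in lexicographic order
#'
#' @format Character vector of the 64 trinucleotides over \{A,C,G,T\},
#'   sorted lexicographically.
#' @keywords internal
CODONS <- sort(as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0)))

#' The three stop codons of the standard code
#' @keywords internal
STOP_CODONS <- c("TAA", "TAG", "TGA")

# per-codon base identities / G+C indicators, in CODONS order
.codon_base <- function(pos) substr(CODONS, pos, pos)
.GC1 <- .codon_base(1) %in% c("G", "C")
.GC2 <- .codon_base(2) %in% c("G", "C")
.GC3 <- .codon_base(3) %in% c("G", "C")

.gc_cache <- new.env(parent = emptyenv())

#' Standard genetic code table
#'
#' Builds (once, then caches) the standard nuclear genetic code: the
#' codon-to-amino-acid map, the synonymous codon families, per-family sizes
#' and the degeneracy classes (amino acids grouped by the number of
#' synonymous codons encoding them). Stop codons are represented by the
#' amino-acid symbol `"*"` and form their own 3-member family.
#'
#' @return An object of class `genetic_code`: a list with elements
#'   `codon_to_aa` (named character, 64 codons -> one-letter amino acid or
#'   `"*"`), `families` (list amino acid -> sorted codon vector),
#'   `family_size` (named integer per amino acid), and `degeneracy_classes`
#'   (list, names `"1"`, `"2"`, `"3"`, `"4"`, `"6"`, each a vector of amino
#'   acids with that many synonymous codons; stops excluded).
#' @examples
#' code <- standard_genetic_code()
#' code$codon_to_aa[["ATG"]]        # "M"
#' code$families[["R"]]             # the six arginine codons
#' @export
standard_genetic_code <- function() {
  if (!is.null(.gc_cache$code)) {
    return(.gc_cache$code)
  }
  codon_to_aa <- Biostrings::GENETIC_CODE[CODONS]
  names(codon_to_aa) <- CODONS
  families <- split(CODONS, codon_to_aa)
  families <- lapply(families, sort)
  family_size <- vapply(families, length, integer(1))
  aas <- setdiff(names(families), "*")
  degeneracy_classes <- split(aas, family_size[aas])
  code <- structure(
    list(
      codon_to_aa = codon_to_aa,
      families = families,
      family_size = family_size,
      degeneracy_classes = degeneracy_classes
    ),
    class = "genetic_code"
  )
  .gc_cache$code <- code
  code
}

#' Synonymous family of a codon
#'
#' @param codon A single trinucleotide over \{A,C,G,T\} (case-insensitive).
#' @param code A `genetic_code`, by default the standard code.
#' @return List with `amino_acid` (one-letter symbol, `"*"` for stop),
#'   `codons` (the synonymous family containing `codon`) and `size`
#'   (family size).
#' @examples
#' codon_family("AGA")$size  # 6
#' @export
codon_family <- function(codon, code = standard_genetic_code()) {
  stopifnot(is.character(codon), length(codon) == 1L)
  codon <- toupper(codon)
  if (!codon %in% CODONS) {
    stop("invalid codon: '", codon, "' is not one of the 64 trinucleotides over {A,C,G,T}")
  }
  aa <- code$codon_to_aa[[codon]]
  list(amino_acid = aa, codons = code$families[[aa]], size = code$family_size[[aa]])
}

# sense codons = the 61 codons coding amino acids, in CODONS order
.sense_codons <- function(code = standard_genetic_code()) {
  setdiff(CODONS, STOP_CODONS)
}

# the 59 codons used in cross-species RSCU comparison: sense minus the
# single-codon families Met (ATG) and Trp (TGG)
.codons59 <- function() {
  setdiff(.sense_codons(), c("ATG", "TGG"))
}
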