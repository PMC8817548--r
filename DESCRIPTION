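Package: cubkit
Title: Codon Usage Bias Analysis for Coding Sequence Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative codon usage bias (CUB) analysis of
    protein-coding sequence (CDS) collections: quality filtering of CDS
    FASTA files, nucleotide composition indices (GC, GC1-GC3, GC3s),
    relative synonymous codon usage (RSCU) and high-frequency codon
    identification, Wright's effective number of codons (ENc) with the
    GC3s-expected curve and deviation statistics, GC12-GC3 neutrality
    regression, codon-pair statistics (junction dinucleotides, RSCPU),
    5'-to-3' GC3 gradients with inter-species Euclidean distances, and
    Euclidean/complete-linkage biclustering of species-by-codon RSCU
    matrices. Includes a seeded generator of synthetic CDS sets with
    controlled codon-usage structure so every analysis stage can be
    exercised without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    graphics,
    grDevices,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
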