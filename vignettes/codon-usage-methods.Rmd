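---
title: "Codon usage bias analysis with cubkit: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias analysis with cubkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubkit)
```

# The problem

Twenty amino acids are encoded by 61 sense codons, so most amino acids
admit a synonymous choice. Genomes do not make that choice uniformly:
directional mutation pressure (visible mainly as G+C content at the
silent third codon position) and natural selection (translational
efficiency, mRNA stability, CpG avoidance) both bias codon usage.
Comparative studies profile these biases per species and then compare the
profiles across a clade. `cubkit` implements that pipeline for CDS FASTA
collections: filtering, composition indices, RSCU, ENc, the neutrality
regression, codon-pair statistics, 5′→3′ GC3 gradients, and cross-species
clustering, plus a synthetic-CDS generator that makes each stage testable
without downloading genomes.

# Filtering

A sequence is kept when it is a positive multiple of 3 in length,
strictly longer than 300 bp, contains only A/C/G/T, starts with ATG, ends
with TAA/TAG/TGA, and has no in-frame internal stop codon. Two details
are deliberate:

* *Strictly longer than 300 bp.* The rule removes sequences of "no more
  than 300 bp", so a 300-bp CDS is rejected and a 303-bp one kept.
* *Triplet length as its own rule.* Codon statistics are undefined for
  out-of-frame sequences, so non-triplet length is a separate rejection
  reason (`not_triplet`), evaluated first, rather than being folded into
  another rule. Rules are evaluated in the fixed order `not_triplet`,
  `too_short`, `ambiguous_base`, `bad_start`, `bad_stop`,
  `internal_stop`, and each rejected record is counted once, under its
  first failing rule, so report counts always sum to the input size.

Any character outside A/C/G/T counts as ambiguous; no IUPAC whitelist is
applied. The terminal stop codon is kept in the stored sequence — it is
needed for stop-codon RSCU — but every sense-codon statistic excludes it.

# Composition indices

GC1/GC2/GC3 are percentages of G+C at codon positions 1/2/3 over all
sense codons (ATG and TGG included, stop excluded), so
`gc = (gc1 + gc2 + gc3) / 3` holds exactly over the same codon set. GC3s
further restricts position 3 to codons of amino acids with at least two
synonymous codons, i.e. it drops ATG and TGG but keeps 3-fold isoleucine
— the codonW convention, chosen so that per-gene GC3s feeds the expected
ENc curve on the same footing as the classical tooling.

# RSCU and high-frequency codons

For codon *j* of a family with *n~i~* members and family total *T~i~*,
`RSCU = n_i * x_ij / T_i`. Families never observed yield `NA`, not 0 —
a zero would mimic extreme bias where there is simply no data. Species
scope is always *pooled counts* over all filtered genes, not a mean of
per-gene RSCU values: genome-wide RSCU is the field's standard and
guarantees every family is observed, which the 59-codon comparison matrix
requires.

High-frequency codons use strict inequalities — RSCU > 1.5 *or*
within-family relative frequency > 0.60 — reflecting the usual "over
1.5 / above 60%" phrasing; exact ties are excluded. Single-codon families
(Met, Trp) and stops are never called.

The XCG/XCC ratio is computed as the ratio of summed RSCU values,
`Σ RSCU(XCG) / Σ RSCU(XCC)` over X ∈ {A,C,G,T}. A mean of per-X ratios
was considered and rejected: the summed form is simpler, never divides by
a single near-zero family member, and both agree at 1 under no bias.

# ENc: observed, expected, deviation

Observed ENc follows Wright's estimator. Per family with total count
n ≥ 2, the codon homozygosity is `F̂ = (n Σ p_j² − 1) / (n − 1)`;
F̂ is averaged within each degeneracy class (2-, 3-, 4-, 6-fold) and

```
ENc = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆ ,  capped at 61.
```

Edge cases follow codonW's conventions, since that is the tool that
classical analyses delegate ENc to:

* a missing 3-fold class (isoleucine absent or counted once) is imputed
  as `F̄₃ = (F̄₂ + F̄₄)/2`;
* any other missing class, or a class average of zero, makes the gene's
  ENc undefined; the gene is excluded and tallied by reason rather than
  raising an error;
* families with a single counted codon contribute no F̂ (the estimator
  divides by n − 1);
* the cap at 61 encodes the saturation semantics: 20 means one codon per
  amino acid, 61 means all synonymous codons equally used.

The expected value under third-position mutation pressure alone is the
closed curve `ENc_exp = 2 + F + 29/(F² + (1 − F)²)` with F the gene's
GC3s fraction, and the per-gene deviation is
`(ENc_exp − ENc_obs)/ENc_exp`. Deviations are binned into seven
half-open intervals `[−0.2, −0.1), …, [0.4, 0.5)`; values outside are
counted as out-of-range so percentages always total 100. Half-open edges
avoid double counting, and the default edge vector is written as
`(-2:5)/10` so each edge is the exact double of the printed decimal —
with `seq(-0.2, 0.5, 0.1)` the accumulated floating-point error
misclassifies values lying exactly on an edge.

The neutrality analysis regresses per-gene GC12 = (GC1 + GC2)/2 on GC3 by
unweighted OLS (percent units, as the classical plots are drawn), with
Pearson's r and its two-sided t-test p-value on n − 2 df.

# Codon pairs

Pairs are *overlapping* adjacent sense codons, (c₁,c₂), (c₂,c₃), …, so a
gene with L sense codons contributes L − 1 pairs; pairs touching the
terminal stop are excluded. The junction table classifies each pair by
the dinucleotide spanning the boundary (third base of the first codon,
first base of the second — the XY of nnXYnn) into 16 percentages.

RSCPU lifts the RSCU formula to pairs. The synonymous family of a pair is
taken to be all pairs encoding the same *ordered dipeptide* (size
n~i~·n~j~), the standard reading; a narrower "same last amino acid only"
grouping is sometimes described in the literature but is ambiguous, so
the dipeptide semantics are used and recorded here. High-frequency pairs
use the same strict 1.5 / 60% rules; by default families with a single
possible pair (e.g. Met–Trp) are not callable — they offer no synonymous
choice, exactly as 1-fold families are excluded at codon level — and
`min_family_size = 1` restores the literal rule.

# GC3 gradients and cross-species comparison

The positional gradient splits each gene's sense codons 5′→3′ into 100
contiguous, equal-as-possible segments (segment b of a gene with L codons
covers codon indices ⌊bL/100⌋ … ⌊(b+1)L/100⌋ − 1) and pools third-position
G+C per segment across genes; genes with fewer than 100 sense codons are
skipped and counted. Because "genes divided into 100 groups" can also be
read as a sorted-quantile construction, a `ranked` mode (genes sorted by
gene-level GC3, split into 100 equal groups, group means reported) is
provided as well; `positional` is the default because the gradient is
described 5′→3′. Neither mode is asserted to be the one any particular
published figure used.

Species gradients are compared by plain Euclidean distance over the
100-bin fraction vectors. The cross-species RSCU matrix has exactly 59
columns — the 61 sense codons minus ATG and TGG, in fixed lexicographic
order — and is biclustered (rows and columns independently) with
Euclidean distance and complete linkage via `stats::hclust`. Rows are not
standardized: RSCU is already family-normalized. Dendrograms export to
Newick with merge heights as branch lengths.

# The synthetic-data generator

The generator emulates the statistical structure the analyses assume,
not real gene architecture. Every record is `ATG` + (L − 1) sampled sense
codons + a stop codon, with L uniform over a configurable range
(default 101–600 sense codons, roughly the span of typical plant CDS
lengths; the minimum of 101 guarantees both the >300 bp filter and a full
100-bin positional gradient). Four codon-choice models are provided:

* **mutation_only(θ)** — within each family, codons are weighted by a
  third-position base probability: G and C each θ/2, A and T each
  (1 − θ)/2 (first/second position factors are uniform and cancel within
  a family). This makes the expected-ENc null literally true up to
  family-structure effects, and for a two-fold T/C family the expected
  RSCU of the C-ending codon is exactly 2θ.
* **weighted(w)** — explicit per-codon weights within families.
* **gradient(θ_start, θ_end)** — θ varies linearly with relative codon
  position along each gene.
* **coupled(slope, intercept, σ)** — per gene, a GC3 target θ_g ~
  U(0.20, 0.70) and a GC12 target
  `intercept + slope · (θ_g − 0.42) + N(0, σ)`; codons are drawn from the
  61 sense codons with product-form position weights. Amino-acid
  composition is emergent here (the `aa_weights` option applies to the
  other models).

The default θ_g range U(0.20, 0.70) was fixed from sampling theory before
any end-to-end checks: per-gene realized GC3 carries binomial noise of
variance ≈ 0.25/L, which attenuates a regression slope by
var(θ)/(var(θ) + 0.25/E[L]); a narrow per-gene GC3 spread would attenuate
any target slope by more than 10% regardless of implementation, while
0.20–0.70 matches the across-gene GC3 spread of broad plant data and
keeps attenuation under ~5%.

Three family-structure effects are worth knowing when interpreting
recovery tests:

* ATG and TGG always end in G, and 3-fold isoleucine's G+C third-position
  share is θ/(2 − θ), so realized GC3 over *all* sense codons is offset
  from θ. Tests that recover θ numerically therefore restrict
  `aa_weights` to families with a free third position.
* Every valid CDS begins with a literal ATG, which contaminates the first
  positional-gradient bin; endpoint recovery is assessed on interior bins
  or a fitted linear trend.
* In the coupled model the three stop codons are excluded from the
  sampling alphabet, which perturbs realized compositions from their
  targets by a small, smooth amount; the recovered slope stays within the
  tolerances used in the tests.

`cg_suppression` multiplies the weights of the four NCG codons by a
factor in (0, 1], emulating CpG avoidance; values below 1 drive the
XCG/XCC ratio below 1 in expectation.

Determinism: `generate_cds` seeds R's RNG from the spec, so identical
specs give byte-identical FASTA output; `generate_panel` derives a
per-label seed from (seed, label) with a small string hash, so panels are
reproducible, label-order independent, and unchanged by removing other
labels.

What the generator does **not** emulate: amino-acid composition of real
proteomes (uniform by default), length distributions of real gene sets
beyond a uniform range, UTRs/introns/splicing, dinucleotide structure
beyond NCG weighting, and between-gene correlation of codon usage with
expression level. Passing recovery tests on this generator therefore
validates the *estimators*, not any biological claim about a particular
genome.

# Problem sizes used in the tests

The test-suite simulations use 100–500 genes of 101–400 codons for
distributional checks, 2000 genes for slope recovery, and a 7-species
panel of 30 genes each for clade-separation checks — sizes at which the
sampling-error bounds in the assertions hold comfortably while the whole
suite runs in seconds.

# Known limitations

* Only the standard nuclear genetic code is supported; organellar codes
  and partial/5′-truncated CDSs are out of scope (they are filtered out).
* ENc edge-case handling mirrors codonW's documented behaviour, but
  codonW's treatment of every rare degenerate input is not published;
  genes whose ENc is undefined here are excluded and tallied rather than
  approximated.
* The species-level numbers printed in published comparative studies
  depend on the exact genome builds they downloaded; this package
  reproduces the *methods* and validates them on synthetic data with
  known truth, not any specific species values.
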