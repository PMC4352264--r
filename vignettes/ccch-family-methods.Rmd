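---
title: "Methods behind ccchfam: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind ccchfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccchfam)
```

`ccchfam` characterizes a plant CCCH zinc-finger gene family end to end.
This vignette records the scientific model behind each stage, the tunable
parameters and why their defaults are what they are, what the synthetic-data
generators do and do not emulate, and the numerical decisions taken where
the procedure was genuinely open. Nothing here reports a result that the
test suite or the acceptance script does not itself compute.

## Coordinates and conventions

All sequence coordinates in this package are **1-based closed intervals**,
the R and Bioconductor convention. A motif hit spanning `start..end`
satisfies `end - start + 1 = i + j + k + 4`. An alternative design would
keep 0-based half-open coordinates internally; we chose a single convention
everywhere because a package whose values flow straight into tibbles and
reports gains nothing from an internal/external split, and mixed conventions
are the classic source of off-by-one defects.

## Motif scanning

The family-defining motif is `C-X(i)-C-X(j)-C-X(k)-H`. The scanner finds
anchor placements directly (no regular-expression engine), with spacer
ranges as parameters:

* `i` in 4..17 and `j` in 4..6 by default — the widest spacer ranges used in
  family surveys; the classical definition caps `i` at 15, so both bounds
  are exposed in `scan_params()`.
* `k = 3` by default; the rarer C-X3-4-H variant is reachable by a second
  scan with `k = 4`.

Because the definition is degenerate, matches can overlap. Two policies are
implemented, and which one a published count used is generally undecidable,
so both are first-class:

* `nonoverlapping_shortest_first` (default): scan left to right, at each
  position admit the match with smallest `i`, then smallest `j`, and resume
  after the matched histidine. This mirrors non-overlapping regex semantics
  and makes the count deterministic.
* `all_matches`: every `(start, i, j)` combination. The test suite proves
  this equal to a brute-force enumeration, and the non-overlapping output is
  always a subset of it.

Position profiles (sequence-logo statistics) require all instances to share
one `(i, j, k)` signature so they align without gaps. Column information
content is `log2(20) - H(column)` in bits, with no small-sample correction —
profile consumers in this package compare planted against recovered
distributions, where the correction would only obscure the comparison.

Molecular weight uses average residue masses plus one water; `X` contributes
the mean residue mass. The isoelectric point solves net charge = 0 by
bisection to `|charge| < 1e-4` over the termini and D/E/C/Y/H/K/R side
chains with the EMBOSS pKa table. Published web tools do not document their
exact table; any consistent table satisfies the defining zero-charge
property, which is what the tests assert.

## Phylogenetics

Distances are **p-distances** (proportion of differing sites), matching
standard practice for protein family trees where model-corrected distances
add parameters without changing clade structure. Gap handling is pairwise
deletion by default (complete deletion available); a pair with zero
comparable sites is an error naming the pair.

Tree building is the Saitou–Nei **neighbor-joining** agglomeration,
implemented in the package: join the pair minimizing
`Q(a,b) = (n-2) d(a,b) - R_a - R_b`, with the standard three-point branch
lengths. Two numerical decisions:

* **Ties** in `Q` are broken by smallest (row, column) index in the current
  matrix order, so results are bit-reproducible.
* **Negative branch lengths** are retained by default (`clamp_negative =
  FALSE`); they are part of the classical estimator, and clamping is a
  presentation choice, offered as a flag.

On additive matrices NJ provably recovers the generating tree; the suite
fuzzes this over 50 random trees and requires branch lengths to 1e-9.

Bootstrap supports resample alignment columns with replacement, rebuild the
tree, and count how often each reference internal bipartition recurs; 1000
replicates is the default, the conventional figure. The reference topology
never depends on the seed. **Clades** are called from edges with support
strictly above the threshold (default 50, i.e. "> 50"): each supported edge
contributes the *smaller* side of its bipartition (the natural unrooted
reading of a supported subtree), and only maximal candidates — those not
nested in another supported candidate — are reported; remaining taxa are
singletons. Clade identifiers are arbitrary but stable (ordered by size).

## Duplicate typing, Ka/Ks, and dating

Chromosome labels carry a number and a subgenome letter (`a`/`b`) of the
allotetraploid. A pair is:

* **tandem** — same chromosome label and fewer than five gene loci in
  between (`|ordinal difference| - 1 <= 4`, strict);
* **homeologous** — same chromosome number, different subgenome letter;
* **paralogous** — both locations known, anything else;
* **unknown** — either location unknown.

Ka/Ks is the **Nei–Gojobori (1986)** proportional method with
**Jukes–Cantor** correction — the default of the software generation that
produced most published family tables, which is why numeric parity with any
specific program is method-level, not implementation-level. Site counts
`S`, `N` are averaged over the two sequences (`S + N = 3 ×` codons); codon
pairs differing at 2–3 positions average fractional difference counts over
all substitution orderings, excluding pathways through stop codons and
renormalizing (counting stops as nonsynonymous is available as
`stop_policy = "nonsynonymous"`); codons containing gaps, ambiguity codes,
or stops are skipped pairwise. `p >= 3/4` raises a saturation error rather
than returning an undefined logarithm.

Selection calling follows the conventional rule: ratio > 1 diversifying,
< 1 purifying, = 1 neutral. When `Ks = 0` with `Ka > 0` the ratio is
undefined but every substitution is nonsynonymous, so the pair is called
diversifying with ratio `NA` — exactly how published tables annotate such
rows. Divergence time is `T = Ks / (2λ) × 10⁻⁶` Mya with λ = 6.5×10⁻⁹
synonymous substitutions per site per year (the grass rate); `Ks = 0` dates
as `NA` by default (the raw 0 is available), because zero silent divergence
carries no clock information.

The packaged selection table (19 duplicated PvC3H pairs) is a transcription
of published values used for parity checks. Recomputing its dates from the
printed 3-decimal Ks reproduces 14 of the 16 non-NA printed values at
one-decimal rounding; two rows (Ks 0.041 and 0.102) and one printed ratio
(0.444/0.282 = 1.574 vs printed 1.575) were evidently computed from
unrounded inputs, and the tests treat them accordingly (agreement to one
unit in the last printed digit).

## Promoter elements

Promoters are taken as the −2000..−1 region 5'→3' on the coding strand.
Scanning matches each IUPAC consensus on the sense strand and its reverse
complement on the antisense strand, reporting all overlapping matches in
sense-strand coordinates — the semantics of classical plant cis-element
databases. Ambiguity codes are degenerate only in the consensus: an `N` in
the promoter sequence never matches a non-`N` position, so masked bases
cannot create hits.

The default library covers the stress elements most often mapped in CCCH
promoter figures — ABRE (`ACGTG` core), DRE (`RCCGAC`), CBFHV (`RYCGAC`),
LTRE (`CCGAC`) — and is plain data, fully overridable from a TSV. These
consensi share the `CCGAC` core, so one genomic site can legitimately count
for several elements; per-element counts are therefore not disjoint, which
matters when comparing against a planting design (see below).

## Expression atlas

Published atlas heatmaps are described as "log2 fold change after value
normalization" without an operational definition. We take the simplest
transform with that reading: `log2(x + 1)` centered on each gene's mean, so
every value is a log2 fold change against the gene's average expression and
a constant gene is exactly zero. The pseudocount (default 1) handles zero
signals. Clustering is agglomerative with Euclidean distance and average
linkage by default (both configurable), via `stats::hclust` — checked in
the tests against a brute-force re-agglomeration.

Pair expression similarity is the Pearson correlation of two genes'
normalized profiles; "similar" means `r >= 0.8` by default. No operational
threshold exists in the literature for the published purifying-vs-
diversifying contrast, so the threshold is a parameter and the contrast is
reproduced qualitatively on synthetic data only (the planted high-`r` class
scores as similar far more often than the uncorrelated class).

## qRT-PCR

Relative expression is `2^(-ΔΔCt)`: the target Ct is normalized against the
arithmetic mean Ct of the reference genes (equivalently the geometric mean
of their expression — the standard multi-reference practice), and treated
conditions are compared to the 0 h control within the same treatment. The
amplification efficiency is fixed at 2 by default and is a parameter.
Induction uses the conventional 2-fold cut-off (fold ≥ 2 or ≤ 0.5).
Significance is a two-sided Welch t on the ΔCt scale (identical to log2
folds); Tukey's HSD is provided for joint comparison of more than two
timepoints. Fewer than two replicates yields `NA` with a warning, not a
fabricated p-value.

## What the generators emulate — and what they do not

Every generator is a pure function of its arguments and seed, and each
emits a truth table the tests consume.

* `gen_proteome()` plants motif instances in a background uniform over the
  18 non-C/non-H residues, with at least 18 residues between instances.
  Under these conditions no accidental anchor placement can exist, so
  scanner recall and precision are exactly 1 — that is the point: a green
  test certifies the scanner, not robustness to compositional biases of
  real proteomes (a `uniform20` background exists for stress testing).
  `paper_scale_design()` reproduces the published family scale: 103
  proteins, 202 motifs, 53 single-motif proteins.
* `gen_codon_pair()` controls *realized* substitution counts: it plants
  exactly the number of synonymous and nonsynonymous single-nucleotide
  changes implied by the targets (inverse-JC inflated), at most one per
  codon and never through stops. Estimator checks are therefore tight at
  small n; what is *not* emulated is multiple hits at one site, codon usage
  bias, or transition/transversion bias — the JC correction's assumptions
  are granted by construction.
* `gen_alignment()` plants groups as private column blocks and makes deep
  structure deliberately unstable by adding balanced, mutually
  contradictory pair-affinity columns, so bootstrap support is high exactly
  on planted group edges. Real alignments have rate heterogeneity and
  indels; none of that is modeled.
* `gen_promoters()` uses an A/C-only background and pads planted instances
  with fixed `A`s; for libraries whose consensi require a G or T on each
  strand this makes accidental matches impossible and planted counts exact.
  Exact-count recovery additionally requires that no library element
  matches inside another's instances — untrue for the full default library
  (the shared `CCGAC` core), so planted-count checks use the ABRE/DRE
  sub-library while strand-symmetry checks use the full one.
* `gen_expression()` and `gen_qpcr()` realize planted correlations and fold
  changes under Gaussian noise on the log2/Ct scale; microarray-specific
  noise (probe cross-hybridization) is out of scope.

## Known limitations

* Ka/Ks is the NG86/JC estimator only; maximum-likelihood codon models and
  sliding windows are out of scope, as is aligning the CDS pairs (in-frame
  aligned input is required).
* The tree machinery is distance-based NJ only — no ML/Bayesian inference —
  and alignment itself is consumed, not computed.
* The promoter scanner does no statistical enrichment; it maps matches.
* Genome-scale published counts (the real family size, clade count, or
  wet-lab fold inductions) depend on external databases and experiments and
  are covered only through the synthetic plantings above; the packaged
  selection table is the one published artifact the package recomputes
  directly.
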