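---
title: "Methods: clone-library diversity analysis with methanodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clone-library diversity analysis with methanodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methanodiv)
```

This vignette is the package's own account of the methods it implements:
the models and their assumptions, the parameters that matter, the
conventions where the literature is ambiguous, and the numerical choices
that make results deterministic. The setting is a classic clone-library
survey: ~50 sequenced amplicons per library for one or two methanogen
markers (archaeal 16S rRNA gene DNA; *mcrA* deduced amino acids), with
libraries compared through OTU-based diversity statistics, a LIBSHUFF
permutation test, and neighbor-joining phylogenies.

## Distances

All OTU work runs on the uncorrected p-distance: the mismatch fraction
over *comparable* sites, i.e. positions where neither sequence has a gap
(`-`) or the ambiguity code (`N` for DNA, `X` for protein). Percent
similarity is `(1 - p) * 100`, so the common OTU criteria translate
exactly: 98% similarity is cutoff 0.02, 95% is 0.05. This is deliberate:
similarity thresholds are defined on the p-distance scale, and corrected
distances (Jukes-Cantor for DNA, Poisson for protein, both available)
exceed p and would silently tighten a similarity criterion if substituted.
Corrections are refused outside their domain (p >= 3/4 for Jukes-Cantor,
p = 1 for Poisson) rather than returning infinities.

Gap handling defaults to pairwise deletion, the standard for clone
libraries with ragged alignment ends; complete deletion (drop any column
containing a gap or ambiguity anywhere) is available. Ambiguity codes
other than `N`/`X` are rejected at parse time: silently treating `R` or
`Y` as a match or mismatch makes distances irreproducible across tools.

## OTU assignment

OTUs are furthest-neighbor (complete-linkage) clusters: two clusters merge
only when *every* inter-cluster sequence pair is within the cutoff, and
merging proceeds in non-decreasing complete-linkage distance until the
smallest possible merge would exceed it. The invariant this buys — no
OTU's diameter ever exceeds the cutoff — is what makes "98% similarity
OTU" a meaningful label for every member.

Two determinism choices are worth stating. Ties between equally distant
merge candidates are broken by the lexicographically smallest pair of
member ids (smallest minimum id, then smallest maximum id). And distances
enter clustering at full precision: some legacy OTU tools bin distances
to 0.01 before clustering, which is an implementation artifact we do not
reproduce; full precision is strictly more accurate and equally
deterministic.

## Cross-marker calibration

When a study uses a second marker without an established OTU criterion,
the criterion is calibrated from the reference marker: over the same
reference taxa, all n(n-1)/2 taxon-pair distances are paired across
markers and a least-squares line through the origin, `Y = bX`, is fitted
with `b = sum(xy)/sum(x^2)`. The reported fit quality is the *uncentered*
`R^2 = 1 - RSS/sum(y^2)` — the appropriate definition with no intercept,
where the centered form can be negative and misleading; the definition is
recorded in the result object. All pairwise taxon pairs are used (23 taxa
give 253 pairs) because the regression relates distance to distance, not
taxon to taxon.

The mapped cutoff is `b * 0.02` for a 98% reference criterion, and the
percent criterion is *floored* to a whole percent:
`floor(100 * (1 - 0.0439)) = 95`, not rounded — flooring is the
convention that turns a mapped distance just under 0.044 into a 95%
criterion, and it is the conservative direction (a finer criterion never
merges sequences a rounded one would split).

```{r}
map_cutoff(2.1944, 0.02)
```

## Diversity statistics and their conventions

Per library (zero-count OTUs dropped first): Shannon-Wiener
`H' = -sum(p_i log p_i)` in nats; evenness `E = H'/H_max`; Good's
coverage `(1 - F1/denominator) * 100`; Chao-1
`S_obs + F1^2/(2 F2)`, with the additive fallback term `F1(F1-1)/2`
when `F2 = 0` so the estimate stays finite and >= `S_obs`. The
bias-corrected Chao-1 variant is deliberately not the default: the
fallback form is what the classic clone-library tables were computed
with.

Two statistics have competing conventions in the printed literature, and
the package makes both first-class rather than guessing:

* **Evenness**: the textbook denominator is `H_max = ln(S)` (observed
  OTUs), but published per-library tables of this kind are often computed
  with `H_max = ln(N)` (total clones). Both are returned
  (`evenness_formula`, `evenness_printed`); the printed variant is the
  reporting default.
* **Coverage**: Good's estimator divides singletons by N (clones); the
  variant dividing by S (OTUs) matches most printed values in this table
  style. Both are returned (`coverage_clones_pct`, `coverage_otus_pct`);
  the OTU denominator is the reporting default.

The convention used is always named in the output and in the run
manifest. Statistics are computed at full precision;
`format_diversity_report()` applies the table rendering (H'/E to 2
decimals, coverage and Chao-1 to 1).

## LIBSHUFF comparison

Two libraries X and Y are compared through coverage curves built from
nearest-neighbor distances: the homologous curve `C_X(D)` is the fraction
of X sequences with another X sequence within distance D (self excluded),
the heterologous `C_XY(D)` the fraction with a Y sequence within D. The
statistic integrates the squared coverage *shortfall* over a distance
grid:

`dC_XY = sum_D max(C_X(D) - C_XY(D), 0)^2 * step`

The one-sided form measures how much worse Y covers X than X covers
itself, which is the directional question the comparison asks; it is
exactly zero when the heterologous curve dominates — in particular, two
sequence-identical libraries give `dC = 0` in both directions and p = 1,
as they must (every X sequence has a zero-distance heterologous
neighbor, so a two-sided squared difference would paradoxically score
identical libraries as maximally different). The grid runs from 0 to the
maximum pooled distance in steps of 0.01; step and integration convention
are recorded in the result, and p-values are invariant to the step
constant because it multiplies observed and permuted statistics alike.

Significance comes from permuting library labels over the pooled
sequence set with library sizes fixed, with the add-one estimator
`p = (1 + #{permuted >= observed})/(1 + B)` (B = 999 by default) — the
estimator is never exactly zero and is valid at small B. Because the two
reciprocal comparisons are reported as one verdict, each is tested at the
experiment-wise threshold `1 - (1 - alpha)^(1/2)`. The RNG seed is a
required part of the result object.

## Neighbor-joining trees

Saitou-Nei neighbor joining with the standard Q-criterion. Determinism
and edge-case conventions: taxa are canonicalized to sorted label order
before any arithmetic (so results are independent of input order, and
floating-point summation order is fixed); Q ties resolve to the smallest
label pair; negative branch lengths are clamped to zero with the deficit
transferred to the sister branch, preserving the sibling sum
(path lengths stay approximately additive). On an exactly additive
matrix the tree reproduces every leaf-to-leaf path length.

Bootstrap support resamples *alignment columns* with replacement — the
unit of evidence is the site, as in standard alignment/NJ pipelines —
rebuilding the distance matrix and tree per replicate and counting
recovery of each internal bipartition of the reference tree. Replicates
that fail (e.g. a pair left with no comparable sites) are skipped and
tallied, not silently imputed. Outgroup rooting places the root at the
midpoint of the outgroup's pendant edge, which conserves leaf-to-leaf
path lengths.

## The synthetic-data generator

The generator exists so that every stage is testable against *known
truth*. A community is S ancestor sequences drawn i.i.d. uniform over the
alphabet, rejection-checked to be at least `inter_otu_divergence` apart
(for random sequences the expected p-distance is ~0.75 for DNA, so the
default floor of 0.20 is essentially always satisfied at realistic
lengths). Clones copy their ancestor with at most
`floor(intra/2 * L)` mutated sites, so any two clones of one OTU are
within `intra_otu_divergence` and clones of different OTUs at least
`inter - intra` apart — both bounds are asserted on the realized distance
matrix before a library is returned. Mutations are i.i.d. per site,
uniform over the other 3 bases / 19 residues, with no indels, so
alignments are gap-free and planted p-distances exact.

Abundances follow a geometric model (weights proportional to
`theta (1-theta)^(i-1)`), whose dominance default `theta = 0.6` with
S = 8 OTUs and 50 clones reproduces the shape of real hindgut methanogen
libraries: one dominant OTU holding roughly 60-70% of clones, a
sub-dominant OTU, and a singleton/doubleton tail. An explicit mode
replays printed count tables verbatim. Library pairs are drawn either
from one shared community (the LIBSHUFF null — labels exchangeable by
construction) or from independent ancestor pools (the alternative, with
disjoint dominant OTUs).

What the generator does *not* emulate: rate heterogeneity among sites,
indels and alignment error, chimeras, PCR/sequencing error, and
phylogenetic correlation among OTU ancestors (they are mutually ~0.75
apart, a star-like radiation — which is why bootstrap supports on
simulated deep branches are unremarkable). Tests passing on this
generator therefore validate the *algorithms* — clustering recovery,
statistic arithmetic, test calibration — not robustness to real-data
artifacts, which pre-aligned curated input is assumed to have handled.

## Problem sizes and determinism in the test suite

The test suite validates the pipeline at the study's own scale: 50-clone
libraries, 16S-length (1254 nt) sequences. Clustering recovery is checked
across 200 generator seeds; NJ additivity across 500 random 4-10 taxon
trees; the LIBSHUFF type-I error across 1000 null library pairs at 199
permutations each, and power across 100 disjoint-community pairs at 999
permutations; calibration recovery across 100 seeds of 253 noisy pairs
(sigma = 0.05). All simulations run under fixed seeds, and every
stochastic API (generators, permutation test, bootstrap) takes an
explicit seed that is echoed in its result.

## Known limitations

* Only p-distance, Jukes-Cantor and Poisson models; no F84/JTT or
  rate-heterogeneous distances, so distances from legacy Phylip runs will
  differ slightly in absolute value (OTU criteria, being
  similarity-based, are unaffected).
* LIBSHUFF is implemented for exactly two libraries (the reciprocal
  pair), not k-way designs.
* Furthest-neighbor is the only linkage; nearest/average-neighbor OTU
  definitions are out of scope.
* The NJ implementation targets clone-library sizes (tens to a few
  hundred sequences); it is exact but not optimized for thousands of
  taxa.
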