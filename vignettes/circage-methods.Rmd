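---
title: "Methods: circRNA specificity analysis across brain regions, sex and age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circRNA specificity analysis across brain regions, sex and age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circage)
```

## The analysis problem

Circular RNAs (circRNAs) are covalently closed transcripts produced by
back-splicing; a sequencing read spanning the head-to-tail (back-splice)
junction is the only unambiguous evidence of the circular isoform, so the
junction-read count is the natural raw expression measure. `circage`
implements a complete downstream analysis for a junction-count experiment
laid out as a multi-region brain design: eight anatomical compartments
(PFC, PCC, TC, PC, OC, CA1, DG, CB), two sexes and two ages (10 y and
20 y), one pooled library per design cell — 32 libraries in total, with
4 libraries per region and 16 per sex or age level.

The pipeline stages are: per-sample candidate filtering, assembly into a
circRNA-by-sample count matrix, an expression-filter cascade that defines
the analysis set, median-of-ratios normalization, spatial / sex / age
specificity screens (Welch t-tests plus a label-permutation null),
simplified weighted co-expression modules, circRNA-to-host-mRNA
correlation, and hypergeometric set-overlap / gene-set enrichment.

## Coordinates and circRNA identity

All coordinates inside the package are 0-based half-open `[start, end)`;
CIRI2-style tables and GTF (both 1-based inclusive) are converted at the
I/O boundary in both directions, so no other module ever reasons about
conventions. A circRNA is identified by the exact back-splice tuple
`chrom:start|end:strand`. Merging per-sample calls into the matrix is
deliberately exact-match: detection tools report single-nucleotide
ambiguity often enough that silent merging would hide it. Tolerant
matching is a separate, explicit operation (`match_circ_sets()`), which
declares two loci equivalent when both coordinates agree within ±5 nt
(tolerance configurable) and strands are compatible, with `"."` acting as
a wildcard because tools disagree on strand assignment.

`classify_genomic_context()` assigns exactly one category per circRNA with
precedence exonic > intronic > antisense > intergenic. "Exonic" requires
both back-splice boundaries to fall inside exons of one same-strand gene —
a permissive rule, since annotation in non-model primates is incomplete; a
`strict_boundary` flag demands coincidence with annotated exon boundaries
instead. Same-strand overlap that fails the exonic test is classed
intronic (including partial overlaps, which the category definitions would
otherwise leave unassigned); chromosomes absent from the gene models fall
back to intergenic with a warning rather than an error, since scaffold
naming mismatches are routine.

## The expression-filter cascade

Junction counts are sparse and low; the analysis set is defined by one
candidate rule and a five-part cascade, all thresholds exposed in
`filter_config()`:

* candidate rule: a library supports a circRNA only with at least 2
  junction reads;
* a sample *expresses* a circRNA at >= 3 junction reads (rule 1);
* a brain area is *expressed* when >= 2 of its samples express it (rule 2);
* keep if >= 2 areas are expressed (route `rule3`); else
* keep if exactly one area is expressed and >= 6 samples express it
  overall (route `rule4`); else
* keep if the total junction reads reach 30 (route `rule5`).

Two interpretation points are worth making explicit. First, rule 4's
"expressed in only one brain area" is read as *exactly one area passes
rule 2*, while its sample count runs over all areas — with only 4 samples
per area, requiring 6 expressing samples inside one area would be
impossible, so this is the only reading consistent with the design.
Second, the routes form a disjunction of monotone conditions; the `route`
label reports the first rule that fired (rule3 → rule4 → rule5), which is
a reporting convention only — the kept set does not depend on the order.
Monotonicity (raising any count can never drop a kept circRNA) is
property-tested against a literal re-implementation of the rules.

## Normalization

Size factors are classic median-of-ratios: for sample $j$,
$s_j = \mathrm{median}_i \, k_{ij} / (\prod_j k_{ij})^{1/m}$ over the rows
$i$ with all-positive counts (rows containing zeros have no geometric mean
in log space and are excluded — standard practice). The median is taken on
the raw ratio scale; this coincides with the log-scale median except for
the interpolation at even reference sizes. One algebraic consequence that
tests make explicit: multiplying one sample's counts by $c$ moves the
geometric-mean reference too, so its raw factor scales by $c^{1-1/m}$ and
everyone else's by $c^{-1/m}$ — size factors are meaningful *relative* to
each other (ratios scale by exactly $c$), not absolutely.

Downstream screens operate on `log2(normalized + 1)` by default
(`pseudocount = 1`, configurable): the log stabilizes the strong
mean-variance relationship of overdispersed counts, and the pseudocount
keeps zeros finite. Fold changes are
`log2((mean2 + 1) / (mean1 + 1))` on the normalized scale, oriented so
that positive values mean higher expression in the 20-y (age) or male
(sex) group.

## Specificity screens

The per-circRNA test is Welch's unequal-variance t-test, vectorized over
rows; `two_group_t_test()` also exposes a paired variant (pairing samples
across regions by sex and age) because the source analyses are described
both ways — unpaired is the default. Degenerate rows are resolved
deterministically: when both group variances vanish, equal means give
`(t = 0, p = 1)` and unequal means give `(t = ±Inf, p = 0)`, the limits of
the statistic.

*Spatial*: each region's 4 samples are tested against the remaining 28
(one-vs-rest), at `alpha = 0.01`; a call additionally requires the region
mean to be strictly higher, and mode `"vs_each"` requires the region mean
to beat every other region's mean ("consistently higher"). A circRNA is
called for at most one region — smallest p wins, ties broken
lexicographically. *Sex / age*: a single 16-vs-16 test per circRNA at
`alpha = 0.05`, the enriched group being the higher-mean level. Calling
uses raw p-value thresholds, matching how such sets are conventionally
reported for this design; Benjamini–Hochberg q-values are emitted as an
extra column but are not used for calling.

Two statistical properties of this calling rule matter when interpreting
results and the recovery tests below. With 4-vs-28 groups, the Welch
denominator has roughly 4 degrees of freedom, so even a 4-fold planted
effect at dispersion 0.1 has power only ~0.85–0.90 at p < 0.01: a region
screen on so few samples per region is power-limited by design. And raw-p
calling admits false positives at close to `alpha` per null row (about 8
× alpha/2 across the eight region screens), so whenever true effects are
a small fraction of the transcriptome, the called set is
false-positive-dominated — precision is bounded near
`planted / (planted + alpha × null)` regardless of effect size. The
q-value column exists precisely for users who need FDR control.

*Permutation null*: the statistic is the difference of group means per
row; group labels are permuted jointly across rows; the two-sided p-value
uses the add-one estimator `(1 + #{|stat_perm| >= |stat_obs|}) / (1 +
n_perm)` (default `n_perm = 10000`), so p is never 0 and never below
`1/(1 + n_perm)`. For small designs `exhaustive = TRUE` enumerates all
label assignments and returns the exact permutation p-value, whose
two-sided minimum is `2 / n_assignments` because every split ties with its
mirror. Tie counting uses a `1e-12` relative epsilon: a mirrored split
equals `-stat_obs` mathematically but not always bitwise. The agreement
between t-test and permutation calls is summarized with
`compare_sets()` (intersection over the permutation set) plus a
hypergeometric overlap p-value.

## Co-expression modules

A deliberately simplified single-block WGCNA-style procedure, chosen to be
deterministic and oracle-testable at desk scale: unsigned soft-threshold
adjacency `a_ij = |cor|^beta` with the cubic power `beta = 3` as default
(a signed variant is a flag), topological overlap
`TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)`, average-linkage
clustering of `1 - TOM`, a *static* cut, and `min_module_size = 30` with
sub-threshold clusters collected in module 0. Eigengenes are the first
principal component across samples of the row-standardized module
submatrix, unit-norm and sign-aligned with the module's mean profile.

The static cut height deserves its own paragraph, because the natural
first guesses are both wrong. On the `1 - TOM` scale with `beta = 3`,
tightly co-expressed blocks (|cor| ≈ 0.9) sit near
`1 - 0.9^3` ≈ 0.2–0.3, so a cut at 0.25 — the conventional height for
*merging eigengenes*, a different tree — splits genuine modules. At the
other end, TOM's `min(k_i, k_j)` denominator lets a sparsely connected
row reach TOM ≈ 0.1–0.15 against a large module (dissimilarity ≈ 0.86),
so a near-top cut such as 0.9 absorbs unrelated rows into modules;
measured scales on a three-planted-module fixture are ~0.22 within
modules, ~0.86 for noise-to-module attachment and ~0.99 between modules.
The default `cut_height = 0.5` separates the two regimes. The trade-off
is explicit: loosely co-expressed modules (|cor| ≲ 0.8, within-block
dissimilarity above 0.5) need a higher cut, at the cost of absorbing
weakly connected features — the parameter is exposed for exactly that
reason, and a dynamic tree cut is out of scope for this simplified
implementation.

## Host-mRNA correlation

For each (circRNA, host gene) pair, the Pearson correlation across the
shared ordered samples is computed together with the two-sided p-value
from `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.
Correlation is unit-free, so the mRNA matrix may carry FPKM, TPM or
counts. Classification uses inclusive thresholds — positive when
`pcc >= 0.3` and `p <= 0.1`, negative when `pcc <= -0.3` and `p <= 0.1` —
reading "no less than" / "no more than" literally. One pair per (circRNA,
gene): several circular isoforms of one gene yield several pairs, and the
summary reports fractions over both denominators (pairs and distinct host
genes) because either convention is found in practice.

## Enrichment

`hypergeom_tail(N, K, n, k)` returns the one-sided upper tail
`P(X >= k)`, accumulated in log space (log-binomial coefficients plus
log-sum-exp) so that tails around 1e-38 are computed without underflow;
`hypergeom_pmf()` exposes the point masses and their sum-to-one check.
`enrich_gene_sets()` applies the tail test per annotation set against a
user-supplied universe with BH q-values; annotation input is a plain
two-column TSV, keeping the engine independent of any ontology database
version. Only enrichment (upper tail) is offered; depletion is not.

## The synthetic-data generator

`sim_config()` / `simulate_counts()` emulate the study: 32 libraries in
the 8 × 2 × 2 design, counts drawn
`NB(mean = lambda_i * s_j * f_ij, dispersion)` with

* `lambda_i` log-normal, `meanlog = 3.5`, `sdlog = 1.0` — calibrated so
  that ~14% of circRNAs exceed 100 junction reads, matching the reported
  abundance tail of a brain circRNA set, with a median around 30 reads as
  expected for a filtered, "well expressed" set;
* `s_j` log-normal library factors (`sdlog = 0.15`), or user-supplied;
* `f_ij = 4` for spiked rows in their target level's samples: by default
  100 CB-enriched, 50 male- plus 50 female-biased, and 50 old- plus 50
  young-biased circRNAs (disjoint sets; 15% of 2,000 rows), fold and
  counts configurable;
* `nb_dispersion = 0.1`, a typical bulk RNA-seq biological dispersion.

`simulate_host_mrna()` plants circRNA–host correlations on the log2
scale: the host profile is `10 + 1.5 h` with
`h = rho z + sqrt(1 - rho^2) u`, `z` the standardized circRNA profile and
`u` a standardized residual made orthogonal to `z`, so the *sample*
correlation equals the planted `rho` exactly (the offset/scale keep
expression strictly positive). Defaults plant 300 pairs each at
rho = +0.8, −0.8 and 0. Ground truth (spike labels, folds, planted rho)
is returned for every row, and everything is reproducible from a single
seed without disturbing the caller's RNG state.

What the generator does *not* emulate — and therefore what passing
recovery tests do not show about real data: correlated circRNAs beyond the
planted structure, isoform families sharing host genes, region-specific
library composition, detection-tool artefacts near splice sites, or
abundance-dependent detection dropout. It validates the statistical
machinery under the stated design, nothing more.

## Problem sizes and numerical choices

The test suite runs everything at desk scale: 2,000-row matrices for
recovery and calibration, 1,000 random 20 × 32 matrices against the
literal filter oracle, 50 random instances each for the size-factor and
TOM brute-force oracles (agreement to 1e-12), 2,000 permutations over
2,000 null rows for calibration, and full enumeration for 3-vs-3
permutation exactness. Matrix permutation work is chunked (500
permutations at a time) to bound memory. The hypergeometric example with
`N = 17050, K = 475, n = 41, k = 30` reproduces the reference tail
2.14e-38 to three significant figures.

## Known limitations

* circRNA detection from reads, alignment and conservation analysis are
  out of scope: the pipeline starts at junction-count tables.
* The spatial screen with 4 samples per region is power-limited (see
  above); raw-p calling does not control FDR — use the q-value columns
  when error control matters.
* The static tree cut trades the flexibility of dynamic cutting for
  determinism; module counts depend visibly on `cut_height`.
* Two time points cannot distinguish aging trajectories from cohort
  differences; the age contrast is a two-group comparison, nothing more.
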