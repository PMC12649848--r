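---
title: "Methods: the embryo–endometrium interactome pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the embryo-endometrium interactome pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endotalk)
```

endotalk models implantation as a signalling problem: a day-5 blastocyst
secretes soluble factors, the secretory-phase endometrium displays plasma
membrane receptors, and physical receptor–ligand contacts form a bipartite
network whose disease-dependent perturbation can be quantified. This
vignette documents the statistical model behind each stage, the tunable
parameters, the synthetic data the package tests itself on, and the design
decisions taken where the methodology was genuinely open.

## The expressed-gene filter

A gene in a dataset is *expressed* when both hold strictly:

1. its median expression across samples exceeds the **global median over
   every entry** of that dataset's matrix, and
2. it is non-zero in **more than half** of the samples.

Choices worth making explicit:

* *Strict inequalities.* "Exceeds" and "more than half" are read strictly,
  so a gene whose median equals the global median, or that is non-zero in
  exactly 50% of samples, is excluded. This is the conservative reading;
  with continuous expression values the boundary has measure zero, but on
  count-like or quantized data ties are real and the tests exercise them
  deliberately.
* *Global median over all entries* rather than over per-gene medians. The
  two conventions differ on skewed data; all-entries is the simpler
  estimand and is applied uniformly. The per-gene criteria record returned
  by `filter_expressed()` makes a sensitivity re-analysis a one-liner.
* *Zero means exactly 0.0.* No epsilon: the filter targets dropout-style
  absence, and any positive reading counts as detection.
* Even-length medians use the usual midpoint convention.

The filter is invariant to row/column permutation and to positive
rescaling of the whole matrix; both properties are tested, as is exact
agreement with an independent loop-written oracle on tie-rich random
matrices.

## Compartments and decoys

The endometrial side keeps expressed genes tagged `plasma_membrane`
(candidate receptors); the embryo side keeps expressed genes tagged
`secreted`, split into ligands and *decoy factors* — secreted molecules
such as soluble cytokine-receptor isoforms that bind partners in solution
and therefore cannot form membrane receptor–ligand edges. Decoys are
excluded from network nodes but retained in the enrichment background,
since they are functionally relevant even without an edge. A gene tagged
both `plasma_membrane` and `secreted` is a receptor on the endometrial
side: each side applies only its own tag. Expressed genes missing from the
annotation are dropped with a logged count rather than raising an error,
because any annotation join loses unmapped identifiers.

## Differential expression

Fold change is computed on linear group means with a pseudocount,
`FC = (x̄₂ + 1)/(x̄₁ + 1)`, and significance from a two-sided Welch t-test
on `log2(x + 1)`, with Benjamini–Hochberg FDR across all tested genes. The
call gates are `FC > 2` (applied symmetrically, i.e. `|log2 FC| > 1`) and
`FDR < 0.01`.

The Welch test was chosen as the default because it is deterministic,
fast, and well calibrated on approximately log-normal expression; the
marker-selection tools this replaces do not pin down a single statistic,
and only the FC/FDR gates are part of the method's definition. A seeded
permutation test on the same t statistic (`test = "permutation"`) is
available where distributional assumptions are in doubt; with 12 + 12
samples its resolution is bounded by `1/(B + 1)`, so B must be large
enough for BH-adjusted calls at FDR < 0.01 (B = 2000 suffices at the test
suite's problem sizes). The pseudocount (default 1.0 on linear values)
guards zero means and is configurable.

## GSEA engine

Genes are ranked by signal-to-noise on `log2(x + 1)`:
`(μ₂ − μ₁)/(σ₂ + σ₁)` with each σ floored at `max(0.2·|μ|, 0.2)`. The
floor prevents near-constant genes from producing unbounded scores; note
that on the non-negative log scale the μ-proportional term dominates
whenever `|μ| > 1`. Ties break lexicographically by gene id so the ranking
is a total order. A plain `log2fc` metric is available.

The enrichment score is the classical signed maximal deviation of the
weighted running sum: hits advance by `|metric|^p` normalized over the
set's hits, misses by `1/(N − k)`; `weight_p = 1` by default, `p = 0`
recovering the unweighted Kolmogorov–Smirnov form. The implementation
evaluates only the 2k candidate extrema (at each hit and immediately
before it); the test suite checks it against a full running-sum oracle on
100 random instances and against an independent external implementation.

The null distribution uses **gene-set permutation**: random same-size sets
from the ranked universe, sharing one null per distinct set size. With a
12 vs. 12 design, phenotype permutation offers limited distinct
relabellings and is left as future configuration; the divergence from
phenotype-permutation GSEA defaults is deliberate and documented here.
NES is ES divided by the mean |null ES| of matching sign; nominal p is the
same-sign tail fraction; FDR follows the NES-distribution ratio
construction (pooled null NES tail over observed NES tail), with BH on
nominal p available via `fdr_method = "bh"`. Sets pass at `FDR < 0.25` and
`|NES| > 1.5`. Under a null ranked list the pass rate of random sets stays
within Monte-Carlo noise of zero; a 50-gene set concentrated in the top
decile passes in every seeded replicate of the test conditions.

## Over-representation and categories

For a network gene set of size n in a background of size N, overlap x with
a pathway of size K is scored by the upper-tail hypergeometric p-value
`P(X ≥ x)` and `strength = log10((x/n)/(K/N))`, i.e. log10 of
observed/expected — the effect-size convention used by interaction
databases. Gates: strength > 0.7 and BH FDR < 0.001. Zero overlaps report
p = 1 with undefined strength and never pass. Exactness is verified
against direct combinatorial enumeration for backgrounds up to 12.
Enriched pathway names are then grouped through a pathway→category map
(shipped skeleton: inflammation, stress response, cell death); unmapped
pathways land in `unassigned`.

## Single-cell arm

*Normalization.* Counts are scaled per cell to the median total count,
then `log2(x + 1)`. This deliberately replaces regularized
negative-binomial variance stabilization: the pipeline's contribution
surface is the typing, averaging and secretome logic downstream, and
rank-based typing is insensitive to the difference. Zero-count cells are
dropped with a warning.

*Typing.* Two tiers, mirroring atlas-then-immune-panel practice: every
cell is Spearman-correlated against each broad profile over the top-500
variable reference genes (variance computed on the reference tier, so the
gene panel does not depend on the query data); cells landing on the
`immune` broad label are re-scored against the immune tier (B,
monocyte/macrophage, NK, CD4+ T, CD8+ T). The label is the argmax, ties
break lexicographically, and the margin to the runner-up is recorded per
cell so an iterative fine-tuning pass could be added without changing the
interface. Spearman is the default because depth normalization plus ranks
make the assignment invariant to any per-cell positive scaling; Pearson is
config-exposed.

*Proportions and pseudobulk.* Per-sample type counts and proportions (the
denominator is the sample's total cell count, so proportions sum to one
exactly); the immune fraction is the summed proportion of immune
sublabels. Pseudobulk is the arithmetic mean of **normalized** (log2)
expression over each (sample × type) with at least `min_cells = 10` cells
— both choices are stated here because raw-count averaging and other
minimum-cell cutoffs are defensible; normalized averaging is what lets the
result feed the bulk filter unchanged, and the cutoff guards mean
estimates from 1–2 cell groups. The secretome step inverts to linear scale
(`2^x − 1`) before the expressed filter and fold-change computation so the
bulk pipeline's semantics are preserved, then restricts to secreted
expressed genes per immune type.

## Network assembly and overlays

Edges require, jointly: one endpoint an expressed receptor and the other
an expressed ligand; combined score ≥ 0.7 (the "high confidence"
convention; scores supplied as 0–1000 integers are auto-detected and
rescaled); a physical interaction; and explicit receptor–ligand evidence.
The evidence flag is input data, standing in for a manual literature
curation that code cannot re-do. The edge set is monotone non-increasing
in the score threshold and the three gates commute — both tested.

Receptor-side overlay: a network receptor is *modulated* iff it is called
significant in the endometrial DEG table; receptors outside the DEG
universe count as non-modulated (arrays and RNA-seq universes differ), and
the modulated share is reported as a percentage rounded **half-up** to one
decimal — the convention that reproduces 13/43 → 30.2, 18/44 → 40.9 and
29/44 → 65.9 exactly. Ligand-side overlay: a receptor is *affected* iff at
least one incident edge carries a ligand significantly perturbed in its
source cell type's secretome table; a receptor with several perturbed
edges counts once, and per-edge direction annotations are kept.
Percentages use connected receptors as the denominator.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *structure* of the study conditions, not the
moments of any real dataset:

* **Bulk**: 12 vs. 12 samples, 2000 genes, 200 planted DE genes at
  |log2 FC| = 2 with directions split evenly, log-normal noise
  (σ = 0.5 on the log2 scale) around uniform per-gene baselines
  (log2 means 3–10). Log-normal noise was chosen because downstream fold
  changes are taken on linear-scale means; the embryo set is 3 samples
  with no planted effect.
* **Annotation**: 10% receptors, 20% secreted, 2% decoys (drawn from the
  secreted class only) — round numbers giving compartment sizes of the
  same order as a filtered transcriptome.
* **Interactions**: planted true pairs pass all three gates; each noise
  pair fails at least one, uniformly among the three failure modes.
* **Single cell**: per-group immune fractions 0.15 vs. 0.30 (a planted
  doubling of the immune compartment), 1000 cells and ~2000 counts per
  cell, counts Poisson around independent log-normal reference profiles;
  the secretome shift multiplies selected secreted genes by 2^2 in
  disease-group NK/CD4+/CD8+ cells. Poisson-on-reference is the simplest
  model under which correlation typing is provably consistent;
  negative-binomial overdispersion, doublets, ambient RNA and batch
  effects are all absent, so passing tests demonstrate the pipeline's
  logic, not robustness to those artefacts. Real references also contain
  correlated, hierarchically related profiles — synthetic near-orthogonal
  profiles make typing easier than HPCA/DICE-scale discrimination.
* One run seed fans out to per-generator child seeds through fixed
  offsets, so adding a generator never shifts existing streams; every
  generator is byte-identical under a repeated seed.

## Numerical choices and degenerate inputs

* Half-up decimal rounding uses a relative-epsilon nudge so values that
  are exactly `.x5` in decimal but land a hair below in binary still round
  up.
* Zero-variance genes in the Welch test get t = 0 (no evidence) rather
  than NaN; the σ floor handles the GSEA analogue.
* An all-zero metric vector makes the weighted ES fall back to equal hit
  weights.
* A gene set covering the whole ranked list has an undefined miss rate and
  raises an error; sets with no overlap raise an error in `gsea_es()` and
  are skipped with a warning in `gsea()`.
* Empty overlap in ORA: p = 1, strength undefined, never passes.
* `depth_mean = 0` in the single-cell simulator warns and produces
  all-zero counts; all-zero datasets are rejected at normalization.
* Thresholds must be strictly positive at config validation; a
  "no calls" run is expressed with an arbitrarily small positive FDR
  threshold rather than 0.

## Problem sizes

The shipped defaults — 2000 genes, 12 + 12 bulk samples, 1000 permutations,
6 single-cell samples at 1000 cells — were chosen so that a full pipeline
run completes in well under a minute on a laptop core while keeping every
planted-signal recovery statistically comfortable; the test suite and the
reproduction script use the same sizes.

## Known limitations

Identifier harmonization (probe → gene, symbol → Ensembl) is out of scope:
inputs are assumed to share one opaque, case-sensitive identifier
universe. Multi-dataset integration and batch correction are not
performed; samples are concatenated with batch carried as metadata. The
typing stage implements a single argmax with two-tier refinement, not
iterative fine-tuning. Strength-based ORA inherits the usual caveat that
overlapping pathways are tested marginally.
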