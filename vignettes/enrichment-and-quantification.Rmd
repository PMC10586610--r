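---
title: "Methods: identity-group gene-set enrichment and RNAscope quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identity-group gene-set enrichment and RNAscope quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igora)
```

# Scope

`igora` answers two questions that arise when a curated gene set (such as the
imprinted genes) is hypothesised to act through specific neuronal
subpopulations:

* is the set over-represented among the genes *upregulated* in a given
  cell-identity group of a single-cell RNA-seq dataset, and
* what do per-cell smFISH (RNAscope) measurements say about molecule counts,
  positive-cell rates and expression intensity in the corresponding cell
  classes in tissue?

Cell identities are *inputs* (cluster labels produced elsewhere); clustering,
batch correction, doublet removal and all pixel-level image processing are
out of scope. The quantification stage consumes per-cell object tables
exported by microscope software, never images.

# The enrichment model

## Upregulation screen

Counts are normalized per cell to a common total and log1p-transformed. The
default scaling target is the **median cell total**: the upstream dataset's
own normalization is study-specific, so the package uses the most common
convention and exposes `scale_target` and `log_base` for studies that need
to match an external pipeline exactly. Cells with zero total counts cannot
be scaled and are rejected by name.

Genes detected in fewer than `min_cells = 20` cells across the whole dataset
are removed before testing; this is both a variance-stabilisation measure
and the definition of the ORA gene universe.

For each gene and identity group the screen runs a **one-sided Wilcoxon
rank-sum test** (group cells greater than all remaining cells), with
midranks for ties. Two regimes:

* combined n ≤ `exact_limit` (default 12): the null is enumerated over all
  C(n, n₁) assignments — exact even under ties;
* above that: normal approximation with tie-corrected variance
  n₁n₂/12 · [(n+1) − Σ(t³−t)/(n(n−1))] and a 0.5 continuity correction.
  At the scale this screen targets (hundreds to thousands of cells per
  group) the approximation error is negligible; the test suite verifies
  uniformity of null p-values empirically.

P-values are floored at the smallest positive double so that the (0, 1]
contract holds even when the normal tail underflows.

## Horizontal BH

The screen produces a genes × identities p-value matrix. The default
correction family is **per gene across identity groups** ("horizontal": the
correction runs along the row). The term is ambiguous in the field — it
could also mean per identity group — so the family is a configuration switch
(`bh_family = "per_gene" | "per_group" | "global"`). The per-gene reading is
the default because the multiplicity being corrected arises from testing
each gene once per identity group. A gene is **upregulated** in a group iff
q ≤ `q_max` (inclusive, default 0.05) and log₂FC > `lfc_min` (strict,
default 1).

Fold change is computed on the normalized scale as
(mean_in + ε)/(mean_out + ε) with ε = 1e-9 — small enough to never move a
reported value at data scale, large enough to make a gene absent outside the
group yield a finite fold change. ε is recorded in the run manifest.

## Eligibility-gated ORA

For each identity group the 2×2 table over the filtered universe is

|            | upregulated | not upregulated |
|------------|-------------|-----------------|
| in set     | a           | b               |
| not in set | c           | d               |

with the set first intersected with the universe (case-insensitive symbol
match; unmatched set genes are reported, not fatal — curated lists routinely
contain genes a given dataset never captured). The one-sided Fisher p is the
hypergeometric upper tail P[X ≥ a]. A group is **eligible** iff
a ≥ `eligibility_fraction` · (a + b) with the exact real product (no
rounding: with a 74-gene set, 4 qualifies and 3 does not). Bonferroni runs
over eligible groups only; ineligible groups keep their raw Fisher p and an
`NA` corrected value, so the family size is honest. The per-group mean
linear fold change of set genes versus the rest is reported alongside; by
default it averages **all** filter-passing genes (an `"upregulated"`-only
switch exists, since either reading is defensible).

Ranking of hits breaks p-value ties by larger a, then identity name, so
output order is deterministic.

# The quantification model

## Thresholds and cluster resolution

Per channel, the detection threshold is mean + 3·SD of the no-probe
control's per-cell maximum intensities. The SD is the **sample** SD (n−1):
control cells are a sample from the background process, not the population.
At least two control cells are required or the threshold is undefined.

Every supra-threshold object is resolved into molecules as
round((integral − background)/single-signal mean intensity). Rounding is
half-up (bench SOPs mean commercial rounding, and `round()`'s half-to-even
would map 2.5 singles to 2); any threshold-passing object is at least one
molecule, so counts clamp at 1. The **single-signal mean intensity is always
a supplied calibration value** — acquisition settings differ per channel and
study — but `estimate_single_intensity()` offers a starting point (median of
the dimmer half of the objects, which clusters rarely contaminate). It is
never applied silently.

## Classification and summaries

Positivity rules are minimum molecule counts per channel (e.g. Gal 2+,
Calcr 2+, Fos 5+); composite classes are conjunctions. The package reports
positives per 1000 cells (section- and animal-size independent), the H-score
(weights 0–4 over molecule bins {0}, {1–3}, {4–9}, {10–15}, {16+}; bounded
by construction in [0, 400] and exactly linear under population mixing), and
fold changes of mean molecule counts between cell classes. H-scores are
pooled **per animal** across sections, and per-animal aggregates are the
experimental units for any cross-animal statistic — the per-section
alternative is not offered because sections within an animal are not
independent.

## Nonparametric comparisons

Molecule-count distributions are heavily tied and skewed, so contrasts are
rank-based: Mann-Whitney (exact enumeration for combined n ≤ 12, otherwise
the tie-corrected continuity-corrected normal approximation), Kruskal-Wallis
with the tie-correction divisor, and two-sided Dunn post-hoc z-tests with
Bonferroni over all pairs performed. The exact-size limit of 12 reflects the
enumeration cost and the fact that real per-cell comparisons involve
thousands of cells (approximation regime); per-animal comparisons with n = 4
per group fall in the exact regime automatically.

# The synthetic world

`simulate_counts()` draws gene baseline means from LogNormal(log 0.5, 1) —
most genes shallowly detected, a tail of strong genes, which matches typical
droplet scRNA-seq depth — and counts from NB(mean, dispersion = 2), variance
mean + mean²/2, the standard overdispersion model for UMI data. The planted
alternative multiplies the means of a random 20 of the 74 set genes by 4 in
one of 10 identity groups of 200 cells; those values are the stated default
scenario of the screen, and the gene universe is set at 1000 genes (a
compromise: large enough for a realistic ORA table, small enough that the
acceptance suite's 300 pipeline runs stay within minutes). With
`planted_identity = NULL` all cells are exchangeable — the null world used
for calibration tests (there, a smaller 400-gene, 8 × 50-cell world keeps
200 replicates cheap; calibration does not depend on universe size).

`simulate_spots()` emits object tables with single-signal intensities
Normal(300, 30) a.u. over a background of 50 a.u., control noise SD 20 a.u.,
and a cluster probability of 0.3 (each molecule joins its cell's single
merged cluster); the default type mix (5% Gal/Calcr-high, 7% Gal-only, 88%
low-expression background) sketches a preoptic-area field of view. These
arbitrary-unit choices put the detection threshold (~120 a.u.) far below a
single signal (~350 a.u.), as a usable RNAscope experiment requires.

What the generators deliberately do **not** emulate: per-gene mean-variance
trends beyond NB, library-size variation between cells, spatial structure,
section-to-section variability, segmentation errors, or optical crowding at
high molecule density. A green test therefore establishes correctness of the
*computation* under the stated statistical assumptions, not robustness to
every real-data pathology.

# Numerical and design notes

* Exact/approximate switch at combined n = 12 for both rank-sum routines;
  identical values at the boundary are included in tails using a 1e-9
  comparison slack to absorb midrank float error.
* Two-sided exact Mann-Whitney p is twice the smaller tail, clamped at 1
  (the convention that reproduces textbook small-sample tables under ties).
* `horizontal_bh` rejects p outside (0, 1]; q is monotone in p within each
  family by construction of the step-up.
* Degenerate inputs fail loudly and early with stage-named errors: zero-total
  cells, filters removing every gene, single-cell control tables, empty cell
  classes, zero denominator means.
* All randomness flows through one integer seed per generator call; run
  manifests omit timestamps so identical inputs produce byte-identical
  result bundles.
* Configuration is plain function arguments plus JSON for calibration files
  and manifests (the environment provides no R YAML parser); every parameter
  is echoed into the run manifest.

# Known limitations

* The screen's q-values depend on the normalization convention; when
  reproducing a published analysis the upstream procedure must be matched
  via `scale_target`/`log_base`.
* The per-gene ("horizontal") BH family is one of two defensible readings;
  the switch exists precisely because the convention is not standardised.
* Cluster resolution assumes cluster intensity is additive in its member
  molecules; optical saturation in very dense clusters would bias counts
  downward.
* The Dunn test uses the large-sample normal approximation; with very few
  cells per class its p-values are approximate.
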