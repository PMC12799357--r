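---
title: "Senescence scoring and T-cell composition: models and design choices"
author: "senskin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Senescence scoring and T-cell composition: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`senskin` estimates, donor by donor, how many cells in a skin scRNA-seq
cohort are senescent, and asks whether that burden co-varies with donor age
and with the composition of the tissue's T-cell compartment. The pipeline
is: cell quality control → library-size log-normalization → cell-type-
specific senescence-signature derivation → per-cell scoring → Gaussian-
mixture senescent-cell calling → donor-level composition and correlation
statistics → Mann–Whitney differential expression and hypergeometric
enrichment. This vignette records the models behind each stage, the
parameters that matter, and the design decisions that were genuinely open.

```{r, eval = FALSE}
library(senskin)
sce <- simulate_cohort(sim_config(seed = 7))
sce <- normalize_log(sce[, filter_cells(compute_qc_metrics(sce))])
sig <- derive_signature(sce, "Keratinocyte")
scores <- score_cells(sce, sig)
fit <- fit_score_mixture(scores, seed = 1)
calls <- call_senescent(scores, senescence_threshold(fit), "Keratinocyte")
```

# Cell quality control

A cell is kept iff all of the following hold, with median absolute
deviations (MADs) computed on the full input population:

* total UMI count ≥ 500;
* |log1p(total) − median| ≤ 5 MAD;
* |log1p(detected genes) − median| ≤ 5 MAD;
* mitochondrial percentage ≤ 15 %, and ≤ 4 MAD above the median.

Three choices here were open and are worth stating. First, the MAD is
*unscaled* (no 1.4826 normal-consistency factor) and applied on the log1p
scale for totals and detected genes — the established single-cell practice
for outlier QC on right-skewed count summaries. Second, the count rules are
two-sided (a cell with an implausibly *high* library is as suspect as a
shallow one, being a doublet candidate) while the mitochondrial rule is
one-sided: low mitochondrial content is not a defect. Third, when a
metric's MAD is zero (e.g. a homogeneous population) its MAD rule is
dropped with a warning and only the absolute cuts apply — the alternative
(removing everything off the median) is never what a user means. All five
thresholds are fields of `qc_thresholds()`. Doublet detection is not
implemented; an external exclusion barcode list can be passed to
`pipeline_config(exclude_barcodes =)`.

# Normalization

`normalize_log()` rescales each cell to a target library size of 10,000
UMIs and stores `log(1 + scaled)` (natural log) as `logcounts`, leaving raw
counts untouched. Expressing-cell fractions throughout the package are
defined on *raw* counts (> 0), which are invariant to this rescaling;
scoring and differential testing use the normalized layer.

# Signature derivation

For a given cell type, cells are pooled within a young-donor group
(age ≤ 30 y) and an old-donor group (age ≥ 55 y); donors in between
contribute no information to selection. With expressing fractions
\(p_y, p_o\), a gene is admitted iff

\[ p_y < 0.05,\qquad 0.01 < p_o < 0.20,\qquad
   \big(p_o \ge 2.5\,p_y \;\text{or}\; p_o - p_y > 0.05\big). \]

The upper bound on \(p_o\) is what distinguishes a senescence program from
ordinary age-regulated expression: senescent cells remain a minority even
in old tissue, so a gene expressed in most old cells is ageing biology, not
senescence. Two conventions had to be fixed: when \(p_y = 0\) the fold rule
is treated as satisfied (the gene is then gated only by the \(p_o\) band),
and fractions are pooled across donors within each age group rather than
averaged per donor — pooling weights donors by their cell numbers, which is
the right behaviour when per-donor cell counts vary by an order of
magnitude, and a per-donor averaging variant was deliberately not added to
keep the selection rule single-valued. The age cutoffs (30/55) are
configurable in `signature_criteria()`; they leave a buffer of unused
middle-aged donors so that the two groups differ in senescent burden by
construction rather than by thresholding noise.

# Per-cell scoring

The score of a cell is the unweighted mean, over signature genes, of the
per-gene z-scored log-normalized expression, with z computed within the
scored cell population (one cell type). This is the package's own scoring
rule, chosen for three properties: it is monotone in both the breadth and
the strength of signature expression, it is affine-stable (adding or
rescaling the score axis moves the mixture fit and the decision threshold
coherently, so calls are invariant), and it has no free weights to tune.
Published per-gene-weighted senescence scores exist, but their weights are
not reproducible from a count matrix alone; the unweighted z-mean is the
transparent default. Zero-variance genes contribute zero; signature genes
absent from the matrix are dropped with a warning.

# Mixture calling

Scores within a cell type are modelled as a univariate Gaussian mixture
with K ∈ {2, 3} components, fitted by EM (10 restarts per K from seeded
k-means++ initializations, log-space responsibilities, a relative
log-likelihood tolerance of 1e-6, and a variance floor of 1e-8 times the
score variance to block the classic single-point singularity). K is chosen
by BIC — "the shape of the distribution decides K" made operational. Fits
whose component means collapse together are discarded in favour of the
other candidate K.

The decision threshold is the point between the means of the two
*rightmost* components at which their weighted densities are equal — the
posterior decision boundary restricted to that interval. The restriction
matters for K = 3: the left components model the non-senescent bulk and
take no part in the boundary. With heavily overlapping components the
weighted densities may not cross between the means at all; the threshold
then falls back to the inter-mean midpoint, with a warning. One consequence
is documented honestly: on a genuinely unimodal score distribution the
fallback can sit near the middle of the data and flag a large fraction of
cells — the mixture threshold is only meaningful when a high-score
subpopulation exists, which is why `fit_score_mixture()` refuses fewer
than 50 scores and the pipeline skips cell types below
`min_cells_per_type`. Calls use a strict inequality: a score exactly at
the threshold is not senescent.

# Donor-level composition and correlation

`subset_proportions()` reports Th/Tc/Treg counts and proportions under both
denominator conventions — relative to the total T-cell pool, and relative
to all cells of the donor — because the two answer different questions
(internal T-compartment balance vs absolute tissue representation), and
keeps the immunological indices Th/Tc, Treg/Tc, Treg/Th, which are
undefined (NA, never zero) when the denominator subset is absent.

Donors with unreliable estimates are removed by the 2-SD rule: for the
cell type concerned, a donor whose cell count falls below the across-donor
mean minus two standard deviations is excluded. The SD is the population
(ddof = 0) form and the rule is one-sided — a donor with unusually *many*
cells is not a problem. Both choices are switchable arguments.

`spearman_cor()` uses average ranks for ties, the Pearson correlation of
ranks, and a two-sided p from the t distribution with n − 2 df — adequate
at the cohort sizes this package targets (tens of donors). Multiplicity is
handled by Bonferroni with the family defined as one correlation scan
(`burden_association_scan()` records m in every row); this per-scan family
is the package's default and any other family can be formed by calling
`bonferroni_adjust()` with an explicit m.

# Differential expression and enrichment

Cells (not donors) are the test units, matching standard single-cell
rank-test usage; this is a pseudoreplication-prone convention, which is why
group sizes and a donor-level view of the same contrast (via
`senescent_fractions()`) should accompany any claim. Per gene,
`mann_whitney_u()` computes U from midranks and a two-sided p from the
tie-corrected normal approximation with continuity correction; for pooled
sizes ≤ 12 an exact p by full enumeration of group assignments
(conditional on the observed ties) is available. A gene passes for a
target group iff BH FDR < 0.01, expressing fraction > 10 % in the target
group and < 50 % in the comparison group, and its mean normalized
expression is higher in the target group; the rule is evaluated once per
direction, since "presence in the target group" is direction-specific.

`ora_hypergeometric()` tests DEG lists against GMT gene sets with the
upper-tail hypergeometric p after intersecting each set with the assayed
universe and dropping sets outside 10–500 genes, then BH across tested
sets. Grouping of enriched sets into narrative categories is left to the
analyst.

# The synthetic cohort generator

`simulate_cohort()` is first-class, tested code: it is the ground-truth
instrument against which every downstream stage is validated. Its defaults
describe the study conditions the package targets: 32 donors with ages
evenly spaced over 18–76 years (uniform random draws optional), ~300 cells
per donor split over keratinocytes, fibroblasts and a T pool (Th 0.45,
Tc 0.40, Treg 0.15 of T — a plausible skin T-compartment balance), and
~1,000 genes with negative-binomial counts whose per-gene means are
lognormal (meanlog log 0.3, sdlog 1.5, size 1), giving ~900 UMIs per cell.
A per-donor lognormal size factor (sd 0.1 on the log scale) acts as a
batch effect.

Each terminal cell type carries a 30-gene senescence program. A cell is
senescent with probability interpolating linearly in donor age from
f_young = 0.02 to f_old = 0.30 — the simplest monotone model consistent
with age accumulation. In a senescent cell each program gene switches on
with probability 0.5 and then counts `1 + NB(boost_mean − 1)` with
boost_mean = 3, over a 1 % background expressing rate. These values are
deliberately coupled to the selection criteria: old-donor expressing
fractions land inside the (1 %, 20 %) admission band while young fractions
stay below 5 %, so the generator produces signatures the derivation stage
can legitimately find. The burden→composition link applies a slope of 4 on
the log-weight scale of the T-subset proportions (Treg up, Th down, in the
donor's centred expected burden); no published coefficient exists for this
effect, so the default is a free parameter chosen to give a clearly
detectable but not deterministic association at ~30 donors.

What the generator does **not** emulate: transcriptome-wide co-expression
structure, doublets, ambient RNA, cell-type misannotation, or spatial
organisation. Passing tests therefore demonstrate that the statistical
machinery recovers planted structure under idealized noise — not that any
biological dataset contains such structure.

# Problem sizes and numerical settings used by the test suite

The suite validates each rule against brute-force oracles on ≥ 1,000
randomized instances, the rank/tail statistics against exact enumeration,
mixture recovery on 20 seeds of a planted 0.5·N(0,1) + 0.5·N(6,1) sample of
2,000 scores, end-to-end call recovery on a 30-donor ~5,000-cell cohort,
composition-scan detection and type-I control on 20 planted and 200 null
replicates (composition-level, with ground-truth flags as calls, since
gene counts do not enter composition), and DEG recovery on 20 replicates
of a 12-donor T-cell cohort. These sizes were chosen so the whole suite
exercises every guarantee at meaningful scale while remaining comfortable
to run locally.

# Known limitations

* The scoring rule is this package's own; it will not numerically
  reproduce scores from weighted senescence-scoring tools.
* GMM thresholds are unstable when no high-score subpopulation exists
  (see the midpoint-fallback discussion above); inspect `fit$bic` and the
  component structure before trusting calls on weakly separated scores.
* Cell-level DEG p-values ignore donor structure; use the pseudobulk view
  of the same contrast before interpreting small effects.
* Cell-type labels are an input. Annotation error propagates directly
  into signatures, calls and composition tables.
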