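# senskin

Quantifying senescent-cell accumulation in multi-donor skin scRNA-seq
cohorts and relating it to T-lymphocyte composition.

## The problem

Senescent cells — growth-arrested cells with a pro-inflammatory secretory
phenotype (SASP) — accumulate with age and are normally cleared by the
immune system. Whether tissue-resident T cells track that accumulation is a
question one can ask directly of multi-donor single-cell RNA-seq data: score
every cell for a senescence program, call senescent cells, and correlate the
per-donor senescent burden with donor age and with the balance of T-helper
(Th, CD4+), cytotoxic (Tc, CD8+) and regulatory (Treg) T cells.

Canonical senescence markers transfer poorly between cell types, so `senskin`
derives a *cell-type-specific* signature from the data itself, scores and
calls cells against it, and provides the donor-level composition and
differential-expression statistics around it. A synthetic-cohort generator
with known ground truth makes every stage testable without any download.

## The method

For each cell type, with cells pooled into young (age ≤ 30 y) and old
(age ≥ 55 y) donor groups and *p*ᵧ, *p*ₒ the expressing-cell fractions
(raw count > 0) of a gene:

**Signature selection.** A gene enters the senescence signature iff

- *p*ᵧ < 0.05 (rare in young donors),
- 0.01 < *p*ₒ < 0.20 (present but still a minority in old donors), and
- *p*ₒ ≥ 2.5 · *p*ᵧ **or** *p*ₒ − *p*ᵧ > 0.05.

**Scoring.** Each cell's senescence score is the unweighted mean over
signature genes of the z-scored log-normalized expression (library-size
normalization to 10,000 UMIs, natural log1p), z computed within the scored
cell population.

**Calling.** A univariate Gaussian mixture (K ∈ {2, 3}, EM with k-means++
restarts, K chosen by BIC) is fitted to each cell type's scores; the
decision threshold is the point between the means of the two *rightmost*
components where their weighted densities are equal (midpoint fallback when
they do not cross). Cells strictly above the threshold are senescent.

**Donor-level statistics.** Subset proportions under two denominators (the
total T pool, or all cells), immunological indices Th/Tc, Treg/Tc, Treg/Th,
a 2-SD low-cell-count donor exclusion rule, and Spearman correlation scans
(t-approximation, Bonferroni within each scan) of T-cell metrics against
age and senescent burden.

**Differential expression.** Mann–Whitney U per gene (old vs young cells of
a T subset; tie-corrected normal approximation, exact enumeration for tiny
groups), BH FDR, and pass filters FDR < 0.01, target-group presence > 10 %,
comparison-group presence < 50 %; plus hypergeometric over-representation
analysis against user-supplied GMT gene sets.

Cell QC precedes everything: keep a cell iff total UMIs ≥ 500, |log1p
total − median| ≤ 5 MAD, |log1p detected genes − median| ≤ 5 MAD,
mitochondrial fraction ≤ 15 % and ≤ 4 MAD above the median (unscaled MADs).

## Worked example

```r
library(senskin)

sce <- simulate_cohort(sim_config(n_donors = 12, seed = 7))
sce <- sce[, filter_cells(compute_qc_metrics(sce))]
sce <- normalize_log(sce)

sig <- derive_signature(sce, "Keratinocyte")
sig
#> senescence signature for cell type 'Keratinocyte': 43 of 1005 genes
#> included (432 young / 489 old cells)
head(subset(as.data.frame(sig), included), 3)
#>       gene    cell_type    p_young     p_old     fold   abs_diff included
#> 1 GENE0001 Keratinocyte 0.02777778 0.1390593 5.006135 0.11128153     TRUE
#> 2 GENE0002 Keratinocyte 0.03703704 0.1206544 3.257669 0.08361736     TRUE
#> 3 GENE0003 Keratinocyte 0.04166667 0.1349693 3.239264 0.09330266     TRUE

scores <- score_cells(sce, sig)
fit <- fit_score_mixture(scores, seed = 1)
#> selected K = 3; component means: -0.21, -0.06, 0.86
thr <- senescence_threshold(fit)     # 0.211
calls <- call_senescent(scores, thr, "Keratinocyte")

fr <- senescent_fractions(calls, sce)
pooled <- subset(fr, cell_type == "(all)")
round(setNames(pooled$fraction, pooled$donor_id), 3)
#>   D01   D02   D03   D04   D05   D06   D07   D08   D09   D10   D11   D12
#> 0.028 0.071 0.087 0.091 0.135 0.135 0.242 0.163 0.233 0.204 0.295 0.293
spearman_cor(pooled$fraction, pooled$age_years)
#> rho = 0.94, p = 3.9e-06
```

The signature table shows, per gene, the young/old expressing fractions and
which selection rule admitted it; the mixture's rightmost component (mean
0.86) captures the high-scoring senescent population and the threshold
0.211 separates it from the bulk; the per-donor pooled senescent fraction
rises from ~3 % at age 18 to ~29 % at age 76, and its rank correlation
with age is strongly positive — the age-accumulation pattern the pipeline
is designed to detect.

`run_pipeline(input, out_dir, pipeline_config(...))` chains all stages
(QC → signatures → scoring/calling → composition/correlation → DEG → ORA)
and writes TSV tables plus a JSON manifest with output checksums; identical
input, config and seed reproduce bit-identical outputs.

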