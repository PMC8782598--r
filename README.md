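# ldnb — landscape dynamic network biomarker analysis

`ldnb` detects **tipping points** — the last predisorder state before a
critical transition — in time-series gene expression data, using the
landscape dynamic network biomarker (l-DNB) framework. It is aimed at
systems-biology analyses of designs with a reference (untreated) cohort and
a treated cohort sampled over time with replicates, such as 3D skin models
under repeated UV irradiation, where the question is *when* the system
commits to a phenotype change (e.g. irreversible pigmentation / lightness
loss) and *which genes* signal it first.

## The method in brief

For each case sample `d` against `n` reference samples, the **single-sample
network** (SSN) contains the gene pairs whose Pearson correlation is
significantly perturbed by adding that one sample:

    sPCC_n(x, y) = PCC_{n+1}(x, y) − PCC_n(x, y),
    z = sPCC · (n − 1) / (1 − PCC_n²)   (two-sided normal test)

Each gene's **local module** (the gene plus its first-order SSN neighbors,
bounded by its second-order neighbors) is scored by the three DNB
conditions — deviation up, internal correlation up, external correlation
down:

    I_s(x) = sED_in · sPCC_in / sPCC_out

A sample's DNB score is the mean of its top-K local scores, a time point's
score is the mean over its samples, and the **tipping point** is the time
with the maximal score. **DNB genes** rank in the top K in at least two
tipping-time samples. Around the tipping point the package derives fused
replicate networks, prior/posterior **differential (rewiring) networks**,
their hub genes (TP-DNGs) and differentially expressed genes (TP-DEGs), and
prioritizes **core DNB genes** against an anchor-signature list over a PPI
background (with a Fisher exact overlap test). A modified survival-style
**risk test** (fixed group sizes, χ²(1)) validates candidate genes against
phenotype-decline events in an independent cohort.

A synthetic-data module generates the full study design — reference and
treated time series with a planted DNB module at a known tipping time, a
declining phenotype, a background PPI, and a two-arm validation cohort —
so every claim the package makes is testable against known ground truth.

## Worked example

```r
library(ldnb)

cfg <- sim_config(seed = 7)                       # 300 genes, planted 10-gene module, tipping at T5
sim <- simulate_expression(cfg)
ppi <- simulate_ppi(rownames(sim$expr), sim$module_genes, p = 0.02,
                    seed = cfg$seed + 30000)

res <- ldnb_analyze(sim$expr, sim$annotation,
                    ldnb_config(top_k = 60),      # K scaled to the 300-gene panel
                    background = ppi,
                    signatures = sim$module_genes[1:5], ppi = ppi)
print(res$tipping)
```

```
l-DNB tipping-point call
 time_label time_order    score n_samples
         T1          1 1.609995         2
         T2          2 1.717429         2
         T3          3 1.970372         2
         T4          4 1.531766         2
         T5          5 2.353353         2
         T6          6 1.930609         2
         T7          7 1.554226         2
         T8          8 1.619149         2
tipping point: T5
```

The planted transition time T5 attains the maximal time-point DNB score.
Eight of the ten planted module genes are recovered as DNB genes, and the
core-gene stage finds the planted signatures with a strongly significant
PPI-neighborhood overlap:

```r
print(res$core)
```

```
Core DNB gene selection
  phenotype-related genes: 36
  DNB overlap: 9 of 12 DNB genes (Fisher p = 3.32e-07)
  core genes: G0022, G0059, G0090, G0103, G0118
  candidate genes: G0218, G0271, G0298
```

The file-based pipeline (`run_pipeline()`, or `inst/cli/ldnb.R` from a
shell) reads TSV inputs and writes per-sample SSN edge lists, the score
table, `tipping_point.json`, fused/differential networks, `core_dnb.json`
and the risk table. `simulate_bundle()` writes a complete synthetic input
set to a directory.

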