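# yaptaz

Quantitative analysis of YAP/TAZ expression, subcellular localization and
the CIN25 chromosomal-instability signature in cholangiocarcinoma (CCA).

The Hippo pathway effectors YAP and TAZ (WWTR1) are transcriptional
co-activators that shuttle between the nucleus (active) and the cytoplasm
(inactive) in response to cell density. In bile-duct cancer they are
studied through four complementary readouts, each of which this package
implements as a tested, reusable workflow for tidyverse users:

1. **Semiquantitative IHC scoring on tissue microarrays.** Per core,
   score = quantity (0–4) × intensity (0–3) ∈ {0,1,2,3,4,6,8,9,12}; per
   tumor, the mean of two cores; classes low (0–3), intermediate
   (3.5–7.5), high (8–12); positivity cross-tabulated per compartment as
   YAP / TAZ / exactly-one (`YAP + TAZ − 2·both`) / both.
2. **Nuclear/cytoplasmic ratio quantification.** Two-channel fields
   (DAPI + stain) are segmented (smoothed Otsu + connected components;
   cytoplasm = cell region minus nuclei), and the field-level ratio
   `mean nuclear intensity / mean cytoplasmic intensity` is stratified by
   cell density at the mean nucleus count, with Mann-Whitney comparison
   and a ratio-on-count regression.
3. **CIN25 signature scoring with survival stratification.** CPM →
   log2(CPM+1) → per-gene z-scaling across all samples → per-sample sum
   (scores sum to 0 by construction); k-means (k = 3, Lloyd, 25 seeded
   restarts) on the scaled signature submatrix; median dichotomization;
   Kaplan-Meier curves and the log-rank (Mantel-Cox) test.
4. **Knockdown readouts.** 2^−ΔΔCt relative expression against a reference
   gene (B2M/RPL41) and the scrambled-siRNA control, fold-of-control
   assay normalization, and genes × conditions heatmap tables.

Every input family has a seeded synthetic generator
(`simulate_tma_cohort()`, `simulate_if_field()`,
`simulate_expression_cohort()`, `simulate_knockdown_plate()`) with known
ground truth, so each stage carries parameter-recovery tests. The
inferential core (Mann-Whitney with exact enumeration, Spearman, OLS) is
implemented in-package and validated against brute-force oracles. All
p-values are two-sided; no multiple-testing correction is applied
anywhere.

See `vignettes/yaptaz-methods.Rmd` for the full account of models,
parameters and design choices.

## Worked example

```r
library(yaptaz)
library(dplyr)

# --- IHC: simulate a 152-tumor cohort, score it, cross-tabulate ---
cohort <- simulate_tma_cohort(tma_cohort_spec(seed = 1))
scored <- score_tumors(cohort$cores)
positivity_table(scored, cohort_label = "synthetic iCCA-like")
#> # A tibble: 3 × 10
#>   row           n   yap   taz exactly_one  both yap_pct taz_pct exactly_one_pct
#> 1 nuclear     152    61    49          74    18    40.1    32.2            48.7
#> 2 cytoplasmic 152    36     5          39     1    23.7     3.3            25.7
#> 3 union       152    84    54          82    28    55.3    35.5            53.9
```

The generator planted nuclear YAP positivity 0.395; the scored cohort
recovers 61/152 = 40.1% within binomial error, and the exactly-one column
satisfies `yap + taz − 2·both` row by row.

```r
# --- localization: density-dependent nuclear exclusion ---
dens <- density_analysis(simulate_field_measurements(seed = 1))
dens
#> Density analysis of 200 fields (threshold 34.48 nuclei/field)
#>   low: 95 fields, high: 105 fields
#>   Mann-Whitney U = 9333, p = 2.17e-26 ***
#>   regression: nc_ratio = 2.916 -0.02747 * count
```

The planted ratio-on-count slope was −0.03: low-density fields show
nuclear enrichment, high-density fields nuclear exclusion, and the
regression recovers the planted slope.

```r
# --- CIN25: score, cluster, stratify survival ---
spec <- expression_cohort_spec(seed = 1) # 104 tumors, 6 normals, 25% planted
co <- simulate_expression_cohort(spec)
logcpm <- cpm_normalize(co$counts, log2 = TRUE)
scores <- score_signature(logcpm, spec$signature_genes)
clusters <- kmeans_cluster(logcpm, genes = spec$signature_genes, k = 3, seed = 1)
cluster_recovery(clusters, scores, co$samples)[c("ari", "prevalence")]
#> $ari        [1] 1
#> $prevalence [1] 0.236364
```

k-means recovers the planted high-CIN cluster exactly (adjusted Rand
index 1) at ~25% prevalence.

```r
# --- knockdown: 2^-ddCt fold changes vs scrambled control ---
rq <- ddct(simulate_knockdown_plate(knockdown_plate_spec(seed = 1)))
filter(rq, gene == "WWTR1")
#>   condition   gene  delta_ct delta_delta_ct    rq  rq_sd n_replicates
#> 1 scrambled   WWTR1     7.12          0     1     0.126             3
#> 2 siTAZ       WWTR1     9.16          2.04  0.244 0.0424            3
#> 3 siYAP       WWTR1     6.83         -0.292 1.22  0.190             3
#> 4 siYAP+siTAZ WWTR1     9.48          2.36  0.195 0.0149            3
```

The planted TAZ residual fraction under siTAZ and the combined silencing
was 0.2; the recovered RQ is 0.24/0.20 under Ct noise, and the scrambled
control is 1 by construction.

The full synthetic end-to-end pipeline, with TSV/JSON outputs and a
provenance-stamped summary, is one call:

```r
run_demo(seed = 1, out_dir = "demo_out")
```

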