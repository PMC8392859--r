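# riverwq

Multivariate assessment of river water quality and apportionment of
pollution sources from long-term, multi-site monitoring records.

Water-quality agencies accumulate decades of monthly measurements —
nutrients, organic matter, solids, conductivity, chlorophyll, coliforms —
across dozens of sites, and the recurring analytical questions are always
the same: how good is the water (index it), is it getting better or worse
(trend it), which sites behave alike (cluster them), what distinguishes
sites and seasons (discriminate), and *where is the pollution coming from*
(apportion it). `riverwq` packages that entire toolkit for the eleven
routinely monitored parameters pH, WT, DO, EC, TSS, TP, TN, BOD, COD,
CHL-a and TCB, aimed at limnologists and environmental data analysts.

## What is implemented

* **Water Quality Index** (weighted arithmetic): unit weights
  `W_n = K / S_n` with `K = 1 / Σ(1/S_n)` (so `Σ W_n = 1`), sub-indices
  `Q_n = (V_n − V_0)/(S_n − V_0) × 100`, overall score
  `WQI = Σ W_n Q_n / Σ W_n`, classes from excellent (≤25) to unsuitable
  (>100).
* **PMF receptor model**: `X = GF + E` with `G, F ≥ 0`, minimizing
  `Q = Σ ((x_ij − Σ_k g_ik f_kj)/u_ij)²` with EPA-style uncertainties
  `u = sqrt((EF·x)² + (0.5·MDL)²)` (and `5/6·MDL` below detection).
  Exact alternating non-negative least squares with monotone-safe
  extrapolation, NNDSVD + random multi-start, and Table-style
  apportionment output (concentration and percentage contributions, R²).
* **Mann–Kendall trend tests** with tie-corrected variance and continuity
  correction, per site × parameter.
* **Bray–Curtis hierarchical clustering** of sites with a similarity-cut
  grouping (default 60%).
* **Stepwise discriminant analysis** on Wilks' Λ partial-F entry/removal
  (3.84 / 2.71), linear classification functions, classification matrices.
* **PCA/FA** on the correlation matrix, varimax rotation with Kaiser
  normalization, KMO and Bartlett sphericity diagnostics,
  strong/moderate loading labels.
* **Correlation networks** filtered at p < 0.05, per season or overall;
  log–log chlorophyll–nutrient regressions; pre/post-impoundment fold
  changes; trophic / coliform / organic-pollution classifications.
* **A synthetic monitoring-data generator** with known 3-source ground
  truth, monsoon modulation and injected trends, so every method above has
  a recovery test without redistributing agency data.

## Worked example

```r
library(riverwq)

# 16 sites x 15 years of monthly samples from the known 3-source model
d <- generate_dataset(generator_config(), seed = 42)

# PMF source apportionment (pH/DO excluded as non-source-like)
keep <- setdiff(wq_parameters(), c("pH", "DO"))
X <- d$matrix$values[, keep]
fit <- fit_pmf(X, uncertainty_matrix(X, ef = 0.1), p = 3, n_starts = 5,
               seed = 42)
apportion(fit, X)
```

The apportionment table prints one row per parameter; percentage columns
sum to 100:

```
  parameter pct_f1 pct_f2 pct_f3   r2
1        WT    7.2   70.8   21.9 0.84
2        EC    1.3   98.7    0.0 0.87
5        TN   42.0   14.1   43.9 0.87
8     CHL-a    4.4    5.5   90.1 0.94
9       TCB   93.8    5.3    0.9 0.76
```

Factor 1 takes 93.8% of total coliforms (the agriculture/livestock
signature), factor 2 takes 98.7% of conductivity (background/ionic), and
factor 3 takes 90.1% of chlorophyll with most BOD/COD (the point-source
signature). Checked against the generator's truth, the matched profiles
have share-normalized cosine similarity
(0.990, 0.993, 0.995 per factor) and the contribution series correlate
0.99/0.92/0.91 with the true source activities.

```r
# Water Quality Index per site and season
head(wqi_report(d$matrix)$report)

# Mann-Kendall trends per site x parameter
trends <- trend_report(d$matrix)
table(trends$parameter, trends$direction)[c("COD", "TP"), ]
#>        decreasing increasing no trend
#>   COD           0         11        5
#>   TP           16          0        0
```

The injected −3%/yr TP decline is detected at all 16 sites; the weaker
+2%/yr COD rise reaches significance at 11 of 16.

The `analysis/` directory holds the full narrated workflow as numbered
scripts (`01_simulate.R` … `07_network_regression.R`); each writes its
tables under `results/`.

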