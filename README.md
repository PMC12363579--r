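# fxtrend

Trend analysis and time-series clustering of per-fraction dose deviations in
fractionated radiotherapy.

## What problem this solves

When a radiotherapy course (e.g. 60 Gy in 30 daily fractions for
non-small-cell lung cancer) is monitored with daily in-room imaging, the
dose actually delivered at each fraction can be recomputed and compared to
the plan. That yields, per patient, fraction and parameter, one scalar: the
percentage deviation from the planning-CT baseline,
`d = 100 (x − x_plan) / x_plan`. Monitored parameters are target and
organ-at-risk (OAR) volumes (GTV, CTV, PTV, lungs, esophagus, heart,
spinal cord) and dose metrics (target D95; OAR Dmean/Dmax).

`fxtrend` answers two questions for physicists and biostatisticians running
offline adaptive-radiotherapy (ART) programmes:

1. **At what rate does each parameter drift, and when does the drift first
   become significant?** Pooled least squares with Cook's-distance outlier
   screening (capped at 6.2% of points), a random-intercept linear mixed
   model `d_if = β0 + β1 f + u_i + ε_if` (REML, AR(1) within-patient
   residuals) for the deviation rate β1 with its Wald 95% CI, and
   Bonferroni-corrected per-fraction t-tests (α/F) whose earliest
   significant fraction is a candidate ART trigger.
2. **Which patients share a deviation trajectory?** Dynamic time warping
   (DTW) between patients' deviation series, a per-patient
   "distinctiveness" statistic (mean DTW dissimilarity to the rest of the
   cohort), k-means on the rows of the DTW distance matrix for paired
   (target D95, OAR dose) 2-D series, the elbow-plus-one rule
   (`k_used = k_elbow + 1`) for the cluster count, and exclusion of
   clusters with fewer than 10 members as outlier cases. Retained clusters
   are summarised as mean trajectories with normal-approximation 95% bands
   (`mean ± 1.96 s/√n`).

Because per-fraction patient tables of this kind are not publicly
deposited, the package ships a synthetic-cohort generator
(`simulateCohort`) calibrated to the published trend table of a 40-patient
cohort: linear per-fraction ramps (GTV −0.33 %/fraction, CTV −0.24,
Lung Dmean +0.13, ...), course-average deviations (GTV −9.79%, ...),
patient-level offsets, AR(1) serial noise with a planted low-variability
majority cluster and a 3×-noisier minority cluster, and sparse
high-leverage outlier points. See the methods vignette
(`vignettes/dose-deviation-monitoring.Rmd`) for the model and every
calibration identity.

## Worked example

```r
library(fxtrend)

sim    <- simulateCohort(defaultCohortConfig(), seed = 1)  # 40 patients x 30 fx
cohort <- buildCohort(sim$records)                         # SummarizedExperiment

trendTable(cohort, parameters = c("GTV", "CTV", "PTV", "Lung_Dmean"))
#>    parameter average_deviation  slope ci_low ci_high earliest_significant_fraction n_outliers_removed
#> 1        GTV             -9.92 -0.324 -0.352  -0.296                             4                 68
#> 2        CTV             -7.09 -0.258 -0.275  -0.242                             5                 50
#> 3        PTV             -5.22 -0.188 -0.204  -0.171                             9                 65
#> 4 Lung_Dmean              3.82  0.132  0.122   0.142                             1                 61
```

The GTV shrinks by ~0.32% of its planned volume per fraction (mixed-model
95% CI −0.352 to −0.296), its cohort-average deviation over the course is
−9.9%, and its deviation first becomes Bonferroni-significant at fraction
4 — an early-response signal. The lung mean dose creeps *up* by ~0.13% per
fraction.

```r
dt <- distinctivenessTable(cohort)   # DTW distinctiveness of GTV/CTV/PTV D95
round(dt$variance, 1)
#> GTV_D95 CTV_D95 PTV_D95
#>     9.0     4.1   904.9
selectRepresentative(dt$variance)$parameter
#> [1] "CTV_D95"

cl <- clusterCohort(cohort, oar = "Lung_Dmean")   # 2-D series: CTV_D95 + OAR
cl
#> ClusterResult [CTV_D95 + Lung_Dmean]: k_elbow = 2, k_used = 3
#>   cluster sizes: 1:7 2:20 3:13
#>   retained (>= 10 members): 2, 3 | outlier patients: 7
```

CTV_D95 has by far the most stable distinctiveness (variance 4.1 vs 904.9
for PTV_D95) and represents target coverage in the 2-D clustering. The
elbow sits at k = 2; clustering with k + 1 = 3 retains two clusters of 20
(stable) and 13 (fluctuating) patients and excludes a 7-patient cluster as
outlier cases. `clusterTrajectories(cohort, cl)` then gives each retained
cluster's mean deviation band per fraction (CTV_D95 stays within 1% of
plan in both clusters; `plotTrajectories` draws the bands).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/fxtrend.R` (subcommands `simulate`, `trends`, `dtwmat`,
`cluster`, `report`).

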