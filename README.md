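# ddpp

Prognostic analysis of paired tumor/normal lung transcriptomes for resected
non-small-cell lung cancer (NSCLC). The package implements the Digital
Display Precision Predictor (DDPP) — a per-patient risk score built from
differential gene expression between a patient's tumor and their own normal
lung tissue — together with a normal-tissue immune-checkpoint tolerance
classifier, the survival statistics used to evaluate both, the specificity
and bootstrap-stability validation designs, and a fully seeded synthetic
cohort generator for parameter-recovery testing.

It is aimed at translational researchers who want to stratify post-surgery
recurrence risk from paired tumor/normal expression profiles, and at
methodologists who want a tested, deterministic reference implementation of
the DDPP procedure to probe on simulated cohorts.

## The model

For gene *g* in patient *p*, the elementary quantity is the **gene weight**

```
w[g, p] = log2( T[g, p] / N[g, p] ) * log1.1( I[g, p] )
```

where `T` and `N` are linear-scale intensities in tumor and matched normal
tissue and `I` is the intensity in a designated tissue (tumor or normal).
Using each patient as their own control removes inter-patient baseline
variability; the `log1.1` factor up-weights fold-changes observed at high
absolute expression.

Within each histology-by-treatment group (AC/SCC/LCC crossed with adjuvant
chemotherapy vs surgery only), every gene's weight is Pearson-correlated
with disease-free survival (DFS, months) and gated at Benjamini–Hochberg
FDR < 0.05. A search over intensity source × aggregation mode
(median/mean/sum) × signature size k selects the gene set whose aggregate
best correlates with DFS; ordinary least squares then gives the group's
**correlator**

```
DFS ≈ intercept + slope * aggregate(w[signature, p])
```

A patient's **DDPP score** is the predicted DFS from their group's
correlator. Pooled scores are cut by exact one-dimensional k-means (k = 2);
the lower cluster (shorter predicted DFS) is **DDPP low**, the high-risk
class. Independently, normal-tissue expression of CTLA-4, PD-L1 and ICOS is
clustered high/low per gene: patients high for all three are
**immune-tolerant**, patients with CTLA-4 low but PD-L1 and ICOS high are
**immune-competent**. Kaplan–Meier/log-rank comparisons and Cox
proportional-hazards models (Efron ties) quantify the prognostic value of
stage, histology, DDPP class and immune status.

## Worked example

```r
library(ddpp)

cfg <- synth_config(n_genes = 2000, seed = 42)   # 123-patient synthetic cohort
coh <- generate_cohort(cfg)
fit <- ddpp(coh$expression, coh$clinical)
summary(fit)
```

```
Per-group DDPP correlators:
   group  n n_genes mode source slope intercept  fit_r     fit_p
1  AC:NC 24      10 mean  tumor 5.012     47.45 1.0000 2.205e-48
2  AC:CT 33      10 mean  tumor 4.997     47.50 1.0000 2.238e-66
3 SCC:NC 32      15 mean  tumor 5.000     47.51 1.0000 1.363e-67
4 SCC:CT 18       7 mean  tumor 5.012     47.43 1.0000 1.006e-33
5 LCC:NC  6       4 mean normal 5.042     47.29 1.0000 6.969e-13
6 LCC:CT 10       7 mean  normal 4.969     47.73 0.9999 3.405e-17

Risk classes: 69 high, 54 low; threshold 47.203 months (centers 24.498 / 69.597)
```

Each row is one group's fitted correlator: the signature size, aggregation
mode and intensity source chosen by the search, and the linear map from
aggregate weight to DFS (here the generator's planted link, slope 5 and
intercept 47.5 months, is recovered almost exactly). The threshold is the
k-means cut on the pooled predicted-DFS scale: 54 patients fall in the
short-DFS (high-risk) class.

```r
st <- immune_status(coh$expression)
st
#> Normal-tissue immune status (CTLA4, PDL1, ICOS):
#>   tolerant 28, competent 17, other 78

suite <- stratified_km_suite(fit$scores, st, coh$clinical)
suite$comparisons$ddpp_immune_3arm$logrank
#> Log-rank test: chisq = 31.238 on 2 df, p = 1.65e-07
```

The three-arm comparison (DDPP-low + tolerant vs DDPP-high + competent vs
all other combinations) shows median DFS of 10.3, 69.6 and 54.0 months
respectively on this cohort — the combined biomarker isolates the
shortest-survival stratum.

`run_ddpp_pipeline(pipeline_config(synth = cfg, seed = 42))` runs the whole
analysis (fit, immune status, the 13-comparison KM suite, univariate and
multivariate Cox models, optional validation) and `write_report()`
serializes it as `report.json` plus flat TSV tables.

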