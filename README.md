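# methet

Quantifies **intra-patient inter-metastatic DNA copy-number
heterogeneity** and **genomic complexity** from SNP-array-like log R ratio
(LRR) data, with the downstream prognostic statistics. It is written for
analysts of multi-deposit tumour cohorts — typically colorectal cancer
liver metastases, where several deposits are resected from the same
patient — who want to ask: *how different are one patient's metastases
from each other, and does that difference predict outcome?*

## What it computes

Given probe-level log ratios for many deposits, the pipeline

1. removes control, duplicate, allosomal and recurrent-artefact probes
   (the artefact blacklist is built from non-cancer cohorts: regions with
   aberration frequency > 10% in *every* cohort);
2. winsorizes outliers and fits the exact piecewise-constant segmentation
   (PCF): the minimizer of
   `Σ_segments Σ_{i∈seg} (y_i − ȳ_seg)² + γ·(#segments − 1)` with ≥ k_min
   probes per segment (defaults γ = 100, k_min = 5 for full-density
   arrays), by dynamic programming; a joint multi-sample variant shares
   breakpoints across a patient's deposits;
3. cuts the genome into **atomic segments** at the union of all samples'
   breakpoints, making profiles comparable as vectors;
4. scores each patient's heterogeneity as the mean pairwise **Euclidean
   distance** `√Σ_s (a_s − b_s)²` over atoms with cross-sample variance
   > 0.03, and alternatively as the mean pairwise **per cent of base
   pairs** whose estimates differ by > 0.1; ploidy-adjusted and
   longitudinal (first vs second resection) variants included;
5. scores each deposit's **genomic complexity** as the per cent of base
   pairs with estimates beyond ±0.1, and quantifies copy-neutral LOH from
   allele-specific profiles (allele copies {0,2});
6. clusters deposits (complete linkage, Euclidean) with **multiscale
   bootstrap** AU/BP cluster support;
7. runs the survival analyses: 3-year Kaplan–Meier rates, log-rank test
   of linear trend, Cox models (Efron ties, Wald tests, P < 0.1 screening
   into a one-step multivariable model), Welch t-tests and segment-wise
   tests with Benjamini–Hochberg q-values.

A synthetic multi-deposit cohort generator (clonal ancestor plus
branch-private events, purity dilution, probe noise, survival coupled to
true heterogeneity) provides ground truth for every stage; see the
methods vignette (`vignettes/methet-methods.Rmd`) for the models, the
parameter choices and their rationale.

## Worked example

```r
library(methet)

cfg <- sim_config(n_patients = 10, genome_scale = 0.1, probe_spacing = 1e5,
                  focal_min_bp = 1e7, seed = 7)
cohort <- simulate_cohort(cfg)
cohort$lrr
#> lrr_matrix: 2879 probes x 44 samples on 22 chromosomes

seg   <- segment_profiles(cohort$lrr, seg_params(gamma = 2, kmin = 5))
first <- cohort$clinical$sample[cohort$clinical$resection == 1]
atoms <- atomic_segments(seg[seg$sample %in% first, ], cohort$lrr$probes)
atoms
#> atomic_matrix: 169 atomic segments x 33 samples; 285700022 bp

head(cohort_heterogeneity(atoms, cohort$clinical, "euclidean"), 5)
#>   patient    score n_samples n_pairs
#> 1     P01 4.207491         5      10
#> 2     P02 3.100299         2       1
#> 3     P03 1.952545         3       3
#> 4     P04 6.747285         4       6
#> 5     P05 2.630252         5      10
```

Patient P04's deposits are about three times as divergent as P03's: the
score is the average Euclidean distance between deposits' atomic
copy-number vectors (variance-filtered), so ~6.7 means many atoms differ
or a few differ strongly. Complexity and a median-split survival contrast:

```r
head(cohort_complexity(seg, cohort$clinical)$patients, 3)
#>   patient  percent
#> 1     P01 34.43822
#> 2     P02 31.16906
#> 3     P03 24.90958

het <- cohort_heterogeneity(atoms, cohort$clinical, "euclidean")
grp <- median_split(het$score)
pat <- cohort_patients(cohort$clinical)
three_year_rate(pat$os_time, pat$os_event, grp[match(pat$patient, het$patient)])
#>   group n rate
#> 1   low 5   60
#> 2  high 5    0
```

In this toy cohort, patients with below-median heterogeneity have a 60%
three-year overall survival rate versus 0% above the median — the
generator couples the hazard to true heterogeneity, and the pipeline
recovers the contrast from the rendered probe data.

`run_pipeline(pipeline_config(...))` (or the thin wrapper
`inst/scripts/methet.R`) orchestrates all stages from one configuration
and writes the result tables, a log, and per-patient strata.

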