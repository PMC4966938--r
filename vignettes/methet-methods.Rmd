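---
title: "Quantifying inter-metastatic copy-number heterogeneity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inter-metastatic copy-number heterogeneity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methet)
```

## The problem

When several liver metastases are resected from one colorectal cancer
patient, their DNA copy-number profiles may be nearly clonal copies of each
other or may differ as much as tumours from unrelated patients. `methet`
quantifies this *intra-patient inter-metastatic heterogeneity* from
SNP-array-like total-intensity data (log R ratios, LRR), together with the
*genomic complexity* of each deposit (the fraction of the genome with
aberrant copy number), and relates both to patient outcome. Analyses are
restricted to the 22 autosomes; allosomal signal is confounded by patient
sex and is excluded at load time.

The pipeline is: probe filtering → winsorization → piecewise-constant
segmentation → atomic segments → heterogeneity and complexity scores →
clustering with bootstrap support → survival statistics. A synthetic
cohort generator with known ground truth exercises every stage.

## Probe filtering

Three probe classes are removed before segmentation: control probes,
duplicate probes (two probes covering overlapping loci; the first in
genomic order is kept — the choice is arbitrary but deterministic), and
probes in regions recurrently "aberrant" in non-cancer tissue, which
reflect technical artefacts. The blacklist is built from one or more
non-cancer cohorts: a region qualifies when its aberration frequency
(fraction of samples with |estimate| above the 0.1 cutoff) is strictly
above 10% in *every* cohort — an intersection rule, so a region must
misbehave consistently across tissues to be excluded. Frequencies are
evaluated on atomic segments (see below); whether the original rule was
applied to segments or probe-level calls is not decidable from published
descriptions, and the atomic-segment reading is the one this package
documents and tests. Filtering precedes winsorization, so outlier limits
are estimated from the probes that will actually be segmented.

## Winsorization

Single-probe outliers would otherwise be fitted as one-probe "segments" or
drag segment means. Each value is clamped to the running median ± 2.5
scaled MADs (constant 1.4826), computed in a centered window of 25 probes,
truncated at chromosome ends. The window and multiplier are the
conventional defaults for this preprocessing step. Clamping is idempotent:
values already inside their local bounds are untouched.

## Segmentation model

Copy-number profiles are piecewise constant in expectation. For probe
values $y_1,\dots,y_n$ on one chromosome, the fit minimizes

$$\sum_{\text{segments } S}\ \sum_{i \in S} (y_i - \bar y_S)^2
  \;+\; \gamma\,(\#\text{segments} - 1),$$

subject to every segment containing at least $k_{\min}$ probes. The
package computes the *exact* minimizer by an $O(n^2)$ dynamic program over
the last segment's start (implemented in C++), rather than a fast
approximation: the model is defined by $(\gamma, k_{\min})$ and the test
suite holds the implementation to exact equality with brute-force
enumeration on small instances. Segment means ("copy number estimates")
are the quantities all downstream statistics consume. The joint
multi-sample variant minimizes the summed within-segment error over all of
a patient's deposits with one shared set of breakpoints; because the cost
is additive over samples it is the same dynamic program with a summed
cost, and it reduces exactly to the single-sample fit for one sample.

Segmentation is per chromosome; no arm boundary constraint is imposed.
Coordinates are 1-based inclusive bp. Internally each probe owns the
territory from the midpoint to its left neighbour through the midpoint to
its right neighbour, so every sample's segments tile the identical covered
territory and lengths add up exactly — this makes the bp bookkeeping of
all downstream fractions exact. Missing probe values are imputed before
fitting by nearest-neighbour carry within the chromosome (count reported);
the fit requires dense input and the handful of missing probes on a real
array do not justify a model-based imputation.

### Choosing the penalty for a marker density

The defaults $\gamma = 100$, $k_{\min} = 5$ are the published settings for
full-density SNP 6.0 data (~1.8M markers, median spacing < 700 bp), where
even a 1 Mb focal event spans over a thousand probes. The penalty competes
with a within-segment error sum that grows with the number of probes an
event spans: an interior event of $k$ probes and amplitude $\Delta$ is
resolved only when $k\Delta^2 \gtrsim 2\gamma$ (two breakpoints). On the
scaled synthetic panels used for validation (0.1 genome, 100 kb spacing,
minimum focal span 10 markers, single-copy amplitudes
$|\log_2(3/2)| \approx 0.585$ at full purity) this gives
$\gamma \lesssim 1.7$, while spurious noise segments at probe noise
sd ≤ 0.15 would require deviations of many standard errors and are
effectively impossible for any $\gamma \ge 1$. The package therefore uses
$\gamma = 2$ for the scaled validation cohorts and keeps $\gamma = 100$ as
the default for full-density data. With these settings the measured
complexity recovers the simulated aberrant fraction within 2 percentage
points (tested), and mis-set penalties are visible as a positive bias:
merged mixed segments whose mean crosses the aberration cutoff.

## Atomic segments

Different samples have different breakpoints. Cutting every chromosome at
the union of all samples' breakpoints yields *atomic segments*: intervals
within which every sample is constant, inheriting its parent segment's
estimate. Atoms make profiles comparable as equal-length vectors and are
the substrate of all heterogeneity and complexity statistics. The
partition conserves territory exactly (tested property). By default atoms
are built cohort-wide across all first-resection deposits; a per-patient
alternative (atoms from one patient's deposits only) is available by
subsetting the segment table, and joint segmentation provides a third
route — the two routes agree closely on simulated data, mirroring the high
concordance reported for the original analyses.

## Heterogeneity scores

**Euclidean score.** For two deposits with atom estimates $a, b$, the
distance is $\sqrt{\sum_s (a_s - b_s)^2}$ over atoms — atoms are
*unweighted* dimensions, no bp weighting; the dimensionality is the number
of atoms retained. Before scoring, atoms are filtered to those with
cross-sample variance strictly above 0.03 (sample variance, denominator
$n-1$), computed across **all samples in the analysis set**, not per
patient: the cohort-wide reading is the one consistent with using the same
filter for cohort-wide clustering, and it makes patients' scores directly
comparable because they live in the same atom space. The patient score is
the mean over all unordered pairs of the patient's first-resection
deposits; patients with a single deposit have no defined score and are
reported absent rather than zero. Robustness variants (cutoff 0.05, or no
filter) are one argument away.

**Proportion of the genome different.** For each pair, the summed bp of
atoms whose estimates differ by more than 0.1 (strict), divided by the
total atom bp, in per cent, averaged over pairs; no variance pre-filter.
This is the bp-weighted counterpart of the Euclidean score and is
invariant to refining the atomic partition (tested). The two scores are
strongly correlated on simulated cohorts, as they are on real data.

**Longitudinal score.** For patients resected twice, the mean Euclidean
distance over *cross-resection* pairs only (first × second); the all-pairs
alternative is exposed by a flag. Cross-resection pairs isolate the
longitudinal contrast instead of mixing it with within-resection
heterogeneity.

**Ploidy-adjusted score.** From allele-specific integer profiles
(purity/ploidy-resolved), total copies $n_A + n_B$ per atom divided by the
sample's ploidy, then the Euclidean score with no filter. Dividing by
ploidy removes whole-genome scaling: a diploid profile and its doubled
copy are at distance zero.

**Cancer-cell-fraction diversity.** The mean absolute pairwise difference
in per-sample purity, with missing estimates excluded — a check that
measured heterogeneity is not merely purity variation.

All cutoffs in the package are strict inequalities (variance > 0.03,
|difference| > 0.1, |estimate| > 0.1, frequency > 10%): "higher than" is
read literally, and an estimate exactly at a threshold never changes
category.

## Genomic complexity

Per deposit: 100 × (bp of segments called gain or loss at the ±0.1
cutoff) / (bp of all segments). The denominator is the retained
(post-filter) autosomal territory, not the full genome length — excluded
regions carry no calls and should not dilute the fraction. Patient-level
complexity is the mean over first-resection deposits. Complexity is
monotonically non-increasing in the cutoff and invariant to atomic
refinement (both tested). The prognostic threshold of 25% for the
patient-level value follows the level reported to separate favourable
outcome, and is exposed as a configuration value. Copy-neutral LOH is
quantified separately from allele-specific profiles as the bp fraction
with allele copies {0, 2}; a (0, 3) segment is LOH but not copy neutral
and does not count.

## Clustering with multiscale bootstrap

Deposits are clustered by complete linkage on Euclidean distances over the
variance-filtered atoms (`stats::hclust`; merge ties are resolved
deterministically). Cluster support is assessed by multiscale bootstrap:
atoms (the clustering features) are resampled with replacement at scales
$r \in \{0.5, 0.6, \dots, 1.4\}$, $n_{boot}$ replicates per scale, and
each original node's bootstrap probability $BP_r$ is the fraction of
replicates whose tree contains exactly that member set. The approximately
unbiased support fits

$$\Phi^{-1}(1 - BP_r) = v\sqrt{r} + c/\sqrt{r}$$

by weighted least squares over scales (binomial weights) and reports
$AU = 1 - \Phi(v - c)$; $BP$ is reported at $r = 1$. Numerical guards:
$BP_r$ is clipped $1/(2 n_{boot})$ from the boundary before the probit
transform, only scales with $BP_r$ strictly inside $(0.001, 0.999)$ inform
the fit, and when fewer than three scales are informative (a node pinned
at 0 or 1 everywhere) the fit is degenerate and AU falls back to 1 or 0 by
the mean BP — the behaviour of the published procedure for perfectly
stable or never-recovered nodes. Both AU and BP are reported since
published support statements do not always say which was used. Seeded runs
are bit-reproducible (tested). A patient is called *monophyletic* when
some node's member set equals exactly the patient's deposit set; solitary
patients are not assessable.

## Survival statistics

All fixed-horizon analyses administratively censor at 36 months
(time' = min(t, 36), event only if within the horizon); time zero is the
start of treatment for the liver metastases. Kaplan–Meier rates are
product-limit estimates at the horizon. The log-rank test of linear trend
over $k$ ordered strata uses equally spaced scores with the 1-df statistic
$(c'(O-E))^2 / (c'Vc)$ from the stratum-wise observed/expected counts and
their covariance; with two strata it reduces exactly to the ordinary
log-rank test (tested). Cox models use the partial likelihood with Efron
tie handling; Wald tests provide per-covariate P-values, and the
proportional-hazards assumption is checked with the scaled Schoenfeld
residual test. Multivariable models enter, in one step, every covariate
with univariable P < 0.1. Group assignment splits at the cohort median
with a patient exactly at the median assigned to the *high* group (so an
odd cohort splits (n−1)/2 low, (n+1)/2 high), and the combined
stratification orders patients by how many of the two favourable
conditions hold (heterogeneity below median, complexity below 25%).
Segment-wise group comparisons use Welch t-tests per atom (vectorised;
validated against `t.test`) with Benjamini–Hochberg q-values; atoms
constant in both groups get q = 1.

## The synthetic cohort generator

The generator emulates the branched-evolution structure the analysis
assumes: each patient has a clonal ancestor profile — diploid plus a
Poisson($\lambda_{anc} = 25$) number of events, each ±1 copy on one allele
of an arm-level (probability 0.5) or focal (shifted-exponential length)
region, with placement weighted 5× towards the arms recurrently gained
(7p, 7q, 8q, 13q, 20q) or lost (1p, 4p, 4q, 8p, 17p, 18q) in colorectal
liver metastases — and every deposit adds its own Poisson number of
branch-private events. Copy-neutral LOH is generated as an explicit,
deliberately rare event type (one allele transferred to the other), since
cnLOH is reported to affect only a few per cent of the genome versus ~35%
for copy-number aberrations.

Two design choices deserve justification:

* **The private-event rate is a patient-level trait.** Each patient draws
  a divergence rate from an exponential distribution with mean
  $\lambda_{div} = 6$ and deposits add Poisson(rate) private events. A
  fixed rate for all patients produces a narrow between-patient spread of
  true heterogeneity, contradicting the defining observation that cohorts
  contain both near-clonal patients and patients whose deposits resemble
  unrelated tumours (roughly half of multi-deposit patients non-monophyletic
  in clustering, scores spanning a ratio of five). The exponential mixing
  reproduces that spread.
* **Purity is hierarchical.** Each patient draws a mean purity uniformly
  from the interior of the cohort range (0.26–0.95) and deposits scatter
  around it (sd 0.1, clamped). Deposits of one patient share etiology and
  tissue handling; fully independent purities would make measured
  heterogeneity mostly a purity artefact, far beyond the weak association
  with cancer-cell-fraction diversity seen in real data.

Rendered probe data follow the two-component mixture
$LRR = \log_2\{((1-\rho)\,2 + \rho\,(n_A+n_B))/2\} + \varepsilon$,
$\varepsilon \sim N(0, sd)$, with zero intensity floored at a configured
minimum. Default noise sd is 0.15, typical of array LRR data. Survival
times are exponential with hazard $h_0 e^{\beta}$ for patients whose true
divergence is above the cohort median ($\beta = -\log HR$, default
low-vs-high HR 0.4 for progression and 0.3 for death; baseline medians 12
and 30 months), censored by an independent uniform time calibrated to the
configured censored fraction (30%). Deposit counts per patient are drawn
from {1..7} with mean ≈ 2.7 and median 2; 45 patients with 8 of them
re-resected (11 second-resection deposits in expectation) match the study
design the pipeline addresses. Each patient derives a private RNG stream
from the master seed, so per-patient output is invariant to cohort size
and emission is byte-identical for a fixed seed.

**What the generator does not emulate** — and hence what passing tests do
not certify about real data: GC-content waves and other spatially
correlated noise, probe-specific biases, B-allele frequencies and
genotyping error, subclonal mixtures within one deposit, whole-genome
doubling dynamics, and any coupling between complexity and outcome beyond
the heterogeneity channel. Recovery results on this generator show the
estimators are correct under the stated model, not that the model is a
complete account of array data.

## Validation scale and known limitations

The test suite and the acceptance script run on a 0.1-scaled genome with
100 kb marker spacing (~3,100 markers), minimum focal span 10 markers and
$\gamma = 2$ — a miniature of the full-density regime in which every event
spans at least $k_{\min}$ markers; all reported statistics are proportions
or distances over a common territory and are scale-free by construction.
Exhaustive-enumeration checks of the segmentation run at n ≤ 20 probes;
end-to-end recovery uses 50 patients per divergence level; Cox recovery
uses 200 patients × 100 replicates; the bootstrap criterion uses 1,000
replicates per scale.

Limitations worth knowing:

* The $O(n^2)$ dynamic program is exact but not suited to millions of
  probes per chromosome; full-density SNP 6.0 data should be segmented
  arm-wise or thinned, or the fit replaced by a fast approximation of the
  same objective.
* With ~40 patients, a median split on a noisily measured score
  misclassifies some patients relative to the true split; the estimated
  hazard ratio is attenuated towards 1 and can invert in unlucky cohorts
  even when the underlying coupling is strong. This is a property of the
  design, visible in the simulator, and a caution for interpreting any
  single small cohort.
* Measured heterogeneity retains a purity component: deposits with
  different cancer-cell fractions show amplitude differences on shared
  (clonal) aberrations. The ploidy-adjusted score and the
  cancer-cell-fraction diversity check are the built-in controls.
* The probe-level exclusion lists of the original platform (control,
  duplicate, recurrent-region probe counts) are treated as data-driven,
  not hard-coded: they are platform properties, and the package recomputes
  them from whatever panel and non-cancer cohorts it is given.
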