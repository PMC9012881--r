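---
title: "Methods: paired serum-metabolome and gut-microbiome analysis of neutropenic fever"
author: "nfomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired serum-metabolome and gut-microbiome analysis of neutropenic fever}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfomics)
```

## The scientific problem

Neutropenic fever (NF) is a common complication of intensive chemotherapy in
patients with acute myeloid leukemia: fever arising while the absolute
neutrophil count is suppressed, usually without an identifiable pathogen.
One working hypothesis is that NF reflects a disturbed crosstalk between the
gut microbiota and the host, visible in the circulating metabolome.
`nfomics` implements an analysis pipeline for longitudinal cohorts in which
serum (metabolite concentrations) and stool (16S ASV counts) are collected
twice weekly from admission through about four weeks of chemotherapy, and
each patient has at most one NF onset day. The pipeline answers two
questions:

1. **Is there a serum metabolomic shift after NF, and what is its minimal
   signature?** Samples are labeled pre-NF (collected before the onset day)
   or post-NF (on or after it), screened univariately, and a sparse PLS
   discriminant analysis with stability selection extracts a small set of
   discriminating metabolites.
2. **Which gut genera predict those signature metabolites?** Each serum
   sample is paired with the patient's nearest preceding stool sample within
   3 days, and a sparse log-contrast regression with a zero-sum constraint
   on genus coefficients — the appropriate linear model for compositional
   covariates — is fitted per metabolite, with bootstrap stability selection
   retaining only persistent genus-metabolite associations.

Because real cohorts of this kind are not freely redistributable, the
package ships a synthetic-cohort generator with known ground truth; every
claim the test suite makes about recovery is a claim about this generator.

## Pre/post-NF labeling and metabolome preprocessing

A serum sample collected on the NF onset day counts as post-NF: fever is
present for most of that day, and the boundary must fall somewhere.
Patients who never develop NF contribute pre-NF samples; they are genuinely
unexposed and discarding them would waste the scarcest samples. Both
conventions are configurable judgments, not forced by the data.

Metabolites detectable in fewer than half of all serum samples are removed
(`filter_detectability()`, threshold 0.5). Remaining missing values are
assumed to be left-censoring at the platform's detection floor and imputed
with half the metabolite's minimum observed value plus Gaussian noise
(`impute_half_min()`). The noise exists only to break ties in rank-based
procedures; its default sd is 1% of the imputed value, small enough that no
test statistic depends on it materially. Imputed values are truncated at
zero; observed cells are never touched.

Downstream two-sample tests operate on natural-log concentrations (the
`log_tests` switch): metabolite concentrations are closer to log-normal than
normal, and fold changes are the natural effect scale. Fold changes are
still reported from raw group means. Bray-Curtis dissimilarities, by
contrast, are computed on the raw imputed concentrations, since that metric
is defined for non-negative abundances.

## Unsupervised structure and univariate screening

`permanova()` implements the one-factor permutational MANOVA partitioning of
a distance matrix: with squared distances `d_ij^2`, the total sum of squares
is over all pairs, the within-group sum over within-group pairs,
`R2 = 1 - SS_within / SS_total`, and the pseudo-F is compared with its
permutation distribution under free relabeling of samples. The p-value
convention includes the observed statistic in numerator and denominator, so
`p >= 1/(n_perm + 1)`. Group labels are permuted freely rather than within
patients by default, matching the observation that patient identity
explains little metabolomic variance in this design; a `strata` argument
provides the blocked alternative. The implementation is exact against
`vegan::adonis2` (same R2 and F) and against an exhaustive-enumeration
oracle in the tests; it is re-implemented rather than delegated so that the
permutation scheme and seeding are part of the package's contract.

Per-metabolite screening uses two-sided Welch (unequal-variance) t-tests
with Benjamini-Hochberg correction (`welch_volcano()`, `bh_adjust()` — the
latter a thin wrapper over `stats::p.adjust`). Metabolites with zero
variance in both groups are assigned `p = 1` rather than an error: under
half-minimum imputation with the noise switched off this situation is
reachable, and such a metabolite carries no evidence either way. PCA is
centered and (by default) unit-variance scaled, with each component's sign
fixed so its largest-magnitude loading is positive; heatmap ordering uses
Euclidean complete-linkage clustering.

## Sparse PLS-DA with stability selection

`splsda_fit()` re-implements two-class sparse PLS-DA: features are centered
and unit-variance scaled, the class is dummy-coded and scaled, and per
component the X-loading is the dominant singular direction of the X-Y
cross-covariance, soft-thresholded so that exactly `keepX` loadings remain
nonzero, renormalized, and iterated to a fixed point; X and Y are deflated
by regression on the component score. The tests verify exact agreement
(support and absolute loadings to 1e-8) with `mixOmics::splsda` as an
independent reference.

`keepX` is tuned by stratified 10-fold cross-validation minimizing the
balanced classification error, ties resolved toward the sparser model.
Stability selection refits the model on every CV training split (10
repeats x 10 folds = 100 refits by default) and retains features selected
on component 1 in strictly more than 90% of refits; component 1 alone
defines the signature because it is the direction that separates the
groups, while later components mostly absorb correlated structure.
Classification performance is summarized by leave-one-out cross-validation:
each left-out sample is scored by the signed difference of distances to the
two class centroids in score space, and the AUC is the rank statistic with
tie correction. The centroid-distance rule is one of several reasonable
prediction conventions; it is symmetric in the classes and yields a
continuous ROC score.

## Microbiome preprocessing

ASVs present in fewer than 10% of stool samples, samples with fewer than
5000 reads, and (when absolute 16S quantification is available) samples
with fewer than 1000 copies/mL are excluded. Prevalence is computed on the
table as supplied, before sample removal — the two orderings differ only
marginally, but one must be fixed; `filter_count_table()` documents this
choice and the thresholds are arguments.

Alpha diversity uses the inverse Simpson index on SRS-normalized counts.
`srs_normalize()` implements scaling with ranked subsampling: counts are
scaled to the target depth (the minimum sample depth by default), integer
parts are kept, and the residual counts are assigned one each to the taxa
with the largest fractional parts, ties broken in a seeded random order.
Unlike rarefaction, the procedure is deterministic up to ties, and every
normalized sample sums to the target depth exactly — a hard invariant in
the tests. Beta diversity uses the Aitchison distance (Euclidean distance
between centered log-ratio rows) with a pseudocount of 0.5 on counts; CLR
rows sum to zero and are invariant to per-sample depth scaling, which makes
the downstream PERMANOVA a statement about composition, not depth.

## Serum-stool pairing and the zero-sum lasso

`pair_samples()` pairs each serum sample with the same patient's nearest
preceding stool sample at a lag of 0-3 days; a same-day stool is eligible
(lag 0), a stool sample may serve several serum samples, and serum samples
without an eligible stool are dropped from the integration stage. The
microbiota state can plausibly influence the blood metabolome over days,
not backwards, hence the asymmetric window.

Signature metabolite concentrations are mapped through the rank-based
inverse normal transform `qnorm((rank - 0.5)/n)` before regression: the
transform removes the arbitrary concentration scale and heavy tails, and is
invariant to any monotone re-expression of the input.

The core estimator, `zerosum_lasso()`, solves

$$\min_{\beta_0,\ \beta}\ \frac{1}{2n}\lVert y - \beta_0 - Z\beta\rVert^2
  + \lambda\lVert\beta\rVert_1
  \quad\text{s.t.}\quad \textstyle\sum_g \beta_g = 0,$$

where `Z` holds log relative genus abundances (pseudocount 0.5, columns
centered). The zero-sum constraint makes fitted values invariant to each
sample's sequencing depth: adding a per-sample constant to a row of log
abundances contributes nothing when the coefficients sum to zero. For this
reason the columns of `Z` are *not* scaled to unit variance by default —
with scaled columns the constraint would apply to rescaled coefficients and
the depth factor would no longer cancel; a `scale` flag exists for users
who want it and accept that trade-off (on the benchmark data it also
selected more spurious genera, not fewer).

The solver is ADMM: the quadratic-plus-constraint subproblem is solved
exactly through a prefactored KKT linear system, the L1 term through soft
thresholding. After convergence the detected support is *polished* by
re-solving the equality-constrained problem on that support with the signs
fixed, so reported coefficients have exact zeros, a zero-sum residual at
machine precision, and a verifiable KKT residual (stored on the fit). At or
above the data-derived `lambda_max` the solution is exactly zero. The test
suite checks the solver against a brute-force oracle that enumerates all
sign patterns and solves each constrained quadratic in closed form
(objective agreement to 1e-4 on random small instances), and against the
1-D soft-threshold closed form in the two-genus case (1e-8).

### Choosing the penalty

`cv_zerosum_lasso()` evaluates a 20-point log-spaced grid from `lambda_max`
down to `1e-3 * lambda_max` by 10-fold cross-validation. The default
selection rule is the **one-standard-error rule**: the largest penalty
whose CV error is within one standard error of the minimum. This is a
deliberate design choice. On data with a strong sparse signal the CV curve
is nearly flat around its minimum — differences between candidate penalties
are far smaller than the fold-to-fold standard error — and the
error-minimizing penalty drifts toward dense solutions in which half the
genera are active. Bootstrap refits at such a penalty re-select noise
genera almost every time, so the stability filter downstream loses its
meaning: stability selection presupposes a penalty in the sparse regime.
The 1-SE rule is the standard resolution and, on the package's recovery
benchmarks, eliminates spurious stable associations entirely while never
losing a planted one. `rule = "min"` restores plain CV-minimization, with
ties toward the larger penalty.

### Bootstrap stability selection

At the selected penalty, `bootstrap_stability()` refits the model on 100
bootstrap resamples of the paired rows; a genus is stable when its
coefficient is nonzero in strictly more than 90% of resamples (at the
defaults, at least 91 of 100). The penalty is held fixed across resamples —
re-tuning inside each resample was evaluated and neither improved recovery
nor suppressed false selections, at twenty times the cost. The association
sign is taken from the full-data fit. Degenerate resamples with constant
response are redrawn. `association_table()` collects the stable (genus,
metabolite, sign, frequency) records across metabolites.

## The synthetic cohort generator

The generator emulates the study design stage by stage, and its defaults
are the cohort shape the pipeline targets:

* **Schedule** (`simulate_schedule()`): 36 patients, twice-weekly serum and
  stool sampling on a Mon/Thu-style grid (week-day offsets 0 and 3) from
  day 0 to day 28, each scheduled day independently jittered by
  uniform {-1, 0, +1} days — the independent jitter of the two sample types
  is what produces the 0-3 day pairing lags. `round(3/36 * n)` patients
  never develop NF; the rest draw an onset day uniformly from [-3, 20]
  days. A bloodstream-infection flag is drawn for 17/36 of patients for the
  sensitivity analyses.
* **Metabolome** (`simulate_metabolome()`): log-normal concentrations
  (log-scale mean 0, sd 1), 945 metabolites of which 18 carry a planted
  post-NF shift of `shift_log2fc * log(2)` on the log scale (default -1,
  i.e. a twofold loss after fever, matching the direction of the biology
  being emulated). Values under the per-metabolite 10% quantile are
  censored to missing, emulating a detection floor.
* **Microbiome** (`simulate_microbiome()`): 30 genera with latent log-normal
  abundances (between-genus means drawn N(0, 2), per-sample sd 1), closed to
  proportions; each genus split over 3 ASVs with fixed Dirichlet(1) weights;
  multinomial counts at a depth drawn uniformly from [5000, 50000].
* **Forward link**: 13 of the 18 signature metabolites are tied to the
  microbiome through a zero-sum coefficient matrix (3 genera per metabolite,
  coefficients `(+1, +1, -2)` times a magnitude of 0.5 by default) applied
  to the paired stool's log relative abundances, plus Gaussian noise with
  sd 0.5 on the metabolite log scale. The zero-sum columns make the planted
  signal exactly depth-invariant, mirroring the fitted model's form; at
  zero noise the forward model has a closed form the tests verify
  literally. The default magnitude keeps the microbiome-driven variance of
  a linked metabolite comparable to its baseline variance: much larger
  values would drown the planted NF shift and the linked metabolites could
  never re-enter the signature, making the emulated cohort internally
  inconsistent.

Concentration distributions, composition parameters and the forward-model
noise are declared assumptions — no public information constrains them — so
recovery results on synthetic cohorts demonstrate the machinery's
correctness and calibration, not expected performance on any real cohort.
Real data differ in ways the generator deliberately omits: within-patient
autocorrelation of both omics, antibiotic-driven compositional regime
shifts, metabolite-metabolite correlation blocks, and informative
missingness beyond a sharp detection floor.

## Pipeline, reproducibility and problem sizes

`run_pipeline()` chains the stages and returns a run report whose counts
reconcile exactly with the stage outputs; `sensitivity_analyses()` re-tests
the signature after excluding flagged patients and on each patient's last
pre-NF / first post-NF sample only. All thresholds live in one
configuration object (`default_pipeline_config()`); unknown configuration
keys are an error so that a misspelled threshold cannot silently fall back
to a default. A single global seed fans out to per-stage seeds through
`stage_seed()` (a fixed affine counter scheme), so any stage can be re-run
in isolation and reproduce the full-pipeline result; two runs with the same
configuration are identical object-for-object.

The validation suite exercises the machinery at deliberately moderate
problem sizes chosen to make the statistical claims testable while keeping
a full run of suite plus acceptance script around two minutes on one CPU:
association recovery uses 200 pairs x 20 genera with 6 planted unit
coefficients and 5 seeds; signature recovery uses ~150 samples x 300
metabolites with 15 planted metabolites at a log2 fold change of 1.5;
PERMANOVA calibration uses 200 null replicates of 40 samples with 999
permutations each. The acceptance script runs the complete pipeline at the
full emulated scale (36 patients, 945 metabolites, 30 genera).

## Known limitations

* Two classes only in the sPLS-DA; the design has exactly two states.
* The PERMANOVA is one-factor; covariate-adjusted designs are out of scope.
* Repeated measures are handled by design conventions (free permutation,
  pooled pre/post pairs, a last/first sensitivity analysis), not by mixed
  models; with few patients and strong within-patient correlation the
  univariate p-values are anti-conservative.
* The zero-sum lasso models one metabolite at a time; joint multi-response
  models and any causal reading of the associations are out of scope.
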