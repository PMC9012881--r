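# nfomics

Paired serum-metabolome and gut-microbiome analysis of neutropenic fever
(NF) in longitudinal chemotherapy cohorts.

Patients with acute myeloid leukemia are sampled twice weekly (serum and
stool) from hospital admission through about four weeks of chemotherapy;
most develop a single episode of neutropenic fever on some study day.
`nfomics` asks two questions of such a cohort:

1. **Does the serum metabolome shift after NF, and what is its minimal
   signature?** Samples are labeled pre-/post-NF by the onset day, screened
   with Welch tests + Benjamini-Hochberg correction and Bray-Curtis
   PERMANOVA, and a two-class sparse PLS discriminant analysis — tuned by
   ten-fold cross-validation, filtered by stability selection (> 90% of 100
   cross-validation refits) and evaluated by leave-one-out ROC — extracts a
   small discriminating metabolite set.
2. **Which gut genera predict those signature metabolites?** Each serum
   sample is paired with the patient's nearest preceding stool sample within
   3 days; after ASV/sample quality control, genus aggregation and a 20%
   prevalence filter, each inverse-normal-transformed metabolite is
   regressed on log relative genus abundances with the **zero-sum
   constrained lasso**

   $$\min_{\beta_0,\beta}\ \tfrac{1}{2n}\lVert y-\beta_0-Z\beta\rVert^2
     + \lambda\lVert\beta\rVert_1
     \quad \text{s.t.} \quad \textstyle\sum_g\beta_g = 0 ,$$

   the sparse log-contrast model for compositional covariates: the zero-sum
   constraint makes predictions invariant to sequencing depth. The penalty
   is chosen by ten-fold cross-validation (one-standard-error rule) and
   associations are kept only when the genus survives > 90 of 100 bootstrap
   refits.

The package also ships a synthetic-cohort generator with known ground truth
(schedule with ±1-day jitter, log-normal metabolome with a planted
post-fever signature and a detection floor, multinomial ASV counts over a
log-normal genus composition, and a zero-sum log-contrast forward model
linking the two), so the whole pipeline can be validated end-to-end against
planted truth. Distances, diversity indices and ordinary tests are
delegated to `vegan` and base R; the estimators themselves
(`zerosum_lasso()`, `splsda_fit()`, `permanova()`, `srs_normalize()`) are
implemented in the package and cross-checked in the test suite against
independent oracles (`vegan::adonis2`, `mixOmics::splsda`, closed forms and
brute-force enumeration).

## Worked example

```r
library(nfomics)

report <- run_pipeline(default_pipeline_config(seed = 1), quiet = TRUE)
print(report)
#> Paired-omics analysis run (seed 1)
#>   thresholds: detectability 0.5 | ASV prevalence 0.1 | reads 5000 | copies 1000 | genus prevalence 0.2 | lag 3d | 10-fold CV | 100 bootstraps | stability 0.9 | 999 permutations
#>   metabolome: 324 samples, 945/945 metabolites detectable, 14 significant (q < 0.05)
#>   PERMANOVA R2: group 0.007 (p = 0.001), patient 0.113
#>   sPLS-DA: keepX = 50/20; 20-metabolite stable signature; LOOCV AUC = 0.918
#>   integration: 296 pairs, 31 stable associations (22 genera x 10 metabolites)
```

Reading the output: 324 serum samples from 36 simulated patients pass
preprocessing; 14 metabolites differ significantly between pre- and post-NF
samples after BH correction; group membership explains 0.7% of Bray-Curtis
metabolomic variance (the planted shift touches 18 of 945 metabolites);
the stability-selected sPLS-DA signature holds 20 metabolites and separates
the groups with a leave-one-out AUC of 0.918; and the integration stage
finds 31 stable genus-metabolite associations among 296 serum-stool pairs.
Against the generator's truth (18 planted signature metabolites, 39 planted
genus-metabolite pairs), the signature recovers 15/18 planted metabolites
and 30 of the 31 associations are planted pairs with the correct sign.

Individual stages are plain functions returning classed objects with the
usual methods:

```r
cohort <- simulate_cohort(cohort_config(seed = 1))
mat    <- impute_half_min(filter_detectability(cohort$metabolome), seed = 1)
Z      <- log_contrast_design(prevalence_filter(aggregate_genera(
            filter_count_table(cohort$counts), cohort$genus_map)))
cv     <- cv_zerosum_lasso(Z, rank_int(log(mat[rownames(Z), 1])))
print(cv$fit)       # coefficients sum to zero exactly; KKT residual reported
```

A thin command-line wrapper (`inst/scripts/nfomics-cli.R`) exposes
`simulate`, `run-all` and `sensitivity` subcommands over the same
functions, with `--config` (YAML overlay of `default_pipeline_config()`),
`--seed` and `--outdir` flags.

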