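#' Default configuration of the end-to-end analysis pipeline
#'
#' All thresholds default to the study design being emulated: metabolite
#' detectability 0.5; ASV prevalence 0.10; sample depth 5000 reads and 1000
#' 16S copies/mL; genus prevalence 0.20; serum-stool pairing lag 3 days;
#' tenfold cross-validation; 100 bootstraps with a 0.90 stability threshold;
#' 999 PERMANOVA permutations. The `simulate` block configures the synthetic
#' cohort used when no input paths are supplied; its defaults are the
#' emulated cohort shape (36 patients, 28 days, 945 metabolites with an
#' 18-metabolite post-fever signature, 13 of which are linked to the
#' microbiome through 3 genera each).
#'
#' @param seed global seed; per-stage seeds are derived with [stage_seed()].
#' @return a nested list of class `nf_pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    input = NULL,
    simulate = list(
      n_patients = 36, followup_days = 28, sampling_days_per_week = 2,
      nf_day_range = c(-3, 20), frac_never_nf = 3 / 36,
      frac_bacteremia = 17 / 36,
      n_metabolites = 945, n_signature = 18, shift_log2fc = -1,
      detection_floor_quantile = 0.1, base_log_mean = 0, base_log_sd = 1,
      n_genera = 30, asv_per_genus = 3, n_associated_metabolites = 13,
      genera_per_metabolite = 3, association_effect = 0.5,
      depth_range = c(5000, 50000), genus_log_sd = 1, noise_sd = 0.5),
    thresholds = list(
      detectability = 0.5, asv_prevalence = 0.10, min_reads = 5000,
      min_copies = 1000, genus_prevalence = 0.20, max_lag_days = 3,
      cv_folds = 10, n_bootstrap = 100, stability = 0.90, n_perm = 999),
    metabolome = list(noise_sd_fraction = 0.01, log_tests = TRUE),
    splsda = list(keepX_grid = c(5, 10, 20, 50), ncomp = 2, tune = TRUE,
                  stability_folds = 10, stability_repeats = 10),
    integration = list(n_lambda = 20, lambda_min_ratio = 1e-3,
                       pseudocount = 0.5)
  ), class = "nf_pipeline_config")
}

## internal: overlay user values onto defaults; unknown keys are an error
.merge_config <- function(defaults, user, path = "") {
  if (!is.list(user)) return(user)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    .nf_stop("unknown configuration key(s): ",
             paste0(sub("^\\.", "", paste0(path, ".", extra)),
                    collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && k != "input")
      .merge_config(defaults[[k]], user[[k]], paste0(path, ".", k))
    else user[[k]]
  }
  defaults
}

#' Read a pipeline configuration from a YAML file
#'
#' Values overlay [default_pipeline_config()]; any key not present in the
#' defaults is an error, guarding against silently misspelled thresholds.
#'
#' @param path YAML file path.
#' @return an `nf_pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- .merge_config(default_pipeline_config(), user)
  class(cfg) <- "nf_pipeline_config"
  cfg
}

## internal: build the cohort described by the simulate block
.simulate_from_config <- function(config) {
  sb <- config$simulate
  cc <- cohort_config(
    n_patients = sb$n_patients, followup_days = sb$followup_days,
    sampling_days_per_week = sb$sampling_days_per_week,
    nf_day_range = sb$nf_day_range, frac_never_nf = sb$frac_never_nf,
    frac_bacteremia = sb$frac_bacteremia,
    seed = stage_seed(config$seed, 1L))
  sig <- seq_len(min(sb$n_signature, sb$n_metabolites))
  mt <- metabolome_truth(
    n_metabolites = sb$n_metabolites, signature_ids = sig,
    shift_log2fc = sb$shift_log2fc,
    detection_floor_quantile = sb$detection_floor_quantile,
    base_log_mean = sb$base_log_mean, base_log_sd = sb$base_log_sd)
  B <- NULL
  n_assoc <- min(sb$n_associated_metabolites, length(sig))
  if (n_assoc > 0)
    B <- association_truth(sb$n_genera, sig[seq_len(n_assoc)],
                           genera_per_metabolite = sb$genera_per_metabolite,
                           effect = sb$association_effect,
                           seed = stage_seed(config$seed, 2L))
  mict <- microbiome_truth(
    n_genera = sb$n_genera, asv_per_genus = sb$asv_per_genus,
    association = B, depth_range = sb$depth_range,
    genus_log_sd = sb$genus_log_sd, noise_sd = sb$noise_sd)
  simulate_cohort(cc, mt, mict)
}

#' Run the full paired-omics analysis
#'
#' Executes, in order: metabolome preprocessing (pre/post-NF labeling,
#' detectability filter, half-minimum imputation), unsupervised and
#' univariate statistics (Bray-Curtis PERMANOVA for group and patient, Welch
#' volcano with BH correction, PCA, clustering of significant metabolites),
#' sPLS-DA tuning / stability selection / LOOCV ROC, microbiome QC (ASV and
#' sample filters, SRS-normalized alpha diversity, Aitchison PERMANOVA,
#' genus aggregation and prevalence filtering), and the integration stage
#' (serum-stool pairing, rank-based inverse normal transform, cross-validated
#' zero-sum lasso with bootstrap stability selection per signature
#' metabolite). Fully reproducible given `config$seed`.
#'
#' @param config an `nf_pipeline_config` (see [default_pipeline_config()],
#'   [read_pipeline_config()]). When `config$input` is `NULL` the cohort is
#'   simulated from the `simulate` block; otherwise `input` must list paths
#'   `metabolome`, `samples`, `patients` and optionally `counts`,
#'   `genus_map`.
#' @param outdir optional directory for stage artifacts (volcano, stability,
#'   ROC, pairing and association tables as TSV; a YAML run report).
#' @param quiet suppress progress messages (default `FALSE`).
#' @return a list of class `nf_run_report`; see the elements documented in
#'   the package vignette.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "nf_pipeline_config") || is.list(config))
  note <- function(...) if (!quiet) message("[nfomics] ", ...)
  th <- config$thresholds
  seed <- config$seed

  ## -- stage 0: data ------------------------------------------------------
  if (is.null(config$input)) {
    note("simulating cohort (seed ", seed, ")")
    cohort <- .simulate_from_config(config)
    metabolome <- cohort$metabolome
    counts <- cohort$counts
    genus_map <- cohort$genus_map
    samples <- cohort$samples
    patients <- cohort$patients
    truth <- cohort$truth
  } else {
    note("reading input tables")
    metabolome <- read_matrix_tsv(config$input$metabolome)
    samples <- read_sample_metadata(config$input$samples)
    patients <- read_sample_metadata(config$input$patients)
    counts <- if (!is.null(config$input$counts))
      read_count_table(config$input$counts) else NULL
    genus_map <- if (!is.null(config$input$genus_map))
      read_genus_map(config$input$genus_map) else NULL
    truth <- NULL
  }
  serum_meta <- samples[samples$type == "serum", , drop = FALSE]
  stool_meta <- samples[samples$type == "stool", , drop = FALSE]
  serum_meta <- serum_meta[serum_meta$sample_id %in% rownames(metabolome), ,
                           drop = FALSE]
  metabolome <- metabolome[serum_meta$sample_id, , drop = FALSE]

  ## -- stage 1: metabolome preprocessing ---------------------------------
  groups <- assign_nf_groups(serum_meta, patients)
  mat_f <- filter_detectability(metabolome, th$detectability)
  note(ncol(mat_f), " of ", ncol(metabolome),
       " metabolites pass the detectability filter")
  mat_i <- impute_half_min(mat_f,
                           noise_sd_fraction = config$metabolome$noise_sd_fraction,
                           seed = stage_seed(seed, 11L))
  logmat <- log(mat_i)
  test_mat <- if (config$metabolome$log_tests) logmat else mat_i

  ## -- stage 2: multivariate statistics ----------------------------------
  note("PERMANOVA and Welch volcano")
  bc <- bray_curtis(mat_i)
  perm_group <- permanova(bc, groups, n_perm = th$n_perm,
                          seed = stage_seed(seed, 12L))
  perm_patient <- permanova(bc, serum_meta$patient_id, n_perm = th$n_perm,
                            seed = stage_seed(seed, 13L))
  volcano <- welch_volcano(mat_i, groups, log = config$metabolome$log_tests)
  sig_mets <- volcano$metabolite[volcano$q < 0.05]
  pca <- pca_ordination(test_mat)
  clustering <- if (length(sig_mets) >= 2)
    cluster_samples(test_mat[, sig_mets, drop = FALSE]) else NULL

  ## -- stage 3: sPLS-DA ---------------------------------------------------
  note("sPLS-DA: tuning, stability selection, LOOCV")
  sp <- config$splsda
  if (isTRUE(sp$tune)) {
    tuned <- tune_splsda(test_mat, groups, keepX_grid = sp$keepX_grid,
                         ncomp = sp$ncomp, folds = th$cv_folds,
                         seed = stage_seed(seed, 14L))
    keepX <- tuned$keepX
  } else {
    tuned <- NULL
    keepX <- rep_len(sp$keepX_grid[1], sp$ncomp)
  }
  model <- splsda_fit(test_mat, groups, ncomp = sp$ncomp, keepX = keepX)
  stability <- splsda_stability(test_mat, groups, keepX = keepX[1],
                                ncomp = 1, folds = sp$stability_folds,
                                repeats = sp$stability_repeats,
                                threshold = th$stability,
                                seed = stage_seed(seed, 15L))
  signature <- stability$stable
  roc <- loocv_auc(test_mat, groups, keepX = keepX[1], ncomp = 1)

  ## -- stage 4: microbiome ------------------------------------------------
  alpha <- perm_micro <- NULL
  genus_f <- NULL
  stool_groups <- NULL
  if (!is.null(counts)) {
    note("microbiome QC, diversity, genus aggregation")
    counts_f <- filter_count_table(counts,
                                   min_asv_prevalence = th$asv_prevalence,
                                   min_reads = th$min_reads,
                                   min_copies = th$min_copies)
    stool_kept <- stool_meta[stool_meta$sample_id %in% rownames(counts_f), ,
                             drop = FALSE]
    counts_f <- counts_f[stool_kept$sample_id, , drop = FALSE]
    stool_groups <- assign_nf_groups(stool_kept, patients)
    srs <- srs_normalize(counts_f, seed = stage_seed(seed, 16L))
    alpha <- alpha_diversity(srs, stool_groups)
    perm_micro <- permanova(aitchison_distance(counts_f), stool_groups,
                            n_perm = th$n_perm,
                            seed = stage_seed(seed, 17L))
    genus <- aggregate_genera(counts_f, genus_map)
    genus_f <- prevalence_filter(genus, th$genus_prevalence)
    note(ncol(genus_f), " genera in ", nrow(genus_f),
         " stool samples after filtering")
  }

  ## -- stage 5: integration ----------------------------------------------
  pairs <- NULL
  assoc <- association_table(list())
  integration_fits <- list()
  if (!is.null(genus_f) && length(signature)) {
    note("integration: pairing and zero-sum lasso for ",
         length(signature), " signature metabolite(s)")
    stool_kept <- stool_meta[stool_meta$sample_id %in% rownames(genus_f), ,
                             drop = FALSE]
    pairs <- pair_samples(serum_meta, stool_kept,
                          max_lag_days = th$max_lag_days)
    if (nrow(pairs) >= 3 * th$cv_folds) {
      Z <- log_contrast_design(genus_f[pairs$stool_id, , drop = FALSE],
                               pseudocount = config$integration$pseudocount)
      for (i in seq_along(signature)) {
        m <- signature[i]
        y <- rank_int(mat_i[pairs$serum_id, m])
        cv <- cv_zerosum_lasso(Z, y,
                               n_lambda = config$integration$n_lambda,
                               lambda_min_ratio = config$integration$lambda_min_ratio,
                               folds = th$cv_folds,
                               seed = stage_seed(seed, 100L + i))
        integration_fits[[m]] <- bootstrap_stability(
          Z, y, cv$lambda_opt, B = th$n_bootstrap,
          threshold = th$stability, seed = stage_seed(seed, 300L + i))
      }
      assoc <- association_table(integration_fits)
    } else {
      note("too few serum-stool pairs (", nrow(pairs),
           "); integration skipped")
    }
  }

  report <- structure(list(
    seed = seed, thresholds = th,
    counts = list(
      patients = nrow(patients),
      serum_samples = nrow(serum_meta),
      stool_samples = nrow(stool_meta),
      metabolites_detected = ncol(metabolome),
      metabolites_detectable = ncol(mat_f),
      significant_metabolites = length(sig_mets),
      component1_metabolites = keepX[1],
      signature_metabolites = length(signature),
      stool_samples_after_qc = if (is.null(genus_f)) NA_integer_ else nrow(genus_f),
      genera_after_filters = if (is.null(genus_f)) NA_integer_ else ncol(genus_f),
      serum_stool_pairs = if (is.null(pairs)) NA_integer_ else nrow(pairs),
      stable_associations = nrow(assoc),
      association_genera = attr(assoc, "n_genera"),
      association_metabolites = attr(assoc, "n_metabolites")),
    permanova = list(group = perm_group, patient = perm_patient,
                     microbiome = perm_micro),
    volcano = volcano, pca = pca, clustering = clustering,
    tuned = tuned, keepX = keepX, model = model,
    stability = stability, signature = signature,
    auc = roc$auc, roc = roc$roc,
    alpha = alpha, pairs = pairs,
    integration = integration_fits, associations = assoc,
    truth = truth,
    data = list(matrix = mat_i, test_matrix = test_mat, groups = groups,
                serum_meta = serum_meta, patients = patients,
                log_tests = config$metabolome$log_tests)
  ), class = "nf_run_report")

  if (!is.null(outdir)) .write_report(report, outdir)
  report
}

## internal: stage artifacts as plain text
.write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) write.table(df, file.path(outdir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wt(report$volcano, "volcano.tsv")
  wt(data.frame(metabolite = names(report$stability$frequency),
                frequency = unname(report$stability$frequency)),
     "splsda_stability.tsv")
  wt(report$roc, "roc.tsv")
  if (!is.null(report$pairs)) wt(report$pairs, "pairs.tsv")
  wt(as.data.frame(report$associations), "associations.tsv")
  yaml::write_yaml(list(seed = report$seed, thresholds = report$thresholds,
                        counts = report$counts,
                        permanova_group_R2 = report$permanova$group$R2,
                        auc = report$auc,
                        signature = as.list(report$signature)),
                   file.path(outdir, "report.yaml"))
  invisible(outdir)
}

#' @export
print.nf_run_report <- function(x, ...) {
  th <- x$thresholds
  cat("Paired-omics analysis run (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  thresholds: detectability %.2g | ASV prevalence %.2g | reads %d | copies %d | genus prevalence %.2g | lag %dd | %d-fold CV | %d bootstraps | stability %.2g | %d permutations\n",
              th$detectability, th$asv_prevalence, th$min_reads,
              th$min_copies, th$genus_prevalence, th$max_lag_days,
              th$cv_folds, th$n_bootstrap, th$stability, th$n_perm))
  cn <- x$counts
  cat(sprintf("  metabolome: %d samples, %d/%d metabolites detectable, %d significant (q < 0.05)\n",
              cn$serum_samples, cn$metabolites_detectable,
              cn$metabolites_detected, cn$significant_metabolites))
  cat(sprintf("  PERMANOVA R2: group %.3f (p = %.3g), patient %.3f\n",
              x$permanova$group$R2, x$permanova$group$p,
              x$permanova$patient$R2))
  cat(sprintf("  sPLS-DA: keepX = %s; %d-metabolite stable signature; LOOCV AUC = %.3f\n",
              paste(x$keepX, collapse = "/"), cn$signature_metabolites,
              x$auc))
  if (!is.na(cn$serum_stool_pairs))
    cat(sprintf("  integration: %d pairs, %d stable associations (%d genera x %d metabolites)\n",
                cn$serum_stool_pairs, cn$stable_associations,
                cn$association_genera, cn$association_metabolites))
  invisible(x)
}

#' Sensitivity analyses of the metabolomic signature
#'
#' Two re-tests of the signature metabolites: (1) excluding patients flagged
#' with bloodstream infection, and (2) restricting each patient to the last
#' pre-NF and first post-NF serum sample, to control for repeated measures.
#' Both re-run per-metabolite Welch tests and report p- and BH q-values.
#'
#' @param report an [run_pipeline()] result with a nonempty signature.
#' @param flags optional logical vector of patient-level infection flags
#'   (named by patient id); defaults to the `bacteremia` column of the
#'   cohort's patient table.
#' @return a list of class `nf_sensitivity` with data.frames
#'   `bacteremia_excluded` and `last_first`, plus `notes`.
#' @export
sensitivity_analyses <- function(report, flags = NULL) {
  stopifnot(inherits(report, "nf_run_report"))
  if (!length(report$signature))
    .nf_stop("the signature is empty; nothing to re-test")
  d <- report$data
  sig <- report$signature
  if (is.null(flags)) {
    if (is.null(d$patients$bacteremia))
      .nf_stop("no infection flags available; supply 'flags'")
    flags <- setNames(d$patients$bacteremia, d$patients$patient_id)
  }
  notes <- character()

  ## analysis 1: drop flagged patients
  keep <- !flags[as.character(d$serum_meta$patient_id)]
  if (all(keep))
    notes <- c(notes, "no flagged patients: analysis 1 equals the main analysis")
  v1 <- welch_volcano(d$matrix[keep, sig, drop = FALSE],
                      droplevels(d$groups[keep]), log = d$log_tests)

  ## analysis 2: last pre-NF and first post-NF sample per patient
  idx <- unlist(lapply(split(seq_len(nrow(d$serum_meta)),
                             d$serum_meta$patient_id), function(ii) {
    pre <- ii[d$groups[ii] == "pre"]
    post <- ii[d$groups[ii] == "post"]
    c(if (length(pre)) pre[which.max(d$serum_meta$day[pre])],
      if (length(post)) post[which.min(d$serum_meta$day[post])])
  }), use.names = FALSE)
  v2 <- welch_volcano(d$matrix[idx, sig, drop = FALSE],
                      droplevels(d$groups[idx]), log = d$log_tests)

  structure(list(bacteremia_excluded = v1, last_first = v2,
                 n_samples = c(analysis1 = sum(keep),
                               analysis2 = length(idx)),
                 notes = notes),
            class = "nf_sensitivity")
}

#' @export
print.nf_sensitivity <- function(x, ...) {
  cat("Sensitivity analyses of the signature metabolites\n")
  cat(sprintf("  1. bloodstream-infection patients excluded (%d samples): %d/%d metabolites p < 0.05\n",
              x$n_samples[1], sum(x$bacteremia_excluded$p < 0.05),
              nrow(x$bacteremia_excluded)))
  cat(sprintf("  2. last pre-NF / first post-NF only (%d samples): %d/%d metabolites p < 0.05\n",
              x$n_samples[2], sum(x$last_first$p < 0.05),
              nrow(x$last_first)))
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}
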