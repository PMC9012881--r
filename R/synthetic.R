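#' Configuration for a synthetic longitudinal paired-omics cohort
#'
#' Describes the study design being emulated: hospitalized chemotherapy
#' patients sampled twice weekly (serum and stool) from admission (day 0)
#' until the end of follow-up, each scheduled day jittered by at most one day.
#' Most patients develop neutropenic fever (NF) on a day drawn uniformly from
#' `nf_day_range`; a fraction never do.
#'
#' @param n_patients number of patients (default 36).
#' @param followup_days last study day (default 28).
#' @param sampling_days_per_week number of collection days per week (default 2,
#'   i.e. a Mon/Thu-style grid).
#' @param nf_day_range integer interval (relative to chemotherapy start, day 0)
#'   from which each febrile patient's NF onset day is drawn uniformly
#'   (default `c(-3, 20)`).
#' @param frac_never_nf fraction of patients who never develop NF
#'   (default 3/36). The number of such patients is
#'   `round(frac_never_nf * n_patients)`.
#' @param frac_bacteremia fraction of patients flagged with bloodstream
#'   infection (default 17/36), used by the sensitivity analyses.
#' @param seed integer seed making the whole cohort reproducible.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 36, followup_days = 28,
                          sampling_days_per_week = 2,
                          nf_day_range = c(-3, 20),
                          frac_never_nf = 3 / 36,
                          frac_bacteremia = 17 / 36,
                          seed = 1L) {
  n_patients <- .check_count(n_patients, "n_patients", min = 2L)
  followup_days <- .check_count(followup_days, "followup_days", min = 7L)
  sampling_days_per_week <- .check_count(sampling_days_per_week,
                                         "sampling_days_per_week")
  if (length(nf_day_range) != 2L || !all(is.finite(nf_day_range)) ||
      nf_day_range[1] > nf_day_range[2])
    .nf_stop("'nf_day_range' must be an integer interval c(lower, upper) with lower <= upper")
  structure(list(
    n_patients = n_patients,
    followup_days = followup_days,
    sampling_days_per_week = sampling_days_per_week,
    nf_day_range = as.integer(round(nf_day_range)),
    frac_never_nf = .check_frac(frac_never_nf, "frac_never_nf"),
    frac_bacteremia = .check_frac(frac_bacteremia, "frac_bacteremia"),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Ground truth for the synthetic serum metabolome
#'
#' Metabolite concentrations are log-normal. A designated subset of
#' "signature" metabolites has its log-mean shifted in post-NF samples by
#' `shift_log2fc * log(2)` (so `shift_log2fc` is the planted log2 fold change
#' of post- over pre-NF means). Values below each metabolite's
#' `detection_floor_quantile` empirical quantile are censored to missing,
#' emulating a detection floor.
#'
#' @param n_metabolites number of metabolites (default 945).
#' @param signature_ids integer indices of metabolites carrying the planted
#'   pre/post shift (default `1:18`).
#' @param shift_log2fc planted log2 fold change, recycled over
#'   `signature_ids`. The default, -1, is a twofold loss after fever.
#' @param detection_floor_quantile fraction of each metabolite's values
#'   censored below the detection floor (default 0.1).
#' @param base_log_mean,base_log_sd natural-log-scale mean and sd of the
#'   concentration distribution (defaults 0 and 1).
#' @return an object of class `metabolome_truth`.
#' @export
metabolome_truth <- function(n_metabolites = 945, signature_ids = 1:18,
                             shift_log2fc = -1,
                             detection_floor_quantile = 0.1,
                             base_log_mean = 0, base_log_sd = 1) {
  n_metabolites <- .check_count(n_metabolites, "n_metabolites")
  signature_ids <- as.integer(signature_ids)
  if (length(signature_ids) &&
      (any(signature_ids < 1L) || any(signature_ids > n_metabolites)))
    .nf_stop("'signature_ids' must index metabolites in 1..n_metabolites")
  if (!all(is.finite(shift_log2fc)))
    .nf_stop("'shift_log2fc' must be finite")
  structure(list(
    n_metabolites = n_metabolites,
    signature_ids = signature_ids,
    shift_log2fc = rep_len(as.numeric(shift_log2fc),
                           max(1L, length(signature_ids))),
    detection_floor_quantile = .check_frac(detection_floor_quantile,
                                           "detection_floor_quantile"),
    base_log_mean = as.numeric(base_log_mean),
    base_log_sd = as.numeric(base_log_sd)
  ), class = "metabolome_truth")
}

#' Zero-sum genus-metabolite association matrix for the forward model
#'
#' Builds the coefficient matrix `B` (genera x target metabolites) of the
#' generative log-contrast model: each associated metabolite's log
#' concentration is augmented by `sum_g B[g, m] * log(relative abundance of
#' genus g)` in the paired stool sample. Every column sums to zero, so the
#' planted association is invariant to sequencing depth, mirroring the model
#' fitted downstream. With an even number of nonzero genera per metabolite the
#' coefficients alternate `+effect`/`-effect`; with an odd number the last
#' coefficient is `-(k-1)*effect` to balance the column.
#'
#' @param n_genera number of genera (rows).
#' @param metabolite_ids integer indices of the target metabolites (columns).
#' @param genera_per_metabolite number of nonzero genera per column
#'   (default 3; must be >= 2 for the zero-sum constraint to be satisfiable).
#' @param effect coefficient magnitude (default 1).
#' @param seed optional seed for the choice of which genera carry each
#'   association.
#' @return a numeric matrix with `length(metabolite_ids)` zero-sum columns and
#'   `metabolite_ids` as column names.
#' @export
association_truth <- function(n_genera, metabolite_ids,
                              genera_per_metabolite = 3, effect = 1,
                              seed = NULL) {
  n_genera <- .check_count(n_genera, "n_genera", min = 2L)
  k <- .check_count(genera_per_metabolite, "genera_per_metabolite", min = 2L)
  if (k > n_genera) .nf_stop("'genera_per_metabolite' exceeds 'n_genera'")
  if (!is.null(seed)) set.seed(seed)
  B <- matrix(0, n_genera, length(metabolite_ids),
              dimnames = list(NULL, as.character(metabolite_ids)))
  coefs <- if (k %% 2L == 0L) rep(c(effect, -effect), k / 2L)
           else c(rep(effect, k - 1L), -(k - 1L) * effect)
  for (j in seq_along(metabolite_ids))
    B[sample.int(n_genera, k), j] <- coefs
  B
}

#' Ground truth for the synthetic stool microbiome
#'
#' Genus relative abundances follow a log-normal composition model: per sample
#' the latent log abundance of genus g is `N(genus_log_mean[g], genus_log_sd)`
#' and abundances are closed to proportions. Each genus is split into
#' `asv_per_genus` amplicon sequence variants with fixed random weights, and
#' ASV counts are multinomial at a per-sample depth drawn uniformly from
#' `depth_range`.
#'
#' @param n_genera number of genera (default 30).
#' @param asv_per_genus ASVs per genus (default 3).
#' @param association optional zero-sum coefficient matrix from
#'   [association_truth()] linking genera (rows) to metabolite indices
#'   (columns) through the forward log-contrast model.
#' @param depth_range integer interval of per-sample read depth
#'   (default `c(5000, 50000)`).
#' @param genus_log_mean optional vector of per-genus log-scale means; drawn
#'   `N(0, 2)` at generation time when `NULL`.
#' @param genus_log_sd per-sample log-scale sd of genus abundances (default 1).
#' @param noise_sd sd of the Gaussian noise added on the metabolite log scale
#'   by the forward model (default 0.5).
#' @return an object of class `microbiome_truth`.
#' @export
microbiome_truth <- function(n_genera = 30, asv_per_genus = 3,
                             association = NULL,
                             depth_range = c(5000, 50000),
                             genus_log_mean = NULL, genus_log_sd = 1,
                             noise_sd = 0.5) {
  n_genera <- .check_count(n_genera, "n_genera", min = 2L)
  asv_per_genus <- .check_count(asv_per_genus, "asv_per_genus")
  if (length(depth_range) != 2L || depth_range[1] > depth_range[2] ||
      depth_range[1] < 1)
    .nf_stop("'depth_range' must be a positive integer interval c(lower, upper)")
  if (!is.null(association)) {
    association <- as.matrix(association)
    if (nrow(association) != n_genera)
      .nf_stop("'association' must have n_genera rows")
    bad <- abs(colSums(association)) > 1e-8
    if (any(bad))
      .nf_stop("every column of 'association' must sum to zero (violated for column ",
               paste(which(bad), collapse = ", "), ")")
    nnz <- colSums(association != 0)
    if (any(nnz == 1L))
      .nf_stop("an association column with a single nonzero cannot satisfy the zero-sum constraint")
  }
  if (!is.null(genus_log_mean) && length(genus_log_mean) != n_genera)
    .nf_stop("'genus_log_mean' must have length n_genera")
  structure(list(
    n_genera = n_genera, asv_per_genus = asv_per_genus,
    association = association,
    depth_range = as.integer(round(depth_range)),
    genus_log_mean = genus_log_mean,
    genus_log_sd = as.numeric(genus_log_sd),
    noise_sd = as.numeric(noise_sd)
  ), class = "microbiome_truth")
}

#' Generate the cohort skeleton: patients, NF days and the sampling schedule
#'
#' Serum and stool are collected on the same twice-weekly grid (day offsets
#' `floor(7 * (0:(k-1)) / k)` within each week, so 0/3 for k = 2) from day 0
#' to `followup_days`, each scheduled day independently jittered by a uniform
#' draw from \{-1, 0, +1\} and clamped to the study window. Independent jitter
#' of the two sample types is what creates the 0-3 day serum-stool lags used
#' by the pairing stage. `round(frac_never_nf * n_patients)` patients receive
#' no NF day; the rest draw one uniformly from `nf_day_range`.
#'
#' @param config a [cohort_config()].
#' @return a list of class `cohort_skeleton` with elements `patients`
#'   (data.frame: `patient_id`, `nf_day` (NA = never febrile), `bacteremia`)
#'   and `samples` (data.frame: `sample_id`, `patient_id`, `day`, `type`
#'   ("serum"/"stool")).
#' @export
simulate_schedule <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  pid <- sprintf("P%02d", seq_len(n))

  n_never <- round(config$frac_never_nf * n)
  never <- if (n_never > 0) sample(pid, n_never) else character()
  nf_day <- ifelse(pid %in% never, NA_integer_,
                   .resample(seq(config$nf_day_range[1],
                                 config$nf_day_range[2]),
                             n, replace = TRUE))
  n_bac <- round(config$frac_bacteremia * n)
  bacteremia <- pid %in% (if (n_bac > 0) sample(pid, n_bac) else character())

  k <- config$sampling_days_per_week
  offsets <- floor(7 * (seq_len(k) - 1) / k)
  grid <- sort(unique(as.vector(outer(seq(0, config$followup_days, by = 7),
                                      offsets, `+`))))
  grid <- grid[grid <= config$followup_days]

  samples <- do.call(rbind, lapply(pid, function(p) {
    do.call(rbind, lapply(c("serum", "stool"), function(type) {
      day <- pmin(pmax(grid + sample(-1:1, length(grid), replace = TRUE), 0),
                  config$followup_days)
      data.frame(sample_id = sprintf("%s_%s_d%02d", p, type, day),
                 patient_id = p, day = day, type = type,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(samples) <- NULL
  structure(list(
    patients = data.frame(patient_id = pid, nf_day = as.integer(nf_day),
                          bacteremia = bacteremia, stringsAsFactors = FALSE),
    samples = samples,
    config = config
  ), class = "cohort_skeleton")
}

## internal: complete natural-log concentration matrix (serum samples x metabolites)
.sim_metabolome_log <- function(skeleton, truth, seed) {
  set.seed(seed)
  serum <- skeleton$samples[skeleton$samples$type == "serum", ]
  nf <- skeleton$patients$nf_day[match(serum$patient_id,
                                       skeleton$patients$patient_id)]
  post <- !is.na(nf) & serum$day >= nf
  n <- nrow(serum)
  m <- truth$n_metabolites
  logx <- matrix(rnorm(n * m, truth$base_log_mean, truth$base_log_sd), n, m,
                 dimnames = list(serum$sample_id,
                                 sprintf("met%04d", seq_len(m))))
  for (i in seq_along(truth$signature_ids))
    logx[post, truth$signature_ids[i]] <-
      logx[post, truth$signature_ids[i]] + truth$shift_log2fc[i] * log(2)
  logx
}

## internal: censor values below each metabolite's detection-floor quantile
.apply_detection_floor <- function(conc, q) {
  if (q <= 0) return(conc)
  for (j in seq_len(ncol(conc))) {
    floor_j <- quantile(conc[, j], q, na.rm = TRUE)
    conc[conc[, j] < floor_j, j] <- NA_real_
  }
  conc
}

#' Generate the serum metabolite concentration matrix
#'
#' Concentrations are log-normal with the planted post-NF shift on signature
#' metabolites; values under the per-metabolite detection floor are censored
#' to `NA`.
#'
#' @param skeleton a [simulate_schedule()] result.
#' @param truth a [metabolome_truth()].
#' @param seed integer seed.
#' @return a numeric matrix (serum samples x metabolites) with `NA` for values
#'   below the detection floor.
#' @export
simulate_metabolome <- function(skeleton, truth, seed = 1L) {
  stopifnot(inherits(skeleton, "cohort_skeleton"),
            inherits(truth, "metabolome_truth"))
  logx <- .sim_metabolome_log(skeleton, truth, seed)
  .apply_detection_floor(exp(logx), truth$detection_floor_quantile)
}

#' Generate the stool ASV count table and the linked metabolite adjustments
#'
#' Per stool sample, genus relative abundances come from the log-normal
#' composition model; ASV counts are multinomial at a depth drawn uniformly
#' from `depth_range` (row sums equal the drawn depth exactly). When the truth
#' carries an association matrix `B`, each serum sample paired to a stool
#' sample (nearest preceding within 3 days, the same convention as
#' [pair_samples()]) receives an additive adjustment on the metabolite log
#' scale: `sum_g B[g, m] * log(true relative abundance of g)` plus
#' `N(0, noise_sd^2)` noise.
#'
#' @param skeleton a [simulate_schedule()] result.
#' @param truth a [microbiome_truth()].
#' @param seed integer seed.
#' @return a list with `counts` (integer matrix, stool samples x ASVs),
#'   `genus_map` (named character vector ASV -> genus), `rel_abundance` (true
#'   genus relative abundances per stool sample), `depths`, and `adjustment`
#'   (serum samples x target metabolites log-scale additive matrix; zero rows
#'   for unpaired serum samples; `NULL` when the truth has no association).
#' @export
simulate_microbiome <- function(skeleton, truth, seed = 1L) {
  stopifnot(inherits(skeleton, "cohort_skeleton"),
            inherits(truth, "microbiome_truth"))
  set.seed(seed)
  stool <- skeleton$samples[skeleton$samples$type == "stool", ]
  n <- nrow(stool)
  G <- truth$n_genera
  genus_ids <- sprintf("g%03d", seq_len(G))

  mu <- truth$genus_log_mean
  if (is.null(mu)) mu <- rnorm(G, 0, 2)

  ## fixed ASV weights within each genus (Dirichlet(1))
  A <- truth$asv_per_genus
  w <- matrix(rexp(G * A), G, A)
  w <- w / rowSums(w)
  asv_ids <- as.vector(t(outer(genus_ids, seq_len(A),
                               function(g, a) sprintf("%s_asv%d", g, a))))
  genus_map <- setNames(rep(genus_ids, each = A), asv_ids)

  rel <- matrix(NA_real_, n, G, dimnames = list(stool$sample_id, genus_ids))
  counts <- matrix(0L, n, G * A, dimnames = list(stool$sample_id, asv_ids))
  depths <- .resample(seq(truth$depth_range[1], truth$depth_range[2]),
                      n, replace = TRUE)
  for (i in seq_len(n)) {
    a <- exp(rnorm(G, mu, truth$genus_log_sd))
    rel[i, ] <- a / sum(a)
    p_asv <- as.vector(t(rel[i, ] * w))
    counts[i, ] <- as.integer(rmultinom(1, depths[i], p_asv))
  }

  adjustment <- NULL
  B <- truth$association
  if (!is.null(B)) {
    serum <- skeleton$samples[skeleton$samples$type == "serum", ]
    pairs <- pair_samples(serum, stool, max_lag_days = 3)
    adjustment <- matrix(0, nrow(serum), ncol(B),
                         dimnames = list(serum$sample_id, colnames(B)))
    if (nrow(pairs)) {
      Zlog <- log(rel[pairs$stool_id, , drop = FALSE])
      noise <- matrix(rnorm(nrow(pairs) * ncol(B), 0, truth$noise_sd),
                      nrow(pairs), ncol(B))
      adjustment[pairs$serum_id, ] <- Zlog %*% B + noise
    }
  }
  list(counts = counts, genus_map = genus_map, rel_abundance = rel,
       depths = setNames(depths, stool$sample_id), adjustment = adjustment)
}

#' Simulate a complete paired-omics cohort with known ground truth
#'
#' Orchestrates [simulate_schedule()], the metabolome model, the microbiome
#' model and the forward log-contrast link: serum log concentrations are
#' augmented by the paired-stool adjustment before the detection floor is
#' applied, so microbiota-driven metabolites can also fall below detection.
#'
#' @param config a [cohort_config()].
#' @param met_truth a [metabolome_truth()].
#' @param mic_truth a [microbiome_truth()], or `NULL` to skip the microbiome.
#' @return an object of class `synthetic_cohort`: `patients`, `samples`,
#'   `metabolome` (serum x metabolites, `NA` = below detection), `counts`,
#'   `genus_map`, and `truth` (the inputs, for benchmarking recovery).
#' @export
simulate_cohort <- function(config = cohort_config(),
                            met_truth = metabolome_truth(),
                            mic_truth = microbiome_truth()) {
  skeleton <- simulate_schedule(config)
  logx <- .sim_metabolome_log(skeleton, met_truth,
                              stage_seed(config$seed, 1L))
  mic <- NULL
  if (!is.null(mic_truth)) {
    mic <- simulate_microbiome(skeleton, mic_truth,
                               stage_seed(config$seed, 2L))
    if (!is.null(mic$adjustment)) {
      cols <- as.integer(colnames(mic$adjustment))
      logx[, cols] <- logx[, cols] + mic$adjustment
    }
  }
  metabolome <- .apply_detection_floor(exp(logx),
                                       met_truth$detection_floor_quantile)
  structure(list(
    patients = skeleton$patients,
    samples = skeleton$samples,
    metabolome = metabolome,
    counts = mic$counts,
    genus_map = mic$genus_map,
    truth = list(config = config, metabolome = met_truth,
                 microbiome = mic_truth,
                 rel_abundance = mic$rel_abundance)
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  serum <- sum(x$samples$type == "serum")
  stool <- sum(x$samples$type == "stool")
  cat("Synthetic paired-omics cohort\n")
  cat(sprintf("  %d patients (%d never febrile), %d serum + %d stool samples\n",
              nrow(x$patients), sum(is.na(x$patients$nf_day)), serum, stool))
  cat(sprintf("  %d metabolites (%.1f%% below detection), %s ASVs\n",
              ncol(x$metabolome), 100 * mean(is.na(x$metabolome)),
              if (is.null(x$counts)) "no" else ncol(x$counts)))
  invisible(x)
}
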