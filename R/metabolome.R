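#' Label serum samples as pre- or post-neutropenic-fever
#'
#' A sample collected before the patient's NF onset day is "pre"; a sample
#' collected on or after it is "post" (fever is present on the onset day
#' itself). Patients who never develop NF contribute pre-NF samples only.
#'
#' @param samples data.frame with at least `patient_id` and `day`.
#' @param nf_days named vector of NF onset days (names = patient ids, `NA` for
#'   never-febrile patients), or a data.frame with `patient_id` and `nf_day`.
#' @return a factor with levels `c("pre", "post")`, one per row of `samples`.
#' @export
assign_nf_groups <- function(samples, nf_days) {
  if (is.data.frame(nf_days))
    nf_days <- setNames(nf_days$nf_day, nf_days$patient_id)
  if (is.null(samples$day))
    .nf_stop("'samples' must have a 'day' column")
  nf <- nf_days[as.character(samples$patient_id)]
  factor(ifelse(!is.na(nf) & samples$day >= nf, "post", "pre"),
         levels = c("pre", "post"))
}

#' Drop metabolites detected in fewer than a fraction of samples
#'
#' Mirrors the standard untargeted-metabolomics filter: a metabolite must be
#' measurable (non-missing) in at least `min_fraction` of all samples to be
#' retained. Column order is preserved; the operation is idempotent.
#'
#' @param mat numeric matrix, samples x metabolites, `NA` = not detected.
#' @param min_fraction minimum detection fraction (default 0.5).
#' @return the matrix restricted to retained metabolites.
#' @export
filter_detectability <- function(mat, min_fraction = 0.5) {
  stopifnot(is.matrix(mat), nrow(mat) > 0, ncol(mat) > 0)
  min_fraction <- .check_frac(min_fraction, "min_fraction")
  keep <- colMeans(!is.na(mat)) >= min_fraction
  if (!any(keep)) warning("no metabolite passes the detectability filter")
  mat[, keep, drop = FALSE]
}

#' Half-minimum imputation of missing metabolite values
#'
#' Each missing cell is replaced by half the minimum observed value of that
#' metabolite plus Gaussian noise with sd `noise_sd_fraction` times the
#' imputed value (so ties are broken while the imputed values remain near the
#' detection floor), truncated at zero. Observed cells are never modified.
#'
#' @param mat numeric matrix, samples x metabolites, `NA` = missing; every
#'   metabolite must have at least one observed value (run
#'   [filter_detectability()] first).
#' @param noise_sd_fraction sd of the noise as a fraction of the half-minimum
#'   (default 0.01).
#' @param seed integer seed for the noise draws.
#' @return the completed matrix (no `NA`, all values >= 0).
#' @export
impute_half_min <- function(mat, noise_sd_fraction = 0.01, seed = 1L) {
  stopifnot(is.matrix(mat))
  if (any(mat < 0, na.rm = TRUE)) .nf_stop("concentrations must be non-negative")
  if (!anyNA(mat)) return(mat)
  all_missing <- colSums(!is.na(mat)) == 0
  if (any(all_missing))
    .nf_stop("metabolite(s) with no observed value: ",
             paste(head(which(all_missing)), collapse = ", "),
             "; run filter_detectability() first")
  set.seed(seed)
  for (j in seq_len(ncol(mat))) {
    miss <- is.na(mat[, j])
    if (!any(miss)) next
    half_min <- 0.5 * min(mat[, j], na.rm = TRUE)
    mat[miss, j] <- pmax(half_min + rnorm(sum(miss), 0,
                                          noise_sd_fraction * half_min), 0)
  }
  mat
}
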