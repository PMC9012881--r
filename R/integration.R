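#' Pair each serum sample with its nearest preceding stool sample
#'
#' For every serum sample, the stool sample from the same patient with the
#' smallest non-negative lag (serum day minus stool day) at most
#' `max_lag_days` is chosen; a stool sample collected on the same day is
#' eligible (lag 0). Serum samples with no eligible stool are left unpaired
#' and dropped from the paired analysis. A stool sample may serve several
#' serum samples.
#'
#' @param serum,stool data.frames with `sample_id`, `patient_id`, `day`.
#' @param max_lag_days maximum allowed lag in days (default 3).
#' @return a data.frame with `serum_id`, `stool_id`, `lag` (one row per
#'   paired serum sample).
#' @export
pair_samples <- function(serum, stool, max_lag_days = 3) {
  for (df in list(serum, stool))
    if (!all(c("sample_id", "patient_id", "day") %in% names(df)))
      .nf_stop("metadata needs columns sample_id, patient_id, day")
  out <- lapply(seq_len(nrow(serum)), function(i) {
    cand <- stool[stool$patient_id == serum$patient_id[i], , drop = FALSE]
    lag <- serum$day[i] - cand$day
    ok <- lag >= 0 & lag <= max_lag_days
    if (!any(ok)) return(NULL)
    j <- which(ok)[which.min(lag[ok])]
    data.frame(serum_id = serum$sample_id[i], stool_id = cand$sample_id[j],
               lag = lag[j], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(serum_id = character(), stool_id = character(),
                      lag = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles of their fractional ranks,
#' `qnorm((rank - 0.5) / n)`, with average ranks for ties. The result depends
#' only on the ranks, so any strictly monotone pre-transform of the input
#' yields the same output.
#'
#' @param x numeric vector without missing values.
#' @return the transformed vector.
#' @export
rank_int <- function(x) {
  if (anyNA(x)) .nf_stop("rank_int() does not accept missing values")
  r <- rank(x, ties.method = "average")
  qnorm((r - 0.5) / length(x))
}

#' Drop genera present in fewer than a fraction of samples
#'
#' @param counts count matrix, samples x genera.
#' @param min_fraction minimum presence fraction (default 0.20; a genus
#'   present in exactly 20% of samples is retained).
#' @return the filtered matrix.
#' @export
prevalence_filter <- function(counts, min_fraction = 0.20) {
  stopifnot(is.matrix(counts))
  counts[, colMeans(counts > 0) >= min_fraction, drop = FALSE]
}

#' Log-contrast design matrix from genus counts
#'
#' `Z[s, g] = log((count + pseudocount) / sum(counts + pseudocount))`, with
#' columns centered to zero mean (unit-variance scaling optional, off by
#' default). Because fitted coefficients are constrained to sum to zero,
#' predictions from this design are invariant to each sample's sequencing
#' depth; column centering preserves that invariance, while unit-variance
#' scaling would not, which is why it is not the default.
#'
#' @param counts count matrix, samples x genera.
#' @param pseudocount value added to counts before closure (default 0.5).
#' @param scale also scale columns to unit variance (default `FALSE`).
#' @return the design matrix `Z` with attributes `center` (and `scale` when
#'   scaling).
#' @export
log_contrast_design <- function(counts, pseudocount = 0.5, scale = FALSE) {
  stopifnot(is.matrix(counts))
  if (pseudocount <= 0 && any(counts == 0))
    .nf_stop("a positive pseudocount is required when the table has zeros")
  a <- counts + pseudocount
  Z <- log(a / rowSums(a))
  ctr <- colMeans(Z)
  Z <- sweep(Z, 2, ctr)
  attr(Z, "center") <- ctr
  if (scale) {
    s <- apply(Z, 2, sd)
    s[s == 0] <- 1
    Z <- sweep(Z, 2, s, `/`)
    attr(Z, "scale") <- s
  }
  Z
}
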