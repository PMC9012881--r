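#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)` between non-negative sample
#' profiles, computed with [vegan::vegdist()]. Pairs of all-zero rows, for
#' which the ratio is 0/0, are assigned distance 0 by convention.
#'
#' @param mat non-negative numeric matrix, samples x features, no missing
#'   values.
#' @return a symmetric matrix of class `dist`-free plain matrix with zero
#'   diagonal and entries in `[0, 1]`.
#' @export
bray_curtis <- function(mat) {
  stopifnot(is.matrix(mat))
  if (anyNA(mat)) .nf_stop("matrix must be complete (impute first)")
  if (any(mat < 0)) .nf_stop("Bray-Curtis requires non-negative values")
  d <- suppressWarnings(as.matrix(vegan::vegdist(mat, method = "bray")))
  d[is.nan(d)] <- 0  # both profiles all-zero
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

## internal: within-group sum of squares from a squared-distance matrix
.ss_within <- function(D2, groups) {
  s <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- s + sum(D2[idx, idx]) / (2 * length(idx))
  }
  s
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance partitioning the total sum
#' of squared distances between and within groups: `SS_total` from all sample
#' pairs, `SS_within` from within-group pairs, `R2 = 1 - SS_within/SS_total`,
#' and a pseudo-F whose null distribution is obtained by permuting group
#' labels freely across samples. The p-value includes the observed statistic
#' in both numerator and denominator:
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`.
#'
#' @param d symmetric distance matrix (plain matrix or `dist`).
#' @param groups group label per sample (>= 2 groups, each non-empty).
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed for the permutations.
#' @param strata optional blocking factor (e.g. patient id); when supplied,
#'   labels are permuted only within blocks. Off by default.
#' @return a list of class `nf_permanova` with `R2`, `F`, `p`, `df`, and the
#'   sums of squares.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L, strata = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.factor(groups)
  if (length(groups) != n)
    .nf_stop("'groups' length must match the distance matrix")
  if (nlevels(droplevels(groups)) < 2)
    .nf_stop("PERMANOVA needs at least two groups")
  a <- nlevels(droplevels(groups))
  D2 <- d^2
  ss_total <- sum(D2) / (2 * n)
  f_stat <- function(g) {
    ssw <- .ss_within(D2, g)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  ssw_obs <- .ss_within(D2, groups)
  F_obs <- ((ss_total - ssw_obs) / (a - 1)) / (ssw_obs / (n - a))
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    gp <- if (is.null(strata)) groups[sample.int(n)] else {
      perm <- seq_len(n)
      for (s in unique(strata)) {
        idx <- which(strata == s)
        perm[idx] <- idx[sample.int(length(idx))]
      }
      groups[perm]
    }
    if (f_stat(gp) >= F_obs) exceed <- exceed + 1L
  }
  structure(list(
    R2 = 1 - ssw_obs / ss_total, F = F_obs,
    p = (1 + exceed) / (1 + n_perm),
    df = c(between = a - 1, within = n - a),
    ss = c(total = ss_total, within = ssw_obs,
           between = ss_total - ssw_obs),
    n_perm = n_perm
  ), class = "nf_permanova")
}

#' @export
print.nf_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: R2 = %.4f, pseudo-F(%d, %d) = %.3f, p = %.4g (%d permutations)\n",
              x$R2, x$df[1], x$df[2], x$F, x$p, x$n_perm))
  invisible(x)
}

#' Per-metabolite Welch tests with fold changes and BH correction
#'
#' For each metabolite, a two-sided Welch (unequal-variance) t-test comparing
#' the two groups, the log2 fold change of the second-level group mean over
#' the first, and Benjamini-Hochberg q-values. With `log = TRUE` the t-tests
#' run on natural-log values while fold changes are still computed from the
#' raw group means. Metabolites with zero variance in both groups and equal
#' means get `t = 0, p = 1` by convention.
#'
#' @param mat complete numeric matrix, samples x metabolites.
#' @param groups two-level factor (first level is the reference, e.g. "pre").
#' @param log test log-transformed values (default `FALSE`).
#' @return a data.frame of class `nf_volcano`: `metabolite`, `mean_ref`,
#'   `mean_alt`, `lfc` (log2 alt/ref), `t`, `p`, `q`.
#' @export
welch_volcano <- function(mat, groups, log = FALSE) {
  stopifnot(is.matrix(mat))
  if (anyNA(mat)) .nf_stop("matrix must be complete (impute first)")
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2)
    .nf_stop("'groups' must have exactly two levels")
  lv <- levels(droplevels(groups))
  i1 <- groups == lv[1]; i2 <- groups == lv[2]
  if (sum(i1) < 2 || sum(i2) < 2)
    .nf_stop("each group needs at least two samples")
  tmat <- if (log) log(mat) else mat
  n_degenerate <- 0L
  res <- t(vapply(seq_len(ncol(mat)), function(j) {
    x1 <- tmat[i1, j]; x2 <- tmat[i2, j]
    m1 <- mean(mat[i1, j]); m2 <- mean(mat[i2, j])
    lfc <- if (m1 > 0 && m2 > 0) log2(m2 / m1) else NA_real_
    if (sd(x1) == 0 && sd(x2) == 0) {
      n_degenerate <<- n_degenerate + 1L
      return(c(m1, m2, lfc, 0, 1))
    }
    tt <- t.test(x2, x1, var.equal = FALSE)
    c(m1, m2, lfc, unname(tt$statistic), tt$p.value)
  }, numeric(5)))
  if (n_degenerate > 0L)
    message(n_degenerate,
            " metabolite(s) with zero variance in both groups: p set to 1")
  out <- data.frame(
    metabolite = colnames(mat) %||% as.character(seq_len(ncol(mat))),
    mean_ref = res[, 1], mean_alt = res[, 2], lfc = res[, 3],
    t = res[, 4], p = res[, 5], q = bh_adjust(res[, 5]),
    stringsAsFactors = FALSE)
  class(out) <- c("nf_volcano", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate q-values,
#' `q_(i) = min_\{j >= i\} p_(j) * m / j` capped at 1 (the standard
#' [stats::p.adjust()] "BH" procedure).
#'
#' @param p vector of p-values.
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Centered principal components analysis with a fixed sign convention
#'
#' Wraps [stats::prcomp()] (centered, optionally unit-variance scaled) and
#' fixes each component's sign so that its largest-magnitude loading is
#' positive, making ordinations reproducible across platforms.
#'
#' @param mat complete numeric matrix, samples x features.
#' @param scale. unit-variance scale features first (default `TRUE`;
#'   constant features are dropped with a warning when scaling).
#' @return a list of class `nf_pca`: `scores` (samples x components),
#'   `loadings` (features x components), `var_explained` (fractions summing
#'   to 1), and `center`/`scale`.
#' @export
pca_ordination <- function(mat, scale. = TRUE) {
  stopifnot(is.matrix(mat))
  if (anyNA(mat)) .nf_stop("matrix must be complete")
  if (scale.) {
    const <- apply(mat, 2, sd) == 0
    if (any(const)) {
      warning(sum(const), " constant feature(s) dropped before scaling")
      mat <- mat[, !const, drop = FALSE]
    }
  }
  pc <- prcomp(mat, center = TRUE, scale. = scale.)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
    v <- pc$rotation[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  structure(list(
    scores = sweep(pc$x, 2, flip, `*`),
    loadings = sweep(pc$rotation, 2, flip, `*`),
    var_explained = pc$sdev^2 / sum(pc$sdev^2),
    center = pc$center, scale = pc$scale
  ), class = "nf_pca")
}

#' Complete-linkage hierarchical clustering of samples
#'
#' Euclidean distances followed by complete agglomeration
#' ([stats::hclust()]), the convention used to order heatmap rows before
#' superimposing group labels.
#'
#' @param mat complete numeric matrix, samples x features.
#' @return an `hclust` object.
#' @export
cluster_samples <- function(mat) {
  stopifnot(is.matrix(mat))
  if (anyNA(mat)) .nf_stop("matrix must be complete")
  hclust(dist(mat, method = "euclidean"), method = "complete")
}
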