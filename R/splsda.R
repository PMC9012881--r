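## internal: stratified fold assignment (uses the current RNG state)
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

## internal: soft-threshold a vector so exactly `keep` entries stay nonzero
.soft_keep <- function(u, keep) {
  p <- length(u)
  if (keep >= p) return(u)
  a <- abs(u)
  thr <- sort(a, decreasing = TRUE)[keep + 1L]
  sign(u) * pmax(a - thr, 0)
}

#' Fit a two-class sparse PLS discriminant analysis model
#'
#' Sparse partial least squares on unit-variance-scaled `X` against the
#' centered/scaled dummy-coded class matrix. Per component, the X-loading is
#' the dominant singular direction of the X-Y cross-covariance,
#' soft-thresholded so exactly `keepX` entries remain nonzero and
#' renormalized (iterated to a fixed point); `X` and `Y` are then deflated by
#' regression on the component score. The fit is deterministic.
#'
#' @param X numeric matrix, samples x features.
#' @param y two-level factor of class labels.
#' @param ncomp number of components (default 1).
#' @param keepX number of nonzero loadings per component, recycled to
#'   `ncomp` (default: all features, i.e. dense PLS-DA).
#' @return an object of class `nf_splsda` with per-component loadings
#'   (`W`, unit L2 norm), X-loadings `P`, sample scores `T`, class centroids
#'   in score space, and the centering/scaling parameters.
#' @export
splsda_fit <- function(X, y, ncomp = 1, keepX = ncol(X)) {
  stopifnot(is.matrix(X))
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) .nf_stop("sPLS-DA here is two-class; got ", nlevels(y))
  if (nrow(X) != length(y)) .nf_stop("nrow(X) must equal length(y)")
  ncomp <- .check_count(ncomp, "ncomp")
  keepX <- rep_len(as.integer(keepX), ncomp)
  if (any(keepX < 1)) .nf_stop("'keepX' must be >= 1")

  sds <- apply(X, 2, sd)
  const <- sds == 0
  if (any(const)) {
    warning(sum(const), " constant feature(s) dropped")
    X <- X[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  p <- ncol(X)
  keepX <- pmin(keepX, p)
  mus <- colMeans(X)
  Xs <- scale(X, center = mus, scale = sds)

  Ydum <- stats::model.matrix(~ y - 1)
  Ys <- scale(Ydum, center = TRUE, scale = TRUE)

  W <- P <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  Tm <- matrix(0, nrow(X), ncomp, dimnames = list(rownames(X), NULL))
  Xh <- Xs; Yh <- Ys
  for (h in seq_len(ncomp)) {
    M <- crossprod(Xh, Yh)
    sv <- svd(M, nu = 1, nv = 1)
    v <- sv$v[, 1]
    u <- numeric(p)
    for (it in seq_len(500)) {
      u_new <- .soft_keep(drop(M %*% v), keepX[h])
      nrm <- sqrt(sum(u_new^2))
      if (nrm == 0) break
      u_new <- u_new / nrm
      v_new <- drop(crossprod(M, u_new))
      v_new <- v_new / sqrt(sum(v_new^2))
      if (max(abs(u_new - u)) < 1e-10) { u <- u_new; v <- v_new; break }
      u <- u_new; v <- v_new
    }
    tt <- drop(Xh %*% u)
    denom <- sum(tt^2)
    ph <- drop(crossprod(Xh, tt)) / denom
    ch <- drop(crossprod(Yh, tt)) / denom
    Xh <- Xh - tcrossprod(tt, ph)
    Yh <- Yh - tcrossprod(tt, ch)
    W[, h] <- u; P[, h] <- ph; Tm[, h] <- tt
  }
  centroids <- rbind(colMeans(Tm[y == levels(y)[1], , drop = FALSE]),
                     colMeans(Tm[y == levels(y)[2], , drop = FALSE]))
  rownames(centroids) <- levels(y)
  structure(list(
    W = W, P = P, scores = Tm, centroids = centroids,
    keepX = keepX, ncomp = ncomp, levels = levels(y), y = y,
    center = mus, scale = sds
  ), class = "nf_splsda")
}

#' @export
print.nf_splsda <- function(x, ...) {
  cat(sprintf("Sparse PLS-DA: %d component(s), keepX = %s, classes %s vs %s\n",
              x$ncomp, paste(x$keepX, collapse = "/"),
              x$levels[1], x$levels[2]))
  cat(sprintf("  component-1 support: %d feature(s)\n", sum(x$W[, 1] != 0)))
  invisible(x)
}

#' @export
coef.nf_splsda <- function(object, comp = 1, ...) object$W[, comp]

#' Project new samples and classify by nearest class centroid
#'
#' New samples are scaled by the training parameters and projected into the
#' component space via `W (P'W)^{-1}`; each is assigned the class whose
#' training-score centroid is nearest. `score` is the signed difference of
#' centroid distances (positive leans to the second class), usable as a
#' continuous ROC score.
#'
#' @param object an `nf_splsda` fit.
#' @param newdata numeric matrix with the training features.
#' @param ... unused.
#' @return a list with `class` (factor), `score` (numeric) and `scores`
#'   (projected components).
#' @export
predict.nf_splsda <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  if (!is.null(colnames(newdata)) && !is.null(names(object$center)))
    newdata <- newdata[, names(object$center), drop = FALSE]
  Xs <- scale(newdata, center = object$center, scale = object$scale)
  R <- object$W %*% solve(crossprod(object$P, object$W))
  Tn <- Xs %*% R
  d1 <- sqrt(rowSums(sweep(Tn, 2, object$centroids[1, ], `-`)^2))
  d2 <- sqrt(rowSums(sweep(Tn, 2, object$centroids[2, ], `-`)^2))
  cls <- factor(ifelse(d2 < d1, object$levels[2], object$levels[1]),
                levels = object$levels)
  list(class = cls, score = d1 - d2, scores = Tn)
}

#' @export
plot.nf_splsda <- function(x, comps = c(1, min(2, x$ncomp)), ...) {
  comps <- unique(comps)
  if (length(comps) == 1) comps <- c(comps, comps)
  plot(x$scores[, comps[1]], x$scores[, comps[2]],
       col = as.integer(x$y), pch = as.integer(x$y),
       xlab = paste("Component", comps[1]),
       ylab = paste("Component", comps[2]), ...)
  invisible(x)
}

## internal: mean per-class error rate of predicted vs true labels
.balanced_error <- function(truth, pred) {
  mean(vapply(levels(truth), function(lv) {
    idx <- truth == lv
    if (!any(idx)) return(NA_real_)
    mean(pred[idx] != lv)
  }, numeric(1)), na.rm = TRUE)
}

#' Tune keepX (and implicitly ncomp) by stratified cross-validation
#'
#' Per component, selects the `keepX` minimizing the mean CV balanced
#' classification error over `repeats` repetitions of `folds`-fold stratified
#' cross-validation; ties go to the smallest `keepX` (the sparser model).
#' Components are tuned sequentially, conditioning on the previous choices.
#'
#' @param X,y as in [splsda_fit()].
#' @param keepX_grid integer vector of candidate support sizes.
#' @param ncomp number of components to tune (default 1).
#' @param folds CV folds (default 10).
#' @param repeats CV repetitions (default 1).
#' @param seed integer seed for fold assignment.
#' @return a list with `keepX` (chosen per component), `ncomp`, and the CV
#'   error matrix `cv_error` (grid x component).
#' @export
tune_splsda <- function(X, y, keepX_grid, ncomp = 1, folds = 10, repeats = 1,
                        seed = 1L) {
  y <- droplevels(as.factor(y))
  keepX_grid <- sort(unique(as.integer(keepX_grid)))
  set.seed(seed)
  chosen <- integer(0)
  err <- matrix(NA_real_, length(keepX_grid), ncomp,
                dimnames = list(keepX_grid, NULL))
  for (h in seq_len(ncomp)) {
    errs <- matrix(0, length(keepX_grid), repeats * folds)
    col <- 0L
    for (r in seq_len(repeats)) {
      fold <- .stratified_folds(y, folds)
      for (f in seq_len(folds)) {
        col <- col + 1L
        tr <- fold != f
        if (nlevels(droplevels(y[tr])) < 2) { errs[, col] <- NA; next }
        for (gi in seq_along(keepX_grid)) {
          fit <- suppressWarnings(
            splsda_fit(X[tr, , drop = FALSE], y[tr], ncomp = h,
                       keepX = c(chosen, keepX_grid[gi])))
          pr <- predict(fit, X[!tr, , drop = FALSE])
          errs[gi, col] <- .balanced_error(y[!tr], pr$class)
        }
      }
    }
    err[, h] <- rowMeans(errs, na.rm = TRUE)
    chosen <- c(chosen, keepX_grid[which.min(err[, h])])
  }
  list(keepX = chosen, ncomp = ncomp, cv_error = err)
}

#' Stability selection for the component-1 sPLS-DA signature
#'
#' Refits the model on every cross-validation training split
#' (`repeats x folds` fits) and records, per feature, the fraction of fits in
#' which it enters the component-1 support. The stable signature is the set
#' of features with frequency strictly above `threshold`.
#'
#' @param X,y as in [splsda_fit()].
#' @param keepX per-component support sizes of the model being stabilized.
#' @param ncomp number of components (default 1).
#' @param folds,repeats CV geometry (defaults 10 and 10, i.e. 100 refits).
#' @param threshold stability threshold (default 0.90, strict inequality).
#' @param seed integer seed.
#' @return a list of class `nf_stability`: `frequency` (named, in `[0,1]`),
#'   `stable` (character vector of stable features), `threshold`, `n_fits`.
#' @export
splsda_stability <- function(X, y, keepX, ncomp = 1, folds = 10, repeats = 10,
                             threshold = 0.90, seed = 1L) {
  y <- droplevels(as.factor(y))
  feat <- colnames(X) %||% as.character(seq_len(ncol(X)))
  colnames(X) <- feat
  set.seed(seed)
  count <- setNames(numeric(length(feat)), feat)
  n_fits <- 0L
  for (r in seq_len(repeats)) {
    fold <- .stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (nlevels(droplevels(y[tr])) < 2) next
      fit <- suppressWarnings(
        splsda_fit(X[tr, , drop = FALSE], y[tr], ncomp = ncomp,
                   keepX = keepX))
      sel <- rownames(fit$W)[fit$W[, 1] != 0]
      count[sel] <- count[sel] + 1
      n_fits <- n_fits + 1L
    }
  }
  freq <- count / n_fits
  structure(list(frequency = freq,
                 stable = names(freq)[freq > threshold],
                 threshold = threshold, n_fits = n_fits),
            class = "nf_stability")
}

#' @export
print.nf_stability <- function(x, ...) {
  cat(sprintf("Stability selection over %d refits: %d feature(s) above %.0f%%\n",
              x$n_fits, length(x$stable), 100 * x$threshold))
  invisible(x)
}

#' Leave-one-out cross-validated ROC curve and AUC
#'
#' Each sample is scored by a model fitted without it (centroid-distance
#' score from [predict.nf_splsda()]); the AUC is the rank statistic (Wilcoxon
#' form, ties handled by average ranks) for predicting the second class.
#'
#' @param X,y as in [splsda_fit()].
#' @param keepX,ncomp model specification.
#' @return a list with `auc` and `roc` (data.frame: `threshold`, `tpr`,
#'   `fpr`).
#' @export
loocv_auc <- function(X, y, keepX, ncomp = 1) {
  y <- droplevels(as.factor(y))
  n <- nrow(X)
  score <- vapply(seq_len(n), function(i) {
    fit <- suppressWarnings(
      splsda_fit(X[-i, , drop = FALSE], y[-i], ncomp = ncomp, keepX = keepX))
    predict(fit, X[i, , drop = FALSE])$score
  }, numeric(1))
  pos <- y == levels(y)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(score)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(score), decreasing = TRUE)
  roc <- data.frame(
    threshold = c(Inf, thr),
    tpr = c(0, vapply(thr, function(t) mean(score[pos] >= t), numeric(1))),
    fpr = c(0, vapply(thr, function(t) mean(score[!pos] >= t), numeric(1))))
  list(auc = auc, roc = roc, score = score)
}
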