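## Zero-sum constrained sparse log-contrast regression.
##
## The estimator solves
##     min_{beta0, beta}  (1/2n) || y - beta0 - Z beta ||^2 + lambda ||beta||_1
##     subject to         sum(beta) = 0,
## the sparse linear log-contrast model for compositional covariates: because
## the coefficients sum to zero, fitted values are invariant to per-sample
## depth scaling of the raw counts behind Z. Solved by ADMM (the equality
## constraint is handled exactly in the beta update through a KKT linear
## system; the L1 term through soft thresholding), followed by a polish step
## that re-solves the equality-constrained problem on the detected support so
## that zeros are exact and the zero-sum residual is at machine precision.

.soft <- function(x, k) sign(x) * pmax(abs(x) - k, 0)

## internal: objective on the original (uncentered) data scale
.zs_objective <- function(Z, y, beta, beta0, lambda) {
  r <- y - beta0 - drop(Z %*% beta)
  sum(r^2) / (2 * length(y)) + lambda * sum(abs(beta))
}

## internal: smallest lambda at which the solution is exactly zero:
## at beta = 0 the KKT conditions hold iff |c_j + mu| <= lambda for some mu,
## minimized by mu = -(max(c) + min(c))/2.
.zs_lambda_max <- function(c_vec) (max(c_vec) - min(c_vec)) / 2

## internal: ADMM iterations for one lambda; Kinv prefactored for rho
.zs_admm <- function(Kinv, c_vec, lambda, rho, p, state = NULL,
                     max_iter = 10000, tol = 1e-9) {
  gamma <- if (is.null(state)) numeric(p) else state$gamma
  u <- if (is.null(state)) numeric(p) else state$u
  it <- 0L
  repeat {
    it <- it + 1L
    rhs <- c(c_vec + rho * (gamma - u), 0)
    beta <- drop(Kinv %*% rhs)[seq_len(p)]
    gamma_new <- .soft(beta + u, lambda / rho)
    dual <- rho * sqrt(sum((gamma_new - gamma)^2))
    gamma <- gamma_new
    u <- u + beta - gamma
    primal <- sqrt(sum((beta - gamma)^2))
    if ((primal < tol && dual < tol) || it >= max_iter) break
  }
  list(beta = beta, gamma = gamma, u = u, iterations = it,
       converged = it < max_iter)
}

## internal: equality-constrained refit on a fixed support with fixed signs
.zs_polish <- function(G, c_vec, lambda, support, signs) {
  k <- length(support)
  K <- rbind(cbind(G[support, support, drop = FALSE], 1), c(rep(1, k), 0))
  sol <- tryCatch(solve(K, c(c_vec[support] - lambda * signs, 0)),
                  error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  b <- sol[seq_len(k)]
  if (any(sign(b) * signs < 0)) return(NULL)  # sign flip: support was wrong
  b
}

#' Fit the zero-sum constrained lasso for one response
#'
#' Sparse linear log-contrast regression of a (typically inverse-normal
#' transformed) metabolite on log relative genus abundances, with an L1
#' penalty for variable selection and the compositional zero-sum constraint
#' `sum(beta) = 0` on the genus coefficients. For `lambda` at or above the
#' data-derived `lambda_max` the solution is exactly zero with
#' `intercept = mean(y)`.
#'
#' @param Z design matrix (samples x genera), e.g. from
#'   [log_contrast_design()].
#' @param y numeric response vector.
#' @param lambda non-negative penalty level.
#' @param rho ADMM penalty parameter; defaults to the mean diagonal of
#'   `Z'Z/n`.
#' @param max_iter,tol ADMM iteration cap and residual tolerance.
#' @return an object of class `zerosum_lasso`: `coefficients` (named, sparse
#'   for large lambda), `intercept`, `lambda`, `lambda_max`, `sum_beta`,
#'   `kkt_residual`, `objective`, `df` (support size), `iterations`,
#'   `fitted.values`, `y`.
#' @seealso [cv_zerosum_lasso()] for penalty selection,
#'   [bootstrap_stability()] for stability selection.
#' @export
zerosum_lasso <- function(Z, y, lambda, rho = NULL, max_iter = 10000,
                          tol = 1e-9) {
  stopifnot(is.matrix(Z))
  if (!all(is.finite(Z)) || !all(is.finite(y)))
    .nf_stop("non-finite values in the design or response")
  if (nrow(Z) != length(y)) .nf_stop("nrow(Z) must equal length(y)")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    .nf_stop("'lambda' must be a single non-negative number")
  n <- nrow(Z); p <- ncol(Z)
  genera <- colnames(Z) %||% as.character(seq_len(p))
  zm <- colMeans(Z); ym <- mean(y)
  Zc <- sweep(Z, 2, zm); yc <- y - ym
  G <- crossprod(Zc) / n
  c_vec <- drop(crossprod(Zc, yc)) / n
  lam_max <- .zs_lambda_max(c_vec)

  beta <- numeric(p)
  iterations <- 0L
  if (p >= 2 && lambda < lam_max) {
    if (is.null(rho)) rho <- max(mean(diag(G)), 1e-3)
    K <- rbind(cbind(G + diag(rho, p), 1), c(rep(1, p), 0))
    Kinv <- solve(K)
    st <- .zs_admm(Kinv, c_vec, lambda, rho, p, max_iter = max_iter,
                   tol = tol)
    iterations <- st$iterations
    ## candidate 1: ADMM gamma projected exactly onto the zero-sum set
    cand <- list()
    supp <- which(st$gamma != 0)
    if (length(supp) >= 2) {
      b <- st$gamma
      b[supp] <- b[supp] - mean(b[supp])
      cand$projected <- b
      polished <- .zs_polish(G, c_vec, lambda, supp, sign(st$gamma[supp]))
      if (!is.null(polished)) {
        b2 <- numeric(p); b2[supp] <- polished
        cand$polished <- b2
      }
    }
    cand$zero <- numeric(p)
    objs <- vapply(cand, function(b)
      .zs_objective(Z, y, b, ym - sum(zm * b), lambda), numeric(1))
    beta <- cand[[which.min(objs)]]
  }

  intercept <- ym - sum(zm * beta)
  fitted <- intercept + drop(Z %*% beta)

  ## KKT diagnostics on the final coefficients
  g <- drop(G %*% beta) - c_vec
  supp <- which(beta != 0)
  mu <- if (length(supp)) -mean(g[supp] + lambda * sign(beta[supp]))
        else -(max(g) + min(g)) / 2
  nonsupp <- setdiff(seq_len(p), supp)
  kkt <- max(abs(sum(beta)),
             if (length(supp)) max(abs(g[supp] + lambda * sign(beta[supp]) + mu)) else 0,
             if (length(nonsupp)) max(pmax(abs(g[nonsupp] + mu) - lambda, 0)) else 0)
  structure(list(
    coefficients = setNames(beta, genera), intercept = intercept,
    lambda = lambda, lambda_max = lam_max,
    sum_beta = sum(beta), kkt_residual = kkt,
    objective = .zs_objective(Z, y, beta, intercept, lambda),
    df = length(supp), iterations = iterations,
    fitted.values = fitted, y = y
  ), class = "zerosum_lasso")
}

#' @export
print.zerosum_lasso <- function(x, digits = 4, ...) {
  cat(sprintf("Zero-sum lasso fit: lambda = %.4g, %d of %d nonzero coefficients\n",
              x$lambda, x$df, length(x$coefficients)))
  cat(sprintf("  sum(beta) = %.2e, KKT residual = %.2e, objective = %.*f\n",
              x$sum_beta, x$kkt_residual, digits, x$objective))
  if (x$df > 0) {
    nz <- x$coefficients[x$coefficients != 0]
    print(round(nz[order(-abs(nz))], digits))
  }
  invisible(x)
}

#' @export
coef.zerosum_lasso <- function(object, ...)
  c("(Intercept)" = object$intercept, object$coefficients)

#' @export
predict.zerosum_lasso <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  object$intercept + drop(newdata %*% object$coefficients)
}

#' @export
fitted.zerosum_lasso <- function(object, ...) object$fitted.values

#' @export
residuals.zerosum_lasso <- function(object, ...)
  object$y - object$fitted.values

#' Cross-validated penalty selection for the zero-sum lasso
#'
#' Fits the solution path on a log-spaced grid descending from the full-data
#' `lambda_max` (the smallest penalty giving an all-zero solution) and
#' computes the mean held-out squared error by k-fold cross-validation. The
#' default selection rule is the one-standard-error rule: the largest
#' penalty whose CV error is within one standard error of the minimum. Near
#' its minimum the CV curve is typically flat, and the error-minimizing
#' penalty drifts to dense solutions whose bootstrap refits select noise
#' genera persistently, defeating downstream stability selection; the 1-SE
#' rule is the standard remedy. `rule = "min"` selects the minimizer
#' instead (ties go to the larger, sparser penalty).
#'
#' @param Z,y as in [zerosum_lasso()].
#' @param lambda optional penalty grid (sorted descending internally);
#'   by default `n_lambda` log-spaced values spanning
#'   `lambda_max` down to `lambda_max * lambda_min_ratio`.
#' @param n_lambda,lambda_min_ratio grid shape (defaults 20 and 1e-3).
#' @param folds number of CV folds (default 10).
#' @param rule `"1se"` (default) or `"min"`.
#' @param seed integer seed for the fold assignment.
#' @return a list of class `cv_zerosum_lasso`: `lambda` (grid), `cvm`,
#'   `cvsd`, `lambda_min`, `lambda_1se`, `lambda_opt` (the selected penalty
#'   under `rule`), `rule`, and `fit` (the full-data [zerosum_lasso()] at
#'   `lambda_opt`).
#' @export
cv_zerosum_lasso <- function(Z, y, lambda = NULL, n_lambda = 20,
                             lambda_min_ratio = 1e-3, folds = 10,
                             rule = c("1se", "min"), seed = 1L) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(Z))
  n <- nrow(Z)
  if (folds < 2 || folds > n) .nf_stop("'folds' must be in [2, n]")
  if (is.null(lambda)) {
    zm <- colMeans(Z); ym <- mean(y)
    c_vec <- drop(crossprod(sweep(Z, 2, zm), y - ym)) / n
    lam_max <- .zs_lambda_max(c_vec)
    if (lam_max <= 0) lam_max <- 1e-3
    lambda <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                      length.out = n_lambda))
  }
  lambda <- sort(lambda, decreasing = TRUE)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  err <- matrix(NA_real_, folds, length(lambda))
  for (f in seq_len(folds)) {
    tr <- fold != f
    for (k in seq_along(lambda)) {
      fit <- zerosum_lasso(Z[tr, , drop = FALSE], y[tr], lambda[k])
      pred <- predict(fit, Z[!tr, , drop = FALSE])
      err[f, k] <- mean((y[!tr] - pred)^2)
    }
  }
  cvm <- colMeans(err)
  cvsd <- apply(err, 2, sd) / sqrt(folds)
  best <- which.min(cvm)  # grid is descending, so ties pick the larger lambda
  lambda_1se <- max(lambda[cvm <= cvm[best] + cvsd[best]])
  lambda_opt <- if (rule == "1se") lambda_1se else lambda[best]
  structure(list(
    lambda = lambda, cvm = cvm, cvsd = cvsd,
    lambda_min = lambda[best], lambda_1se = lambda_1se,
    lambda_opt = lambda_opt, rule = rule,
    fit = zerosum_lasso(Z, y, lambda_opt)
  ), class = "cv_zerosum_lasso")
}

#' @export
print.cv_zerosum_lasso <- function(x, ...) {
  cat(sprintf("CV zero-sum lasso (%s rule): lambda = %.4g (grid of %d), min CV MSE = %.4f\n",
              x$rule, x$lambda_opt, length(x$lambda), min(x$cvm)))
  print(x$fit)
  invisible(x)
}

#' @export
plot.cv_zerosum_lasso <- function(x, ...) {
  plot(log(x$lambda), x$cvm, type = "b", xlab = "log(lambda)",
       ylab = "CV mean squared error", ...)
  abline(v = log(x$lambda_opt), lty = 2)
  invisible(x)
}

#' Bootstrap stability selection for the zero-sum lasso
#'
#' Refits the model at a fixed penalty on `B` bootstrap resamples of the
#' paired rows; a genus's selection frequency is the fraction of resamples in
#' which its coefficient is nonzero. Genera with frequency strictly above
#' `threshold` are retained; their association sign is the sign of the
#' full-data coefficient. Degenerate resamples (constant response) are
#' redrawn.
#'
#' @param Z,y as in [zerosum_lasso()].
#' @param lambda penalty, typically `lambda_opt` from [cv_zerosum_lasso()].
#' @param B number of bootstrap resamples (default 100).
#' @param threshold stability threshold (default 0.90; strict inequality, so
#'   at the default a genus must appear in at least 91 of 100 resamples).
#' @param seed integer seed.
#' @return a list of class `nf_bootstrap_stability`: `frequency` (named),
#'   `sign` (named, -1/0/+1 from the full-data fit), `stable` (genus names),
#'   `threshold`, `B`, `fit` (the full-data fit).
#' @export
bootstrap_stability <- function(Z, y, lambda, B = 100, threshold = 0.90,
                                seed = 1L) {
  stopifnot(is.matrix(Z))
  n <- nrow(Z)
  genera <- colnames(Z) %||% as.character(seq_len(ncol(Z)))
  colnames(Z) <- genera
  full <- zerosum_lasso(Z, y, lambda)
  set.seed(seed)
  count <- setNames(numeric(ncol(Z)), genera)
  redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, replace = TRUE)
      if (sd(y[idx]) > 0) break
      redrawn <- redrawn + 1L
      if (redrawn > 100L) .nf_stop("response is (nearly) constant; cannot bootstrap")
    }
    fit <- zerosum_lasso(Z[idx, , drop = FALSE], y[idx], lambda)
    sel <- fit$coefficients != 0
    count[sel] <- count[sel] + 1
  }
  if (redrawn > 0L)
    message(redrawn, " degenerate bootstrap resample(s) redrawn")
  freq <- count / B
  structure(list(
    frequency = freq, sign = sign(full$coefficients),
    stable = names(freq)[freq > threshold],
    threshold = threshold, B = B, fit = full
  ), class = "nf_bootstrap_stability")
}

#' @export
print.nf_bootstrap_stability <- function(x, ...) {
  cat(sprintf("Bootstrap stability (%d resamples, threshold > %.0f%%): %d stable genus/genera\n",
              x$B, 100 * x$threshold, length(x$stable)))
  if (length(x$stable)) {
    df <- data.frame(genus = x$stable,
                     frequency = unname(x$frequency[x$stable]),
                     sign = c("-", "0", "+")[x$sign[x$stable] + 2])
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Assemble the stable genus-metabolite association table
#'
#' Combines per-metabolite bootstrap stability results into one table of
#' stable associations: one record per (genus, metabolite) pair whose
#' bootstrap frequency exceeds the threshold, with the association direction
#' taken from the full-data fit.
#'
#' @param results named list of [bootstrap_stability()] objects, one per
#'   metabolite (names are metabolite ids).
#' @return a data.frame of class `nf_association_table` with columns
#'   `metabolite`, `genus`, `sign` (`"+"`/`"-"`), `frequency`, and attributes
#'   `n_genera` / `n_metabolites` (distinct counts among the records).
#' @export
association_table <- function(results) {
  stopifnot(is.list(results))
  if (length(results) && is.null(names(results)))
    .nf_stop("'results' must be a named list (metabolite ids)")
  rows <- lapply(names(results), function(m) {
    st <- results[[m]]
    if (!length(st$stable)) return(NULL)
    data.frame(metabolite = m, genus = st$stable,
               sign = ifelse(st$sign[st$stable] >= 0, "+", "-"),
               frequency = unname(st$frequency[st$stable]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(metabolite = character(), genus = character(),
                      sign = character(), frequency = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_genera") <- length(unique(out$genus))
  attr(out, "n_metabolites") <- length(unique(out$metabolite))
  class(out) <- c("nf_association_table", "data.frame")
  out
}

#' @export
print.nf_association_table <- function(x, ...) {
  cat(sprintf("%d stable association(s) between %d genus/genera and %d metabolite(s)\n",
              nrow(x), attr(x, "n_genera"), attr(x, "n_metabolites")))
  if (nrow(x)) print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
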