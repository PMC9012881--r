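make_two_class <- function(n = 40, p = 25, shift = 1.5, n_inf = 3, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- factor(rep(c("a", "b"), each = n / 2))
  X[y == "b", seq_len(n_inf)] <- X[y == "b", seq_len(n_inf)] + shift
  list(X = X, y = y)
}

test_that("loadings honour keepX exactly and have unit norm", {
  d <- make_two_class()
  fit <- splsda_fit(d$X, d$y, ncomp = 2, keepX = c(5, 4))
  expect_equal(colSums(fit$W != 0), c(5, 4))
  expect_equal(sqrt(colSums(fit$W^2)), c(1, 1), tolerance = 1e-9)
  # scores are the data projected on the loadings
  expect_equal(dim(fit$scores), c(40, 2))
})

test_that("sparse and dense fits match the mixOmics reference", {
  skip_if_not_installed("mixOmics")
  d <- make_two_class()
  fit <- splsda_fit(d$X, d$y, ncomp = 2, keepX = c(5, 4))
  ref <- mixOmics::splsda(d$X, d$y, ncomp = 2, keepX = c(5, 4))
  for (h in 1:2) {
    expect_setequal(names(which(fit$W[, h] != 0)),
                    rownames(ref$loadings$X)[ref$loadings$X[, h] != 0])
    expect_equal(abs(fit$W[, h]), abs(ref$loadings$X[, h]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # keepX = p: no thresholding, equals dense PLS-DA
  dense <- splsda_fit(d$X, d$y, ncomp = 1, keepX = ncol(d$X))
  ref_dense <- mixOmics::plsda(d$X, d$y, ncomp = 1)
  expect_equal(abs(dense$W[, 1]), abs(ref_dense$loadings$X[, 1]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a perfectly separating feature is the sole keepX = 1 selection", {
  set.seed(2)
  X <- matrix(rnorm(60 * 10), 60, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- factor(rep(c("a", "b"), each = 30))
  X[, 7] <- ifelse(y == "a", -5, 5) + rnorm(60, 0, 0.1)
  fit <- splsda_fit(X, y, ncomp = 1, keepX = 1)
  expect_identical(names(which(fit$W[, 1] != 0)), "f7")
})

test_that("fits are invariant to row duplication and feature order", {
  d <- make_two_class(seed = 5)
  fit <- splsda_fit(d$X, d$y, ncomp = 1, keepX = 5)
  dup <- splsda_fit(rbind(d$X, d$X), factor(c(d$y, d$y), labels = levels(d$y)),
                    ncomp = 1, keepX = 5)
  expect_equal(fit$W[, 1], dup$W[, 1], tolerance = 1e-8)
  perm <- sample(ncol(d$X))
  fit_p <- splsda_fit(d$X[, perm], d$y, ncomp = 1, keepX = 5)
  expect_equal(fit_p$W[colnames(d$X), 1], fit$W[, 1], tolerance = 1e-10)
  expect_equal(fit_p$scores, fit$scores, tolerance = 1e-10)
})

test_that("constant features are dropped with a warning", {
  d <- make_two_class()
  d$X[, 2] <- 7
  expect_warning(fit <- splsda_fit(d$X, d$y, ncomp = 1, keepX = 5),
                 "constant")
  expect_false("f2" %in% rownames(fit$W))
})

test_that("CV tuning returns the sole grid value and behaves on noise", {
  d <- make_two_class(seed = 7)
  one <- tune_splsda(d$X, d$y, keepX_grid = 8, ncomp = 1, folds = 5, seed = 1)
  expect_equal(one$keepX, 8L)
  # pure noise: balanced CV error hovers around chance for every grid point
  set.seed(9)
  Xn <- matrix(rnorm(60 * 30), 60, 30)
  yn <- factor(rep(c("a", "b"), each = 30))
  tn <- tune_splsda(Xn, yn, keepX_grid = c(5, 15), ncomp = 1, folds = 5,
                    repeats = 2, seed = 2)
  expect_true(all(tn$cv_error[, 1] > 0.3 & tn$cv_error[, 1] < 0.7))
})

test_that("stability selection saturates for an overwhelming feature and obeys threshold 0", {
  set.seed(3)
  X <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(NULL, paste0("f", 1:20)))
  y <- factor(rep(c("a", "b"), each = 25))
  X[, 4] <- ifelse(y == "a", 0, 10) + rnorm(50, 0, 1)
  st <- splsda_stability(X, y, keepX = 3, folds = 5, repeats = 4,
                         threshold = 0.9, seed = 1)
  expect_equal(unname(st$frequency["f4"]), 1)
  expect_true("f4" %in% st$stable)
  expect_equal(st$n_fits, 20)
  st0 <- splsda_stability(X, y, keepX = 3, folds = 5, repeats = 2,
                          threshold = 0, seed = 1)
  expect_setequal(st0$stable, names(which(st0$frequency > 0)))
})

test_that("LOOCV AUC is exact for separable classes and equals pair counting", {
  set.seed(6)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- factor(rep(c("a", "b"), each = 15))
  X[y == "b", 1] <- X[y == "b", 1] + 20
  res <- loocv_auc(X, y, keepX = 2)
  expect_equal(res$auc, 1)

  # pair-counting oracle on a small noisy instance
  d <- make_two_class(n = 10, p = 6, shift = 1, n_inf = 2, seed = 8)
  r2 <- loocv_auc(d$X, d$y, keepX = 3)
  expect_equal(r2$auc, auc_pair_count(r2$score, d$y == levels(d$y)[2]),
               tolerance = 1e-12)
  expect_true(all(diff(r2$roc$tpr) >= 0) && all(diff(r2$roc$fpr) >= 0))
})

test_that("LOOCV AUC is near chance for shuffled labels", {
  set.seed(10)
  aucs <- replicate(3, {
    X <- matrix(rnorm(40 * 15), 40, 15)
    y <- factor(sample(rep(c("a", "b"), each = 20)))
    loocv_auc(X, y, keepX = 5)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})
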