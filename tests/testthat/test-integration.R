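test_that("serum-stool pairing picks the nearest preceding stool within the lag window", {
  serum <- data.frame(sample_id = "ser9", patient_id = "P1", day = 9)
  stool <- data.frame(sample_id = c("st5", "st8"), patient_id = "P1",
                      day = c(5, 8))
  p <- pair_samples(serum, stool)
  expect_equal(p$stool_id, "st8")
  expect_equal(p$lag, 1)

  # outside the window: unpaired
  p2 <- pair_samples(serum, stool[1, , drop = FALSE])
  expect_equal(nrow(p2), 0)

  # same-day stool pairs at lag zero
  p3 <- pair_samples(serum, data.frame(sample_id = "st9", patient_id = "P1",
                                       day = 9))
  expect_equal(p3$lag, 0)

  # a stool sample may serve several serum samples
  serum2 <- data.frame(sample_id = c("a", "b"), patient_id = "P1",
                       day = c(8, 9))
  p4 <- pair_samples(serum2, stool[2, , drop = FALSE])
  expect_equal(p4$stool_id, c("st8", "st8"))

  # pairing never crosses patients
  p5 <- pair_samples(serum, data.frame(sample_id = "other", patient_id = "P2",
                                       day = 8))
  expect_equal(nrow(p5), 0)
})

test_that("rank-based inverse normal transform matches its closed form", {
  x <- c(3, 1, 2)
  expect_equal(rank_int(x),
               qnorm(c(5, 1, 3) / 6), tolerance = 1e-12)
  expect_equal(rank_int(x)[3], 0)  # median of odd-n distinct values
  # rank invariance under strictly monotone transforms
  set.seed(1)
  v <- rnorm(25)
  expect_equal(rank_int(v), rank_int(exp(v)), tolerance = 1e-12)
  expect_equal(rank_int(v), rank_int(rank(v)), tolerance = 1e-12)
  expect_error(rank_int(c(1, NA)), "missing")
})

test_that("genus prevalence filter applies the 20% boundary inclusively", {
  m <- matrix(0L, 10, 3, dimnames = list(NULL, c("rare", "edge", "common")))
  m[1, "rare"] <- 1L
  m[1:2, "edge"] <- 1L
  m[, "common"] <- 5L
  f <- prevalence_filter(m, 0.20)
  expect_identical(colnames(f), c("edge", "common"))
  expect_identical(prevalence_filter(m, 0), m)
})

test_that("log-contrast design is centered and depth-invariant", {
  set.seed(3)
  tab <- random_count_table(12, 6)
  Z <- log_contrast_design(tab)
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  # no -Inf even with zeros
  tab0 <- tab; tab0[1, 1] <- 0L
  expect_true(all(is.finite(log_contrast_design(tab0))))
  # equal counts in a sample give an equal (pre-centering) row
  eqrow <- rbind(tab, rep(7L, 6))
  Zeq <- log_contrast_design(eqrow)
  raw <- sweep(Zeq, 2, attr(Zeq, "center"), `+`)
  expect_equal(unname(raw[13, ]), rep(raw[13, 1], 6), tolerance = 1e-12)
  # doubling a sample's depth leaves its row unchanged (pseudocount 0)
  pos <- tab + 1L
  dbl <- pos; dbl[2, ] <- 2L * dbl[2, ]
  Z1 <- log_contrast_design(pos, pseudocount = 0)
  Z2 <- log_contrast_design(dbl, pseudocount = 0)
  raw1 <- sweep(Z1, 2, attr(Z1, "center"), `+`)
  raw2 <- sweep(Z2, 2, attr(Z2, "center"), `+`)
  expect_equal(raw1[2, ], raw2[2, ], tolerance = 1e-12)
})

test_that("zero-sum lasso: full shrinkage, zero-sum and KKT residuals", {
  set.seed(4)
  n <- 40; p <- 6
  Z <- matrix(rnorm(n * p), n, p)
  y <- drop(Z %*% c(1, -1, rep(0, p - 2))) + rnorm(n, 0, 0.3)
  fit <- zerosum_lasso(Z, y, lambda = 1e6)
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$intercept, mean(y), tolerance = 1e-12)
  fit2 <- zerosum_lasso(Z, y, lambda = 0.05)
  expect_lt(abs(fit2$sum_beta), 1e-8)
  expect_lt(fit2$kkt_residual, 1e-7)
  expect_gt(fit2$df, 0)
  expect_error(zerosum_lasso(Z, c(y[-1], NA), 0.1), "non-finite")
  expect_error(zerosum_lasso(Z, y, -1), "non-negative")
})

test_that("p = 2 zero-sum lasso equals the 1-D soft-threshold closed form", {
  set.seed(5)
  n <- 50
  Z <- cbind(rnorm(n), rnorm(n))
  y <- Z[, 1] - Z[, 2] + rnorm(n, 0, 0.4)
  w <- (Z[, 1] - Z[, 2]) - mean(Z[, 1] - Z[, 2])
  yc <- y - mean(y)
  lambdas <- exp(seq(log(2), log(1e-3), length.out = 20))
  for (lam in lambdas) {
    # with beta2 = -beta1 = -b the problem is a 1-D lasso on the difference
    # covariate with penalty 2*lambda
    b <- sign(sum(w * yc) / n) * max(abs(sum(w * yc) / n) - 2 * lam, 0) /
      (sum(w^2) / n)
    fit <- zerosum_lasso(Z, y, lam)
    expect_lt(max(abs(fit$coefficients - c(b, -b))), 1e-8)
  }
})

test_that("zero-sum lasso matches the sign-pattern oracle on random instances", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(10:30, 1); p <- sample(2:4, 1)
    Z <- matrix(rnorm(n * p), n, p)
    beta <- c(1, -1, rep(0, p - 2))[sample(p)]
    y <- drop(Z %*% beta) + rnorm(n, 0, 0.5)
    lam <- runif(1, 0.01, 0.5)
    fit <- zerosum_lasso(Z, y, lam)
    expect_lt(abs(fit$objective - zs_oracle_objective(Z, y, lam)), 1e-4)
    expect_lt(abs(fit$sum_beta), 1e-8)
  }
})

test_that("support size is non-increasing in lambda along the grid", {
  for (s in 1:5) {
    set.seed(s)
    n <- 60; p <- 8
    Z <- matrix(rnorm(n * p), n, p)
    y <- drop(Z %*% c(1, -1, 0.5, -0.5, rep(0, p - 4))) + rnorm(n, 0, 0.5)
    lam <- exp(seq(log(1), log(0.001), length.out = 20))
    dfs <- vapply(lam, function(l) zerosum_lasso(Z, y, l)$df, numeric(1))
    expect_true(all(diff(dfs) >= 0))  # grid is descending in lambda
  }
})

test_that("CV lambda selection: degenerate grid, noise and signal regimes", {
  set.seed(7)
  n <- 80; p <- 8
  Z <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
  y <- drop(Z %*% c(1.5, -1.5, rep(0, p - 2))) + rnorm(n, 0, 0.3)
  one <- cv_zerosum_lasso(Z, y, lambda = 0.1, folds = 5, seed = 1)
  expect_equal(one$lambda_opt, 0.1)

  cv <- cv_zerosum_lasso(Z, y, folds = 5, seed = 2)
  expect_gt(cv$fit$df, 0)                     # signal: interior solution
  expect_lt(cv$lambda_opt, max(cv$lambda))
  expect_gte(cv$lambda_opt, cv$lambda_min)    # 1-SE never smaller than min-MSE

  ynull <- rnorm(n)
  cvn <- cv_zerosum_lasso(Z, ynull, folds = 5, seed = 3)
  expect_lte(cvn$fit$df, 2)                   # null: near-empty model wins
  expect_gte(cvn$lambda_opt, sort(cvn$lambda, decreasing = TRUE)[5])
})

test_that("bootstrap stability recovers a planted pair and respects B = 1", {
  set.seed(8)
  n <- 120; p <- 8
  Z <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
  y <- drop(Z %*% c(1, -1, rep(0, p - 2))) + rnorm(n, 0, 0.1)
  bs <- bootstrap_stability(Z, y, lambda = 0.05, B = 40, seed = 1)
  expect_gt(bs$frequency["g1"], 0.9)
  expect_gt(bs$frequency["g2"], 0.9)
  expect_equal(unname(bs$sign[c("g1", "g2")]), c(1, -1))
  expect_true(all(c("g1", "g2") %in% bs$stable))

  b1 <- bootstrap_stability(Z, y, lambda = 0.05, B = 1, seed = 2)
  expect_true(all(b1$frequency %in% c(0, 1)))

  # pure-noise genera stay unstable at the CV-selected penalty
  ynull <- rnorm(n)
  lam <- cv_zerosum_lasso(Z, ynull, folds = 5, seed = 4)$lambda_opt
  bn <- bootstrap_stability(Z, ynull, lam, B = 40, seed = 3)
  expect_equal(length(bn$stable), 0)
})

test_that("association table aggregates stable records and counts entities", {
  empty <- association_table(list())
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_genera"), 0)

  fake <- structure(list(
    frequency = c(gA = 0.97, gB = 0.95, gC = 0.4),
    sign = c(gA = 1, gB = -1, gC = 1),
    stable = c("gA", "gB"), threshold = 0.9, B = 100),
    class = "nf_bootstrap_stability")
  tab <- association_table(list(met1 = fake))
  expect_equal(nrow(tab), 2)
  expect_equal(attr(tab, "n_genera"), 2)
  expect_equal(attr(tab, "n_metabolites"), 1)
  expect_equal(tab$sign, c("+", "-"))
  expect_error(association_table(list(fake)), "named")
})

test_that("end-to-end compositional scale invariance: depth factors change no fit", {
  set.seed(9)
  tab <- random_count_table(50, 6) + 1L
  y <- rnorm(50)
  scaled <- tab
  scaled[7, ] <- 5L * scaled[7, ]
  Z1 <- log_contrast_design(tab, pseudocount = 0)
  Z2 <- log_contrast_design(scaled, pseudocount = 0)
  f1 <- zerosum_lasso(Z1, y, 0.1)
  f2 <- zerosum_lasso(Z2, y, 0.1)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
  expect_equal(fitted(f1), fitted(f2), tolerance = 1e-6)
})
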