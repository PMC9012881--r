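# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: closed-form enumeration, explicit pair loops and
# naive definitions.

# Brute-force oracle for the zero-sum lasso: enumerate all sign patterns of
# the coefficient vector, solve each equality-constrained quadratic in closed
# form, and return the smallest value of the true objective among the
# zero-sum-feasible candidates (always including beta = 0). The optimum is
# attained at the candidate of the optimal sign pattern, so the minimum
# equals the optimal objective value.
zs_oracle_objective <- function(Z, y, lambda) {
  n <- nrow(Z); p <- ncol(Z)
  obj <- function(beta) {
    b0 <- mean(y - drop(Z %*% beta))
    sum((y - b0 - drop(Z %*% beta))^2) / (2 * n) + lambda * sum(abs(beta))
  }
  best <- obj(numeric(p))
  Zc <- scale(Z, scale = FALSE)
  yc <- y - mean(y)
  G <- crossprod(Zc) / n
  cv <- drop(crossprod(Zc, yc)) / n
  signs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  for (r in seq_len(nrow(signs))) {
    s <- signs[r, ]
    S <- which(s != 0)
    if (length(S) < 2) next  # a single nonzero cannot sum to zero
    K <- rbind(cbind(G[S, S, drop = FALSE], 1), c(rep(1, length(S)), 0))
    sol <- tryCatch(solve(K, c(cv[S] - lambda * s[S], 0)),
                    error = function(e) NULL)
    if (is.null(sol)) next
    beta <- numeric(p)
    beta[S] <- sol[seq_along(S)]
    best <- min(best, obj(beta))
  }
  best
}

# Naive O(m^2) step-up Benjamini-Hochberg: q_(i) = min_{j >= i} p_(j) * m / j,
# capped at 1.
bh_naive <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m))
    q[o[i]] <- min(1, min(ps[i:m] * m / seq(i, m)))
  q
}

# PERMANOVA by explicit pair sums plus exhaustive enumeration of all label
# orders (feasible for n <= 7).
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

permanova_oracle <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  g <- as.factor(groups)
  a <- nlevels(g)
  fstat <- function(lab) {
    sst <- 0; ssw <- 0
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      sst <- sst + d[i, j]^2 / n
      if (lab[i] == lab[j]) ssw <- ssw + d[i, j]^2 / sum(lab == lab[i])
    }
    c(F = ((sst - ssw) / (a - 1)) / (ssw / (n - a)), R2 = 1 - ssw / sst)
  }
  obs <- fstat(g)
  Fs <- vapply(all_perms(seq_len(n)), function(pm) fstat(g[pm])["F"],
               numeric(1))
  list(F = unname(obs["F"]), R2 = unname(obs["R2"]),
       p_exact = mean(Fs >= obs["F"] - 1e-12))
}

# Random multinomial count table with variable depth.
random_count_table <- function(n, p, depth_range = c(500, 3000)) {
  m <- t(vapply(seq_len(n), function(i) {
    as.integer(rmultinom(1, sample(seq(depth_range[1], depth_range[2]), 1),
                         rexp(p)))
  }, integer(p)))
  dimnames(m) <- list(sprintf("s%03d", seq_len(n)), sprintf("t%03d", seq_len(p)))
  m
}

# AUC by explicit concordant-pair counting (ties count one half).
auc_pair_count <- function(score, positive) {
  sp <- score[positive]; sn <- score[!positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}
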