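# Independent oracles and fixture builders used across the suite.
# Everything here is straight-line textbook code, deliberately kept apart
# from the package's own solvers.

# Textbook least squares: coefficients and the 1/n moment covariance.
oracle_ols <- function(y, Z) {
  XtX <- t(Z) %*% Z
  theta <- solve(XtX, t(Z) %*% y)
  r <- y - Z %*% theta
  list(theta = drop(theta),
       residuals = drop(r),
       Sigma = solve(XtX) * mean(r^2))
}

# Grid argmax of an exact Gaussian KDE with Silverman bandwidth
# (512 points, min - 3h .. max + 3h), written without stats::density.
oracle_kde_mode <- function(v) {
  h <- 0.9 * min(sd(v), IQR(v) / 1.34) * length(v)^(-1 / 5)
  xs <- seq(min(v) - 3 * h, max(v) + 3 * h, length.out = 512)
  dens <- sapply(xs, function(x) sum(dnorm((x - v) / h)) / (length(v) * h))
  xs[which.max(dens)]
}

# Straight-line reimplementation of the squared-loss CLR recipe:
# pseudo-count 0.5, CLR, per-taxon OLS, 1/n plug-in variance, kernel-mode
# shift correction, two-sided t p-values, step-up BH.
oracle_l2_pipeline <- function(counts, u) {
  Y <- counts + 0.5
  L <- log(Y)
  W <- sweep(L, 2, colMeans(L), "-")
  n <- length(u)
  Z <- cbind(u, 1)
  m <- nrow(W)
  alpha <- se <- numeric(m)
  for (i in seq_len(m)) {
    o <- oracle_ols(W[i, ], Z)
    alpha[i] <- o$theta[1]
    se[i] <- sqrt(o$Sigma[1, 1])
  }
  shift <- oracle_kde_mode(sqrt(n) * alpha) / sqrt(n)
  alpha_hat <- alpha - shift
  df <- n - 2
  p <- 2 * pt(abs(alpha_hat / se), df, lower.tail = FALSE)
  list(alpha_tilde = alpha, alpha_hat = alpha_hat, se = se,
       pvalue = p, padj = oracle_bh(p))
}

# Step-up BH from the definition: cumulative minimum of m p_(k) / k from
# the largest rank downwards, capped at 1, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force minimization of an empirical loss over (slope, intercept)
# on a grid, for robustness checks on simple regressions.
oracle_grid_minimum <- function(y, x, lossfun, slopes, intercepts) {
  best <- c(NA, NA); best_val <- Inf
  for (b in slopes) for (a in intercepts) {
    val <- mean(lossfun(y - a - b * x))
    if (val < best_val) { best_val <- val; best <- c(b, a) }
  }
  list(slope = best[1], intercept = best[2], value = best_val)
}

# Small random count-table fixture: Poisson counts with excess zeros.
make_fixture_counts <- function(m = 20, n = 16, seed = 1,
                                zero_frac = 0.2, mean_depth = 60) {
  set.seed(seed)
  Y <- matrix(rpois(m * n, mean_depth / m * exp(rnorm(m))), m, n)
  Y[runif(m * n) < zero_frac] <- 0
  keep <- rowSums(Y > 0) > 0
  Y <- Y[keep, , drop = FALSE]
  count_table(Y)
}
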