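#' Simulation configuration
#'
#' Parameters of the log-linear data-generating process used throughout the
#' package's power/FDR experiments: log-normal baseline absolute
#' abundances, Bernoulli signal assignment with abundance-weighted effect
#' sizes, optional confounded treatment assignment, one of four error
#' families, multinomial read sampling at log-normal depths, and optional
#' outlier injection by fold-inflation of nonzero counts.
#'
#' @param m number of taxa (default 500).
#' @param n number of samples.
#' @param p_gamma fraction of differential taxa (0.05 sparse, 0.2 dense).
#' @param mu signal strength, typically in [1.05, 2].
#' @param confounded include two confounders driving treatment assignment.
#' @param error_family `"normal"` (taxon-specific variance sigma_i*^2),
#'   `"t3"` (Student t, df 3), `"lognormal"` (LogNormal(0, 0.8) recentred
#'   by its theoretical mean), or `"weibull"` (Weibull(shape 0.5, scale
#'   0.3) recentred by its theoretical mean 0.6).
#' @param rho average outliers per taxon (0, 0.5, 1, 2, 4 in the study
#'   design); `round(rho * m)` nonzero cells are inflated.
#' @param fold outlier fold change (default 20).
#' @param baseline list of hyper-distribution parameters: `beta_mean`,
#'   `beta_sd` for `beta_i* ~ N`, `sigma_min`, `sigma_max` for
#'   `sigma_i* ~ Uniform`, `depth_meanlog`, `depth_sdlog` for
#'   `N_s ~ round(LogNormal)`. Defaults give a realistic rank-abundance
#'   skew and depth spread; override to match parameters estimated from a
#'   real dataset.
#' @param signal_factor overrides the sample-size-dependent factor in the
#'   effect-size formula (default NULL: 2 when n < 100, else 1).
#' @param seed integer RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(m = 500, n = 100, p_gamma = 0.05, mu = 1.5,
                       confounded = FALSE,
                       error_family = c("normal", "t3", "lognormal",
                                        "weibull"),
                       rho = 0, fold = 20,
                       baseline = list(), signal_factor = NULL,
                       seed = 1L) {
  error_family <- match.arg(error_family)
  stopifnot(m >= 2, n >= 2, p_gamma >= 0, p_gamma <= 1,
            mu >= 1, rho >= 0, fold > 1)
  base_default <- list(beta_mean = 0, beta_sd = 2,
                       sigma_min = 0.5, sigma_max = 2,
                       depth_meanlog = log(1e4), depth_sdlog = 0.5)
  baseline <- utils::modifyList(base_default, baseline)
  structure(list(m = m, n = n, p_gamma = p_gamma, mu = mu,
                 confounded = confounded, error_family = error_family,
                 rho = rho, fold = fold, baseline = baseline,
                 signal_factor = signal_factor, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw baseline absolute abundances
#'
#' `log X*_is ~ N(beta_i*, sigma_i*^2)` i.i.d. with `beta_i*` and
#' `sigma_i*` drawn from the configured hyper-distributions; returns the
#' latent baseline, the true proportions `pi*_is = X*_is / sum_j X*_js`,
#' and their per-taxon means `pibar_i*` used to weight effect sizes.
#'
#' @param config a [sim_config]. Uses the current RNG state (seed the
#'   stream before calling, or go through [build_dataset()]).
#' @return list: `beta_star`, `sigma_star` (length m), `X_star`, `pi_star`
#'   (m x n), `pi_bar` (length m, sums to ... mean proportions, sum 1).
#' @export
sample_baseline <- function(config) {
  b <- config$baseline
  m <- config$m; n <- config$n
  beta_star <- stats::rnorm(m, b$beta_mean, b$beta_sd)
  sigma_star <- stats::runif(m, b$sigma_min, b$sigma_max)
  X_star <- exp(matrix(stats::rnorm(m * n, mean = beta_star,
                                    sd = sigma_star), m, n))
  pi_star <- sweep(X_star, 2, colSums(X_star), "/")
  list(beta_star = beta_star, sigma_star = sigma_star,
       X_star = X_star, pi_star = pi_star,
       pi_bar = rowMeans(pi_star))
}

#' Assign differential taxa and effect sizes
#'
#' Each taxon is differential with probability `p_gamma`. The log-fold
#' effect is abundance-weighted so rare taxa (mean proportion below
#' 5e-3) receive an upweighted effect `log(f mu (5e-3 / pibar)^(1/3))`
#' while abundant taxa get `log(f mu)`; the factor `f` is 2 for small
#' samples (n < 100) and 1 otherwise, compensating the lower power.
#'
#' @param pi_bar per-taxon mean baseline proportions (> 0).
#' @param mu signal strength (>= 1).
#' @param n sample count (selects the factor f).
#' @param p_gamma differential fraction.
#' @param signal_factor optional override of f.
#' @return list: `gamma` (0/1 indicators), `alpha` (= mu_i * gamma_i),
#'   `mu_i` (per-taxon effect magnitudes).
#' @export
assign_effects <- function(pi_bar, mu, n, p_gamma, signal_factor = NULL) {
  stopifnot(mu >= 1)
  if (any(pi_bar <= 0)) stop("pi_bar must be strictly positive")
  f <- if (is.null(signal_factor)) (if (n < 100) 2 else 1) else signal_factor
  mu_i <- ifelse(pi_bar > 5e-3,
                 log(f * mu),
                 log(f * mu * (5e-3 / pi_bar)^(1 / 3)))
  gamma <- stats::rbinom(length(pi_bar), 1, p_gamma)
  list(gamma = gamma, alpha = mu_i * gamma, mu_i = mu_i)
}

#' Draw the treatment/covariate design
#'
#' Without confounders, `u ~ Bernoulli(0.5)`. With confounders,
#' `c1 ~ Bernoulli(0.5)`, `c2 ~ N(0,1)` and
#' `u ~ Bernoulli(plogis(0.5 c1 + 0.5 c2))`, so treatment probability
#' increases with both confounders. A degenerate draw (constant u) is
#' resampled up to 100 times.
#'
#' @param n sample count.
#' @param confounded logical.
#' @return list: `u` (0/1), and when confounded `c1`, `c2` plus the matrix
#'   `C = cbind(c1, c2)`.
#' @export
sample_design <- function(n, confounded = FALSE) {
  stopifnot(n >= 2)
  for (attempt in seq_len(100)) {
    if (confounded) {
      c1 <- stats::rbinom(n, 1, 0.5)
      c2 <- stats::rnorm(n)
      u <- stats::rbinom(n, 1, stats::plogis(0.5 * c1 + 0.5 * c2))
    } else {
      c1 <- c2 <- NULL
      u <- stats::rbinom(n, 1, 0.5)
    }
    if (length(unique(u)) > 1L) {
      out <- list(u = u)
      if (confounded) {
        out$c1 <- c1; out$c2 <- c2; out$C <- cbind(c1 = c1, c2 = c2)
      }
      return(out)
    }
  }
  stop("failed to draw a non-degenerate treatment assignment")
}

#' Draw error terms
#'
#' Four families, all mean-zero:
#' \itemize{
#'   \item `normal`: `N(0, sigma_i*^2)` per taxon (row-specific variance).
#'   \item `t3`: Student t with 3 df.
#'   \item `lognormal`: LogNormal(meanlog 0, sdlog 0.8) minus its
#'     theoretical mean `exp(0.8^2/2) = exp(0.32)`.
#'   \item `weibull`: Weibull(shape 0.5, scale 0.3) minus its theoretical
#'     mean `0.3 * Gamma(1 + 1/0.5) = 0.6`.
#' }
#' Recentring uses the theoretical (not sample) mean so draws stay i.i.d.
#'
#' @param family error family name.
#' @param m,n matrix dimensions (taxa x samples).
#' @param sigma_star per-taxon standard deviations (required for
#'   `"normal"`).
#' @return m x n matrix of errors.
#' @export
sample_errors <- function(family, m, n, sigma_star = NULL) {
  switch(family,
    normal = {
      if (is.null(sigma_star)) stop("normal errors need sigma_star")
      matrix(stats::rnorm(m * n, 0, sigma_star), m, n)
    },
    t3 = matrix(stats::rt(m * n, df = 3), m, n),
    lognormal = matrix(stats::rlnorm(m * n, 0, 0.8) - exp(0.8^2 / 2), m, n),
    weibull = matrix(stats::rweibull(m * n, shape = 0.5, scale = 0.3) -
                       0.3 * gamma(1 + 1 / 0.5), m, n),
    stop("unknown error family: ", family)
  )
}

#' Inflate randomly chosen nonzero counts
#'
#' Samples `k = round(rho * m)` cells uniformly without replacement from
#' the nonzero cells of the observed count matrix and multiplies each by
#' `fold`. The selection takes the first `k` positions of one random
#' permutation of the nonzero cells, so at a fixed RNG state the injected
#' sets are nested across increasing `rho` — larger contamination levels
#' contain smaller ones, which keeps matched-seed comparisons across
#' contamination levels monotone by construction. Library sizes are
#' recomputed, so an injected outlier perturbs the CLR values of every
#' taxon in its sample.
#'
#' @param table a [count_table].
#' @param rho average outliers per taxon (k = round(rho * m)).
#' @param fold multiplicative inflation (> 1).
#' @return list: `table` (inflated counts), `mask` (k x 2 matrix of
#'   (taxon, sample) indices; zero rows when rho = 0).
#' @export
inject_outliers <- function(table, rho, fold = 20) {
  stopifnot(inherits(table, "count_table"), rho >= 0, fold > 1)
  Y <- table$counts
  m <- nrow(Y)
  k <- round(rho * m)
  if (k == 0) {
    return(list(table = table,
                mask = matrix(integer(0), 0, 2,
                              dimnames = list(NULL, c("taxon", "sample")))))
  }
  nz <- which(Y > 0)
  if (k > length(nz)) stop("fewer nonzero cells than requested outliers")
  chosen <- nz[sample.int(length(nz))][seq_len(k)]
  Y[chosen] <- fold * Y[chosen]
  idx <- arrayInd(chosen, dim(Y))
  colnames(idx) <- c("taxon", "sample")
  list(table = rebuild_count_table(Y), mask = idx)
}

#' Generate one simulated dataset
#'
#' Composes the full data-generating process: baseline abundances, signal
#' assignment, treatment/confounder design, error draw, log-linear
#' absolute abundances `log X_is = beta_i* + u_s alpha_i [+ c_s' beta_i] +
#' eps_is` (confounder coefficients `beta_i1 ~ N(1,1)`,
#' `beta_i2 ~ N(2,1)`), true proportions, multinomial read sampling at
#' depths `N_s ~ round(LogNormal)`, and outlier injection when `rho > 0`.
#'
#' @param config a [sim_config]; `config$seed` fully determines the draw.
#' @return object of class `sim_dataset`: `counts` ([count_table]),
#'   `design` (list u/c1/c2), `truth` (gamma, alpha, mu_i, beta0 and,
#'   when confounded, beta1, beta2), `proportions` (true pi, m x n),
#'   `abundance` (latent X), `baseline` (from [sample_baseline()]),
#'   `outlier_mask`, and the `config`.
#' @export
build_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$m; n <- config$n

  base <- sample_baseline(config)
  eff <- assign_effects(base$pi_bar, config$mu, n, config$p_gamma,
                        config$signal_factor)
  des <- sample_design(n, config$confounded)
  eps <- sample_errors(config$error_family, m, n, base$sigma_star)

  logX <- base$beta_star + outer(eff$alpha, des$u) + eps
  truth <- list(gamma = eff$gamma, alpha = eff$alpha, mu_i = eff$mu_i,
                beta0 = base$beta_star)
  if (config$confounded) {
    beta1 <- stats::rnorm(m, 1, 1)
    beta2 <- stats::rnorm(m, 2, 1)
    logX <- logX + outer(beta1, des$c1) + outer(beta2, des$c2)
    truth$beta1 <- beta1
    truth$beta2 <- beta2
  }
  X <- exp(logX)
  pi_true <- sweep(X, 2, colSums(X), "/")

  b <- config$baseline
  N <- pmax(round(stats::rlnorm(n, b$depth_meanlog, b$depth_sdlog)), 1)
  Y <- vapply(seq_len(n),
              function(s) stats::rmultinom(1, N[s], pi_true[, s])[, 1],
              numeric(m))
  rownames(Y) <- paste0("taxon", seq_len(m))
  colnames(Y) <- paste0("sample", seq_len(n))
  tab <- count_table(Y)

  mask <- matrix(integer(0), 0, 2,
                 dimnames = list(NULL, c("taxon", "sample")))
  if (config$rho > 0) {
    inj <- inject_outliers(tab, config$rho, config$fold)
    tab <- inj$table
    mask <- inj$mask
  }

  structure(list(counts = tab,
                 design = des,
                 truth = truth,
                 proportions = pi_true,
                 abundance = X,
                 baseline = base,
                 outlier_mask = mask,
                 config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "sim_dataset: m = %d taxa, n = %d samples, %d differential, %s errors%s\n",
    x$config$m, x$config$n, sum(x$truth$gamma), x$config$error_family,
    if (nrow(x$outlier_mask)) sprintf(", %d injected outliers",
                                      nrow(x$outlier_mask)) else ""))
  invisible(x)
}

#' Empirical FDR and power of a DAA result against simulation truth
#'
#' Discoveries are taxa with adjusted p-value at or below `level`. The
#' empirical false discovery proportion uses the `max(|D|, 1)` convention
#' (no discoveries gives FDR 0); power is the fraction of true signals
#' discovered, `NA` when the truth contains no signals.
#'
#' @param result a `daa_result` (or a data.frame with columns `taxon`,
#'   `padj`).
#' @param gamma 0/1 truth vector aligned with the result's taxa.
#' @param level FDR level (default 0.05).
#' @return list: `fdr`, `power`, `discoveries`.
#' @export
evaluate_fdr_power <- function(result, gamma, level = 0.05) {
  tab <- if (inherits(result, "daa_result")) result$table else result
  if (nrow(tab) != length(gamma)) {
    stop("result and truth have different numbers of taxa")
  }
  disc <- tab$padj <= level
  n_disc <- sum(disc)
  fdr <- sum(disc & gamma == 0) / max(n_disc, 1)
  power <- if (sum(gamma) == 0) NA_real_ else sum(disc & gamma == 1) / sum(gamma)
  list(fdr = fdr, power = power, discoveries = n_disc)
}

#' Derive a reproducible child seed
#'
#' Deterministic seed for (setting, replicate) pairs under one master
#' seed, kept within the 32-bit integer range.
#'
#' @param master master seed.
#' @param setting setting index.
#' @param replicate replicate index.
#' @return integer seed.
#' @export
child_seed <- function(master, setting = 1L, replicate = 1L) {
  as.integer((as.numeric(master) * 10007 + setting * 101 + replicate) %%
               2147483647)
}
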