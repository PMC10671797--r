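test_that("baseline proportions behave like a composition", {
  cfg <- sim_config(m = 50, n = 30, seed = 2)
  set.seed(cfg$seed)
  base <- sample_baseline(cfg)
  expect_equal(sum(base$pi_bar), 1, tolerance = 1e-12)
  expect_true(all(abs(colSums(base$pi_star) - 1) < 1e-12))
  # higher baseline log-abundance means larger mean proportion
  expect_gt(cor(base$beta_star, base$pi_bar, method = "spearman"), 0.5)

  # symmetric composition: equal beta, zero sigma -> uniform proportions
  cfg0 <- sim_config(m = 10, n = 5, seed = 3,
                     baseline = list(beta_sd = 0, sigma_min = 0, sigma_max = 0))
  set.seed(cfg0$seed)
  b0 <- sample_baseline(cfg0)
  expect_equal(b0$pi_bar, rep(0.1, 10), tolerance = 1e-12)
})

test_that("effect sizes follow the abundance-weighted formula", {
  set.seed(1)
  # abundant taxon, large sample: log(mu)
  expect_equal(assign_effects(0.01, 2, n = 200, p_gamma = 1)$mu_i, log(2),
               tolerance = 1e-12)
  # abundant taxon, small sample: the factor 2 kicks in
  expect_equal(assign_effects(0.01, 2, n = 50, p_gamma = 1)$mu_i, log(4),
               tolerance = 1e-12)
  # rare taxon gets upweighted by the cube-root ratio
  expect_equal(assign_effects(5e-4, 2, n = 200, p_gamma = 1)$mu_i,
               log(2 * 10^(1 / 3)), tolerance = 1e-12)

  # gamma is Bernoulli(p_gamma) and alpha vanishes off-signal
  set.seed(15)
  eff <- assign_effects(rep(0.01, 4000), 1.5, 200, 0.05)
  expect_lt(abs(mean(eff$gamma) - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))
  expect_true(all(eff$alpha[eff$gamma == 0] == 0))
  expect_error(assign_effects(c(0.1, 0), 1.5, 50, 0.1), "positive")
})

test_that("treatment assignment is balanced and confounder-linked", {
  set.seed(16)
  d <- sample_design(10000, confounded = FALSE)
  expect_lt(abs(mean(d$u) - 0.5), 3 * 0.005)
  expect_null(d$C)

  dc <- sample_design(10000, confounded = TRUE)
  expect_true(all(dc$c1 %in% 0:1))
  # logistic link: treatment probability increases with the confounders
  score <- 0.5 * dc$c1 + 0.5 * dc$c2
  expect_gt(mean(dc$u[score > 0]), mean(dc$u[score <= 0]))
  # at score 0 the assignment is a fair coin
  expect_equal(plogis(0), 0.5)
})

test_that("error families are recentred by their theoretical means", {
  # constants used for recentring
  expect_equal(0.3 * gamma(1 + 1 / 0.5), 0.6)
  expect_equal(exp(0.8^2 / 2), exp(0.32))

  set.seed(17)
  n_draw <- 1e6
  for (fam in c("t3", "lognormal", "weibull")) {
    e <- sample_errors(fam, 1000, n_draw / 1000)
    se <- sd(e) / sqrt(n_draw)
    expect_lt(abs(mean(e)), 3 * se)
  }
  e <- sample_errors("normal", 4, 50000, sigma_star = c(0.5, 1, 1.5, 2))
  expect_equal(apply(e, 1, sd), c(0.5, 1, 1.5, 2), tolerance = 0.02)
  expect_error(sample_errors("cauchy", 2, 2), "unknown")
})

test_that("generated datasets satisfy the multinomial constraints", {
  cfg <- sim_config(m = 80, n = 40, p_gamma = 0.1, mu = 1.5,
                    error_family = "normal", seed = 23)
  sim <- build_dataset(cfg)
  expect_true(all(abs(colSums(sim$proportions) - 1) < 1e-12))
  expect_identical(dim(sim$counts$counts), c(80L, 40L))
  expect_true(all(sim$counts$counts == round(sim$counts$counts)))
  expect_true(all(sim$truth$alpha[sim$truth$gamma == 0] == 0))

  # the same seed reproduces the dataset exactly
  sim2 <- build_dataset(cfg)
  expect_identical(sim$counts$counts, sim2$counts$counts)

  # confounded designs carry the confounders and their coefficients
  simc <- build_dataset(sim_config(m = 30, n = 40, confounded = TRUE,
                                   seed = 29))
  expect_length(simc$truth$beta1, 30)
  expect_true(!is.null(simc$design$C))
})

test_that("sample proportions converge to the truth as depth grows", {
  errs <- sapply(c(3, 6), function(lg) {
    cfg <- sim_config(m = 30, n = 20, p_gamma = 0, mu = 1, seed = 31,
                      baseline = list(depth_meanlog = log(10^lg),
                                      depth_sdlog = 0))
    sim <- build_dataset(cfg)
    phat <- sweep(sim$counts$counts, 2, sim$counts$library_sizes, "/")
    max(abs(phat - sim$proportions))
  })
  expect_lt(errs[2], errs[1] / 5)
  expect_lt(errs[2], 2e-3)
})

test_that("outlier injection hits the requested number of nonzero cells", {
  set.seed(37)
  tab <- make_fixture_counts(500, 20, seed = 37, zero_frac = 0.3,
                             mean_depth = 5000)

  set.seed(41)
  none <- inject_outliers(tab, rho = 0)
  expect_identical(none$table$counts, tab$counts)
  expect_identical(nrow(none$mask), 0L)

  m <- nrow(tab$counts)
  set.seed(41)
  inj <- inject_outliers(tab, rho = 0.5, fold = 20)
  expect_identical(nrow(inj$mask), as.integer(round(0.5 * m)))
  changed <- which(inj$table$counts != tab$counts)
  expect_identical(length(changed), nrow(inj$mask))
  # every masked cell is exactly fold times its original value
  for (r in seq_len(nrow(inj$mask))) {
    i <- inj$mask[r, 1]; s <- inj$mask[r, 2]
    expect_identical(inj$table$counts[i, s], 20 * tab$counts[i, s])
    expect_gt(tab$counts[i, s], 0)
  }

  # at a fixed RNG state, contamination sets are nested across rho
  set.seed(41)
  inj2 <- inject_outliers(tab, rho = 1, fold = 20)
  key <- function(mask) paste(mask[, 1], mask[, 2])
  expect_true(all(key(inj$mask) %in% key(inj2$mask)))

  expect_error({set.seed(41); inject_outliers(tab, rho = 1e6)}, "fewer")
})

test_that("FDR and power are counted by the discovery-set definitions", {
  truth <- c(rep(1, 10), rep(0, 30))
  padj <- rep(1, 40)
  padj[c(1, 2, 3, 11)] <- 0.01   # 3 true signals + 1 null discovered
  res <- data.frame(taxon = paste0("t", 1:40), padj = padj)
  ev <- evaluate_fdr_power(res, truth, level = 0.05)
  expect_equal(ev$fdr, 0.25)
  expect_equal(ev$power, 0.3)

  # no discoveries: FDR 0 by the max(|D|, 1) convention
  ev0 <- evaluate_fdr_power(data.frame(taxon = "a", padj = 0.9), 0, 0.05)
  expect_equal(ev0$fdr, 0)
  expect_true(is.na(ev0$power))

  # perfect recovery
  ev1 <- evaluate_fdr_power(
    data.frame(taxon = c("a", "b"), padj = c(0.01, 0.9)), c(1, 0), 0.05)
  expect_equal(ev1$power, 1)
  expect_equal(ev1$fdr, 0)

  expect_error(evaluate_fdr_power(res, truth[1:5]), "different")
})

test_that("count tables and metadata round-trip through text files", {
  tab <- make_fixture_counts(12, 8, seed = 43)
  tsv <- file.path(tempdir(), "counts.tsv")
  df <- data.frame(taxon = tab$taxon_ids, tab$counts, check.names = FALSE)
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_count_table(tsv)
  expect_equal(back$counts, tab$counts)

  md <- data.frame(sample = tab$sample_ids,
                   group = rep(c(0, 1), 4), age = rnorm(8))
  mtsv <- file.path(tempdir(), "meta.tsv")
  write.table(md, mtsv, sep = "\t", quote = FALSE, row.names = FALSE)
  md_back <- read_metadata(mtsv)
  expect_equal(rownames(md_back), tab$sample_ids)
  expect_equal(md_back$group, md$group)
  unlink(c(tsv, mtsv))
})
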