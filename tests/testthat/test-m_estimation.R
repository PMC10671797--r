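test_that("squared-loss fits and covariances reproduce textbook least squares", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(8:30, 1)
    d <- sample(0:2, 1)
    u <- rnorm(n)
    C <- if (d > 0) matrix(rnorm(n * d), n, d) else NULL
    design <- daa_design(u, C)
    y <- rnorm(n)
    fit <- fit_taxon(y, design, loss_spec("l2"))
    o <- oracle_ols(y, design$Z)
    expect_equal(unname(fit$theta_tilde), unname(o$theta), tolerance = 1e-8)
    expect_equal(unname(fit$Sigma_hat), unname(o$Sigma), tolerance = 1e-8)
    expect_equal(unname(fit$residuals), unname(o$residuals), tolerance = 1e-8)
  }
})

test_that("every family recovers an exact linear relationship", {
  set.seed(5)
  n <- 24
  u <- rnorm(n)
  C <- matrix(rnorm(n), n, 1)
  design <- daa_design(u, C)
  theta_true <- c(1.5, -0.3, 0.8)
  w <- drop(design$Z %*% theta_true)
  for (fam in c("l2", "huber", "bisquare", "quantile")) {
    fit <- fit_taxon(w, design, loss_spec(fam))
    expect_equal(unname(fit$theta_tilde), theta_true, tolerance = 1e-5)
  }
})

test_that("huber with a huge corner constant degenerates to least squares", {
  set.seed(6)
  n <- 40
  design <- daa_design(rnorm(n))
  y <- 2 + rnorm(n)
  ls <- fit_taxon(y, design, loss_spec("l2"))
  hb <- fit_taxon(y, design, loss_spec("huber", hyper = 1e6))
  expect_equal(hb$theta_tilde, ls$theta_tilde, tolerance = 1e-6)
  expect_equal(hb$Sigma_hat, ls$Sigma_hat, tolerance = 1e-4)
})

test_that("a gross outlier moves the huber fit less than least squares", {
  n <- 20
  x <- seq(-1, 1, length.out = n)
  y <- 2 * x
  y[7] <- 1000
  design <- daa_design(x)
  ls <- fit_taxon(y, design, loss_spec("l2"))
  hb <- fit_taxon(y, design, loss_spec("huber"))
  expect_lt(abs(hb$theta_tilde[1] - 2), abs(ls$theta_tilde[1] - 2))

  # brute-force grid minimization of the huber objective (at the converged
  # scale) confirms the IRLS solution
  s <- hb$scale
  gr <- oracle_grid_minimum(
    y, x,
    function(r) {
      u <- r / s
      ifelse(abs(u) <= 1.345, 0.5 * u^2, 1.345 * abs(u) - 0.5 * 1.345^2)
    },
    slopes = seq(hb$theta_tilde[1] - 1, hb$theta_tilde[1] + 1, by = 0.01),
    intercepts = seq(hb$theta_tilde[2] - 1, hb$theta_tilde[2] + 1, by = 0.01)
  )
  expect_lt(abs(gr$slope - hb$theta_tilde[1]), 0.02)

  # the redescending bisquare rejects the outlier almost entirely
  bi <- fit_taxon(y, design, loss_spec("bisquare"))
  expect_lt(abs(bi$theta_tilde[1] - 2), 0.05)
})

test_that("robust slopes stay bounded while least squares diverges linearly", {
  set.seed(21)
  n <- 30
  x <- rnorm(n)
  y0 <- 1 + 2 * x + rnorm(n, sd = 0.3)
  design <- daa_design(x)
  mags <- c(10, 100, 1000)
  dev_l2 <- dev_hb <- numeric(length(mags))
  for (k in seq_along(mags)) {
    y <- y0
    y[4] <- mags[k]
    dev_l2[k] <- abs(fit_taxon(y, design, loss_spec("l2"))$theta_tilde[1] - 2)
    dev_hb[k] <- abs(fit_taxon(y, design, loss_spec("huber"))$theta_tilde[1] - 2)
  }
  # least squares deviation grows roughly linearly with the outlier
  expect_gt(dev_l2[3] / dev_l2[1], 10)
  # huber deviation is bounded (stops responding once the point is clipped)
  expect_lt(max(dev_hb), 0.5)
  expect_lt(diff(range(dev_hb[2:3])), 0.05)
})

test_that("fits agree with an established robust-regression implementation", {
  skip_if_not_installed("MASS")
  set.seed(33)
  for (rep in 1:10) {
    n <- 60
    x <- rnorm(n)
    y <- 1 + 0.5 * x + rt(n, df = 3)
    design <- daa_design(x)
    hb <- fit_taxon(y, design, loss_spec("huber"))
    rl <- MASS::rlm(y ~ x, psi = MASS::psi.huber, k = 1.345,
                    scale.est = "MAD", maxit = 200)
    expect_equal(unname(hb$theta_tilde[c(2, 1)]), unname(coef(rl)),
                 tolerance = 1e-4)
    bi <- fit_taxon(y, design, loss_spec("bisquare"))
    rb <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685,
                    scale.est = "MAD", maxit = 200)
    expect_equal(unname(bi$theta_tilde[c(2, 1)]), unname(coef(rb)),
                 tolerance = 1e-3)
  }
})

test_that("fits are regression-equivariant for every family", {
  set.seed(44)
  n <- 30
  u <- rnorm(n)
  C <- matrix(rnorm(n), n, 1)
  design <- daa_design(u, C)
  w <- rnorm(n)
  delta <- c(0.7, -1.2, 0.4)
  shift <- drop(design$Z %*% delta)
  for (fam in c("l2", "huber", "bisquare", "quantile")) {
    f0 <- fit_taxon(w, design, loss_spec(fam))
    f1 <- fit_taxon(w + shift, design, loss_spec(fam))
    expect_equal(unname(f1$theta_tilde), unname(f0$theta_tilde + delta),
                 tolerance = 1e-5)
  }
})

test_that("plug-in covariance handles limits and degenerate residuals", {
  set.seed(55)
  n <- 25
  design <- daa_design(rnorm(n))
  y <- 1 + rnorm(n)

  # zero residuals give a (numerically) zero covariance
  exact <- fit_taxon(drop(design$Z %*% c(2, 1)), design, loss_spec("huber"))
  expect_lt(max(abs(exact$Sigma_hat)), 1e-16)
  expect_gte(exact$sigma2_alpha, 0)

  # huber c -> infinity converges to the l2 covariance
  ls <- fit_taxon(y, design, loss_spec("l2"))
  hb <- fit_taxon(y, design, loss_spec("huber", hyper = 1e8))
  expect_equal(hb$Sigma_hat, ls$Sigma_hat, tolerance = 1e-6)

  # symmetric positive semidefinite with a nonnegative (1,1) entry
  hb2 <- fit_taxon(y, design, loss_spec("huber"))
  ev <- eigen(hb2$Sigma_hat, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
  expect_gte(hb2$sigma2_alpha, 0)

  # a tuning constant so small that every residual is clipped is an error
  r <- fit_taxon(y, design, loss_spec("l2"))$residuals
  expect_error(plug_in_covariance(design, r, sd(r), "bisquare", 1e-6),
               "tuning constant")
})

test_that("quantile covariance follows the sparsity formula", {
  set.seed(66)
  n <- 4000
  design <- daa_design(rnorm(n))
  r <- rnorm(n)
  S <- quantile_covariance(design, r, 0.5)
  # tau(1-tau)/f(0)^2 = 0.25 * 2*pi = pi/2 for standard normal residuals
  expected <- pi / 2 * chol2inv(chol(crossprod(design$Z)))
  expect_equal(unname(S), unname(expected), tolerance = 0.08)

  # sign symmetry and exact scaling: doubling the spread quadruples Sigma
  expect_equal(quantile_covariance(design, -r, 0.5), S, tolerance = 1e-10)
  expect_equal(quantile_covariance(design, 2 * r, 0.5), 4 * S,
               tolerance = 1e-10)
})

test_that("default hyperparameter grids have the documented shapes", {
  gh <- default_loss_grid("huber")
  expect_length(gh, 10)
  expect_equal(gh[1], 1.345)
  expect_equal(gh[10], 5)
  expect_equal(diff(log(gh)), rep(diff(log(c(1.345, 5))) / 9, 9))

  gb <- default_loss_grid("bisquare")
  expect_length(gb, 10)
  expect_equal(range(gb), c(4.685, 20))

  gq <- default_loss_grid("quantile")
  expect_length(gq, 11)
  expect_equal(gq, seq(0.25, 0.75, by = 0.05))
})
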