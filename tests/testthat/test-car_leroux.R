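test_that("Leroux precision has the stated closed form", {
  g <- path_graph(2)
  expect_equal(leroux_precision(g, 0), diag(2), ignore_attr = TRUE)
  expect_equal(leroux_logdet(g, 0), 0)
  Q <- leroux_precision(g, 0.5)
  expect_equal(unname(Q), rbind(c(1, -0.5), c(-0.5, 1)))
  expect_equal(det(Q), 0.75)
  expect_error(leroux_precision(g, 1), "rho")
})

test_that("eigenvalue log-determinant matches dense evaluation", {
  for (s in 1:4) {
    n <- sample(5:30, 1)
    g <- random_connected_graph(n, seed = s)
    lam <- laplacian_eigenvalues(g)
    for (rho in c(0, 0.2, 0.5, 0.9, 0.999)) {
      dense <- determinant(leroux_precision(g, rho), logarithm = TRUE)
      expect_equal(leroux_logdet(g, rho, lam),
                   as.numeric(dense$modulus), tolerance = 1e-9)
    }
  }
})

test_that("full conditional moments follow the closed form", {
  g <- path_graph(3)
  # rho = 0: independence limit
  fc <- full_conditional_phi(2, c(1, 0, -1), 0, 2.5, g)
  expect_equal(fc$mean, 0)
  expect_equal(fc$variance, 2.5)
  # node with 2 neighbors at phi = 1, rho = 0.5, tau2 = 1
  fc2 <- full_conditional_phi(2, c(1, 0, 1), 0.5, 1, g)
  expect_equal(fc2$mean, 2 / 3)
  expect_equal(fc2$variance, 1 / 1.5)
  # isolated node: N(0, tau2 / (1 - rho))
  iso <- region_graph(c("a", "b"), matrix(0, 2, 2), warn_isolated = FALSE)
  fc3 <- full_conditional_phi(1, c(5, -5), 0.5, 2, iso)
  expect_equal(fc3$mean, 0)
  expect_equal(fc3$variance, 4)
})

test_that("full conditionals reconstruct the joint Leroux density", {
  # Brook's-lemma check: Q_ij recovered from the conditional moments must
  # reproduce the dense zero-mean Gaussian log-density
  for (s in 1:5) {
    n <- sample(4:10, 1)
    g <- random_connected_graph(n, seed = 100 + s)
    rho <- runif(1, 0, 0.95); tau2 <- runif(1, 0.2, 2)
    Qrec <- matrix(0, n, n)
    for (i in seq_len(n)) {
      base <- full_conditional_phi(i, numeric(n), rho, tau2, g)
      Qrec[i, i] <- 1 / base$variance
      for (j in seq_len(n)[-i]) {
        e <- numeric(n); e[j] <- 1
        coef_ij <- full_conditional_phi(i, e, rho, tau2, g)$mean
        Qrec[i, j] <- -coef_ij / base$variance
      }
    }
    expect_equal(Qrec, t(Qrec), tolerance = 1e-12)
    phi <- rnorm(n)
    ld_rec <- 0.5 * as.numeric(determinant(Qrec)$modulus) -
      0.5 * n * log(2 * pi) - 0.5 * drop(phi %*% Qrec %*% phi)
    # dense oracle built directly from W
    Qdense <- (rho * (diag(rowSums(g$W)) - g$W) + (1 - rho) * diag(n)) / tau2
    ld_dense <- 0.5 * as.numeric(determinant(Qdense)$modulus) -
      0.5 * n * log(2 * pi) - 0.5 * drop(phi %*% Qdense %*% phi)
    expect_equal(ld_rec, ld_dense, tolerance = 1e-8)
  }
})

test_that("the Poisson log-likelihood matches hand and brute-force values", {
  ds0 <- region_dataset(
    data.frame(region_id = c("a", "b"), observed = c(0L, 0L),
               expected = c(2, 3), x = c(0.5, -0.5)),
    covariates = "x")
  expect_equal(leroux_loglik(ds0, c(0, 0)), -5)

  ds1 <- region_dataset(
    data.frame(region_id = "a", observed = 3L, expected = 1, x = 0),
    covariates = "x")
  expect_equal(leroux_loglik(ds1, c(0, 0)), -1 - log(6))

  set.seed(12)
  n <- 15
  reg <- data.frame(region_id = sprintf("r%d", 1:n),
                    observed = rpois(n, 8), expected = runif(n, 4, 12),
                    x = rnorm(n), w = rnorm(n))
  ds <- region_dataset(reg, covariates = c("x", "w"))
  beta <- c(0.1, -0.2, 0.3)
  phi <- rnorm(n, sd = 0.2)
  mu <- reg$expected * exp(beta[1] + beta[2] * reg$x + beta[3] * reg$w + phi)
  manual <- sum(dpois(reg$observed, mu, log = TRUE))
  expect_equal(leroux_loglik(ds, beta, phi), manual, tolerance = 1e-12)

  expect_error(leroux_loglik(ds, c(1000, 0, 0)), "non-finite")
})

test_that("fits are deterministic given the seed", {
  sim <- generate_dataset(small_config(seed = 41))
  st <- smr(sim$counts)
  ds <- region_dataset(sim$regions,
                       covariates = c("cta_institutions", "smoking"),
                       observed = st$observed, expected = st$expected)
  f1 <- fit_leroux(ds, sim$graph, short_mcmc(seed = 5, n = 1500, burn = 300))
  f2 <- fit_leroux(ds, sim$graph, short_mcmc(seed = 5, n = 1500, burn = 300))
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$rho, f2$rho)
  expect_identical(f1$loglik, f2$loglik)
  f3 <- fit_leroux(ds, sim$graph, short_mcmc(seed = 6, n = 1500, burn = 300))
  expect_false(identical(f1$beta, f3$beta))
})

test_that("conjugate tau2 draws follow the analytic inverse-gamma", {
  sim <- generate_dataset(small_config(seed = 51))
  st <- smr(sim$counts)
  ds <- region_dataset(sim$regions, covariates = c("cta_institutions"),
                       observed = st$observed, expected = st$expected)
  n <- length(ds$observed)
  set.seed(77)
  phi0 <- rnorm(n, sd = 0.3)
  rho0 <- 0.4
  cfg <- mcmc_config(n_iterations = 5000, burn_in = 0, seed = 13)
  fit <- suppressWarnings(fit_leroux(
    ds, sim$graph, cfg, store_loglik = FALSE,
    update = list(beta = FALSE, phi = FALSE, rho = FALSE),
    init = list(phi = phi0, rho = rho0)))
  Q <- leroux_precision(sim$graph, rho0)
  quad <- drop(phi0 %*% Q %*% phi0)
  shape <- 1 + n / 2
  rate <- 0.01 + quad / 2
  ks <- stats::ks.test(1 / fit$tau2, "pgamma", shape = shape, rate = rate)
  expect_gt(ks$p.value, 0.01)
})

test_that("with phi fixed at zero the posterior matches the IRLS oracle", {
  sim <- generate_dataset(small_config(seed = 61))
  st <- smr(sim$counts)
  ds <- region_dataset(sim$regions,
                       covariates = c("cta_institutions", "smoking"),
                       observed = st$observed, expected = st$expected)
  fit <- fit_nonspatial(ds, mcmc_config(n_iterations = 12000, burn_in = 2000,
                                        seed = 3))
  mle <- unname(coef(glm(ds$observed ~ ds$X, offset = log(ds$expected),
                         family = poisson())))
  for (j in 1:3) {
    err <- abs(mean(fit$beta[, j]) - mle[j])
    mc_se <- sqrt(spectrum0_ar(fit$beta[, j]) / nrow(fit$beta))
    expect_lt(err, 2 * mc_se + 1e-8)
  }
})

test_that("metropolis acceptance rates land in the adapted band", {
  sim <- generate_dataset(synthetic_config(n_regions = 100, seed = 71))
  st <- smr(sim$counts)
  ds <- region_dataset(sim$regions,
                       covariates = c("cta_institutions", "unemployment"),
                       observed = st$observed, expected = st$expected)
  fit <- fit_leroux(ds, sim$graph, short_mcmc(seed = 8, n = 6000, burn = 2000))
  expect_gt(fit$accept$beta, 0.2); expect_lt(fit$accept$beta, 0.6)
  expect_gt(fit$accept$phi, 0.2); expect_lt(fit$accept$phi, 0.6)
  expect_gt(fit$accept$rho, 0.2); expect_lt(fit$accept$rho, 0.6)
})

test_that("config and alignment errors are caught", {
  expect_error(mcmc_config(n_iterations = 100, burn_in = 100), "burn_in")
  expect_error(mcmc_config(thin = 0), "thin")
  sim <- generate_dataset(small_config(seed = 81))
  st <- smr(sim$counts)
  reg <- sim$regions[rev(seq_len(nrow(sim$regions))), ]
  ds <- region_dataset(reg, covariates = "cta_institutions",
                       observed = rev(st$observed),
                       expected = rev(st$expected))
  expect_error(fit_leroux(ds, sim$graph, short_mcmc()), "aligned")
  expect_error(region_dataset(sim$regions, covariates = "nope"),
               "not in regions")
})
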