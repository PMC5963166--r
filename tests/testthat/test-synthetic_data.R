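test_that("rho = 0 Leroux field is iid with the requested variance", {
  g <- grid_rook_graph(10, 10)
  draws <- sapply(1:50, function(s) sample_leroux_field(g, 0, 1, seed = s))
  v <- var(as.vector(draws))
  expect_equal(v, 1, tolerance = 0.07)
  expect_equal(mean(draws), 0, tolerance = 0.05)
})

test_that("field covariance matches the dense precision inverse (3-node path)", {
  g <- path_graph(3)
  rho <- 0.7; tau2 <- 1.3
  draws <- t(sapply(1:20000, function(s) {
    sample_leroux_field(g, rho, tau2, seed = s)
  }))
  S <- cov(draws)
  Sigma <- tau2 * solve(leroux_precision(g, rho))
  expect_equal(S, Sigma, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("leroux field draws are deterministic given seed and reject bad rho", {
  g <- path_graph(5)
  expect_identical(sample_leroux_field(g, 0.5, 1, seed = 3),
                   sample_leroux_field(g, 0.5, 1, seed = 3))
  expect_error(sample_leroux_field(g, 1, 1), "singular")
  expect_error(sample_leroux_field(g, -0.1, 1), "rho")
  expect_error(sample_leroux_field(g, 0.5, 0), "tau2")
})

test_that("generated datasets are reproducible and internally consistent", {
  cfg <- small_config(seed = 21)
  s1 <- generate_dataset(cfg)
  s2 <- generate_dataset(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$regions, s2$regions)
  expect_identical(s1$graph$W, s2$graph$W)
  expect_identical(s1$truth$phi, s2$truth$phi)

  # stratum deaths sum to the region total exactly
  o <- tapply(s1$counts$deaths, s1$counts$region_id, sum)
  expect_equal(as.vector(o[s1$regions$region_id]), s1$regions$observed)
  # 16 strata per region
  expect_true(all(table(s1$counts$region_id) == 16))
  # one connected component
  expect_length(connected_components(s1$graph), 1)
})

test_that("null-model data have mean O/E near 1", {
  cfg <- synthetic_config(n_regions = 150, true_tau2 = 1e-8, seed = 5)
  cfg$true_beta[] <- 0
  cfg$true_intercept <- 0
  sim <- generate_dataset(cfg)
  tab <- smr(sim$counts, rates = sim$truth$baseline_rates)
  se <- sd(tab$smr) / sqrt(nrow(tab))
  expect_lt(abs(mean(tab$smr) - 1), 3 * se + 0.01)
})

test_that("covariate marginals sit at the configured scales", {
  sim <- generate_dataset(synthetic_config(seed = 31))
  spec <- default_covariate_spec()
  for (k in seq_len(nrow(spec))) {
    x <- sim$regions[[spec$name[k]]]
    m <- median(x)
    # medians within ~15% (relative) of the specified values at n = 349
    expect_lt(abs(m - spec$median[k]) / spec$median[k], 0.15)
  }
})

test_that("requested covariate collinearity is realized", {
  spec <- add_collinear_covariates()
  ok <- 0
  for (s in 1:10) {
    cfg <- synthetic_config(covariate_spec = spec, seed = s)
    sim <- generate_dataset(cfg)
    r1 <- cor(sim$regions$income, sim$regions$log_pop_density)
    r2 <- cor(sim$regions$university_graduates, sim$regions$log_pop_density)
    if (abs(r1 - 0.85) < 0.1 && abs(r2 - 0.9) < 0.1) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("strongly spatial configurations produce positive Moran's I", {
  hits <- 0
  for (s in 1:10) {
    cfg <- synthetic_config(n_regions = 100, true_rho = 0.9, true_tau2 = 0.5,
                            seed = s)
    sim <- generate_dataset(cfg)
    tab <- smr(sim$counts)
    p <- morans_i_test(sim$graph, log(pmax(tab$smr, 0.01)),
                       n_permutations = 499, seed = s)$p_value
    if (p <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(n_regions = 1), "n_regions")
  expect_error(synthetic_config(true_rho = 1), "true_rho")
  expect_error(synthetic_config(true_tau2 = 0), "true_tau2")
  spec <- default_covariate_spec()
  spec$cor_with[2] <- "nonexistent"
  spec$cor_r[2] <- 0.5
  expect_error(synthetic_config(covariate_spec = spec), "unknown covariate")
  expect_error(synthetic_config(true_beta = c(bogus = 1)), "named")
})

test_that("datasets write to disk with all components", {
  sim <- generate_dataset(small_config(seed = 2))
  d <- tempfile()
  write_dataset(sim, d)
  expect_true(all(file.exists(file.path(
    d, c("regions.csv", "strata.csv", "edges.csv", "truth.json",
         "config.json")))))
  # regions round-trip
  rt <- read.csv(file.path(d, "regions.csv"), stringsAsFactors = FALSE)
  expect_equal(rt$observed, sim$regions$observed)
})
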