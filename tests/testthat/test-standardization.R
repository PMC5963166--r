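test_that("national rates pool deaths over regions within strata", {
  one <- stratified_counts(data.frame(
    region_id = "r1", sex = "f", age_band = "all",
    population = 1000, deaths = 10))
  expect_equal(national_rates(one)$rate, 0.01)

  two <- stratified_counts(data.frame(
    region_id = c("r1", "r2"), sex = "f", age_band = "all",
    population = c(500, 500), deaths = c(3, 7)))
  expect_equal(national_rates(two)$rate, 0.01)
})

test_that("rates match a brute-force column-sum oracle on a random table", {
  set.seed(7)
  counts <- generate_dataset(small_config(seed = 3))$counts
  r <- national_rates(counts)
  key <- paste(counts$sex, counts$age_band)
  for (k in seq_len(nrow(r))) {
    rows <- key == paste(r$sex[k], r$age_band[k])
    expect_equal(r$rate[k],
                 sum(counts$deaths[rows]) / sum(counts$population[rows]))
  }
  expect_equal(nrow(r), 16)
})

test_that("expected deaths apply rates stratum-by-stratum", {
  cts <- stratified_counts(data.frame(
    region_id = "r1", sex = "f", age_band = c("young", "old"),
    population = c(100, 50), deaths = c(0, 0)))
  rates <- data.frame(sex = "f", age_band = c("young", "old"),
                      rate = c(0.01, 0.02))
  expect_equal(expected_deaths(cts, rates)$expected, 2.0)

  # brute-force double loop on a random table
  counts <- tiny_counts(n = 5, seed = 2)
  r <- national_rates(counts)
  e <- expected_deaths(counts, r)
  for (i in seq_along(e$region_id)) {
    rows <- counts[counts$region_id == e$region_id[i], ]
    manual <- 0
    for (k in seq_len(nrow(rows))) {
      rk <- r$rate[r$sex == rows$sex[k] & r$age_band == rows$age_band[k]]
      manual <- manual + rk * rows$population[k]
    }
    expect_equal(e$expected[i], manual)
  }
})

test_that("stratum label mismatches and zero-population strata error", {
  cts <- tiny_counts()
  expect_error(expected_deaths(cts, data.frame(sex = "f", age_band = "young",
                                               rate = 0.1)),
               "missing stratum")
  bad <- as.data.frame(tiny_counts())
  bad$population[1] <- 0
  expect_error(stratified_counts(bad), "population")
})

test_that("internal standardization is self-consistent: sum E = sum O", {
  for (s in 1:3) {
    counts <- generate_dataset(small_config(seed = s))$counts
    tab <- smr(counts)
    expect_equal(sum(tab$expected), sum(tab$observed),
                 tolerance = 1e-9)
    expect_true(all(tab$smr >= 0))
  }
})

test_that("SMR is invariant to a common scaling of population and deaths", {
  counts <- tiny_counts(n = 5, seed = 4)
  s1 <- smr(counts)
  scaled <- as.data.frame(counts)
  scaled$population <- scaled$population * 3
  scaled$deaths <- scaled$deaths * 3
  s2 <- smr(stratified_counts(scaled, region_ids = attr(counts, "region_ids")))
  expect_equal(s1$smr, s2$smr)
})

test_that("permuting region order permutes SMRs identically", {
  counts <- tiny_counts(n = 6, seed = 5)
  ids <- attr(counts, "region_ids")
  s1 <- smr(counts)
  perm <- rev(ids)
  s2 <- smr(stratified_counts(as.data.frame(counts), region_ids = perm))
  expect_equal(s2$smr, s1$smr[match(perm, s1$region_id)])
})

test_that("synthetic null data give mean SMR near 1", {
  cfg <- synthetic_config(n_regions = 100, true_beta = NULL, true_tau2 = 1e-6,
                          seed = 8)
  cfg$true_beta[] <- 0
  cfg$true_intercept <- 0
  tab <- smr(generate_dataset(cfg)$counts)
  # mean of O/E over regions within 3 standard errors of 1
  se <- sd(tab$smr) / sqrt(nrow(tab))
  expect_lt(abs(mean(tab$smr) - 1), 3 * se + 1e-6)
})

test_that("undefined 0/0 SMR flags the region instead of failing", {
  cts <- data.frame(
    region_id = rep(c("a", "b"), each = 2),
    sex = "f", age_band = rep(c("y", "o"), 2),
    population = c(100, 100, 100, 100),
    deaths = c(5, 3, 0, 0))
  # external rates that are zero in region b's only populated strata
  rates <- data.frame(sex = "f", age_band = c("y", "o"), rate = c(0.05, 0.03))
  tab <- smr(stratified_counts(cts), rates)
  expect_true(all(is.finite(tab$smr)))
  rates0 <- data.frame(sex = "f", age_band = c("y", "o"), rate = c(0, 0))
  expect_error(smr(stratified_counts(cts), rates0), "zero expected")

  quiet <- cts[cts$region_id == "b", ]
  expect_warning(tab0 <- smr(stratified_counts(quiet), rates0), "undefined")
  expect_true(is.na(tab0$smr))
})
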