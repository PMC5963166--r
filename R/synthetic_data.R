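#' Default covariate specification for synthetic regions
#'
#' Marginal scales mimic a nationwide region-level cardiovascular dataset:
#' medical-resource densities per 100,000 population (cardiologists,
#' CT-angiography institutions, catheterization laboratories), log
#' population density, socioeconomic percentages, body-mass index,
#' step-count and smoking/drinking prevalences. Skewed densities are
#' log-normal, the rest normal, each parameterized by its median and
#' interquartile range. `smooth` marks covariates given one pass of
#' neighbor averaging (geographically structured variables); `cor_with` /
#' `cor_r` request a target correlation with a previously generated
#' covariate (used by [add_collinear_covariates()] to exercise VIF
#' screening).
#'
#' @return data.frame with columns `name`, `dist`, `median`, `q25`, `q75`,
#'   `smooth`, `cor_with`, `cor_r`.
#' @export
default_covariate_spec <- function() {
  data.frame(
    name = c("cardiologists", "cta_institutions", "ccl_institutions",
             "log_pop_density", "unemployment", "divorce_rate",
             "bmi", "daily_steps_tenth", "smoking", "drinking"),
    dist = c("lognormal", "lognormal", "lognormal",
             "normal", "normal", "normal",
             "normal", "normal", "normal", "normal"),
    median = c(6.274, 0.926, 0.925, 1.969, 6.350, 1.851,
               23.12, 716.3, 19.11, 42.90),
    q25 = c(4.180, 0.546, 0.571, 1.378, 5.529, 1.641,
            22.85, 680.0, 17.98, 40.42),
    q75 = c(9.142, 1.379, 1.332, 2.658, 7.167, 2.028,
            23.44, 749.5, 20.53, 43.91),
    smooth = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
               FALSE, FALSE, FALSE, FALSE),
    cor_with = NA_character_,
    cor_r = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Append collinear socioeconomic covariates to a specification
#'
#' Adds per-capita income and university-graduate proportion, each strongly
#' correlated with log population density, so that the VIF screen has
#' realistic collinearity to act on.
#'
#' @param spec a covariate specification (default
#'   [default_covariate_spec()]).
#' @param r target correlations with `log_pop_density` (length 2).
#' @return the extended specification.
#' @export
add_collinear_covariates <- function(spec = default_covariate_spec(),
                                     r = c(0.85, 0.9)) {
  rbind(spec, data.frame(
    name = c("income", "university_graduates"),
    dist = "normal",
    median = c(2750, 12.04),
    q25 = c(2546, 8.78),
    q75 = c(3050, 16.20),
    smooth = FALSE,
    cor_with = "log_pop_density",
    cor_r = r,
    stringsAsFactors = FALSE
  ))
}

#' Default generative coefficients (log relative risks)
#'
#' One log-RR per covariate of [default_covariate_spec()], at magnitudes
#' representative of region-level mortality analyses: a protective
#' CT-angiography density effect of RR 0.900 per institution per 100,000,
#' near-null effects for the other medical resources, and modest lifestyle
#' effects.
#'
#' @return named numeric vector of log RRs.
#' @export
default_true_beta <- function() {
  rr <- c(cardiologists = 0.997, cta_institutions = 0.900,
          ccl_institutions = 1.026, log_pop_density = 0.950,
          unemployment = 1.017, divorce_rate = 0.949, bmi = 1.045,
          daily_steps_tenth = 1.001, smoking = 1.035, drinking = 0.963)
  log(rr)
}

#' Configuration of a synthetic study dataset
#'
#' Defines the generative model for a complete region-level mortality
#' study: a contiguity graph over `n_regions`, stratified populations
#' (2 sexes x 8 age bands = 16 strata), covariates, a Leroux spatial field
#' `phi`, and Poisson death counts
#' `O_i ~ Poisson(E_i exp(b0 + x_i' beta + phi_i))` allocated to strata.
#' Baseline stratum rates grow geometrically with age (factor
#' `age_rate_factor` per band) with a male/female rate ratio, so indirect
#' standardization is non-trivial.
#'
#' @param n_regions number of regions (default 349).
#' @param layout `"geometric"` (random geometric graph on the unit square,
#'   components linked by nearest pairs) or `"grid"` (rook-adjacent cells).
#' @param grid_shape optional `c(nrow, ncol)` for the grid layout.
#' @param true_beta named log-RR vector, one per covariate in
#'   `covariate_spec` (defaults to [default_true_beta()]; extra spec
#'   covariates get coefficient 0).
#' @param true_intercept baseline log RR (default `log(0.540)`, balancing
#'   the covariate contributions at their central values).
#' @param true_rho spatial dependence of the Leroux field, in `[0, 1)`.
#' @param true_tau2 spatial variance (> 0).
#' @param covariate_spec covariate marginal specification (see
#'   [default_covariate_spec()]).
#' @param age_rate_factor geometric growth of baseline mortality per age
#'   band (default 3).
#' @param base_rate baseline annual death rate in the youngest female band.
#' @param sex_rate_ratio male:female baseline rate ratio.
#' @param pop_meanlog,pop_sdlog log-normal parameters of region population
#'   totals.
#' @param seed root RNG seed; named substreams (graph, populations,
#'   covariates, phi, deaths) are derived from it so components can be
#'   varied ceteris paribus.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_regions = 349,
                             layout = c("geometric", "grid"),
                             grid_shape = NULL,
                             true_beta = NULL,
                             true_intercept = log(0.540),
                             true_rho = 0.444,
                             true_tau2 = 0.1,
                             covariate_spec = default_covariate_spec(),
                             age_rate_factor = 3,
                             base_rate = 2e-6,
                             sex_rate_ratio = 1.6,
                             pop_meanlog = log(250000),
                             pop_sdlog = 0.8,
                             seed = 1L) {
  layout <- match.arg(layout)
  if (n_regions < 2) stop("n_regions must be >= 2")
  if (true_rho < 0 || true_rho >= 1) stop("true_rho must lie in [0, 1)")
  if (true_tau2 <= 0) stop("true_tau2 must be > 0")
  if (anyDuplicated(covariate_spec$name)) {
    stop("covariate_spec names must be unique")
  }
  partners <- covariate_spec$cor_with[!is.na(covariate_spec$cor_with)]
  bad <- setdiff(partners, covariate_spec$name)
  if (length(bad)) {
    stop("cor_with references unknown covariate(s): ",
         paste(bad, collapse = ", "))
  }
  if (is.null(true_beta)) {
    tb <- default_true_beta()
    true_beta <- stats::setNames(rep(0, nrow(covariate_spec)),
                                 covariate_spec$name)
    shared <- intersect(names(tb), covariate_spec$name)
    true_beta[shared] <- tb[shared]
  } else {
    if (is.null(names(true_beta)) ||
        !all(names(true_beta) %in% covariate_spec$name)) {
      stop("true_beta must be named after covariate_spec covariates")
    }
    full <- stats::setNames(rep(0, nrow(covariate_spec)), covariate_spec$name)
    full[names(true_beta)] <- true_beta
    true_beta <- full
  }
  structure(list(n_regions = as.integer(n_regions), layout = layout,
                 grid_shape = grid_shape, true_beta = true_beta,
                 true_intercept = true_intercept, true_rho = true_rho,
                 true_tau2 = true_tau2, covariate_spec = covariate_spec,
                 age_rate_factor = age_rate_factor, base_rate = base_rate,
                 sex_rate_ratio = sex_rate_ratio,
                 pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

age_bands <- function() {
  c("<20", "21-30", "31-40", "41-50", "51-60", "61-70", "71-80", ">80")
}

# Fractional age composition loosely shaped like an aged industrial country.
age_shares <- function() {
  s <- c(0.18, 0.11, 0.13, 0.13, 0.13, 0.14, 0.11, 0.07)
  s / sum(s)
}

#' Draw one Leroux Gaussian Markov random field
#'
#' Exact draw from `N(0, tau2 * Q(rho)^{-1})` with
#' `Q(rho) = rho (D - W) + (1 - rho) I`, via the Cholesky factor of the
#' precision. `rho = 1` (the intrinsic CAR limit) is singular and
#' rejected.
#'
#' @param graph a [region_graph()].
#' @param rho spatial dependence in `[0, 1)`.
#' @param tau2 spatial variance (> 0).
#' @param seed optional RNG seed; the draw is deterministic given the seed.
#' @return numeric vector `phi` in region order.
#' @export
sample_leroux_field <- function(graph, rho, tau2, seed = NULL) {
  if (length(rho) == 1L && is.finite(rho) && rho == 1) {
    stop("rho = 1: the intrinsic CAR precision is singular; Leroux requires rho < 1")
  }
  check_rho(rho)
  if (tau2 <= 0) stop("tau2 must be > 0")
  Q <- leroux_precision(graph, rho) / tau2
  U <- chol(Q)
  n <- length(graph$region_ids)
  z <- with_seed(seed, rnorm(n))
  backsolve(U, z)
}

# Random geometric layout: uniform points, distance-threshold adjacency,
# components linked through their closest point pairs.
geometric_graph <- function(n, ids) {
  pts <- cbind(runif(n), runif(n))
  radius <- sqrt(6 / (pi * n))   # expected degree about 6
  d <- as.matrix(stats::dist(pts))
  W <- (d > 0 & d <= radius) * 1
  diag(W) <- 0
  g <- region_graph(ids, W, warn_isolated = FALSE)
  repeat {
    comp <- connected_components(g)
    if (length(comp) == 1L) break
    # link the first component to its nearest other point
    a <- match(comp[[1L]], ids)
    b <- setdiff(seq_len(n), a)
    sub <- d[a, b, drop = FALSE]
    hit <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
    W[a[hit[1L]], b[hit[2L]]] <- W[b[hit[2L]], a[hit[1L]]] <- 1
    g <- region_graph(ids, W, warn_isolated = FALSE)
  }
  attr(g, "coords") <- pts
  g
}

grid_graph <- function(n, ids, grid_shape = NULL) {
  if (is.null(grid_shape)) {
    nr <- floor(sqrt(n))
    nc <- ceiling(n / nr)
  } else {
    nr <- grid_shape[1L]; nc <- grid_shape[2L]
    if (nr * nc < n) stop("grid_shape too small for n_regions")
  }
  cell <- cbind(row = (seq_len(n) - 1L) %/% nc, col = (seq_len(n) - 1L) %% nc)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    right <- which(cell[, 1] == cell[i, 1] & cell[, 2] == cell[i, 2] + 1L)
    below <- which(cell[, 1] == cell[i, 1] + 1L & cell[, 2] == cell[i, 2])
    for (j in c(right, below)) { W[i, j] <- W[j, i] <- 1 }
  }
  g <- region_graph(ids, W, warn_isolated = FALSE)
  attr(g, "coords") <- cbind(cell[, 2], -cell[, 1])
  g
}

# Integer allocation of `total` across shares, largest-remainder method.
allocate_integer <- function(total, shares) {
  raw <- total * shares / sum(shares)
  base <- floor(raw)
  short <- total - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# One pass of neighbor averaging (weight w to the neighbor mean).
smooth_on_graph <- function(graph, x, w = 0.5) {
  nb_mean <- as.numeric(graph$W %*% x) / pmax(graph$degrees, 1)
  nb_mean[graph$degrees == 0] <- x[graph$degrees == 0]
  (1 - w) * x + w * nb_mean
}

#' Generate a complete synthetic study dataset
#'
#' Builds the region graph, draws stratified populations, covariates, the
#' Leroux spatial field, and Poisson death counts under the configured
#' log-linear model, then allocates each region's deaths to its strata
#' multinomially in proportion to stratum-expected deaths (so stratum
#' deaths sum exactly to the region total). Returns every piece plus the
#' generative truth for parameter-recovery studies.
#'
#' @param config a [synthetic_config()].
#' @return list of class `leroux_simulation` with elements `graph`
#'   ([region_graph()]), `counts` ([stratified_counts()] long table),
#'   `regions` (data.frame: `region_id`, covariates, `observed`),
#'   `truth` (list: `intercept`, `beta`, `rho`, `tau2`, `phi`,
#'   `baseline_rates`, `expected_true`), and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_regions
  ids <- sprintf("R%04d", seq_len(n))

  graph <- with_seed(substream_seed(config$seed, "graph"), {
    if (config$layout == "grid") grid_graph(n, ids, config$grid_shape)
    else geometric_graph(n, ids)
  })

  bands <- age_bands()
  sexes <- c("female", "male")
  strata <- expand.grid(sex = sexes, age_band = bands,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  strata <- strata[order(match(strata$sex, sexes), match(strata$age_band, bands)), ]
  ns <- nrow(strata)   # 16

  pop <- with_seed(substream_seed(config$seed, "populations"), {
    totals <- pmax(1000L, as.integer(round(rlnorm(n, config$pop_meanlog,
                                                  config$pop_sdlog))))
    base_shares <- age_shares()[match(strata$age_band, bands)] / length(sexes)
    # region-level jitter of the stratum composition
    t(vapply(seq_len(n), function(i) {
      sh <- base_shares * exp(rnorm(ns, 0, 0.15))
      allocate_integer(totals[i], sh)
    }, integer(ns)))
  })
  covs <- with_seed(substream_seed(config$seed, "covariates"), {
    spec <- config$covariate_spec
    out <- matrix(NA_real_, n, nrow(spec),
                  dimnames = list(NULL, spec$name))
    for (k in seq_len(nrow(spec))) {
      med <- spec$median[k]; q25 <- spec$q25[k]; q75 <- spec$q75[k]
      if (spec$dist[k] == "lognormal") {
        sdlog <- log(q75 / q25) / (2 * stats::qnorm(0.75))
        x <- rlnorm(n, meanlog = log(med), sdlog = sdlog)
      } else {
        sdv <- (q75 - q25) / (2 * stats::qnorm(0.75))
        x <- rnorm(n, mean = med, sd = sdv)
      }
      if (!is.na(spec$cor_with[k])) {
        partner <- out[, spec$cor_with[k]]
        r <- spec$cor_r[k]
        zp <- as.numeric(scale(partner))
        zx <- as.numeric(scale(x))
        mix <- r * zp + sqrt(1 - r^2) * zx
        x <- mean(x) + stats::sd(x) * mix
      }
      if (spec$smooth[k]) x <- smooth_on_graph(graph, x)
      out[, k] <- x
    }
    out
  })

  phi <- sample_leroux_field(graph, config$true_rho, config$true_tau2,
                             seed = substream_seed(config$seed, "phi"))

  # baseline stratum rates: geometric in age, sex ratio split symmetrically
  sex_mult <- ifelse(strata$sex == "male", sqrt(config$sex_rate_ratio),
                     1 / sqrt(config$sex_rate_ratio))
  rate_k <- config$base_rate *
    config$age_rate_factor^(match(strata$age_band, bands) - 1) * sex_mult

  E_true <- as.numeric(pop %*% rate_k)
  eta <- config$true_intercept + drop(covs %*% config$true_beta) + phi
  mu <- E_true * exp(eta)

  deaths <- with_seed(substream_seed(config$seed, "deaths"), {
    O <- rpois(n, mu)
    t(vapply(seq_len(n), function(i) {
      w <- pop[i, ] * rate_k
      if (sum(w) == 0) w <- rep(1, ns)
      as.integer(rmultinom(1L, O[i], prob = w))
    }, integer(ns)))
  })

  counts <- data.frame(
    region_id = rep(ids, each = ns),
    sex = rep(strata$sex, times = n),
    age_band = rep(strata$age_band, times = n),
    population = as.vector(t(pop)),
    deaths = as.vector(t(deaths)),
    stringsAsFactors = FALSE
  )
  counts <- stratified_counts(counts, region_ids = ids)

  regions <- data.frame(region_id = ids, covs,
                        observed = as.integer(rowSums(deaths)),
                        stringsAsFactors = FALSE)

  structure(list(
    graph = graph,
    counts = counts,
    regions = regions,
    truth = list(intercept = config$true_intercept,
                 beta = config$true_beta,
                 rho = config$true_rho, tau2 = config$true_tau2,
                 phi = phi,
                 baseline_rates = data.frame(sex = strata$sex,
                                             age_band = strata$age_band,
                                             rate = rate_k,
                                             stringsAsFactors = FALSE),
                 expected_true = E_true),
    config = config
  ), class = "leroux_simulation")
}

#' Write a synthetic dataset to disk
#'
#' Emits `regions.csv` (covariates + observed deaths), `strata.csv` (long
#' region/sex/age_band population and deaths), `edges.csv` (adjacency),
#' `truth.json`, and `config.json` under `dir`.
#'
#' @param sim a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "leroux_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(sim$regions, file.path(dir, "regions.csv"), row.names = FALSE)
  write.csv(as.data.frame(sim$counts), file.path(dir, "strata.csv"),
            row.names = FALSE)
  write_edges_csv(sim$graph, file.path(dir, "edges.csv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- sim$config
  cfg$covariate_spec <- as.data.frame(cfg$covariate_spec)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
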