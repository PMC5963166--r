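#' Region-level modelling dataset
#'
#' Bundles the pieces the Poisson spatial regression consumes: per-region
#' observed deaths `O_i`, expected deaths `E_i` (the offset from indirect
#' standardization), and the covariate design.
#'
#' @param regions data.frame with one row per region containing `region_id`
#'   plus the covariate columns.
#' @param covariates character vector naming the covariate columns to model.
#' @param observed,expected either column names in `regions` or numeric
#'   vectors in region order. All `E_i` must be positive.
#' @return object of class `region_dataset`: list with `region_id`,
#'   `observed`, `expected`, and `X` (numeric covariate matrix, no
#'   intercept).
#' @export
region_dataset <- function(regions, covariates,
                           observed = "observed", expected = "expected") {
  regions <- as.data.frame(regions)
  if (!"region_id" %in% names(regions)) stop("regions must have a region_id column")
  grab <- function(what, nm) {
    if (is.character(what) && length(what) == 1L) {
      if (!what %in% names(regions)) stop("column '", what, "' not in regions")
      regions[[what]]
    } else {
      if (length(what) != nrow(regions)) stop(nm, " has wrong length")
      as.numeric(what)
    }
  }
  O <- grab(observed, "observed")
  E <- grab(expected, "expected")
  unknown <- setdiff(covariates, names(regions))
  if (length(unknown)) {
    stop("covariate(s) not in regions table: ", paste(unknown, collapse = ", "))
  }
  if (any(O < 0) || any(O != round(O))) stop("observed must be non-negative integers")
  if (any(E <= 0)) {
    stop("expected deaths must be positive; offending region(s): ",
         paste(regions$region_id[E <= 0], collapse = ", "))
  }
  X <- as.matrix(regions[, covariates, drop = FALSE])
  if (!is.numeric(X)) stop("covariates must be numeric")
  structure(list(region_id = as.character(regions$region_id),
                 observed = as.integer(round(O)), expected = as.numeric(E),
                 X = X),
            class = "region_dataset")
}

#' MCMC configuration
#'
#' Defaults follow the reported analysis protocol: 110,000 iterations with
#' the first 10,000 discarded as burn-in (`profile = "paper"`). The
#' `"desk"` profile (20,000 / 2,000) is a scaled-down setting for
#' simulation studies and test suites. Priors: `beta_j ~ N(0, 1e5)`,
#' `tau2 ~ inverse-gamma(1, 0.01)`, `rho ~ Uniform[0, 1)`.
#'
#' @param n_iterations total MCMC iterations.
#' @param burn_in iterations discarded before retention.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed RNG seed (optional).
#' @param prior_beta_var Gaussian prior variance for each regression
#'   coefficient.
#' @param prior_tau2_shape,prior_tau2_scale inverse-gamma prior for the
#'   spatial variance `tau2`.
#' @param profile `"paper"`, `"desk"`, or `NULL` to use the explicit
#'   `n_iterations`/`burn_in` values.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 110000, burn_in = 10000, thin = 1,
                        seed = NULL, prior_beta_var = 1e5,
                        prior_tau2_shape = 1, prior_tau2_scale = 0.01,
                        profile = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("paper", "desk"))
    if (profile == "paper") { n_iterations <- 110000; burn_in <- 10000 }
    else { n_iterations <- 20000; burn_in <- 2000 }
  }
  if (burn_in >= n_iterations) stop("burn_in must be < n_iterations")
  if (thin < 1) stop("thin must be >= 1")
  if (prior_tau2_shape <= 0 || prior_tau2_scale <= 0) {
    stop("inverse-gamma prior parameters must be positive")
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = seed, prior_beta_var = prior_beta_var,
                 prior_tau2_shape = prior_tau2_shape,
                 prior_tau2_scale = prior_tau2_scale),
            class = "mcmc_config")
}

#' Leroux CAR precision matrix
#'
#' `Q(rho) = rho (D - W) + (1 - rho) I`, the (unit-variance) precision of
#' the Leroux Gaussian Markov random field. Symmetric positive definite for
#' `rho` in `[0, 1)`; the intrinsic CAR limit `rho = 1` is singular and not
#' supported.
#'
#' @param graph a [region_graph()].
#' @param rho spatial dependence parameter in `[0, 1)`.
#' @return dense symmetric matrix, rows/columns in region order.
#' @export
leroux_precision <- function(graph, rho) {
  stopifnot(inherits(graph, "region_graph"))
  check_rho(rho)
  diag(rho * graph$degrees + 1 - rho, length(graph$region_ids)) - rho * graph$W
}

check_rho <- function(rho) {
  if (length(rho) != 1L || !is.finite(rho) || rho < 0 || rho >= 1) {
    if (isTRUE(rho == 1)) stop("rho = 1 makes the Leroux precision singular")
    stop("rho must lie in [0, 1)")
  }
  invisible(rho)
}

#' Eigenvalues of the graph Laplacian D - W
#'
#' Precomputed once per graph; `log det Q(rho) = sum_k log(rho * lambda_k +
#' 1 - rho)` is then available for any `rho` without refactorizing.
#'
#' @param graph a [region_graph()].
#' @return numeric vector of the `n` (non-negative) eigenvalues.
#' @export
laplacian_eigenvalues <- function(graph) {
  stopifnot(inherits(graph, "region_graph"))
  L <- diag(graph$degrees, length(graph$region_ids)) - graph$W
  eigen(L, symmetric = TRUE, only.values = TRUE)$values
}

#' Log-determinant of the Leroux precision
#'
#' @inheritParams leroux_precision
#' @param lambda optional precomputed [laplacian_eigenvalues()].
#' @return scalar `log det Q(rho)`.
#' @export
leroux_logdet <- function(graph, rho, lambda = NULL) {
  check_rho(rho)
  if (is.null(lambda)) lambda <- laplacian_eigenvalues(graph)
  sum(log(rho * lambda + 1 - rho))
}

#' Full-conditional prior moments of a spatial effect
#'
#' Under the Leroux prior the distribution of `phi_i` given all other
#' effects is Gaussian with
#' `mean = rho * sum_j w_ij phi_j / (rho * d_i + 1 - rho)` and
#' `variance = tau2 / (rho * d_i + 1 - rho)`. For an isolated region
#' (`d_i = 0`) this reduces to `N(0, tau2 / (1 - rho))`, which is proper
#' for `rho < 1`.
#'
#' @param i region index (1-based, in graph order).
#' @param phi current spatial effect vector.
#' @param rho,tau2 Leroux dependence and variance parameters.
#' @param graph a [region_graph()].
#' @return list with `mean` and `variance`.
#' @export
full_conditional_phi <- function(i, phi, rho, tau2, graph) {
  stopifnot(inherits(graph, "region_graph"))
  check_rho(rho)
  if (tau2 <= 0) stop("tau2 must be > 0")
  n <- length(graph$region_ids)
  if (length(phi) != n) stop("phi must have one value per region")
  if (i < 1 || i > n) stop("region index out of range")
  prec <- unname(rho * graph$degrees[i] + 1 - rho)
  list(mean = unname(rho * sum(graph$W[i, ] * phi)) / prec,
       variance = tau2 / prec)
}

#' Poisson log-likelihood of a region dataset
#'
#' `sum_i [O_i log mu_i - mu_i - log(O_i!)]` with
#' `log mu_i = log E_i + x_i' beta + phi_i`. `beta` includes the intercept
#' as its first element.
#'
#' @param dataset a [region_dataset()].
#' @param beta coefficient vector `(intercept, covariates...)`.
#' @param phi spatial effect vector (default all zero).
#' @return scalar log-likelihood.
#' @export
leroux_loglik <- function(dataset, beta, phi = NULL) {
  stopifnot(inherits(dataset, "region_dataset"))
  n <- length(dataset$observed)
  if (is.null(phi)) phi <- numeric(n)
  X1 <- cbind(1, dataset$X)
  if (length(beta) != ncol(X1)) {
    stop("beta must have length ", ncol(X1), " (intercept + covariates)")
  }
  mu <- exp(log(dataset$expected) + drop(X1 %*% beta) + phi)
  if (any(!is.finite(mu))) {
    stop("non-finite Poisson mean for region(s): ",
         paste(dataset$region_id[!is.finite(mu)], collapse = ", "))
  }
  sum(dpois(dataset$observed, mu, log = TRUE))
}

#' Fit the Leroux CAR Poisson model by MCMC
#'
#' Metropolis-within-Gibbs for `O_i ~ Poisson(E_i exp(x_i' beta + phi_i))`
#' with `phi ~ N(0, tau2 Q(rho)^{-1})`, `Q(rho) = rho (D - W) + (1 - rho) I`.
#' The regression block uses adaptive random-walk Metropolis with a
#' proposal shaped by the GLM covariance; each `phi_i` is updated by
#' univariate Metropolis against its CAR full conditional; `tau2` by its
#' conjugate inverse-gamma draw; `rho` by reflected random-walk Metropolis
#' using the eigenvalue form of the log-determinant. Proposal scales adapt
#' during burn-in only. Initialization: `beta` at the Poisson ML fit
#' (`phi = 0`), `phi = 0`, `tau2 = 0.01`, `rho = 0.5`.
#'
#' @param dataset a [region_dataset()], rows aligned with `graph`.
#' @param graph a [region_graph()] (ignored when `spatial = FALSE`).
#' @param config an [mcmc_config()].
#' @param spatial set `FALSE` for the non-spatial Poisson baseline (no
#'   `phi`, `tau2`, `rho` blocks); see [fit_nonspatial()].
#' @param store_loglik keep the per-region pointwise log-likelihood of each
#'   retained draw (needed for [waic()]).
#' @param store_phi keep full `phi` draws (memory-heavy; the running mean
#'   is always returned).
#' @param update controls for fixing individual blocks (named logical list
#'   with elements among `beta`, `phi`, `tau2`, `rho`); fixing blocks at
#'   their initial values is intended for sampler diagnostics.
#' @param init optional named list overriding initial values (`beta`,
#'   `phi`, `tau2`, `rho`).
#' @return object of class `leroux_fit`: retained draws (`beta` matrix with
#'   named columns, `tau2`, `rho`, optional `loglik`/`phi` matrices),
#'   `phi_mean`, acceptance rates, the config, and data dimensions.
#' @export
fit_leroux <- function(dataset, graph = NULL,
                       config = mcmc_config(profile = "desk"),
                       spatial = TRUE, store_loglik = TRUE, store_phi = FALSE,
                       update = list(), init = list()) {
  stopifnot(inherits(dataset, "region_dataset"), inherits(config, "mcmc_config"))
  n <- length(dataset$observed)
  if (spatial) {
    stopifnot(inherits(graph, "region_graph"))
    if (length(graph$region_ids) != n) {
      stop("dataset and graph have different numbers of regions")
    }
    if (!identical(dataset$region_id, graph$region_ids)) {
      stop("dataset rows are not aligned with graph region order")
    }
  }
  # collinearity advisory (screening is the caller's job, not enforced)
  if (ncol(dataset$X) >= 2L) {
    v <- suppressWarnings(vif(dataset$X))
    if (any(v >= 2.5)) {
      warning("covariate(s) with VIF >= 2.5 entering the model: ",
              paste(names(v)[v >= 2.5], collapse = ", "), call. = FALSE)
    }
  }
  # covariates are centered internally: a pure reparameterization that
  # removes the intercept/covariate ridge raw scales induce (slopes and
  # their RRs are unchanged; the raw-scale intercept is recovered below)
  xbar <- colMeans(dataset$X)
  Xc <- sweep(dataset$X, 2L, xbar)
  X1 <- cbind(`(Intercept)` = 1, Xc)
  p <- ncol(X1)
  if (n < p + 1L) stop("need more regions than coefficients")

  glm_fit <- glm(dataset$observed ~ Xc,
                 offset = log(dataset$expected), family = poisson())
  beta0 <- unname(coef(glm_fit))
  if (anyNA(beta0)) stop("ML initialization failed (aliased covariates?)")
  V <- vcov(glm_fit)
  U <- chol((V + t(V)) / 2)

  upd <- utils::modifyList(list(beta = TRUE, phi = TRUE, tau2 = TRUE,
                                rho = TRUE), update)
  ini <- utils::modifyList(list(beta = beta0, phi = numeric(n), tau2 = 0.01,
                                rho = 0.5), init)
  if (spatial) check_rho(ini$rho)

  if (spatial) {
    e <- graph_edges(graph)
    edges <- cbind(match(e$id_from, graph$region_ids),
                   match(e$id_to, graph$region_ids)) - 1L
    if (nrow(e) == 0L) edges <- matrix(integer(), 0, 2)
    storage.mode(edges) <- "integer"
    degree <- as.integer(graph$degrees)
    lambda <- laplacian_eigenvalues(graph)
  } else {
    edges <- matrix(integer(), 0, 2)
    degree <- integer(n)
    lambda <- numeric(n)
  }

  run <- function() leroux_mcmc_cpp(
    dataset$observed, log(dataset$expected), X1,
    edges, degree, lambda,
    config$n_iterations, config$burn_in, config$thin,
    config$prior_beta_var, config$prior_tau2_shape, config$prior_tau2_scale,
    ini$beta, ini$phi, ini$tau2, ini$rho, U,
    spatial, upd$beta, upd$phi && spatial, upd$tau2 && spatial,
    upd$rho && spatial,
    store_loglik, store_phi)
  out <- with_seed(config$seed, run())

  # map the centered-model intercept back to the raw covariate scale
  if (ncol(dataset$X) > 0L) {
    out$beta[, 1L] <- out$beta[, 1L] -
      drop(out$beta[, -1L, drop = FALSE] %*% xbar)
  }
  colnames(out$beta) <- colnames(X1)
  if (!is.null(out$loglik)) colnames(out$loglik) <- dataset$region_id
  structure(list(beta = out$beta,
                 tau2 = if (spatial) out$tau2 else NULL,
                 rho = if (spatial) out$rho else NULL,
                 loglik = out$loglik, phi = out$phi,
                 phi_mean = if (spatial) out$phi_mean else NULL,
                 accept = out$accept, proposal_sd = out$proposal_sd,
                 spatial = spatial, config = config,
                 region_id = dataset$region_id,
                 covariates = colnames(dataset$X),
                 n_retained = nrow(out$beta)),
            class = "leroux_fit")
}

#' Fit the non-spatial Bayesian Poisson baseline
#'
#' Same likelihood, offset, and `beta` priors as [fit_leroux()] but without
#' the spatial random effect — the comparison model for the WAIC contrast.
#'
#' @inheritParams fit_leroux
#' @return a `leroux_fit` with `spatial = FALSE` (no `tau2`, `rho`, `phi`).
#' @export
fit_nonspatial <- function(dataset, config = mcmc_config(profile = "desk"),
                           store_loglik = TRUE) {
  fit_leroux(dataset, graph = NULL, config = config, spatial = FALSE,
             store_loglik = store_loglik)
}

#' @export
print.leroux_fit <- function(x, ...) {
  cat(if (x$spatial) "Leroux CAR Poisson fit:" else "Non-spatial Poisson fit:",
      x$n_retained, "retained draws,",
      length(x$covariates), "covariates\n")
  a <- unlist(x$accept)
  a <- a[!is.na(a)]
  if (length(a)) {
    cat("acceptance:", paste(sprintf("%s %.2f", names(a), a), collapse = ", "),
        "\n")
  }
  invisible(x)
}
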