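#' Spectral density of a chain at frequency zero
#'
#' Estimated from an autoregressive fit with AIC order selection (the
#' standard route for MCMC standard errors): for an AR(k) fit with
#' innovation variance `s2` and coefficients `a`, the spectral density at
#' zero is `s2 / (1 - sum(a))^2`. An order-0 fit reduces to the sample
#' variance.
#'
#' @param x numeric chain segment.
#' @param max_order cap on the AR order offered to AIC selection.
#' @return scalar spectral density estimate.
#' @export
spectrum0_ar <- function(x, max_order = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10L) stop("segment too short for a spectral estimate")
  v <- var(x)
  if (!is.finite(v) || v == 0) stop("degenerate (zero-variance) chain segment")
  if (is.null(max_order)) max_order <- min(n - 1L, floor(10 * log10(n)))
  fit <- tryCatch(ar(x, aic = TRUE, order.max = max_order),
                  error = function(e) NULL)
  if (is.null(fit)) return(v)
  if (fit$order == 0L) return(unname(fit$var.pred))
  unname(fit$var.pred / (1 - sum(fit$ar))^2)
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of an early chain window against a late window:
#' `z = (mean_first - mean_last) / sqrt(se2_first + se2_last)` with
#' squared standard errors `spectrum0 / n_segment` estimated on each
#' segment by [spectrum0_ar()]. For a stationary chain `z` is
#' approximately standard normal; `|z| >= 1.96` flags non-convergence at
#' the 5% level.
#'
#' @param chain numeric vector of MCMC draws (length >= 100).
#' @param first_frac fraction of the chain in the early window (default
#'   0.1).
#' @param last_frac fraction in the late window (default 0.5).
#' @return the z score (scalar).
#' @export
geweke_z <- function(chain, first_frac = 0.1, last_frac = 0.5) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (n < 100L) stop("chain must have at least 100 draws")
  if (first_frac <= 0 || last_frac <= 0 || first_frac + last_frac > 1) {
    stop("window fractions must be positive with first_frac + last_frac <= 1")
  }
  if (var(chain) == 0) stop("degenerate (constant) chain")
  n1 <- max(10L, floor(first_frac * n))
  n2 <- max(10L, floor(last_frac * n))
  a <- chain[seq_len(n1)]
  b <- chain[seq.int(n - n2 + 1L, n)]
  se2a <- spectrum0_ar(a) / n1
  se2b <- spectrum0_ar(b) / n2
  (mean(a) - mean(b)) / sqrt(se2a + se2b)
}

# Monte-Carlo standard error of a chain mean.
mcse <- function(chain) sqrt(spectrum0_ar(chain) / length(chain))

# Degenerate (constant) chains summarize as NA rather than erroring.
geweke_or_na <- function(chain) {
  tryCatch(geweke_z(chain), error = function(e) NA_real_)
}

#' Posterior summary table in publication shape
#'
#' One row per coefficient (intercept first, then covariates) plus, for
#' spatial fits, the dependence parameter `rho`. Coefficients are reported
#' on the relative-risk (RR) scale: the posterior quantiles of `beta` are
#' exponentiated, so RR columns are exact monotone transforms of the
#' log-scale quantiles. An effect is flagged significant when its 95%
#' credible interval excludes RR = 1; `rho` is reported on its own scale
#' and carries no flag. Each row also carries the Geweke z of its chain.
#'
#' @param fit a [fit_leroux()] / [fit_nonspatial()] result.
#' @param probs central quantiles (default 2.5%, 50%, 97.5%).
#' @return data.frame with columns `parameter`, `scale` (`"RR"` or
#'   `"rho"`), `median`, `lower`, `upper`, `significant`, `geweke_z`;
#'   acceptance rates are attached as `attr(, "accept")`.
#' @export
summarize_fit <- function(fit, probs = c(0.025, 0.5, 0.975)) {
  stopifnot(inherits(fit, "leroux_fit"))
  if (fit$n_retained == 0L) stop("fit has no retained draws")
  stopifnot(length(probs) == 3L)
  rows <- lapply(seq_len(ncol(fit$beta)), function(j) {
    q <- quantile(fit$beta[, j], probs = probs, names = FALSE)
    rr <- exp(q)
    data.frame(parameter = colnames(fit$beta)[j], scale = "RR",
               median = rr[2L], lower = rr[1L], upper = rr[3L],
               significant = (rr[1L] > 1) || (rr[3L] < 1),
               geweke_z = geweke_or_na(fit$beta[, j]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (fit$spatial) {
    q <- quantile(fit$rho, probs = probs, names = FALSE)
    out <- rbind(out, data.frame(
      parameter = "rho", scale = "rho",
      median = q[2L], lower = q[1L], upper = q[3L],
      significant = NA, geweke_z = geweke_or_na(fit$rho),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  attr(out, "accept") <- fit$accept
  out
}

#' Geweke z for every monitored parameter of a fit
#'
#' @param fit a `leroux_fit`.
#' @return named numeric vector: one z per regression coefficient, plus
#'   `tau2` and `rho` for spatial fits.
#' @export
geweke_all <- function(fit) {
  stopifnot(inherits(fit, "leroux_fit"))
  z <- vapply(seq_len(ncol(fit$beta)), function(j) geweke_z(fit$beta[, j]),
              numeric(1))
  names(z) <- colnames(fit$beta)
  if (fit$spatial) {
    z <- c(z, tau2 = geweke_z(fit$tau2), rho = geweke_z(fit$rho))
  }
  z
}
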