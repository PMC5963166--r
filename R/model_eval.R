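#' Widely applicable information criterion (WAIC)
#'
#' Computed from the pointwise posterior log-likelihood matrix:
#' `lppd = sum_i log( mean_s p(O_i | theta_s) )` (log-mean-exp evaluated
#' stably) and the effective parameter count
#' `p_waic = sum_i var_s( log p(O_i | theta_s) )` (posterior-variance
#' variant, unbiased `n - 1` denominator). Reported on the deviance scale,
#' `waic = -2 (lppd - p_waic)`; lower is better.
#'
#' @param x a `leroux_fit` fitted with `store_loglik = TRUE`, or a numeric
#'   matrix of pointwise log-likelihoods (draws in rows, regions in
#'   columns).
#' @param min_draws guard on the number of retained draws (default 100);
#'   set lower only for toy checks.
#' @return object of class `waic_result`: list with `lppd`, `p_waic`,
#'   `waic`, and `pointwise` (per-region `lppd_i`, `p_waic_i`, `waic_i`).
#' @export
waic <- function(x, min_draws = 100) {
  ll <- if (inherits(x, "leroux_fit")) {
    if (is.null(x$loglik)) stop("fit was run with store_loglik = FALSE")
    x$loglik
  } else {
    as.matrix(x)
  }
  s <- nrow(ll)
  if (s < min_draws) stop("need at least ", min_draws, " retained draws")
  if (anyNA(ll) || any(ll == Inf)) stop("invalid log-likelihood values")
  # stable log-mean-exp per region
  mx <- apply(ll, 2L, max)
  if (any(mx == -Inf)) {
    stop("all draws give zero likelihood for region(s): ",
         paste(colnames(ll)[mx == -Inf], collapse = ", "))
  }
  lppd_i <- mx + log(colMeans(exp(sweep(ll, 2L, mx))))
  p_i <- apply(ll, 2L, var)
  waic_i <- -2 * (lppd_i - p_i)
  structure(list(lppd = sum(lppd_i), p_waic = sum(p_i),
                 waic = -2 * (sum(lppd_i) - sum(p_i)),
                 pointwise = data.frame(region_id = colnames(ll),
                                        lppd = unname(lppd_i),
                                        p_waic = unname(p_i),
                                        waic = unname(waic_i),
                                        stringsAsFactors = FALSE)),
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC %.3f (lppd %.3f, p_waic %.3f)\n",
              x$waic, x$lppd, x$p_waic))
  invisible(x)
}

#' Compare two models by WAIC
#'
#' The model with the lower WAIC is the better fit. Also reports the
#' per-region WAIC contribution difference so the comparison can be
#' localized.
#'
#' @param spatial,nonspatial `waic_result`s (or fits, which are passed
#'   through [waic()]) for the two models; names reflect the canonical use
#'   but any two models can be compared.
#' @return list of class `waic_comparison`: `table` (one row per model:
#'   `model`, `lppd`, `p_waic`, `waic`, `delta_waic`), `better` (name of
#'   the lower-WAIC model), `pointwise_diff` (spatial minus nonspatial
#'   per-region WAIC contributions, when region ids align).
#' @export
compare_waic <- function(spatial, nonspatial) {
  w1 <- if (inherits(spatial, "waic_result")) spatial else waic(spatial)
  w2 <- if (inherits(nonspatial, "waic_result")) nonspatial else waic(nonspatial)
  tab <- data.frame(
    model = c("spatial", "nonspatial"),
    lppd = c(w1$lppd, w2$lppd),
    p_waic = c(w1$p_waic, w2$p_waic),
    waic = c(w1$waic, w2$waic),
    stringsAsFactors = FALSE)
  tab$delta_waic <- tab$waic - min(tab$waic)
  pd <- NULL
  if (identical(w1$pointwise$region_id, w2$pointwise$region_id)) {
    pd <- data.frame(region_id = w1$pointwise$region_id,
                     waic_diff = w1$pointwise$waic - w2$pointwise$waic,
                     stringsAsFactors = FALSE)
  }
  structure(list(table = tab,
                 better = tab$model[which.min(tab$waic)],
                 pointwise_diff = pd),
            class = "waic_comparison")
}

#' @export
print.waic_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("better fit:", x$better, "\n")
  invisible(x)
}
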