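#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is the coefficient of
#' determination from the least-squares regression of covariate `j` on all
#' other covariates plus an intercept. Exact linear dependence is reported
#' as `Inf`, not an error, so screening can remove the offender.
#'
#' @param design data.frame or matrix of numeric covariates (columns), at
#'   least two columns and `ncol + 2` rows; no constant columns.
#' @return named numeric vector of VIFs, one per covariate, all `>= 1`.
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  if (!is.numeric(X)) stop("design must be numeric")
  p <- ncol(X)
  if (p < 2L) stop("need at least 2 covariates to compute VIFs")
  if (nrow(X) < p + 2L) stop("need at least ncol(design) + 2 rows")
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("x", seq_len(p))
  const <- apply(X, 2L, function(v) var(v) == 0)
  if (any(const)) {
    stop("constant covariate column(s): ", paste(cn[const], collapse = ", "))
  }
  out <- vapply(seq_len(p), function(j) {
    y <- X[, j]
    Z <- cbind(`(Intercept)` = 1, X[, -j, drop = FALSE])
    fit <- lm.fit(Z, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- cn
  out
}

#' Greedy VIF screening of a covariate table
#'
#' Iteratively removes the single covariate with the greatest VIF
#' (recomputing VIFs after each removal; ties broken by column order, first
#' wins) until every remaining VIF is below `threshold`. Covariates named
#' in `protected` are never removed; if one still exceeds the threshold at
#' convergence a warning is raised.
#'
#' @inheritParams vif
#' @param threshold VIF cutoff (> 1); the conventional screen keeps
#'   covariates with VIF < 2.5.
#' @param protected character vector of covariate names exempt from
#'   removal.
#' @return object of class `vif_screen`: list with `design` (the reduced
#'   table), `vif` (final VIFs of the survivors), `removed` (data.frame
#'   `name`, `vif` in removal order), and `threshold`.
#' @export
screen_covariates <- function(design, threshold = 2.5, protected = character()) {
  if (threshold <= 1) stop("threshold must be > 1")
  design <- as.data.frame(design)
  unknown <- setdiff(protected, names(design))
  if (length(unknown)) {
    stop("protected covariate(s) not in design: ",
         paste(unknown, collapse = ", "))
  }
  if (ncol(design) < 2L) stop("need at least 2 covariates to screen")
  removed <- data.frame(name = character(), vif = numeric(),
                        stringsAsFactors = FALSE)
  repeat {
    v <- vif(design)
    candidates <- setdiff(names(v)[v >= threshold], protected)
    if (!length(candidates)) break
    # greatest VIF among removable; first column wins ties (which.max)
    worst <- candidates[which.max(v[candidates])]
    if (ncol(design) - 1L < 2L) {
      stop("VIF screening cannot satisfy threshold ", threshold,
           ": removing '", worst, "' would leave fewer than 2 covariates")
    }
    removed <- rbind(removed,
                     data.frame(name = worst, vif = unname(v[worst]),
                                stringsAsFactors = FALSE))
    design <- design[, setdiff(names(design), worst), drop = FALSE]
  }
  over <- names(v)[v >= threshold]   # only protected ones can remain over
  if (length(over)) {
    warning("protected covariate(s) exceed the VIF threshold: ",
            paste(over, collapse = ", "), call. = FALSE)
  }
  structure(list(design = design, vif = v, removed = removed,
                 threshold = threshold),
            class = "vif_screen")
}

#' @export
print.vif_screen <- function(x, ...) {
  cat("VIF screen (threshold ", x$threshold, "): ", nrow(x$removed),
      " removed, ", ncol(x$design), " kept\n", sep = "")
  if (nrow(x$removed)) {
    cat("removed:", paste(sprintf("%s (%.2f)", x$removed$name, x$removed$vif),
                          collapse = ", "), "\n")
  }
  invisible(x)
}
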