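#' Moran's I spatial autocorrelation statistic
#'
#' Computes Moran's I for a region-indexed variable under the graph's
#' binary (non-row-standardized) neighborhood matrix:
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with `S0 = sum_ij w_ij`. Isolated regions stay in `x`: they contribute
#' to the variance but not to the cross-product.
#'
#' @param graph a [region_graph()] with at least one edge.
#' @param x numeric vector in the graph's region order; must not be
#'   constant.
#' @return the Moran's I statistic (scalar).
#' @export
morans_i <- function(graph, x) {
  stopifnot(inherits(graph, "region_graph"))
  n <- length(graph$region_ids)
  if (length(x) != n) stop("x must have one value per region (", n, ")")
  if (anyNA(x)) stop("x contains NA")
  z <- x - mean(x)
  ss <- sum(z^2)
  if (ss == 0) stop("x is constant: Moran's I undefined (zero variance)")
  s0 <- sum(graph$W)
  if (s0 == 0) stop("graph has no edges: Moran's I undefined")
  e <- graph_edges(graph)
  i <- match(e$id_from, graph$region_ids)
  j <- match(e$id_to, graph$region_ids)
  num <- 2 * sum(z[i] * z[j])   # both (i,j) and (j,i) terms
  (n / s0) * num / ss
}

#' Permutation test for Moran's I
#'
#' Monte-Carlo inference for positive spatial autocorrelation: the observed
#' I is compared against its distribution under random relabelling of the
#' regions. The one-sided (greater) p-value uses the add-one correction
#' `p = (1 + #permuted I >= observed) / (1 + n_permutations)`, so it is
#' never exactly zero. A normal-approximation z-test (under the
#' randomization null moments) is available as an alternative.
#'
#' @inheritParams morans_i
#' @param n_permutations number of random permutations (>= 99).
#' @param seed RNG seed for the permutations (optional; the global RNG
#'   stream is used when `NULL`).
#' @param method `"permutation"` (default) or `"normal"` for the
#'   randomization-moment z approximation.
#' @return object of class `moran_test`: list with `I`, `expected_I`
#'   (`-1/(n-1)`), `p_value`, `n_permutations`, `seed`, `method`, and for
#'   the normal method `z`.
#' @export
morans_i_test <- function(graph, x, n_permutations = 999, seed = NULL,
                          method = c("permutation", "normal")) {
  method <- match.arg(method)
  obs <- morans_i(graph, x)
  n <- length(x)
  expected <- -1 / (n - 1)
  if (method == "permutation") {
    if (n_permutations < 99) stop("n_permutations must be >= 99")
    # the permuted statistic only changes through the edge cross-product:
    # the variance term and S0 are permutation-invariant
    e <- graph_edges(graph)
    i <- match(e$id_from, graph$region_ids)
    j <- match(e$id_to, graph$region_ids)
    z0 <- x - mean(x)
    scale_fac <- (n / sum(graph$W)) * 2 / sum(z0^2)
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(n_permutations), function(k) {
        zp <- z0[sample.int(n)]
        scale_fac * sum(zp[i] * zp[j])
      }, numeric(1)) >= obs)
    })
    p <- (1 + exceed) / (1 + n_permutations)
    z <- NA_real_
  } else {
    # randomization-null moments of I for binary symmetric W
    W <- graph$W
    s0 <- sum(W)
    s1 <- sum((W + t(W))^2) / 2
    s2 <- sum((rowSums(W) + colSums(W))^2)
    z0 <- x - mean(x)
    b2 <- (sum(z0^4) / n) / (sum(z0^2) / n)^2
    ei <- expected
    ei2 <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
              b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * s0^2)
    vi <- ei2 - ei^2
    z <- (obs - ei) / sqrt(vi)
    p <- stats::pnorm(z, lower.tail = FALSE)
    n_permutations <- 0L
  }
  structure(
    list(I = obs, expected_I = expected, p_value = p,
         n_permutations = n_permutations, seed = seed, method = method,
         z = z),
    class = "moran_test"
  )
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f under null), p = %.4g [%s]\n",
              x$I, x$expected_I, x$p_value,
              if (x$method == "permutation")
                paste0(x$n_permutations, " permutations, one-sided greater")
              else "normal approximation"))
  invisible(x)
}
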