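#' Kraskov k-nearest-neighbor mutual information estimate
#'
#' Nonparametric MI estimator for two continuous variables (KSG, first
#' variant): for each joint point, `eps_i` is the max-norm distance to its
#' k-th nearest neighbor in the joint space, `n_xi` and `n_yi` count the
#' points strictly within `eps_i` in each marginal, and
#'
#' `MI = psi(k) - mean(psi(n_xi + 1) + psi(n_yi + 1)) + psi(N)`.
#'
#' Ties (exactly repeated values, common after discretisation) are broken
#' by adding deterministic jitter of magnitude 1e-10 seeded by `rng_seed`.
#' The estimate can be slightly negative by sampling noise; callers using
#' it as a similarity weight floor it at 0.
#'
#' @param x,y numeric vectors of equal length `N >= k + 2`.
#' @param k number of neighbors (default 3).
#' @param rng_seed seed for the tie-breaking jitter (default 0).
#' @return scalar MI estimate in nats.
#' @export
ksg_mutual_information <- function(x, y, k = 3, rng_seed = 0) {
  n <- length(x)
  if (length(y) != n) {
    abort_riskmod("x and y must have equal length", "riskmod_input_error")
  }
  if (n < k + 2) {
    abort_riskmod(sprintf("need at least k + 2 = %d points", k + 2),
                  "riskmod_input_error")
  }
  jit <- with_rng_seed(rng_seed, {
    list(x = runif(n, -1, 1) * 1e-10, y = runif(n, -1, 1) * 1e-10)
  })
  x <- as.numeric(x) + jit$x
  y <- as.numeric(y) + jit$y
  nx <- integer(n)
  ny <- integer(n)
  for (i in seq_len(n)) {
    dx <- abs(x - x[i])
    dy <- abs(y - y[i])
    dm <- pmax(dx, dy)
    dm[i] <- Inf
    eps <- sort(dm, partial = k)[k]
    nx[i] <- sum(dx < eps) - 1L
    ny[i] <- sum(dy < eps) - 1L
  }
  digamma(k) - mean(digamma(nx + 1) + digamma(ny + 1)) + digamma(n)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length `N >= 3` with nonzero
#'   variance.
#' @return correlation in [-1, 1].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort_riskmod("need equal-length vectors with N >= 3",
                  "riskmod_input_error")
  }
  if (var(x) == 0 || var(y) == 0) {
    abort_riskmod("correlation undefined for zero-variance input",
                  "riskmod_undefined_correlation_error")
  }
  cor(x, y)
}

# memoising pairwise-MI lookup over the pooled samples of `expr`;
# returns function(u, v) -> MI estimate (cached by unordered pair)
mi_cache <- function(expr, k = 3, rng_seed = 0) {
  cache <- new.env(parent = emptyenv())
  vals <- expr$values
  function(u, v) {
    key <- paste(min(u, v), max(u, v), sep = "\r")
    hit <- cache[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
    mi <- ksg_mutual_information(vals[u, ], vals[v, ], k = k,
                                 rng_seed = rng_seed)
    cache[[key]] <- mi
    mi
  }
}
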