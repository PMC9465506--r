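#' Never-seen-again probabilities (chi recursion)
#'
#' `chi[i]` is the probability that a population alive at occasion `i` is
#' never detected at any occasion after `i`.  With `phi[i]` the persistence
#' over interval `i -> i+1` and `p[i]` the detection probability at occasion
#' `i + 1` (both of length `T - 1`), the backward recursion is
#' `chi[T] = 1` and
#' `chi[i] = 1 - phi[i] * (1 - (1 - p[i]) * chi[i+1])`.
#'
#' @param phi Per-interval persistence probabilities, length `T - 1`.
#' @param p Detection probabilities at occasions `2..T`, length `T - 1`.
#' @return Numeric vector `chi` of length `T`.
#' @export
#' @examples
#' chi_vector(phi = 0.5, p = 0.5)  # T = 2: chi_1 = 0.75
chi_vector <- function(phi, p) {
  assert_probabilities(phi, "phi")
  assert_probabilities(p, "p")
  if (length(phi) != length(p) || length(phi) < 1L) {
    stop("`phi` and `p` must have equal length T - 1 >= 1", call. = FALSE)
  }
  T <- length(phi) + 1L
  chi <- numeric(T)
  chi[T] <- 1
  for (i in (T - 1L):1L) {
    chi[i] <- 1 - phi[i] * (1 - (1 - p[i]) * chi[i + 1L])
  }
  chi
}

# first/last detection occasion per history row
history_bounds <- function(y) {
  T <- ncol(y)
  if (any(rowSums(y) == 0L)) {
    stop("all-zero detection history: the CJS likelihood conditions on first detection",
         call. = FALSE)
  }
  idx <- col(y)
  idx[y == 0L] <- NA_integer_
  list(f = apply(idx, 1L, min, na.rm = TRUE),
       l = apply(idx, 1L, max, na.rm = TRUE))
}

#' Cormack-Jolly-Seber log-likelihood
#'
#' Conditional-on-first-detection log-likelihood of a set of binary detection
#' histories.  A history first detected at occasion `f` and last detected at
#' `l` contributes
#' `prod(i = f..l-1) phi_i * p_(i+1)^y_(i+1) * (1 - p_(i+1))^(1 - y_(i+1))`
#' times `chi_l`, the probability of never being seen after `l`.
#'
#' @param histories A [build_detection_histories()] result or a binary
#'   matrix (rows = histories, columns = occasions); every row must contain
#'   at least one 1.
#' @param phi Per-interval persistence, length `T - 1`.
#' @param p Detection at occasions `2..T`, length `T - 1`.
#' @return The summed log-likelihood (may be `-Inf` for impossible data).
#' @export
cjs_loglik <- function(histories, phi, p) {
  y <- history_matrix(histories)
  T <- ncol(y)
  assert_probabilities(phi, "phi")
  assert_probabilities(p, "p")
  if (length(phi) != T - 1L || length(p) != T - 1L) {
    stop("`phi` and `p` must have length T - 1 = ", T - 1L, call. = FALSE)
  }
  b <- history_bounds(y)
  chi <- chi_vector(phi, p)
  lphi <- log(phi); lp <- log(p); lq <- log(1 - p)
  contrib <- vapply(seq_len(nrow(y)), function(h) {
    f <- b$f[h]; l <- b$l[h]
    ll <- log(chi[l])
    if (l > f) {
      i <- f:(l - 1L)
      yi <- y[h, i + 1L]
      ll <- ll + sum(lphi[i]) + sum(ifelse(yi == 1L, lp[i], lq[i]))
    }
    ll
  }, numeric(1))
  sum(contrib)
}

# Sufficient statistics for the conditional CJS likelihood (equivalent to the
# m-array): A[k] = weighted #histories at risk over interval k (f <= k < l),
# B[k] = those detected at occasion k+1, W[l] = weighted #histories last
# detected at l, n_eff = #release events (detections at occasions 1..T-1).
cjs_suffstats <- function(y, weights = NULL) {
  T <- ncol(y)
  n <- nrow(y)
  w <- weights %||% rep(1, n)
  b <- history_bounds(y)
  A <- B <- numeric(T - 1L)
  for (k in seq_len(T - 1L)) {
    at_risk <- b$f <= k & b$l >= k + 1L
    A[k] <- sum(w[at_risk])
    B[k] <- sum(w[at_risk] * y[at_risk, k + 1L])
  }
  W <- numeric(T)
  for (l in unique(b$l)) W[l] <- sum(w[b$l == l])
  n_eff <- sum(w * rowSums(y[, -T, drop = FALSE]))
  list(A = A, B = B, W = W, n_eff = n_eff, T = T, n_histories = sum(w))
}

cjs_loglik_stats <- function(stats, phi, p) {
  chi <- chi_vector(phi, p)
  xlogy <- function(a, b) ifelse(a == 0, 0, a * log(b))
  sum(xlogy(stats$A, phi)) + sum(xlogy(stats$B, p)) +
    sum(xlogy(stats$A - stats$B, 1 - p)) + sum(xlogy(stats$W, chi))
}

# Analytic gradient of the log-likelihood w.r.t. the real-scale (phi, p)
# vectors, via the backward derivative recursion of chi.
cjs_grad_stats <- function(stats, phi, p) {
  T <- stats$T
  n <- T - 1L
  chi <- chi_vector(phi, p)
  Dphi <- matrix(0, T, n)
  Dp <- matrix(0, T, n)
  for (i in n:1L) {
    carry <- phi[i] * (1 - p[i])
    if (i < n) {
      Dphi[i, (i + 1L):n] <- carry * Dphi[i + 1L, (i + 1L):n]
      Dp[i, (i + 1L):n] <- carry * Dp[i + 1L, (i + 1L):n]
    }
    Dphi[i, i] <- -(1 - (1 - p[i]) * chi[i + 1L])
    Dp[i, i] <- -phi[i] * chi[i + 1L]
  }
  wchi <- stats$W / chi
  g_phi <- stats$A / phi + colSums(wchi * Dphi)
  g_p <- stats$B / p - (stats$A - stats$B) / (1 - p) + colSums(wchi * Dp)
  list(phi = g_phi, p = g_p)
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 log L + 2K + 2K(K + 1) / (n_eff - K - 1)`.
#'
#' @param minus_two_log_lik Model deviance `-2 log L`.
#' @param K Number of estimable parameters.
#' @param n_eff Effective sample size; must exceed `K + 1` for the correction
#'   to be defined.  For CJS fits the package uses the number of release
#'   events (detections at occasions `1..T-1`).
#' @return The AICc value.
#' @export
aicc <- function(minus_two_log_lik, K, n_eff) {
  if (!is_count(K)) stop("`K` must be a non-negative integer", call. = FALSE)
  if (!is.numeric(n_eff) || length(n_eff) != 1L || n_eff <= K + 1) {
    stop("`n_eff` must exceed K + 1 for the AICc correction", call. = FALSE)
  }
  minus_two_log_lik + 2 * K + 2 * K * (K + 1) / (n_eff - K - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AICc_i - min(AICc)`.  Invariant to adding a constant to all
#' values.
#'
#' @param aicc_values Numeric vector of AICc values (at least one finite).
#' @return Numeric weights summing to 1.
#' @export
#' @examples
#' akaike_weights(c(1491.25, 1497.94, 1498.39))
akaike_weights <- function(aicc_values) {
  if (!is.numeric(aicc_values) || !any(is.finite(aicc_values))) {
    stop("`aicc_values` must contain at least one finite value", call. = FALSE)
  }
  delta <- aicc_values - min(aicc_values, na.rm = TRUE)
  w <- exp(-delta / 2)
  w / sum(w, na.rm = TRUE)
}

#' Probability of persisting over several intervals
#'
#' Product of per-interval persistence probabilities; a constant `phi` over
#' `n` decades gives `phi^n`, e.g. `0.46^10` for a century at the estimate
#' typical of a strongly declining species.
#'
#' @param phi A single persistence probability or a vector of length
#'   `n_intervals`.
#' @param n_intervals Number of intervals spanned (>= 0).
#' @return The persistence probability over the whole span.
#' @export
persistence_over <- function(phi, n_intervals) {
  assert_probabilities(phi, "phi")
  if (!is_count(n_intervals)) {
    stop("`n_intervals` must be a non-negative integer", call. = FALSE)
  }
  if (n_intervals == 0) return(1)
  if (length(phi) == 1L) return(phi^n_intervals)
  if (length(phi) != n_intervals) {
    stop("vector `phi` must have length `n_intervals`", call. = FALSE)
  }
  prod(phi)
}
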