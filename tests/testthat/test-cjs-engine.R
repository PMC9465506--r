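test_that("chi recursion matches hand-computed cases and guards its inputs", {
  expect_equal(chi_vector(rep(0, 3), rep(0.5, 3)), rep(1, 4))  # dead stays unseen
  expect_equal(chi_vector(rep(1, 2), rep(1, 2)), c(0, 0, 1))   # certain redetection
  expect_equal(chi_vector(0.5, 0.5), c(0.75, 1))               # 1 - 0.5*(1 - 0.5)
  expect_error(chi_vector(1.2, 0.5), "probabilities")
  expect_error(chi_vector(c(0.5, 0.5), 0.5), "equal length")
})

test_that("cjs_loglik matches hand arithmetic and perfect-detection limits", {
  expect_equal(cjs_loglik(matrix(c(1, 1), 1), 0.5, 0.5), log(0.25))
  # all-ones history under phi = p = 1 has probability 1
  expect_equal(cjs_loglik(matrix(1, 3, 4), rep(1, 3), rep(1, 3)), 0)
  expect_error(cjs_loglik(matrix(c(1, 0, 0, 0), 2), rep(0.5, 1), rep(0.5, 1)),
               "all-zero")
})

test_that("suffix-history probabilities sum to one and match the enumeration oracle", {
  for (T in 3:5) {
    for (phi0 in c(0.2, 0.5, 0.8)) {
      for (p0 in c(0.1, 0.4, 0.9)) {
        phi <- rep(phi0, T - 1)
        p <- rep(p0, T - 1)
        for (f in 1:(T - 1)) {
          y <- all_suffix_histories(T, f)
          probs <- apply(y, 1, oracle_history_prob, phi = phi, p = p)
          expect_equal(sum(probs), 1, tolerance = 1e-12)
          ll <- cjs_loglik(y[rowSums(y) > 0, , drop = FALSE], phi, p)
          expect_equal(ll, sum(log(probs[rowSums(y) > 0])), tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("sufficient-statistic likelihood equals the per-history likelihood", {
  set.seed(31)
  for (rep in 1:5) {
    T <- sample(4:12, 1)
    y <- matrix(rbinom(40 * T, 1, 0.4), 40, T)
    y <- y[rowSums(y) > 0, , drop = FALSE]
    phi <- runif(T - 1, 0.2, 0.9)
    p <- runif(T - 1, 0.1, 0.8)
    stats <- declineCJS:::cjs_suffstats(y)
    expect_equal(declineCJS:::cjs_loglik_stats(stats, phi, p),
                 cjs_loglik(y, phi, p), tolerance = 1e-10)
  }
})

test_that("analytic gradient agrees with central finite differences", {
  set.seed(41)
  y <- matrix(rbinom(600, 1, 0.35), 50, 12)
  y <- y[rowSums(y) > 0, , drop = FALSE]
  stats <- declineCJS:::cjs_suffstats(y)
  phi <- runif(11, 0.2, 0.8)
  p <- runif(11, 0.1, 0.7)
  g <- declineCJS:::cjs_grad_stats(stats, phi, p)
  h <- 1e-6
  for (k in c(1, 5, 11)) {
    up <- dn <- phi
    up[k] <- phi[k] + h; dn[k] <- phi[k] - h
    fd <- (declineCJS:::cjs_loglik_stats(stats, up, p) -
             declineCJS:::cjs_loglik_stats(stats, dn, p)) / (2 * h)
    expect_equal(g$phi[k], fd, tolerance = 1e-4)
    up <- dn <- p
    up[k] <- p[k] + h; dn[k] <- p[k] - h
    fd <- (declineCJS:::cjs_loglik_stats(stats, phi, up) -
             declineCJS:::cjs_loglik_stats(stats, phi, dn)) / (2 * h)
    expect_equal(g$p[k], fd, tolerance = 1e-4)
  }
})

test_that("design matrices have the documented shapes and full rank", {
  s12 <- cjs_spec("constant", "full", 12)
  d <- build_design(s12)
  expect_equal(d$X_phi, matrix(1, 11, 1))
  expect_equal(d$X_p, diag(11))
  dq <- build_design(cjs_spec("quadratic", "linear", 12))
  expect_equal(ncol(dq$X_phi), 3L)
  expect_equal(dq$X_phi[, 2], dq$s)
  expect_equal(dq$X_phi[, 3], dq$s^2)
  expect_equal(range(dq$s), c(-1, 1))
  expect_equal(qr(dq$X_phi)$rank, 3L)
})

test_that("parameter counts follow the structure sizes and the confounding rule", {
  T12 <- function(phi, p) count_parameters(cjs_spec(phi, p, 12))
  expect_equal(T12("quadratic", "full"), 14L)
  expect_equal(T12("constant", "full"), 12L)
  expect_equal(T12("linear", "full"), 13L)
  expect_equal(T12("constant", "linear"), 3L)
  expect_equal(T12("constant", "quadratic"), 4L)
  expect_equal(T12("quadratic", "linear"), 5L)
  expect_equal(T12("constant", "constant"), 2L)
  expect_equal(T12("linear", "constant"), 3L)
  expect_equal(T12("full", "full"), 21L)
})

test_that("the full-by-full likelihood Hessian has the confounded rank", {
  # the terminal phi and p enter only through their product, so the
  # 2(T-1)-coefficient Hessian must have exactly one zero eigenvalue
  st <- generate_study(sim_config(n_initial = 600, phi = 0.6, p = 0.5,
                                  n_occasions = 4, species = "sim"), seed = 5)
  dh <- build_detection_histories(st$records, occasion_grid(1900, 1939))
  fit <- fit_cjs(dh, cjs_spec("full", "full", 4))
  stats <- declineCJS:::cjs_suffstats(dh$y)
  d <- build_design(cjs_spec("full", "full", 4))
  negll <- function(beta) {
    phi <- plogis(drop(d$X_phi %*% beta[1:3]))
    p <- plogis(drop(d$X_p %*% beta[4:6]))
    -declineCJS:::cjs_loglik_stats(stats, phi, p)
  }
  H <- stats::optimHess(fit$beta, negll)
  ev <- abs(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(sum(ev > max(ev) * 1e-7), count_parameters(fit$spec))
  expect_true(is.finite(fit$terminal_product))
  expect_true(is.na(fit$phi_hat[3]) && is.na(fit$p_hat[3]))
})

test_that("aicc applies the small-sample correction and guards n_eff", {
  expect_equal(aicc(100, 3, 10), 110)          # 100 + 6 + 24/6
  expect_equal(aicc(250, 0, 50), 250)          # no parameters
  expect_equal(aicc(100, 3, 1e12), 106, tolerance = 1e-9)  # AIC limit
  expect_error(aicc(100, 3, 4), "n_eff")
})

test_that("akaike weights normalise, order and shift-invariance hold", {
  w <- akaike_weights(c(1491.25, 1497.94, 1498.39))
  expect_equal(round(w[1], 2), 0.94)
  expect_equal(sum(w), 1)
  expect_equal(akaike_weights(42), 1)
  expect_equal(akaike_weights(rep(7, 4)), rep(0.25, 4))
  expect_equal(akaike_weights(c(10, 12, 15) + 1000),
               akaike_weights(c(10, 12, 15)))
})

test_that("constant-model ML estimates match an exhaustive grid search", {
  y <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 1), c(1, 0, 0),
             c(0, 1, 1), c(0, 1, 0))
  grid <- seq(0.01, 0.99, by = 0.01)
  ll <- outer(grid, grid, Vectorize(function(phi, p) {
    cjs_loglik(y, rep(phi, 2), rep(p, 2))
  }))
  best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  fit <- fit_cjs(y, cjs_spec("constant", "constant", 3))
  expect_true(fit$converged)
  expect_lt(abs(fit$phi_hat[1] - grid[best["row"]]), 0.011)
  expect_lt(abs(fit$p_hat[1] - grid[best["col"]]), 0.011)
  expect_gte(fit$loglik, max(ll) - 1e-6)
})

test_that("saturated detection data drive the phi*p product to the boundary", {
  y <- matrix(1, 40, 5)
  fit <- suppressWarnings(fit_cjs(y, cjs_spec("constant", "constant", 5)))
  expect_gte(fit$phi_hat[1] * fit$p_hat[1], 0.999)
})

test_that("a constant-structure fit recovers simulated rates", {
  st <- generate_study(sim_config(n_initial = 800, phi = 0.46, p = 0.36,
                                  n_occasions = 12, species = "sim"), seed = 17)
  dh <- build_detection_histories(st$records, occasion_grid(1900, 2019))
  fit <- fit_cjs(dh, cjs_spec("constant", "constant", 12))
  expect_true(fit$converged)
  expect_equal(fit$phi_hat[1], 0.46, tolerance = 0.05)
  expect_equal(fit$p_hat[1], 0.36, tolerance = 0.05)
  expect_gte(fit$aicc, fit$minus_two_log_lik + 2 * fit$K)
})

test_that("real-scale estimates are invariant to affine time rescaling", {
  st <- generate_study(sim_config(n_initial = 500,
                                  phi = list(structure = "linear", beta = c(0, -0.8)),
                                  p = 0.4, n_occasions = 8, species = "sim"),
                       seed = 23)
  dh <- build_detection_histories(st$records, occasion_grid(1900, 1979))
  spec <- cjs_spec("linear", "linear", 8)
  f1 <- fit_cjs(dh, spec)
  f2 <- fit_cjs(dh, spec, design = build_design(spec, time_range = c(0, 1)))
  expect_equal(f1$phi_hat, f2$phi_hat, tolerance = 1e-6)
  expect_equal(f1$p_hat, f2$p_hat, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("maximized likelihoods respect the nesting order", {
  st <- generate_study(sim_config(n_initial = 700,
                                  phi = list(structure = "quadratic", beta = c(0.3, -0.6, -0.5)),
                                  p = 0.35, n_occasions = 12, species = "sim"),
                       seed = 29)
  dh <- build_detection_histories(st$records, occasion_grid(1900, 2019))
  ll <- vapply(c("constant", "linear", "quadratic", "full"), function(s) {
    fit_cjs(dh, cjs_spec(s, "constant", 12))$loglik
  }, numeric(1))
  expect_true(all(diff(ll) >= -1e-6))
})

test_that("model selection ranks by AICc with coherent deltas and weights", {
  st <- generate_study(sim_config(n_initial = 600, phi = 0.5, p = 0.4,
                                  n_occasions = 6, species = "sim"), seed = 37)
  dh <- build_detection_histories(st$records, occasion_grid(1900, 1959))
  tab <- model_selection(dh, specs = cjs_model_set(6)[c("Phi(.)p(.)", "Phi(Time)p(.)",
                                                        "Phi(.)p(Time)", "Phi(Time^2)p(Time)")])
  expect_equal(tab$delta_AICc[1], 0)
  expect_false(is.unsorted(tab$AICc))
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_s3_class(best_fit(tab), "cjs_fit")
})

test_that("persistence_over multiplies per-interval survival", {
  expect_equal(persistence_over(1, 25), 1)
  expect_equal(persistence_over(0.46, 10), 0.46^10)
  phis <- c(0.72, 0.65, 0.5, 0.44, 0.31)
  acc <- 1
  for (x in phis) acc <- acc * x  # sequential multiplication oracle
  expect_equal(persistence_over(phis, 5), acc)
  expect_equal(persistence_over(0.9, 0), 1)
  expect_error(persistence_over(phis, 3), "length")
})
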