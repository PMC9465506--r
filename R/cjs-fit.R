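#' Optimiser settings for CJS fitting
#'
#' @param n_restarts Number of random restarts in addition to the zero start.
#' @param seed Seed for the (deterministic) restart draws.
#' @param maxit Maximum BFGS iterations per start.
#' @param reltol Relative convergence tolerance on the objective.
#' @param restart_sd Standard deviation of the random logit-scale starts.
#' @param boundary Linear predictors beyond this magnitude are treated as
#'   boundary estimates and pinned to 0/1 on the real scale.
#' @return A list of class `cjs_control`.
#' @export
cjs_control <- function(n_restarts = 5, seed = 1, maxit = 1000,
                        reltol = 1e-8, restart_sd = 1.5, boundary = 15) {
  structure(list(n_restarts = n_restarts, seed = seed, maxit = maxit,
                 reltol = reltol, restart_sd = restart_sd, boundary = boundary),
            class = "cjs_control")
}

#' Fit a Cormack-Jolly-Seber model by maximum likelihood
#'
#' Maximises the conditional CJS likelihood over logit-scale coefficients
#' mapped through the structure's design matrices ([build_design()]), using
#' BFGS with an analytic gradient, a zero start and seeded random restarts.
#' Real-scale estimates are the inverse-logit transforms of the fitted linear
#' predictors.  When both `Phi` and `p` are fully time-dependent, the
#' terminal pair `phi_(T-1)`, `p_T` is confounded and reported only through
#' the derived product `terminal_product`; the separate entries are `NA`.
#'
#' @param histories A [build_detection_histories()] result or binary matrix.
#' @param spec A [cjs_spec()]; its `n_occasions` must match the histories.
#' @param control A [cjs_control()].
#' @param design Optional [build_design()] override (e.g. with a different
#'   `time_range`); defaults to the spec's standard design.
#' @return An object of class `cjs_fit` with elements `spec`, `beta`,
#'   `phi_hat`, `p_hat` (real scale; `p_hat[j]` is detection at occasion
#'   `j + 1`), `phi_se`/`p_se` (approximate delta-method standard errors),
#'   `loglik`, `minus_two_log_lik`, `K`, `n_eff`, `aicc`, `converged`,
#'   `boundary_phi`/`boundary_p`, `terminal_product` and `n_histories`.
#' @export
fit_cjs <- function(histories, spec, control = cjs_control(), design = NULL) {
  stopifnot(inherits(spec, "cjs_spec"))
  y <- history_matrix(histories)
  T <- ncol(y)
  if (T != spec$n_occasions) {
    stop("spec has ", spec$n_occasions, " occasions but histories have ", T,
         call. = FALSE)
  }
  b <- history_bounds(y)
  if (!any(b$l > b$f)) {
    warning("no history has a detection after its first detection; ",
            "persistence is not identifiable", call. = FALSE)
  }
  design <- design %||% build_design(spec)
  X_phi <- design$X_phi
  X_p <- design$X_p
  k_phi <- ncol(X_phi)
  k_beta <- k_phi + ncol(X_p)
  stats <- cjs_suffstats(y)

  to_probs <- function(beta) {
    list(phi = clamp_prob(plogis(drop(X_phi %*% beta[seq_len(k_phi)]))),
         p = clamp_prob(plogis(drop(X_p %*% beta[-seq_len(k_phi)]))))
  }
  negll <- function(beta) {
    pr <- to_probs(beta)
    v <- -cjs_loglik_stats(stats, pr$phi, pr$p)
    if (!is.finite(v)) 1e10 else v
  }
  neggr <- function(beta) {
    pr <- to_probs(beta)
    g <- cjs_grad_stats(stats, pr$phi, pr$p)
    -c(drop(crossprod(X_phi, g$phi * pr$phi * (1 - pr$phi))),
       drop(crossprod(X_p, g$p * pr$p * (1 - pr$p))))
  }

  starts <- rbind(rep(0, k_beta),
                  withr::with_seed(control$seed,
                    matrix(stats::rnorm(control$n_restarts * k_beta,
                                        sd = control$restart_sd),
                           nrow = control$n_restarts)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], negll, neggr, method = "BFGS",
            control = list(maxit = control$maxit, reltol = control$reltol)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    stop("all optimizer starts failed", call. = FALSE)
  }
  beta <- best$par
  pr <- to_probs(beta)
  eta_phi <- drop(X_phi %*% beta[seq_len(k_phi)])
  eta_p <- drop(X_p %*% beta[-seq_len(k_phi)])
  boundary_phi <- abs(eta_phi) > control$boundary
  boundary_p <- abs(eta_p) > control$boundary
  phi_hat <- ifelse(boundary_phi, as.numeric(eta_phi > 0), plogis(eta_phi))
  p_hat <- ifelse(boundary_p, as.numeric(eta_p > 0), plogis(eta_p))

  converged <- best$convergence == 0 && all(is.finite(c(phi_hat, p_hat)))
  K <- count_parameters(spec)
  n_eff <- stats$n_eff
  loglik <- -best$value
  m2ll <- 2 * best$value
  aicc_val <- if (n_eff > K + 1) aicc(m2ll, K, n_eff) else {
    warning("effective sample size too small for AICc", call. = FALSE)
    NA_real_
  }

  # approximate (delta-method) standard errors from the numeric Hessian;
  # unavailable when the Hessian is singular (e.g. boundary or confounding)
  vcov_beta <- tryCatch({
    H <- stats::optimHess(beta, negll, neggr)
    solve(H)
  }, error = function(e) NULL)
  se_from <- function(X, idx, prob) {
    if (is.null(vcov_beta)) return(rep(NA_real_, nrow(X)))
    v <- diag(X %*% vcov_beta[idx, idx, drop = FALSE] %*% t(X))
    se <- rep(NA_real_, nrow(X))
    ok <- is.finite(v) & v > 0
    se[ok] <- sqrt(v[ok]) * prob[ok] * (1 - prob[ok])
    se
  }
  phi_se <- se_from(X_phi, seq_len(k_phi), phi_hat)
  p_se <- se_from(X_p, k_phi + seq_len(ncol(X_p)), p_hat)

  terminal_product <- NA_real_
  if (spec$phi == "full" && spec$p == "full") {
    terminal_product <- phi_hat[T - 1L] * p_hat[T - 1L]
    phi_hat[T - 1L] <- NA_real_
    p_hat[T - 1L] <- NA_real_
    phi_se[T - 1L] <- NA_real_
    p_se[T - 1L] <- NA_real_
  }

  structure(list(
    spec = spec, design = design, beta = beta,
    phi_hat = phi_hat, p_hat = p_hat, phi_se = phi_se, p_se = p_se,
    loglik = loglik, minus_two_log_lik = m2ll, K = K, n_eff = n_eff,
    aicc = aicc_val, converged = converged,
    boundary_phi = boundary_phi, boundary_p = boundary_p,
    terminal_product = terminal_product,
    n_histories = nrow(y)
  ), class = "cjs_fit")
}

#' @export
print.cjs_fit <- function(x, digits = 3, ...) {
  cat(sprintf("CJS fit %s: K = %d, -2lnL = %.2f, AICc = %.2f (n_eff = %g)%s\n",
              model_name(x$spec), x$K, x$minus_two_log_lik, x$aicc, x$n_eff,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("  phi:", paste(format(round(x$phi_hat, digits)), collapse = " "), "\n")
  cat("  p:  ", paste(format(round(x$p_hat, digits)), collapse = " "), "\n")
  if (!is.na(x$terminal_product)) {
    cat(sprintf("  terminal phi*p (confounded): %.3f\n", x$terminal_product))
  }
  invisible(x)
}

#' Tidy per-occasion estimates from a CJS fit
#'
#' @param fit A [cjs_fit()] result.
#' @param grid Optional [occasion_grid()] used to label intervals/occasions
#'   with calendar decades.
#' @return A tibble with columns `parameter` (`"phi"` or `"p"`), `index`
#'   (interval `i` for phi; occasion `i + 1` for p), `estimate`, `se`,
#'   `boundary`, and decade labels when `grid` is supplied.
#' @export
cjs_estimates <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "cjs_fit"))
  T <- fit$spec$n_occasions
  out <- dplyr::bind_rows(
    tibble::tibble(parameter = "phi", index = seq_len(T - 1L),
                   estimate = fit$phi_hat, se = fit$phi_se,
                   boundary = fit$boundary_phi),
    tibble::tibble(parameter = "p", index = seq_len(T - 1L) + 1L,
                   estimate = fit$p_hat, se = fit$p_se,
                   boundary = fit$boundary_p)
  )
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "occasion_grid"))
    out$decade <- grid$occasions$label[ifelse(out$parameter == "phi",
                                              out$index, out$index)]
  }
  out
}

#' Fit and rank a set of candidate CJS models by AICc
#'
#' Fits every specification, then ranks models by AICc (ties broken by the
#' smaller parameter count) and computes delta-AICc and Akaike weights.
#' Models that fail to converge are retained and flagged but excluded from
#' the weight normalisation, with a warning.
#'
#' @param histories A [build_detection_histories()] result or binary matrix.
#' @param specs List of [cjs_spec()]; defaults to the full 16-model crossing
#'   ([cjs_model_set()]).
#' @param control A [cjs_control()] shared by all fits.
#' @return A tibble of class `cjs_model_table` with columns `model`, `K`,
#'   `minus_two_log_lik`, `AICc`, `delta_AICc`, `weight`, `converged`;
#'   the fitted objects are attached as attribute `"fits"`.
#' @export
model_selection <- function(histories, specs = NULL, control = cjs_control()) {
  y <- history_matrix(histories)
  specs <- specs %||% cjs_model_set(ncol(y))
  if (length(specs) == 0L) stop("`specs` must be non-empty", call. = FALSE)
  for (s in specs) {
    stopifnot(inherits(s, "cjs_spec"))
    if (s$n_occasions != ncol(y)) {
      stop("all specs must share the histories' occasion count", call. = FALSE)
    }
  }
  fits <- lapply(specs, function(s) fit_cjs(y, s, control = control))
  names(fits) <- vapply(fits, function(f) model_name(f$spec), character(1))
  tab <- tibble::tibble(
    model = names(fits),
    K = unname(vapply(fits, `[[`, integer(1), "K")),
    minus_two_log_lik = unname(vapply(fits, `[[`, numeric(1), "minus_two_log_lik")),
    AICc = unname(vapply(fits, `[[`, numeric(1), "aicc")),
    converged = unname(vapply(fits, `[[`, logical(1), "converged"))
  )
  usable <- tab$converged & is.finite(tab$AICc)
  if (!all(usable)) {
    warning("non-converged model(s) excluded from Akaike weights: ",
            paste(tab$model[!usable], collapse = ", "), call. = FALSE)
  }
  tab$delta_AICc <- tab$AICc - min(tab$AICc[usable])
  tab$weight <- NA_real_
  if (any(usable)) tab$weight[usable] <- akaike_weights(tab$AICc[usable])
  ord <- order(tab$AICc, tab$K)
  tab <- tab[ord, c("model", "K", "minus_two_log_lik", "AICc",
                    "delta_AICc", "weight", "converged")]
  structure(tab, class = unique(c("cjs_model_table", class(tab))),
            fits = fits[tab$model])
}

#' @export
print.cjs_model_table <- function(x, n = Inf, ...) {
  cat("CJS model selection (AICc, best first)\n")
  df <- as.data.frame(x)
  df$minus_two_log_lik <- round(df$minus_two_log_lik, 2)
  df$AICc <- round(df$AICc, 2)
  df$delta_AICc <- round(df$delta_AICc, 2)
  df$weight <- round(df$weight, 3)
  print(head(df, n), row.names = FALSE)
  invisible(x)
}

#' Extract a fitted model from a model table
#'
#' @param table A [model_selection()] result.
#' @param model Model name (as printed); default the best-ranked converged
#'   model.
#' @return The corresponding `cjs_fit`.
#' @export
best_fit <- function(table, model = NULL) {
  stopifnot(inherits(table, "cjs_model_table"))
  fits <- attr(table, "fits")
  if (is.null(model)) {
    ok <- table$model[table$converged]
    if (length(ok) == 0L) stop("no converged model in the table", call. = FALSE)
    model <- ok[[1L]]
  }
  fits[[model]]
}
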