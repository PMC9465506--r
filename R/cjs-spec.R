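cjs_structures <- c("constant", "linear", "quadratic", "full")

#' Specify a Cormack-Jolly-Seber model structure
#'
#' A CJS model for locality detection histories is defined by the time
#' structure of population persistence `Phi` (per decade-to-decade interval)
#' and population detectability `p` (per occasion from the second onwards),
#' each one of: `"constant"` (MARK's `.`), `"linear"` (`Time`),
#' `"quadratic"` (`Time^2`) or `"full"` (`t`, one free parameter per
#' interval/occasion).  Trend structures act on the logit scale through a
#' centred time covariate (see [build_design()]).
#'
#' @param phi,p Time structure of persistence and detection.
#' @param n_occasions Number of occasions `T` (>= 2; linear needs `T >= 3`,
#'   quadratic `T >= 4` so the design keeps full column rank).
#' @return An object of class `cjs_spec`.
#' @export
#' @examples
#' cjs_spec("quadratic", "full", n_occasions = 12)
cjs_spec <- function(phi = "constant", p = "constant", n_occasions) {
  phi <- match.arg(phi, cjs_structures)
  p <- match.arg(p, cjs_structures)
  if (!is_count(n_occasions) || n_occasions < 2) {
    stop("`n_occasions` must be an integer >= 2", call. = FALSE)
  }
  n_occasions <- as.integer(n_occasions)
  need <- function(st) switch(st, constant = 2L, linear = 3L, quadratic = 4L, full = 2L)
  if (n_occasions < max(need(phi), need(p))) {
    stop("n_occasions too small for the requested time structure", call. = FALSE)
  }
  structure(list(phi = phi, p = p, n_occasions = n_occasions),
            class = "cjs_spec")
}

#' MARK-style model name
#'
#' Renders a model specification in the conventional capture-recapture
#' notation, e.g. `"Phi(Time^2)p(t)"`.
#'
#' @param spec A [cjs_spec()].
#' @return A single string.
#' @export
model_name <- function(spec) {
  stopifnot(inherits(spec, "cjs_spec"))
  code <- c(constant = ".", linear = "Time", quadratic = "Time^2", full = "t")
  sprintf("Phi(%s)p(%s)", code[[spec$phi]], code[[spec$p]])
}

#' @export
print.cjs_spec <- function(x, ...) {
  cat(sprintf("CJS model %s, T = %d occasions, K = %d parameters\n",
              model_name(x), x$n_occasions, count_parameters(x)))
  invisible(x)
}

#' The default candidate model set
#'
#' All 16 combinations of {constant, linear, quadratic, full} time structures
#' for `Phi` crossed with the same four structures for `p`.
#'
#' @param n_occasions Number of occasions.
#' @return A list of [cjs_spec()] objects, named by [model_name()].
#' @export
cjs_model_set <- function(n_occasions) {
  combos <- expand.grid(p = cjs_structures, phi = cjs_structures,
                        stringsAsFactors = FALSE)
  specs <- lapply(seq_len(nrow(combos)), function(i) {
    cjs_spec(combos$phi[i], combos$p[i], n_occasions)
  })
  names(specs) <- vapply(specs, model_name, character(1))
  specs
}

#' Count estimable parameters of a CJS structure
#'
#' `K = K_phi + K_p` with constant -> 1, linear -> 2, quadratic -> 3 and full
#' -> `T - 1` coefficients, minus 1 if and only if *both* parameters are
#' fully time-dependent: in that case the terminal persistence
#' `phi_(T-1)` and detection `p_T` are confounded and only their product is
#' estimable.
#'
#' @param spec A [cjs_spec()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "cjs_spec"))
  k <- function(st) switch(st, constant = 1L, linear = 2L, quadratic = 3L,
                           full = spec$n_occasions - 1L)
  k(spec$phi) + k(spec$p) - as.integer(spec$phi == "full" && spec$p == "full")
}

#' Design matrices mapping coefficients to logit(Phi) and logit(p)
#'
#' Builds the `(T-1) x K` matrices that map logit-scale coefficients to the
#' `T - 1` persistence intervals and to detection at occasions `2..T`.  The
#' time covariate for linear/quadratic columns is the interval (or occasion)
#' index mapped affinely onto `time_range` (default `[-1, 1]`), which keeps
#' the optimisation well conditioned; real-scale estimates are invariant to
#' this choice.
#'
#' @param spec A [cjs_spec()].
#' @param time_range Length-2 numeric; image of the affine time mapping.
#' @return A list of class `cjs_design` with `X_phi`, `X_p` and the scaled
#'   covariate `s`.
#' @export
build_design <- function(spec, time_range = c(-1, 1)) {
  stopifnot(inherits(spec, "cjs_spec"), length(time_range) == 2)
  n <- spec$n_occasions - 1L
  s <- if (n == 1L) mean(time_range) else
    seq(time_range[1], time_range[2], length.out = n)
  one <- function(st) {
    X <- switch(st,
                constant = matrix(1, n, 1),
                linear = cbind(1, s),
                quadratic = cbind(1, s, s^2),
                full = diag(n))
    if (qr(X)$rank < ncol(X)) {
      stop("design matrix is rank deficient for structure ", st, call. = FALSE)
    }
    unname(X)
  }
  structure(list(X_phi = one(spec$phi), X_p = one(spec$p), s = s,
                 spec = spec),
            class = "cjs_design")
}
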