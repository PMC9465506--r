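#' @importFrom stats optim plogis qlogis rbinom rgeom setNames
#' @importFrom utils head
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# keep probabilities strictly inside (0, 1) so log terms stay finite
clamp_prob <- function(x, eps = 1e-12) {
  pmin(pmax(x, eps), 1 - eps)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

assert_probabilities <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop(sprintf("`%s` must be probabilities in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
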