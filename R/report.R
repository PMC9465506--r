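#' Render an analysis bundle as a Markdown report
#'
#' Formats (without recomputing anything) the run log, the summary counts,
#' the tail of the pooled relative decline curve, and per stratum either a
#' model-comparison table (Model, Parameters, -2lnL, AICc, deltaAICc,
#' Weight) with the best model's per-occasion estimates, or a
#' "skipped (sparse)" marker.
#'
#' @param bundle A [run_analysis()] result.
#' @return A character vector of Markdown lines.
#' @export
render_report <- function(bundle) {
  stopifnot(inherits(bundle, "decline_analysis"))
  fmt <- function(x, d = 2) ifelse(is.na(x), "-", sprintf(paste0("%.", d, "f"), x))
  lines <- c("# Locality decline analysis", "",
             "## Run log", "", paste0("- ", bundle$log), "",
             "## Summary counts", "",
             sprintf("- records analysed: %d (of %d read; %d dated)",
                     bundle$summary$n_records, bundle$summary_raw$n_records,
                     bundle$summary_raw$n_dated_records),
             sprintf("- distinct localities: %d", bundle$summary$n_localities),
             "")
  tail_rel <- utils::tail(bundle$curve_pooled$relative_percent, 1)
  lines <- c(lines, "## Pooled decline", "",
             sprintf("- localities ever recorded (earliest decade onward): %d",
                     bundle$curve_pooled$cumulative[1]),
             sprintf("- still recorded in the latest decade: %d (%s%%)",
                     utils::tail(bundle$curve_pooled$cumulative, 1),
                     fmt(tail_rel, 1)),
             "")
  for (res in bundle$strata) {
    lines <- c(lines, sprintf("## Stratum: %s", res$stratum), "")
    if (res$status != "fitted") {
      lines <- c(lines, sprintf("skipped (sparse): %d detection events",
                                res$n_detections), "")
      next
    }
    tab <- res$model_table
    lines <- c(lines,
               sprintf("- %d histories, %d detection events; best model: %s",
                       res$n_histories, res$n_detections, res$best_model),
               sprintf("- derived persistence over %d intervals: %s",
                       bundle$config$n_persistence_intervals,
                       format(res$persistence, digits = 3)),
               "",
               "| Model | Parameters | -2lnL | AICc | deltaAICc | Weight |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %d | %s | %s | %s | %s |",
                       tab$model, tab$K, fmt(tab$minus_two_log_lik),
                       fmt(tab$AICc), fmt(tab$delta_AICc), fmt(tab$weight)),
               "", "Best-model estimates:", "",
               "| Parameter | Decade | Estimate | SE |", "|---|---|---|---|",
               sprintf("| %s | %s | %s | %s |",
                       res$estimates$parameter, res$estimates$decade,
                       fmt(res$estimates$estimate), fmt(res$estimates$se)),
               "")
  }
  lines
}

#' Write an analysis bundle to disk
#'
#' Writes `counts.csv` / `counts.json` (per-species summary), `curves.csv`
#' (tidy per-stratum decline curves), one `model_table_<stratum>.csv` and
#' `estimates_<stratum>.csv` per fitted stratum, the Markdown `report.md`
#' and the run `log.txt`.  Output is deterministic for a fixed configuration
#' and seed.
#'
#' @param bundle A [run_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(bundle, dir) {
  stopifnot(inherits(bundle, "decline_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  slug <- function(x) gsub("[^A-Za-z0-9]+", "_", x)
  readr::write_csv(bundle$summary$per_species, file.path(dir, "counts.csv"))
  jsonlite::write_json(
    list(n_records = bundle$summary$n_records,
         n_dated_records = bundle$summary$n_dated_records,
         n_localities = bundle$summary$n_localities,
         per_species = bundle$summary$per_species,
         per_country = bundle$summary$per_country),
    file.path(dir, "counts.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(tibble::as_tibble(bundle$curves), file.path(dir, "curves.csv"))
  for (res in bundle$strata) {
    if (res$status != "fitted") next
    readr::write_csv(tibble::as_tibble(res$model_table),
                     file.path(dir, paste0("model_table_", slug(res$stratum), ".csv")))
    readr::write_csv(res$estimates,
                     file.path(dir, paste0("estimates_", slug(res$stratum), ".csv")))
  }
  writeLines(render_report(bundle), file.path(dir, "report.md"))
  writeLines(bundle$log, file.path(dir, "log.txt"))
  invisible(dir)
}

#' Plot a decline curve
#'
#' Line plot of the absolute (and, when present, relative) cumulative
#' locality counts per decade, one panel per stratum.  Requires ggplot2.
#'
#' @param curve A [cumulative_locality_curve()] (optionally after
#'   [relative_decline()]).
#' @return A ggplot object.
#' @export
plot_decline_curve <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  stopifnot(inherits(curve, "decline_curve"))
  stratify_by <- attr(curve, "stratify_by")
  df <- tibble::as_tibble(curve)
  df$stratum <- if (is.null(stratify_by)) "pooled" else
    do.call(paste, c(unname(df[stratify_by]), sep = " / "))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$decade_start,
                                         y = .data$cumulative,
                                         group = .data$stratum)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~stratum, scales = "free_y") +
    ggplot2::labs(x = "decade", y = "localities recorded in or after decade")
  gg
}

#' Plot per-occasion CJS estimates
#'
#' Persistence and detection trajectories of a fitted model with approximate
#' standard-error ribbons.  Requires ggplot2.
#'
#' @param fit A [fit_cjs()] result.
#' @param grid Optional [occasion_grid()] for decade labels.
#' @return A ggplot object.
#' @export
plot_cjs_estimates <- function(fit, grid = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  df <- cjs_estimates(fit, grid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$estimate,
                                   colour = .data$parameter)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "occasion", y = "probability") +
    ggplot2::ylim(0, 1)
}
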