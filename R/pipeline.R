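#' End-to-end analysis configuration
#'
#' Bundles everything [run_analysis()] needs: the input (a delimited record
#' file or a synthetic study configuration), the analysis year window and
#' decade width, the stratification, the candidate CJS model set, the
#' sparse-stratum rule and the seed.
#'
#' @param input Path to a delimited record table, or `NULL` to simulate.
#' @param synthetic A `sim_config` or list of them used when `input` is
#'   `NULL`; defaults to [study_config()].
#' @param columns Column mapping passed to [read_records()].
#' @param year_min,year_max Analysis window (inclusive); the span must be a
#'   multiple of `bin_width`.
#' @param bin_width Occasion width in years.
#' @param stratify_by Record columns defining strata (default `"species"`).
#' @param models Candidate model list (`cjs_spec` objects) or `NULL` for the
#'   full 16-model crossing.
#' @param min_detections CJS models are skipped (curves are still produced)
#'   for strata with fewer detection events than this; mirrors excluding
#'   species whose records are too sparse for temporal trend analysis.
#' @param n_persistence_intervals Span (in intervals) of the derived
#'   long-term persistence probability reported for the best model.
#' @param seed Seed used for simulation and fitting restarts.
#' @param out_dir Optional output directory for [write_analysis()].
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(input = NULL, synthetic = NULL,
                            columns = c(species = "species", locality = "locality",
                                        country = "country", year = "year"),
                            year_min = 1900, year_max = 2019, bin_width = 10,
                            stratify_by = "species", models = NULL,
                            min_detections = 30, n_persistence_intervals = 10,
                            seed = 1, out_dir = NULL) {
  grid <- occasion_grid(year_min, year_max, bin_width)  # validates the window
  if (!is.null(models)) {
    stopifnot(length(models) > 0L,
              all(vapply(models, inherits, logical(1), "cjs_spec")))
  }
  structure(list(input = input, synthetic = synthetic, columns = columns,
                 year_min = year_min, year_max = year_max,
                 bin_width = bin_width, grid = grid,
                 stratify_by = stratify_by, models = models,
                 min_detections = min_detections,
                 n_persistence_intervals = n_persistence_intervals,
                 seed = seed, out_dir = out_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Recognised keys mirror the [analysis_config()] arguments (`input`,
#' `year_min`, `year_max`, `bin_width`, `stratify_by`, `min_detections`,
#' `n_persistence_intervals`, `seed`, `out_dir`, and `columns` as a mapping).
#' `synthetic: default` selects [study_config()]; alternatively `synthetic`
#' may be a list of stratum mappings passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  synthetic <- NULL
  if (!is.null(cfg$synthetic)) {
    synthetic <- if (identical(cfg$synthetic, "default")) study_config()
                 else lapply(cfg$synthetic, function(s) do.call(sim_config, s))
  }
  columns <- if (is.null(cfg$columns)) {
    c(species = "species", locality = "locality", country = "country",
      year = "year")
  } else unlist(cfg$columns)
  analysis_config(
    input = cfg$input, synthetic = synthetic, columns = columns,
    year_min = cfg$year_min %||% 1900, year_max = cfg$year_max %||% 2019,
    bin_width = cfg$bin_width %||% 10,
    stratify_by = cfg$stratify_by %||% "species",
    min_detections = cfg$min_detections %||% 30,
    n_persistence_intervals = cfg$n_persistence_intervals %||% 10,
    seed = cfg$seed %||% 1, out_dir = cfg$out_dir
  )
}

#' Run the full decline analysis
#'
#' Reads (or simulates) occurrence records, restricts them to the analysis
#' window, computes summary counts, pooled and per-stratum cumulative decline
#' curves, builds detection histories per stratum and, for every stratum with
#' enough detection events, fits and ranks the candidate CJS model set.  The
#' run log records record counts before and after each filter so the audit
#' trail is reproducible.
#'
#' @param config An [analysis_config()].
#' @return A list of class `decline_analysis` with elements `config`, `log`
#'   (character), `summary_raw`, `summary` (post-filter), `curve_pooled`,
#'   `curves` (per stratum, with relative decline), and `strata`: per stratum
#'   a list with `n_histories`, `n_detections`, `status`
#'   (`"fitted"`/`"skipped (sparse)"`), `model_table`, `best_model`,
#'   `estimates` and the derived `persistence` over
#'   `n_persistence_intervals`.  If `config$out_dir` is set the bundle is
#'   also written via [write_analysis()].
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  log <- character()
  note <- function(...) {
    log <<- c(log, sprintf(...))
    invisible(NULL)
  }
  if (!is.null(config$input)) {
    records <- read_records(config$input, columns = config$columns)
    note("input: %s", config$input)
  } else {
    synthetic <- config$synthetic %||% study_config()
    records <- generate_study(synthetic, seed = config$seed)$records
    note("input: synthetic study (seed %d)", config$seed)
  }
  note("records read: %d (%d dated)", nrow(records), sum(!is.na(records$year)))
  filtered <- filter_by_years(records, config$year_min, config$year_max)
  note("records in %d-%d: %d", config$year_min, config$year_max, nrow(filtered))
  if (nrow(filtered) == 0L) {
    stop(sprintf("no records left after the %d-%d year filter",
                 config$year_min, config$year_max), call. = FALSE)
  }
  grid <- config$grid
  summary_raw <- summarize_records(records)
  summary_win <- summarize_records(filtered)
  note("distinct localities in window: %d", summary_win$n_localities)

  curve_pooled <- relative_decline(cumulative_locality_curve(filtered, grid))
  curves <- relative_decline(
    cumulative_locality_curve(filtered, grid, stratify_by = config$stratify_by))

  strata_keys <- dplyr::distinct(filtered[, config$stratify_by, drop = FALSE])
  strata_keys <- dplyr::arrange(strata_keys,
                                dplyr::across(dplyr::all_of(config$stratify_by)))
  models <- config$models %||% cjs_model_set(grid$n_occasions)
  control <- cjs_control(seed = config$seed)

  strata <- list()
  for (i in seq_len(nrow(strata_keys))) {
    key <- strata_keys[i, , drop = FALSE]
    name <- paste(unlist(key), collapse = " / ")
    sel <- rep(TRUE, nrow(filtered))
    for (col in config$stratify_by) sel <- sel & filtered[[col]] == key[[col]]
    sub <- filtered[sel, , drop = FALSE]
    dh <- build_detection_histories(sub, grid)
    n_det <- sum(dh$y)
    res <- list(stratum = name, n_records = nrow(sub),
                n_histories = dh$n_histories, n_detections = n_det)
    if (n_det < config$min_detections) {
      warning(sprintf("stratum '%s' skipped: %d detection events < %d",
                      name, n_det, config$min_detections), call. = FALSE)
      note("stratum %s: skipped (sparse; %d detection events)", name, n_det)
      res$status <- "skipped (sparse)"
    } else {
      tab <- model_selection(dh, specs = models, control = control)
      best <- best_fit(tab)
      res$status <- "fitted"
      res$model_table <- tab
      res$best_model <- model_name(best$spec)
      res$estimates <- cjs_estimates(best, grid)
      res$persistence <- if (best$spec$phi == "constant") {
        persistence_over(best$phi_hat[1], config$n_persistence_intervals)
      } else {
        phi_ok <- best$phi_hat[!is.na(best$phi_hat)]
        persistence_over(phi_ok, length(phi_ok))
      }
      note("stratum %s: best model %s (AICc %.2f, %d histories)",
           name, res$best_model, tab$AICc[1], dh$n_histories)
    }
    strata[[name]] <- res
  }
  bundle <- structure(list(config = config, log = log,
                           summary_raw = summary_raw, summary = summary_win,
                           curve_pooled = curve_pooled, curves = curves,
                           strata = strata),
                      class = "decline_analysis")
  if (!is.null(config$out_dir)) write_analysis(bundle, config$out_dir)
  bundle
}

#' @export
print.decline_analysis <- function(x, ...) {
  cat("Decline analysis\n")
  cat(paste0("  ", x$log, "\n"), sep = "")
  invisible(x)
}
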