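#' Cumulative locality decline curve
#'
#' Computes, for every occasion (decade) `d` of the grid, the number of
#' distinct localities with at least one record in `d` *or any later decade*:
#' the count for the most recent decade plus the localities added while
#' walking backwards through time.  Read forward, the curve is non-increasing
#' and traces the apparent loss of occupied localities.  Note that the curve
#' cannot separate true disappearance from non-detection; that correction is
#' the job of the Cormack-Jolly-Seber module ([fit_cjs()]).
#'
#' @param records A record set, filtered to the grid span (undated or
#'   out-of-window records are an error).
#' @param grid An [occasion_grid()].
#' @param stratify_by Optional character vector of record columns; one curve
#'   per stratum.  Unstratified curves pool localities by union, so a
#'   locality shared by two species counts once.
#' @return A tibble of class `decline_curve`, ordered earliest to latest
#'   decade within stratum, with columns `decade`, `decade_start`,
#'   `cumulative` and any stratum columns.
#' @export
cumulative_locality_curve <- function(records, grid, stratify_by = NULL) {
  check_records(records)
  stopifnot(inherits(grid, "occasion_grid"))
  bad <- which(is.na(records$year) | records$year < grid$start_year |
                 records$year > grid$end_year)
  if (length(bad) > 0L) {
    stop("records undated or outside the grid span (filter first); row(s): ",
         paste(head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  occ <- grid$occasions
  one_curve <- function(df) {
    # C(d) = #{localities whose latest record falls in decade >= d}
    last_occ <- if (nrow(df) == 0L) integer() else
      as.integer(tapply(occasion_index(grid, df$year), df$locality, max))
    counts <- tabulate(last_occ, nbins = grid$n_occasions)
    tibble::tibble(decade = occ$label, decade_start = occ$start,
                   cumulative = rev(cumsum(rev(counts))))
  }
  if (is.null(stratify_by)) {
    out <- one_curve(records)
  } else {
    missing_cols <- setdiff(stratify_by, names(records))
    if (length(missing_cols) > 0L) {
      stop("stratify_by column(s) not in records: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    out <- records |>
      dplyr::group_by(dplyr::across(dplyr::all_of(stratify_by))) |>
      dplyr::group_modify(~ one_curve(.x)) |>
      dplyr::ungroup()
  }
  structure(out, class = unique(c("decline_curve", class(out))),
            grid = grid, stratify_by = stratify_by)
}

#' Relative decline curve
#'
#' Adds `relative_percent = 100 * C(d) / C(earliest)` to a decline curve,
#' per stratum.  The earliest decade is by construction 100%.
#'
#' @param curve A [cumulative_locality_curve()] result.
#' @return The curve with a `relative_percent` column; absolute counts are
#'   unchanged.
#' @export
relative_decline <- function(curve) {
  stopifnot(inherits(curve, "decline_curve"))
  stratify_by <- attr(curve, "stratify_by")
  rel <- function(df) {
    base <- df$cumulative[which.min(df$decade_start)]
    if (base == 0) {
      stop("all-zero decline curve: no localities in the earliest decade or later",
           call. = FALSE)
    }
    df$relative_percent <- 100 * df$cumulative / base
    df
  }
  out <- if (is.null(stratify_by)) {
    rel(curve)
  } else {
    curve |>
      dplyr::group_by(dplyr::across(dplyr::all_of(stratify_by))) |>
      dplyr::group_modify(~ rel(.x)) |>
      dplyr::ungroup()
  }
  structure(out, class = unique(c("decline_curve", class(out))),
            grid = attr(curve, "grid"), stratify_by = stratify_by)
}

#' Localities confirmed after a cutoff year
#'
#' Counts distinct localities with at least one dated record strictly after
#' `year` ("confirmed after the year 2000" means `year > 2000`).
#'
#' @param records A record set.
#' @param year Cutoff calendar year (exclusive).
#' @return Integer count.
#' @export
localities_confirmed_after <- function(records, year) {
  check_records(records)
  dplyr::n_distinct(records$locality[!is.na(records$year) & records$year > year])
}
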