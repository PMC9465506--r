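#' Read dated species-occurrence records from delimited text
#'
#' Ingests a header-bearing CSV/TSV table of occurrence records (one row per
#' record) into a validated record set with the standard columns `species`,
#' `locality`, `country`, `year` and a `dated` flag.  Years that cannot be
#' parsed as integers, or that fall outside the plausible 1700--2100 window,
#' are stored as missing; the row is retained so that ingestion preserves the
#' row count and undated records remain available for audit.
#'
#' @param path Path to a delimited text file with a header row.
#' @param columns Named character vector mapping the standard roles
#'   `species`, `locality`, `country`, `year` to the column names used in the
#'   file.
#' @param delim Field delimiter.  `NULL` (default) auto-detects among comma,
#'   semicolon and tab by inspecting the header line.
#' @param provenance Free-text source label attached to the result; defaults
#'   to the file path.
#'
#' @return A tibble of class `record_set` with columns `species`, `locality`,
#'   `country`, `year` (integer, `NA` when undated) and `dated` (logical),
#'   one row per input data row, plus a `provenance` attribute.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("species,locality,country,year",
#'              "Jordanita notata,L001,AT,1954",
#'              "Jordanita notata,L002,AT,"), f)
#' read_records(f)
read_records <- function(path,
                         columns = c(species = "species", locality = "locality",
                                     country = "country", year = "year"),
                         delim = NULL,
                         provenance = path) {
  required <- c("species", "locality", "country", "year")
  if (!all(required %in% names(columns))) {
    stop("`columns` must map all of: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L || !nzchar(trimws(header))) {
    warning("empty input file: returning an empty record set", call. = FALSE)
    return(empty_record_set(provenance))
  }
  delim <- delim %||% detect_delim(header)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           trim_ws = TRUE, progress = FALSE)
  missing_cols <- setdiff(unname(columns[required]), names(raw))
  if (length(missing_cols) > 0L) {
    stop("mapped column(s) not found in input: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("no data rows in input: returning an empty record set", call. = FALSE)
    return(empty_record_set(provenance))
  }
  year <- suppressWarnings(as.integer(raw[[columns[["year"]]]]))
  out_of_range <- !is.na(year) & (year < 1700L | year > 2100L)
  if (any(out_of_range)) {
    warning(sprintf("%d year value(s) outside [1700, 2100] treated as undated",
                    sum(out_of_range)), call. = FALSE)
    year[out_of_range] <- NA_integer_
  }
  rs <- tibble::tibble(
    species  = as.character(raw[[columns[["species"]]]]),
    locality = as.character(raw[[columns[["locality"]]]]),
    country  = as.character(raw[[columns[["country"]]]]),
    year     = year,
    dated    = !is.na(year)
  )
  bad <- which(is.na(rs$species) | !nzchar(rs$species) |
                 is.na(rs$locality) | !nzchar(rs$locality))
  if (length(bad) > 0L) {
    stop("species and locality must be non-empty; offending row(s): ",
         paste(head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  new_record_set(rs, provenance)
}

detect_delim <- function(header) {
  candidates <- c(",", ";", "\t")
  hits <- vapply(candidates,
                 function(d) lengths(regmatches(header, gregexpr(d, header, fixed = TRUE))),
                 integer(1))
  if (all(hits == 0L)) return(",")
  candidates[[which.max(hits)]]
}

new_record_set <- function(df, provenance = "unknown") {
  df <- tibble::as_tibble(df)
  if (!"dated" %in% names(df)) df$dated <- !is.na(df$year)
  df$year <- as.integer(df$year)
  class(df) <- unique(c("record_set", class(df)))
  attr(df, "provenance") <- provenance
  df
}

empty_record_set <- function(provenance = "unknown") {
  new_record_set(tibble::tibble(species = character(), locality = character(),
                                country = character(), year = integer(),
                                dated = logical()),
                 provenance)
}

check_records <- function(records) {
  required <- c("species", "locality", "country", "year")
  if (!is.data.frame(records) || !all(required %in% names(records))) {
    stop("`records` must be a data frame with columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  invisible(records)
}

#' Write a record set back to CSV
#'
#' Writes the four record columns (`species`, `locality`, `country`, `year`)
#' so that [read_records()] on the output reproduces the records
#' field-by-field.
#'
#' @param records A record set (or any data frame with the record columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  check_records(records)
  readr::write_csv(records[, c("species", "locality", "country", "year")], path,
                   na = "")
  invisible(path)
}

#' Restrict records to a year window
#'
#' Keeps dated records with `min_year <= year <= max_year` (both bounds
#' inclusive).  Undated records are dropped: the temporal analyses are defined
#' only for records with observation dates.
#'
#' @param records A record set.
#' @param min_year,max_year Inclusive calendar-year bounds.
#' @return The filtered record set.
#' @export
filter_by_years <- function(records, min_year, max_year) {
  check_records(records)
  if (!is.numeric(min_year) || !is.numeric(max_year) || length(min_year) != 1L ||
      length(max_year) != 1L || min_year > max_year) {
    stop("`min_year` must be <= `max_year` (single years)", call. = FALSE)
  }
  keep <- !is.na(records$year) & records$year >= min_year & records$year <= max_year
  out <- records[keep, , drop = FALSE]
  new_record_set(out, attr(records, "provenance") %||% "unknown")
}

#' Count records of one species
#'
#' @param records A record set (year-filter it first if the count should be
#'   restricted to an analysis window).
#' @param species Species name; exact match.  An unknown species yields 0.
#' @return Integer count of matching records.
#' @export
count_species_records <- function(records, species) {
  check_records(records)
  sum(records$species == species, na.rm = TRUE)
}

#' Summary counts for a record set
#'
#' Reports total and dated record counts, the number of distinct localities,
#' and per-species / per-country breakdowns.  A locality shared by two species
#' is counted once in the overall total and once within each species.
#'
#' @param records A record set.
#' @return An object of class `record_summary`: a list with `n_records`,
#'   `n_dated_records`, `n_localities`, and tibbles `per_species`,
#'   `per_country` (columns `n_records`, `n_localities`).
#' @export
summarize_records <- function(records) {
  check_records(records)
  per_group <- function(key) {
    records |>
      dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
      dplyr::summarise(n_records = dplyr::n(),
                       n_localities = dplyr::n_distinct(.data$locality),
                       .groups = "drop") |>
      dplyr::arrange(dplyr::across(dplyr::all_of(key)))
  }
  structure(
    list(
      n_records = nrow(records),
      n_dated_records = sum(!is.na(records$year)),
      n_localities = dplyr::n_distinct(records$locality),
      per_species = per_group("species"),
      per_country = per_group("country"),
      provenance = attr(records, "provenance") %||% "unknown"
    ),
    class = "record_summary"
  )
}

#' @export
print.record_summary <- function(x, ...) {
  cat(sprintf("Occurrence record summary (%s)\n", x$provenance))
  cat(sprintf("  records: %d (%d dated), distinct localities: %d\n",
              x$n_records, x$n_dated_records, x$n_localities))
  cat("  per species:\n")
  print(x$per_species, n = Inf)
  invisible(x)
}

#' Decade occasion grid
#'
#' Defines the contiguous, non-overlapping year bins ("occasions") used for
#' detection histories, e.g. the 12 calendar decades 1900--1909, ...,
#' 2010--2019 for the 1900--2019 window.  Both interval ends are inclusive.
#'
#' @param start_year First year of the first occasion.
#' @param end_year Last year of the last occasion; `end_year - start_year + 1`
#'   must be divisible by `bin_width`.
#' @param bin_width Occasion width in years (default 10, one decade).
#' @return An object of class `occasion_grid` with the occasion table
#'   (`index`, `start`, `end`, `label`) and `n_occasions`.
#' @export
#' @examples
#' occasion_grid(1900, 2019)
occasion_grid <- function(start_year = 1900, end_year = 2019, bin_width = 10) {
  span <- end_year - start_year + 1
  if (span <= 0 || span %% bin_width != 0) {
    stop("(end_year - start_year + 1) must be a positive multiple of `bin_width`",
         call. = FALSE)
  }
  n <- span %/% bin_width
  if (n < 1) stop("grid must contain at least one occasion", call. = FALSE)
  starts <- start_year + bin_width * (seq_len(n) - 1L)
  occasions <- tibble::tibble(
    index = seq_len(n),
    start = as.integer(starts),
    end = as.integer(starts + bin_width - 1L),
    label = sprintf("%d-%d", starts, starts + bin_width - 1L)
  )
  structure(list(start_year = as.integer(start_year),
                 end_year = as.integer(end_year),
                 bin_width = as.integer(bin_width),
                 n_occasions = n,
                 occasions = occasions),
            class = "occasion_grid")
}

#' @export
print.occasion_grid <- function(x, ...) {
  cat(sprintf("Occasion grid: %d occasions of %d years, %d-%d\n",
              x$n_occasions, x$bin_width, x$start_year, x$end_year))
  invisible(x)
}

occasion_index <- function(grid, year) {
  (year - grid$start_year) %/% grid$bin_width + 1L
}

#' Build per-locality detection histories on an occasion grid
#'
#' Converts dated occurrence records into one binary detection history per
#' locality (optionally per locality-within-stratum): the bit for an occasion
#' is 1 if at least one record of that locality falls in that occasion, and
#' multiple records within one occasion collapse to a single 1.  Localities
#' with no in-window record do not appear, so every history contains at least
#' one detection -- the form required by the Cormack-Jolly-Seber likelihood,
#' which conditions on first detection.
#'
#' @param records A record set; all records must be dated and inside the grid
#'   span (apply [filter_by_years()] first).
#' @param grid An [occasion_grid()].
#' @param stratify_by Optional character vector of record columns (e.g.
#'   `"species"` or `c("species", "country")`); one history is built per
#'   locality x stratum combination.
#' @return An object of class `detection_history_set`: list with the binary
#'   matrix `y` (histories x occasions), `locality_ids`, the aligned `strata`
#'   tibble (`NULL` when unstratified), `grid` and `n_histories`.
#' @export
build_detection_histories <- function(records, grid, stratify_by = NULL) {
  check_records(records)
  stopifnot(inherits(grid, "occasion_grid"))
  bad <- which(is.na(records$year) | records$year < grid$start_year |
                 records$year > grid$end_year)
  if (length(bad) > 0L) {
    stop("records undated or outside the grid span (filter first); row(s): ",
         paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) ", ..." else "", call. = FALSE)
  }
  if (!is.null(stratify_by)) {
    missing_cols <- setdiff(stratify_by, names(records))
    if (length(missing_cols) > 0L) {
      stop("stratify_by column(s) not in records: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  }
  T <- grid$n_occasions
  if (nrow(records) == 0L) {
    return(structure(list(y = matrix(0L, 0L, T), locality_ids = character(),
                          strata = NULL, grid = grid, n_histories = 0L),
                     class = "detection_history_set"))
  }
  keycols <- c(stratify_by, "locality")
  keys <- do.call(paste, c(unname(records[keycols]), sep = "\r"))
  occ <- occasion_index(grid, records$year)
  units <- sort(unique(keys))
  y <- matrix(0L, nrow = length(units), ncol = T)
  y[cbind(match(keys, units), occ)] <- 1L
  parts <- records[match(units, keys), keycols, drop = FALSE]
  rownames(y) <- units
  structure(list(
    y = y,
    locality_ids = parts$locality,
    strata = if (is.null(stratify_by)) NULL else
      tibble::as_tibble(parts[, stratify_by, drop = FALSE]),
    grid = grid,
    n_histories = nrow(y)
  ), class = "detection_history_set")
}

#' @export
print.detection_history_set <- function(x, ...) {
  cat(sprintf("Detection histories: %d localities x %d occasions (%d-%d)\n",
              x$n_histories, x$grid$n_occasions, x$grid$start_year,
              x$grid$end_year))
  if (x$n_histories > 0L) {
    cat(sprintf("  detections: %d; occupied occasions per history: median %g\n",
                sum(x$y), stats::median(rowSums(x$y))))
  }
  invisible(x)
}

# accept either a detection_history_set or a plain 0/1 matrix
history_matrix <- function(histories) {
  y <- if (inherits(histories, "detection_history_set")) histories$y
       else as.matrix(histories)
  if (!all(y %in% c(0L, 1L))) stop("histories must be binary", call. = FALSE)
  storage.mode(y) <- "integer"
  if (ncol(y) < 2L) stop("histories need at least 2 occasions", call. = FALSE)
  y
}
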