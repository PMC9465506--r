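write_fixture <- function(lines, sep = ",") {
  f <- tempfile(fileext = ".csv")
  writeLines(vapply(lines, paste, character(1), collapse = sep), f)
  f
}

test_that("read_records parses delimited files and flags undated rows", {
  f <- write_fixture(list(
    c("species", "locality", "country", "year"),
    c("Jordanita notata", "L001", "AT", "1954"),
    c("Jordanita notata", "L002", "AT", "1987"),
    c("Jordanita chloros", "L003", "DE", "2001")))
  rs <- read_records(f)
  expect_s3_class(rs, "record_set")
  expect_equal(nrow(rs), 3L)
  expect_equal(sum(!rs$dated), 0L)

  f5 <- write_fixture(list(
    c("species", "locality", "country", "year"),
    c("A", "L1", "AT", "1910"),
    c("A", "L1", "AT", ""),
    c("A", "L2", "DE", "1950"),
    c("B", "L3", "DE", "1970"),
    c("B", "L4", "FR", "1990")))
  rs5 <- read_records(f5)
  expect_equal(nrow(rs5), 5L)
  expect_equal(sum(!rs5$dated), 1L)
  expect_true(is.na(rs5$year[2]))
})

test_that("read_records auto-detects semicolon and tab delimiters", {
  for (sep in c(";", "\t")) {
    f <- write_fixture(list(c("species", "locality", "country", "year"),
                            c("A", "L1", "AT", "1910"),
                            c("B", "L2", "DE", "1950")), sep = sep)
    rs <- read_records(f)
    expect_equal(rs$locality, c("L1", "L2"))
    expect_equal(rs$year, c(1910L, 1950L))
  }
})

test_that("read_records errors on missing mapped columns, warns on empty file", {
  f <- write_fixture(list(c("sp", "loc", "country", "year"), c("A", "L1", "AT", "1910")))
  expect_error(read_records(f), "species")
  rs <- read_records(f, columns = c(species = "sp", locality = "loc",
                                    country = "country", year = "year"))
  expect_equal(rs$species, "A")

  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_warning(rs0 <- read_records(empty), "empty")
  expect_equal(nrow(rs0), 0L)
})

test_that("years outside the plausible range are treated as undated", {
  f <- write_fixture(list(c("species", "locality", "country", "year"),
                          c("A", "L1", "AT", "1650"),
                          c("A", "L2", "AT", "1950")))
  expect_warning(rs <- read_records(f), "1700")
  expect_true(is.na(rs$year[1]))
  expect_equal(nrow(rs), 2L)
})

test_that("record sets round-trip through write_records/read_records", {
  rs <- make_records(c("A", "A", "B"), c("L1", "L2", "L3"),
                     c("AT", "DE", "FR"), c(1910, 1950, 1990))
  f <- tempfile(fileext = ".csv")
  write_records(rs, f)
  back <- read_records(f)
  expect_equal(tibble::as_tibble(back)[names(rs)], rs, ignore_attr = TRUE)
})

test_that("filter_by_years keeps inclusive bounds, drops undated, is idempotent", {
  years <- c(1880, 1895, 1900, 1925, 1950, 1975, 2000, 2010, 2019, NA)
  rs <- make_records("A", sprintf("L%02d", 1:10), year = years)
  out <- filter_by_years(rs, 1900, 2019)
  expect_equal(nrow(out), 7L)  # hand count: 1900..2019 inclusive, NA dropped
  expect_true(all(out$year >= 1900 & out$year <= 2019))
  expect_equal(filter_by_years(out, 1900, 2019), out)
  expect_error(filter_by_years(rs, 2000, 1900), "min_year")
  expect_equal(nrow(filter_by_years(rs[0, ], 1900, 2019)), 0L)
})

test_that("filter_by_years commutes with stratified subsetting", {
  set.seed(11)
  rs <- make_records(sample(c("A", "B"), 40, TRUE), sample(sprintf("L%d", 1:12), 40, TRUE),
                     year = sample(1880:2019, 40, TRUE))
  a <- filter_by_years(rs[rs$species == "A", ], 1900, 2019)
  b <- filter_by_years(rs, 1900, 2019)
  b <- b[b$species == "A", ]
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))
})

test_that("count_species_records counts exact matches only", {
  rs <- make_records(rep(c("A", "B"), c(4, 5)), sprintf("L%d", 1:9), year = 1950)
  expect_equal(count_species_records(rs, "A"), 4L)
  expect_equal(count_species_records(rs, "absent species"), 0L)
})

test_that("summarize_records uses distinct-count semantics", {
  rs <- make_records(c("A", "A", "B", "B"), c("L1", "L2", "L1", "L3"),
                     c("AT", "AT", "DE", "DE"), c(1950, 1960, 1970, NA))
  s <- summarize_records(rs)
  expect_equal(s$n_records, 4L)
  expect_equal(s$n_dated_records, 3L)
  expect_equal(s$n_localities, 3L)  # L1 shared by A and B counts once overall
  expect_equal(s$per_species$n_localities, c(2L, 2L))  # once per species
  expect_true(all(s$per_species$n_localities <= s$n_localities))

  one <- summarize_records(make_records("A", "L1", year = 1950))
  expect_equal(unlist(one[c("n_records", "n_dated_records", "n_localities")]),
               c(n_records = 1L, n_dated_records = 1L, n_localities = 1L))
})

test_that("occasion grid enforces divisibility and inclusive decade bins", {
  g <- occasion_grid(1900, 2019, 10)
  expect_equal(g$n_occasions, 12L)
  expect_equal(g$occasions$start[1], 1900L)
  expect_equal(g$occasions$end[12], 2019L)
  expect_equal(diff(g$occasions$start), rep(10L, 11))
  expect_error(occasion_grid(1900, 2018, 10), "multiple")
})

test_that("detection histories bin records into decade occasions", {
  g <- occasion_grid(1900, 2019)
  rs <- make_records("A", c("L1", "L1"), year = c(1905, 1963))
  dh <- build_detection_histories(rs, g)
  expect_equal(as.vector(dh$y), as.integer(seq_len(12) %in% c(1, 7)))

  # several records in one decade collapse to one detection
  rs2 <- make_records("A", rep("L1", 3), year = c(1954, 1956, 1958))
  dh2 <- build_detection_histories(rs2, g)
  expect_equal(sum(dh2$y), 1L)
  expect_equal(which(dh2$y[1, ] == 1), 6L)

  empty <- build_detection_histories(make_records(character(), character(),
                                                  character(), integer()), g)
  expect_equal(empty$n_histories, 0L)
  expect_error(build_detection_histories(make_records("A", "L1", year = 1850), g),
               "outside")
})

test_that("detection histories are invariant to record order and stratify correctly", {
  set.seed(21)
  rs <- make_records(sample(c("A", "B"), 60, TRUE), sample(sprintf("L%d", 1:15), 60, TRUE),
                     year = sample(1900:2019, 60, TRUE))
  g <- occasion_grid(1900, 2019)
  dh1 <- build_detection_histories(rs, g)
  dh2 <- build_detection_histories(rs[sample(nrow(rs)), ], g)
  expect_equal(dh1$y, dh2$y)
  expect_equal(dh1$locality_ids, dh2$locality_ids)

  dhs <- build_detection_histories(rs, g, stratify_by = "species")
  expect_equal(ncol(dhs$y), 12L)
  expect_true(all(rowSums(dhs$y) >= 1))
  # locality recorded for both species appears once per stratum
  expect_equal(dhs$n_histories,
               nrow(unique(rs[, c("species", "locality")])))
})

test_that("total detections never exceed the number of dated in-window records", {
  g <- occasion_grid(1900, 2019)
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:80, 1)
    rs <- make_records("A", sample(sprintf("L%d", 1:20), n, TRUE),
                       year = sample(1900:2019, n, TRUE))
    dh <- build_detection_histories(rs, g)
    expect_lte(sum(dh$y), nrow(rs))
  }
})
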