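test_that("long CSV reading parses valid rows and rejects bad ones", {
  path <- write_long_fixture(c(
    "S1,2010-03-15,TP,120.5",
    "S1,2010-03-15,TN,3.2",
    "S2,2010-03-15,BOD,4.1"))
  rec <- read_long_csv(path)
  expect_s3_class(rec, "wq_records")
  expect_equal(nrow(rec), 3L)
  expect_equal(attr(rec, "n_rejected"), 0L)
  expect_s3_class(rec$date, "Date")

  path2 <- write_long_fixture(c(
    "S1,2010-03-15,TP,120.5",
    "S1,2010-03-15,XYZ,1.0",
    "S2,2010-03-15,BOD,4.1"))
  rec2 <- read_long_csv(path2)
  expect_equal(nrow(rec2), 2L)
  expect_equal(attr(rec2, "n_rejected"), 1L)
  expect_equal(attr(rec2, "rejected")$reason, "unknown parameter")
  expect_equal(attr(rec2, "rejected")$row, 2L)

  empty <- write_long_fixture(character(0))
  expect_warning(rec3 <- read_long_csv(empty), "empty")
  expect_equal(nrow(rec3), 0L)

  bad_date <- write_long_fixture("S1,not-a-date,TP,5")
  expect_error(read_long_csv(bad_date), "row")
})

test_that("negative values and out-of-range pH are rejected with row numbers", {
  path <- write_long_fixture(c(
    "S1,2010-01-15,TP,-4",
    "S1,2010-01-15,pH,15",
    "S1,2010-01-15,pH,7.4"))
  rec <- read_long_csv(path)
  expect_equal(nrow(rec), 1L)
  expect_setequal(attr(rec, "rejected")$reason,
                  c("negative value", "pH outside [0,14]"))
})

test_that("pivoting averages duplicates, masks gaps, and round-trips", {
  path <- write_long_fixture(c(
    "S1,2010-03-15,TP,4",
    "S1,2010-03-15,TP,6",
    "S1,2010-03-15,TN,2"))
  m <- pivot_to_matrix(read_long_csv(path))
  expect_equal(unname(m$values[1, "TP"]), 5)       # mean of the pair
  expect_equal(m$n_duplicates, 1L)
  expect_equal(nrow(m$values), 1L)
  expect_equal(sum(is.na(m$values)), 9L)           # 11 params, 2 observed

  # dense 2 sites x 2 dates x all parameters: direct-construction oracle
  params <- wq_parameters()
  set.seed(42)
  grid <- expand.grid(site_id = c("A", "B"),
                      date = as.Date(c("2010-01-15", "2010-07-15")),
                      parameter = params, stringsAsFactors = FALSE)
  grid$value <- round(runif(nrow(grid), 1, 9), 3)
  grid$date <- as.Date(grid$date)
  rec <- structure(grid[, c("site_id", "date", "parameter", "value")],
                   class = c("wq_records", "data.frame"))
  m2 <- pivot_to_matrix(rec)
  expect_equal(dim(m2$values), c(4L, 11L))
  expect_false(anyNA(m2$values))
  i <- which(m2$meta$site_id == "B" & m2$meta$date == as.Date("2010-07-15"))
  expect_equal(unname(m2$values[i, "COD"]),
               grid$value[grid$site_id == "B" &
                          grid$date == as.Date("2010-07-15") &
                          grid$parameter == "COD"])
  expect_equal(m2$meta$season[i], "monsoon")

  # round-trip back to deduplicated records
  back <- matrix_to_records(m2)
  expect_equal(nrow(back), nrow(grid))
  expect_equal(sort(back$value), sort(grid$value))
})

test_that("season assignment partitions the year 6/2/4", {
  expect_equal(season_of(7L), "monsoon")
  expect_equal(season_of(1L), "premonsoon")
  expect_equal(season_of(9L), "postmonsoon")
  all_seasons <- season_of(1:12)
  expect_equal(as.vector(table(all_seasons)[c("premonsoon", "monsoon",
                                              "postmonsoon")]),
               c(6L, 2L, 4L))
  expect_error(season_of(0L))
  expect_error(season_of(13L))
})

test_that("period assignment uses the weir-construction boundaries", {
  expect_equal(period_of(as.Date("2008-05-01")), "pre-weir")
  expect_equal(period_of(as.Date("2012-06-01")), "transition")
  expect_equal(period_of(as.Date("2015-03-01")), "post-weir")
  expect_error(period_boundaries(pre_end = "2014-01-01",
                                 post_start = "2013-01-01"))
})

test_that("coliform classification follows the pollution bands", {
  expect_equal(classify_tcb(75274.6), "critical pollution")
  expect_equal(classify_tcb(400), "little pollution")
  expect_equal(classify_tcb(2e6), "excessive pollution")
  expect_equal(classify_tcb(500), "little pollution")     # inclusive edge
  expect_equal(classify_tcb(500.1), "moderate pollution")
  expect_error(classify_tcb(-1))
  # monotone step function
  x <- sort(runif(50, 0, 2e6))
  bands <- match(classify_tcb(x), threshold_rules()$tcb_labels)
  expect_true(all(diff(bands) >= 0))
})

test_that("trophic flags and TN/TP limitation follow the thresholds", {
  r <- classify_trophic(tp = 430.40, tn = 7.95, chl = 49.26)
  expect_true(all(r$tp_eutrophic, r$tn_eutrophic, r$chl_eutrophic))
  r2 <- classify_trophic(tp = 50, tn = 1.0, chl = 10)
  expect_false(any(r2$tp_eutrophic, r2$tn_eutrophic, r2$chl_eutrophic))
  # mass-basis ratio: TN 2 mg/L vs TP 100 ug/L -> 2000/100 = 20 (edge),
  # TN 4 -> ratio 40 -> P-limited
  r3 <- classify_trophic(tp = 100, tn = 4, chl = 10)
  expect_equal(r3$tn_tp_ratio, 40)
  expect_equal(r3$limitation, "P-limited")
  r4 <- classify_trophic(tp = 100, tn = 2, chl = 10)
  expect_equal(r4$limitation, "indeterminate/co-limited")
  r5 <- classify_trophic(tp = 0, tn = 2, chl = 10)
  expect_equal(r5$limitation, "undefined")
})

test_that("wide CSV round-trips a matrix including missing cells", {
  fx <- fixtures()
  m <- fx$tiny$matrix
  m$values[3, "TP"] <- NA
  path <- tempfile(fileext = ".csv")
  write_wide_csv(m, path)
  m2 <- read_wide_csv(path)
  expect_equal(m2$values, m$values, tolerance = 1e-12)
  expect_equal(m2$meta$season, m$meta$season)
  expect_equal(m2$meta$period, m$meta$period)
})
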