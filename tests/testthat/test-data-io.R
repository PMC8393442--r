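test_that("stratified counts round-trip through delimited text", {
  cts <- toy_counts(c(rep(0.01, 10), 0.4, 0.6, 0.7))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stratified_counts(cts, path)
  back <- read_stratified_counts(path)
  expect_s3_class(back, "stratified_counts")
  expect_equal(back$deaths, cts$deaths)
  expect_equal(back$population, cts$population)
  expect_identical(back$period, cts$period)
})

test_that("cells absent from the file stay masked, never zeroed", {
  cts <- toy_counts(rep(0.02, 13))
  # Swedish-style gap: death counts unavailable at ages 85 and 90
  cts$deaths[, c("85", "90")] <- NA_real_
  path <- withr::local_tempfile(fileext = ".csv")
  write_stratified_counts(cts, path)
  # the writer drops only fully-empty cells; deaths-only gaps survive as NA
  back <- read_stratified_counts(path, dialect = "csv")
  expect_true(all(is.na(back$deaths[, c("85", "90")])))
  expect_false(anyNA(back$population))
})

test_that("malformed and invalid counts are rejected with location info", {
  cts <- toy_counts()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stratified_counts(cts, path)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  df$deaths[3] <- -1
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_stratified_counts(path), "negative deaths")
  df$deaths[3] <- 1
  dup <- rbind(df, df[5, ])
  utils::write.table(dup, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_stratified_counts(path), "duplicate cell")
  utils::write.table(df[-1], path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_stratified_counts(path), "missing column")
})

test_that("delimited reference rates read back on the full age range", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ages <- 30:110
  utils::write.table(data.frame(age = ages, rate = 5e-4 * exp(0.09 * (ages - 30))),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  ref <- read_reference_rates(path, "delimited")
  expect_length(ref$rates, 81)
  expect_identical(ref$ages, 30:110)
})

test_that("HMD-style layout parses, assigns 110+ to omega, honours sex", {
  path <- withr::local_tempfile(fileext = ".txt")
  ages <- 30:110
  age_lab <- c(as.character(30:109), "110+")
  lines <- c("Synthia, Death rates (period 1x1)", "",
             sprintf("%6s %6s %10s %10s %10s", "Year", "Age",
                     "Female", "Male", "Total"),
             sprintf("%6d %6s %10.6f %10.6f %10.6f", 1993, age_lab,
                     5e-4 * exp(0.09 * (ages - 30)),
                     8e-4 * exp(0.09 * (ages - 30)),
                     6e-4 * exp(0.09 * (ages - 30))))
  writeLines(lines, path)
  ref_f <- read_reference_rates(path, "hmd_fixed", sex = "female")
  ref_m <- read_reference_rates(path, "hmd_fixed", sex = "male")
  expect_equal(ref_f$ages[length(ref_f$ages)], 110)
  expect_equal(ref_f$rates[81], 5e-4 * exp(0.09 * 80), tolerance = 1e-6)
  expect_gt(ref_m$rates[1], ref_f$rates[1])
})

test_that("reference rates ending short of omega report the gap ages", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ages <- 30:100
  utils::write.table(data.frame(age = ages, rate = rep(0.01, length(ages))),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_reference_rates(path, "delimited"), "101.*110")
  bad <- data.frame(age = 30:110, rate = c(rep(0.01, 80), 0))
  utils::write.table(bad, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_reference_rates(path, "delimited"), "non-positive")
})

test_that("life tables round-trip through the tab-separated writer", {
  ages <- c(seq(30, 105, 5), 110)
  lt <- build_lifetable(6e-4 * exp(0.095 * (ages - 30)), ages = ages,
                        country = "X", period = "p", sex = "female",
                        education = "high")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lifetables(lt, path)
  lines <- readLines(path)
  expect_length(lines, length(ages) + 1L)  # header + one row per age
  back <- read_lifetables(path)[[1]]
  for (col in c("mx", "qx", "ax", "lx", "dx", "Lx", "Tx", "ex")) {
    # values are printed with 6 decimal places
    expect_true(all(abs(back[[col]] - lt[[col]]) <= 5.0001e-7))
  }
  expect_identical(attr(back, "education"), "high")
  # degenerate input: an empty collection writes a header-only file
  write_lifetables(list(), path)
  expect_length(readLines(path), 1L)
  expect_identical(read_lifetables(path), list())
})

test_that("packaged published life expectancies satisfy their orderings", {
  t1 <- table1_life_expectancy()
  expect_equal(nrow(t1), 2 * 2 * 4 * 2 * 2)  # country x period x edu x sex x age
  wide <- reshape(t1, idvar = c("country", "period", "sex", "age"),
                  timevar = "education", direction = "wide")
  expect_true(all(wide$ex.low <= wide$ex.middle))
  expect_true(all(wide$ex.middle <= wide$ex.high))
  by30 <- t1[t1$age == 30, ]
  by65 <- t1[t1$age == 65, ]
  m <- merge(by30, by65, by = c("country", "period", "education", "sex"))
  expect_true(all(m$ex.x > m$ex.y & m$ex.x - m$ex.y < 35))
})
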