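test_that("read_use_table normalizes lb/acre sources and validates rows", {
  f <- write_csv_fixture(data.frame(
    Crop = "maize", Year = 1990:1992, Chem = "atrazine",
    Pounds = c(100, 200, 300), Rate = c(1, 2, 3)))
  cm <- c(crop = "Crop", year = "Year", ingredient = "Chem",
          amount = "Pounds", rate = "Rate")

  rec <- read_use_table(f, column_map = cm, units = c(mass = "lb", area = "acre"))
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$amount_applied, c(100, 200, 300) * 0.45359237)
  expect_equal(rec$avg_rate, c(1, 2, 3) * 0.45359237 / 0.40468564224)

  # already-metric read is idempotent: re-normalizing changes nothing
  g <- write_csv_fixture(data.frame(
    Crop = rec$crop, Year = rec$year, Chem = rec$ingredient_label,
    Pounds = rec$amount_applied, Rate = rec$avg_rate))
  again <- read_use_table(g, column_map = cm, units = c(mass = "kg", area = "ha"))
  expect_equal(again$amount_applied, rec$amount_applied)
  expect_equal(again$avg_rate, rec$avg_rate)

  cm_bad <- cm
  cm_bad[["amount"]] <- "NotThere"
  expect_error(read_use_table(f, column_map = cm_bad,
                              units = c(mass = "lb", area = "acre")),
               class = "herbtrends_config_error")
})

test_that("header-only use file yields an empty collection without error", {
  f <- tempfile(fileext = ".csv")
  writeLines("crop,year,ingredient,amount,rate", f)
  rec <- read_use_table(f)
  expect_s3_class(rec, "data.frame")
  expect_equal(nrow(rec), 0L)
})

test_that("write/read round trip preserves records", {
  rec <- make_use("maize", 1990:1994, "atrazine",
                  c(10.25, 0, 3.125, 40.468564224, 7),
                  c(1.5, 2, 0.125, 1, 0.0625))
  f <- write_output_table(rec, tempfile(fileext = ".csv"))
  back <- read_use_table(f, column_map = c(crop = "crop", year = "year",
                                           ingredient = "ingredient_label",
                                           amount = "amount_applied",
                                           rate = "avg_rate"))
  expect_identical(back, rec)
})

test_that("rows with missing amounts are dropped and counted; bad cells error with line numbers", {
  f <- write_csv_fixture(data.frame(
    crop = "maize", year = 1990, ingredient = c("a", "b", "c"),
    amount = c("1", "", "3"), rate = "1"))
  expect_message(rec <- read_use_table(f), "dropped 1 row")
  expect_equal(nrow(rec), 2L)  # rows read = input rows - logged drops

  g <- write_csv_fixture(data.frame(
    crop = "maize", year = 1990, ingredient = c("a", "b"),
    amount = c("1", "oops"), rate = "1"))
  expect_error(read_use_table(g), "line\\(s\\) 3", class = "herbtrends_data_error")
})

test_that("use-table invariants are enforced", {
  base <- data.frame(crop = "maize", year = 1990, ingredient = "a",
                     amount = 1, rate = 1)
  ok <- function(df) read_use_table(write_csv_fixture(df))
  expect_error(ok(transform(base, year = 1980)), class = "herbtrends_data_error")
  expect_error(ok(transform(base, amount = -1)), class = "herbtrends_data_error")
  expect_error(ok(transform(base, rate = 0)), class = "herbtrends_data_error")
  expect_error(read_use_table(write_csv_fixture(base), crops = c("rice")),
               class = "herbtrends_data_error")
  expect_silent(quiet(ok(base)))
})

test_that("read_toxicity_table parses censored LD50s and enforces uniqueness", {
  f <- write_csv_fixture(data.frame(
    ai = c("glyphosate", "paraquat"),
    acute_ld50 = c(">5,000", "112"),
    chronic_noel = c(100, 0.45), wssa_group = c("9", "22")))
  tox <- read_toxicity_table(f)
  expect_equal(tox$acute_ld50, c(5000, 112))
  expect_equal(tox$acute_censored, c(TRUE, FALSE))

  dup <- write_csv_fixture(data.frame(
    ai = c("a", "A"), acute_ld50 = 1, chronic_noel = 1, wssa_group = "1"))
  expect_error(read_toxicity_table(dup), "duplicate",
               class = "herbtrends_data_error")
  zero <- write_csv_fixture(data.frame(
    ai = "a", acute_ld50 = 10, chronic_noel = 0, wssa_group = "1"))
  expect_error(read_toxicity_table(zero), class = "herbtrends_data_error")
})

test_that("read_area_table converts acres and rejects duplicates", {
  f <- write_csv_fixture(data.frame(crop = "maize", year = 1990, area = 100))
  got <- read_area_table(f, units = c(area = "acre"))
  expect_equal(got$planted_area, 40.468564224)

  dup <- write_csv_fixture(data.frame(crop = "maize", year = c(1990, 1990),
                                      area = c(1, 2)))
  expect_error(read_area_table(dup), "duplicate", class = "herbtrends_data_error")

  empty <- tempfile(fileext = ".csv")
  writeLines("crop,year,area", empty)
  expect_equal(nrow(read_area_table(empty)), 0L)
})
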