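# Reading, validating and unit-normalizing the three input tables:
# pesticide-use survey records, the toxicity reference table, and crop
# planted-area tables. All readers return plain data.frames with fixed,
# metric column conventions so downstream modules never see source units.

#' Crops covered by the analysis
#' @return character vector of the six crop names.
#' @export
default_crops <- function() {
  c("maize", "soybean", "cotton", "rice", "spring wheat", "winter wheat")
}

check_columns <- function(df, wanted, path) {
  missing <- setdiff(wanted, names(df))
  if (length(missing)) {
    stop_config("file '%s' is missing mapped column(s): %s (found: %s)",
                path, paste(missing, collapse = ", "),
                paste(names(df), collapse = ", "))
  }
}

# Parse a numeric column, raising a row-level error (CSV line numbers, where
# the header is line 1) for cells that are present but unparsable. Blank
# cells pass through as NA.
parse_numeric_column <- function(raw, colname, path) {
  parsed <- parse_numeric(raw)
  blank <- is.na(raw) | !nzchar(trimws(as.character(raw)))
  bad <- is.na(parsed) & !blank
  if (any(bad)) {
    stop_data("file '%s': unparsable numeric value(s) in column '%s' at line(s) %s",
              path, colname, paste(which(bad) + 1L, collapse = ", "))
  }
  parsed
}

read_delim_file <- function(path) {
  if (!file.exists(path)) stop_config("input file does not exist: '%s'", path)
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
           colClasses = "character")
}

#' Read a pesticide-use survey table
#'
#' Reads a delimited table of (crop, year, ingredient label, total amount
#' applied, average application rate) observations and normalizes amounts to
#' kg and rates to kg/ha. Column names in the source file are supplied
#' through `column_map`, since survey extracts do not share a fixed header
#' layout. Rows with a missing amount are dropped with a logged count; rows
#' with a missing rate are kept (the rate may be recoverable from other
#' years, see [at_table()]).
#'
#' @param path CSV file (comma-separated, UTF-8, header row required).
#' @param column_map named character vector mapping the fields
#'   `crop`, `year`, `ingredient`, `amount`, `rate` to source column names.
#' @param units named character vector declaring source units:
#'   `mass` is `"kg"` or `"lb"`, `area` (the denominator of the rate) is
#'   `"ha"` or `"acre"`.
#' @param crops allowed crop names (`NULL` to accept any).
#' @param year_range two-element integer vector of allowed years.
#' @return data.frame with columns `crop`, `year`, `ingredient_label`,
#'   `amount_applied` (kg), `avg_rate` (kg/ha, possibly `NA`).
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(crop = "maize", year = 1990, ingredient = "atrazine",
#'                      amount = 100, rate = 1), f, row.names = FALSE)
#' read_use_table(f, units = c(mass = "lb", area = "acre"))
read_use_table <- function(path,
                           column_map = c(crop = "crop", year = "year",
                                          ingredient = "ingredient",
                                          amount = "amount", rate = "rate"),
                           units = c(mass = "kg", area = "ha"),
                           crops = NULL,
                           year_range = c(1990L, 2015L)) {
  needed <- c("crop", "year", "ingredient", "amount", "rate")
  if (!all(needed %in% names(column_map))) {
    stop_config("column_map must name source columns for: %s",
                paste(setdiff(needed, names(column_map)), collapse = ", "))
  }
  mf <- mass_factor_for(units[["mass"]])
  af <- area_factor_for(units[["area"]])

  raw <- read_delim_file(path)
  check_columns(raw, unname(column_map[needed]), path)
  if (nrow(raw) == 0L) {
    return(data.frame(crop = character(), year = integer(),
                      ingredient_label = character(),
                      amount_applied = numeric(), avg_rate = numeric()))
  }

  out <- data.frame(
    crop = trimws(raw[[column_map[["crop"]]]]),
    year = parse_numeric_column(raw[[column_map[["year"]]]], column_map[["year"]], path),
    ingredient_label = trimws(raw[[column_map[["ingredient"]]]]),
    amount_applied = parse_numeric_column(raw[[column_map[["amount"]]]],
                                          column_map[["amount"]], path),
    avg_rate = parse_numeric_column(raw[[column_map[["rate"]]]],
                                    column_map[["rate"]], path),
    stringsAsFactors = FALSE
  )

  dropped <- is.na(out$amount_applied)
  if (any(dropped)) {
    ht_log(sprintf("read_use_table: dropped %d row(s) with missing amount from '%s'",
                   sum(dropped), path))
    out <- out[!dropped, , drop = FALSE]
  }

  if (anyNA(out$year) || any(out$year != as.integer(out$year))) {
    stop_data("file '%s': non-integer or missing year values", path)
  }
  out$year <- as.integer(out$year)
  bad_year <- out$year < year_range[1] | out$year > year_range[2]
  if (any(bad_year)) {
    stop_data("file '%s': %d row(s) with year outside [%d, %d]",
              path, sum(bad_year), year_range[1], year_range[2])
  }
  if (!is.null(crops)) {
    unknown <- setdiff(unique(out$crop), crops)
    if (length(unknown)) {
      stop_data("file '%s': crop(s) not in configured crop list: %s",
                path, paste(unknown, collapse = ", "))
    }
  }
  if (any(out$amount_applied < 0)) {
    stop_data("file '%s': negative amount_applied", path)
  }
  if (any(!is.na(out$avg_rate) & out$avg_rate <= 0)) {
    stop_data("file '%s': non-positive avg_rate", path)
  }

  out$amount_applied <- out$amount_applied * mf
  out$avg_rate <- out$avg_rate * (mf / af)
  rownames(out) <- NULL
  out
}

#' Read the active-ingredient toxicity reference table
#'
#' Expects columns `ai`, `acute_ld50`, `chronic_noel`, `wssa_group`.
#' `acute_ld50` may be a plain number (mg/kg) or a censoring bound written
#' `">5,000"`; bounds are substituted conservatively via [censor_ld50()] and
#' flagged. `chronic_noel` is the 24-month rat NOEL in mg/kg/d. Each active
#' ingredient must appear exactly once.
#'
#' @param path CSV file.
#' @return data.frame with columns `ai`, `acute_ld50`, `acute_censored`,
#'   `chronic_noel`, `wssa_group`.
#' @export
read_toxicity_table <- function(path) {
  raw <- read_delim_file(path)
  check_columns(raw, c("ai", "acute_ld50", "chronic_noel", "wssa_group"), path)
  if (nrow(raw) == 0L) {
    return(data.frame(ai = character(), acute_ld50 = numeric(),
                      acute_censored = logical(), chronic_noel = numeric(),
                      wssa_group = character()))
  }
  ai <- trimws(raw$ai)
  dup <- duplicated(tolower(ai))
  if (any(dup)) {
    stop_data("file '%s': duplicate active ingredient(s): %s",
              path, paste(unique(ai[dup]), collapse = ", "))
  }
  acute <- censor_ld50(raw$acute_ld50)
  chronic <- parse_numeric_column(raw$chronic_noel, "chronic_noel", path)
  if (anyNA(chronic) || any(chronic <= 0)) {
    stop_data("file '%s': chronic_noel must be present and > 0 for every ai", path)
  }
  data.frame(ai = ai,
             acute_ld50 = acute$value,
             acute_censored = acute$censored,
             chronic_noel = chronic,
             wssa_group = trimws(raw$wssa_group),
             stringsAsFactors = FALSE)
}

#' Read a crop planted-area table
#'
#' Planted (not harvested) area per crop-year, normalized to hectares.
#' Exactly one record per (crop, year) is required.
#'
#' @param path CSV file.
#' @param column_map named character vector mapping `crop`, `year`, `area`
#'   to source column names.
#' @param units named character vector; `area` is `"ha"` or `"acre"`.
#' @return data.frame with columns `crop`, `year`, `planted_area` (ha).
#' @export
read_area_table <- function(path,
                            column_map = c(crop = "crop", year = "year",
                                           area = "area"),
                            units = c(area = "ha")) {
  needed <- c("crop", "year", "area")
  if (!all(needed %in% names(column_map))) {
    stop_config("column_map must name source columns for: %s",
                paste(setdiff(needed, names(column_map)), collapse = ", "))
  }
  af <- area_factor_for(units[["area"]])
  raw <- read_delim_file(path)
  check_columns(raw, unname(column_map[needed]), path)
  if (nrow(raw) == 0L) {
    return(data.frame(crop = character(), year = integer(),
                      planted_area = numeric()))
  }
  out <- data.frame(
    crop = trimws(raw[[column_map[["crop"]]]]),
    year = parse_numeric_column(raw[[column_map[["year"]]]], column_map[["year"]], path),
    planted_area = parse_numeric_column(raw[[column_map[["area"]]]],
                                        column_map[["area"]], path),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$year)) stop_data("file '%s': missing year values", path)
  out$year <- as.integer(out$year)
  key <- paste(out$crop, out$year, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)]
    stop_data("file '%s': duplicate (crop, year) record(s): %s",
              path, paste(unique(gsub("\r", " ", d)), collapse = "; "))
  }
  if (anyNA(out$planted_area) || any(out$planted_area <= 0)) {
    stop_data("file '%s': planted_area must be present and > 0", path)
  }
  out$planted_area <- out$planted_area * af
  rownames(out) <- NULL
  out
}

#' Write a pipeline output table
#'
#' Plain CSV with a header row and no row names; numeric columns keep full
#' double precision so a write/read round trip preserves values exactly for
#' finite-decimal inputs.
#'
#' @param df data.frame to write.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_output_table <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
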