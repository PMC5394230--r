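# Unit conversion constants. All downstream math is metric: mass in kg,
# area in ha, per-hectare amounts in mg/ha. Conversions happen once, at
# read time.
LB_TO_KG <- 0.45359237
ACRE_TO_HA <- 0.40468564224
MG_PER_KG <- 1e6

# Default bound used when an acute LD50 is reported only as ">5,000":
# EPA Category IV starts at 5,000 mg/kg, so registrants do not test above it.
LD50_CENSOR_BOUND <- 5000

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

#' Set the logging verbosity
#'
#' Structured log lines go to standard error via [message()]. Levels:
#' `"debug"`, `"info"` (default), `"warn"`, `"quiet"`.
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"quiet"`.
#' @return the previous level, invisibly.
#' @export
ht_log_level <- function(level = c("info", "debug", "warn", "quiet")) {
  level <- match.arg(level)
  old <- getOption("herbtrends.log_level", "info")
  options(herbtrends.log_level = level)
  invisible(old)
}

ht_log <- function(msg, level = "info") {
  threshold <- getOption("herbtrends.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[threshold]]) {
    message(sprintf("[herbtrends:%s] %s", level, msg))
  }
  invisible(NULL)
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("herbtrends_config_error", "herbtrends_error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("herbtrends_data_error", "herbtrends_error")))
}

# Parse numbers that may carry thousands separators or surrounding space
# ("5,000" -> 5000). Returns NA for unparsable input; callers decide whether
# NA is a dropped row or an error (with a line number).
parse_numeric <- function(x) {
  x <- gsub(",", "", trimws(as.character(x)), fixed = TRUE)
  x[!nzchar(x)] <- NA_character_
  suppressWarnings(as.numeric(x))
}

mass_factor_for <- function(unit) {
  switch(unit,
         kg = 1,
         lb = LB_TO_KG,
         stop_config("unknown mass unit '%s' (expected 'kg' or 'lb')", unit))
}

area_factor_for <- function(unit) {
  switch(unit,
         ha = 1,
         acre = ACRE_TO_HA,
         stop_config("unknown area unit '%s' (expected 'ha' or 'acre')", unit))
}

# Run code under a temporary RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed for a named pseudo-random stream, kept in
# [1, 2^31 - 2] so set.seed() always accepts it. Streams are independent of
# each other's draw counts, so adding one table/crop does not perturb others.
derive_seed <- function(master, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  ((as.double(master) * 48271 + h * 8191) %% 2147483646) + 1
}
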