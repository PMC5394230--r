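# Relative toxicity as hazard quotients (HQ): for one crop-year,
#   HQ = sum over active ingredients of Amount_ai / Toxicity_ai,
# with Amount in mg applied per planted hectare and Toxicity either the
# chronic 24-month rat NOEL (mg/kg/d) or the acute oral rat LD50 (mg/kg).
# HQ reads as the number of NOEL or LD50 doses applied per hectare; larger
# means a more toxic herbicide program.

#' Parse a possibly censored LD50 entry
#'
#' Acute oral LD50 values above 5,000 mg/kg fall in EPA Category IV, the
#' least toxic class, so registrants report them only as a bound
#' (`">5,000"`). The bound itself is substituted as a conservative
#' (hazard-overestimating) value and flagged as censored.
#'
#' @param raw numeric vector, or character vector of plain numbers or
#'   `">N"` bounds (thousands separators allowed).
#' @return data.frame with columns `value` (mg/kg) and `censored`.
#' @export
#' @examples
#' censor_ld50(c(">5,000", "112", "3556"))
censor_ld50 <- function(raw) {
  txt <- trimws(as.character(raw))
  censored <- startsWith(txt, ">")
  num <- parse_numeric(sub("^>", "", txt))
  bad <- is.na(num) | num <= 0
  if (any(bad)) {
    stop_data("censor_ld50: unparsable or non-positive LD50 value(s): %s",
              paste(unique(txt[bad]), collapse = ", "))
  }
  data.frame(value = num, censored = censored)
}

toxicity_values <- function(profiles, endpoint = c("chronic", "acute")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "chronic") profiles$chronic_noel else profiles$acute_ld50
}

#' Hazard quotient for one crop-year
#'
#' Converts each ingredient's total amount to mg per planted hectare
#' (`kg * 1e6 / ha`), divides by its toxicity value for the chosen
#' endpoint, and sums. Ingredients without a toxicity profile are excluded
#' from the quotient with a logged warning (they still count toward
#' area-treatments elsewhere).
#'
#' @param records aggregated use records ([aggregate_by_ai()]) for a single
#'   (crop, year).
#' @param areas planted-area table.
#' @param profiles toxicity table from [read_toxicity_table()].
#' @param endpoint `"chronic"` (NOEL) or `"acute"` (LD50).
#' @return object of class `hazard_result`: a list with `crop`, `year`,
#'   `endpoint`, `hq`, `contributions` (data.frame `ai`, `amount_mg_ha`,
#'   `partial_hq`, `share_pct`) and `excluded` (ais lacking a profile).
#' @export
hazard_quotient <- function(records, areas, profiles,
                            endpoint = c("chronic", "acute")) {
  endpoint <- match.arg(endpoint)
  if (nrow(records) == 0L) {
    res <- list(crop = NA_character_, year = NA_integer_, endpoint = endpoint,
                hq = 0,
                contributions = data.frame(ai = character(),
                                           amount_mg_ha = numeric(),
                                           partial_hq = numeric(),
                                           share_pct = numeric()),
                excluded = character())
    class(res) <- "hazard_result"
    return(res)
  }
  if (length(unique(paste(records$crop, records$year))) != 1L) {
    stop_data("hazard_quotient: records span more than one (crop, year); use hazard_table()")
  }
  crop <- records$crop[1]; year <- records$year[1]
  area <- lookup_area(records[1, , drop = FALSE], areas, "hazard_quotient")

  idx <- match(records$ai, profiles$ai)
  excluded <- sort(unique(records$ai[is.na(idx)]))
  if (length(excluded)) {
    ht_log(sprintf("hazard_quotient: %s/%d: no toxicity profile for %s; excluded",
                   crop, year, paste(excluded, collapse = ", ")),
           level = "warn")
  }
  keep <- !is.na(idx)
  tox <- toxicity_values(profiles, endpoint)[idx[keep]]
  amount_mg_ha <- records$amount_applied[keep] * MG_PER_KG / area
  partial <- amount_mg_ha / tox
  hq <- sum(partial)
  contributions <- data.frame(ai = records$ai[keep],
                              amount_mg_ha = amount_mg_ha,
                              partial_hq = partial,
                              share_pct = if (hq > 0) 100 * partial / hq else
                                rep(NA_real_, length(partial)),
                              stringsAsFactors = FALSE)
  contributions <- contributions[order(contributions$ai), , drop = FALSE]
  rownames(contributions) <- NULL
  res <- list(crop = crop, year = year, endpoint = endpoint, hq = hq,
              contributions = contributions, excluded = excluded)
  class(res) <- "hazard_result"
  res
}

#' @export
print.hazard_result <- function(x, ...) {
  cat(sprintf("Hazard quotient (%s): %s %s  HQ = %g\n",
              x$endpoint, x$crop, x$year, x$hq))
  if (nrow(x$contributions)) {
    top <- x$contributions[order(-x$contributions$partial_hq), , drop = FALSE]
    print(utils::head(top, 5), row.names = FALSE)
  }
  if (length(x$excluded)) {
    cat("excluded (no toxicity profile):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Hazard quotients for every crop-year in a use table
#'
#' @inheritParams hazard_quotient
#' @return list with `hq` (data.frame `crop`, `year`, `endpoint`, `hq`),
#'   `contributions` (long data.frame of per-ai contributions) and
#'   `excluded` (unique ais without profiles).
#' @export
hazard_table <- function(records, areas, profiles,
                         endpoint = c("chronic", "acute")) {
  endpoint <- match.arg(endpoint)
  if (nrow(records) == 0L) {
    return(list(hq = data.frame(crop = character(), year = integer(),
                                endpoint = character(), hq = numeric()),
                contributions = data.frame(crop = character(), year = integer(),
                                           endpoint = character(), ai = character(),
                                           amount_mg_ha = numeric(),
                                           partial_hq = numeric(),
                                           share_pct = numeric()),
                excluded = character()))
  }
  key <- paste(records$crop, records$year, sep = "\r")
  groups <- split(seq_len(nrow(records)), key)
  results <- lapply(groups, function(i) {
    hazard_quotient(records[i, , drop = FALSE], areas, profiles, endpoint)
  })
  hq <- do.call(rbind, lapply(results, function(r) {
    data.frame(crop = r$crop, year = r$year, endpoint = r$endpoint, hq = r$hq,
               stringsAsFactors = FALSE)
  }))
  contributions <- do.call(rbind, lapply(results, function(r) {
    if (nrow(r$contributions) == 0L) return(NULL)
    cbind(data.frame(crop = r$crop, year = r$year, endpoint = r$endpoint,
                     stringsAsFactors = FALSE),
          r$contributions)
  }))
  if (is.null(contributions)) {
    contributions <- data.frame(crop = character(), year = integer(),
                                endpoint = character(), ai = character(),
                                amount_mg_ha = numeric(), partial_hq = numeric(),
                                share_pct = numeric())
  }
  hq <- hq[order(hq$crop, hq$year), , drop = FALSE]
  contributions <- contributions[order(contributions$crop, contributions$year,
                                       contributions$ai), , drop = FALSE]
  rownames(hq) <- rownames(contributions) <- NULL
  list(hq = hq, contributions = contributions,
       excluded = sort(unique(unlist(lapply(results, `[[`, "excluded")))))
}

#' Contribution of one active ingredient to a hazard quotient
#'
#' @param result a `hazard_result`.
#' @param ai active-ingredient name.
#' @return percentage of the total hazard quotient (0 for an ai absent from
#'   the crop-year).
#' @export
contribution_share <- function(result, ai) {
  stopifnot(inherits(result, "hazard_result"))
  if (result$hq == 0) {
    stop_data("contribution_share: hazard quotient is 0; shares are undefined")
  }
  i <- match(normalize_label(ai), result$contributions$ai)
  if (is.na(i)) return(0)
  100 * result$contributions$partial_hq[i] / result$hq
}

#' Toxicity percentile of one active ingredient
#'
#' Percentage of the *other* profiled ingredients that are strictly more
#' toxic (strictly lower toxicity value). Ties do not count as more toxic.
#'
#' @param profiles toxicity table.
#' @param ai active-ingredient name (must be profiled).
#' @param endpoint `"chronic"` or `"acute"`.
#' @return percentage in \[0, 100\].
#' @export
toxicity_percentile <- function(profiles, ai, endpoint = c("chronic", "acute")) {
  endpoint <- match.arg(endpoint)
  i <- match(normalize_label(ai), normalize_label(profiles$ai))
  if (is.na(i)) stop_data("toxicity_percentile: unknown active ingredient '%s'", ai)
  vals <- toxicity_values(profiles, endpoint)
  others <- vals[-i]
  if (length(others) == 0L) {
    stop_data("toxicity_percentile: need at least two profiles")
  }
  100 * sum(others < vals[i]) / length(others)
}

#' Distribution summary of toxicity values
#'
#' @param profiles toxicity table (at least one row).
#' @param endpoint `"chronic"` or `"acute"`.
#' @param threshold count values strictly below this bound (default 500
#'   mg/kg, the EPA acute Category II boundary).
#' @return list with `min`, `median` (midpoint convention for even counts),
#'   `max`, `n_below`, `threshold`, `n`.
#' @export
toxicity_summary <- function(profiles, endpoint = c("chronic", "acute"),
                             threshold = 500) {
  endpoint <- match.arg(endpoint)
  if (nrow(profiles) == 0L) stop_data("toxicity_summary: empty profile table")
  vals <- toxicity_values(profiles, endpoint)
  list(min = min(vals), median = median(vals), max = max(vals),
       n_below = sum(vals < threshold), threshold = threshold,
       n = length(vals))
}
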