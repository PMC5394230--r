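# Herbicide use intensity as area-treatments (AT): the amount of an active
# ingredient applied, divided by its average application rate and by the
# crop's planted area. AT is dimensionless — the fraction of the crop area
# treated at the average rate — and per-crop totals routinely exceed 1
# (e.g., four ingredients each at half rate over the whole area: 0.5 x 4 = 2).

#' Area-treatments for one (crop, year, ai) observation
#'
#' `amount / rate / area`, vectorized. With amount in kg, rate in kg/ha and
#' area in ha the result is dimensionless.
#'
#' @param amount total amount applied (kg), `>= 0`.
#' @param rate average application rate (kg/ha), `> 0`.
#' @param area planted area (ha), `> 0`.
#' @param key optional character vector naming each observation (used in
#'   error messages).
#' @return numeric vector of area-treatments.
#' @export
#' @examples
#' area_treatments(200, 2, 50)            # 2 full-rate passes
#' sum(area_treatments(rep(0.5 * 1.1 * 1000, 4), 1.1, 1000))  # 0.5 x 4 = 2
area_treatments <- function(amount, rate, area, key = NULL) {
  n <- max(length(amount), length(rate), length(area))
  amount <- rep_len(amount, n); rate <- rep_len(rate, n); area <- rep_len(area, n)
  bad <- is.na(rate) | rate <= 0 | is.na(area) | area <= 0 | is.na(amount) | amount < 0
  if (any(bad)) {
    who <- if (is.null(key)) paste("observation", which(bad)) else rep_len(key, n)[bad]
    stop_data("area_treatments: rate and area must be > 0 and amount >= 0 for: %s",
              paste(unique(who), collapse = "; "))
  }
  amount / rate / area
}

lookup_area <- function(records, areas, context) {
  idx <- match(paste(records$crop, records$year, sep = "\r"),
               paste(areas$crop, areas$year, sep = "\r"))
  if (anyNA(idx)) {
    miss <- unique(paste(records$crop[is.na(idx)], records$year[is.na(idx)]))
    stop_data("%s: no planted-area record for: %s", context,
              paste(miss, collapse = "; "))
  }
  areas$planted_area[idx]
}

# Fill missing per-(crop, year, ai) rates from the same crop+ai in other
# years (amount-weighted mean), logged. The survey occasionally reports an
# amount without a usable rate; dropping such use silently would bias AT low.
fill_missing_rates <- function(records) {
  miss <- is.na(records$avg_rate)
  if (!any(miss)) return(records)
  for (i in which(miss)) {
    j <- which(records$crop == records$crop[i] & records$ai == records$ai[i] &
                 !is.na(records$avg_rate))
    if (length(j)) {
      w <- records$amount_applied[j]
      records$avg_rate[i] <- if (sum(w) > 0) {
        weighted.mean(records$avg_rate[j], w)
      } else {
        mean(records$avg_rate[j])
      }
      ht_log(sprintf("intensity: filled missing rate for %s/%d/%s from %d other year(s)",
                     records$crop[i], records$year[i], records$ai[i], length(j)),
             level = "warn")
    }
  }
  still <- is.na(records$avg_rate)
  if (any(still)) {
    stop_data("intensity: no application rate available for: %s",
              paste(unique(paste(records$crop[still], records$year[still],
                                 records$ai[still])), collapse = "; "))
  }
  records
}

#' Per-ingredient area-treatments table
#'
#' Joins aggregated use records with planted areas and computes AT for each
#' (crop, year, ai). Every (crop, year) present in `records` must have an
#' area record.
#'
#' @param records aggregated use records from [aggregate_by_ai()].
#' @param areas planted-area table from [read_area_table()].
#' @return data.frame with columns `crop`, `year`, `ai`, `at`, ordered by
#'   crop, year, ai.
#' @export
at_table <- function(records, areas) {
  if (nrow(records) == 0L) {
    return(data.frame(crop = character(), year = integer(), ai = character(),
                      at = numeric()))
  }
  records <- fill_missing_rates(records)
  area <- lookup_area(records, areas, "at_table")
  out <- data.frame(crop = records$crop, year = records$year, ai = records$ai,
                    at = area_treatments(records$amount_applied, records$avg_rate,
                                         area,
                                         key = paste(records$crop, records$year,
                                                     records$ai)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$crop, out$year, out$ai), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Total area-treatments per crop and year
#'
#' Sums per-ingredient area-treatments within each surveyed (crop, year).
#' Unsurveyed years simply do not appear — no interpolation.
#'
#' @inheritParams at_table
#' @return data.frame with columns `crop`, `year`, `total_at`, ordered by
#'   crop then year.
#' @export
total_area_treatments <- function(records, areas) {
  per_ai <- at_table(records, areas)
  if (nrow(per_ai) == 0L) {
    return(data.frame(crop = character(), year = integer(), total_at = numeric()))
  }
  agg <- aggregate(per_ai$at,
                   by = list(crop = per_ai$crop, year = per_ai$year), FUN = sum)
  names(agg)[3] <- "total_at"
  agg <- agg[order(agg$crop, agg$year), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
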