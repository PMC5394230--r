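# Consolidation of formulation/salt-specific ingredient labels into
# canonical active ingredients. Survey extracts list e.g. eight salts of
# 2,4-D and seven salts of glyphosate as distinct entries; intensity and
# hazard math must run on the active ingredient.

normalize_label <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Read an ingredient-label mapping file
#'
#' Two- or three-column CSV: `label` (raw formulation text), `ai` (canonical
#' active ingredient), optional `mass_factor` (dimensionless multiplier
#' applied to amounts, default 1.0 — reported amounts are assumed to be
#' acid-equivalent already, the USDA-NASS convention; the factor is a hook
#' for sources that report salt weight).
#'
#' A starter mapping covering common glyphosate and 2,4-D salts ships with
#' the package:
#' `system.file("extdata", "ingredient_mapping.csv", package = "herbtrends")`.
#'
#' @param path CSV file.
#' @return data.frame with columns `label` (normalized key), `ai`,
#'   `mass_factor`.
#' @export
read_ingredient_mapping <- function(path) {
  raw <- read_delim_file(path)
  check_columns(raw, c("label", "ai"), path)
  mf <- if ("mass_factor" %in% names(raw)) {
    f <- parse_numeric(raw$mass_factor)
    f[is.na(f)] <- 1
    f
  } else {
    rep(1, nrow(raw))
  }
  if (any(mf <= 0)) stop_data("file '%s': mass_factor must be > 0", path)
  out <- data.frame(label = normalize_label(raw$label),
                    ai = normalize_label(raw$ai),
                    mass_factor = mf,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$label)) {
    stop_data("file '%s': duplicate label(s) after normalization: %s", path,
              paste(unique(out$label[duplicated(out$label)]), collapse = ", "))
  }
  out
}

#' Map raw ingredient labels to canonical active ingredients
#'
#' Matching is case-insensitive and whitespace-normalized. Labels without a
#' mapping entry pass through as their normalized form (logged), so a use
#' table can always be processed even with an incomplete mapping.
#'
#' @param labels character vector of raw labels.
#' @param mapping data.frame from [read_ingredient_mapping()], or `NULL`
#'   (identity mapping).
#' @return character vector of canonical active-ingredient names.
#' @export
#' @examples
#' m <- data.frame(label = "glyphosate isopropylamine salt",
#'                 ai = "glyphosate", mass_factor = 1)
#' canonicalize("  Glyphosate Isopropylamine  Salt ", m)
canonicalize <- function(labels, mapping = NULL) {
  key <- normalize_label(labels)
  if (is.null(mapping) || nrow(mapping) == 0L) return(key)
  idx <- match(key, normalize_label(mapping$label))
  unmapped <- is.na(idx)
  if (any(unmapped)) {
    ht_log(sprintf("canonicalize: %d label(s) not in mapping, passed through: %s",
                   sum(unmapped),
                   paste(unique(key[unmapped]), collapse = ", ")),
           level = "debug")
  }
  ifelse(unmapped, key, mapping$ai[idx])
}

mapped_mass_factor <- function(labels, mapping) {
  if (is.null(mapping) || nrow(mapping) == 0L) return(rep(1, length(labels)))
  idx <- match(normalize_label(labels), normalize_label(mapping$label))
  ifelse(is.na(idx), 1, mapping$mass_factor[idx])
}

#' Aggregate use records by canonical active ingredient
#'
#' Sums amounts (after any per-label mass factor) within (crop, year, ai)
#' and recomputes the average application rate as the amount-weighted mean
#' of the input rates, so a dominant formulation dominates the merged rate.
#' Rows with missing rates contribute amount but not rate weight; if no row
#' in a group carries a rate the merged rate is `NA`.
#'
#' @param records use table from [read_use_table()].
#' @param mapping optional mapping from [read_ingredient_mapping()].
#' @return data.frame with columns `crop`, `year`, `ai`, `amount_applied`,
#'   `avg_rate`, ordered by crop, year, ai.
#' @export
aggregate_by_ai <- function(records, mapping = NULL) {
  if (nrow(records) == 0L) {
    return(data.frame(crop = character(), year = integer(), ai = character(),
                      amount_applied = numeric(), avg_rate = numeric()))
  }
  label_col <- if ("ai" %in% names(records)) "ai" else "ingredient_label"
  ai <- canonicalize(records[[label_col]], mapping)
  amount <- records$amount_applied * mapped_mass_factor(records[[label_col]], mapping)
  g <- data.frame(crop = records$crop, year = records$year, ai = ai,
                  amount = amount, rate = records$avg_rate,
                  stringsAsFactors = FALSE)
  key <- paste(g$crop, g$year, g$ai, sep = "\r")
  first <- !duplicated(key)
  levels <- key[first]

  has_rate <- !is.na(g$rate)
  amt_sum <- rowsum(g$amount, key)[levels, ]
  # amount-weighted mean of the rates that are present; fall back to the
  # simple mean when all rate-bearing rows have zero amount
  w <- ifelse(has_rate, g$amount, 0)
  rate_w_num <- rowsum(ifelse(has_rate, g$rate, 0) * w, key)[levels, ]
  rate_w_den <- rowsum(w, key)[levels, ]
  rate_n <- rowsum(as.numeric(has_rate), key)[levels, ]
  rate_sum <- rowsum(ifelse(has_rate, g$rate, 0), key)[levels, ]
  merged_rate <- ifelse(rate_w_den > 0, rate_w_num / rate_w_den,
                        ifelse(rate_n > 0, rate_sum / rate_n, NA_real_))

  out <- data.frame(crop = g$crop[first], year = g$year[first], ai = g$ai[first],
                    amount_applied = amt_sum, avg_rate = merged_rate,
                    stringsAsFactors = FALSE)
  out <- out[order(out$crop, out$year, out$ai), , drop = FALSE]
  rownames(out) <- NULL
  out
}
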