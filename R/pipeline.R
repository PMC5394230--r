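# End-to-end orchestration: read configuration, run every stage
# (read -> consolidate -> area-treatments -> hazard quotients -> trend
# tests), write output tables with a fixed row ordering, and record a run
# manifest (input checksums, configuration snapshot, per-stage record
# counts, warnings).

#' Read a run-configuration file
#'
#' JSON (always available) or YAML (when the `yaml` package is installed).
#' Recognized top-level fields, all optional except `paths`:
#'
#' * `paths`: named list — `use`, `toxicity`, `area`, required; `mapping`
#'   optional.
#' * `units`: `use_mass` (`"kg"`/`"lb"`), `use_area`, `area_area`
#'   (`"ha"`/`"acre"`); defaults are metric.
#' * `column_maps`: `use` and `area` column maps (see [read_use_table()]).
#' * `crops`: allowed crop names (default [default_crops()]).
#' * `year_range`: two integers, default `c(1990, 2015)`.
#' * `endpoints`: subset of `c("chronic", "acute")`, default both.
#' * `out_dir`: where [run_pipeline()] writes outputs.
#'
#' @param path configuration file.
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("configuration file does not exist: '%s'", path)
  ext <- tolower(file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_config("YAML configuration requires the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_run_config(cfg, base_dir = dirname(path))
}

validate_run_config <- function(cfg, base_dir = ".") {
  if (is.null(cfg$paths) || !all(c("use", "toxicity", "area") %in% names(cfg$paths))) {
    stop_config("configuration must name paths$use, paths$toxicity and paths$area")
  }
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base_dir, p) else p
  }
  cfg$paths <- lapply(cfg$paths, resolve)
  defaults <- list(
    units = list(use_mass = "kg", use_area = "ha", area_area = "ha"),
    column_maps = list(
      use = c(crop = "crop", year = "year", ingredient = "ingredient_label",
              amount = "amount_applied", rate = "avg_rate"),
      area = c(crop = "crop", year = "year", area = "planted_area")
    ),
    crops = default_crops(),
    year_range = c(1990L, 2015L),
    endpoints = c("chronic", "acute")
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  cfg$column_maps <- lapply(cfg$column_maps, unlist)
  cfg$units <- lapply(cfg$units, as.character)
  bad_ep <- setdiff(cfg$endpoints, c("chronic", "acute"))
  if (length(bad_ep)) stop_config("unknown endpoint(s): %s", paste(bad_ep, collapse = ", "))
  if (length(cfg$year_range) != 2L) stop_config("year_range must have two elements")
  cfg$out_dir <- resolve(cfg$out_dir)
  cfg
}

run_stage <- function(stage, code) {
  withCallingHandlers(
    tryCatch(code, error = function(e) {
      stop_data("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
    }),
    warning = function(w) w  # warnings are collected by the caller
  )
}

#' Run the full intensity + toxicity pipeline
#'
#' Reads the three input tables, consolidates ingredient labels,
#' computes per-ingredient and total area-treatments, chronic and acute
#' hazard quotients with per-ingredient contribution shares, and
#' Mann-Kendall and OLS trend tests per crop (on the AT series and on each
#' hazard-quotient series). Outputs are written to `out_dir` (if set) with
#' deterministic row ordering, alongside a `manifest.json`.
#'
#' @param config configuration list from [read_run_config()] (or a path to
#'   a configuration file).
#' @param out_dir overrides `config$out_dir` when not `NULL`.
#' @return (invisibly) list with `use`, `aggregated`, `at`, `at_series`,
#'   `hazard` (per endpoint: `hq`, `contributions`, `excluded`), `trends`,
#'   and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config, base_dir = ".")
  if (!is.null(out_dir)) config$out_dir <- out_dir

  warnings_seen <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    }, message = function(m) {
      if (grepl("\\[herbtrends:warn\\]", conditionMessage(m))) {
        warnings_seen <<- c(warnings_seen, trimws(conditionMessage(m)))
      }
      invokeRestart("muffleMessage")
    })
  }

  inputs <- Filter(Negate(is.null),
                   config$paths[c("use", "toxicity", "area", "mapping")])
  checksums <- vapply(inputs, function(p) unname(md5sum(p)), character(1))

  use <- run_stage("read_use", collect(
    read_use_table(config$paths$use, column_map = config$column_maps$use,
                   units = c(mass = config$units$use_mass,
                             area = config$units$use_area),
                   crops = config$crops, year_range = config$year_range)))
  tox <- run_stage("read_toxicity", collect(read_toxicity_table(config$paths$toxicity)))
  areas <- run_stage("read_area", collect(
    read_area_table(config$paths$area, column_map = config$column_maps$area,
                    units = c(area = config$units$area_area))))
  mapping <- if (!is.null(config$paths$mapping)) {
    run_stage("read_mapping", collect(read_ingredient_mapping(config$paths$mapping)))
  }

  aggregated <- run_stage("aggregate", collect(aggregate_by_ai(use, mapping)))
  at <- run_stage("area_treatments", collect(at_table(aggregated, areas)))
  at_series <- run_stage("area_treatments", collect(total_area_treatments(aggregated, areas)))

  missing_tox <- setdiff(unique(aggregated$ai), tox$ai)
  hazard <- lapply(setNames(config$endpoints, config$endpoints), function(ep) {
    run_stage(paste0("hazard_", ep), collect(hazard_table(aggregated, areas, tox, ep)))
  })

  trends <- run_stage("trends", collect(trend_test_table(at_series, hazard)))

  counts <- list(use_rows = nrow(use), toxicity_rows = nrow(tox),
                 area_rows = nrow(areas),
                 aggregated_rows = nrow(aggregated),
                 at_rows = nrow(at), at_series_rows = nrow(at_series),
                 hazard_rows = sum(vapply(hazard, function(h) nrow(h$hq), 0L)),
                 trend_rows = nrow(trends),
                 ais_without_toxicity = length(missing_tox))

  manifest <- list(package_version = as.character(packageVersion("herbtrends")),
                   inputs = lapply(names(inputs), function(n) {
                     list(name = n, path = inputs[[n]],
                          md5 = unname(checksums[[n]]))
                   }),
                   config = config[setdiff(names(config), "paths")],
                   counts = counts,
                   warnings = warnings_seen,
                   outputs = character())

  result <- list(use = use, aggregated = aggregated, at = at,
                 at_series = at_series, hazard = hazard, trends = trends,
                 manifest = manifest)

  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    files <- c(area_treatments = file.path(d, "area_treatments.csv"),
               total_area_treatments = file.path(d, "total_area_treatments.csv"),
               hazard = file.path(d, "hazard.csv"),
               contributions = file.path(d, "contributions.csv"),
               trends = file.path(d, "trends.csv"))
    write_output_table(at, files[["area_treatments"]])
    write_output_table(at_series, files[["total_area_treatments"]])
    hq_all <- do.call(rbind, lapply(hazard, `[[`, "hq"))
    contrib_all <- do.call(rbind, lapply(hazard, `[[`, "contributions"))
    ord <- order(hq_all$crop, hq_all$year, hq_all$endpoint)
    write_output_table(hq_all[ord, , drop = FALSE], files[["hazard"]])
    ord <- order(contrib_all$crop, contrib_all$year, contrib_all$endpoint,
                 contrib_all$ai)
    write_output_table(contrib_all[ord, , drop = FALSE], files[["contributions"]])
    write_output_table(trends, files[["trends"]])
    result$manifest$outputs <- unname(files)
    jsonlite::write_json(result$manifest, file.path(d, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(result)
}

# Per-crop trend tests: Mann-Kendall + OLS on the total-AT series and on
# each hazard-quotient series (series with < 3 surveyed years are reported
# as NA rather than erroring the whole run).
trend_test_table <- function(at_series, hazard) {
  rows <- list()
  add <- function(crop, metric, res) {
    rows[[length(rows) + 1L]] <<- data.frame(
      crop = crop, metric = metric,
      statistic_kind = res$statistic_kind, estimate = res$estimate,
      p_value = res$p_value, n = res$n, method_note = res$method_note,
      stringsAsFactors = FALSE)
  }
  run_both <- function(crop, metric, year, value) {
    if (length(year) < 3L) return(invisible(NULL))
    add(crop, metric, mann_kendall(year, value))
    add(crop, metric, ols_slope(year, value))
  }
  for (crop in unique(at_series$crop)) {
    s <- at_series[at_series$crop == crop, , drop = FALSE]
    run_both(crop, "total_at", s$year, s$total_at)
  }
  for (ep in names(hazard)) {
    hq <- hazard[[ep]]$hq
    for (crop in unique(hq$crop)) {
      s <- hq[hq$crop == crop, , drop = FALSE]
      run_both(crop, paste0("hq_", ep), s$year, s$hq)
    }
  }
  if (!length(rows)) {
    return(data.frame(crop = character(), metric = character(),
                      statistic_kind = character(), estimate = numeric(),
                      p_value = numeric(), n = integer(),
                      method_note = character()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$crop, out$metric, out$statistic_kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize pipeline results for one crop
#'
#' First/last surveyed-year hazard quotients and area-treatments, percent
#' change over the surveyed period (`100 * (last - first) / first`;
#' not applicable for single-year series), top contributing ingredients in
#' the first and last year, and the crop's trend statistics.
#'
#' @param crop crop name.
#' @param results a [run_pipeline()] result.
#' @param top_k number of top contributors to list per endpoint per year.
#' @return object of class `crop_summary`.
#' @export
summarize_crop <- function(crop, results, top_k = 3L) {
  if (!crop %in% results$at_series$crop) {
    stop_data("summarize_crop: no results for crop '%s'", crop)
  }
  pct_change <- function(v) {
    if (length(v) < 2L) NA_real_ else 100 * (v[length(v)] - v[1]) / v[1]
  }
  s <- results$at_series[results$at_series$crop == crop, , drop = FALSE]
  out <- list(crop = crop,
              years = range(s$year),
              at = list(first = s$total_at[1], last = s$total_at[nrow(s)],
                        pct_change = pct_change(s$total_at)),
              endpoints = list(),
              trends = results$trends[results$trends$crop == crop, , drop = FALSE])
  for (ep in names(results$hazard)) {
    hq <- results$hazard[[ep]]$hq
    hq <- hq[hq$crop == crop, , drop = FALSE]
    if (!nrow(hq)) next
    contrib <- results$hazard[[ep]]$contributions
    top_in <- function(y) {
      cc <- contrib[contrib$crop == crop & contrib$year == y, , drop = FALSE]
      cc <- cc[order(-cc$partial_hq), , drop = FALSE]
      utils::head(cc[, c("ai", "share_pct")], top_k)
    }
    out$endpoints[[ep]] <- list(
      first_year = hq$year[1], last_year = hq$year[nrow(hq)],
      first_hq = hq$hq[1], last_hq = hq$hq[nrow(hq)],
      pct_change = pct_change(hq$hq),
      top_first = top_in(hq$year[1]),
      top_last = top_in(hq$year[nrow(hq)]))
  }
  class(out) <- "crop_summary"
  out
}

#' @export
print.crop_summary <- function(x, ...) {
  cat(sprintf("== %s (%d-%d) ==\n", x$crop, x$years[1], x$years[2]))
  cat(sprintf("area-treatments: %.3g -> %.3g (%s)\n",
              x$at$first, x$at$last,
              if (is.na(x$at$pct_change)) "single year, change n/a"
              else sprintf("%+.1f%%", x$at$pct_change)))
  for (ep in names(x$endpoints)) {
    e <- x$endpoints[[ep]]
    cat(sprintf("%s HQ: %.4g (%d) -> %.4g (%d) (%s)\n", ep,
                e$first_hq, e$first_year, e$last_hq, e$last_year,
                if (is.na(e$pct_change)) "single year, change n/a"
                else sprintf("%+.1f%%", e$pct_change)))
    tops <- paste(sprintf("%s %.1f%%", e$top_last$ai, e$top_last$share_pct),
                  collapse = ", ")
    cat(sprintf("  top contributors in %d: %s\n", e$last_year, tops))
  }
  if (nrow(x$trends)) {
    cat("trend tests:\n")
    print(x$trends, row.names = FALSE)
  }
  invisible(x)
}
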