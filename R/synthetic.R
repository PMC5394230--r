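# Synthetic survey-data generator with exact ground truth. Amounts are
# derived from target area-treatments (amount = AT x rate x area), so at
# noise_sd = 0 the pipeline must recover the configured per-crop AT trend
# exactly; multiplicative log-normal noise emulates survey estimation error.
#
# The default world mirrors the structure of the 1990-2015 US herbicide
# record: six crops with their reported active-ingredient counts, rice
# surveyed only six times, linear AT growth with slopes in the 0.02-0.09
# per-year range, chronic NOELs log-spread over 0.03-20,000 mg/kg/d, acute
# LD50s over 112-9,000 mg/kg with a censoring mass at the 5,000 bound, and
# a few dominant ingredients carrying most of the use (the
# atrazine/molinate pattern).

default_crop_configs <- function() {
  list(
    list(name = "maize", years = 1990:2014, n_ais = 75,
         at_baseline = 2.2, at_slope = 0.05, area = 35e6),
    list(name = "soybean", years = 1990:2015, n_ais = 57,
         at_baseline = 1.5, at_slope = 0.02, area = 33e6),
    list(name = "cotton", years = 1990:2015, n_ais = 54,
         at_baseline = 2.0, at_slope = 0.05, area = 4.5e6),
    list(name = "rice", years = c(1990L, 1992L, 1995L, 2000L, 2006L, 2013L),
         n_ais = 34, at_baseline = 2.5, at_slope = 0.07, area = 1.2e6),
    list(name = "spring wheat", years = 1990:2015, n_ais = 44,
         at_baseline = 1.2, at_slope = 0.09, area = 5.5e6),
    list(name = "winter wheat", years = 1990:2015, n_ais = 56,
         at_baseline = 1.0, at_slope = 0.06, area = 14e6)
  )
}

#' Build and validate a simulation configuration
#'
#' @param seed master seed; each output table draws from its own stream
#'   split off this seed, so adding a crop does not perturb other tables.
#' @param crops list of per-crop specs, each a list with `name`, `years`
#'   (surveyed years), `n_ais`, `at_baseline`, `at_slope` (area-treatments
#'   per year of the ground-truth linear trend), `area` (planted ha,
#'   constant over years), and optional `dominance_weights` (per-ai share of
#'   total AT, summing to 1; default geometric decay with ratio
#'   `dominance_decay`).
#' @param n_labels_per_ai salt/formulation multiplicity per active
#'   ingredient (`>= 1`); with `k > 1` each ai's amount is split over `k`
#'   distinct labels and a label-to-ai mapping table is emitted.
#' @param n_ai_pool size of the global active-ingredient pool crops sample
#'   from (shared ingredients across crops).
#' @param dominance_decay geometric ratio of the default dominance weights.
#' @param noel_range,ld50_range log-uniform bounds for chronic NOEL
#'   (mg/kg/d) and acute LD50 (mg/kg).
#' @param censor_prob probability an LD50 is censored at the 5,000 mg/kg
#'   bound instead of drawn from `ld50_range`.
#' @param rate_range log-uniform bounds for average application rates
#'   (kg/ha).
#' @param noise_sd standard deviation of multiplicative log-normal noise on
#'   amounts (0 = exact ground truth).
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              crops = default_crop_configs(),
                              n_labels_per_ai = 1L,
                              n_ai_pool = 118L,
                              dominance_decay = 0.6,
                              noel_range = c(0.03, 20000),
                              ld50_range = c(112, 9000),
                              censor_prob = 0.3,
                              rate_range = c(0.02, 2),
                              noise_sd = 0.1) {
  fail <- function(msg, ...) stop_config(paste0("simulation_config: ", msg), ...)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) fail("invalid seed")
  if (n_labels_per_ai < 1L) fail("n_labels_per_ai must be >= 1")
  if (n_ai_pool < 1L) fail("n_ai_pool must be >= 1")
  for (rng in list(noel_range, ld50_range, rate_range)) {
    if (length(rng) != 2L || any(rng <= 0) || rng[1] > rng[2]) {
      fail("ranges must be positive increasing pairs")
    }
  }
  if (censor_prob < 0 || censor_prob > 1) fail("censor_prob must be in [0, 1]")
  if (noise_sd < 0) fail("noise_sd must be >= 0")
  if (dominance_decay <= 0 || dominance_decay > 1) fail("dominance_decay in (0, 1]")
  if (!length(crops)) fail("at least one crop required")
  for (cr in crops) {
    need <- c("name", "years", "n_ais", "at_baseline", "at_slope", "area")
    if (!all(need %in% names(cr))) {
      fail("crop spec missing field(s): %s",
           paste(setdiff(need, names(cr)), collapse = ", "))
    }
    if (anyDuplicated(cr$years) || length(cr$years) < 1L) fail("invalid years for '%s'", cr$name)
    if (cr$n_ais < 1L || cr$n_ais > n_ai_pool) {
      fail("n_ais for '%s' must be in [1, n_ai_pool]", cr$name)
    }
    if (cr$area <= 0 || cr$at_baseline < 0) fail("invalid area/baseline for '%s'", cr$name)
    if (any(cr$at_baseline + cr$at_slope *
              (sort(cr$years) - min(cr$years)) < 0)) {
      fail("AT trend for '%s' goes negative within its surveyed years", cr$name)
    }
    if (!is.null(cr$dominance_weights)) {
      w <- cr$dominance_weights
      if (length(w) != cr$n_ais || any(w < 0) || abs(sum(w) - 1) > 1e-8) {
        fail("dominance_weights for '%s' must have length n_ais and sum to 1", cr$name)
      }
    }
  }
  cfg <- list(seed = as.integer(seed), crops = crops,
              n_labels_per_ai = as.integer(n_labels_per_ai),
              n_ai_pool = as.integer(n_ai_pool),
              dominance_decay = dominance_decay,
              noel_range = noel_range, ld50_range = ld50_range,
              censor_prob = censor_prob, rate_range = rate_range,
              noise_sd = noise_sd)
  class(cfg) <- "simulation_config"
  cfg
}

.salt_suffixes <- c(
  "isopropylamine salt", "potassium salt", "ammonium salt",
  "dimethylamine salt", "diammonium salt", "sodium salt",
  "monoethanolamine salt", "2-ethylhexyl ester", "butoxyethyl ester",
  "isooctyl ester", "diethanolamine salt", "triisopropanolamine salt"
)

#' Distinct salt/formulation labels for one active ingredient
#'
#' With `k = 1` the label is the ai name itself; otherwise `k` distinct
#' formulation-style labels, each mapping back to the ai.
#'
#' @param ai active-ingredient name.
#' @param k multiplicity (`>= 1`).
#' @param seed optional seed controlling the order suffixes are assigned.
#' @return character vector of `k` distinct labels.
#' @export
generate_salt_labels <- function(ai, k, seed = NULL) {
  if (k < 1L) stop_config("generate_salt_labels: k must be >= 1")
  if (k == 1L) return(ai)
  suffixes <- .salt_suffixes
  if (k > length(suffixes)) {
    suffixes <- c(suffixes, paste("formulation", seq_len(k - length(suffixes))))
  }
  if (!is.null(seed)) {
    suffixes <- with_seed(seed, sample(suffixes))
  }
  paste(ai, suffixes[seq_len(k)])
}

loguniform <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))

#' Generate synthetic survey, toxicity and area tables with ground truth
#'
#' @param config a [simulation_config()].
#' @return list with `use` (label-level use table), `toxicity`, `area`,
#'   `mapping` (label-to-ai table) and `truth`: the exact noiseless
#'   per-crop AT series (`at_series`), per-(crop, year, ai) ATs
#'   (`at_by_ai`), the toxicity table, and expected hazard quotients per
#'   crop-year for both endpoints (`hq`).
#' @export
generate_survey_data <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  pool <- sprintf("ai%03d", seq_len(config$n_ai_pool))

  # toxicity stream: one draw block for the whole pool
  tox <- with_seed(derive_seed(config$seed, "toxicity"), {
    noel <- loguniform(config$n_ai_pool, config$noel_range)
    censored <- runif(config$n_ai_pool) < config$censor_prob
    ld50 <- loguniform(config$n_ai_pool, config$ld50_range)
    ld50[censored] <- LD50_CENSOR_BOUND
    data.frame(ai = pool, acute_ld50 = ld50, acute_censored = censored,
               chronic_noel = noel,
               wssa_group = as.character(sample(1:29, config$n_ai_pool,
                                                replace = TRUE)),
               stringsAsFactors = FALSE)
  })

  k <- config$n_labels_per_ai
  use_rows <- list()
  truth_rows <- list()
  area_rows <- list()

  for (cr in config$crops) {
    crop_seed <- derive_seed(config$seed, paste0("crop:", cr$name))
    years <- sort(as.integer(cr$years))
    w <- cr$dominance_weights
    if (is.null(w)) {
      w <- config$dominance_decay^(seq_len(cr$n_ais) - 1)
      w <- w / sum(w)
    }
    crop_data <- with_seed(crop_seed, {
      ais <- sort(sample(pool, cr$n_ais))
      rates <- loguniform(cr$n_ais, config$rate_range)
      splits <- if (k > 1L) {
        # fixed per-ai label split proportions (Dirichlet via gamma draws)
        m <- matrix(stats::rgamma(cr$n_ais * k, shape = 2), nrow = cr$n_ais)
        m / rowSums(m)
      } else {
        matrix(1, nrow = cr$n_ais, ncol = 1)
      }
      noise <- if (config$noise_sd > 0) {
        matrix(exp(rnorm(cr$n_ais * length(years), 0, config$noise_sd)),
               nrow = cr$n_ais)
      } else {
        matrix(1, nrow = cr$n_ais, ncol = length(years))
      }
      list(ais = ais, rates = rates, splits = splits, noise = noise)
    })

    total_at <- cr$at_baseline + cr$at_slope * (years - years[1])
    at_by_ai <- outer(w, total_at)          # n_ais x n_years
    amount <- at_by_ai * crop_data$rates * cr$area  # kg, noiseless

    labels <- lapply(crop_data$ais, function(a) {
      generate_salt_labels(a, k, seed = derive_seed(crop_seed, a))
    })

    for (yi in seq_along(years)) {
      for (ai_i in seq_len(cr$n_ais)) {
        amt <- amount[ai_i, yi] * crop_data$noise[ai_i, yi] *
          crop_data$splits[ai_i, ]
        use_rows[[length(use_rows) + 1L]] <- data.frame(
          crop = cr$name, year = years[yi],
          ingredient_label = labels[[ai_i]],
          amount_applied = amt,
          avg_rate = crop_data$rates[ai_i],
          stringsAsFactors = FALSE)
      }
    }

    area_rows[[length(area_rows) + 1L]] <- data.frame(
      crop = cr$name, year = years, planted_area = cr$area,
      stringsAsFactors = FALSE)

    tox_idx <- match(crop_data$ais, tox$ai)
    hq_chronic <- colSums(amount * MG_PER_KG / cr$area / tox$chronic_noel[tox_idx])
    hq_acute <- colSums(amount * MG_PER_KG / cr$area / tox$acute_ld50[tox_idx])
    truth_rows[[length(truth_rows) + 1L]] <- list(
      at_series = data.frame(crop = cr$name, year = years, total_at = total_at,
                             stringsAsFactors = FALSE),
      at_by_ai = data.frame(crop = cr$name,
                            year = rep(years, each = cr$n_ais),
                            ai = rep(crop_data$ais, length(years)),
                            at = as.vector(at_by_ai),
                            stringsAsFactors = FALSE),
      hq = data.frame(crop = cr$name, year = rep(years, 2),
                      endpoint = rep(c("chronic", "acute"), each = length(years)),
                      hq = c(hq_chronic, hq_acute),
                      stringsAsFactors = FALSE),
      mapping = data.frame(label = unlist(labels),
                           ai = rep(crop_data$ais, each = k),
                           mass_factor = 1,
                           stringsAsFactors = FALSE)
    )
  }

  use <- do.call(rbind, use_rows)
  use <- use[order(use$crop, use$year, use$ingredient_label), , drop = FALSE]
  area <- do.call(rbind, area_rows)
  area <- area[order(area$crop, area$year), , drop = FALSE]
  mapping <- unique(do.call(rbind, lapply(truth_rows, `[[`, "mapping")))
  mapping <- mapping[order(mapping$label), , drop = FALSE]
  truth <- list(
    at_series = do.call(rbind, lapply(truth_rows, `[[`, "at_series")),
    at_by_ai = do.call(rbind, lapply(truth_rows, `[[`, "at_by_ai")),
    hq = do.call(rbind, lapply(truth_rows, `[[`, "hq")),
    toxicity = tox,
    config = config
  )
  rownames(use) <- rownames(area) <- rownames(mapping) <- NULL
  truth <- lapply(truth, function(x) {
    if (is.data.frame(x)) rownames(x) <- NULL
    x
  })
  list(use = use, toxicity = tox, area = area, mapping = mapping, truth = truth)
}

#' Write a simulation to disk in the formats the readers accept
#'
#' Emits `use.csv`, `toxicity.csv` (LD50s serialized back to `">5,000"`
#' style strings when censored), `area.csv`, `mapping.csv` and
#' `truth.json`.
#'
#' @param sim result of [generate_survey_data()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(use = file.path(dir, "use.csv"),
             toxicity = file.path(dir, "toxicity.csv"),
             area = file.path(dir, "area.csv"),
             mapping = file.path(dir, "mapping.csv"),
             truth = file.path(dir, "truth.json"))
  write_output_table(sim$use, paths[["use"]])
  tox_out <- sim$toxicity
  tox_out$acute_ld50 <- ifelse(tox_out$acute_censored,
                               paste0(">", format(tox_out$acute_ld50,
                                                  scientific = FALSE, trim = TRUE)),
                               as.character(tox_out$acute_ld50))
  tox_out$acute_censored <- NULL
  write_output_table(tox_out, paths[["toxicity"]])
  write_output_table(sim$area, paths[["area"]])
  write_output_table(sim$mapping, paths[["mapping"]])
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths[["truth"]], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
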