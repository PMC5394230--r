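test_that("generation is deterministic in the seed and streams are independent", {
  cfg <- tiny_sim_config(seed = 42, noise_sd = 0.1)
  a <- generate_survey_data(cfg)
  b <- generate_survey_data(cfg)
  expect_identical(a, b)

  # byte-identical on disk too
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(a, d1); write_simulation(b, d2)
  for (f in c("use.csv", "toxicity.csv", "area.csv", "mapping.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  # adding a crop must not perturb the toxicity table or the first crop's rows
  cfg2 <- tiny_sim_config(seed = 42, noise_sd = 0.1)
  cfg2$crops <- c(cfg2$crops, list(list(name = "rice", years = 1990:1995,
                                        n_ais = 3L, at_baseline = 2,
                                        at_slope = 0.07, area = 500)))
  cfg2 <- do.call(simulation_config, unclass(cfg2))
  c2 <- generate_survey_data(cfg2)
  expect_identical(c2$toxicity, a$toxicity)
  expect_identical(c2$use[c2$use$crop == "maize", ], a$use)
})

test_that("invalid configurations fail before any output", {
  expect_error(tiny_sim_config(noise_sd = -1), class = "herbtrends_config_error")
  expect_error(tiny_sim_config(censor_prob = 2), class = "herbtrends_config_error")
  expect_error(tiny_sim_config(at_slope = -1),  # AT would go negative
               class = "herbtrends_config_error")
  expect_error(simulation_config(crops = list(list(name = "x"))),
               class = "herbtrends_config_error")
  expect_error(generate_salt_labels("glyphosate", 0),
               class = "herbtrends_config_error")
})

test_that("toxicity draws respect configured ranges and the censoring mass", {
  cfg <- simulation_config(seed = 3, n_ai_pool = 600L, censor_prob = 0.3,
                           crops = list(list(name = "maize", years = 1990:1992,
                                             n_ais = 5L, at_baseline = 1,
                                             at_slope = 0, area = 100)))
  tox <- generate_survey_data(cfg)$toxicity
  expect_true(all(tox$chronic_noel >= 0.03 & tox$chronic_noel <= 20000))
  uncensored <- tox$acute_ld50[!tox$acute_censored]
  expect_true(all(uncensored >= 112 & uncensored <= 9000))
  expect_true(all(tox$acute_ld50[tox$acute_censored] == 5000))
  # binomial tolerance: 4 sd of p(1-p)/n around 0.3
  expect_lt(abs(mean(tox$acute_censored) - 0.3), 4 * sqrt(0.3 * 0.7 / 600))
})

test_that("salt labels are distinct, map back to the ai, and aggregate away", {
  expect_identical(generate_salt_labels("glyphosate", 1), "glyphosate")
  labs <- generate_salt_labels("glyphosate", 7, seed = 1)
  expect_length(unique(labs), 7L)
  expect_true(all(startsWith(labs, "glyphosate ")))

  cfg <- tiny_sim_config(seed = 2, noise_sd = 0, n_labels_per_ai = 3L)
  sim <- generate_survey_data(cfg)
  expect_equal(nrow(sim$mapping), 4L * 3L)
  agg <- aggregate_by_ai(sim$use, sim$mapping)
  expect_equal(length(unique(agg$ai)), 4L)  # exactly n_ais survive
  expect_equal(nrow(agg), 4L * 10L)
})

test_that("zero-noise worlds are recovered exactly by the pipeline", {
  cfg <- tiny_sim_config(seed = 5, noise_sd = 0, at_slope = 0.09,
                         n_labels_per_ai = 2L)
  sim <- generate_survey_data(cfg)
  agg <- aggregate_by_ai(sim$use, sim$mapping)
  series <- total_area_treatments(agg, sim$area)
  expect_equal(series$total_at, sim$truth$at_series$total_at, tolerance = 1e-12)
  expect_equal(ols_slope(series$year, series$total_at)$estimate, 0.09,
               tolerance = 1e-12)
  for (ep in c("chronic", "acute")) {
    hq <- hazard_table(agg, sim$area, sim$toxicity, ep)$hq
    want <- sim$truth$hq[sim$truth$hq$endpoint == ep, ]
    expect_equal(hq$hq, want$hq, tolerance = 1e-12)
  }
})

test_that("dominance weights surface as contribution shares under flat toxicity and rates", {
  w <- c(0.6, 0.25, 0.1, 0.05)
  cfg <- simulation_config(
    seed = 4, noise_sd = 0, n_ai_pool = 6L,
    rate_range = c(0.5, 0.5), noel_range = c(10, 10),
    ld50_range = c(3000, 3000), censor_prob = 0,
    crops = list(list(name = "maize", years = 1990:1995, n_ais = 4L,
                      at_baseline = 2, at_slope = 0, area = 1000,
                      dominance_weights = w)))
  sim <- generate_survey_data(cfg)
  agg <- aggregate_by_ai(sim$use, sim$mapping)
  res <- hazard_quotient(agg[agg$year == 1990, ], sim$area, sim$toxicity,
                         "chronic")
  got <- res$contributions$share_pct[order(-res$contributions$share_pct)]
  expect_equal(got, 100 * sort(w, decreasing = TRUE), tolerance = 1e-9)
})

test_that("noisy amounts stay unbiased: mean of log-noise multipliers is near exp(sd^2/2)", {
  cfg <- tiny_sim_config(seed = 10, noise_sd = 0.2)
  cfg0 <- tiny_sim_config(seed = 10, noise_sd = 0)
  noisy <- generate_survey_data(cfg)$use$amount_applied
  clean <- generate_survey_data(cfg0)$use$amount_applied
  ratio <- noisy / clean
  expect_true(all(ratio > 0))
  expect_lt(abs(mean(log(ratio))), 4 * 0.2 / sqrt(length(ratio)))
})
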