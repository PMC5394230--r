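# Fixtures are built in code at test time; nothing binary ships with the
# package.

write_csv_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

make_profiles <- function(ai, acute_ld50, chronic_noel,
                          acute_censored = FALSE, wssa_group = "0") {
  data.frame(ai = ai, acute_ld50 = acute_ld50,
             acute_censored = rep_len(acute_censored, length(ai)),
             chronic_noel = chronic_noel,
             wssa_group = rep_len(wssa_group, length(ai)),
             stringsAsFactors = FALSE)
}

make_use <- function(crop, year, label, amount, rate) {
  data.frame(crop = crop, year = as.integer(year), ingredient_label = label,
             amount_applied = amount, avg_rate = rate, stringsAsFactors = FALSE)
}

make_areas <- function(crop, year, area) {
  data.frame(crop = crop, year = as.integer(year), planted_area = area,
             stringsAsFactors = FALSE)
}

# Small single-crop world for fast parameterised tests.
tiny_sim_config <- function(seed = 1L, noise_sd = 0, at_slope = 0.05,
                            at_baseline = 1, n_ais = 4L, years = 1990:1999,
                            ...) {
  simulation_config(
    seed = seed, noise_sd = noise_sd, n_ai_pool = 10L,
    crops = list(list(name = "maize", years = years, n_ais = n_ais,
                      at_baseline = at_baseline, at_slope = at_slope,
                      area = 1000)),
    ...)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
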