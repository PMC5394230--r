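one_crop_year <- function(ais, amounts_kg, area_ha = 1000) {
  list(records = data.frame(crop = "maize", year = 2014L, ai = ais,
                            amount_applied = amounts_kg,
                            avg_rate = 1, stringsAsFactors = FALSE),
       areas = make_areas("maize", 2014, area_ha))
}

test_that("censor_ld50 substitutes bounds conservatively and flags them", {
  got <- censor_ld50(c(">5,000", "112", "3556", "> 9000"))
  expect_equal(got$value, c(5000, 112, 3556, 9000))
  expect_equal(got$censored, c(TRUE, FALSE, FALSE, TRUE))
  expect_error(censor_ld50(">0"), class = "herbtrends_data_error")
  expect_error(censor_ld50("-5"), class = "herbtrends_data_error")
  expect_error(censor_ld50("abc"), class = "herbtrends_data_error")
})

test_that("hazard_quotient matches the worked sums and populates contributions", {
  profiles <- make_profiles(c("a", "b"), acute_ld50 = c(10, 100),
                            chronic_noel = c(50, 100))
  # one ai at 5000 mg/ha with toxicity 50 -> hq 100, share 100%
  w <- one_crop_year("a", amounts_kg = 5000 / 1e6 * 1000)
  res <- hazard_quotient(w$records, w$areas, profiles, "chronic")
  expect_equal(res$hq, 100)
  expect_equal(res$contributions$share_pct, 100)
  expect_equal(contribution_share(res, "a"), 100)
  expect_equal(contribution_share(res, "absent"), 0)

  # two ais: 1000 mg/ha / 10 + 500 mg/ha / 100 = 105
  w2 <- one_crop_year(c("a", "b"), c(1000, 500) / 1e6 * 1000)
  res2 <- hazard_quotient(w2$records, w2$areas, profiles, "acute")
  expect_equal(res2$hq, 105)
  expect_equal(res2$contributions$share_pct, c(100 * 100 / 105, 100 * 5 / 105))

  # empty record set: zero quotient, empty contributions
  res0 <- hazard_quotient(w$records[0, ], w$areas, profiles, "chronic")
  expect_equal(res0$hq, 0)
  expect_equal(nrow(res0$contributions), 0L)
  expect_error(contribution_share(res0, "a"), class = "herbtrends_data_error")
})

test_that("ais without toxicity profiles are excluded with a log record", {
  profiles <- make_profiles("a", 100, 10)
  w <- one_crop_year(c("a", "mystery"), c(1, 1))
  expect_message(res <- hazard_quotient(w$records, w$areas, profiles, "chronic"),
                 "mystery")
  expect_equal(res$excluded, "mystery")
  expect_equal(nrow(res$contributions), 1L)
  expect_error(hazard_quotient(w$records, make_areas("rice", 1990, 1), profiles),
               class = "herbtrends_data_error")
})

test_that("hazard properties: linearity, toxicity monotonicity, conservative censoring, shares sum to 100", {
  set.seed(9)
  for (rep in 1:5) {
    n <- 6L
    ais <- paste0("ai", seq_len(n))
    profiles <- make_profiles(ais, acute_ld50 = runif(n, 100, 9000),
                              chronic_noel = runif(n, 0.05, 500))
    w <- one_crop_year(ais, runif(n, 1, 50))
    for (ep in c("chronic", "acute")) {
      res <- hazard_quotient(w$records, w$areas, profiles, ep)
      expect_equal(sum(res$contributions$share_pct), 100, tolerance = 1e-9)

      doubled <- w$records; doubled$amount_applied <- 2 * doubled$amount_applied
      res2 <- hazard_quotient(doubled, w$areas, profiles, ep)
      expect_equal(res2$hq, 2 * res$hq)
      expect_equal(res2$contributions$share_pct, res$contributions$share_pct)
    }
    # raising one ai's toxicity value (less toxic) strictly lowers hq
    p2 <- profiles; p2$chronic_noel[1] <- p2$chronic_noel[1] * 3
    expect_lt(hazard_quotient(w$records, w$areas, p2, "chronic")$hq,
              hazard_quotient(w$records, w$areas, profiles, "chronic")$hq)
    # censored value 5000 never understates hazard vs any true LD50 > 5000
    p_cens <- profiles; p_cens$acute_ld50[1] <- 5000; p_cens$acute_censored[1] <- TRUE
    p_true <- profiles; p_true$acute_ld50[1] <- runif(1, 5000, 20000)
    expect_gte(hazard_quotient(w$records, w$areas, p_cens, "acute")$hq,
               hazard_quotient(w$records, w$areas, p_true, "acute")$hq)
  }
})

test_that("contribution shares split equally among identical partials", {
  profiles <- make_profiles(paste0("ai", 1:4), 100, 10)
  w <- one_crop_year(paste0("ai", 1:4), rep(5, 4))
  res <- hazard_quotient(w$records, w$areas, profiles, "acute")
  expect_equal(res$contributions$share_pct, rep(25, 4))
})

test_that("toxicity_percentile counts strictly-more-toxic others", {
  profiles <- make_profiles(paste0("ai", 1:5),
                            acute_ld50 = c(112, 500, 3556, 5000, 9000),
                            chronic_noel = c(5, 4, 3, 2, 1))
  # brute-force count over the 4 others: ai4 has 3 others with lower LD50
  expect_equal(toxicity_percentile(profiles, "ai4", "acute"), 75)
  expect_equal(toxicity_percentile(profiles, "ai1", "acute"), 0)  # most toxic
  expect_equal(toxicity_percentile(profiles, "ai1", "chronic"), 100)
  tied <- make_profiles(paste0("ai", 1:3), 100, 10)
  expect_equal(toxicity_percentile(tied, "ai2", "acute"), 0)  # ties aren't "more toxic"
  expect_error(toxicity_percentile(profiles, "nope", "acute"),
               class = "herbtrends_data_error")
})

test_that("toxicity_summary reports order statistics and the sub-500 count", {
  p3 <- make_profiles(paste0("a", 1:3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(toxicity_summary(p3, "acute")$median, 2)
  p4 <- make_profiles(paste0("a", 1:4), c(1, 2, 3, 4), 1)
  expect_equal(toxicity_summary(p4, "acute")$median, 2.5)  # midpoint convention
  p <- make_profiles(paste0("a", 1:6), c(112, 330, 499, 500, 3556, 9000), 1)
  s <- toxicity_summary(p, "acute")
  expect_equal(s$min, 112)
  expect_equal(s$max, 9000)
  expect_equal(s$n_below, 3L)  # strictly below the Category II boundary
  expect_error(toxicity_summary(p[0, ], "acute"), class = "herbtrends_data_error")
})
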