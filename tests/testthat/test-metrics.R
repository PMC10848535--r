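# lifetime metrics and derived summary ratios

test_that("survival-weighted sums match hand calculations", {
  S <- surv_curve(c(1, 0.8, 0.5))
  E <- cond_curve(c(0.6, 0.5, 0.25))
  expect_equal(as.numeric(expected_lifetime_employment(S, E)),
               0.6 + 0.4 + 0.125)
  N <- cond_curve(c(1000, 800), kind = "earnings")
  expect_equal(expected_lifetime_earnings(surv_curve(c(1, 0.5)), N), 1400)
  expect_equal(as.numeric(expected_lifetime_employment(
    S, cond_curve(c(0, 0, 0)))), 0)
  # step survival and employment: ELED = T months
  T <- 24
  S2 <- surv_curve(c(rep(1, T), rep(0, 11)))
  E2 <- cond_curve(c(rep(1, T), rep(0, 11)))
  expect_equal(as.numeric(expected_lifetime_employment(S2, E2)), T)
})

test_that("doubling earnings doubles ELN; masked months inside L error out", {
  S <- surv_curve(c(1, 0.9, 0.7))
  N <- cond_curve(c(100, 90, 50), kind = "earnings")
  N2 <- cond_curve(c(200, 180, 100), kind = "earnings")
  expect_equal(expected_lifetime_earnings(S, N2),
               2 * expected_lifetime_earnings(S, N))
  Nm <- cond_curve(c(100, NA, 50), kind = "earnings",
                   masked = c(FALSE, TRUE, FALSE))
  expect_error(expected_lifetime_earnings(S, Nm), "masked")
})

test_that("derived metrics reproduce the published male 25-34 row", {
  row <- derive_loss_metrics(tibble::tibble(
    sex = "male", age_band = "25-34", le_index = 28.7, le_ref = 47.9,
    led_index = 11.6, led_ref = 24.0, eln_index = 151637, eln_ref = 387970
  ))
  expect_equal(row$lled, 12.4)
  expect_equal(round(row$rel_lled_pct), 52)   # 51.7% rounds to 52%
  expect_equal(row$le_loss, 19.2)
  expect_equal(row$llep, 236333)
  expect_equal(round(row$rel_llep_pct), 61)
})

test_that("the annual-earnings ratio matches its published derivation", {
  row <- derive_loss_metrics(tibble::tibble(
    sex = "male", age_band = "35-40", le_index = 19.7, le_ref = 40.9,
    led_index = 8.1, led_ref = 18.1, eln_index = 109220, eln_ref = 297409
  ))
  expect_equal(row$annual_ratio_pct,
               100 * (109220 / 8.1) / (297409 / 18.1), tolerance = 1e-12)
  expect_equal(round(row$annual_ratio_pct, 1), 82.1)
})

test_that("annual ratio equals relative productivity over relative employment", {
  df <- derive_loss_metrics(published_cohort_estimates())
  lhs <- df$annual_ratio_pct
  rhs <- 100 * (df$eln_index / df$eln_ref) / (df$led_index / df$led_ref)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("identical cohorts give zero losses and a 100% annual ratio", {
  df <- derive_loss_metrics(tibble::tibble(
    sex = "male", age_band = "41-45", le_index = 30, le_ref = 30,
    led_index = 12, led_ref = 12, eln_index = 2e5, eln_ref = 2e5
  ))
  expect_equal(df$lled, 0)
  expect_equal(df$llep, 0)
  expect_equal(df$annual_ratio_pct, 100)
})

test_that("relative metrics are invariant to a currency rescaling", {
  base <- published_cohort_estimates()
  scaled <- dplyr::mutate(base, eln_index = eln_index * 31.95,
                          eln_ref = eln_ref * 31.95)
  a <- derive_loss_metrics(base)
  b <- derive_loss_metrics(scaled)
  expect_equal(b$rel_llep_pct, a$rel_llep_pct, tolerance = 1e-12)
  expect_equal(b$annual_ratio_pct, a$annual_ratio_pct, tolerance = 1e-12)
  expect_equal(b$llep, a$llep * 31.95, tolerance = 1e-12)
})

test_that("zero reference employment yields missing relative metrics", {
  df <- derive_loss_metrics(tibble::tibble(
    sex = "male", age_band = "61-64", le_index = 5, le_ref = 10,
    led_index = 0, led_ref = 0, eln_index = 0, eln_ref = 0
  ))
  expect_true(is.na(df$rel_lled_pct))
  expect_true(is.na(df$annual_ratio_pct))
})

test_that("strata summary extrema span the published ranges", {
  est <- derive_loss_metrics(published_cohort_estimates())
  s <- strata_summary(est)
  ov <- s$extrema[s$extrema$sex == "overall", ]
  lled <- ov[ov$metric == "rel_lled_pct", ]
  expect_equal(round(lled$min), 25)
  expect_equal(round(lled$max), 56)
  llep <- ov[ov$metric == "rel_llep_pct", ]
  expect_equal(round(llep$min), 32)
  expect_equal(round(llep$max), 66)
  male <- s$extrema[s$extrema$sex == "male" &
                      s$extrema$metric == "annual_ratio_pct", ]
  expect_equal(round(male$min, 1), 75.5)
  expect_equal(round(male$max, 1), 82.1)
})

test_that("a single stratum has min equal to max", {
  est <- derive_loss_metrics(published_cohort_estimates())[1, ]
  s <- strata_summary(est)
  expect_equal(s$extrema$min, s$extrema$max)
})

test_that("formatting rounds the way the summary tables print", {
  est <- derive_loss_metrics(published_cohort_estimates())
  fmt <- format_estimates(est)
  expect_equal(fmt$rel_lled[fmt$sex == "male" & fmt$age_band == "25-34"], "52%")
  expect_equal(fmt$annual_ratio[fmt$sex == "male" & fmt$age_band == "35-40"],
               "82.1%")
  expect_equal(fmt$led_index[fmt$sex == "female" & fmt$age_band == "61-64"],
               "0.6")
})

test_that("ELED from the curves equals mean individual employment months", {
  # fully observed simulated cohort: the Eq-1 algebraic identity is exact
  sc <- test_scenario(n = 300, seed = 21)
  sim <- simulate_index_cohort(sc, simulate_reference_tables(sc))
  cfg <- lifeprod_config(min_at_risk = 0)
  km <- kaplan_meier(sim$records)
  E <- conditional_curve(sim$records, "emratio", cfg)
  eled <- as.numeric(expected_lifetime_employment(km, E))
  indiv <- dplyr::summarise(dplyr::group_by(sim$records, patient_id),
                            months = sum(employed), .groups = "drop")
  expect_equal(eled, mean(indiv$months), tolerance = 1e-12)
  N <- conditional_curve(sim$records, "earnings",
                         lifeprod_config(min_at_risk = 0, wage_cap_usd = Inf))
  eln <- expected_lifetime_earnings(km, N)
  indiv_n <- dplyr::summarise(dplyr::group_by(sim$records, patient_id),
                              twd = sum(wage_twd), .groups = "drop")
  expect_equal(eln, mean(indiv_n$twd), tolerance = 1e-12)
})

test_that("LLED is exactly the difference of the two ELED sums", {
  S1 <- surv_curve(exp(-0.02 * (0:100)))
  S2 <- surv_curve(exp(-0.01 * (0:100)))
  E1 <- cond_curve(rep(0.5, 101))
  E2 <- cond_curve(rep(0.7, 101))
  N1 <- cond_curve(rep(500, 101), kind = "earnings")
  N2 <- cond_curve(rep(900, 101), kind = "earnings")
  cfg <- lifeprod_config()
  row <- lifetime_losses(S1, E1, N1, S2, E2, N2, "male", "41-45", cfg)
  expect_equal(row$lled, row$led_ref - row$led_index, tolerance = 1e-12)
  expect_equal(row$lled * 12,
               sum(S2$value * E2$value) - sum(S1$value * E1$value),
               tolerance = 1e-12)
  expect_equal(row$llep * cfg$twd_per_usd,
               sum(S2$value * N2$value) - sum(S1$value * N1$value),
               tolerance = 1e-9)
  expect_lte(row$led_index, row$le_index)
})
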