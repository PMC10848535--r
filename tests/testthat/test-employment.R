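# conditional curves, link transforms, link regression, extrapolation

test_that("conditional curves average over the alive set", {
  # 5 patients, one dies at month 2: denominators 5,5,4,4
  cohort <- dplyr::bind_rows(
    make_patient("p1", employed = c(1, 1, 1, 1), wage = c(1000, 1000, 1000, 1000)),
    make_patient("p2", employed = c(1, 0, 0, 0), wage = c(800, 0, 0, 0)),
    make_patient("p3", employed = c(0, 0, 1, 1), wage = c(0, 0, 500, 500)),
    make_patient("p4", employed = c(1, 1, 0), wage = c(2000, 2000, 0)),
    make_patient("p5", employed = c(0, 0, 0, 0), status = "censored")
  )
  cfg <- lifeprod_config(min_at_risk = 1)
  e <- conditional_curve(cohort, "emratio", cfg)
  expect_equal(e$value[e$t == 0], 3 / 5)
  expect_equal(e$value[e$t == 1], 2 / 5)
  expect_equal(e$value[e$t == 2], 2 / 4) # p4 died in month 2: out of the alive set
  n <- conditional_curve(cohort, "earnings", cfg)
  expect_equal(n$value[n$t == 0], (1000 + 800 + 0 + 2000 + 0) / 5)
  expect_equal(n$value[n$t == 2], (1000 + 0 + 500 + 0) / 4)
  expect_equal(n$value[n$t == 3], 0) # only the censored p5 remains alive at 3
})

test_that("earnings means include unemployed zeros", {
  cohort <- dplyr::bind_rows(
    make_patient("p1", employed = c(1, 1), wage = c(1000, 1000)),
    make_patient("p2", employed = c(0, 0), wage = c(0, 0))
  )
  n <- conditional_curve(cohort, "earnings", lifeprod_config(min_at_risk = 1))
  expect_equal(n$value[n$t == 0], 500)
})

test_that("months with fewer at-risk patients than the threshold are masked", {
  # 60 patients; 15 die in month 3, leaving 45 < 50 afterwards
  cohort <- dplyr::bind_rows(lapply(1:60, function(i) {
    f <- if (i <= 15) 4 else 8
    make_patient(sprintf("p%02d", i), employed = rep(1, f),
                 status = if (i <= 15) "dead" else "censored")
  }))
  e <- conditional_curve(cohort, "emratio", lifeprod_config(min_at_risk = 50))
  expect_false(any(e$masked[e$t <= 2]))
  expect_true(all(e$masked[e$t >= 4]))
  expect_true(all(is.na(e$value[e$masked])))
  expect_equal(e$at_risk[e$t == 4], 45)
})

test_that("wage caps bind before averaging", {
  cfg <- lifeprod_config(min_at_risk = 1, wage_cap_usd = 100, twd_per_usd = 10)
  cohort <- make_patient("p1", employed = c(1, 1), wage = c(5000, 400),
                         status = "censored")
  n <- conditional_curve(cohort, "earnings", cfg)
  expect_equal(n$value, c(1000, 400)) # 5000 capped at 100 USD * 10 TWD/USD
})

test_that("link transforms match closed forms and round-trip exactly", {
  expect_equal(link_transform(0.5, "logit"), 0)
  expect_equal(link_transform(0.82, "logit"), log(0.82 / 0.18),
               tolerance = 1e-12)
  expect_equal(link_inverse(link_transform(0.3, "logit"), "logit"), 0.3,
               tolerance = 1e-12)
  expect_equal(link_transform(2, "log"), log(2))
  expect_equal(link_inverse(link_transform(7, "log"), "log"), 7,
               tolerance = 1e-12)
  # clipping keeps transforms finite at the boundary
  expect_true(is.finite(link_transform(0, "logit")))
  expect_true(is.finite(link_transform(1, "logit")))
  expect_true(is.finite(link_transform(0, "log")))
  expect_error(link_transform(NaN, "logit"), "NaN")
})

test_that("a noiseless linear relation is recovered to machine precision", {
  FF <- 120L
  z <- 0.3 + 0.4 * sin((1:FF) / 15)            # log HR(t), varying
  ref <- cond_curve(rep(0.5, FF + 1))
  idx_val <- plogis(qlogis(0.5) + 0.3 - 0.5 * c(0, z))
  idx <- cond_curve(idx_val)
  fit <- fit_link_regression(idx, ref, hr_curve(exp(z)), "logit",
                             lifeprod_config())
  expect_equal(fit$beta0, 0.3, tolerance = 1e-10)
  expect_equal(fit$beta1, -0.5, tolerance = 1e-10)
  expect_lt(fit$sigma, 1e-10)
})

test_that("the closed-form OLS agrees with lm on noisy data", {
  set.seed(99)
  FF <- 60L
  z <- stats::rnorm(FF, 0.5, 0.3)
  ed <- 0.2 - 0.4 * z + stats::rnorm(FF, 0, 0.01)
  ref <- cond_curve(rep(0.6, FF + 1))
  idx <- cond_curve(plogis(qlogis(0.6) + c(0, ed)))
  cfg <- lifeprod_config(reg_start = 1)
  fit <- fit_link_regression(idx, ref, hr_curve(exp(z)), "logit", cfg)
  lmfit <- stats::lm(ed ~ z)
  expect_equal(fit$beta0, unname(coef(lmfit)[1]), tolerance = 1e-8)
  expect_equal(fit$beta1, unname(coef(lmfit)[2]), tolerance = 1e-8)
  expect_equal(fit$sigma, summary(lmfit)$sigma, tolerance = 1e-8)
  # recovered within 3 standard errors of the truth
  se <- summary(lmfit)$coefficients[, 2]
  expect_lt(abs(fit$beta0 - 0.2), 3 * se[1])
  expect_lt(abs(fit$beta1 + 0.4), 3 * se[2])
})

test_that("identical cohorts with a flat hazard ratio give zero coefficients", {
  ref <- cond_curve(rep(0.6, 101))
  idx <- cond_curve(rep(0.6, 101))
  expect_warning(
    fit <- fit_link_regression(idx, ref, hr_curve(rep(1, 100)), "logit",
                               lifeprod_config()),
    "zero variance"
  )
  expect_equal(fit$beta0, 0)
  expect_equal(fit$beta1, 0)
})

test_that("masked months never enter the regression", {
  FF <- 40L
  z <- seq(0.1, 0.9, length.out = FF)
  ref <- cond_curve(rep(0.5, FF + 1))
  vals <- plogis(0.2 - 0.3 * c(0, z))
  masked <- rep(FALSE, FF + 1)
  masked[c(25, 30)] <- TRUE
  poisoned <- vals
  poisoned[c(25, 30)] <- 0.99
  cfg <- lifeprod_config()
  f1 <- fit_link_regression(cond_curve(poisoned, masked = masked), ref,
                            hr_curve(exp(z)), "logit", cfg)
  f2 <- fit_link_regression(cond_curve(vals, masked = masked), ref,
                            hr_curve(exp(z)), "logit", cfg)
  expect_equal(f1$beta0, f2$beta0, tolerance = 1e-12)
  expect_equal(f1$beta1, f2$beta1, tolerance = 1e-12)
  expect_error(
    fit_link_regression(cond_curve(vals[1:5], masked = rep(TRUE, 5)), ref,
                        hr_curve(exp(z)), "logit", cfg),
    "3 usable"
  )
})

test_that("extrapolation reduces to the reference when both coefficients are 0", {
  L <- 200L
  ref <- cond_curve(plogis(seq(1, -1, length.out = L + 1)))
  hr <- hr_curve(rep(1.5, L))
  idx <- cond_curve(ref$value[1:61], F = 60L)
  fit <- structure(list(link = "logit", beta0 = 0, beta1 = 0,
                        window = c(a = 30, F = 60), n_points = 31,
                        sigma = 0), class = "link_fit")
  out <- extrapolate_conditional(ref, hr, fit, idx, lifeprod_config())
  expect_equal(out$value[out$t > 60], ref$value[ref$t > 60], tolerance = 1e-12)
  expect_equal(out$source[out$t <= 60], rep("observed", 61))
})

test_that("pointwise extrapolation formulas match hand-computed values", {
  # logit link: expit(logit(0.7311) - 0.2 + 0.5 * 0.8) ~ expit(1.2)
  L <- 70L
  ref_val <- rep(plogis(1), L + 1)
  hr <- hr_curve(rep(exp(0.8), L))
  idx <- cond_curve(rep(plogis(1), 62), F = 61L)
  fit <- structure(list(link = "logit", beta0 = -0.2, beta1 = 0.5,
                        window = c(a = 30, F = 61), n_points = 31, sigma = 0),
                   class = "link_fit")
  out <- extrapolate_conditional(cond_curve(ref_val), hr, fit, idx,
                                 lifeprod_config())
  expect_equal(out$value[out$t == 65], plogis(1.2), tolerance = 1e-10)
  # log link: 1000 * exp(-0.1 - 0.2 * 1.0) = 1000 * exp(-0.3)
  refn <- cond_curve(rep(1000, L + 1), kind = "earnings")
  idxn <- cond_curve(rep(1000, 62), kind = "earnings", F = 61L)
  hrn <- hr_curve(rep(exp(1), L))
  fitn <- structure(list(link = "log", beta0 = -0.1, beta1 = -0.2,
                         window = c(a = 30, F = 61), n_points = 31, sigma = 0),
                    class = "link_fit")
  outn <- extrapolate_conditional(refn, hrn, fitn, idxn, lifeprod_config())
  expect_equal(outn$value[outn$t == 65], 1000 * exp(-0.3), tolerance = 1e-8)
})

test_that("extrapolated curves respect their ranges and the retirement zero", {
  L <- 120L
  ref_val <- c(plogis(seq(2, 0, length.out = 100)), rep(0, L - 99 + 1 - 1))
  ref_val[100:(L + 1)] <- 0 # retirement from month 99 on
  ref <- cond_curve(ref_val)
  hr <- hr_curve(exp(stats::rnorm(L, 0, 2)))
  idx <- cond_curve(ref_val[1:41] * 0.8, F = 40L)
  fit <- structure(list(link = "logit", beta0 = 3, beta1 = 2,
                        window = c(a = 20, F = 40), n_points = 21, sigma = 0),
                   class = "link_fit")
  out <- extrapolate_conditional(ref, hr, fit, idx, lifeprod_config())
  expect_true(all(out$value >= 0 & out$value <= 1))
  expect_true(all(out$value[ref$value == 0] == 0))
})

test_that("with a positive slope a larger hazard ratio raises the extrapolation", {
  L <- 80L
  ref <- cond_curve(rep(0.6, L + 1))
  idx <- cond_curve(rep(0.6, 41), F = 40L)
  fit <- structure(list(link = "logit", beta0 = 0, beta1 = 0.7,
                        window = c(a = 20, F = 40), n_points = 21, sigma = 0),
                   class = "link_fit")
  lo <- extrapolate_conditional(ref, hr_curve(rep(1.2, L)), fit, idx,
                                lifeprod_config())
  hi <- extrapolate_conditional(ref, hr_curve(rep(2.0, L)), fit, idx,
                                lifeprod_config())
  expect_true(all(hi$value[hi$t > 40] > lo$value[lo$t > 40]))
  fit$beta1 <- -0.7
  lo2 <- extrapolate_conditional(ref, hr_curve(rep(1.2, L)), fit, idx,
                                 lifeprod_config())
  hi2 <- extrapolate_conditional(ref, hr_curve(rep(2.0, L)), fit, idx,
                                 lifeprod_config())
  expect_true(all(hi2$value[hi2$t > 40] < lo2$value[lo2$t > 40]))
})

test_that("masked follow-up months are filled with the model prediction", {
  L <- 60L
  ref <- cond_curve(rep(0.5, L + 1))
  hr <- hr_curve(rep(exp(0.4), L))
  masked <- rep(FALSE, 31)
  masked[29:31] <- TRUE
  vals <- rep(0.45, 31)
  vals[29:31] <- NA
  idx <- cond_curve(vals, F = 30L, masked = masked)
  fit <- structure(list(link = "logit", beta0 = 0.1, beta1 = 0.2,
                        window = c(a = 15, F = 30), n_points = 14, sigma = 0),
                   class = "link_fit")
  out <- extrapolate_conditional(ref, hr, fit, idx, lifeprod_config())
  pred <- plogis(qlogis(0.5) + 0.1 + 0.2 * 0.4)
  expect_equal(out$source[out$t %in% 28:30], c("filled", "filled", "filled"))
  expect_equal(out$value[out$t == 29], pred, tolerance = 1e-12)
  expect_equal(out$value[out$t == 20], 0.45)
})
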