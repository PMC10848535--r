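# Full estimation pipeline ---------------------------------------------------
#
# A stratum is compiled once into dense per-patient matrices so the whole
# pipeline (reference curves, KM, rolling extrapolation, hazard ratio, link
# fits, lifetime metrics) can be re-run cheaply under bootstrap case weights.

compile_stratum <- function(records, mortality, emratio, wages,
                            config = lifeprod_config()) {
  if (!all(c("onset_age", "dx_year") %in% names(records))) {
    records <- stratify_cohort(records)
  }
  ev <- event_table(records)
  profiles <- build_referent_profiles(records, mortality, config)
  # align the profile patient order with ev (both sorted by patient_id)
  stopifnot(identical(profiles$patients$patient_id, ev$patient_id))
  L <- profiles$L

  emat <- ref_expected_matrix(profiles, emratio)
  cap <- config$wage_cap_usd * config$twd_per_usd
  nmat <- ref_expected_matrix(profiles, wages, cap = cap)
  # past the retirement age the wage table no longer applies, like emratio
  att_age <- outer(profiles$profiles$onset_age, (0:L) %/% 12L, "+")
  nmat[att_age > config$retire_age] <- 0
  alive <- outer(profiles$T, 0:L, ">=")
  alive[, 1] <- TRUE

  FF <- as.integer(max(ev$time))
  n <- nrow(ev)
  irow <- match(records$patient_id, ev$patient_id)
  icol <- records$t + 1L
  keep <- records$t <= FF
  A <- matrix(0, n, FF + 1L)
  under_obs <- records$t < ev$time[irow] + (ev$status[irow] == 0L)
  sel <- keep & under_obs
  A[cbind(irow[sel], icol[sel])] <- 1
  AE <- matrix(0, n, FF + 1L)
  AE[cbind(irow[sel], icol[sel])] <- records$employed[sel]
  AW <- matrix(0, n, FF + 1L)
  AW[cbind(irow[sel], icol[sel])] <- pmin(records$wage_twd[sel], cap)

  list(
    ev = ev, profiles = profiles, L = L, FF = FF,
    surv_ref = profiles$surv, alive_ref = alive,
    AM_E = alive * emat, AM_N = alive * nmat,
    SM_E = profiles$surv * emat, SM_N = profiles$surv * nmat,
    A = A, AE = AE, AW = AW,
    sex = records$sex[1], age_band = as.character(records$age_band[1]),
    config = config
  )
}

wcurve <- function(t, num, denom, kind, FF, min_at_risk) {
  masked <- denom < min_at_risk
  value <- ifelse(masked, NA_real_, num / pmax(denom, .Machine$double.eps))
  value[!masked & denom == 0] <- 0
  new_curve(t, value, kind, F = FF, at_risk = denom, masked = masked)
}

estimate_stratum <- function(comp, weights = NULL) {
  config <- comp$config
  n <- nrow(comp$ev)
  w <- weights %||% rep(1, n)
  wsum <- sum(w)
  if (wsum <= 0) abort("stratum has no weight")
  pw <- profile_weights(comp$profiles, w)
  L <- comp$L

  # reference curves
  s_ref <- new_curve(0:L, as.vector(crossprod(comp$surv_ref, pw)) / wsum,
                     "survival", F = NA_integer_)
  denom_ref <- if (config$alive_rule == "survival") {
    as.vector(crossprod(comp$surv_ref, pw))
  } else {
    as.vector(crossprod(comp$alive_ref, pw))
  }
  num_e <- if (config$alive_rule == "survival") {
    as.vector(crossprod(comp$SM_E, pw))
  } else {
    as.vector(crossprod(comp$AM_E, pw))
  }
  num_n <- if (config$alive_rule == "survival") {
    as.vector(crossprod(comp$SM_N, pw))
  } else {
    as.vector(crossprod(comp$AM_N, pw))
  }
  e_ref <- new_curve(0:L, ifelse(denom_ref > 0, num_e / pmax(denom_ref, 1e-300), 0),
                     "emratio", F = NA_integer_)
  n_ref <- new_curve(0:L, ifelse(denom_ref > 0, num_n / pmax(denom_ref, 1e-300), 0),
                     "earnings", F = NA_integer_)

  # index survival: KM within follow-up, rolling extrapolation to L
  s_obs <- kaplan_meier(comp$ev, weights = w)
  s_index <- rolling_extrapolate(s_obs, s_ref, config)
  hr <- hazard_ratio_curve(s_index, s_ref, config)

  # index conditional curves within follow-up
  FFw <- curve_F(s_obs)
  M <- as.vector(crossprod(comp$A, w))[seq_len(FFw + 1L)]
  e_obs <- wcurve(0:FFw, as.vector(crossprod(comp$AE, w))[seq_len(FFw + 1L)],
                  M, "emratio", FFw, config$min_at_risk)
  n_obs <- wcurve(0:FFw, as.vector(crossprod(comp$AW, w))[seq_len(FFw + 1L)],
                  M, "earnings", FFw, config$min_at_risk)

  fit_e <- fit_link_regression(e_obs, e_ref, hr, "logit", config)
  fit_n <- fit_link_regression(n_obs, n_ref, hr, "log", config)
  e_index <- extrapolate_conditional(e_ref, hr, fit_e, e_obs, config)
  n_index <- extrapolate_conditional(n_ref, hr, fit_n, n_obs, config)

  est <- lifetime_losses(s_index, e_index, n_index, s_ref, e_ref, n_ref,
                         sex = comp$sex, age_band = comp$age_band,
                         config = config)
  list(
    estimates = est,
    curves = list(s_index = s_index, s_ref = s_ref, e_index = e_index,
                  e_ref = e_ref, n_index = n_index, n_ref = n_ref, hr = hr,
                  s_obs = s_obs, e_obs = e_obs, n_obs = n_obs),
    fits = list(emratio = fit_e, earnings = fit_n)
  )
}

#' Estimate lifetime employment and productivity losses for a cohort
#'
#' Runs the full pipeline per sex-by-age-band stratum: matched referent
#' curves from the rate tables, Kaplan-Meier survival within follow-up,
#' rolling extrapolation of the logit relative-survival ratio to the
#' lifetime horizon, the smoothed hazard-ratio curve, link regressions for
#' the conditional EMRATIO (logit) and conditional earnings (log), their
#' extrapolation beyond follow-up, and the lifetime metrics
#' ELED / ELN / LLED / LLEP with relative losses and annual-earnings ratios.
#'
#' @param records Eligible patient-month tibble (filters already applied).
#' @param mortality,emratio,wages Rate tables (annual mortality probability,
#'   employment ratio, population-average monthly wage in TWD).
#' @param config A [lifeprod_config()].
#' @return An object of class `"lifeprod_fit"`: `estimates` (one tibble row
#'   per stratum), per-stratum `strata` (curves and link fits), and the
#'   resolved `config`. Supports [tidy()], [glance()], [autoplot()].
#' @export
estimate_productivity <- function(records, mortality, emratio, wages,
                                  config = lifeprod_config()) {
  records <- stratify_cohort(records)
  keys <- dplyr::distinct(dplyr::as_tibble(records[c("sex", "age_band")]))
  keys <- dplyr::arrange(keys, .data$sex, .data$age_band)
  strata <- vector("list", nrow(keys))
  rows <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    sub <- records[records$sex == keys$sex[k] &
                     records$age_band == keys$age_band[k], , drop = FALSE]
    comp <- compile_stratum(sub, mortality, emratio, wages, config)
    res <- estimate_stratum(comp)
    strata[[k]] <- res
    rows[[k]] <- res$estimates
  }
  names(strata) <- paste(keys$sex, keys$age_band, sep = ":")
  structure(
    list(estimates = dplyr::bind_rows(rows), strata = strata, config = config),
    class = "lifeprod_fit"
  )
}

#' @export
print.lifeprod_fit <- function(x, ...) {
  cat(sprintf("<lifeprod_fit: %d strata>\n", nrow(x$estimates)))
  print(as.data.frame(format_estimates(x$estimates)), row.names = FALSE)
  invisible(x)
}
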