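# Synthetic cohort simulator -------------------------------------------------
#
# Generates reference rate tables (deterministic, smooth shapes) and index
# cohorts with known ground truth, emulating the structure of the national
# registry data the estimators are designed for: proportional excess
# mortality, a hump-shaped employment-ratio age profile depressed under
# disease, hump-shaped wages depressed under disease, retirement at 65.

#' Scenario configuration for the cohort simulator
#'
#' The defaults define the reference study conditions used throughout the
#' package's validation: a proportional excess-mortality multiplier of 2.5,
#' an employment penalty of 0.7 and a wage penalty of 0.8 for the index
#' cohort, Gompertz reference mortality by sex, an employment-ratio age
#' profile peaking in the early 50s, and wage age profiles peaking at 44
#' (male) / 50 (female). Diagnosis years span 2000-2017 and follow-up is
#' administratively cut at 210 months.
#'
#' @param n_per_stratum Patients per (sex, age-band) stratum.
#' @param sexes,age_bands Strata to generate.
#' @param years Diagnosis-year range (also the rate tables' year coverage).
#' @param theta Excess-hazard multiplier for the index cohort (>= 1).
#' @param emp_penalty Multiplier (0, 1] on the employment-ratio profile for
#'   index patients.
#' @param wage_penalty Multiplier (0, 1] on per-worker wages for index
#'   patients.
#' @param frailty_sdlog Log-sd of the individual lognormal wage frailty
#'   (mean 1).
#' @param persistence Month-to-month employment persistence in `[0, 1)`:
#'   probability that a patient follows the maximally persistent coupling to
#'   the target profile rather than an independent redraw. Either branch
#'   leaves the marginal employment ratio exactly on target.
#' @param follow_up Administrative follow-up cutoff in months.
#' @param horizon_age Everyone is treated as dead by this age.
#' @param retire_age Employment and wages are 0 from this attained age on.
#' @param gompertz Per-sex Gompertz parameters `c(b, g)`: annual hazard at
#'   age `a` is `b * exp(g * (a - 25))`.
#' @param mort_improvement Proportional annual decline of mortality with
#'   calendar year.
#' @param em_peak,em_peak_age,em_sigma_rise,em_sigma_fall Employment-ratio
#'   hump: per-sex peak level, peak age, and Gaussian widths below/above the
#'   peak.
#' @param wage_peak_twd,wage_peak_age,wage_sigma_rise,wage_sigma_fall
#'   Population-average wage hump (TWD/month), same parameterisation.
#' @param seed Simulation seed.
#' @return A named list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_per_stratum = 5000,
                            sexes = c("male", "female"),
                            age_bands = AGE_BANDS$band,
                            years = 2000:2017,
                            theta = 2.5,
                            emp_penalty = 0.7,
                            wage_penalty = 0.8,
                            frailty_sdlog = 0.5,
                            persistence = 0.9,
                            follow_up = 210,
                            horizon_age = 100,
                            retire_age = 65,
                            gompertz = list(male = c(b = 6e-4, g = 0.085),
                                            female = c(b = 3e-4, g = 0.090)),
                            mort_improvement = 0.005,
                            em_peak = c(male = 0.85, female = 0.78),
                            em_peak_age = 52,
                            em_sigma_rise = 30,
                            em_sigma_fall = 10,
                            wage_peak_twd = c(male = 42000, female = 31950),
                            wage_peak_age = c(male = 44, female = 50),
                            wage_sigma_rise = 25,
                            wage_sigma_fall = c(male = 12, female = 8),
                            seed = 1L) {
  stopifnot(
    theta >= 1, emp_penalty > 0, emp_penalty <= 1,
    wage_penalty > 0, wage_penalty <= 1, n_per_stratum >= 1,
    persistence >= 0, persistence < 1, follow_up >= 1,
    all(age_bands %in% AGE_BANDS$band), all(sexes %in% c("male", "female"))
  )
  structure(
    list(n_per_stratum = as.integer(n_per_stratum), sexes = sexes,
         age_bands = age_bands, years = years, theta = theta,
         emp_penalty = emp_penalty, wage_penalty = wage_penalty,
         frailty_sdlog = frailty_sdlog, persistence = persistence,
         follow_up = as.integer(follow_up), horizon_age = horizon_age,
         retire_age = retire_age, gompertz = gompertz,
         mort_improvement = mort_improvement, em_peak = em_peak,
         em_peak_age = em_peak_age, em_sigma_rise = em_sigma_rise,
         em_sigma_fall = em_sigma_fall, wage_peak_twd = wage_peak_twd,
         wage_peak_age = wage_peak_age, wage_sigma_rise = wage_sigma_rise,
         wage_sigma_fall = wage_sigma_fall, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

# asymmetric Gaussian hump over age
hump <- function(age, peak, peak_age, sigma_rise, sigma_fall) {
  sigma <- ifelse(age <= peak_age, sigma_rise, sigma_fall)
  peak * exp(-0.5 * ((age - peak_age) / sigma)^2)
}

#' Simulate the reference rate tables
#'
#' Deterministic smooth tables over the scenario's calendar years, ages
#' 25-100 and both sexes: Gompertz annual mortality with a mild calendar
#' improvement, a hump-shaped employment ratio (0 from the retirement age
#' on), and a hump-shaped population-average wage (also 0 in retirement,
#' since it is employment-weighted).
#'
#' @param scenario A [scenario_config()].
#' @return A list of three `rate_table`s: `mortality`, `emratio`, `wage`.
#' @export
simulate_reference_tables <- function(scenario = scenario_config()) {
  grid <- tidyr::expand_grid(year = scenario$years, age = 25:100,
                             sex = scenario$sexes)
  y0 <- min(scenario$years)
  gp <- do.call(rbind, scenario$gompertz[grid$sex])
  haz <- gp[, "b"] * exp(gp[, "g"] * (grid$age - 25)) *
    (1 - scenario$mort_improvement)^(grid$year - y0)
  mortality <- rate_table(
    dplyr::mutate(grid, value = 1 - exp(-haz)), "mortality"
  )
  em <- hump(grid$age, scenario$em_peak[grid$sex], scenario$em_peak_age,
             scenario$em_sigma_rise, scenario$em_sigma_fall)
  em[grid$age >= scenario$retire_age] <- 0
  emratio <- rate_table(dplyr::mutate(grid, value = pmin(em, 1)), "emratio")
  wg <- hump(grid$age, scenario$wage_peak_twd[grid$sex],
             scenario$wage_peak_age[grid$sex], scenario$wage_sigma_rise,
             scenario$wage_sigma_fall[grid$sex])
  wg[grid$age >= scenario$retire_age] <- 0
  wage <- rate_table(dplyr::mutate(grid, value = wg), "wage")
  list(mortality = mortality, emratio = emratio, wage = wage)
}

#' Simulate an index cohort with full lifetime trajectories and ground truth
#'
#' Death months are drawn from the reference life-table hazard multiplied by
#' the excess-hazard multiplier `theta` (with certain death by
#' `horizon_age`). Monthly employment follows a two-state chain whose
#' marginal matches the reference employment-ratio profile deflated by the
#' disease employment penalty exactly; wages of employed months are the
#' per-worker reference wage (population-average wage over employment ratio)
#' times the disease wage penalty and an individual lognormal frailty.
#' Employment and wages are 0 in the death month and from the retirement age
#' on.
#'
#' Ground truth per stratum is computed from the untruncated cohort: index
#' quantities by direct averaging of the full trajectories, reference
#' quantities by exact expectation over the matched life-table survival
#' curves.
#'
#' @param scenario A [scenario_config()].
#' @param tables Output of [simulate_reference_tables()].
#' @param seed Seed; defaults to the scenario seed.
#' @return A list: `records` (patient-month tibble over full lifetimes, all
#'   `end_status = "dead"`) and `truth` (per-stratum tibble of true LE, ELED
#'   and ELN for both cohorts plus LLED and LLEP; months and TWD).
#' @export
simulate_index_cohort <- function(scenario = scenario_config(),
                                  tables = simulate_reference_tables(scenario),
                                  seed = NULL) {
  set.seed(seed %||% scenario$seed)
  mortality <- cache_rate_index(tables$mortality)
  emratio <- cache_rate_index(tables$emratio)
  wage <- cache_rate_index(tables$wage)

  strata <- tidyr::expand_grid(sex = scenario$sexes, band = scenario$age_bands)
  rec_parts <- vector("list", nrow(strata))
  truth_parts <- vector("list", nrow(strata))
  for (k in seq_len(nrow(strata))) {
    s <- strata$sex[k]
    band <- AGE_BANDS[AGE_BANDS$band == strata$band[k], ]
    n <- scenario$n_per_stratum
    age <- sample(band$lo:band$hi, n, replace = TRUE)
    dx_year <- sample(scenario$years, n, replace = TRUE)
    dx_m <- sample(0:11, n, replace = TRUE)
    dx_ym <- dx_year * 12L + dx_m
    birth_ym <- dx_ym - age * 12L - sample(0:11, n, replace = TRUE)

    sim <- simulate_stratum(s, age, dx_year, scenario, mortality, emratio, wage)
    m <- sim$death_month

    fup <- m + 1L
    rows <- sum(fup)
    idx <- rep.int(seq_len(n), fup)
    tt <- sequence(fup) - 1L
    pid <- sprintf("%s_%s_%05d", substr(s, 1, 1), band$band, seq_len(n))
    end_ym <- dx_ym + m
    rec_parts[[k]] <- tibble::tibble(
      patient_id = pid[idx], sex = s,
      birth_ym = birth_ym[idx], dx_ym = dx_ym[idx],
      end_ym = end_ym[idx], end_status = "dead",
      t = tt,
      employed = sim$emp[cbind(idx, tt + 1L)],
      wage_twd = sim$wage[cbind(idx, tt + 1L)]
    )
    truth_parts[[k]] <- tibble::tibble(
      sex = s, age_band = band$band, n = n,
      le_index_mo = mean(m) - 0.5,
      le_ref_mo = sim$ref_le_mo,
      eled_index_mo = mean(sim$emp_months),
      eled_ref_mo = sim$ref_eled_mo,
      eln_index_twd = mean(sim$earn_twd),
      eln_ref_twd = sim$ref_eln_twd
    )
  }
  truth <- dplyr::bind_rows(truth_parts)
  truth$lled_mo <- truth$eled_ref_mo - truth$eled_index_mo
  truth$llep_twd <- truth$eln_ref_twd - truth$eln_index_twd
  list(records = dplyr::bind_rows(rec_parts), truth = truth)
}

# one stratum: death months, employment/wage matrices, per-patient sums and
# exact reference expectations
simulate_stratum <- function(sex, age, dx_year, scenario,
                             mortality, emratio, wage) {
  n <- length(age)
  Lmax <- (scenario$horizon_age - min(age)) * 12L
  prof <- dplyr::distinct(tibble::tibble(age = age, dx_year = dx_year))
  prof_of <- match(paste(age, dx_year), paste(prof$age, prof$dx_year))
  np <- nrow(prof)
  n_years <- (Lmax - 1L) %/% 12L + 1L

  # per-profile monthly reference hazard over the full horizon
  grid_k <- rep(0:(n_years - 1L), times = np)
  grid_p <- rep(seq_len(np), each = n_years)
  q <- rate_lookup(mortality, prof$dx_year[grid_p] + grid_k,
                   prof$age[grid_p] + grid_k, sex, carry_forward = TRUE)
  hq <- matrix(-log(pmax(1 - q, 1e-12)) / 12, nrow = np, byrow = TRUE)
  hm <- hq[, rep(seq_len(n_years), each = 12L), drop = FALSE][, 1:Lmax, drop = FALSE]
  cumhaz <- t(apply(hm, 1, cumsum))
  if (Lmax == 1L) cumhaz <- matrix(hm, nrow = np)
  surv_ref <- exp(-cumhaz)          # P(referent survives beyond month t)
  surv_idx <- exp(-scenario$theta * cumhaz)

  # death month: first t with S_index(t) < U, certain death at the horizon
  U <- stats::runif(n)
  L_i <- (scenario$horizon_age - age) * 12L
  survived <- integer(n)
  for (p in seq_len(np)) {
    sel <- prof_of == p
    # months survived = #{t: S(t) >= U}; the row is non-increasing
    survived[sel] <- Lmax - findInterval(U[sel], rev(surv_idx[p, ]))
  }
  death_month <- pmin(survived + 1L, L_i)

  # per-profile monthly target profiles over t = 0..Lmax
  ky <- rep(0:(Lmax %/% 12L), times = np)
  kp <- rep(seq_len(np), each = Lmax %/% 12L + 1L)
  e_ref <- rate_lookup(emratio, prof$dx_year[kp] + ky, prof$age[kp] + ky, sex,
                       carry_forward = TRUE, retire_age = scenario$retire_age)
  w_ref <- rate_lookup(wage, prof$dx_year[kp] + ky, prof$age[kp] + ky, sex,
                       carry_forward = TRUE)
  nyy <- Lmax %/% 12L + 1L
  e_mat <- matrix(e_ref, nrow = np, byrow = TRUE)[, rep(seq_len(nyy), each = 12L),
                                                  drop = FALSE][, 1:(Lmax + 1L), drop = FALSE]
  w_mat <- matrix(w_ref, nrow = np, byrow = TRUE)[, rep(seq_len(nyy), each = 12L),
                                                  drop = FALSE][, 1:(Lmax + 1L), drop = FALSE]
  # retirement truncation along attained age, per profile
  att <- outer(prof$age, (0:Lmax) %/% 12L, "+")
  e_mat[att >= scenario$retire_age] <- 0
  w_mat[att >= scenario$retire_age] <- 0
  ws_mat <- ifelse(e_mat > 0, w_mat / pmax(e_mat, 1e-12), 0) # per-worker wage

  # two-state employment chain with exact marginals pi_t = e * penalty
  kappa <- scenario$persistence
  pi_mat <- e_mat * scenario$emp_penalty
  tmax <- max(death_month)
  emp <- matrix(0L, n, tmax + 1L)
  pi_prev <- pi_mat[cbind(prof_of, 1L)]
  e_prev <- as.integer(stats::runif(n) < pi_prev)
  emp[, 1L] <- e_prev
  if (tmax >= 1L) {
    for (tt in 1:tmax) {
      pi_t <- pi_mat[cbind(prof_of, tt + 1L)]
      up <- pi_t >= pi_prev
      # maximal coupling toward the new marginal
      hire_p <- ifelse(up, (pi_t - pi_prev) / pmax(1 - pi_prev, 1e-12), 0)
      stay_p <- ifelse(up, 1, pi_t / pmax(pi_prev, 1e-12))
      u1 <- stats::runif(n)
      coupled <- ifelse(e_prev == 1L, as.integer(u1 < stay_p),
                        as.integer(u1 < hire_p))
      fresh <- as.integer(stats::runif(n) < pi_t)
      e_new <- ifelse(stats::runif(n) < kappa, coupled, fresh)
      emp[, tt + 1L] <- e_new
      e_prev <- e_new
      pi_prev <- pi_t
    }
  }
  # no employment in the death month, none after
  col <- col(emp)
  emp[col > death_month] <- 0L
  emp[cbind(seq_len(n), death_month + 1L)] <- 0L

  frailty <- stats::rlnorm(n, meanlog = -scenario$frailty_sdlog^2 / 2,
                           sdlog = scenario$frailty_sdlog)
  wg <- emp * ws_mat[cbind(rep(prof_of, tmax + 1L), as.vector(col))] *
    scenario$wage_penalty * frailty
  wg <- matrix(wg, n, tmax + 1L)

  # exact reference expectations per profile, averaged over patients
  pw <- tabulate(prof_of, nbins = np)
  s0 <- cbind(1, surv_ref)               # t = 0..Lmax
  # per-patient horizon: zero out months beyond age 100 (survival is already
  # essentially 0 there; the explicit cut keeps the truth exact)
  beyond <- outer(prof$age, 0:Lmax, function(a, t) t > (scenario$horizon_age - a) * 12L)
  s0[beyond] <- 0
  ref_le_mo <- sum(pw * rowSums(s0[, -1, drop = FALSE])) / n + 0.5
  ref_eled_mo <- sum(pw * rowSums(s0 * e_mat)) / n
  ref_eln_twd <- sum(pw * rowSums(s0 * w_mat)) / n

  list(
    death_month = death_month,
    emp = emp, wage = wg,
    emp_months = rowSums(emp),
    earn_twd = rowSums(wg),
    ref_le_mo = ref_le_mo, ref_eled_mo = ref_eled_mo, ref_eln_twd = ref_eln_twd
  )
}

#' Truncate a simulated cohort at an administrative follow-up cutoff
#'
#' Trajectories are cut at month `F`; patients alive at `F` become censored
#' at `F`. No information after `F` is retained, which recreates the
#' estimation problem the extrapolation pipeline solves. Idempotent.
#'
#' @param records Patient-month tibble with full lifetimes.
#' @param F Follow-up cutoff in months (>= 1).
#' @return The truncated patient-month tibble.
#' @export
truncate_followup <- function(records, F) {
  stopifnot(F >= 1)
  F <- as.integer(F)
  out <- records[records$t <= F, , drop = FALSE]
  cens <- out$end_ym - out$dx_ym > F
  out$end_status[cens] <- "censored"
  out$end_ym[cens] <- out$dx_ym[cens] + F
  out
}
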