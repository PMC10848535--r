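# Matched reference cohort --------------------------------------------------
#
# Each index patient is matched to a deterministic referent of the same sex,
# onset age and diagnosis year. The referent's survival comes from the
# national life table (annual probability q converted to a constant monthly
# hazard -log(1-q)/12 within each life-table year); employment and earnings
# come from the (year, age, sex) rate tables looked up along the referent's
# attained age and calendar year. Referents are expected-value constructs,
# not sampled individuals, so all reference curves are deterministic.

#' Build matched referent profiles
#'
#' One referent per index patient, matched on sex, onset age (whole years)
#' and diagnosis year. Patients sharing a (sex, age, year) combination share
#' a profile; profile-level survival curves are stored once.
#'
#' @param records Stratified patient-month tibble (see [stratify_cohort()]),
#'   or any tibble with one row per patient and columns `patient_id`, `sex`,
#'   `onset_age`, `dx_year`.
#' @param mortality A mortality `rate_table` (annual death probabilities).
#' @param config A [lifeprod_config()].
#' @return An object of class `"referent_profiles"`: patient-to-profile map,
#'   per-profile monthly survival matrix on `0..L`, and life expectancies
#'   `T_i` (months, the sum of monthly survival probabilities over the
#'   horizon).
#' @export
build_referent_profiles <- function(records, mortality, config = lifeprod_config()) {
  stopifnot(inherits(mortality, "rate_table"), rate_kind(mortality) == "mortality")
  if (!all(c("onset_age", "dx_year") %in% names(records))) {
    records <- stratify_cohort(records)
  }
  pat <- dplyr::distinct(records, .data$patient_id, .data$sex,
                         .data$onset_age, .data$dx_year)
  pat <- dplyr::arrange(pat, .data$patient_id)
  if (nrow(pat) == 0) abort("no patients to build referents for")
  L <- horizon_for(min(pat$onset_age), config)
  prof <- dplyr::distinct(pat, .data$sex, .data$onset_age, .data$dx_year)
  prof$profile_id <- seq_len(nrow(prof))
  pat <- dplyr::left_join(pat, prof,
                          by = c("sex", "onset_age", "dx_year"))
  mortality <- cache_rate_index(mortality)

  n_years <- (L - 1L) %/% 12L + 1L
  # annual q for each profile x year-offset, then spread over months
  grid <- tidyr::expand_grid(profile_id = prof$profile_id, k = 0:(n_years - 1L))
  grid <- dplyr::left_join(grid, prof, by = "profile_id")
  q <- rate_lookup(mortality, grid$dx_year + grid$k, grid$onset_age + grid$k,
                   grid$sex, carry_forward = config$carry_forward)
  h_month <- -log(pmax(1 - q, 1e-12)) / 12
  # grid is profile-major, so fill by row
  hmat <- matrix(h_month, nrow = nrow(prof), ncol = n_years, byrow = TRUE)
  hm <- hmat[, rep(seq_len(n_years), each = 12L), drop = FALSE][, 1:L, drop = FALSE]
  surv <- cbind(1, exp(-t(apply(hm, 1, cumsum))))
  if (L == 1L) surv <- cbind(1, exp(-hm)) # apply() degenerates for 1 column
  Ti <- rowSums(surv[, -1, drop = FALSE])

  structure(
    list(patients = pat, profiles = prof, surv = surv, T = Ti, L = L,
         config = config),
    class = "referent_profiles"
  )
}

#' @export
print.referent_profiles <- function(x, ...) {
  cat(sprintf("<referent_profiles: %d patients, %d distinct profiles, horizon %d months>\n",
              nrow(x$patients), nrow(x$profiles), x$L))
  invisible(x)
}

# patient-level weights -> profile-level weights (default: one per patient)
profile_weights <- function(profiles, weights = NULL) {
  pat <- profiles$patients
  if (is.null(weights)) weights <- rep(1, nrow(pat))
  stopifnot(length(weights) == nrow(pat))
  w <- numeric(nrow(profiles$profiles))
  agg <- rowsum(weights, pat$profile_id)
  w[as.integer(rownames(agg))] <- agg[, 1]
  w
}

#' Reference-cohort survival curve
#'
#' The average of the matched referents' life-table survival curves,
#' optionally with patient-level case weights (used by the bootstrap).
#'
#' @param profiles A `referent_profiles` object.
#' @param weights Optional per-patient weights (order of `profiles$patients`).
#' @return A survival `lifeprod_curve` on `0..L`.
#' @export
reference_survival <- function(profiles, weights = NULL) {
  w <- profile_weights(profiles, weights)
  if (sum(w) <= 0) abort("reference survival needs a non-empty cohort")
  s <- as.vector(crossprod(profiles$surv, w)) / sum(w)
  new_curve(0:profiles$L, s, "survival", F = NA_integer_,
            observed = rep(TRUE, profiles$L + 1L))
}

# (profiles x months) matrix of rate-table lookups along attained age/year;
# cap is an optional ceiling applied to each looked-up value
ref_expected_matrix <- function(profiles, table, cap = Inf) {
  config <- profiles$config
  prof <- profiles$profiles
  L <- profiles$L
  n_years <- L %/% 12L + 1L
  grid <- tidyr::expand_grid(profile_id = prof$profile_id, k = 0:(n_years - 1L))
  grid <- dplyr::left_join(grid, prof, by = "profile_id")
  v <- rate_lookup(cache_rate_index(table), grid$dx_year + grid$k,
                   grid$onset_age + grid$k, grid$sex,
                   carry_forward = config$carry_forward,
                   retire_age = config$retire_age)
  v <- pmin(v, cap)
  vmat <- matrix(v, nrow = nrow(prof), ncol = n_years, byrow = TRUE)
  vmat[, rep(seq_len(n_years), each = 12L), drop = FALSE][, 1:(L + 1L), drop = FALSE]
}

#' Expected employment trajectory of one referent
#'
#' Looks up the employment-ratio table along the referent's attained age and
#' calendar year: the value at month `t` is
#' `e(y + floor(t/12), a + floor(t/12), s)`, defined for `0 <= t <= T_i`.
#'
#' @param profiles A `referent_profiles` object.
#' @param patient_id The matched patient.
#' @param emratio An employment-ratio `rate_table`.
#' @return A tibble with `t` and `value` over `0..floor(T_i)`.
#' @export
expected_employment_trajectory <- function(profiles, patient_id, emratio) {
  row <- profiles$patients[profiles$patients$patient_id == patient_id, ]
  if (nrow(row) != 1) abort(sprintf("unknown patient_id '%s'", patient_id))
  p <- row$profile_id
  emat <- ref_expected_matrix(profiles, emratio)
  Ti <- floor(profiles$T[p])
  tt <- 0:min(Ti, profiles$L)
  tibble::tibble(t = tt, value = emat[p, tt + 1L])
}

ref_conditional <- function(profiles, table, kind, weights = NULL, cap = Inf) {
  w <- profile_weights(profiles, weights)
  emat <- ref_expected_matrix(profiles, table, cap = cap)
  L <- profiles$L
  if (profiles$config$alive_rule == "survival") {
    denom <- as.vector(crossprod(profiles$surv, w))
    numer <- as.vector(crossprod(profiles$surv * emat, w))
  } else {
    # Eq-3 rule: a referent counts while t <= T_i
    alive <- outer(profiles$T, 0:L, ">=")
    alive[, 1] <- TRUE # every referent is alive at the diagnosis month
    denom <- as.vector(crossprod(alive, w))
    numer <- as.vector(crossprod(alive * emat, w))
  }
  val <- ifelse(denom > 0, numer / pmax(denom, .Machine$double.eps), 0)
  new_curve(0:L, val, kind, F = NA_integer_,
            at_risk = denom, masked = rep(FALSE, L + 1L))
}

#' Reference conditional EMRATIO curve
#'
#' The average expected employment status of the referents still counted as
#' alive at month `t`: the numerator sums the table lookups of referents with
#' `t <= T_i` and the denominator counts those referents (0 by convention
#' when none remain).
#'
#' @inheritParams expected_employment_trajectory
#' @param weights Optional per-patient case weights.
#' @return An emratio `lifeprod_curve` on `0..L`.
#' @export
reference_emratio <- function(profiles, emratio, weights = NULL) {
  stopifnot(rate_kind(emratio) == "emratio")
  ref_conditional(profiles, emratio, "emratio", weights)
}

#' Reference conditional average-earnings curve
#'
#' As [reference_emratio()], averaging the population-average wage table
#' (already employment-weighted: total salary over the civilian population,
#' so it is not multiplied by the employment ratio). The configured wage cap
#' is applied to each lookup.
#'
#' @inheritParams reference_emratio
#' @param wages A wage `rate_table` (currency per month, TWD).
#' @return An earnings `lifeprod_curve` on `0..L`.
#' @export
reference_earnings <- function(profiles, wages, weights = NULL) {
  stopifnot(rate_kind(wages) == "wage")
  cfg <- profiles$config
  cap <- cfg$wage_cap_usd * cfg$twd_per_usd
  cv <- ref_conditional(profiles, wages, "earnings", weights, cap = cap)
  # earnings are 0 from the attained retirement age on, like employment
  emat0 <- ref_expected_matrix(profiles, wages, cap = cap)
  age_zero <- outer(profiles$profiles$onset_age, (0:profiles$L) %/% 12L, "+") >
    cfg$retire_age
  if (any(age_zero & emat0 > 0)) {
    w <- profile_weights(profiles, weights)
    emat0[age_zero] <- 0
    alive <- outer(profiles$T, 0:profiles$L, ">=")
    alive[, 1] <- TRUE
    denom <- as.vector(crossprod(alive, w))
    numer <- as.vector(crossprod(alive * emat0, w))
    cv$value <- ifelse(denom > 0, numer / pmax(denom, .Machine$double.eps), 0)
  }
  cv
}
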