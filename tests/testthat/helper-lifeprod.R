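# shared fixture builders (all fixtures are generated in code)

# one patient's monthly rows from compact arguments
make_patient <- function(id, sex = "male", birth = "1960-01", dx = "2005-01",
                         employed = c(1, 1, 0), wage = NULL,
                         status = "dead", cancer = 0, pre_transplant = 0) {
  f <- length(employed)
  if (is.null(wage)) wage <- employed * 30000
  dxi <- ym_index(dx)
  tibble::tibble(
    patient_id = id, sex = sex,
    birth_ym = if (is.na(birth)) NA_integer_ else ym_index(birth),
    dx_ym = dxi, end_ym = dxi + f - 1L, end_status = status,
    t = 0:(f - 1L), employed = as.integer(employed), wage_twd = as.double(wage),
    cancer = cancer, pre_transplant = pre_transplant
  )
}

# constant-valued rate tables over a generous grid
const_tables <- function(q = 0.01, em = 0.6, wg = 30000,
                         years = 1995:2030, ages = 25:100) {
  grid <- tidyr::expand_grid(year = years, age = ages,
                             sex = c("male", "female"))
  list(
    mortality = rate_table(dplyr::mutate(grid, value = q), "mortality"),
    emratio = rate_table(dplyr::mutate(
      grid, value = ifelse(age >= 65, 0, em)), "emratio"),
    wage = rate_table(dplyr::mutate(
      grid, value = ifelse(age >= 65, 0, wg)), "wage")
  )
}

# survival curve from an explicit vector of values on t = 0..length-1
surv_curve <- function(values, F = length(values) - 1L) {
  lifeprod:::new_curve(seq_along(values) - 1L, values, "survival", F = F,
                       observed = rep(TRUE, length(values)))
}

cond_curve <- function(values, kind = "emratio", F = length(values) - 1L,
                       masked = rep(FALSE, length(values))) {
  lifeprod:::new_curve(seq_along(values) - 1L, values, kind, F = F,
                       at_risk = rep(1e6, length(values)), masked = masked)
}

hr_curve <- function(values, F = NA_integer_) {
  lifeprod:::new_curve(seq_along(values), values, "hazard_ratio", F = F)
}

# single-stratum scenario used by most simulation tests
test_scenario <- function(n = 500, band = "46-50", sex = "male", ...) {
  scenario_config(n_per_stratum = n, sexes = sex, age_bands = band, ...)
}
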