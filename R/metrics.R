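# Lifetime metrics -----------------------------------------------------------

# align a survival curve and a conditional curve on the monthly grid and
# return the summed product (months, or currency-months for earnings)
survival_weighted_sum <- function(S, E) {
  tt <- S$t
  ev <- E$value[match(tt, E$t)]
  msk <- if ("masked" %in% names(E)) E$masked[match(tt, E$t)] else rep(FALSE, length(tt))
  msk[is.na(msk)] <- FALSE
  missing_e <- is.na(ev) | msk
  if (any(missing_e & S$value > 0)) {
    abort("conditional curve is masked or missing where survival is positive")
  }
  ev[missing_e] <- 0
  extra <- setdiff(E$t, tt)
  if (length(extra) > 0 && any(E$value[match(extra, E$t)] > 0, na.rm = TRUE)) {
    warn("conditional curve extends beyond the survival curve; extra months ignored")
  }
  sum(S$value * ev)
}

#' Expected lifetime employment duration (ELED)
#'
#' `ELED = sum_{t=0..L} S(t) * E(t)` in months: the survival-weighted
#' conditional EMRATIO. On a fully observed cohort this equals the mean of
#' the patients' individual employment-month counts exactly.
#'
#' @param S Survival `lifeprod_curve` on `0..L`.
#' @param E Conditional EMRATIO curve on `0..L` (extrapolated, or reference).
#' @return Months of expected lifetime employment (attribute `years`).
#' @export
expected_lifetime_employment <- function(S, E) {
  v <- survival_weighted_sum(S, E)
  structure(v, years = v / 12)
}

#' Expected lifetime earnings (ELN)
#'
#' `ELN = sum_{t=0..L} S(t) * N(t)`: the survival-weighted conditional
#' average earnings, undiscounted, in the currency of `N` (TWD internally).
#'
#' @param S Survival `lifeprod_curve` on `0..L`.
#' @param N Conditional earnings curve on `0..L`.
#' @return Lifetime earnings in the curve's currency.
#' @export
expected_lifetime_earnings <- function(S, N) {
  survival_weighted_sum(S, N)
}

#' Derive loss metrics from per-cohort lifetime values
#'
#' Takes per-stratum point values for the index and reference cohorts -- life
#' expectancy (years), lifetime employment duration (years) and lifetime
#' earnings (USD) -- and computes every derived quantity of the summary
#' tables: losses (reference minus index), relative losses (percent of the
#' reference), annual earnings (lifetime earnings over lifetime employment
#' duration) and the index/reference annual-earnings ratio (percent). All
#' derivations use the values as given and round nothing.
#'
#' @param df Tibble with columns `sex`, `age_band`, `le_index`, `le_ref`,
#'   `led_index`, `led_ref`, `eln_index`, `eln_ref`.
#' @return The input with columns `le_loss`, `lled`, `rel_lled_pct`, `llep`,
#'   `rel_llep_pct`, `annual_index`, `annual_ref`, `annual_ratio_pct` added.
#' @export
#' @examples
#' derive_loss_metrics(tibble::tibble(
#'   sex = "male", age_band = "25-34", le_index = 28.7, le_ref = 47.9,
#'   led_index = 11.6, led_ref = 24.0, eln_index = 151637, eln_ref = 387970
#' ))
derive_loss_metrics <- function(df) {
  df <- tibble::as_tibble(df)
  df$le_loss <- df$le_ref - df$le_index
  df$lled <- df$led_ref - df$led_index
  df$rel_lled_pct <- ifelse(df$led_ref > 0, 100 * df$lled / df$led_ref, NA_real_)
  df$llep <- df$eln_ref - df$eln_index
  df$rel_llep_pct <- ifelse(df$eln_ref > 0, 100 * df$llep / df$eln_ref, NA_real_)
  df$annual_index <- ifelse(df$led_index > 0, df$eln_index / df$led_index, NA_real_)
  df$annual_ref <- ifelse(df$led_ref > 0, df$eln_ref / df$led_ref, NA_real_)
  df$annual_ratio_pct <- ifelse(
    !is.na(df$annual_index) & !is.na(df$annual_ref) & df$annual_ref > 0,
    100 * df$annual_index / df$annual_ref, NA_real_
  )
  df
}

#' Lifetime losses of a stratum from its estimated curves
#'
#' Combines the survival and conditional curves of the index and reference
#' cohorts into the full set of lifetime estimates: LE, ELED and ELN per
#' cohort, the losses `LLED = sum[S_r E_r - S_i E_i]` and
#' `LLEP = sum[S_r N_r - S_i N_i]`, relative losses, and the annual-earnings
#' ratio. Earnings are converted from TWD to USD at the configured rate.
#'
#' @param s_index,e_index,n_index Index-cohort survival, EMRATIO and earnings
#'   curves on `0..L`.
#' @param s_ref,e_ref,n_ref Reference-cohort curves on `0..L`.
#' @param sex,age_band Stratum labels.
#' @param config A [lifeprod_config()].
#' @return A one-row tibble of lifetime estimates (years / USD / percent).
#' @export
lifetime_losses <- function(s_index, e_index, n_index,
                            s_ref, e_ref, n_ref,
                            sex = NA_character_, age_band = NA_character_,
                            config = lifeprod_config()) {
  usd <- function(twd) twd / config$twd_per_usd
  df <- tibble::tibble(
    sex = sex, age_band = as.character(age_band),
    le_index = as.numeric(life_expectancy(s_index)) / 12,
    le_ref = as.numeric(life_expectancy(s_ref)) / 12,
    led_index = as.numeric(expected_lifetime_employment(s_index, e_index)) / 12,
    led_ref = as.numeric(expected_lifetime_employment(s_ref, e_ref)) / 12,
    eln_index = usd(expected_lifetime_earnings(s_index, n_index)),
    eln_ref = usd(expected_lifetime_earnings(s_ref, n_ref))
  )
  derive_loss_metrics(df)
}

#' Summarise per-stratum estimates with extrema
#'
#' @param estimates Tibble of per-stratum lifetime estimates (rows from
#'   [lifetime_losses()] or [derive_loss_metrics()]).
#' @return A list: `table` (the input, ordered by sex and band) and
#'   `extrema`, a tibble of min/max of each relative-loss and ratio column
#'   per sex and overall.
#' @export
strata_summary <- function(estimates) {
  stopifnot(nrow(estimates) >= 1)
  est <- dplyr::arrange(estimates, .data$sex, .data$age_band)
  one <- function(df, label) {
    tibble::tibble(
      sex = label,
      metric = c("rel_lled_pct", "rel_llep_pct", "annual_ratio_pct"),
      min = c(min(df$rel_lled_pct, na.rm = TRUE),
              min(df$rel_llep_pct, na.rm = TRUE),
              min(df$annual_ratio_pct, na.rm = TRUE)),
      max = c(max(df$rel_lled_pct, na.rm = TRUE),
              max(df$rel_llep_pct, na.rm = TRUE),
              max(df$annual_ratio_pct, na.rm = TRUE))
    )
  }
  parts <- lapply(unique(est$sex), function(s) one(est[est$sex == s, ], s))
  extrema <- dplyr::bind_rows(c(parts, list(one(est, "overall"))))
  list(table = est, extrema = extrema)
}

#' Format lifetime estimates the way the summary tables print them
#'
#' Durations in years to 1 decimal, money to whole USD, relative losses to
#' whole percent, annual ratios to 1 decimal percent. Rounding happens here,
#' last; all internal computation is unrounded.
#'
#' @param estimates Per-stratum estimates tibble.
#' @return A tibble of formatted strings.
#' @export
format_estimates <- function(estimates) {
  f1 <- function(x) sprintf("%.1f", x)
  money <- function(x) formatC(round(x), format = "d", big.mark = ",")
  pct0 <- function(x) sprintf("%d%%", as.integer(round(x)))
  pct1 <- function(x) sprintf("%.1f%%", x)
  tibble::tibble(
    sex = estimates$sex, age_band = estimates$age_band,
    le_index = f1(estimates$le_index), le_ref = f1(estimates$le_ref),
    le_loss = f1(estimates$le_loss),
    led_index = f1(estimates$led_index), led_ref = f1(estimates$led_ref),
    lled = f1(estimates$lled), rel_lled = pct0(estimates$rel_lled_pct),
    eln_index = money(estimates$eln_index), eln_ref = money(estimates$eln_ref),
    llep = money(estimates$llep), rel_llep = pct0(estimates$rel_llep_pct),
    annual_ratio = pct1(estimates$annual_ratio_pct)
  )
}

#' Write the per-stratum report
#'
#' Emits a CSV of the unrounded estimates and prints a formatted text table.
#'
#' @param estimates Per-stratum estimates tibble.
#' @param path Optional CSV path.
#' @return The formatted tibble, invisibly.
#' @export
write_report <- function(estimates, path = NULL) {
  if (!is.null(path)) readr::write_csv(estimates, path)
  fmt <- format_estimates(estimates)
  print(as.data.frame(fmt), row.names = FALSE)
  invisible(fmt)
}
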