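# Index-cohort survival -----------------------------------------------------

# per-patient event summary: time = end - dx (months), status 1 = dead
event_table <- function(records) {
  dplyr::summarise(
    dplyr::group_by(records, .data$patient_id),
    time = .data$end_ym[1] - .data$dx_ym[1],
    status = as.integer(.data$end_status[1] == "dead"),
    .groups = "drop"
  )
}

#' Kaplan-Meier survival of the index cohort on the monthly grid
#'
#' Product-limit estimate evaluated at whole months since diagnosis, with
#' deaths preceding censorings within a month. `S(t)` is the probability of
#' surviving beyond month `t`, so without censoring `S(t)` equals the
#' fraction of patients whose event time exceeds `t` (the alive-set size
#' `M_t / N` used by the conditional curves).
#'
#' @param records Patient-month tibble, or a per-patient tibble with `time`
#'   and `status` columns.
#' @param weights Optional per-patient case weights (bootstrap).
#' @return A survival `lifeprod_curve` on `0..F`, where `F` is the last month
#'   with at least one patient at risk.
#' @export
kaplan_meier <- function(records, weights = NULL) {
  ev <- if (all(c("time", "status") %in% names(records))) {
    records
  } else {
    event_table(records)
  }
  if (nrow(ev) == 0) abort("empty cohort")
  if (is.null(weights)) weights <- rep(1, nrow(ev))
  keep <- weights > 0
  if (!any(keep)) abort("all case weights are zero")
  if (all(ev$time[keep] == 0 & ev$status[keep] == 1)) {
    abort("all patients dead in the diagnosis month; no survival to estimate")
  }
  fit <- survival::survfit(survival::Surv(time, status) ~ 1,
                           data = ev[keep, ], weights = weights[keep])
  FF <- as.integer(max(ev$time[keep]))
  s <- summary(fit, times = 0:FF, extend = TRUE)$surv
  new_curve(0:FF, s, "survival", F = FF, observed = rep(TRUE, FF + 1L))
}

#' Rolling extrapolation of index survival beyond follow-up
#'
#' The observed index survival is expressed relative to the reference curve,
#' `W(t) = S_index(t) / S_ref(t)` (clipped into `[eps, 1 - ratio_ceiling]`;
#' an excess-mortality cohort cannot outlive its reference, so values above
#' the ceiling are sampling noise), and the
#' logit of `W` is extended one month at a time: for each `t > F` a straight
#' line is fitted to the most recent `window` months of logit `W` (observed
#' or previously extrapolated), its one-step-ahead prediction is mapped back
#' through the inverse logit, and multiplied by the reference survival.
#' Monotone non-increase is enforced by capping at the previous month.
#'
#' @param s_index Observed survival curve on `0..F` (from [kaplan_meier()]).
#' @param s_ref Reference survival curve on `0..L` with `L > F`, strictly
#'   positive.
#' @param config A [lifeprod_config()] (uses `window` and `eps`).
#' @return A survival `lifeprod_curve` on `0..L` with an `observed` flag.
#' @export
rolling_extrapolate <- function(s_index, s_ref, config = lifeprod_config()) {
  FF <- curve_F(s_index)
  if (is.na(FF)) FF <- max(s_index$t)
  L <- max(s_ref$t)
  if (FF >= L) abort("follow-up end F must be smaller than the horizon L")
  if (any(s_ref$value <= 0)) abort("reference survival must stay positive up to L")
  w <- window_for(FF, config)
  if (w > FF + 1L) abort("extrapolation window exceeds the available follow-up")
  eps <- config$eps
  ceil <- 1 - config$ratio_ceiling

  sref <- s_ref$value
  s <- numeric(L + 1L)
  s[1:(FF + 1L)] <- s_index$value
  lw <- numeric(L + 1L)
  lw[1:(FF + 1L)] <- qlogis(pmin(pmax(s[1:(FF + 1L)] / sref[1:(FF + 1L)], eps), ceil))

  xc <- seq_len(w) - (w + 1) / 2           # centered abscissa of the window
  denx <- sum(xc^2)
  step <- (w + 1) / 2                      # one-step-ahead point on that scale
  for (tt in (FF + 1L):L) {                # month index tt, vector slot tt + 1
    y <- lw[(tt - w + 1L):tt]
    ybar <- mean(y)
    slope <- sum(xc * y) / denx
    pred <- ybar + slope * step
    st <- plogis(pred) * sref[tt + 1L]
    st <- min(st, s[tt])                   # monotone repair
    s[tt + 1L] <- st
    lw[tt + 1L] <- qlogis(min(max(st / sref[tt + 1L], eps), ceil))
  }
  new_curve(0:L, s, "survival", F = FF,
            observed = c(rep(TRUE, FF + 1L), rep(FALSE, L - FF)))
}

#' Life expectancy of a monthly survival curve
#'
#' `LE = sum_{t=1..L} S(t) + 0.5` months; the half-month term centres the
#' discrete sum on the monthly grid. If the curve has not decayed to
#' (near) zero at its end, the value is a restricted mean and is flagged.
#'
#' @param S A survival `lifeprod_curve`.
#' @param tol Survival level under which the curve counts as exhausted.
#' @return Months of life expectancy, with attributes `years` and
#'   `restricted`.
#' @export
life_expectancy <- function(S, tol = 1e-3) {
  le <- sum(S$value[S$t >= 1]) + 0.5
  structure(le, years = le / 12, restricted = S$value[nrow(S)] > tol)
}

#' Monthly hazard of a survival curve
#'
#' `h(t) = -log(S(t) / S(t-1))` for `t = 1..L`; 0 where the curve is flat.
#' When survival hits exactly 0 the hazard is capped at `config$hazard_cap`
#' with a warning, and is 0 thereafter.
#'
#' @param S A survival `lifeprod_curve`.
#' @param config A [lifeprod_config()].
#' @return A tibble with `t` (1..L) and `hazard`.
#' @export
monthly_hazard <- function(S, config = lifeprod_config()) {
  v <- S$value
  n <- length(v)
  if (n < 2) abort("survival curve too short for hazards")
  ratio <- v[-1] / v[-n]
  h <- -log(ratio)
  dead <- v[-1] <= 0
  if (any(dead & v[-n] > 0)) {
    warn("survival reaches 0: monthly hazard capped at configured maximum")
    h[dead & v[-n] > 0] <- config$hazard_cap
  }
  h[v[-n] <= 0] <- 0
  h[!is.finite(h)] <- config$hazard_cap
  tibble::tibble(t = S$t[-1], hazard = pmin(h, config$hazard_cap))
}

# centered moving average with partial windows at the edges
moving_average <- function(x, width) {
  if (width <= 1) return(x)
  n <- length(x)
  half <- (width - 1) %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (width - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Hazard-ratio curve between index and reference cohorts
#'
#' `HR(t) = h_index(t) / h_ref(t)` after smoothing both monthly hazard
#' series with a centered moving average (`config$smooth_width` months), then
#' clipping into `[eps_hr, 1/eps_hr]`. With `config$hr_single = TRUE` the
#' curve is replaced by the single proportional-hazards constant
#' `H_index(F) / H_ref(F)` (ratio of cumulative hazards at the end of
#' follow-up).
#'
#' @param s_index Index survival curve on `0..L` (extrapolated).
#' @param s_ref Reference survival curve on `0..L`.
#' @param config A [lifeprod_config()].
#' @return A hazard-ratio `lifeprod_curve` with `t = 1..L`.
#' @export
hazard_ratio_curve <- function(s_index, s_ref, config = lifeprod_config()) {
  if (nrow(s_index) != nrow(s_ref)) {
    abort("index and reference curves must share the monthly grid")
  }
  hi <- monthly_hazard(s_index, config)$hazard
  hr <- monthly_hazard(s_ref, config)$hazard
  if (config$hr_single) {
    FF <- curve_F(s_index)
    if (is.na(FF)) FF <- max(s_index$t)
    ratio <- sum(hi[seq_len(FF)]) / sum(hr[seq_len(FF)])
    val <- rep(ratio, length(hi))
  } else {
    his <- moving_average(hi, config$smooth_width)
    hrs <- moving_average(hr, config$smooth_width)
    if (any(hrs <= 0)) {
      abort("reference hazard is 0 over a smoothing window; HR undefined")
    }
    val <- his / hrs
  }
  clipped <- val < config$eps_hr | val > 1 / config$eps_hr
  if (any(clipped)) {
    warn(sprintf("hazard ratio clipped at %d month(s)", sum(clipped)))
  }
  val <- pmin(pmax(val, config$eps_hr), 1 / config$eps_hr)
  new_curve(s_index$t[-1], val, "hazard_ratio", F = curve_F(s_index),
            smooth_width = rep(config$smooth_width, length(val)))
}
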