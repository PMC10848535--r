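#' Run configuration for lifetime productivity estimation
#'
#' Collects every tunable the estimation pipeline uses: the lifetime horizon
#' rule, the rolling-extrapolation window, hazard smoothing, the minimum
#' at-risk rule for conditional curves, clipping constants, bootstrap
#' settings, and the reporting constants (currency conversion, wage cap,
#' retirement age).
#'
#' @param horizon_age Age (years) at which the lifetime horizon `L` ends; the
#'   horizon for a stratum is `(horizon_age - min onset age) * 12` months.
#' @param horizon_months Optional fixed horizon in months overriding the age
#'   rule.
#' @param window Rolling-extrapolation window width in months. The default
#'   (`NULL`) scales with follow-up, `max(24, F/4)`: a short follow-up keeps
#'   the 24-month local window, while long follow-up uses a quarter of the
#'   observed history so the fitted trend of the logit survival ratio is not
#'   dominated by the random-walk noise of the product-limit estimate.
#' @param smooth_width Centered moving-average width (months) applied to
#'   monthly hazards before forming the hazard-ratio curve.
#' @param min_at_risk Months of the conditional employment/earnings curves
#'   based on fewer than this many at-risk patients are masked (default 50).
#' @param eps Clipping constant for logit/log transforms, in (0, 0.5).
#' @param ratio_ceiling Upper bound offset for the relative-survival ratio
#'   `W(t) = S_index(t)/S_ref(t)` in the rolling extrapolation: `W` is capped
#'   at `1 - ratio_ceiling`. Under an excess-mortality model `W` cannot
#'   exceed 1; sampling noise that pushes the Kaplan-Meier estimate above
#'   the reference is flattened at this ceiling rather than at `1 - eps`,
#'   which would let numerically extreme logits dominate the fitting
#'   window.
#' @param eps_hr Hazard-ratio clipping: HR is kept in `[eps_hr, 1/eps_hr]`.
#' @param hazard_cap Cap on a monthly hazard when survival drops to exactly 0.
#' @param reg_start Start month `a` of the link-regression window `[a, F]`;
#'   `NULL` means `ceiling(F / 2)` (the later half of follow-up).
#' @param boot_b Bootstrap replicates.
#' @param level Interval level for bootstrap percentiles.
#' @param seed Random seed used by resampling.
#' @param twd_per_usd Currency conversion applied at reporting time.
#' @param wage_cap_usd Monthly wage cap (USD); applied in TWD before averaging.
#' @param retire_age Statutory retirement age; employment and earnings are 0
#'   from this attained age on.
#' @param carry_forward Allow rate-table lookups beyond the covered calendar
#'   years (and attained ages) to reuse the last available row. Off by
#'   default: out-of-range lookups are then an error.
#' @param alive_rule Referent alive-set rule for the reference conditional
#'   curves: `"T"` counts a referent while `t <= T_i` (life expectancy
#'   cutoff, the default), `"survival"` weights by the referent's survival
#'   probability.
#' @param hr_single If `TRUE`, replace the time-varying hazard-ratio curve by
#'   a single proportional-hazards constant (ratio of cumulative hazards at
#'   end of follow-up).
#' @param gap_employed How months with no insurance record would be coded by
#'   the reader; retained as documentation of the convention (gaps are
#'   treated as unemployed).
#'
#' @return A named list with class `"lifeprod_config"`.
#' @export
#' @examples
#' cfg <- lifeprod_config(min_at_risk = 1)
#' cfg$window
lifeprod_config <- function(horizon_age = 100,
                            horizon_months = NULL,
                            window = NULL,
                            smooth_width = 12,
                            min_at_risk = 50,
                            eps = 1e-6,
                            ratio_ceiling = 1e-3,
                            eps_hr = 1e-3,
                            hazard_cap = 5,
                            reg_start = NULL,
                            boot_b = 200,
                            level = 0.95,
                            seed = 1L,
                            twd_per_usd = 31.95,
                            wage_cap_usd = 6070,
                            retire_age = 65,
                            carry_forward = FALSE,
                            alive_rule = c("T", "survival"),
                            hr_single = FALSE,
                            gap_employed = FALSE) {
  alive_rule <- match.arg(alive_rule)
  stopifnot(
    horizon_age > 0, is.null(window) || window >= 2,
    smooth_width >= 1, min_at_risk >= 0,
    eps > 0, eps < 0.5, ratio_ceiling > 0, ratio_ceiling < 0.5,
    eps_hr > 0, eps_hr < 1, hazard_cap > 0,
    boot_b >= 2, level > 0, level < 1, twd_per_usd > 0, wage_cap_usd > 0,
    retire_age > 0
  )
  if (!is.null(reg_start)) stopifnot(reg_start >= 0)
  if (!is.null(horizon_months)) stopifnot(horizon_months >= 1)
  structure(
    list(
      horizon_age = horizon_age, horizon_months = horizon_months,
      window = if (is.null(window)) NULL else as.integer(window),
      smooth_width = as.integer(smooth_width),
      min_at_risk = min_at_risk, eps = eps, ratio_ceiling = ratio_ceiling,
      eps_hr = eps_hr,
      hazard_cap = hazard_cap, reg_start = reg_start,
      boot_b = as.integer(boot_b), level = level, seed = as.integer(seed),
      twd_per_usd = twd_per_usd, wage_cap_usd = wage_cap_usd,
      retire_age = retire_age, carry_forward = carry_forward,
      alive_rule = alive_rule, hr_single = hr_single,
      gap_employed = gap_employed
    ),
    class = "lifeprod_config"
  )
}

#' @export
print.lifeprod_config <- function(x, ...) {
  cat("<lifeprod_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-15s %s\n", nm, if (is.null(val)) "NULL" else format(val)))
  }
  invisible(x)
}

# resolved extrapolation window for a follow-up of F months
window_for <- function(F, config) {
  w <- config$window %||% max(24L, as.integer(round(F / 4)))
  as.integer(w)
}

# months horizon for a stratum given its minimum onset age
horizon_for <- function(min_onset_age, config) {
  if (!is.null(config$horizon_months)) return(as.integer(config$horizon_months))
  as.integer(max(12L, round((config$horizon_age - min_onset_age) * 12)))
}
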