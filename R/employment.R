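# Conditional EMRATIO / earnings of the index cohort -------------------------

#' Conditional EMRATIO or average-earnings curve within follow-up
#'
#' At each month `t` since diagnosis the denominator is the number of
#' patients still alive and under follow-up (`M_t`; deaths leave the alive
#' set in their event month, censored patients after their last observed
#' month). The numerator is the sum of the employment indicators
#' (`kind = "emratio"`) or of the capped monthly wages (`kind = "earnings"`,
#' so unemployed survivors contribute 0 and the value is per-capita earnings
#' of survivors). Months whose at-risk count falls below
#' `config$min_at_risk` are masked.
#'
#' @param records Patient-month tibble.
#' @param kind `"emratio"` or `"earnings"`.
#' @param config A [lifeprod_config()].
#' @param weights Optional per-patient case weights (bootstrap), in the order
#'   of `sort(unique(patient_id))`.
#' @return A `lifeprod_curve` on `0..F` with `at_risk` and `masked` columns;
#'   masked months carry `NA` values.
#' @export
conditional_curve <- function(records, kind = c("emratio", "earnings"),
                              config = lifeprod_config(), weights = NULL) {
  kind <- match.arg(kind)
  if (nrow(records) == 0) abort("empty cohort")
  ev <- event_table(records)
  if (is.null(weights)) weights <- rep(1, nrow(ev))
  stopifnot(length(weights) == nrow(ev))
  df <- dplyr::left_join(records, ev, by = "patient_id")
  df$w <- weights[match(df$patient_id, ev$patient_id)]
  alive <- df$t < df$time + (df$end_status == "censored")
  df <- df[alive, , drop = FALSE]
  df$y <- if (kind == "emratio") {
    as.double(df$employed)
  } else {
    pmin(df$wage_twd, config$wage_cap_usd * config$twd_per_usd)
  }
  agg <- dplyr::summarise(dplyr::group_by(df, .data$t),
                          at_risk = sum(.data$w),
                          num = sum(.data$w * .data$y), .groups = "drop")
  FF <- as.integer(max(ev$time))
  full <- tibble::tibble(t = 0:FF)
  agg <- dplyr::left_join(full, agg, by = "t")
  agg$at_risk[is.na(agg$at_risk)] <- 0
  agg$num[is.na(agg$num)] <- 0
  masked <- agg$at_risk < config$min_at_risk
  value <- ifelse(masked, NA_real_, agg$num / pmax(agg$at_risk, .Machine$double.eps))
  value[!masked & agg$at_risk == 0] <- 0
  new_curve(agg$t, value, kind, F = FF, at_risk = agg$at_risk, masked = masked)
}

#' Link transformations for bounded curves
#'
#' `logit` (for the EMRATIO, clipped into `[eps, 1 - eps]`) and `log` (for
#' earnings, clipped below at `eps`), with exact inverses.
#'
#' @param p Values to transform.
#' @param link `"logit"` or `"log"`.
#' @param eps Clipping constant.
#' @return Transformed values.
#' @export
#' @examples
#' link_transform(0.82, "logit")
#' link_inverse(link_transform(0.3, "logit"), "logit")
link_transform <- function(p, link = c("logit", "log"), eps = 1e-6) {
  link <- match.arg(link)
  if (any(is.nan(p))) abort("NaN passed to link_transform")
  if (link == "logit") qlogis(pmin(pmax(p, eps), 1 - eps)) else log(pmax(p, eps))
}

#' @rdname link_transform
#' @param x Transformed values to invert.
#' @export
link_inverse <- function(x, link = c("logit", "log")) {
  link <- match.arg(link)
  if (link == "logit") plogis(x) else exp(x)
}

#' Fit the link regression of the transformed index/reference difference on
#' the log hazard ratio
#'
#' Over the window `[a, F]` (default `a = ceiling(F/2)`, the later half of
#' follow-up), ordinary least squares of
#' `E_d(t) = g(index(t)) - g(ref(t))` on `log(HR(t))`, where `g` is the curve
#' link (logit for EMRATIO, log for earnings). Masked months and months where
#' the reference value is structurally 0 (post-retirement) are excluded.
#'
#' @param index_curve Observed index conditional curve on `0..F`.
#' @param ref_curve Reference conditional curve on `0..L`.
#' @param hr Hazard-ratio curve (`t = 1..L`).
#' @param link `"logit"` or `"log"`; must match the curve kind.
#' @param config A [lifeprod_config()].
#' @return An object of class `"link_fit"` with `beta0`, `beta1`, the fitting
#'   window, the number of months used, and the residual standard deviation.
#' @export
fit_link_regression <- function(index_curve, ref_curve, hr,
                                link = c("logit", "log"),
                                config = lifeprod_config()) {
  link <- match.arg(link)
  expected <- if (link == "logit") "emratio" else "earnings"
  if (!is.na(curve_kind(index_curve)) && curve_kind(index_curve) != expected) {
    abort(sprintf("link '%s' expects a %s curve", link, expected))
  }
  FF <- curve_F(index_curve)
  if (is.na(FF)) FF <- max(index_curve$t)
  a <- config$reg_start %||% ceiling(FF / 2)
  tt <- seq.int(max(a, 1L), FF)
  iv <- index_curve$value[match(tt, index_curve$t)]
  msk <- if ("masked" %in% names(index_curve)) {
    index_curve$masked[match(tt, index_curve$t)]
  } else rep(FALSE, length(tt))
  rv <- ref_curve$value[match(tt, ref_curve$t)]
  hv <- hr$value[match(tt, hr$t)]
  use <- !msk & !is.na(iv) & !is.na(rv) & !is.na(hv) & rv > 0
  tt <- tt[use]; iv <- iv[use]; rv <- rv[use]; hv <- hv[use]
  if (length(tt) < 3) abort("fewer than 3 usable months in the regression window")
  y <- link_transform(iv, link, config$eps) - link_transform(rv, link, config$eps)
  x <- log(hv)
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  if (sxx < 1e-12 * max(1, mean(x^2))) {
    warn("log hazard ratio has (near) zero variance; fitting intercept only")
    beta1 <- 0
    beta0 <- ybar
    resid <- y - beta0
    sigma <- if (length(y) > 1) sqrt(sum(resid^2) / (length(y) - 1)) else NA_real_
  } else {
    beta1 <- sum((x - xbar) * (y - ybar)) / sxx
    beta0 <- ybar - beta1 * xbar
    resid <- y - beta0 - beta1 * x
    sigma <- if (length(y) > 2) sqrt(sum(resid^2) / (length(y) - 2)) else NA_real_
  }
  structure(
    list(link = link, beta0 = beta0, beta1 = beta1, window = c(a = a, F = FF),
         n_points = length(y), sigma = sigma,
         data = tibble::tibble(t = tt, log_hr = x, e_d = y)),
    class = "link_fit"
  )
}

#' @export
print.link_fit <- function(x, ...) {
  cat(sprintf("<link_fit (%s): E_d(t) = %.4f %+.4f log HR(t), window [%d, %d], n = %d, sigma = %.4g>\n",
              x$link, x$beta0, x$beta1, x$window[1], x$window[2], x$n_points,
              x$sigma))
  invisible(x)
}

#' Extrapolate a conditional curve beyond follow-up
#'
#' For `t <= F` the observed values are kept (masked months are filled with
#' the model prediction); for `t > F` the curve is the reference curve shifted
#' on the link scale: `g^{-1}(g(ref(t)) + beta0 + beta1 log HR(t))`. Months
#' where the reference value is 0 (post-retirement) are forced to 0.
#'
#' @param ref_curve Reference conditional curve on `0..L`.
#' @param hr Hazard-ratio curve.
#' @param fit A `link_fit` whose link matches the curve kind.
#' @param index_obs Observed index conditional curve on `0..F`.
#' @param config A [lifeprod_config()].
#' @return A `lifeprod_curve` on `0..L` with a `source` column
#'   (`"observed"`, `"filled"`, `"extrapolated"`).
#' @export
extrapolate_conditional <- function(ref_curve, hr, fit, index_obs,
                                    config = lifeprod_config()) {
  kind <- curve_kind(index_obs)
  expected <- if (fit$link == "logit") "emratio" else "earnings"
  if (!is.na(kind) && kind != expected) {
    abort(sprintf("fit link '%s' does not match curve kind '%s'", fit$link, kind))
  }
  L <- max(ref_curve$t)
  FF <- curve_F(index_obs)
  if (is.na(FF)) FF <- max(index_obs$t)
  tt <- 0:L
  rv <- ref_curve$value[match(tt, ref_curve$t)]
  hv <- c(NA_real_, hr$value[match(1:L, hr$t)])
  pred <- rep(NA_real_, L + 1L)
  ok <- rv > 0 & !is.na(hv)
  pred[ok] <- link_inverse(
    link_transform(rv[ok], fit$link, config$eps) + fit$beta0 +
      fit$beta1 * log(hv[ok]),
    fit$link
  )
  pred[rv <= 0] <- 0
  if (fit$link == "log" && any(rv <= 0 & tt <= FF)) {
    nonterminal <- rv <= 0 & rev(cummax(rev(rv))) > 0
    if (any(nonterminal)) {
      warn("reference earnings are 0 before retirement; extrapolated value set to 0")
    }
  }
  if (is.na(pred[1])) pred[1] <- rv[1] # t = 0 has no hazard ratio

  value <- pred
  src <- rep("extrapolated", L + 1L)
  obs_idx <- match(0:FF, index_obs$t)
  obs_val <- index_obs$value[obs_idx]
  msk <- if ("masked" %in% names(index_obs)) {
    index_obs$masked[obs_idx]
  } else rep(FALSE, FF + 1L)
  keep <- !msk & !is.na(obs_val)
  value[which(keep)] <- obs_val[keep]
  src[seq_len(FF + 1L)] <- ifelse(keep, "observed", "filled")
  if (kind == "emratio") value <- pmin(pmax(value, 0), 1)
  value <- pmax(value, 0)
  new_curve(tt, value, kind, F = FF, source = src)
}
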