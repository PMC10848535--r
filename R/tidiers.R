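# broom-style methods ---------------------------------------------------------

#' Tidy a fitted lifetime-productivity estimate
#'
#' @param x A `lifeprod_fit`.
#' @param ... Unused.
#' @return The per-stratum estimates tibble (one row per sex-by-age-band
#'   stratum, unrounded).
#' @method tidy lifeprod_fit
#' @export
tidy.lifeprod_fit <- function(x, ...) x$estimates

#' One-row summary of a fitted lifetime-productivity estimate
#'
#' @param x A `lifeprod_fit`.
#' @param ... Unused.
#' @return A one-row tibble with stratum count and the min/max of the
#'   relative losses and annual-earnings ratio across strata.
#' @method glance lifeprod_fit
#' @export
glance.lifeprod_fit <- function(x, ...) {
  s <- strata_summary(x$estimates)
  ov <- s$extrema[s$extrema$sex == "overall", ]
  g <- function(m, side) ov[[side]][ov$metric == m]
  tibble::tibble(
    n_strata = nrow(x$estimates),
    rel_lled_min_pct = g("rel_lled_pct", "min"),
    rel_lled_max_pct = g("rel_lled_pct", "max"),
    rel_llep_min_pct = g("rel_llep_pct", "min"),
    rel_llep_max_pct = g("rel_llep_pct", "max"),
    annual_ratio_min_pct = g("annual_ratio_pct", "min"),
    annual_ratio_max_pct = g("annual_ratio_pct", "max")
  )
}

#' @rdname tidy.lifeprod_fit
#' @method tidy link_fit
#' @export
tidy.link_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "log_hr"),
    estimate = c(x$beta0, x$beta1)
  )
}

#' @rdname glance.lifeprod_fit
#' @method glance link_fit
#' @export
glance.link_fit <- function(x, ...) {
  tibble::tibble(
    link = x$link, sigma = x$sigma, n_points = x$n_points,
    window_start = unname(x$window[1]), window_end = unname(x$window[2])
  )
}
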