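# Plots ----------------------------------------------------------------------

#' Plot survival-weighted employment or earnings curves of a fit
#'
#' Shows the index and reference survival-weighted curves per stratum; the
#' area between them is the lifetime loss (LLED for employment months, LLEP
#' for earnings).
#'
#' @param object A `lifeprod_fit`.
#' @param kind `"employment"` or `"earnings"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lifeprod_fit
#' @export
autoplot.lifeprod_fit <- function(object, kind = c("employment", "earnings"),
                                  ...) {
  kind <- match.arg(kind)
  parts <- lapply(names(object$strata), function(nm) {
    cv <- object$strata[[nm]]$curves
    idx <- if (kind == "employment") cv$e_index else cv$n_index
    ref <- if (kind == "employment") cv$e_ref else cv$n_ref
    dplyr::bind_rows(
      tibble::tibble(stratum = nm, cohort = "index", t = cv$s_index$t,
                     value = cv$s_index$value * idx$value),
      tibble::tibble(stratum = nm, cohort = "reference", t = cv$s_ref$t,
                     value = cv$s_ref$value * ref$value)
    )
  })
  df <- dplyr::bind_rows(parts)
  ylab <- if (kind == "employment") {
    "Survival-weighted employment ratio"
  } else {
    "Survival-weighted monthly earnings (TWD)"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t / 12, y = .data$value,
                                   colour = .data$cohort)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~stratum, scales = "free_y") +
    ggplot2::labs(x = "Years since diagnosis", y = ylab, colour = NULL)
}

#' Plot per-stratum relative losses
#'
#' @param estimates Per-stratum estimates tibble.
#' @return A ggplot of relative LLED and LLEP by stratum.
#' @export
plot_relative_losses <- function(estimates) {
  df <- tidyr::pivot_longer(
    estimates[c("sex", "age_band", "rel_lled_pct", "rel_llep_pct")],
    cols = c("rel_lled_pct", "rel_llep_pct"),
    names_to = "metric", values_to = "pct"
  )
  df$metric <- ifelse(df$metric == "rel_lled_pct",
                      "Employment duration", "Productivity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_band, y = .data$pct,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "Onset-age band", y = "Relative lifetime loss (%)",
                  fill = NULL)
}
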