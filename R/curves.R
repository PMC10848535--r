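# Monthly curves -------------------------------------------------------------
#
# All monthly curves (survival, conditional EMRATIO, conditional earnings,
# hazard ratio) are tibbles with a `t` column (months since diagnosis) and a
# `value` column, plus curve-specific columns. Attributes carry the curve
# kind and the end of follow-up F.

new_curve <- function(t, value, kind, F = NA_integer_, ...) {
  extra <- list(...)
  df <- tibble::tibble(t = as.integer(t), value = as.double(value))
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  structure(df, kind = kind, F = F,
            class = c("lifeprod_curve", class(tibble::tibble())))
}

curve_kind <- function(x) attr(x, "kind")
curve_F <- function(x) attr(x, "F")

#' @export
print.lifeprod_curve <- function(x, ...) {
  cat(sprintf("<lifeprod_curve: %s, %d months%s>\n", curve_kind(x),
              nrow(x) - 1L,
              if (!is.na(curve_F(x))) sprintf(", follow-up F = %d", curve_F(x)) else ""))
  NextMethod()
}

#' Export a monthly curve as a plain tibble
#'
#' @param x A `lifeprod_curve`.
#' @return A tibble with `t`, `value` and any flag columns.
#' @export
curve_tbl <- function(x) tibble::as_tibble(unclass(x)[!vapply(unclass(x), is.null, TRUE)])

#' Write a monthly curve to CSV
#'
#' @param x A `lifeprod_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(x, path) {
  readr::write_csv(curve_tbl(x), path)
  invisible(path)
}

#' @method autoplot lifeprod_curve
#' @export
autoplot.lifeprod_curve <- function(object, ...) {
  df <- curve_tbl(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t / 12, y = .data$value)) +
    ggplot2::labs(x = "Years since diagnosis", y = curve_kind(object))
  if ("observed" %in% names(df)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(linetype = .data$observed))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p
}
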