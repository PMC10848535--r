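# Bootstrap intervals ---------------------------------------------------------

#' Bootstrap percentile intervals for every lifetime estimate
#'
#' Nonparametric patient-level bootstrap: patients are resampled with
#' replacement `B` times, the full pipeline (reference build, survival
#' extrapolation, link fits, lifetime metrics) is re-run per resample with
#' case weights, and percentile bounds are taken at the configured level.
#' Reference rate tables are held fixed. The reported point estimate is
#' always the full-sample estimate, never the resample mean. Replicates in
#' which a stratum loses all members (or in which the pipeline fails, e.g.
#' too few usable regression months) are dropped for that stratum with a
#' warning; the drop count is reported.
#'
#' @param records Eligible patient-month tibble.
#' @param mortality,emratio,wages Rate tables.
#' @param config A [lifeprod_config()]; `boot_b`, `level` and `seed` control
#'   the resampling.
#' @param B,level,seed Optional overrides of the config values.
#' @return A tibble with one row per stratum and metric: `point`, `lower`,
#'   `upper`, `level`, `B` (replicates used) and `dropped`.
#' @export
bootstrap_intervals <- function(records, mortality, emratio, wages,
                                config = lifeprod_config(),
                                B = NULL, level = NULL, seed = NULL) {
  B <- as.integer(B %||% config$boot_b)
  level <- level %||% config$level
  seed <- as.integer(seed %||% config$seed)
  if (B < 2) abort("bootstrap needs B >= 2 replicates")
  records <- stratify_cohort(records)
  keys <- dplyr::distinct(dplyr::as_tibble(records[c("sex", "age_band")]))
  keys <- dplyr::arrange(keys, .data$sex, .data$age_band)

  comps <- list()
  points <- list()
  for (k in seq_len(nrow(keys))) {
    sub <- records[records$sex == keys$sex[k] &
                     records$age_band == keys$age_band[k], , drop = FALSE]
    comps[[k]] <- compile_stratum(sub, mortality, emratio, wages, config)
    points[[k]] <- estimate_stratum(comps[[k]])$estimates
  }

  metric_cols <- setdiff(names(points[[1]]), c("sex", "age_band"))
  all_ids <- unique(records$patient_id)
  id_of <- lapply(comps, function(cm) match(cm$ev$patient_id, all_ids))
  n_all <- length(all_ids)

  set.seed(seed)
  draws <- lapply(seq_len(nrow(keys)), function(k) {
    matrix(NA_real_, B, length(metric_cols), dimnames = list(NULL, metric_cols))
  })
  dropped <- integer(nrow(keys))
  for (b in seq_len(B)) {
    cnt <- tabulate(sample.int(n_all, n_all, replace = TRUE), nbins = n_all)
    for (k in seq_len(nrow(keys))) {
      w <- cnt[id_of[[k]]]
      if (sum(w) == 0) {
        dropped[k] <- dropped[k] + 1L
        next
      }
      res <- tryCatch(
        suppressWarnings(estimate_stratum(comps[[k]], weights = w)),
        error = function(e) NULL
      )
      if (is.null(res)) {
        dropped[k] <- dropped[k] + 1L
        next
      }
      draws[[k]][b, ] <- unlist(res$estimates[1, metric_cols])
    }
  }
  if (any(dropped > 0)) {
    warn(sprintf("%d bootstrap replicate(s) dropped across strata", sum(dropped)))
  }

  alpha <- (1 - level) / 2
  out <- list()
  for (k in seq_len(nrow(keys))) {
    mat <- draws[[k]]
    ok <- stats::complete.cases(mat)
    qs <- apply(mat[ok, , drop = FALSE], 2, quantile,
                probs = c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
    out[[k]] <- tibble::tibble(
      sex = keys$sex[k], age_band = as.character(keys$age_band[k]),
      metric = metric_cols,
      point = unname(unlist(points[[k]][1, metric_cols])),
      lower = unname(qs[1, ]), upper = unname(qs[2, ]),
      level = level, B = sum(ok), dropped = B - sum(ok)
    )
  }
  res <- dplyr::bind_rows(out)
  outside <- !is.na(res$point) & (res$point < res$lower | res$point > res$upper)
  if (any(outside)) {
    warn("a percentile interval excludes its point estimate (skewed resamples)")
  }
  res
}

#' Render intervals in "point (lower-upper)" style
#'
#' @param intervals Output of [bootstrap_intervals()].
#' @param digits Decimal places.
#' @return The input with a formatted `display` column added.
#' @export
format_intervals <- function(intervals, digits = 1) {
  fmt <- function(x) formatC(x, format = "f", digits = digits, big.mark = "")
  intervals$display <- sprintf("%s (%s-%s)", fmt(intervals$point),
                               fmt(intervals$lower), fmt(intervals$upper))
  intervals
}
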