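#' Published Taiwan ESKD cohort summary estimates
#'
#' Per-stratum point estimates reported for the Taiwanese end-stage kidney
#' disease dialysis cohort (2000-2017) and its age-, sex-, calendar-year-
#' matched referents: life expectancy and lifetime employment duration in
#' years, lifetime earnings in USD. These are inputs for the derived-metric
#' calculations of [derive_loss_metrics()]; the raw registry data behind
#' them are not public.
#'
#' @return A tibble with columns `sex`, `age_band`, `le_index`, `le_ref`,
#'   `led_index`, `led_ref`, `eln_index`, `eln_ref`.
#' @export
#' @examples
#' derive_loss_metrics(published_cohort_estimates())
published_cohort_estimates <- function() {
  path <- system.file("extdata", "eskd_taiwan_2000_2017.csv",
                      package = "lifeprod", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
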