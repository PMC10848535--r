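#' Calendar-month helpers
#'
#' Calendar months are held internally as integer month indices
#' (`year * 12 + month - 1`); CSV files carry them as `"YYYY-MM"` strings.
#'
#' @param x `"YYYY-MM"` strings (`ym_index`) or integer indices (`ym_label`).
#' @return Integer month indices, or `"YYYY-MM"` strings.
#' @export
#' @examples
#' ym_index("2005-03")
#' ym_label(ym_index("2005-03"))
ym_index <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  ok <- grepl("^\\d{4}-\\d{2}$", x) | is.na(x)
  if (!all(ok)) abort(sprintf("malformed calendar month: '%s'", x[!ok][1]))
  y <- as.integer(substr(x, 1, 4))
  m <- as.integer(substr(x, 6, 7))
  if (any(!is.na(m) & (m < 1 | m > 12))) abort("calendar month outside 01-12")
  as.integer(y * 12L + m - 1L)
}

#' @rdname ym_index
#' @export
ym_label <- function(x) {
  sprintf("%04d-%02d", x %/% 12L, x %% 12L + 1L)
}

ym_year <- function(x) as.integer(x %/% 12L)

#' Coerce and validate a patient-month table
#'
#' Index-cohort records are a long tibble with one row per patient-month:
#' `patient_id`, `sex`, `birth_ym`, `dx_ym`, `end_ym`, `end_status`
#' (`"dead"`/`"censored"`), `t` (months since diagnosis, 0 at the diagnosis
#' month), `employed` (0/1) and `wage_twd` (monthly insured wage, 0 when
#' unemployed). Optional 0/1 flag columns `cancer` and `pre_transplant`, and
#' missing `sex`/`birth_ym`, are allowed so that eligibility filtering can be
#' applied afterwards.
#'
#' Validation enforces: `end_ym >= dx_ym`; each patient's months are the
#' contiguous block `0 .. end_ym - dx_ym`; wages are non-negative and 0 in
#' unemployed months; and employment is 0 from the attained retirement age on.
#'
#' @param df Data frame in the long dialect (calendar months either as
#'   `"YYYY-MM"` or integer month indices).
#' @param retire_age Retirement age used for the employment-zero check.
#' @return A validated tibble sorted by `patient_id`, `t`.
#' @export
as_patient_records <- function(df, retire_age = 65) {
  df <- tibble::as_tibble(df)
  need <- c("patient_id", "sex", "birth_ym", "dx_ym", "end_ym", "end_status",
            "t", "employed", "wage_twd")
  if (!all(need %in% names(df))) {
    abort(paste("patient records need columns:",
                paste(setdiff(need, names(df)), collapse = ", ")))
  }
  df$patient_id <- as.character(df$patient_id)
  df$sex <- as.character(df$sex)
  for (col in c("birth_ym", "dx_ym", "end_ym")) df[[col]] <- ym_index(df[[col]])
  df$t <- as.integer(df$t)
  df$employed <- as.integer(df$employed)
  df$wage_twd <- as.double(df$wage_twd)
  if (!all(df$end_status %in% c("dead", "censored"))) {
    abort("end_status must be 'dead' or 'censored'")
  }
  if (!all(is.na(df$sex) | df$sex %in% c("male", "female"))) {
    abort("sex must be 'male', 'female' or missing")
  }
  if (any(df$end_ym < df$dx_ym)) {
    bad <- df$patient_id[df$end_ym < df$dx_ym][1]
    abort(sprintf("patient %s: end month precedes diagnosis month", bad))
  }
  if (any(df$wage_twd < 0)) {
    bad <- df[df$wage_twd < 0, ][1, ]
    abort(sprintf("patient %s, month %d: negative wage", bad$patient_id, bad$t))
  }
  if (!all(df$employed %in% c(0L, 1L))) abort("employed must be 0 or 1")
  if (any(df$employed == 0L & df$wage_twd > 0)) {
    bad <- df[df$employed == 0L & df$wage_twd > 0, ][1, ]
    abort(sprintf("patient %s, month %d: wage > 0 while unemployed",
                  bad$patient_id, bad$t))
  }
  if (anyDuplicated(df[c("patient_id", "t")]) > 0) {
    dup <- df[duplicated(df[c("patient_id", "t")]), ][1, ]
    abort(sprintf("duplicate row for patient %s, month %d", dup$patient_id, dup$t))
  }
  df <- dplyr::arrange(df, .data$patient_id, .data$t)
  if (nrow(df) == 0) return(df)
  # contiguous trajectories covering 0 .. end - dx
  chk <- dplyr::summarise(
    dplyr::group_by(df, .data$patient_id),
    n = dplyr::n(), tmax = max(.data$t), tmin = min(.data$t),
    fup = .data$end_ym[1] - .data$dx_ym[1] + 1L, .groups = "drop"
  )
  bad <- chk[chk$tmin != 0L | chk$tmax != chk$fup - 1L | chk$n != chk$fup, ]
  if (nrow(bad) > 0) {
    abort(sprintf("patient %s: trajectory months are not the contiguous block 0..%d",
                  bad$patient_id[1], bad$fup[1] - 1L))
  }
  # retirement: employment must be 0 past t = (retire_age - onset age) * 12,
  # with onset age in whole years
  has_birth <- !is.na(df$birth_ym)
  a0 <- (df$dx_ym - df$birth_ym) %/% 12L
  over <- has_birth & df$t > (retire_age - a0) * 12L & df$employed == 1L
  if (any(over)) {
    bad <- df[over, ][1, ]
    abort(sprintf("patient %s, month %d: employed at attained age >= %d",
                  bad$patient_id, bad$t, retire_age))
  }
  df
}

#' Read index-cohort patient records from CSV
#'
#' Two dialects are supported. `"long"`: one row per patient-month with the
#' columns of [as_patient_records()]. `"packed"`: one row per patient, with
#' `employment` and `wage_twd` holding `;`-separated per-month sequences
#' starting at the diagnosis month.
#'
#' @param path CSV path.
#' @param dialect `"long"` or `"packed"`.
#' @param retire_age Passed to validation.
#' @return A validated patient-month tibble (possibly empty).
#' @export
read_patient_records <- function(path, dialect = c("long", "packed"),
                                 retire_age = 65) {
  dialect <- match.arg(dialect)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) {
    return(as_patient_records(tibble::tibble(
      patient_id = character(), sex = character(), birth_ym = integer(),
      dx_ym = integer(), end_ym = integer(), end_status = character(),
      t = integer(), employed = integer(), wage_twd = double()
    )))
  }
  if (dialect == "packed") {
    emp <- strsplit(raw$employment, ";", fixed = TRUE)
    wag <- strsplit(raw$wage_twd, ";", fixed = TRUE)
    len <- lengths(emp)
    if (any(len != lengths(wag))) {
      abort(sprintf("patient %s: employment and wage sequences differ in length",
                    raw$patient_id[which(len != lengths(wag))[1]]))
    }
    raw <- tibble::tibble(
      patient_id = rep(raw$patient_id, len),
      sex = rep(raw$sex, len),
      birth_ym = rep(raw$birth_ym, len),
      dx_ym = rep(raw$dx_ym, len),
      end_ym = rep(raw$end_ym, len),
      end_status = rep(raw$end_status, len),
      t = unlist(lapply(len, function(k) seq_len(k) - 1L)),
      employed = as.integer(unlist(emp)),
      wage_twd = as.double(unlist(wag)),
      cancer = if ("cancer" %in% names(raw)) rep(raw$cancer, len) else NULL,
      pre_transplant = if ("pre_transplant" %in% names(raw)) {
        rep(raw$pre_transplant, len)
      } else NULL
    )
  }
  num <- intersect(c("t", "employed", "wage_twd", "cancer", "pre_transplant"),
                   names(raw))
  for (col in num) raw[[col]] <- as.numeric(raw[[col]])
  as_patient_records(raw, retire_age = retire_age)
}

#' Write patient records to CSV (long dialect)
#'
#' @param records Patient-month tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patient_records <- function(records, path) {
  out <- records
  for (col in c("birth_ym", "dx_ym", "end_ym")) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA_character_, ym_label(out[[col]]))
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# per-patient one-row summary used by filters / stratification
patient_index <- function(records) {
  dplyr::summarise(
    dplyr::group_by(records, .data$patient_id),
    sex = .data$sex[1], birth_ym = .data$birth_ym[1], dx_ym = .data$dx_ym[1],
    end_ym = .data$end_ym[1], end_status = .data$end_status[1],
    cancer = if ("cancer" %in% names(records)) {
      as.integer(max(.data$cancer))
    } else 0L,
    pre_transplant = if ("pre_transplant" %in% names(records)) {
      as.integer(max(.data$pre_transplant))
    } else 0L,
    .groups = "drop"
  )
}

#' Onset age in whole years
#'
#' @param dx_ym,birth_ym Integer month indices.
#' @return Integer ages.
#' @export
onset_age <- function(dx_ym, birth_ym) as.integer((dx_ym - birth_ym) %/% 12L)

#' Apply the cohort eligibility filters
#'
#' Patients are excluded, in order, for: missing sex, missing birth date,
#' onset age outside 25-64, death before diagnosis, a cancer flag, and a
#' pre-dialysis transplant flag. Each patient is counted once, under the
#' first matching criterion.
#'
#' @param records Patient-month tibble (raw, possibly with `cancer` /
#'   `pre_transplant` flag columns).
#' @param age_range Inclusive onset-age bounds.
#' @return A list with `records` (the eligible patient-month rows) and
#'   `report`, a tibble of per-criterion removal counts plus the eligible
#'   count.
#' @export
apply_eligibility_filters <- function(records, age_range = c(25, 64)) {
  idx <- patient_index(records)
  age <- onset_age(idx$dx_ym, idx$birth_ym)
  crit <- dplyr::case_when(
    is.na(idx$sex) ~ "missing_sex",
    is.na(idx$birth_ym) ~ "missing_birth_date",
    age < age_range[1] | age > age_range[2] ~ "age_outside_range",
    idx$end_status == "dead" & idx$end_ym < idx$dx_ym ~ "death_before_diagnosis",
    idx$cancer == 1L ~ "cancer",
    idx$pre_transplant == 1L ~ "pre_dialysis_transplant",
    TRUE ~ "eligible"
  )
  levels <- c("missing_sex", "missing_birth_date", "age_outside_range",
              "death_before_diagnosis", "cancer", "pre_dialysis_transplant")
  report <- tibble::tibble(
    criterion = c(levels, "eligible"),
    count = c(vapply(levels, function(l) sum(crit == l), integer(1)),
              sum(crit == "eligible"))
  )
  keep <- idx$patient_id[crit == "eligible"]
  list(
    records = records[records$patient_id %in% keep, , drop = FALSE],
    report = report
  )
}

# the seven strata of the published cohort tables
AGE_BANDS <- tibble::tibble(
  band = c("25-34", "35-40", "41-45", "46-50", "51-55", "56-60", "61-64"),
  lo = c(25L, 35L, 41L, 46L, 51L, 56L, 61L),
  hi = c(34L, 40L, 45L, 50L, 55L, 60L, 64L)
)

#' Assign onset-age bands
#'
#' Strata use 10-year intervals under 35 and 5-year intervals above:
#' 25-34, 35-40, 41-45, 46-50, 51-55, 56-60, 61-64.
#'
#' @param age Integer onset ages.
#' @return Factor of band labels.
#' @export
age_band <- function(age) {
  if (any(age < 25L | age > 64L, na.rm = TRUE)) {
    abort(sprintf("onset age %d outside the 25-64 study range",
                  age[which(age < 25L | age > 64L)[1]]))
  }
  i <- findInterval(age, AGE_BANDS$lo)
  factor(AGE_BANDS$band[i], levels = AGE_BANDS$band)
}

#' Stratify an eligible cohort by sex and onset-age band
#'
#' Adds `onset_age`, `dx_year` and `age_band` columns; together with `sex`
#' these define the analysis strata (a partition of the cohort).
#'
#' @param records Eligible patient-month tibble.
#' @return The tibble with stratification columns added.
#' @export
stratify_cohort <- function(records) {
  records$onset_age <- onset_age(records$dx_ym, records$birth_ym)
  records$dx_year <- ym_year(records$dx_ym)
  records$age_band <- age_band(records$onset_age)
  records
}
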