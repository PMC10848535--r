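#' Construct a (year, age, sex) rate table
#'
#' A rate table maps calendar year, age in whole years, and sex to a value:
#' an annual mortality probability (`kind = "mortality"`), an
#' employed-to-population ratio (`"emratio"`), or an average monthly wage of
#' the civilian population (`"wage"`, currency per month). Employment-ratio
#' lookups return 0 for ages above the statutory retirement age regardless of
#' the stored value.
#'
#' @param df Data frame with columns `year`, `age`, `sex`, `value`.
#' @param kind One of `"mortality"`, `"emratio"`, `"wage"`.
#' @return A tibble of class `"rate_table"` with the `kind` attribute set.
#' @export
#' @examples
#' tab <- rate_table(
#'   expand.grid(year = 2000, age = 25:70, sex = "male", value = 0.01),
#'   kind = "mortality"
#' )
#' rate_lookup(tab, 2000, 40, "male")
rate_table <- function(df, kind = c("mortality", "emratio", "wage")) {
  kind <- match.arg(kind)
  df <- tibble::as_tibble(df)
  need <- c("year", "age", "sex", "value")
  if (!all(need %in% names(df))) {
    abort(paste("rate table needs columns:", paste(need, collapse = ", ")))
  }
  df <- dplyr::select(df, dplyr::all_of(need))
  df$year <- as.integer(df$year)
  df$age <- as.integer(df$age)
  df$sex <- as.character(df$sex)
  if (!all(df$sex %in% c("male", "female"))) {
    abort("rate table sex must be 'male' or 'female'")
  }
  if (anyNA(df$value)) abort("rate table contains missing values")
  if (kind %in% c("mortality", "emratio")) {
    if (any(df$value < 0 | df$value > 1)) {
      abort(sprintf("%s values must lie in [0, 1]", kind))
    }
  } else if (any(df$value < 0)) {
    abort("wage values must be non-negative")
  }
  if (anyDuplicated(df[c("year", "age", "sex")]) > 0) {
    abort("duplicate (year, age, sex) rows in rate table")
  }
  # complete grid per sex over the declared year x age ranges
  for (s in unique(df$sex)) {
    sub <- df[df$sex == s, ]
    yrs <- range(sub$year)
    ags <- range(sub$age)
    n_expect <- (yrs[2] - yrs[1] + 1) * (ags[2] - ags[1] + 1)
    if (nrow(sub) != n_expect) {
      abort(sprintf("rate table has holes in the (year, age) grid for sex '%s'", s))
    }
  }
  df <- dplyr::arrange(df, .data$sex, .data$year, .data$age)
  structure(df, kind = kind, class = c("rate_table", class(tibble::tibble())))
}

#' Read a rate table from CSV
#'
#' @param path CSV file with columns `year`, `age`, `sex`, `value`.
#' @inheritParams rate_table
#' @return A `rate_table`.
#' @export
read_rate_table <- function(path, kind = c("mortality", "emratio", "wage")) {
  kind <- match.arg(kind)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  rate_table(df, kind)
}

#' Write a rate table to CSV
#'
#' @param x A `rate_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Look up rate-table values
#'
#' Vectorised over `year`, `age`, `sex`. Employment-ratio tables return 0 for
#' `age > retire_age` irrespective of the stored values. Lookups outside the
#' covered (year, age) range are an error unless `carry_forward = TRUE`, in
#' which case the nearest covered year/age row is used (needed when
#' extrapolating into future calendar time or very old ages).
#'
#' @param table A `rate_table`.
#' @param year,age,sex Vectors (recycled to a common length).
#' @param carry_forward Clamp out-of-range years/ages to the covered range.
#' @param retire_age Retirement age for the emratio zero rule.
#' @return Numeric vector of values.
#' @export
rate_lookup <- function(table, year, age, sex, carry_forward = FALSE,
                        retire_age = 65) {
  stopifnot(inherits(table, "rate_table"))
  n <- max(length(year), length(age), length(sex))
  year <- rep_len(as.integer(year), n)
  age <- rep_len(as.integer(age), n)
  sex <- rep_len(as.character(sex), n)
  idx <- rate_index(table)
  out <- numeric(n)
  for (s in unique(sex)) {
    g <- idx[[s]]
    if (is.null(g)) abort(sprintf("rate table has no rows for sex '%s'", s))
    sel <- sex == s
    yy <- year[sel]
    aa <- age[sel]
    if (carry_forward) {
      yy <- pmin(pmax(yy, g$years[1]), g$years[length(g$years)])
      aa <- pmin(pmax(aa, g$ages[1]), g$ages[length(g$ages)])
    } else if (any(yy < g$years[1] | yy > g$years[length(g$years)] |
                   aa < g$ages[1] | aa > g$ages[length(g$ages)])) {
      bad <- which(yy < g$years[1] | yy > g$years[length(g$years)] |
                     aa < g$ages[1] | aa > g$ages[length(g$ages)])[1]
      abort(sprintf(
        "rate-table lookup (%d, %d, %s) outside covered range; set carry_forward = TRUE to reuse boundary rows",
        yy[bad], aa[bad], s
      ))
    }
    out[sel] <- g$mat[cbind(yy - g$years[1] + 1L, aa - g$ages[1] + 1L)]
  }
  if (attr(table, "kind") == "emratio") out[age > retire_age] <- 0
  out
}

# dense per-sex (year x age) matrices for fast lookup
rate_index <- function(table) {
  cached <- attr(table, "index")
  if (!is.null(cached)) return(cached)
  idx <- list()
  for (s in unique(table$sex)) {
    sub <- table[table$sex == s, ]
    years <- seq(min(sub$year), max(sub$year))
    ages <- seq(min(sub$age), max(sub$age))
    mat <- matrix(NA_real_, length(years), length(ages))
    mat[cbind(sub$year - years[1] + 1L, sub$age - ages[1] + 1L)] <- sub$value
    idx[[s]] <- list(years = years, ages = ages, mat = mat)
  }
  idx
}

# attach the lookup cache once, for repeated pipeline use
cache_rate_index <- function(table) {
  attr(table, "index") <- rate_index(table)
  table
}

rate_kind <- function(table) attr(table, "kind")
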