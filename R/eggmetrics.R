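# Egg-quality derived measures, group laying milestones, annualized laying
# performance, and the IQR outlier filter applied before eggshell analyses.

#' Relative eggshell weight
#'
#' Shell weight divided by egg weight, in percent.
#'
#' @param shell_weight,egg_weight grams (vectorized).
#' @return percent.
#' @export
relative_shell_weight <- function(shell_weight, egg_weight) {
  if (any(!is.finite(egg_weight) | egg_weight <= 0))
    stop("domain error: egg_weight must be > 0")
  100 * shell_weight / egg_weight
}

#' Tukey-fence outlier filter
#'
#' Removes values strictly below `Q1 - 1.5 IQR` or strictly above
#' `Q3 + 1.5 IQR`. Quartiles use linear interpolation between order
#' statistics (the common statistics-software default; a value exactly on a
#' fence is kept).
#'
#' @param values numeric vector of at least 4 values.
#' @return list with `kept` (order-preserving), `removed` and `fences`.
#' @export
iqr_filter <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4)
    stop("insufficient data: need at least 4 values for the IQR filter")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
  out <- values < fences[1] | values > fences[2]
  list(kept = values[!out], removed = values[out], fences = fences)
}

#' Per-cell outlier filtering of egg measurements
#'
#' Applies [iqr_filter()] within every genotype x sampling-period cell (the
#' analysis unit of the eggshell models); `by = character()` filters
#' globally instead.
#'
#' @param df data.frame of egg records.
#' @param var column to filter on.
#' @param by grouping columns (default genotype and period).
#' @return `df` restricted to the kept rows.
#' @export
filter_egg_outliers <- function(df, var, by = c("genotype", "period")) {
  if (!var %in% names(df)) stop("unknown column: ", var)
  if (!length(by)) {
    f <- iqr_filter(df[[var]])
    return(df[df[[var]] >= f$fences[1] & df[[var]] <= f$fences[2], ,
              drop = FALSE])
  }
  groups <- interaction(df[by], drop = TRUE)
  keep <- unlist(lapply(split(seq_len(nrow(df)), groups), function(idx) {
    f <- iqr_filter(df[[var]][idx])
    idx[df[[var]][idx] >= f$fences[1] & df[[var]][idx] <= f$fences[2]]
  }))
  df[sort(keep), , drop = FALSE]
}

#' Group laying milestones
#'
#' First egg day (first day with any egg) and the day the group reaches 10%
#' laying performance (first day with `daily_eggs / n_hens >= 0.10`; the
#' single-day rate, no smoothing). Absent milestones are `NA`, not errors.
#'
#' @param daily_eggs nonnegative integer egg counts indexed by `days`.
#' @param n_hens hens in the group.
#' @param days day-of-age index parallel to `daily_eggs` (defaults to
#'   `seq_along(daily_eggs)`).
#' @return list with `first_egg_day` and `day_10pct` (both possibly `NA`).
#' @export
laying_milestones <- function(daily_eggs, n_hens,
                              days = seq_along(daily_eggs)) {
  if (!length(daily_eggs)) stop("empty laying series")
  if (n_hens < 1) stop("domain error: n_hens must be >= 1")
  if (any(daily_eggs < 0)) stop("domain error: negative egg counts")
  first <- which(daily_eggs > 0)[1]
  tenth <- which(daily_eggs / n_hens >= 0.10)[1]
  list(first_egg_day = if (is.na(first)) NA_real_ else days[first],
       day_10pct = if (is.na(tenth)) NA_real_ else days[tenth])
}

# Week of age containing a day of age (days 1..7 are week 1).
day_to_week <- function(day) ((day - 1) %/% 7) + 1

#' Annualized laying performance
#'
#' Eggs per hen per year: total eggs over the observation window (which
#' starts when the group reached 10% laying performance) extrapolated to
#' 365 days and divided by the number of hens.
#'
#' @param total_eggs eggs counted over `observed_days`.
#' @param observed_days days with egg counts (>= 1).
#' @param n_hens hens in the group.
#' @return eggs per hen per year.
#' @export
annualize <- function(total_eggs, observed_days, n_hens) {
  if (observed_days <= 0) stop("domain error: observed_days must be >= 1")
  if (n_hens < 1) stop("domain error: n_hens must be >= 1")
  total_eggs * (365 / observed_days) / n_hens
}
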