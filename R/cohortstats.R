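# Cohort statistics: exact binomial prevalence intervals, time-to-complete-
# ossification survival with pairwise log-rank + Holm, Pearson correlation
# with Fisher CI, the duplicate-assay QC rule, follicle-status assignment
# and the relative body weight covariate.

#' Clopper-Pearson exact binomial confidence interval
#'
#' `lower = 100 * qbeta((1-conf)/2; x, n-x+1)` (0 when `x = 0`) and
#' `upper = 100 * qbeta(1-(1-conf)/2; x+1, n-x)` (100 when `x = n`), with
#' the point estimate `100 * x / n`, all in percent.
#'
#' @param x successes.
#' @param n trials.
#' @param conf confidence level in (0, 1).
#' @return list of class `binom_ci`: `x`, `n`, `conf`, `point`, `lower`,
#'   `upper` (percent).
#' @export
#' @examples
#' clopper_pearson(5, 12)  # 41.7% (15.2, 72.2)
clopper_pearson <- function(x, n, conf = 0.95) {
  if (n < 1 || x < 0 || x > n || x != round(x) || n != round(n))
    stop("domain error: need integers 0 <= x <= n, n >= 1")
  if (conf <= 0 || conf >= 1) stop("domain error: conf must be in (0, 1)")
  alpha <- 1 - conf
  lower <- if (x == 0) 0 else 100 * stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 100 else 100 * stats::qbeta(1 - alpha / 2, x + 1, n - x)
  structure(list(x = x, n = n, conf = conf, point = 100 * x / n,
                 lower = lower, upper = upper), class = "binom_ci")
}

#' @export
print.binom_ci <- function(x, ...) {
  cat(sprintf("%s%% (%d/%d; %d%% exact binomial CI: %s-%s)\n",
              fmt_pct(x$point), x$x, x$n, round(100 * x$conf),
              fmt_pct(x$lower), fmt_pct(x$upper)))
  invisible(x)
}

#' Round percentages half away from zero
#'
#' Formatting convention for reported percentages (e.g., 41.7).
#'
#' @param x numeric.
#' @param digits decimals.
#' @return numeric rounded half away from zero.
#' @export
fmt_pct <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Ossification survival records
#'
#' Collapses a longitudinal ossification table to one record per animal:
#' the event is the first exam week at which the ossification degree
#' strictly exceeds 0.95 (complete ossification); animals that drop out or
#' whose keel cannot be measured are censored at their last informative
#' exam week.
#'
#' @param df data.frame with columns `animal`, `genotype`, `week`, `degree`
#'   and optionally `evaluable`.
#' @return data.frame with columns `animal`, `genotype`, `time`, `status`
#'   (1 = complete ossification observed, 0 = censored).
#' @export
ossification_records <- function(df) {
  need <- c("animal", "genotype", "week", "degree")
  if (!all(need %in% names(df)))
    stop("input must have columns ", paste(need, collapse = ", "))
  if (is.null(df$evaluable)) df$evaluable <- TRUE
  out <- lapply(split(df, df$animal), function(d) {
    d <- d[d$evaluable & is.finite(d$degree), , drop = FALSE]
    if (!nrow(d)) return(NULL)
    d <- d[order(d$week), , drop = FALSE]
    hit <- which(d$degree > 0.95)[1]
    if (is.na(hit))
      data.frame(animal = d$animal[1], genotype = d$genotype[1],
                 time = max(d$week), status = 0L, stringsAsFactors = FALSE)
    else
      data.frame(animal = d$animal[1], genotype = d$genotype[1],
                 time = d$week[hit], status = 1L, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Kaplan-Meier estimate of time to complete ossification
#'
#' Product-limit estimate per group over the discrete exam weeks; censored
#' animals remain at risk through their censoring week.
#'
#' @param records data.frame with columns `genotype` (or `group`), `time`,
#'   `status`.
#' @return data.frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `surv`.
#' @export
km_estimate <- function(records) {
  records <- normalize_records(records)
  fit <- survival::survfit(survival::Surv(time, status) ~ group,
                           data = records)
  if (is.null(fit$strata)) {
    grp <- rep(unique(records$group), length(fit$time))
  } else {
    grp <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv,
             stringsAsFactors = FALSE)
}

normalize_records <- function(records) {
  if (is.null(records$group)) records$group <- records$genotype
  if (is.null(records$group) || is.null(records$time) ||
      is.null(records$status))
    stop("records need columns group/genotype, time, status")
  if (!nrow(records)) stop("domain error: empty records")
  records$group <- as.character(records$group)
  records
}

#' Log-rank comparison of ossification-completion curves
#'
#' Global log-rank test across all groups (hypergeometric expected event
#' counts, no continuity correction, df = groups - 1) and, optionally, all
#' pairwise log-rank tests with Holm adjustment.
#'
#' @param records data.frame with columns `genotype` (or `group`), `time`,
#'   `status`.
#' @param pairwise run all pairwise tests and Holm-adjust their p-values.
#' @return object of class `logrank_result`: `chi2`, `df`, `p` and, when
#'   requested, `pairwise` (data.frame with `group1`, `group2`, `chi2`,
#'   `p`, `p_holm`).
#' @export
logrank <- function(records, pairwise = TRUE) {
  records <- normalize_records(records)
  groups <- sort(unique(records$group))
  if (length(groups) < 2) stop("domain error: need at least 2 groups")
  sd_fit <- survival::survdiff(survival::Surv(time, status) ~ group,
                               data = records)
  df <- length(groups) - 1
  res <- list(chi2 = unname(sd_fit$chisq), df = df,
              p = stats::pchisq(sd_fit$chisq, df, lower.tail = FALSE))
  if (pairwise) {
    pairs <- utils::combn(groups, 2)
    pw <- apply(pairs, 2, function(pr) {
      sub <- records[records$group %in% pr, , drop = FALSE]
      f <- survival::survdiff(survival::Surv(time, status) ~ group,
                              data = sub)
      c(chi2 = unname(f$chisq),
        p = stats::pchisq(f$chisq, 1, lower.tail = FALSE))
    })
    res$pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                               chi2 = pw["chi2", ], p = pw["p", ],
                               p_holm = holm_adjust(pw["p", ]),
                               stringsAsFactors = FALSE)
  }
  structure(res, class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank: chi2(%d) = %.4g, p = %.4g\n", x$df, x$chi2, x$p))
  if (!is.null(x$pairwise)) {
    cat("Pairwise (Holm-adjusted):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Holm step-down adjustment
#'
#' @param p raw p-values.
#' @return adjusted p-values (monotone, never smaller than the raw ones).
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")

#' Pearson correlation with Fisher confidence interval
#'
#' Sample Pearson r with the confidence interval from the Fisher z
#' transform (variance `1/(n-3)`).
#'
#' @param x,y paired numeric vectors (n >= 4, nonzero variance).
#' @param conf confidence level.
#' @return list with `r`, `lower`, `upper`, `n`, `p`.
#' @export
pearson_ci <- function(x, y, conf = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("domain error: need at least 4 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("domain error: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf)
  list(r = unname(ct$estimate), lower = ct$conf.int[1],
       upper = ct$conf.int[2], n = length(x), p = ct$p.value)
}

#' Duplicate-assay quality control
#'
#' Two-point sample standard deviation (`|v1 - v2| / sqrt(2)`) and
#' coefficient of variation; the measurement is repeated only when *both*
#' CV > 15% *and* sd > 10.
#'
#' @param v1,v2 duplicate measurements (>= 0, positive mean).
#' @return list of class `duplicate_qc`: `mean`, `sd`, `cv` (percent),
#'   `decision` (`"pass"` or `"repeat"`).
#' @export
duplicate_qc <- function(v1, v2) {
  if (v1 < 0 || v2 < 0) stop("domain error: values must be >= 0")
  m <- (v1 + v2) / 2
  if (m <= 0) stop("domain error: mean must be > 0")
  s <- abs(v1 - v2) / sqrt(2)
  cv <- 100 * s / m
  structure(list(values = c(v1, v2), mean = m, sd = s, cv = cv,
                 decision = if (cv > 15 && s > 10) "repeat" else "pass"),
            class = "duplicate_qc")
}

#' Follicle status assignment
#'
#' F+ when a dominant follicle (> 10 mm) is seen on ultrasound, or when an
#' egg is visible on sonography or the radiograph (clear evidence of laying
#' activity); otherwise F-. At the pre-onset baseline week the status is
#' forced to F- by convention (no ultrasonography was conducted then).
#'
#' @param follicle_seen,egg_visible logical flags (vectorized).
#' @param week examination week of age.
#' @param baseline_week the forced-F- baseline week (default 16).
#' @return character vector of `"F+"` / `"F-"`.
#' @export
assign_follicle_status <- function(follicle_seen, egg_visible, week,
                                   baseline_week = 16) {
  n <- max(length(follicle_seen), length(egg_visible), length(week))
  follicle_seen <- rep_len(follicle_seen, n)
  egg_visible <- rep_len(egg_visible, n)
  week <- rep_len(week, n)
  ifelse(week == baseline_week, "F-",
         ifelse(follicle_seen | egg_visible, "F+", "F-"))
}

#' Relative body weight
#'
#' Body weight divided by the mean body weight of animals of the same
#' genotype at the same age; within every genotype x age group the ratios
#' average exactly 1.
#'
#' @param weight body weights (> 0).
#' @param genotype,age grouping vectors parallel to `weight`.
#' @return numeric vector of ratios.
#' @export
relative_body_weight <- function(weight, genotype, age) {
  if (any(!is.finite(weight) | weight <= 0))
    stop("domain error: weights must be > 0")
  g <- interaction(genotype, age, drop = TRUE)
  weight / stats::ave(weight, g, FUN = mean)
}

#' Normalize dual-age-group exam weeks
#'
#' The two hatching batches were examined in the 50th or 52nd and the 70th
#' or 72nd week of age; for pooling, raw weeks map to the nominal schedule
#' labels {16, 25, 33, 51, 71}.
#'
#' @param week raw exam weeks.
#' @return nominal label weeks.
#' @export
normalize_exam_week <- function(week) {
  out <- week
  out[week %in% c(50, 52)] <- 51
  out[week %in% c(70, 72)] <- 71
  out
}
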