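# Synthetic cohort tables: genotype-, age- and follicle-status-structured
# egg, laying, body-weight, ossification, blood-duplicate and follicle
# tables with the statistical structure of a three-genotype longitudinal
# keel bone study (a high-performing hybrid layer vs two low-performing
# genotypes). Defaults encode the study conditions: group sizes 12/14/12,
# first eggs in weeks 18/24/31, 10% laying performance in weeks 21/26/32,
# exam schedule {16, 25, 33, 51, 71}, ossification completed around week 25
# in the layer and around week 33-51 in the late genotype.

#' Cohort generator configuration
#'
#' @param genotypes group labels.
#' @param n_hens hens per group.
#' @param first_egg_week,week_10pct laying milestones per group (week of age).
#' @param annual_eggs_per_hen plateau laying performance, eggs/hen/year.
#' @param exam_weeks radiograph/blood exam schedule (weeks of age).
#' @param completion_probs per-genotype named probability vectors: the exam
#'   week at which complete (> 95%) ossification is first observed.
#' @param dropouts per-genotype censoring weeks (animals leaving the study).
#' @param egg_quality data.frame of per genotype x sampling-period means and
#'   SDs for egg weight, shell weight, shell thickness, breaking strength.
#' @param eggs_per_period intact eggs measured per group and sampling period.
#' @param adult_weight_mean,adult_weight_sd adult body weight (g) per group.
#' @param growth per-genotype multiplier of adult weight at each exam week.
#' @param degree_sd SD of the pre-completion ossification-degree noise.
#' @param fracture_cases animals with the binary damage outcome per group.
#' @param blood list: `mean`, `sd` of the assayed analyte and `dup_cv`
#'   (percent) of the duplicate measurement error.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(
    genotypes = c("LSL", "JF", "Su"),
    n_hens = c(12L, 14L, 12L),
    first_egg_week = c(18, 24, 31),
    week_10pct = c(21, 26, 32),
    annual_eggs_per_hen = c(315, 83, 92),
    exam_weeks = c(16, 25, 33, 51, 71),
    completion_probs = list(
      LSL = c("25" = 0.75, "33" = 0.25),
      JF = c("25" = 0.75, "33" = 0.25),
      Su = c("33" = 0.75, "51" = 0.25)),
    dropouts = list(JF = c(33, 51, 51), Su = 51),
    egg_quality = default_egg_quality(genotypes),
    eggs_per_period = c(140, 28, 32),
    adult_weight_mean = c(1782, 812, 1873),
    adult_weight_sd = c(145, 99, 228),
    growth = list(
      LSL = c(0.55, 0.92, 1, 1, 1),
      JF = c(0.55, 0.92, 1, 1, 1),
      Su = c(0.50, 0.78, 0.92, 1, 1)),
    degree_sd = 0.02,
    fracture_cases = c(5L, 0L, 0L),
    blood = list(mean = 150, sd = 30, dup_cv = 5)) {
  k <- length(genotypes)
  recycle <- function(v) stats::setNames(rep_len(v, k), genotypes)
  cfg <- list(genotypes = genotypes, n_hens = recycle(as.integer(n_hens)),
              first_egg_week = recycle(first_egg_week),
              week_10pct = recycle(week_10pct),
              annual_eggs_per_hen = recycle(annual_eggs_per_hen),
              exam_weeks = exam_weeks, completion_probs = completion_probs,
              dropouts = dropouts, egg_quality = egg_quality,
              eggs_per_period = recycle(as.integer(eggs_per_period)),
              adult_weight_mean = recycle(adult_weight_mean),
              adult_weight_sd = recycle(adult_weight_sd),
              growth = growth, degree_sd = degree_sd,
              fracture_cases = recycle(as.integer(fracture_cases)),
              blood = blood)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (any(cfg$n_hens <= 0) || any(cfg$eggs_per_period <= 0))
    stop("invalid config: group sizes must be positive")
  sds <- c(cfg$adult_weight_sd, cfg$degree_sd, cfg$blood$sd, cfg$blood$dup_cv,
           cfg$egg_quality$egg_weight_sd, cfg$egg_quality$shell_weight_sd,
           cfg$egg_quality$shell_thickness_sd, cfg$egg_quality$strength_sd)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("invalid config: SDs must be nonnegative")
  if (any(cfg$week_10pct < cfg$first_egg_week))
    stop("invalid config: 10% milestone before first egg")
  for (g in cfg$genotypes) {
    p <- cfg$completion_probs[[g]]
    if (is.null(p) || abs(sum(p) - 1) > 1e-9 || any(p < 0))
      stop("invalid config: completion_probs must be probabilities per group")
    if (!all(as.numeric(names(p)) %in% cfg$exam_weeks))
      stop("invalid config: completion weeks must be exam weeks")
  }
  invisible(cfg)
}

#' @rdname cohort_config
#' @export
default_egg_quality <- function(genotypes = c("LSL", "JF", "Su")) {
  # Genotype x sampling-period least-squares means of a hybrid layer vs two
  # low-performing genotypes; SDs are plausible per-egg dispersions.
  q <- expand.grid(genotype = genotypes, period = 1:3,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  q <- q[order(match(q$genotype, genotypes), q$period), ]
  means <- list(
    LSL = list(egg = c(59.18, 64.77, 64.39), shell = c(9.47, 9.48, 8.79),
               strength = c(57.76, 53.62, 45.69),
               thickness = c(0.3947, 0.3891, 0.3863)),
    JF = list(egg = c(32.62, 33.94, 34.31), shell = c(4.79, 4.77, 4.74),
              strength = c(37.33, 36.28, 37.08),
              thickness = c(0.3147, 0.3014, 0.3082)),
    Su = list(egg = c(46.24, 49.49, 49.96), shell = c(6.33, 6.38, 6.50),
              strength = c(42.84, 41.95, 39.51),
              thickness = c(0.3455, 0.3436, 0.3603)))
  sds <- list(LSL = c(3.5, 0.9, 10, 0.025), JF = c(2.3, 0.35, 7, 0.023),
              Su = c(3.3, 0.6, 8, 0.024))
  g <- q$genotype; idx <- q$period
  pick <- function(field) mapply(function(gg, i) means[[gg]][[field]][i], g, idx)
  q$egg_weight_mean <- pick("egg")
  q$egg_weight_sd <- vapply(g, function(gg) sds[[gg]][1], 0)
  q$shell_weight_mean <- pick("shell")
  q$shell_weight_sd <- vapply(g, function(gg) sds[[gg]][2], 0)
  q$strength_mean <- pick("strength")
  q$strength_sd <- vapply(g, function(gg) sds[[gg]][3], 0)
  q$shell_thickness_mean <- pick("thickness")
  q$shell_thickness_sd <- vapply(g, function(gg) sds[[gg]][4], 0)
  rownames(q) <- NULL
  q
}

#' Generate synthetic cohort tables
#'
#' Produces reproducible (seeded) tables with the declared statistical
#' structure: group laying series hitting the configured milestones exactly,
#' per-egg quality measurements, longitudinal body weights, ossification
#' degrees whose first > 95% exam week follows the configured per-genotype
#' distribution (with censoring for dropouts), duplicate blood assays, and
#' follicle observations coupled to onset of lay.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return named list of data.frames: `laying`, `eggs`, `body_weight`,
#'   `ossification`, `outcomes`, `blood`, `follicle`.
#' @export
generate_cohort_tables <- function(config = cohort_config(), seed = 1L) {
  validate_cohort_config(config)
  set.seed(as.integer(seed))
  gts <- config$genotypes
  n_days <- (max(config$exam_weeks) + 33) * 7

  # --- laying: daily group egg counts --------------------------------------
  laying <- do.call(rbind, lapply(gts, function(g) {
    n <- config$n_hens[[g]]
    first_day <- (config$first_egg_week[[g]] - 1) * 7 + 1
    d10 <- (config$week_10pct[[g]] - 1) * 7 + 1
    r0 <- ceiling(0.1 * n)
    lambda <- max((config$annual_eggs_per_hen[[g]] * n - 14 * r0) / 351, r0)
    eggs <- numeric(n_days)
    eggs[first_day:(d10 - 1)] <- 1
    ramp_end <- d10 + 27
    eggs[d10:ramp_end] <- round(seq(r0, lambda, length.out = 28))
    post <- (ramp_end + 1):n_days
    eggs[post] <- stats::rpois(length(post), lambda)
    data.frame(genotype = g, day = seq_len(n_days),
               week = day_to_week(seq_len(n_days)), egg_count = eggs,
               n_hens = n, stringsAsFactors = FALSE)
  }))

  # --- egg quality ---------------------------------------------------------
  eggs <- do.call(rbind, lapply(seq_len(nrow(config$egg_quality)), function(i) {
    r <- config$egg_quality[i, ]
    n <- config$eggs_per_period[[r$genotype]]
    ew <- stats::rnorm(n, r$egg_weight_mean, r$egg_weight_sd)
    sw <- pmin(stats::rnorm(n, r$shell_weight_mean, r$shell_weight_sd),
               0.5 * ew)
    data.frame(genotype = r$genotype, period = r$period, egg_weight = ew,
               shell_weight = sw,
               shell_thickness = stats::rnorm(n, r$shell_thickness_mean,
                                              r$shell_thickness_sd),
               breaking_strength = stats::rnorm(n, r$strength_mean,
                                                r$strength_sd),
               stringsAsFactors = FALSE)
  }))

  animals <- do.call(rbind, lapply(gts, function(g)
    data.frame(animal = sprintf("%s_%02d", g, seq_len(config$n_hens[[g]])),
               genotype = g, stringsAsFactors = FALSE)))

  # --- body weight ---------------------------------------------------------
  body_weight <- do.call(rbind, lapply(seq_len(nrow(animals)), function(i) {
    g <- animals$genotype[i]
    mult <- rep_len(config$growth[[g]], length(config$exam_weeks))
    data.frame(animal = animals$animal[i], genotype = g,
               week = config$exam_weeks,
               weight = stats::rnorm(length(config$exam_weeks),
                                     config$adult_weight_mean[[g]] * mult,
                                     config$adult_weight_sd[[g]] * mult),
               stringsAsFactors = FALSE)
  }))

  # --- ossification (with dropout censoring) -------------------------------
  completion <- vapply(seq_len(nrow(animals)), function(i) {
    p <- config$completion_probs[[animals$genotype[i]]]
    as.numeric(sample(names(p), 1, prob = p))
  }, 0)
  censor_week <- rep(Inf, nrow(animals))
  for (g in names(config$dropouts)) {
    idx <- which(animals$genotype == g)
    cw <- config$dropouts[[g]]
    censor_week[utils::tail(idx, length(cw))] <- cw
  }
  ossification <- do.call(rbind, lapply(seq_len(nrow(animals)), function(i) {
    weeks <- config$exam_weeks[config$exam_weeks <= censor_week[i]]
    if (!length(weeks)) return(NULL)
    degree <- ifelse(
      weeks >= completion[i],
      stats::runif(length(weeks), 0.96, 1),
      pmax(pmin(0.95 * weeks / completion[i] +
                  stats::rnorm(length(weeks), 0, config$degree_sd), 0.95), 0))
    data.frame(animal = animals$animal[i], genotype = animals$genotype[i],
               week = weeks, degree = degree, evaluable = TRUE,
               stringsAsFactors = FALSE)
  }))

  # --- binary fracture outcomes --------------------------------------------
  outcomes <- do.call(rbind, lapply(gts, function(g) {
    ids <- animals$animal[animals$genotype == g]
    dmg <- integer(length(ids))
    dmg[sample(length(ids), config$fracture_cases[[g]])] <- 1L
    data.frame(animal = ids, genotype = g, any_damage = dmg,
               evaluable = TRUE, stringsAsFactors = FALSE)
  }))

  # --- duplicate blood assays ----------------------------------------------
  blood_weeks <- config$exam_weeks[config$exam_weeks >= 25]
  blood <- do.call(rbind, lapply(seq_len(nrow(animals)), function(i) {
    truth <- pmax(stats::rnorm(length(blood_weeks), config$blood$mean,
                               config$blood$sd), 1)
    rel <- config$blood$dup_cv / 100
    data.frame(animal = animals$animal[i], genotype = animals$genotype[i],
               week = blood_weeks,
               v1 = truth * (1 + stats::rnorm(length(truth), 0, rel)),
               v2 = truth * (1 + stats::rnorm(length(truth), 0, rel)),
               stringsAsFactors = FALSE)
  }))

  # --- follicle observations (coupled to onset of lay) ---------------------
  follicle <- do.call(rbind, lapply(seq_len(nrow(animals)), function(i) {
    g <- animals$genotype[i]
    weeks <- config$exam_weeks
    laying_now <- weeks >= config$first_egg_week[[g]] &
      stats::runif(length(weeks)) < ifelse(g == gts[1], 0.95, 0.7)
    egg_vis <- laying_now & stats::runif(length(weeks)) < 0.05
    data.frame(animal = animals$animal[i], genotype = g, week = weeks,
               follicle_seen = laying_now & !egg_vis, egg_visible = egg_vis,
               stringsAsFactors = FALSE)
  }))
  follicle$status <- assign_follicle_status(
    follicle$follicle_seen, follicle$egg_visible, follicle$week,
    baseline_week = min(config$exam_weeks))

  rownames(laying) <- rownames(eggs) <- rownames(body_weight) <-
    rownames(ossification) <- rownames(outcomes) <- rownames(blood) <-
    rownames(follicle) <- NULL
  list(laying = laying, eggs = eggs, body_weight = body_weight,
       ossification = ossification, outcomes = outcomes, blood = blood,
       follicle = follicle)
}
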