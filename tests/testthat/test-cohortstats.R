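test_that("Clopper-Pearson intervals match the binomial-tail oracle", {
  for (case in list(c(5, 12), c(0, 8), c(3, 3), c(1, 20), c(7, 10))) {
    ci <- clopper_pearson(case[1], case[2])
    orc <- clopper_pearson_oracle(case[1], case[2])
    expect_equal(ci$lower, orc[["lower"]], tolerance = 1e-9)
    expect_equal(ci$upper, orc[["upper"]], tolerance = 1e-9)
    expect_lte(ci$lower, ci$point)
    expect_lte(ci$point, ci$upper)
  }
  # boundary rules
  expect_equal(clopper_pearson(0, 12)$lower, 0)
  expect_equal(clopper_pearson(12, 12)$upper, 100)
  # zero numerator at n = 8: closed form 100 * (1 - 0.025^(1/8))
  expect_equal(clopper_pearson(0, 8)$upper, 100 * (1 - 0.025^(1 / 8)),
               tolerance = 1e-9)
  expect_equal(fmt_pct(clopper_pearson(0, 8)$upper), 36.9)
  expect_error(clopper_pearson(5, 4), "domain")
  expect_error(clopper_pearson(5, 12, 1.2), "domain")
})

test_that("interval width shrinks with n at fixed proportion", {
  widths <- vapply(c(12, 24, 48, 96), function(n) {
    ci <- clopper_pearson(round(5 * n / 12), n)
    ci$upper - ci$lower
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("Kaplan-Meier estimates follow the product-limit by hand", {
  # four animals, all events at week 25: single-step drop to zero
  rec <- data.frame(group = "A", time = rep(25, 4), status = 1)
  km <- km_estimate(rec)
  expect_equal(km$surv[km$time == 25], 0)
  # two events, two censored at 25: S(25) = 1 - 2/4
  rec <- data.frame(group = "A", time = rep(25, 4), status = c(1, 1, 0, 0))
  km <- km_estimate(rec)
  expect_equal(km$surv[km$time == 25], 0.5)
  # all censored: S stays at 1
  rec <- data.frame(group = "A", time = c(25, 33, 51), status = 0)
  expect_true(all(km_estimate(rec)$surv == 1))
  expect_error(km_estimate(data.frame(group = character(), time = numeric(),
                                      status = integer())), "empty")
})

test_that("log-rank chi2 matches the hypergeometric enumeration oracle", {
  rec <- data.frame(group = rep(c("A", "B"), each = 3),
                    time = c(25, 25, 33, 50, 50, 52), status = 1)
  lr <- logrank(rec, pairwise = FALSE)
  orc <- logrank_oracle_2g(rec)
  expect_equal(lr$chi2, orc$chi2, tolerance = 1e-9)
  expect_equal(lr$p, orc$p, tolerance = 1e-9)
  # with censoring mixed in
  rec2 <- data.frame(group = rep(c("A", "B"), each = 5),
                     time = c(25, 25, 33, 33, 51, 25, 33, 51, 51, 51),
                     status = c(1, 1, 1, 0, 1, 0, 1, 1, 1, 0))
  expect_equal(logrank(rec2, pairwise = FALSE)$chi2,
               logrank_oracle_2g(rec2)$chi2, tolerance = 1e-9)
  # identical groups: exchangeable, chi2 = 0, p = 1
  rec3 <- data.frame(group = rep(c("A", "B"), each = 4),
                     time = rep(c(25, 33, 33, 51), 2),
                     status = rep(c(1, 1, 0, 1), 2))
  lr3 <- logrank(rec3, pairwise = FALSE)
  expect_equal(lr3$chi2, 0, tolerance = 1e-12)
  expect_equal(lr3$p, 1)
  expect_error(logrank(rec[rec$group == "A", ]), "2 groups")
})

test_that("pairwise mode Holm-adjusts all group pairs", {
  set.seed(17)
  rec <- data.frame(
    group = rep(c("A", "B", "C"), each = 12),
    time = c(sample(c(25, 25, 25, 33), 12, TRUE),
             sample(c(25, 33, 33), 12, TRUE),
             sample(c(33, 51, 51, 51), 12, TRUE)),
    status = 1)
  lr <- logrank(rec)
  expect_equal(lr$df, 2)
  expect_equal(nrow(lr$pairwise), 3)
  expect_equal(lr$pairwise$p_holm, as.numeric(holm_adjust(lr$pairwise$p)))
  # Holm never shrinks a p-value and stays monotone in the raw ordering
  expect_true(all(lr$pairwise$p_holm >= lr$pairwise$p))
  ord <- order(lr$pairwise$p)
  expect_true(all(diff(lr$pairwise$p_holm[ord]) >= -1e-15))
})

test_that("Holm step-down reproduces the hand computation", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.20)), c(0.03, 0.08, 0.20))
})

test_that("log-rank p-values are near-uniform under label permutation", {
  set.seed(29)
  n <- 24
  times <- sample(seq(20, 60, by = 0.5), n, replace = FALSE)
  status <- rep(1L, n)
  p <- vapply(1:500, function(i) {
    grp <- sample(rep(c("A", "B"), n / 2))
    logrank(data.frame(group = grp, time = times, status = status),
            pairwise = FALSE)$p
  }, 0)
  ks <- max(abs(sort(p) - (seq_len(500) / 500)))
  expect_lt(ks, 0.1)
})

test_that("ossification records collapse longitudinal degrees correctly", {
  df <- data.frame(
    animal = rep(c("h1", "h2", "h3"), each = 3),
    genotype = "LSL",
    week = rep(c(16, 25, 33), 3),
    degree = c(0.8, 0.96, 0.99,   # event at 25
               0.7, 0.95, 0.95,   # exactly 0.95 never -> censored at 33
               0.6, NA, 0.97),    # missing mid-exam, event at 33
    evaluable = c(rep(TRUE, 3), rep(TRUE, 3), TRUE, FALSE, TRUE))
  rec <- ossification_records(df)
  rec <- rec[order(rec$animal), ]
  expect_equal(rec$time, c(25, 33, 33))
  expect_equal(rec$status, c(1L, 0L, 1L))
})

test_that("Fisher correlation interval behaves and covers", {
  x <- 1:20
  expect_equal(pearson_ci(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_ci(x, -x)$r, -1)
  expect_error(pearson_ci(x, rep(1, 20)), "zero variance")
  # coverage at n = 184, rho = 0.93 over 500 replicates >= 93%
  set.seed(37)
  rho <- 0.93
  hits <- vapply(1:500, function(i) {
    z <- rnorm(184)
    e <- rnorm(184)
    y <- rho * z + sqrt(1 - rho^2) * e
    ci <- pearson_ci(z, y)
    ci$lower <= rho && rho <= ci$upper
  }, TRUE)
  expect_gte(mean(hits), 0.93)
})

test_that("duplicate QC repeats only when CV and SD both exceed limits", {
  q <- duplicate_qc(100, 100)
  expect_equal(q$cv, 0)
  expect_equal(q$decision, "pass")
  # high CV, low SD: conjunction not met
  q <- duplicate_qc(10, 14)
  expect_gt(q$cv, 15)
  expect_lt(q$sd, 10)
  expect_equal(q$decision, "pass")
  # both exceeded: sd = |v1 - v2| / sqrt(2)
  q <- duplicate_qc(100, 140)
  expect_equal(q$sd, 40 / sqrt(2))
  expect_gt(q$cv, 15)
  expect_equal(q$decision, "repeat")
  expect_error(duplicate_qc(0, 0), "domain")
})

test_that("follicle status follows the dominant-follicle and egg rules", {
  expect_equal(assign_follicle_status(TRUE, FALSE, 25), "F+")
  expect_equal(assign_follicle_status(FALSE, TRUE, 25), "F+")
  expect_equal(assign_follicle_status(FALSE, FALSE, 25), "F-")
  # baseline week forced F- regardless of flags
  expect_equal(assign_follicle_status(TRUE, TRUE, 16), "F-")
  expect_equal(assign_follicle_status(c(TRUE, TRUE), c(FALSE, FALSE),
                                      c(16, 25)), c("F-", "F+"))
})

test_that("relative body weight centers each genotype-age cell at 1", {
  expect_equal(relative_body_weight(rep(1500, 5), "A", 25), rep(1, 5))
  r <- relative_body_weight(c(1500, 2100), c("A", "A"), c(25, 25))
  expect_equal(r, c(1500, 2100) / 1800)
  set.seed(41)
  w <- runif(60, 800, 2000)
  g <- sample(c("LSL", "JF", "Su"), 60, TRUE)
  a <- sample(c(16, 25, 33), 60, TRUE)
  r <- relative_body_weight(w, g, a)
  means <- tapply(r, interaction(g, a, drop = TRUE), mean)
  expect_equal(as.numeric(means), rep(1, length(means)))
  expect_error(relative_body_weight(c(-1, 2), "A", 1), "domain")
})

test_that("dual-age exam weeks normalize to the nominal schedule", {
  expect_equal(normalize_exam_week(c(16, 25, 33, 50, 52, 70, 72)),
               c(16, 25, 33, 51, 51, 71, 71))
})
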