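test_that("Clopper-Pearson reproduces the published intervals", {
  expect_equal(round(100 * clopper_pearson(26, 26), 1),
               c(lower = 86.8, upper = 100.0))
  expect_equal(round(100 * clopper_pearson(88, 88), 1),
               c(lower = 95.9, upper = 100.0))
  expect_equal(round(100 * clopper_pearson(88, 107), 1),
               c(lower = 73.7, upper = 89.0))
  expect_equal(round(100 * clopper_pearson(26, 45), 1),
               c(lower = 42.2, upper = 72.3))
})

test_that("Clopper-Pearson boundary and argument handling", {
  expect_identical(clopper_pearson(0, 10)[["lower"]], 0)
  expect_identical(clopper_pearson(10, 10)[["upper"]], 1)
  expect_error(clopper_pearson(1, 0), ">= 1")
  expect_error(clopper_pearson(5, 3), "0 <= k <= n")
  expect_error(clopper_pearson(1, 2, conf_level = 1), "strictly")
})

test_that("beta-quantile bounds agree with tail-probability bisection (n <= 60)", {
  worst <- 0
  for (n in 1:60) {
    for (k in 0:n) {
      a <- clopper_pearson(k, n)
      b <- cp_bisect(k, n)
      worst <- max(worst, abs(a - b))
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("interval duality and monotonicity in k", {
  for (n in c(7, 26, 107)) {
    prev_lo <- prev_up <- -1
    for (k in 0:n) {
      ci <- clopper_pearson(k, n)
      refl <- clopper_pearson(n - k, n)
      expect_equal(unname(ci), unname(1 - rev(refl)), tolerance = 1e-12)
      expect_gte(ci[["lower"]], prev_lo)
      expect_gte(ci[["upper"]], prev_up)
      prev_lo <- ci[["lower"]]; prev_up <- ci[["upper"]]
      expect_true(ci[["lower"]] <= k / n && k / n <= ci[["upper"]])
    }
  }
})

test_that("accuracy panel reproduces the point-of-care results", {
  panel <- performance_panel(two_by_two(26, 19, 0, 88), "POC")
  expect_equal(round(100 * panel$sensitivity$point, 1), 100)
  expect_equal(round(100 * panel$specificity$point, 1), 82.2)
  expect_equal(round(100 * panel$ppv$point, 1), 57.8)
  expect_equal(round(100 * panel$npv$point, 1), 100)
  expect_equal(round(panel$plr, 2), 5.63)
  expect_equal(panel$nlr, 0)
  expect_equal(round(100 * panel$prevalence$point, 1), 19.5)
})

test_that("accuracy panel matches the reconstructed serology tables", {
  ttg <- performance_panel(two_by_two(25, 9, 1, 98), "IgA-TTG")
  expect_equal(round(100 * ttg$sensitivity$point, 1), 96.2)
  expect_equal(round(100 * ttg$specificity$point, 1), 91.6)
  expect_equal(round(100 * ttg$ppv$point, 1), 73.5)
  expect_equal(round(100 * ttg$npv$point, 1), 99.0)
  expect_equal(round(100 * c(ttg$sensitivity$lower,
                             ttg$sensitivity$upper), 1), c(80.4, 99.9))
  expect_equal(round(100 * c(ttg$npv$lower, ttg$npv$upper), 1),
               c(94.5, 100.0))
  ema <- performance_panel(two_by_two(22, 1, 4, 106), "IgA-EMA")
  expect_equal(round(100 * ema$sensitivity$point, 1), 84.6)
  expect_equal(round(100 * ema$specificity$point, 1), 99.1)
  expect_equal(round(100 * ema$ppv$point, 1), 95.7)
  expect_equal(round(100 * ema$npv$point, 1), 96.4)
  expect_equal(round(100 * c(ema$sensitivity$lower,
                             ema$sensitivity$upper), 1), c(65.1, 95.6))
})

test_that("degenerate tables yield undefined metrics, not failures", {
  perfect <- performance_panel(two_by_two(1, 0, 0, 1), "perfect")
  expect_equal(perfect$sensitivity$point, 1)
  expect_equal(perfect$specificity$point, 1)
  expect_identical(perfect$plr, Inf)
  no_disease <- performance_panel(two_by_two(0, 2, 0, 8), "nd")
  expect_true(is.na(no_disease$sensitivity$point))
  expect_true(is.na(no_disease$ppv$point) ||
                no_disease$ppv$point == 0)
  expect_error(two_by_two(0, 0, 0, 0))
})

test_that("likelihood-ratio log-method intervals are labelled optional extras", {
  p <- performance_panel(two_by_two(25, 9, 1, 98), "ttg", lr_ci = TRUE)
  expect_true(p$plr_ci[["lower"]] < p$plr && p$plr < p$plr_ci[["upper"]])
  expect_true(p$nlr_ci[["lower"]] < p$nlr && p$nlr < p$nlr_ci[["upper"]])
  # NLR exactly 0: no interval is computable
  p0 <- performance_panel(two_by_two(26, 19, 0, 88), "poc",
                          lr_ci = TRUE)
  expect_true(all(is.na(p0$nlr_ci)))
})

test_that("Bayes predictive values match table and brute-force evaluations", {
  pv <- predictive_values_at_prevalence(1, 88 / 107, 26 / 133)
  expect_equal(pv[["ppv"]], 26 / 45, tolerance = 1e-12)
  expect_equal(pv[["npv"]], 1, tolerance = 1e-12)
  expect_equal(predictive_values_at_prevalence(0.9, 0.8, 0)[["npv"]], 1)
  pv2 <- predictive_values_at_prevalence(0.962, 0.915, 0.05)
  expect_equal(pv2, pv_brute(0.962, 0.915, 0.05), tolerance = 1e-12)
  # degenerate denominator is an explicit NA
  expect_true(is.na(
    predictive_values_at_prevalence(0.5, 1, 0)[["ppv"]]))
})

test_that("panel predictive values equal the Bayes formula at the table's own prevalence", {
  set.seed(91)
  for (i in 1:25) {
    cells <- rmultinom(1, 200, c(0.2, 0.1, 0.05, 0.65))
    tab <- tryCatch(two_by_two(cells[1], cells[2], cells[3], cells[4]),
                    error = function(e) NULL)
    if (is.null(tab)) next
    p <- performance_panel(tab, "sim")
    if (is.na(p$sensitivity$point) || is.na(p$specificity$point)) next
    pv <- predictive_values_at_prevalence(p$sensitivity$point,
                                          p$specificity$point,
                                          p$prevalence$point)
    if (!is.na(p$ppv$point) && !is.na(pv[["ppv"]])) {
      expect_equal(p$ppv$point, pv[["ppv"]], tolerance = 1e-12)
    }
    if (!is.na(p$npv$point) && !is.na(pv[["npv"]])) {
      expect_equal(p$npv$point, pv[["npv"]], tolerance = 1e-12)
    }
  }
})

test_that("exact intervals are conservative on simulated binomial draws", {
  set.seed(107)
  n <- 107; p <- 0.82; reps <- 10000
  k <- rbinom(reps, n, p)
  bounds <- vapply(0:n, function(kk) clopper_pearson(kk, n),
                   c(lower = 0, upper = 0))
  covered <- bounds["lower", k + 1] <= p & p <= bounds["upper", k + 1]
  expect_gte(mean(covered), 0.95)
})
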