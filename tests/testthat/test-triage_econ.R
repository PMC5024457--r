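test_that("cost chain reproduces the cohort economics", {
  e <- cohort_economics(133, 88, econ_params())
  expect_equal(e$gross_saving_pence, 88 * 8600)
  expect_equal(e$kit_spend_pence, 133 * 2000)
  expect_equal(e$net_saving_pence, 490800)
  expect_equal(round(100 * e$avoided_fraction, 1), 66.2)
  # per-100 figures round half-away-from-zero to whole pounds
  expect_equal(round(e$net_saving_per_100_pence / 100), 3690)
  expect_equal(round(e$tariff_saving_per_100_pence / 100), 2514)
})

test_that("cost chain edge cases and errors", {
  none <- cohort_economics(100, 0)
  expect_equal(none$gross_saving_pence, 0)
  expect_equal(none$net_saving_pence, -200000)
  all_neg <- cohort_economics(100, 100)
  expect_equal(all_neg$net_saving_pence, 100 * (8600 - 2000))
  expect_error(cohort_economics(0, 0), ">= 1")
  expect_error(cohort_economics(10, 11), "lie in")
  expect_error(econ_params(kit_cost = -1), "non-negative")
})

test_that("money is exact in pence for integer counts", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(1:500, 1)
    k <- sample(0:n, 1)
    e <- cohort_economics(n, k)
    expect_true(e$gross_saving_pence %% 1 == 0)
    expect_true(e$kit_spend_pence %% 1 == 0)
    expect_equal(e$net_saving_pence,
                 e$gross_saving_pence - e$kit_spend_pence)
  }
})

test_that("net saving is monotone in negatives and kit cost", {
  set.seed(33)
  for (i in 1:10) {
    n <- sample(50:300, 1)
    ks <- sort(sample(0:n, 5))
    nets <- vapply(ks, function(k) {
      cohort_economics(n, k)$net_saving_pence
    }, numeric(1))
    expect_true(all(diff(nets) >= 0))
    kits <- sort(runif(5, 0, 100))
    nets2 <- vapply(kits, function(kc) {
      cohort_economics(n, n %/% 2,
                       econ_params(kit_cost = round(kc, 2)))$net_saving_pence
    }, numeric(1))
    expect_true(all(diff(nets2) <= 0))
  }
})

test_that("expected negative fraction reproduces the observed cohort identity", {
  expect_equal(expected_negative_fraction(26 / 133, 1, 88 / 107),
               88 / 133, tolerance = 1e-15)
  expect_equal(expected_negative_fraction(0, 0.9, 1), 1)
  expect_equal(expected_negative_fraction(1, 1, 0.5), 0)
})

test_that("prevalence sweep matches the cohort economics at its own parameters", {
  p0 <- 26 / 133
  sweep <- prevalence_sweep(c(0.05, p0), 1, 88 / 107)
  row <- sweep[sweep$prevalence == p0, ]
  expect_equal(row$expected_negative_fraction, 88 / 133,
               tolerance = 1e-12)
  cohort <- cohort_economics(133, 88)
  expect_equal(row$net_saving, cohort$net_saving_per_100_pence / 100,
               tolerance = 1e-9)
  expect_equal(round(row$net_saving), 3690)
  expect_equal(round(row$tariff_saving), 2514)
})

test_that("prevalence sweep closed form under perfect accuracy", {
  p <- c(0.1, 0.3)
  sweep <- prevalence_sweep(p, 1, 1)
  # negatives = (1 - p); net per 100 = (1-p)*100*86 - 100*20
  expect_equal(sweep$net_saving, (1 - p) * 100 * 86 - 100 * 20,
               tolerance = 1e-9)
})

test_that("sweep saving decreases with prevalence for a perfectly sensitive test", {
  sweep <- prevalence_sweep(seq(0, 0.5, by = 0.05), 1, 88 / 107)
  expect_true(all(diff(sweep$net_saving) < 0))
  expect_error(prevalence_sweep(numeric(0), 1, 1), "empty")
  expect_error(prevalence_sweep(c(0.3, 0.1), 1, 1), "increasing")
})

test_that("break-even fraction is kit/biopsy cost with a sign flip around it", {
  be <- break_even(econ_params())
  f <- be$break_even_negative_fraction
  expect_equal(f, 20 / 86, tolerance = 1e-12)
  below <- cohort_economics(1000, round(1000 * (f - 0.02)))
  above <- cohort_economics(1000, round(1000 * (f + 0.02)))
  expect_lt(below$net_saving_pence, 0)
  expect_gt(above$net_saving_pence, 0)
  expect_equal(break_even(econ_params(kit_cost = 0))$break_even_negative_fraction,
               0)
  expect_equal(be$break_even_kit_cost_at(88 / 133), 86 * 88 / 133,
               tolerance = 1e-9)
  # any kit cost below that break-even keeps the cohort in profit
  cheaper <- cohort_economics(133, 88, econ_params(kit_cost = 56))
  expect_gt(cheaper$net_saving_pence, 0)
  expect_error(break_even(econ_params(biopsy_histology_cost = 0)),
               "positive")
})

test_that("break-even randomized grid: sign of net saving tracks the threshold", {
  set.seed(55)
  for (i in 1:20) {
    biopsy <- round(runif(1, 10, 200), 2)
    kit <- round(runif(1, 0, biopsy), 2)
    params <- econ_params(biopsy_histology_cost = biopsy,
                          kit_cost = kit)
    f_star <- break_even(params)$break_even_negative_fraction
    f <- runif(1)
    e <- cohort_economics(10000, round(10000 * f), params)
    if (abs(f - f_star) > 0.01) {
      expect_equal(e$net_saving_pence > 0, f > f_star)
    }
  }
})

test_that("economic config round-trips through JSON and YAML", {
  js <- tempfile(fileext = ".json")
  writeLines('{"biopsy_histology_cost": 86, "kit_cost": 20, "tariff_delta": 38}',
             js)
  p <- read_econ_config(js)
  expect_equal(p$biopsy_histology_cost_pence, 8600L)
  ym <- tempfile(fileext = ".yaml")
  writeLines(c("biopsy_histology_cost: 92.50", "kit_cost: 18.25",
               "tariff_delta: 38", "currency_label: EUR"), ym)
  q <- read_econ_config(ym)
  expect_equal(q$biopsy_histology_cost_pence, 9250L)
  expect_equal(q$kit_cost_pence, 1825L)
  expect_equal(q$currency_label, "EUR")
  bad <- tempfile(fileext = ".json")
  writeLines('{"kit_cost": 20}', bad)
  expect_error(read_econ_config(bad), "missing key")
})
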