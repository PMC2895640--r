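test_that("recombinant frequency is per viable cell", {
  # full viability: 20 Tyr+ on 1e7 plated -> 2e-6
  r <- frequency_record(20, 1e7, 100, 100)
  expect_equal(recomb_frequency(r)$frequency, 2e-6)
  # 50% survival doubles the per-survivor frequency
  r2 <- frequency_record(20, 1e7, 50, 100)
  expect_equal(recomb_frequency(r2)$frequency, 4e-6)
  expect_error(recomb_frequency(frequency_record(5, 1e6, 0, 100)), "> 0")
})

test_that("zero selective colonies report a detection limit", {
  out <- recomb_frequency(frequency_record(0, 1e7, 100, 100))
  expect_equal(out$frequency, 0)
  expect_equal(out$resolution_bound, 1e-7)
})

test_that("frequency is invariant to dilution bookkeeping", {
  a <- recomb_frequency(frequency_record(20, 1e7, 100, 100))
  b <- recomb_frequency(frequency_record(20, 1e5, 100, 100,
                                         selective_dilution = 100))
  expect_equal(a$frequency, b$frequency)
})

test_that("net frequency subtracts the unirradiated baseline", {
  expect_equal(as.numeric(net_frequency(12e-6, 2e-6)), 10e-6)
  expect_equal(as.numeric(net_frequency(2e-6, 2e-6)), 0)
  neg <- net_frequency(1e-6, 2e-6)
  expect_equal(as.numeric(neg), -1e-6)
  expect_true(attr(neg, "negative"))
})

test_that("induction efficiency is the through-origin slope vs dose", {
  expect_equal(induction_efficiency(c(10, 20), c(50e-6, 100e-6))$efficiency,
               5e-6, tolerance = 1e-12)
  expect_equal(induction_efficiency(c(10, 20), c(0, 0))$efficiency, 0)
  expect_error(induction_efficiency(10, 1e-6), ">= 2")
})

test_that("induction efficiency is recovered from 20% noisy dose series", {
  doses <- c(5, 10, 20, 40)
  set.seed(31)
  net <- 7e-6 * doses * (1 + stats::rnorm(length(doses), 0, 0.2))
  est <- induction_efficiency(doses, net)$efficiency
  expect_equal(est, 7e-6, tolerance = 0.20)
})

test_that("pooled summary t test reproduces the printed p = 0.002", {
  out <- summary_t_test(18, 3, 6, 60, 10, 6)
  expect_equal(abs(out$t), 4.0229, tolerance = 1e-4)
  expect_equal(out$df, 10)
  expect_equal(round(out$p, 3), 0.002)
})

test_that("Welch variant uses Satterthwaite df and is more conservative", {
  pooled <- summary_t_test(18, 3, 6, 60, 10, 6)
  welch <- summary_t_test(18, 3, 6, 60, 10, 6, var_equal = FALSE)
  expect_equal(welch$df, 5.89, tolerance = 0.01)
  expect_gt(welch$p, pooled$p)
})

test_that("summary t test handles identical groups and one tail", {
  same <- summary_t_test(10, 2, 6, 10, 2, 6)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  two <- summary_t_test(18, 3, 6, 60, 10, 6, tails = 2)
  one <- summary_t_test(18, 3, 6, 60, 10, 6, tails = 1)
  expect_equal(one$p, two$p / 2)
  expect_error(summary_t_test(1, 1, 1, 2, 1, 6), ">= 2")
})

test_that("summary t equals a raw-data pooled t fed the same summaries", {
  set.seed(8)
  x <- rnorm(7, 10, 3)
  y <- rnorm(9, 14, 5)
  raw <- stats::t.test(x, y, var.equal = TRUE)
  out <- summary_t_test(mean(x), sd(x) / sqrt(7), 7,
                        mean(y), sd(y) / sqrt(9), 9)
  expect_equal(out$t, unname(raw$statistic), tolerance = 1e-10)
  expect_equal(out$p, raw$p.value, tolerance = 1e-10)
})

test_that("Lea-Coulson median equation root matches the frozen oracle", {
  # root of 5/m - ln(m) = 1.24, solved independently by bisection
  expect_equal(lea_coulson_m(5), 2.375203, tolerance = 1e-6)
  # the returned m satisfies the defining equation
  m <- lea_coulson_m(12)
  expect_equal(12 / m - log(m), 1.24, tolerance = 1e-8)
})

test_that("median rate scales as m / cells-per-culture", {
  counts <- c(0, 1, 2, 5, 5, 7, 9, 20, 3, 4, 6, 5)
  a1 <- median_rate(fluctuation_assay(counts, 1e7), n_boot = 50, seed = 1)
  a2 <- median_rate(fluctuation_assay(counts, 2e7), n_boot = 50, seed = 1)
  expect_equal(a1$rate, 2 * a2$rate, tolerance = 1e-12)
  expect_equal(a1$m, lea_coulson_m(5))
})

test_that("an all-zero median yields a P0 upper bound, not a rate", {
  out <- median_rate(fluctuation_assay(c(0, 0, 0, 0, 1, 2), 1e7),
                     n_boot = 10, seed = 1)
  expect_true(is.na(out$rate))
  expect_equal(out$upper_bound, -log(4 / 6) / 1e7)
  expect_error(median_rate(fluctuation_assay(c(1, 2), 1e7)), ">= 5")
})

test_that("dose-modifying factor is exact for exponential curves", {
  a <- simulate_survival(40, c(10, 20, 40, 80))
  b <- simulate_survival(20, c(10, 20, 40, 80))
  expect_equal(dose_modifying_factor(a, a, 0.5), 1)
  for (level in c(0.7, 0.5, 0.2)) {
    expect_equal(dose_modifying_factor(a, b, level), 2, tolerance = 1e-9)
  }
  # reciprocity
  expect_equal(dose_modifying_factor(a, b, 0.4) *
                 dose_modifying_factor(b, a, 0.4), 1, tolerance = 1e-12)
  expect_error(dose_modifying_factor(a, b, 1e-6), "outside")
})
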