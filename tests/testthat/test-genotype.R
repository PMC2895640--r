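test_that("overlap length reproduces the heteroallele geometry", {
  expect_equal(overlap_length(c(1, 700), c(300, 1358)), 400)
  expect_equal(overlap_length(c(1, 700), c(1, 700)), 699)
  expect_equal(overlap_length(c(1, 100), c(200, 300)), 0)
})

test_that("genotypes are classified by nearest amplicon within tolerance", {
  map <- tyr1_allele_map()
  full <- classify_genotype(c(1360, 1060, 700, 400), map)
  expect_setequal(full$alleles, c("TYR1", "yr1", "ty", "y"))
  expect_true(full$re_positive)

  parental <- classify_genotype(c(1060, 700), map)
  expect_setequal(parental$alleles, c("yr1", "ty"))
  expect_false(parental$re_positive)

  odd <- classify_genotype(1500, map)
  expect_length(odd$alleles, 0)
  expect_equal(odd$unclassified, 1500)

  # gel sizing error within tolerance still classifies
  fuzzy <- classify_genotype(c(1335, 425), map)
  expect_setequal(fuzzy$alleles, c("TYR1", "y"))
})

test_that("classification round-trips every non-empty allele subset", {
  map <- tyr1_allele_map()
  names_all <- map$alleles$name
  for (bits in 1:15) {
    subset <- names_all[as.logical(bitwAnd(bits, c(1L, 2L, 4L, 8L)))]
    sizes <- map$alleles$amplicon_bp[match(subset, map$alleles$name)]
    call <- classify_genotype(sizes, map)
    expect_setequal(call$alleles, subset)
    expect_equal(call$re_positive, "y" %in% subset)
  }
})

test_that("ambiguous allele maps are rejected at validation", {
  expect_error(
    allele_map(data.frame(name = c("a", "b"), start = c(1, 1),
                          end = c(500, 600), amplicon_bp = c(500, 580)),
               tolerance_bp = 50),
    "ambiguous")
})

test_that("re_fraction gives the y-positive proportion with exact CI", {
  map <- tyr1_allele_map()
  mk <- function(y_pos) {
    sizes <- if (y_pos) c(1360, 1060, 700, 400) else c(1360, 1060, 700)
    classify_genotype(sizes, map)
  }
  calls <- c(lapply(1:5, function(i) mk(TRUE)),
             lapply(1:95, function(i) mk(FALSE)))
  out <- re_fraction(calls)
  expect_equal(out$fraction, 0.05)
  expect_equal(out$ci, stats::binom.test(5, 100)$conf.int,
               ignore_attr = TRUE)

  none <- re_fraction(lapply(1:50, function(i) mk(FALSE)))
  expect_equal(none$fraction, 0)
  expect_gt(none$ci[2], 0) # upper bound still reported
  expect_error(re_fraction(list()), "no genotype")
})

test_that("Clopper-Pearson CI is conservative on simulated panels", {
  set.seed(17)
  p <- 0.05
  hits <- vapply(1:400, function(i) {
    k <- stats::rbinom(1, 100, p)
    ci <- stats::binom.test(k, 100)$conf.int
    ci[1] <= p && p <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("expected RE frequency applies the phase correction", {
  g2 <- expected_re_frequency(0.05, 100e-6, phase = "G2")
  expect_equal(g2$frequency, 10e-6)
  expect_equal(g2$correction, 2)
  g1 <- expected_re_frequency(0.05, 100e-6, phase = "G1")
  expect_equal(g1$frequency, 5e-6)
  expect_equal(g2$frequency, 2 * g1$frequency)
  # linear in both arguments
  expect_equal(expected_re_frequency(0.10, 100e-6)$frequency,
               2 * g2$frequency)
  expect_equal(expected_re_frequency(0.05, 200e-6)$frequency,
               2 * g2$frequency)
  expect_error(expected_re_frequency(1.2, 1e-6), "\\[0, 1\\]")
})

test_that("the Monte-Carlo G2 correction matches the analytic factor 2", {
  res <- simulate_re_segregation(segregation_scenario("G2", trials = 1e5,
                                                      seed = 19))
  se <- sqrt(0.25 / 1e5)
  expect_lt(abs(res$retention_probability - 0.5), 3 * se)
  out <- expected_re_frequency(0.05, 100e-6, correction = res$correction)
  expect_equal(out$frequency, 10e-6, tolerance = 0.02)
})

test_that("marker retention percentage", {
  expect_equal(marker_retention(160, 4), 2.5)
  expect_equal(marker_retention(160, 0), 0)
  expect_equal(marker_retention(10, 10), 100)
  expect_error(marker_retention(0, 0), "> 0")
  expect_error(marker_retention(10, 11), "exceed")
})
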