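test_that("zero breakage rate leaves every band at full intensity", {
  kar <- yeast_karyotype(ploidy = 4, replicated = TRUE)
  tab <- simulate_gel_lanes(kar, breakage_params(0, 80, seed = 1))
  ctrl <- tab$bands[tab$bands$lane_id == "control", ]
  dose <- tab$bands[tab$bands$lane_id != "control", ]
  expect_equal(dose$intensity[match(ctrl$band_id, dose$band_id)],
               ctrl$intensity)
})

test_that("noise-free intensity ratio follows the closed form exp(-k*D*L)", {
  kar <- one_chrom_karyotype(1.0)
  tab <- simulate_gel_lanes(kar, breakage_params(0.07, 80, noise_cv = 0,
                                                 seed = 1))
  ctrl <- tab$bands$intensity[tab$bands$lane_id == "control"]
  dose <- tab$bands$intensity[tab$bands$lane_id != "control"]
  expect_equal(dose / ctrl, exp(-5.6), tolerance = 1e-12)
})

test_that("Monte-Carlo unbroken fraction agrees with the closed form", {
  kar <- one_chrom_karyotype(1.0)
  n <- 1e4
  tab <- simulate_gel_lanes(kar, breakage_params(0.07, 80, seed = 42),
                            mc_copies = n)
  ctrl <- tab$bands$intensity[tab$bands$lane_id == "control"]
  dose <- tab$bands$intensity[tab$bands$lane_id != "control"]
  p <- exp(-5.6)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(dose / ctrl - p), 3 * se)
})

test_that("chromosomes within the comigration threshold share a band", {
  kar <- karyotype(data.frame(name = c("a", "b", "c"),
                              size_mb = c(0.560, 0.575, 1.0)))
  tab <- simulate_gel_lanes(kar, breakage_params(0, 10, seed = 1))
  ctrl <- tab$bands[tab$bands$lane_id == "control", ]
  expect_equal(nrow(ctrl), 2L)
  merged <- ctrl[ctrl$comigrating, ]
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$chromosomes, "a;b")
  expect_equal(merged$intensity, 2) # summed copies at full intensity
})

test_that("bands outside the CHEF resolution window are flagged", {
  kar <- karyotype(data.frame(name = c("small", "big", "mid"),
                              size_mb = c(0.1, 2.0, 1.0)))
  tab <- simulate_gel_lanes(kar, breakage_params(0.07, 40, seed = 1))
  ctrl <- tab$bands[tab$bands$lane_id == "control", ]
  expect_equal(ctrl$resolvable[order(ctrl$size_kb)], c(FALSE, TRUE, FALSE))
})

test_that("identical seeds give identical tables and seeds matter", {
  kar <- yeast_karyotype(ploidy = 4, replicated = TRUE)
  p <- breakage_params(0.07, 80, noise_cv = 0.05, loading_factor_sd = 0.1,
                       seed = 9)
  t1 <- simulate_gel_lanes(kar, p)
  t2 <- simulate_gel_lanes(kar, p)
  expect_identical(t1, t2)
  p2 <- breakage_params(0.07, 80, noise_cv = 0.05, loading_factor_sd = 0.1,
                        seed = 10)
  t3 <- simulate_gel_lanes(kar, p2)
  expect_false(identical(t1$bands$intensity, t3$bands$intensity))
})

test_that("invalid simulation inputs are rejected", {
  kar <- yeast_karyotype()
  expect_error(simulate_gel_lanes(kar, breakage_params(0.07, 80),
                                  timepoints = -1), "non-negative")
  expect_error(breakage_params(-0.1, 80), ">= 0")
  expect_error(repair_kinetics(1, plateau = 1.5), "0, 1")
})
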