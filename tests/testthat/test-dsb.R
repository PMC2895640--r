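test_that("fraction unbroken is the dose/control intensity ratio", {
  expect_equal(as.numeric(fraction_unbroken(100, 100)), 1)
  expect_equal(as.numeric(fraction_unbroken(50, 100)), 0.5)
  f <- fraction_unbroken(110, 100)
  expect_equal(as.numeric(f), 1)
  expect_true(attr(f, "clamped"))
  expect_false(attr(fraction_unbroken(90, 100), "clamped"))
  expect_error(fraction_unbroken(10, 0), "control")
  expect_error(fraction_unbroken(-1, 100), ">= 0")
})

test_that("zero-class estimator maps F to mean breaks per chromosome", {
  expect_equal(breaks_per_chromosome(1), 0)
  expect_equal(breaks_per_chromosome(exp(-1)), 1)
  expect_equal(breaks_per_chromosome(0.5), log(2))
  expect_error(breaks_per_chromosome(0), "excluded")
  expect_error(breaks_per_chromosome(1.1), "excluded|\\(0, 1\\]")
})

test_that("through-origin fit recovers an exact Poisson line", {
  est <- fit_dsb_density(c(0.25, 1, 1.5), c(1.40, 5.60, 8.40))
  expect_equal(est$density, 5.6, tolerance = 1e-12)
  expect_lt(est$stderr, 1e-10)
  expect_equal(fit_dsb_density(c(0.5, 1), c(0, 0))$density, 0)
  expect_error(fit_dsb_density(1, 1), "at least 2")
})

test_that("free-intercept mode is available for diagnostics", {
  est <- fit_dsb_density(c(0.25, 1, 1.5), c(1.40, 5.60, 8.40) + 0.5,
                         through_origin = FALSE)
  expect_equal(est$density, 5.6, tolerance = 1e-10)
  expect_equal(est$intercept, 0.5, tolerance = 1e-10)
})

test_that("quantify_dsb reproduces exact densities from a manual table", {
  tab <- make_manual_gel()
  dens <- quantify_dsb(tab)
  # N = (1.4, 5.6, 8.4) at L = (0.25, 1.0, 1.5): exact slope 5.6 DSB/Mb
  expect_equal(dens$density, 5.6, tolerance = 1e-10)
  expect_equal(dens$n_bands, 3L)
})

test_that("density recovery from noisy synthetic lanes is within 10%", {
  kar <- yeast_karyotype(ploidy = 4, replicated = TRUE)
  tab <- simulate_gel_lanes(kar, breakage_params(0.07, 80, noise_cv = 0.05,
                                                 seed = 7))
  dens <- quantify_dsb(tab)
  expect_equal(dens$density / 80, 0.07, tolerance = 0.10)
})

test_that("the slope is invariant under a global intensity rescale", {
  kar <- yeast_karyotype(ploidy = 4, replicated = TRUE)
  tab <- simulate_gel_lanes(kar, breakage_params(0.07, 40, noise_cv = 0.05,
                                                 seed = 5))
  base <- quantify_dsb(tab)
  scaled <- tab
  scaled$bands$intensity <- scaled$bands$intensity * 37.4
  expect_identical(quantify_dsb(scaled)$density, base$density)
})

test_that("identical tables give bit-identical estimates", {
  tab <- make_manual_gel()
  expect_identical(quantify_dsb(tab), quantify_dsb(tab))
})

test_that("comigrating and unresolvable bands are excluded with reasons", {
  kar <- karyotype(data.frame(name = c("a", "b", "c", "d", "tiny"),
                              size_mb = c(0.560, 0.575, 1.0, 1.4, 0.05)))
  tab <- simulate_gel_lanes(kar, breakage_params(0.05, 40, seed = 2))
  dens <- quantify_dsb(tab)
  est <- dens$estimate[[1]]
  expect_setequal(est$excluded$reason,
                  c("comigrating", "outside resolution window"))
  expect_equal(est$n_bands, 2L) # only c and d enter the fit
})

test_that("repair time course recovers the generating unrepaired fraction", {
  kar <- yeast_karyotype(ploidy = 4, replicated = TRUE)
  # q(4h) ~ plateau when rate is fast: 30% of breaks remain
  kin <- repair_kinetics(rate = 10, plateau = 0.30)
  tab <- simulate_gel_lanes(kar, breakage_params(0.07, 80, seed = 3),
                            timepoints = c(0, 4), kinetics = kin)
  tc <- repair_time_course(tab)
  expect_equal(tc$fraction_unrepaired[tc$time_h == 0], 1)
  expect_equal(tc$fraction_unrepaired[tc$time_h == 4], 0.30,
               tolerance = 1e-6)
  expect_equal(tc$fraction_repaired[tc$time_h == 4], 0.70,
               tolerance = 1e-6)
})

test_that("a 4-fold strain contrast in unrepaired breaks is recovered", {
  kar <- yeast_karyotype(ploidy = 4, replicated = TRUE)
  mk <- function(plateau, seed, strain) {
    simulate_gel_lanes(kar, breakage_params(0.07, 80, noise_cv = 0.05,
                                            seed = seed),
                       timepoints = c(0, 4),
                       kinetics = repair_kinetics(10, plateau),
                       strain = strain)
  }
  wt <- repair_time_course(mk(0.06, 21, "WT"))
  mut <- repair_time_course(mk(0.24, 22, "simplex"))
  ratio <- mut$fraction_unrepaired[mut$time_h == 4] /
    wt$fraction_unrepaired[wt$time_h == 4]
  expect_equal(ratio, 4, tolerance = 0.25)
})

test_that("repair time course requires a t = 0 lane", {
  kar <- yeast_karyotype(ploidy = 4, replicated = TRUE)
  tab <- simulate_gel_lanes(kar, breakage_params(0.07, 80, seed = 1),
                            timepoints = c(1, 4),
                            kinetics = repair_kinetics(1))
  expect_error(repair_time_course(tab), "t = 0")
})

test_that("expected DSB burden is kappa * dose * genome megabases", {
  g2_tetra <- yeast_karyotype(ploidy = 4, replicated = TRUE)
  expect_equal(expected_dsbs(0.07, 0, g2_tetra), 0)
  expect_equal(expected_dsbs(0.07, 80, g2_tetra), 0.07 * 80 * 8 * 12.071,
               tolerance = 1e-9)
  # linear in dose and genome size
  expect_equal(expected_dsbs(0.07, 40, g2_tetra),
               expected_dsbs(0.07, 80, g2_tetra) / 2)
  haploid <- yeast_karyotype()
  expect_equal(expected_dsbs(0.07, 80, g2_tetra),
               8 * expected_dsbs(0.07, 80, haploid))
})
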