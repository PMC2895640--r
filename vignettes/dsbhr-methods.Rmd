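---
title: "Models and methods behind dsbhr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dsbhr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbhr)
```

This vignette explains the statistical models the package implements, the
assumptions they carry, what the synthetic-data generators do and do not
emulate, and the numerical and design choices that were genuinely open.

## Random-breakage quantification of DSBs

A dose `D` krad of ionizing radiation deposits double-strand breaks
approximately uniformly along the genome, so the number of breaks on a
chromosome of size `L` Mb is Poisson with mean `r L`, where `r = kappa * D`
and `kappa` is the induction efficiency in DSBs/Mb/krad. A pulsed-field gel
only retains a chromosome in its full-length band if it carries *zero*
breaks, so the band-intensity ratio against the unirradiated control lane
estimates the Poisson zero class:

```
F = I_dose / I_control,     N = -ln(F),     N = r * L.
```

`fit_dsb_density()` regresses `N` on `L`. The regression runs **through the
origin by default**: a chromosome of zero length can carry no breaks, and
the Poisson model forces exact proportionality, so a free intercept only
adds variance (it remains available, `through_origin = FALSE`, as a
diagnostic for background-subtraction problems in the intensity table).
Because each `F` is a within-gel ratio, every downstream quantity is
invariant to a global rescaling of intensities, i.e. to the amount of DNA
loaded; this is asserted as a property test.

Assumptions worth keeping in mind: breaks land independently and uniformly
(no hotspots), band intensity is proportional to the number of full-length
molecules (background-corrected "net" intensities), and the control lane
measures the same loading regime as the dose lanes of its strain group —
`quantify_dsb()` therefore never ratios across strains.

### Band-level policies

* **`F > 1` (clamp policy).** Densitometry noise can push a ratio above 1.
  The default clamps to 1 (`N = 0`) and flags the band, preserving the band
  count; `clamp = FALSE` excludes such bands instead. Clamping introduces a
  small downward bias at very low doses but keeps short chromosomes (whose
  true `N` is near 0) in the fit.
* **`F <= 0`.** A band with no remaining signal has lost the quantity being
  measured; it is excluded with a recorded reason rather than mapped to an
  infinite break count.
* **Comigration.** Chromosomes whose sizes differ by less than 5%
  (configurable) are merged into one band with summed intensity and
  excluded from fits by default: the merged intensity mixes two break
  probabilities and no longer estimates a single zero class. With the
  packaged karyotype this collapses V/VIII, XIV/II, XIII/XVI and
  VII/XV/XII, leaving six single-chromosome bands in the resolvable range.
* **Resolution window.** Bands outside 250–1600 kb (the window the CHEF
  program separates) are flagged unresolvable and excluded by default.

### Expected burden and repair

`expected_dsbs(kappa, dose, karyotype)` is `kappa * dose * genome_Mb`,
with genome size ploidy-aware and doubled for replicated (G2/M) cells. The
packaged karyotype uses the conventional 16-chromosome size table
(12.071 Mb per haploid set, rDNA array not counted), so a G2/M tetraploid
at `kappa = 0.07`, 80 krad gives ~541 DSBs/cell; published round figures
of "about 600" correspond to a slightly larger assumed genome (the rDNA
array alone adds 1–2 Mb per set). The package reports the value its
stated genome implies rather than forcing agreement with any rounded
figure; the karyotype file is the single place the assumption lives.

Repair is summarized as `density(t) / density(0)` from per-timepoint fits,
pooling all resolvable bands rather than averaging per-band ratios; the
complement is the repaired fraction. This requires a lane taken
immediately after irradiation (`t = 0`), which anchors the induced burden.

## The gel simulator

`simulate_gel_lanes()` inverts the estimator: expected band intensity is
`loading * copies * exp(-kappa * D * L * u(t)) * noise`, where `u(t)` is
the unrepaired fraction under exponential rejoining kinetics
(`u(t) = plateau + (1 - plateau) e^{-rate t}`), `loading` is a per-lane
log-normal scalar (SD `loading_factor_sd`), and `noise` is mean-1
multiplicative log-normal with coefficient of variation `noise_cv`.
Multiplicative noise reflects how densitometry errors scale with signal;
additive background is assumed already subtracted. An optional
`mc_copies` mode replaces the expectation `exp(-kappa D L u)` with a
binomial draw over a finite number of chromatids, which is how the
closed-form/Monte-Carlo agreement test (3 binomial SEs at 10^4 copies)
is run.

The paper trail for densitometry noise magnitudes in this kind of assay is
thin; `noise_cv` has no privileged default and is surfaced in every
configuration (the recovery tests use 0.05, a mid-range densitometry CV).
What the simulator does **not** model: gel physics (migration, smearing,
compression near the well), partial-length fragments, hotspot breakage, or
inter-gel calibration. Passing recovery tests therefore show the
estimators are correct *under the random-breakage model with proportional
noise*, not that real gels are free of systematic artifacts.

## Fluctuation analysis

`simulate_fluctuation()` uses the generation-wise approximation: cultures
double deterministically from an inoculum of `n_final / 2^G` cells
(`G = floor(log2 n_final)`); each wild-type division mutates with
probability `rate`; mutant lineages double deterministically with no death
and no differential fitness. Early mutations found jackpot clones, giving
the Luria–Delbrück over-dispersion the variance/mean property test checks.

`median_rate()` estimates the expected mutations per culture `m` from the
Lea–Coulson median equation `r/m - ln m = 1.24` (unique root, solved by
bracketed bisection to 1e-10) and reports `rate = m / N`.

**Confidence intervals.** The default is a parametric ratio-pivot
bootstrap: each resample simulates a complete assay from the package's own
growth model at the fitted rate, re-estimates `m*`, and the empirical
distribution of `m*/m_hat` is inverted into an interval for `m`. This
choice was forced by measurement. A naive percentile bootstrap over
cultures undercovers badly at 24 cultures (observed ~65–80% against a 95%
nominal level) for two reasons: the median of two dozen small counts
resamples on a coarse grid, and the median equation — derived for
continuous-time growth — sits slightly high relative to the synchronized
discrete-generation process (independent continuous-time simulations
match the 1.24 relation; the discrete process's median is ~15% lower).
The ratio pivot carries both effects, and its measured self-consistency
coverage is 92–95% at generating rates 1.5–2.5e-6 with 24 cultures of
1e7 cells. The percentile bootstrap remains available
(`ci_method = "nonparametric"`) for comparison. Each parametric resample
simulates a full assay, so `n_boot` defaults to 1000 (distinct medians
are root-solved once and cached in the nonparametric path).

When the median count is 0 the median method is uninformative and the
package reports only an upper bound from the P0 (zero-class) relation
`m <= -ln(fraction of mutant-free cultures)` rather than a point estimate.

## Survival, DMF and summary t tests

Survival curves store dilution-corrected colony ratios with `S(0) = 1` by
construction; sampling can push later points above 1, which is kept but
flagged. The dose-modifying factor interpolates dose as a function of
log-survival — exact for exponential killing, near-exact between adjacent
doses otherwise — and satisfies the reciprocity identity
`DMF(A,B) * DMF(B,A) = 1` by construction. No parametric curve is fitted
unless the user does so explicitly; `simulate_survival()` generates pure
exponentials (optionally with binomial plating noise) for testing.

`summary_t_test()` exists because published comparisons are often given
only as mean ± SEM with n. The pooled-variance form (`SD = SEM * sqrt(n)`,
`df = n1 + n2 - 2`) exactly reproduces a raw-data pooled t fed the same
summaries — a property test checks this — and reproduces a published
p = 0.002 benchmark (18±3 vs 60±10, n = 6 per group) to the printed
precision. The Welch variant is available; one- vs two-tailed is always
caller-specified. Summary-based tests cannot recover information lost in
summarization (pairing, non-normality), so results on other people's
summaries are indicative, not exact.

## Reciprocal-exchange genotyping and the G2 correction

The heteroallele reporter: `ty` spans ORF nucleotides 1–700, `yr1` spans
300–1358, a 400 bp overlap (`overlap_length()` uses the
`min(end) - max(start)` convention, which reproduces the printed 400 from
those coordinates). Amplicon sizes 1360/1060/700/400 bp identify
`TYR1`/`yr1`/`ty`/`y`. The expected sizes are carried **verbatim** rather
than recomputed from coordinates, because the full-length amplicon (1360)
exceeds the ORF span (1358) by primer context; interval arithmetic is
used only for overlap geometry. Band matching assigns each observed size
to the nearest expected size within ±50 bp (typical agarose sizing error,
configurable); maps whose expected sizes are separated by less than twice
the tolerance are rejected at validation, so classification can never be
ambiguous per call.

A colony with the `y` allele arose by reciprocal exchange. The observed
`y` fraction is a *minimal* estimate: a G2 exchange involves one chromatid
of each homolog, and random sister segregation delivers the `y` chromatid
to the selected `TYR1+` daughter only half the time.
`simulate_re_segregation()` implements exactly this bookkeeping — one
exchange between a `ty` chromatid and a `yr1` chromatid, independent
uniform segregation of each sister pair — and its retention probability
converges to 1/2 (G2) and is exactly 1 (G1, returned without simulation
since the result is deterministic). `expected_re_frequency()` multiplies
fraction × correction × induced frequency, taking the correction either
analytically (2 for G2, 1 for G1) or from the Monte Carlo as
`1/retention`. Both the uncorrected fraction and the corrected expectation
are always reported, never one silently replacing the other. Long-tract
crossovers produce no `y` allele and are invisible to this assay; the
correction does not (and cannot) account for them.

`re_fraction()` uses the exact Clopper–Pearson interval: colony panels are
small (tens to low hundreds) and the `y` fraction is near the boundary,
where normal approximations fail; conservativeness is acceptable for a
bound that is already labelled minimal.

## Synthetic data: what passing tests mean

The generators reproduce the *statistical structure the estimators
assume* — Poisson breakage, proportional noise, per-lane loading,
Luria–Delbrück jackpots, binomial segregation, exponential killing — with
every source of randomness behind an explicit seed (simulators save and
restore the caller's RNG state, so there is no hidden global coupling).
Recovery and coverage results on them validate the estimators'
correctness and internal consistency, not the biological fidelity of any
particular experiment: systematic gel artifacts, culture-to-culture
growth variation, plating efficiency drift and genotyping errors are all
outside the generators' scope.

Problem sizes used by the shipped tests were chosen as the smallest that
make the statistical assertions sharp: 10^4 chromatid copies for the
closed-form/Monte-Carlo bound (3 binomial SEs), 10^5 trials for the
segregation correction, 24 cultures × 1e7 cells × 120 replicate assays
per rate for CI coverage, and two doses (40/80 krad) at 5% band noise for
density recovery.

## Known limitations

* The zero-class estimator saturates at high `kappa * D * L`: once `F`
  approaches the noise floor the band is excluded and large chromosomes
  stop contributing, narrowing the fitted size range.
* The repair summary assumes rejoined chromosomes are full-length;
  misrepair that restores size is indistinguishable from correct repair on
  a gel.
* The fluctuation machinery assumes equal culture sizes and no post-plating
  death; the parametric CI is calibrated on the package's growth model and
  inherits its idealizations.
* The G2 correction assumes all selected recombinants arose in the assayed
  phase; mixed-phase populations need the fraction partitioned externally.
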