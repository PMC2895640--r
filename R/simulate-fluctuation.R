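#' Simulate Luria-Delbruck fluctuation cultures
#'
#' Grows each culture from a small inoculum by deterministic doubling; at
#' every generation each newly produced wild-type cell mutates independently
#' with probability `rate`, and each mutant lineage thereafter doubles
#' deterministically (no death, no differential fitness). Mutants arising
#' early therefore found large "jackpot" clones, producing the heavy-tailed
#' mutant-count distribution characteristic of fluctuation assays.
#'
#' The number of generations is `floor(log2(n_final))`; the inoculum is
#' `n_final / 2^generations` (between 1 and 2 cells), so the final
#' population size is exactly `n_final`.
#'
#' @param rate mutation probability per cell per division (`0 <= rate << 1`).
#' @param n_final cells per culture at plating (>= 10).
#' @param cultures number of parallel cultures.
#' @param seed integer seed.
#' @return A [fluctuation_assay()] with per-culture mutant counts.
#' @examples
#' a <- simulate_fluctuation(1.5e-6, 1e7, cultures = 24, seed = 11)
#' a$counts
#' @export
simulate_fluctuation <- function(rate, n_final, cultures, seed = 1L) {
  stop_scalar(rate, "rate", nonneg = TRUE)
  stop_scalar(n_final, "n_final", positive = TRUE)
  stop_scalar(cultures, "cultures", positive = TRUE)
  if (n_final < 10) stop("`n_final` must be >= 10", call. = FALSE)
  if (rate >= 0.1) stop("`rate` must be << 1", call. = FALSE)
  if (rate * n_final > 1e6) {
    stop("rate * n_final too large; counts would overflow the simulation",
         call. = FALSE)
  }
  counts <- with_seed(seed, .sim_fluct_counts(rate, n_final, cultures))
  fluctuation_assay(counts, cells_per_culture = n_final)
}

# Vectorized core: one generation-wise binomial draw across all cultures.
# One mutation opportunity per wild-type cell division; mutant lineages
# double deterministically. Uses the current RNG state (callers seed it).
.sim_fluct_counts <- function(rate, n_final, cultures) {
  gens <- floor(log2(n_final))
  n0 <- n_final / 2^gens
  mutants <- numeric(cultures)
  n_wt <- rep(n0, cultures)
  for (g in seq_len(gens)) {
    new_mut <- stats::rbinom(cultures, round(n_wt), rate)
    mutants <- 2 * mutants + new_mut
    n_wt <- 2 * n_wt - new_mut
  }
  mutants
}

#' Fluctuation-assay container
#'
#' Per-culture mutant (recombinant) counts with the final cell number per
#' culture, as consumed by [median_rate()].
#'
#' @param counts non-negative integer vector, one element per culture.
#' @param cells_per_culture cells per culture at plating.
#' @return A `fluctuation_assay` object.
#' @export
fluctuation_assay <- function(counts, cells_per_culture) {
  if (!is.numeric(counts) || any(counts < 0) || any(!is.finite(counts))) {
    stop("`counts` must be non-negative numbers", call. = FALSE)
  }
  stop_scalar(cells_per_culture, "cells_per_culture", positive = TRUE)
  structure(list(counts = as.numeric(counts),
                 cells_per_culture = cells_per_culture),
            class = "fluctuation_assay")
}

#' @export
print.fluctuation_assay <- function(x, ...) {
  cat(sprintf(
    "fluctuation_assay: %d cultures, median count %g, %.3g cells/culture\n",
    length(x$counts), stats::median(x$counts), x$cells_per_culture))
  invisible(x)
}
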