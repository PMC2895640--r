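#' Segregation scenario for reciprocal-exchange Monte Carlo
#'
#' Describes when a reciprocal exchange (RE) between the 5'-truncated `ty`
#' allele and the 3'-truncated `yr1` allele occurs relative to replication.
#' In G1 the exchange happens before replication, so both sister chromatids
#' of each product are identical and every daughter inherits the full set of
#' products. In G2 the exchange involves one `ty` chromatid and one `yr1`
#' chromatid; sister chromatids then segregate randomly at mitosis, so only
#' half the daughters that receive the reconstituted `TYR1` chromatid also
#' receive the reciprocal `y` chromatid.
#'
#' @param phase `"G1"` or `"G2"`.
#' @param n_ty,n_yr1 numbers of `ty` and `yr1` homologs (tetraploid default
#'   2 + 2).
#' @param trials Monte-Carlo trials (>= 1).
#' @param seed integer seed.
#' @return A `segregation_scenario` list.
#' @export
segregation_scenario <- function(phase = c("G2", "G1"), n_ty = 2L,
                                 n_yr1 = 2L, trials = 1e5, seed = 1L) {
  phase <- match.arg(phase)
  stop_scalar(n_ty, "n_ty", positive = TRUE)
  stop_scalar(n_yr1, "n_yr1", positive = TRUE)
  stop_scalar(trials, "trials", positive = TRUE)
  structure(list(phase = phase, n_ty = as.integer(n_ty),
                 n_yr1 = as.integer(n_yr1), trials = as.integer(trials),
                 seed = as.integer(seed)),
            class = "segregation_scenario")
}

#' Monte-Carlo y-allele retention after a reciprocal exchange
#'
#' Simulates one reciprocal exchange within the `ty`/`yr1` overlap and the
#' subsequent mitotic segregation, and returns the probability that a
#' daughter selected for carrying the reconstituted `TYR1` chromatid also
#' carries the reciprocal `y` chromatid. For G1 exchanges this probability
#' is exactly 1 (both products are replicated into both daughters' lineages
#' equally: each daughter receives one chromatid of each product). For G2
#' exchanges, the `TYR1` and `y` products sit on sister-chromatid pairs of
#' two different homologs which segregate independently and uniformly, so
#' retention converges to 1/2. The reciprocal of the retention probability
#' is the correction factor applied by [expected_re_frequency()].
#'
#' @param scenario a [segregation_scenario()].
#' @return List with `retention_probability`, its binomial `se`,
#'   `correction` (= 1/retention), `phase` and `trials`.
#' @examples
#' simulate_re_segregation(segregation_scenario("G2", trials = 1e4, seed = 3))
#' @export
simulate_re_segregation <- function(scenario) {
  stopifnot(inherits(scenario, "segregation_scenario"))
  if (scenario$phase == "G1") {
    # exchange precedes replication: the TYR1 product and the y product are
    # each replicated, and mitosis delivers one sister of every homolog to
    # each daughter, so every TYR1+ daughter carries y deterministically
    return(list(retention_probability = 1, se = 0, correction = 1,
                phase = "G1", trials = scenario$trials))
  }
  retained <- with_seed(scenario$seed, {
    n_hom <- scenario$n_ty + scenario$n_yr1
    vapply(seq_len(scenario$trials), function(i) {
      # After replication each homolog is a sister pair. The RE converts one
      # chromatid of one ty homolog into TYR1 and one chromatid of one yr1
      # homolog into y; the untouched sisters keep their parental alleles.
      # Each homolog's two sisters segregate independently, one per daughter.
      side <- sample(c(1L, 2L), n_hom, replace = TRUE)
      tyr1_daughter <- side[1L]      # homolog 1 = the exchanged ty homolog
      y_daughter <- side[scenario$n_ty + 1L] # the exchanged yr1 homolog
      as.numeric(y_daughter == tyr1_daughter)
    }, numeric(1))
  })
  p <- mean(retained)
  se <- sqrt(p * (1 - p) / scenario$trials)
  list(retention_probability = p, se = se,
       correction = if (p > 0) 1 / p else NA_real_,
       phase = "G2", trials = scenario$trials)
}
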