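#' Allele map for TYR1 heteroallele genotyping
#'
#' The recombination reporter places two truncated alleles of `TYR1` on
#' homologous chromosomes: `ty` keeps the 5' portion of the ORF
#' (nucleotides 1-700) and `yr1` the 3' portion (nucleotides 300-1358),
#' sharing a 400 bp overlap. Recombination within the overlap reconstitutes
#' `TYR1`; a reciprocal exchange additionally produces the `y` allele that
#' retains only the overlap. PCR across the locus distinguishes the four
#' alleles by amplicon size: 1360 bp (`TYR1`), 1060 bp (`yr1`), 700 bp
#' (`ty`) and 400 bp (`y`). Expected sizes are carried verbatim (they are
#' the printed amplicon sizes, which include primer context beyond the ORF
#' coordinates); ORF intervals are used only for overlap arithmetic.
#'
#' @param alleles data.frame with columns `name`, `start`, `end` (1-based
#'   inclusive ORF coordinates), `amplicon_bp` (expected PCR product size).
#' @param tolerance_bp size-matching tolerance (default 50 bp, a typical
#'   agarose sizing error). Expected sizes must be separated by more than
#'   twice the tolerance or classification would be ambiguous.
#' @return An `allele_map` object.
#' @examples
#' tyr1_allele_map()
#' @export
allele_map <- function(alleles, tolerance_bp = 50) {
  need <- c("name", "start", "end", "amplicon_bp")
  if (!is.data.frame(alleles) || !all(need %in% names(alleles))) {
    stop("`alleles` must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  stop_scalar(tolerance_bp, "tolerance_bp", positive = TRUE)
  sizes <- sort(alleles$amplicon_bp)
  if (any(diff(sizes) <= 2 * tolerance_bp)) {
    stop("expected amplicon sizes must be separated by more than twice ",
         "the tolerance; classification would be ambiguous", call. = FALSE)
  }
  if (any(alleles$start < 1) || any(alleles$end <= alleles$start)) {
    stop("allele intervals must satisfy 1 <= start < end", call. = FALSE)
  }
  structure(list(alleles = alleles, tolerance_bp = tolerance_bp),
            class = "allele_map")
}

#' Default TYR1 heteroallele map
#'
#' @inheritParams allele_map
#' @return An [allele_map()] with the four TYR1-locus alleles.
#' @export
tyr1_allele_map <- function(tolerance_bp = 50) {
  allele_map(
    data.frame(
      name = c("TYR1", "yr1", "ty", "y"),
      start = c(1, 300, 1, 300),
      end = c(1358, 1358, 700, 700),
      amplicon_bp = c(1360, 1060, 700, 400),
      stringsAsFactors = FALSE
    ),
    tolerance_bp = tolerance_bp
  )
}

#' Read an allele map from a YAML config
#'
#' The file holds `tolerance_bp` and a list `alleles` of records with
#' `name`, `start`, `end`, `amplicon_bp`; the packaged default (matching
#' [tyr1_allele_map()]) lives at
#' `system.file("extdata", "tyr1_alleles.yaml", package = "dsbhr")`.
#'
#' @param path YAML file.
#' @return An [allele_map()].
#' @export
read_allele_map <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("allele map file not found: %s", path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  alleles <- do.call(rbind, lapply(cfg$alleles, function(a) {
    data.frame(name = as.character(a$name), start = a$start, end = a$end,
               amplicon_bp = a$amplicon_bp, stringsAsFactors = FALSE)
  }))
  allele_map(alleles, tolerance_bp = cfg$tolerance_bp)
}

#' Overlap length between two allele intervals
#'
#' Length of the intersection of two 1-based inclusive intervals under the
#' `min(end) - max(start)` convention, which reproduces the 400 bp overlap
#' of the `ty` (1-700) and `yr1` (300-1358) truncations; disjoint intervals
#' give 0.
#'
#' @param a,b length-2 numeric vectors `c(start, end)`.
#' @return Overlap length in bp.
#' @examples
#' overlap_length(c(1, 700), c(300, 1358)) # 400
#' @export
overlap_length <- function(a, b) {
  stopifnot(length(a) == 2L, length(b) == 2L, a[1] <= a[2], b[1] <= b[2])
  max(0, min(a[2], b[2]) - max(a[1], b[1]))
}

#' Classify a colony's alleles from observed amplicon sizes
#'
#' Assigns each observed band to the nearest expected amplicon size within
#' the map's tolerance; bands matching nothing are reported unclassified.
#' A colony is scored as a reciprocal-exchange product (`re_positive`) when
#' the `y` allele is present.
#'
#' @param sizes_bp observed band sizes in bp (positive).
#' @param map an [allele_map()].
#' @param colony_id optional identifier carried into the call.
#' @return A `genotype_call`: list with `colony_id`, `alleles` (character
#'   subset of the map's names), `re_positive`, `unclassified` (numeric).
#' @examples
#' classify_genotype(c(1360, 1060, 700, 400), tyr1_allele_map())$re_positive
#' @export
classify_genotype <- function(sizes_bp, map = tyr1_allele_map(),
                              colony_id = NA_character_) {
  stopifnot(inherits(map, "allele_map"))
  if (length(sizes_bp) > 0 && any(sizes_bp <= 0)) {
    stop("band sizes must be positive", call. = FALSE)
  }
  alleles <- character()
  unclassified <- numeric()
  for (s in sizes_bp) {
    d <- abs(map$alleles$amplicon_bp - s)
    i <- which.min(d)
    if (d[i] <= map$tolerance_bp) {
      alleles <- union(alleles, map$alleles$name[i])
    } else {
      unclassified <- c(unclassified, s)
    }
  }
  structure(
    list(colony_id = colony_id, alleles = alleles,
         re_positive = "y" %in% alleles, unclassified = unclassified),
    class = "genotype_call"
  )
}

#' Minimal reciprocal-exchange fraction among Tyr+ recombinants
#'
#' The fraction of genotyped colonies carrying the `y` allele, with an
#' exact (Clopper-Pearson) binomial confidence interval. This is a
#' *minimal* estimate of the reciprocal-exchange fraction: G2 exchanges
#' lose the `y` chromatid to the sister daughter half the time, and long
#' conversion tracts erase the `y` product altogether.
#'
#' @param calls list of `genotype_call` objects (>= 1).
#' @param conf confidence level (default 0.95).
#' @return List with `n_colonies`, `n_y_positive`, `fraction`, `ci`.
#' @export
re_fraction <- function(calls, conf = 0.95) {
  if (length(calls) == 0L) stop("no genotype calls supplied", call. = FALSE)
  stopifnot(all(vapply(calls, inherits, logical(1), "genotype_call")))
  n <- length(calls)
  k <- sum(vapply(calls, `[[`, logical(1), "re_positive"))
  ci <- stats::binom.test(k, n, conf.level = conf)$conf.int
  list(n_colonies = n, n_y_positive = k, fraction = k / n,
       ci = as.numeric(ci))
}

#' Expected reciprocal-exchange frequency per survivor
#'
#' Multiplies the minimal RE fraction among Tyr+ recombinants by the
#' phase-dependent segregation correction (2 for G2 exchanges, where random
#' sister-chromatid segregation hides half the `y` alleles; 1 for G1) and
#' by the induced Tyr+ recombinant frequency. The correction can instead be
#' supplied explicitly, e.g. `1 / retention_probability` from
#' [simulate_re_segregation()]. Both the uncorrected fraction and the
#' corrected expectation are returned.
#'
#' @param fraction minimal RE fraction in [0, 1].
#' @param induced_freq net Tyr+ frequency per survivor (>= 0).
#' @param phase `"G2"` (default) or `"G1"`; ignored when `correction` is
#'   given.
#' @param correction optional explicit correction factor (>= 1).
#' @return List with `frequency`, `correction`, `fraction`,
#'   `correction_source`.
#' @examples
#' expected_re_frequency(0.05, 100e-6, phase = "G2")$frequency # 1e-5
#' @export
expected_re_frequency <- function(fraction, induced_freq,
                                  phase = c("G2", "G1"),
                                  correction = NULL) {
  stop_scalar(fraction, "fraction", nonneg = TRUE)
  if (fraction > 1) stop("`fraction` must lie in [0, 1]", call. = FALSE)
  stop_scalar(induced_freq, "induced_freq", nonneg = TRUE)
  if (is.null(correction)) {
    phase <- match.arg(phase)
    correction <- if (phase == "G2") 2 else 1
    source <- sprintf("analytic (%s)", phase)
  } else {
    stop_scalar(correction, "correction", positive = TRUE)
    if (correction < 1) stop("`correction` must be >= 1", call. = FALSE)
    source <- "supplied (e.g. Monte Carlo)"
  }
  list(frequency = correction * fraction * induced_freq,
       correction = correction, fraction = fraction,
       correction_source = source)
}

#' Percent marker loss among verified colonies
#'
#' Colonies losing one of the strain-identity markers, as a percentage of
#' colonies tested (used to bound contamination of a selected population by
#' genotype changes).
#'
#' @param n_tested colonies tested (> 0).
#' @param n_lost colonies that lost a marker (0 <= n_lost <= n_tested).
#' @return Percent lost.
#' @examples
#' marker_retention(160, 4) # 2.5
#' @export
marker_retention <- function(n_tested, n_lost) {
  stop_scalar(n_tested, "n_tested", positive = TRUE)
  stop_scalar(n_lost, "n_lost", nonneg = TRUE)
  if (n_lost > n_tested) {
    stop("`n_lost` cannot exceed `n_tested`", call. = FALSE)
  }
  100 * n_lost / n_tested
}
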