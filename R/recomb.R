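#' Plating record for a recombination frequency
#'
#' Colony counts on selective (e.g. tyrosine dropout) and complete media for
#' one culture/treatment, with the cells plated on each and their dilution
#' factors. The effective number of cells deposited on a plate is
#' `cells_plated * dilution`.
#'
#' @param selective_colonies,total_colonies colony counts (>= 0).
#' @param selective_cells_plated,total_cells_plated cells plated (> 0).
#' @param selective_dilution,total_dilution dilution factors (default 1).
#' @param strain,treatment optional labels.
#' @return A `frequency_record` list.
#' @export
frequency_record <- function(selective_colonies, selective_cells_plated,
                             total_colonies, total_cells_plated,
                             selective_dilution = 1, total_dilution = 1,
                             strain = NA_character_,
                             treatment = NA_character_) {
  stop_scalar(selective_colonies, "selective_colonies", nonneg = TRUE)
  stop_scalar(total_colonies, "total_colonies", nonneg = TRUE)
  stop_scalar(selective_cells_plated, "selective_cells_plated",
              positive = TRUE)
  stop_scalar(total_cells_plated, "total_cells_plated", positive = TRUE)
  structure(
    list(selective_colonies = selective_colonies,
         selective_cells_plated = selective_cells_plated,
         selective_dilution = selective_dilution,
         total_colonies = total_colonies,
         total_cells_plated = total_cells_plated,
         total_dilution = total_dilution,
         strain = strain, treatment = treatment),
    class = "frequency_record"
  )
}

#' Recombinant frequency per survivor
#'
#' Recombinants per viable cell: the selective-plate colony density divided
#' by the complete-plate (viability) colony density, each corrected for the
#' cells deposited after dilution. When no selective colonies were seen the
#' frequency is 0 and the detection limit (one colony over the effective
#' cells plated, viability-corrected) is reported as `resolution_bound`.
#'
#' @param record a [frequency_record()].
#' @return List with `frequency`, `survival_density` (viable fraction among
#'   plated cells) and, for zero counts, `resolution_bound`.
#' @examples
#' recomb_frequency(frequency_record(20, 1e7, 100, 100))$frequency # 2e-6
#' @export
recomb_frequency <- function(record) {
  stopifnot(inherits(record, "frequency_record"))
  if (record$total_colonies <= 0) {
    stop("total (complete-medium) colonies must be > 0 to correct for ",
         "survival", call. = FALSE)
  }
  sel_cells <- record$selective_cells_plated * record$selective_dilution
  tot_cells <- record$total_cells_plated * record$total_dilution
  viability <- record$total_colonies / tot_cells
  freq <- (record$selective_colonies / sel_cells) / viability
  out <- list(frequency = freq, survival_density = viability,
              resolution_bound = NA_real_)
  if (record$selective_colonies == 0) {
    out$resolution_bound <- (1 / sel_cells) / viability
  }
  out
}

#' Net (induced minus spontaneous) frequency
#'
#' Treated-minus-untreated recombination frequency for the same strain.
#' Negative differences (sampling noise at low induction) are reported
#' as-is, flagged via the `negative` attribute, so downstream averaging
#' stays unbiased; display layers may clamp them to zero.
#'
#' @param treated,untreated frequencies (recombinants per survivor).
#' @return Numeric vector with logical attribute `negative`.
#' @examples
#' net_frequency(12e-6, 2e-6)
#' @export
net_frequency <- function(treated, untreated) {
  net <- treated - untreated
  attr(net, "negative") <- net < 0
  net
}

#' Induction efficiency (net frequency per unit dose)
#'
#' Through-origin least-squares slope of net recombination frequency versus
#' dose: recombinants per survivor per krad (or per J/m^2 etc.). Dose 0 is
#' implicitly on the line at net frequency 0.
#'
#' @param dose numeric vector of doses (>= 2 points).
#' @param net_freq net frequencies at those doses.
#' @return List with `efficiency` (slope) and `stderr`.
#' @examples
#' induction_efficiency(c(10, 20), c(50e-6, 100e-6))$efficiency # 5e-6
#' @export
induction_efficiency <- function(dose, net_freq) {
  if (length(dose) != length(net_freq) || length(dose) < 2L) {
    stop("need >= 2 (dose, net frequency) points", call. = FALSE)
  }
  if (all(net_freq == 0)) {
    return(list(efficiency = 0, stderr = 0))
  }
  fit <- stats::lm(net_freq ~ 0 + dose)
  co <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  list(efficiency = unname(co[1L, "Estimate"]),
       stderr = unname(co[1L, "Std. Error"]))
}

#' Two-sample t test from summary statistics
#'
#' Pooled-variance two-sample t computed from group means, standard errors
#' of the mean, and sample sizes (`SD_i = SEM_i * sqrt(n_i)`), with
#' `df = n1 + n2 - 2`; set `var_equal = FALSE` for the Welch variant with
#' Welch-Satterthwaite degrees of freedom. `tails = 1` halves the p-value
#' (testing in the direction of the observed difference).
#'
#' @param mean1,sem1,n1 first group summary (n >= 2, SEM > 0).
#' @param mean2,sem2,n2 second group summary.
#' @param tails 1 or 2 (default 2).
#' @param var_equal pooled variance if `TRUE` (default), Welch otherwise.
#' @return List with `t`, `df`, `p`, `method`.
#' @examples
#' summary_t_test(18, 3, 6, 60, 10, 6)$p # ~0.002
#' @export
summary_t_test <- function(mean1, sem1, n1, mean2, sem2, n2, tails = 2,
                           var_equal = TRUE) {
  for (nm in c("n1", "n2")) {
    n <- get(nm)
    if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
      stop(sprintf("`%s` must be an integer >= 2", nm), call. = FALSE)
    }
  }
  if (sem1 <= 0 || sem2 <= 0) stop("SEMs must be > 0", call. = FALSE)
  if (!tails %in% c(1, 2)) stop("`tails` must be 1 or 2", call. = FALSE)
  s1sq <- (sem1 * sqrt(n1))^2
  s2sq <- (sem2 * sqrt(n2))^2
  if (var_equal) {
    sp2 <- ((n1 - 1) * s1sq + (n2 - 1) * s2sq) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "pooled"
  } else {
    v1 <- s1sq / n1
    v2 <- s2sq / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    method <- "welch"
  }
  t <- (mean1 - mean2) / se
  p <- tails * stats::pt(-abs(t), df)
  list(t = t, df = df, p = min(p, 1), method = method, tails = tails)
}

#' Dose-modifying factor between two survival curves
#'
#' The ratio of doses at which two strains reach the same surviving
#' fraction (`dose_A(level) / dose_B(level)`), with doses interpolated
#' linearly on log-survival between measured points (exact for exponential
#' killing). Reciprocity holds: `dmf(A, B, s) * dmf(B, A, s) = 1`.
#'
#' @param curve_a,curve_b [survival_curve()] objects.
#' @param level surviving fraction at which to compare, inside both curves'
#'   measured ranges.
#' @return Numeric dose ratio.
#' @examples
#' a <- simulate_survival(40, c(20, 40, 80))
#' b <- simulate_survival(20, c(20, 40, 80))
#' dose_modifying_factor(a, b, 0.5) # 2
#' @export
dose_modifying_factor <- function(curve_a, curve_b, level) {
  stopifnot(inherits(curve_a, "survival_curve"),
            inherits(curve_b, "survival_curve"))
  stop_scalar(level, "level", positive = TRUE)
  .dose_at(curve_a, level) / .dose_at(curve_b, level)
}

.dose_at <- function(curve, level) {
  s <- curve$surviving_fraction
  d <- curve$doses
  keep <- s > 0
  s <- s[keep]
  d <- d[keep]
  if (level > max(s) || level < min(s)) {
    stop(sprintf(
      "surviving fraction %g is outside the curve's measured range [%g, %g]",
      level, min(s), max(s)), call. = FALSE)
  }
  # interpolate dose as a function of log-survival
  ord <- order(s)
  stats::approx(x = log(s)[ord], y = d[ord], xout = log(level),
                ties = "ordered")$y
}
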