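#' Breakage parameters for gel-lane simulation
#'
#' @param efficiency_kappa DSB induction efficiency, breaks per megabase per
#'   krad (the gamma-ray value in G2/M yeast is about 0.07).
#' @param dose radiation dose in krad.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   band-intensity noise (densitometry error; 0 disables noise).
#' @param loading_factor_sd standard deviation of the per-lane DNA-loading
#'   scalar (lanes receive `exp(rnorm(1, 0, loading_factor_sd))` times the
#'   nominal amount; 0 gives identical loading).
#' @param seed integer seed; every simulation is reproducible given the seed.
#' @return A `breakage_params` list.
#' @export
breakage_params <- function(efficiency_kappa, dose, noise_cv = 0,
                            loading_factor_sd = 0, seed = 1L) {
  stop_scalar(efficiency_kappa, "efficiency_kappa", nonneg = TRUE)
  stop_scalar(dose, "dose", nonneg = TRUE)
  stop_scalar(noise_cv, "noise_cv", nonneg = TRUE)
  stop_scalar(loading_factor_sd, "loading_factor_sd", nonneg = TRUE)
  structure(
    list(efficiency_kappa = efficiency_kappa, dose = dose,
         noise_cv = noise_cv, loading_factor_sd = loading_factor_sd,
         seed = as.integer(seed)),
    class = "breakage_params"
  )
}

#' Exponential repair kinetics
#'
#' Each induced break is independently rejoined with first-order kinetics:
#' the probability that a break is still open at time `t` hours is
#' `plateau + (1 - plateau) * exp(-rate * t)`. `plateau` is the fraction of
#' breaks that are never rejoined.
#'
#' @param rate per-hour rejoining rate (>= 0).
#' @param plateau fraction of breaks never rejoined, in [0, 1].
#' @return A `repair_kinetics` list.
#' @export
repair_kinetics <- function(rate, plateau = 0) {
  stop_scalar(rate, "rate", nonneg = TRUE)
  stop_scalar(plateau, "plateau")
  if (plateau < 0 || plateau > 1) {
    stop("`plateau` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(model = "exponential", rate = rate, plateau = plateau),
            class = "repair_kinetics")
}

# Fraction of initial breaks still open at time t.
.unrepaired_at <- function(kinetics, t) {
  if (is.null(kinetics)) {
    return(rep(1, length(t)))
  }
  kinetics$plateau + (1 - kinetics$plateau) * exp(-kinetics$rate * t)
}

# Cluster chromosome sizes into comigrating bands: successive sizes whose
# relative gap is below `threshold` share a band (chain rule).
.comigration_groups <- function(size_mb, threshold) {
  ord <- order(size_mb)
  s <- size_mb[ord]
  grp <- integer(length(s))
  g <- 1L
  grp[1L] <- g
  if (length(s) > 1L) {
    for (i in 2L:length(s)) {
      if ((s[i] - s[i - 1L]) / s[i - 1L] >= threshold) g <- g + 1L
      grp[i] <- g
    }
  }
  out <- integer(length(s))
  out[ord] <- grp
  out
}

#' Simulate PFGE band-intensity lanes under Poisson random breakage
#'
#' Generates the band-intensity table a stained CHEF gel would yield for a
#' karyotype irradiated at `params$dose` krad and incubated for each time in
#' `timepoints`. Under Poisson random breakage the probability that a
#' chromosome of size L megabases carries no open break at time t is
#' `exp(-kappa * dose * L * u(t))` where `u(t)` is the unrepaired fraction
#' from `kinetics` (1 when `kinetics` is `NULL`). The full-length band
#' intensity is `loading_factor(lane) * copies * F * (1 + noise)`; an
#' unirradiated control lane (dose 0, the denominator of all
#' fraction-unbroken ratios) is always included.
#'
#' Chromosomes whose sizes differ by less than `comigration_threshold`
#' (relative) comigrate: their intensities are summed into one band flagged
#' `comigrating`. Bands outside `resolution_range_kb` are flagged
#' unresolvable; downstream fits exclude both by default.
#'
#' @param karyotype a [karyotype()].
#' @param params a [breakage_params()].
#' @param timepoints post-irradiation incubation times in hours (default 0,
#'   i.e. induction only). All must be >= 0.
#' @param kinetics a [repair_kinetics()] or `NULL` for no repair.
#' @param strain strain label stored in the lane metadata.
#' @param comigration_threshold relative size difference below which two
#'   chromosomes share a band (default 0.05).
#' @param resolution_range_kb size window resolved by the gel program,
#'   default `c(250, 1600)` kb.
#' @param mc_copies if not `NULL`, the unbroken fraction of every band is
#'   drawn as a binomial proportion over this many simulated chromatid
#'   copies instead of using its expectation; exposes Monte-Carlo sampling
#'   error for validation against the closed form.
#' @return A `gel_lane_table`: list with data.frames `bands` (band_id,
#'   chromosomes, size_kb, lane_id, intensity, comigrating, resolvable) and
#'   `lanes` (lane_id, strain, dose_krad, time_h, is_control).
#' @examples
#' kar <- yeast_karyotype(ploidy = 4, replicated = TRUE)
#' tab <- simulate_gel_lanes(kar, breakage_params(0.07, 80, seed = 7))
#' head(tab$bands)
#' @export
simulate_gel_lanes <- function(karyotype, params, timepoints = 0,
                               kinetics = NULL, strain = "WT",
                               comigration_threshold = 0.05,
                               resolution_range_kb = c(250, 1600),
                               mc_copies = NULL) {
  stopifnot(inherits(karyotype, "karyotype"),
            inherits(params, "breakage_params"))
  if (length(timepoints) < 1L || any(!is.finite(timepoints)) ||
      any(timepoints < 0)) {
    stop("`timepoints` must be non-negative hours", call. = FALSE)
  }
  if (!is.null(kinetics)) stopifnot(inherits(kinetics, "repair_kinetics"))
  chroms <- karyotype$chromosomes
  copies <- chromosome_copies(karyotype)

  lanes <- data.frame(
    lane_id = c("control",
                sprintf("d%g_t%g", params$dose, timepoints)),
    strain = strain,
    dose_krad = c(0, rep(params$dose, length(timepoints))),
    time_h = c(0, timepoints),
    is_control = c(TRUE, rep(FALSE, length(timepoints))),
    stringsAsFactors = FALSE
  )

  grp <- .comigration_groups(chroms$size_mb, comigration_threshold)

  bands <- with_seed(params$seed, {
    out <- vector("list", nrow(lanes))
    for (i in seq_len(nrow(lanes))) {
      lane <- lanes[i, ]
      loading <- if (params$loading_factor_sd > 0) {
        exp(stats::rnorm(1, 0, params$loading_factor_sd))
      } else {
        1
      }
      u <- .unrepaired_at(kinetics, lane$time_h)
      lambda <- params$efficiency_kappa * lane$dose_krad * chroms$size_mb * u
      f <- exp(-lambda)
      if (!is.null(mc_copies)) {
        stop_scalar(mc_copies, "mc_copies", positive = TRUE)
        f <- stats::rbinom(length(f), as.integer(mc_copies), f) /
          as.integer(mc_copies)
      }
      intensity <- loading * copies * f *
        lognormal_noise(length(f), params$noise_cv)
      # merge comigrating chromosomes into shared bands
      per_band <- lapply(split(seq_len(nrow(chroms)), grp), function(idx) {
        data.frame(
          band_id = sprintf("band_%04.0f",
                            round(mean(chroms$size_mb[idx]) * 1000)),
          chromosomes = paste(chroms$name[idx], collapse = ";"),
          size_kb = mean(chroms$size_mb[idx]) * 1000,
          lane_id = lane$lane_id,
          intensity = sum(intensity[idx]),
          comigrating = length(idx) > 1L,
          stringsAsFactors = FALSE
        )
      })
      out[[i]] <- do.call(rbind, per_band)
    }
    do.call(rbind, out)
  })
  bands$resolvable <- bands$size_kb >= resolution_range_kb[1] &
    bands$size_kb <= resolution_range_kb[2]
  rownames(bands) <- NULL
  gel_lane_table(bands, lanes)
}

#' Construct a gel-lane table
#'
#' Validates the invariants of a PFGE band-intensity table: non-negative
#' intensities, exactly one control lane per strain, and every band present
#' in every lane of its strain group.
#'
#' @param bands data.frame with columns band_id, chromosomes, size_kb,
#'   lane_id, intensity (and optionally comigrating, resolvable).
#' @param lanes data.frame with columns lane_id, strain, dose_krad, time_h,
#'   is_control.
#' @return A `gel_lane_table` object.
#' @export
gel_lane_table <- function(bands, lanes) {
  need_b <- c("band_id", "chromosomes", "size_kb", "lane_id", "intensity")
  need_l <- c("lane_id", "strain", "dose_krad", "time_h", "is_control")
  if (!is.data.frame(bands) || !all(need_b %in% names(bands))) {
    stop("`bands` must have columns: ", paste(need_b, collapse = ", "),
         call. = FALSE)
  }
  if (!is.data.frame(lanes) || !all(need_l %in% names(lanes))) {
    stop("`lanes` must have columns: ", paste(need_l, collapse = ", "),
         call. = FALSE)
  }
  if (any(bands$intensity < 0)) {
    bad <- which(bands$intensity < 0)[1L]
    stop(sprintf("negative intensity in bands row %d", bad), call. = FALSE)
  }
  if (anyDuplicated(lanes$lane_id)) {
    stop("duplicate lane_id in lane metadata", call. = FALSE)
  }
  for (s in unique(lanes$strain)) {
    sub <- lanes[lanes$strain == s, ]
    if (sum(sub$is_control) != 1L) {
      stop(sprintf("strain %s must have exactly one control lane", s),
           call. = FALSE)
    }
    ids <- unique(bands$band_id[bands$lane_id %in% sub$lane_id])
    for (ln in sub$lane_id) {
      miss <- setdiff(ids, bands$band_id[bands$lane_id == ln])
      if (length(miss) > 0L) {
        stop(sprintf("lane %s is missing band(s): %s", ln,
                     paste(miss, collapse = ", ")), call. = FALSE)
      }
    }
  }
  if (is.null(bands$comigrating)) bands$comigrating <- FALSE
  if (is.null(bands$resolvable)) bands$resolvable <- TRUE
  structure(list(bands = bands, lanes = lanes), class = "gel_lane_table")
}

#' @export
print.gel_lane_table <- function(x, ...) {
  cat(sprintf("gel_lane_table: %d lanes (%d control), %d bands/lane\n",
              nrow(x$lanes), sum(x$lanes$is_control),
              length(unique(x$bands$band_id))))
  invisible(x)
}
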