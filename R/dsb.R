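#' Fraction of chromosomes remaining unbroken
#'
#' The Poisson zero class: the net intensity of a full-length chromosome
#' band in a dose lane divided by the net intensity of the corresponding
#' band in the unirradiated control lane. Densitometry noise can push the
#' ratio above 1; such values are clamped to 1 (no detectable breakage) and
#' flagged in the `clamped` attribute.
#'
#' @param intensity_dose net band intensity in the dose lane (>= 0).
#' @param intensity_control net band intensity in the control lane (> 0).
#' @param clamp clamp ratios above 1 to 1 (default `TRUE`).
#' @return Numeric vector of fractions with a logical attribute `clamped`.
#' @examples
#' fraction_unbroken(50, 100)
#' attr(fraction_unbroken(110, 100), "clamped")
#' @export
fraction_unbroken <- function(intensity_dose, intensity_control,
                              clamp = TRUE) {
  if (any(intensity_control <= 0)) {
    stop("control intensity must be > 0", call. = FALSE)
  }
  if (any(intensity_dose < 0)) {
    stop("dose-lane intensity must be >= 0", call. = FALSE)
  }
  f <- intensity_dose / intensity_control
  clamped <- f > 1
  if (clamp) f[clamped] <- 1
  attr(f, "clamped") <- clamped
  f
}

#' Mean breaks per chromosome from the unbroken fraction
#'
#' Under Poisson random breakage the zero class satisfies `F = exp(-N)`,
#' so the average number of DSBs per chromosome is `N = -ln(F)`.
#'
#' @param f fraction unbroken, in (0, 1]. A band with `F <= 0` has lost all
#'   full-length signal and cannot be quantified; callers such as
#'   [quantify_dsb()] exclude it rather than reporting infinity.
#' @return Numeric vector of mean break counts.
#' @examples
#' breaks_per_chromosome(exp(-1)) # 1
#' @export
breaks_per_chromosome <- function(f) {
  f <- as.numeric(f)
  if (any(f <= 0) || any(f > 1)) {
    stop("fraction unbroken must lie in (0, 1]; bands with no remaining ",
         "signal are unquantifiable and must be excluded", call. = FALSE)
  }
  -log(f)
}

#' Fit the DSB density (breaks per megabase)
#'
#' Plotting mean breaks per chromosome `N` against chromosome size `L`
#' (megabases) gives a straight line through the origin whose slope is the
#' break density in DSBs/Mb: Poisson breakage forces `N = r * L` exactly, so
#' the default regression has no intercept (a free-intercept fit is
#' available for diagnostics). Because every `N` derives from an intensity
#' ratio within a lane pair, the fit is invariant to rescaling all input
#' intensities, i.e. to the amount of DNA loaded.
#'
#' @param size_mb chromosome/band sizes in megabases (> 0).
#' @param breaks mean breaks per chromosome for each band.
#' @param through_origin force the fit through the origin (default `TRUE`).
#' @param excluded optional data.frame (`band_id`, `reason`) of bands left
#'   out upstream, carried into the result for auditability.
#' @return A `break_estimate`: list with `per_band` (size_mb, breaks),
#'   `density` (DSBs/Mb), `stderr`, `n_bands`, `through_origin`, `excluded`.
#' @examples
#' fit_dsb_density(c(0.25, 1, 1.5), c(1.4, 5.6, 8.4))$density # 5.6
#' @export
fit_dsb_density <- function(size_mb, breaks, through_origin = TRUE,
                            excluded = NULL) {
  if (length(size_mb) != length(breaks)) {
    stop("size_mb and breaks lengths differ", call. = FALSE)
  }
  if (length(size_mb) < 2L) {
    stop("at least 2 usable bands are required to fit a density",
         call. = FALSE)
  }
  if (any(size_mb <= 0)) stop("sizes must be > 0", call. = FALSE)
  if (any(breaks < 0)) stop("break counts must be >= 0", call. = FALSE)
  fit <- if (through_origin) {
    stats::lm(breaks ~ 0 + size_mb)
  } else {
    stats::lm(breaks ~ size_mb)
  }
  # exact Poisson lines are legitimate inputs; lm warns on perfect fits
  co <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  slope_row <- if (through_origin) 1L else 2L
  structure(
    list(
      per_band = data.frame(size_mb = size_mb, breaks = breaks),
      density = unname(co[slope_row, "Estimate"]),
      stderr = unname(co[slope_row, "Std. Error"]),
      intercept = if (through_origin) 0 else unname(co[1L, "Estimate"]),
      n_bands = length(size_mb),
      through_origin = through_origin,
      excluded = if (is.null(excluded)) {
        data.frame(band_id = character(), reason = character())
      } else {
        excluded
      }
    ),
    class = "break_estimate"
  )
}

#' @export
print.break_estimate <- function(x, ...) {
  cat(sprintf(
    "break_estimate: %.4g DSB/Mb (SE %.3g) from %d bands (%d excluded)\n",
    x$density, x$stderr, x$n_bands, nrow(x$excluded)))
  invisible(x)
}

#' Quantify DSB densities for every dose lane of a gel table
#'
#' For each non-control lane, computes the fraction unbroken of every band
#' against the control lane of the same strain, converts to mean breaks per
#' chromosome via the zero-class estimator, and fits the DSB density.
#' Bands flagged comigrating or outside the gel's resolution window, and
#' bands whose full-length signal is entirely lost (`F <= 0`), are excluded
#' from the fit with a recorded reason; clamped bands (`F > 1`) enter with
#' `N = 0` under the default clamp policy.
#'
#' @param table a `gel_lane_table`.
#' @param use_comigrating include comigrating bands in fits (default
#'   `FALSE`).
#' @param use_unresolvable include bands outside the resolution window
#'   (default `FALSE`).
#' @param clamp clamp policy passed to [fraction_unbroken()]; when `FALSE`,
#'   bands with `F > 1` are excluded instead of clamped.
#' @param through_origin passed to [fit_dsb_density()].
#' @return data.frame with one row per dose lane: lane_id, strain,
#'   dose_krad, time_h, density, stderr, n_bands, n_excluded, and a list
#'   column `estimate` holding each `break_estimate`.
#' @export
quantify_dsb <- function(table, use_comigrating = FALSE,
                         use_unresolvable = FALSE, clamp = TRUE,
                         through_origin = TRUE) {
  stopifnot(inherits(table, "gel_lane_table"))
  lanes <- table$lanes
  out <- list()
  for (s in unique(lanes$strain)) {
    grp <- lanes[lanes$strain == s, ]
    ctrl_id <- grp$lane_id[grp$is_control]
    ctrl <- table$bands[table$bands$lane_id == ctrl_id, ]
    for (ln in grp$lane_id[!grp$is_control]) {
      lane_bands <- table$bands[table$bands$lane_id == ln, ]
      m <- match(lane_bands$band_id, ctrl$band_id)
      f <- fraction_unbroken(lane_bands$intensity, ctrl$intensity[m],
                             clamp = clamp)
      reason <- rep(NA_character_, nrow(lane_bands))
      reason[lane_bands$comigrating & !use_comigrating] <- "comigrating"
      reason[!lane_bands$resolvable & !use_unresolvable & is.na(reason)] <-
        "outside resolution window"
      reason[f <= 0 & is.na(reason)] <- "signal lost (F <= 0)"
      if (!clamp) reason[f > 1 & is.na(reason)] <- "F > 1 (not clamped)"
      usable <- is.na(reason)
      excluded <- data.frame(band_id = lane_bands$band_id[!usable],
                             reason = reason[!usable])
      est <- fit_dsb_density(lane_bands$size_kb[usable] / 1000,
                             breaks_per_chromosome(pmin(f[usable], 1)),
                             through_origin = through_origin,
                             excluded = excluded)
      li <- grp[grp$lane_id == ln, ]
      out[[length(out) + 1L]] <- data.frame(
        lane_id = ln, strain = s, dose_krad = li$dose_krad,
        time_h = li$time_h, density = est$density, stderr = est$stderr,
        n_bands = est$n_bands, n_excluded = nrow(excluded),
        stringsAsFactors = FALSE
      )
      attr(out[[length(out)]], "estimate") <- est
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$estimate <- I(lapply(out, attr, "estimate"))
  res
}

#' Repair time course from fitted DSB densities
#'
#' For each strain and dose, the unrepaired fraction at time `t` is the
#' fitted DSB density at `t` divided by the density immediately after
#' irradiation (`t = 0`); the repaired fraction is its complement. Pooling
#' across bands through the density fit uses every resolvable chromosome
#' rather than a single band.
#'
#' @param table a `gel_lane_table` containing, for each strain/dose, a
#'   `t = 0` post-irradiation lane and at least one later timepoint.
#' @param ... passed to [quantify_dsb()].
#' @return data.frame with strain, dose_krad, time_h, density,
#'   fraction_unrepaired, fraction_repaired.
#' @export
repair_time_course <- function(table, ...) {
  dens <- quantify_dsb(table, ...)
  out <- list()
  for (key in unique(paste(dens$strain, dens$dose_krad))) {
    sub <- dens[paste(dens$strain, dens$dose_krad) == key, ]
    if (!any(sub$time_h == 0)) {
      stop(sprintf(
        "strain %s at %g krad has no t = 0 post-irradiation lane",
        sub$strain[1L], sub$dose_krad[1L]), call. = FALSE)
    }
    d0 <- sub$density[sub$time_h == 0][1L]
    out[[key]] <- data.frame(
      strain = sub$strain, dose_krad = sub$dose_krad, time_h = sub$time_h,
      density = sub$density,
      fraction_unrepaired = sub$density / d0,
      fraction_repaired = 1 - sub$density / d0,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$strain, res$dose_krad, res$time_h), ]
}

#' Expected genome-wide DSB burden
#'
#' Induction efficiency (DSBs/Mb/krad) times dose times total genome size
#' in megabases; the genome size accounts for ploidy and, in replicated
#' (G2/M) cells, for both sister chromatids.
#'
#' @param efficiency_kappa DSBs per megabase per krad (>= 0).
#' @param dose krad (>= 0).
#' @param karyotype a [karyotype()].
#' @return Expected DSBs per cell.
#' @examples
#' expected_dsbs(0.07, 80, yeast_karyotype(ploidy = 4, replicated = TRUE))
#' @export
expected_dsbs <- function(efficiency_kappa, dose, karyotype) {
  stop_scalar(efficiency_kappa, "efficiency_kappa", nonneg = TRUE)
  stop_scalar(dose, "dose", nonneg = TRUE)
  stopifnot(inherits(karyotype, "karyotype"))
  efficiency_kappa * dose * genome_size_mb(karyotype)
}
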