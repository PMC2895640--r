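#' Simulate an exponential dose-response survival curve
#'
#' Surviving fraction `S(D) = exp(-D / d0)` at each dose, optionally with
#' binomial colony-sampling noise: when `cells_plated` is given, the number
#' of colonies at each dose is drawn as `Binomial(cells_plated, S)` and the
#' surviving fraction is the colony ratio against the unirradiated plating.
#'
#' @param d0 dose (krad) reducing survival to 1/e; must be > 0.
#' @param doses vector of doses in krad (0 is prepended if absent so that
#'   `S(0) = 1` by construction).
#' @param cells_plated cells plated per dose for binomial sampling noise, or
#'   `NULL` (default) for the noise-free curve.
#' @param seed integer seed (used only when `cells_plated` is given).
#' @return A [survival_curve()].
#' @examples
#' simulate_survival(40, c(20, 40, 80))
#' @export
simulate_survival <- function(d0, doses, cells_plated = NULL, seed = 1L) {
  stop_scalar(d0, "d0", positive = TRUE)
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  doses <- sort(unique(c(0, doses)))
  s <- exp(-doses / d0)
  if (!is.null(cells_plated)) {
    stop_scalar(cells_plated, "cells_plated", positive = TRUE)
    s <- with_seed(seed, {
      colonies <- stats::rbinom(length(doses), as.integer(cells_plated), s)
      colonies / colonies[1L]
    })
    s[1L] <- 1
  }
  survival_curve(doses, s)
}

#' Survival-curve container
#'
#' Doses and dilution-corrected surviving fractions (colonies at dose over
#' colonies at dose 0). `S(0)` must equal 1; sampling noise can push other
#' fractions slightly above 1, which is kept but flagged.
#'
#' @param doses numeric vector of doses, starting at 0.
#' @param surviving_fraction numeric vector, same length.
#' @param sem optional per-dose standard errors.
#' @return A `survival_curve` object with a `flagged_gt1` logical vector.
#' @export
survival_curve <- function(doses, surviving_fraction, sem = NULL) {
  if (length(doses) != length(surviving_fraction)) {
    stop("doses and surviving_fraction lengths differ", call. = FALSE)
  }
  if (doses[1L] != 0 || surviving_fraction[1L] != 1) {
    stop("curve must start at dose 0 with surviving fraction 1",
         call. = FALSE)
  }
  if (any(surviving_fraction < 0)) {
    stop("surviving fractions must be >= 0", call. = FALSE)
  }
  structure(list(doses = as.numeric(doses),
                 surviving_fraction = as.numeric(surviving_fraction),
                 sem = sem,
                 flagged_gt1 = surviving_fraction > 1),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("survival_curve:\n")
  print(data.frame(dose = x$doses, S = signif(x$surviving_fraction, 4)))
  invisible(x)
}
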