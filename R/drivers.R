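# Exogenous time functions: firing rate fire(t), unblocked-SERT fraction
# fluox(t), and serum tryptophan btrp(t), plus the composed dosing / pulse /
# meal profiles used by the scripted experiments.

#' Driver bundle
#'
#' Packages the three exogenous time functions.  Each may be given as a
#' constant (coerced to a constant function) or as a vectorised function of
#' time in hours.  `breakpoints` lists the times at which any driver is
#' non-smooth; the integrator restarts there so that sub-second pulse edges
#' are resolved reproducibly.
#'
#' @param fire firing rate, /hr (baseline 1/hr: the vesicular pool turns
#'   over once per hour under tonic firing).
#' @param fluox fraction of SERTs unblocked, in `[0, 1]`.
#' @param btrp serum tryptophan, uM (baseline 96 uM, fasted).
#' @param breakpoints numeric vector of non-smooth times, hours.
#' @return an object of class `seroterm_drivers`.
#' @export
drivers <- function(fire = 1, fluox = 1, btrp = 96, breakpoints = numeric(0)) {
  as_fun <- function(x, what) {
    if (is.function(x)) return(x)
    if (is.numeric(x) && length(x) == 1 && is.finite(x)) {
      force(x)
      return(function(t) rep(x, length(t)))
    }
    stop(what, " must be a single number or a function of time", call. = FALSE)
  }
  fire_f <- as_fun(fire, "fire")
  fluox_f <- as_fun(fluox, "fluox")
  btrp_f <- as_fun(btrp, "btrp")
  probe <- c(0, 0.5, 1, 24)
  if (isTRUE(any(fire_f(probe) < 0))) stop("fire must be >= 0", call. = FALSE)
  fl <- fluox_f(probe)
  if (isTRUE(any(fl < 0)) || isTRUE(any(fl > 1)))
    stop("fluox must lie in [0, 1]", call. = FALSE)
  if (isTRUE(any(btrp_f(probe) < 0))) stop("btrp must be >= 0", call. = FALSE)
  structure(list(fire = fire_f, fluox = fluox_f, btrp = btrp_f,
                 breakpoints = sort(unique(breakpoints))),
            class = "seroterm_drivers")
}

#' Unblocked-SERT fraction after a single SSRI dose
#'
#' Pharmacokinetic-like profile for a dose given at `dose_time`: 1 before
#' the dose, then
#' `1 - depth * u^2/(shape + u^2) * exp(-u/washout)` with `u = t - dose_time`.
#' Continuous at the dose time; returns to 1 as the drug washes out.  The
#' default washout constant of 37 h corresponds to a drug half-life of a
#' little more than a day (fluoxetine-like); the blockade reaches its
#' maximum (~77% of SERTs blocked) about 5.2 h after the dose.
#'
#' @param t time, hours (vectorised).
#' @param dose_time hour at which the dose is given.
#' @param depth maximal blockade depth (0.95 = up to 95% of SERTs blocked,
#'   scaling the dose).
#' @param shape half-rise constant of the onset, hr^2.
#' @param washout exponential washout constant, hours.
#' @return fraction of SERTs unblocked, in `(0, 1]`.
#' @export
fluox_dose <- function(t, dose_time = 1, depth = 0.95, shape = 2.04,
                       washout = 37) {
  u <- t - dose_time
  ifelse(u <= 0, 1, 1 - depth * u^2 / (shape + u^2) * exp(-u / washout))
}

#' Occupancy profile sharing the dosing shape
#'
#' The blockade/occupancy time course implied by [fluox_dose()]:
#' `depth * u^2/(shape + u^2) * exp(-u/washout)`, zero before the dose.
#' Used to drive raphe firing suppression with a configurable washout.
#'
#' @inheritParams fluox_dose
#' @return occupancy in `[0, depth)`.
#' @export
occupancy_profile <- function(t, dose_time = 1, depth = 0.95, shape = 2.04,
                              washout = 37) {
  u <- t - dose_time
  ifelse(u <= 0, 0, depth * u^2 / (shape + u^2) * exp(-u / washout))
}

#' Square firing pulse
#'
#' Tonic firing at `base` except during `[t_on, t_on + duration)`, where it
#' is raised to `pulse`.  The default duration 1/18000 hr is exactly 0.2 s,
#' emulating brief high-frequency stimulation.
#'
#' @param t time, hours (vectorised).
#' @param base tonic firing rate, /hr.
#' @param pulse firing rate inside the window, /hr.
#' @param t_on pulse onset, hours.
#' @param duration pulse width, hours.
#' @return firing rate, /hr.
#' @export
square_pulse_fire <- function(t, base = 1, pulse = 5000, t_on,
                              duration = 1 / 18000) {
  stopifnot(duration > 0)
  ifelse(t >= t_on & t < t_on + duration, pulse, base)
}

#' Serum tryptophan meal profile
#'
#' Smooth raised-cosine bump per meal: serum tryptophan climbs over `rise`
#' hours from baseline to `baseline * peak_factor` and relaxes back to
#' baseline `relax` hours after the meal starts.  Bumps add on overlap and
#' the profile extends 24-h periodically.  `peak_factor = 1` gives the
#' constant fasted baseline.
#'
#' @param t time, hours (vectorised).
#' @param meal_starts meal start hours within the day.
#' @param rise hours from meal start to peak.
#' @param relax hours from meal start back to baseline.
#' @param baseline fasted serum tryptophan, uM.
#' @param peak_factor peak-to-baseline ratio per meal (plasma amino acids
#'   typically vary 2- to 4-fold over a day).
#' @return serum tryptophan, uM.
#' @export
meal_profile <- function(t, meal_starts = c(7, 12, 18), rise = 3, relax = 6,
                         baseline = 96, peak_factor = 2) {
  stopifnot(peak_factor >= 1, rise > 0, relax > rise)
  amp <- baseline * (peak_factor - 1)
  out <- rep(baseline, length(t))
  for (m in meal_starts) {
    u <- (t - m) %% 24
    bump <- ifelse(u <= rise,
                   0.5 * (1 - cos(pi * u / rise)),
                   ifelse(u <= relax,
                          0.5 * (1 + cos(pi * (u - rise) / (relax - rise))),
                          0))
    out <- out + amp * bump
  }
  out
}

#' Firing rate suppressed in proportion to a blockade profile
#'
#' Raphe 5-HT1A autoreceptor stimulation (by an agonist, or by the raised
#' extracellular 5-HT that follows SERT blockade in the raphe) lowers the
#' tonic firing rate of the neurons projecting to the terminal.  The
#' suppression is tied proportionally to a blockade/occupancy profile:
#' `fire(t) = 1 - (1 - f_min) * blockade(t) / max_t blockade`, so firing
#' equals `f_min` at peak blockade and returns to 1 as the profile washes
#' out.
#'
#' @param t time, hours (vectorised).
#' @param f_min firing rate at peak blockade, as a fraction of tonic
#'   (e.g. 0.58 hippocampus/MRN, 0.20 frontal cortex/DRN).
#' @param blockade function of time giving the blockade/occupancy profile.
#' @param blockade_max its maximum over the simulated span (computed by a
#'   dense grid search over `[0, 400]` h when omitted).
#' @return firing rate, /hr.
#' @export
suppressed_fire <- function(t, f_min, blockade, blockade_max = NULL) {
  stopifnot(f_min > 0, f_min <= 1)
  if (is.null(blockade_max)) {
    grid <- seq(0, 400, by = 0.01)
    blockade_max <- max(blockade(grid))
  }
  if (blockade_max <= 0)
    stop("blockade profile is identically zero", call. = FALSE)
  1 - (1 - f_min) * blockade(t) / blockade_max
}
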