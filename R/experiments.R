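# Scripted, reproducible in-silico experiments.  Every experiment is
# deterministic; the returned config echo is sufficient to re-run it
# bit-identically.

.experiment_result <- function(name, config, tables = list(),
                               trajectories = list(), summary = list()) {
  structure(list(name = name, config = config, tables = tables,
                 trajectories = trajectories, summary = summary),
            class = "seroterm_experiment")
}

#' @export
print.seroterm_experiment <- function(x, ...) {
  cat("<seroterm_experiment>", x$name, "\n")
  if (length(x$summary)) {
    cat("summary:\n")
    for (k in names(x$summary)) {
      v <- x$summary[[k]]
      if (is.numeric(v) && length(v) == 1) cat(sprintf("  %s: %.6g\n", k, v))
    }
  }
  cat("tables:", paste(names(x$tables), collapse = ", "), "\n")
  invisible(x)
}

#' SERT-fraction sweep (wild type to SERT knockout)
#'
#' Solves the steady state at a series of constant unblocked-SERT fractions
#' `f`, from wild type (`f = 1`) through progressively higher SSRI doses to
#' complete knockout (`f = 0`), and tabulates the concentrations and
#' velocities.  Extracellular 5-HT is reported in nM; everything else in uM
#' and uM/hr.
#'
#' @param p calibrated kinetic parameters.
#' @param cfg autoreceptor configuration.
#' @param fractions unblocked fractions to sweep.
#' @return a `seroterm_experiment` with table `sweep` (one row per
#'   fraction: `f`, `trp`, `c5ht`, `v5ht`, `e5ht_nM`, `hiaa5`, `v_tph`,
#'   `v_mat`, `v_sert`, `v_rem`, `v_catab`).
#' @export
table4_sweep <- function(p, cfg = autoreceptor_config(),
                         fractions = c(1, 0.5, 0.2, 0.1, 0.05, 0)) {
  fractions <- sort(fractions, decreasing = TRUE)
  seed <- baseline_state(p)
  rows <- vector("list", length(fractions))
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    ss <- tryCatch(
      find_steady_state(p, cfg, fluox = f, seed = seed),
      error = function(e)
        stop("steady state failed at f = ", f, ": ", conditionMessage(e),
             call. = FALSE))
    seed <- ss$state  # continuation seeding along the sweep
    v <- ss$velocities
    rows[[i]] <- data.frame(
      f = f, trp = ss$state[["trp"]], c5ht = ss$state[["c5ht"]],
      v5ht = ss$state[["v5ht"]], e5ht_nM = ss$state[["e5ht"]] * 1000,
      hiaa5 = ss$state[["hiaa5"]],
      v_tph = v$v_tph, v_mat = v$v_mat_net, v_sert = v$v_sert,
      v_rem = v$v_rem, v_catab = v$v_catab_c + v$v_catab_e)
  }
  tab <- do.call(rbind, rows)
  .experiment_result("table4_sweep",
                     list(fractions = fractions, cfg = unclass(cfg)),
                     tables = list(sweep = tab),
                     summary = list(
                       e5ht_fold_increase_ko =
                         tab$e5ht_nM[nrow(tab)] / tab$e5ht_nM[1]))
}

#' Stimulation-pulse release and reuptake
#'
#' From the pre-equilibrated baseline, raises the firing rate from `base`
#' to `pulse` /hr for `duration` hours (default 0.2 s) with a constant
#' fraction of SERTs blocked, and follows extracellular 5-HT at sub-second
#' resolution.  Reports the peak (from the densely sampled solution), the
#' decay half-life of the elevation, the fraction of the vesicular store
#' released, and a linearity measure of the decay (saturated reuptake makes
#' it near-linear while e5ht is far above the SERT Km).
#'
#' @param p calibrated kinetic parameters.
#' @param cfg autoreceptor configuration.
#' @param blocked_fraction fraction of SERTs blocked (0 = none, 0.5 = half).
#' @param base,pulse tonic and stimulated firing rates, /hr.
#' @param duration pulse width, hours (1/18000 hr = 0.2 s).
#' @param t_on pulse onset, hours.
#' @param follow_s seconds of post-pulse follow-up.
#' @return a `seroterm_experiment` with the e5ht trajectory and summary
#'   metrics (`peak_e5ht_uM`, `half_life_s`, `v5ht_released_frac`,
#'   `decay_linearity_r2`, `peak_detected`).
#' @export
pulse_release <- function(p, cfg = autoreceptor_config(), blocked_fraction = 0,
                          base = 1, pulse = 5000, duration = 1 / 18000,
                          t_on = 0.002, follow_s = 40) {
  stopifnot(blocked_fraction >= 0, blocked_fraction <= 1)
  fire_fun <- function(t) square_pulse_fire(t, base = base, pulse = pulse,
                                            t_on = t_on, duration = duration)
  drv <- drivers(fire = fire_fun, fluox = 1 - blocked_fraction,
                 breakpoints = c(t_on, t_on + duration))
  s0 <- baseline_state(p)
  t_end <- t_on + duration + follow_s / 3600
  times <- sort(unique(c(
    seq(0, t_on, length.out = 6),
    seq(t_on, t_on + duration, length.out = 121),
    t_on + duration + seq(0, follow_s, by = 0.005) / 3600)))
  traj <- integrate_terminal(p, drv, times, state0 = s0, cfg = cfg,
                             rtol = 1e-8, atol = 1e-12,
                             hmax = duration / 60)
  base_e <- s0[["e5ht"]]
  peak <- max(traj$e5ht)
  detected <- peak > base_e * (1 + 1e-4)
  hl <- if (detected) half_life(traj, "e5ht", baseline = base_e) * 3600 else NA_real_
  # linearity of the decay while e5ht is far above the SERT Km
  lin <- NA_real_
  if (detected && peak > 5 * p$sert_km) {
    ipk <- which.max(traj$e5ht)
    dec <- traj[ipk:nrow(traj), ]
    dec <- dec[dec$e5ht > 3 * p$sert_km, ]
    if (nrow(dec) > 10)
      lin <- summary(stats::lm(e5ht ~ time_hr, data = dec))$r.squared
  }
  .experiment_result(
    "pulse_release",
    list(blocked_fraction = blocked_fraction, base = base, pulse = pulse,
         duration_hr = duration, t_on = t_on, follow_s = follow_s,
         cfg = unclass(cfg)),
    trajectories = list(e5ht = traj),
    summary = list(peak_e5ht_uM = peak, t_peak_hr = traj$time_hr[which.max(traj$e5ht)],
                   half_life_s = hl,
                   v5ht_released_frac = (s0[["v5ht"]] - min(traj$v5ht)) / s0[["v5ht"]],
                   decay_linearity_r2 = lin, peak_detected = detected))
}

#' Meal-driven serum tryptophan experiment
#'
#' Drives serum tryptophan with the meal profile (three meals a day) at
#' tonic firing and no SSRI, after a periodic warm-up, and reports 24-h
#' curves of serum tryptophan, free tryptophan, the synthesis velocity, and
#' extracellular / vesicular 5-HT, all as percent of their baseline values,
#' together with their peak-to-trough swings.
#'
#' @param p calibrated kinetic parameters.
#' @param cfg autoreceptor configuration.
#' @param peak_factor meal peak-to-baseline ratio (1 = no meals).
#' @param meal_starts meal start hours.
#' @param warmup_days days of warm-up before the reported day.
#' @return a `seroterm_experiment` with table `percent_of_baseline`
#'   (columns `hour`, `btrp`, `trp`, `v_tph`, `e5ht`, `v5ht`) and the
#'   percent swings in `summary`.
#' @export
meals_experiment <- function(p, cfg = autoreceptor_config(), peak_factor = 2,
                             meal_starts = c(7, 12, 18), warmup_days = 2) {
  btrp_fun <- function(t) meal_profile(t, meal_starts = meal_starts,
                                       peak_factor = peak_factor)
  days <- warmup_days + 1
  knots <- as.vector(outer(c(meal_starts, meal_starts + 3, meal_starts + 6),
                           24 * (0:(days - 1)), `+`))
  drv <- drivers(fire = 1, fluox = 1, btrp = btrp_fun,
                 breakpoints = knots[knots > 0 & knots < 24 * days])
  times <- seq(0, 24 * days, by = 0.05)
  traj <- integrate_terminal(p, drv, times, cfg = cfg, fluxes = TRUE)
  day <- traj$time_hr >= 24 * warmup_days
  hour <- traj$time_hr[day] - 24 * warmup_days
  s0 <- baseline_state(p)
  v_tph0 <- calibration_targets()$synthesis_flux
  fx <- attr(traj, "fluxes")
  pct <- data.frame(
    hour = hour,
    btrp = 100 * drv$btrp(traj$time_hr[day]) / 96,
    trp = 100 * traj$trp[day] / s0[["trp"]],
    v_tph = 100 * fx$v_tph[day] / v_tph0,
    e5ht = 100 * traj$e5ht[day] / s0[["e5ht"]],
    v5ht = 100 * traj$v5ht[day] / s0[["v5ht"]])
  swing <- function(x) max(x) - min(x)
  .experiment_result(
    "meals",
    list(peak_factor = peak_factor, meal_starts = meal_starts,
         warmup_days = warmup_days, cfg = unclass(cfg)),
    tables = list(percent_of_baseline = pct),
    summary = list(btrp_swing_pct = swing(pct$btrp),
                   trp_swing_pct = swing(pct$trp),
                   v_tph_swing_pct = swing(pct$v_tph),
                   e5ht_swing_pct = swing(pct$e5ht),
                   v5ht_swing_pct = swing(pct$v5ht)))
}

#' Autoreceptor homeostasis sweep
#'
#' Sweeps one model input -- the tonic firing rate, the SERT expression
#' level (`sert_vmax` scaling), or the TPH activity (`tph_vmax` scaling) --
#' over a grid of scale factors and solves the steady state twice at each
#' point: with both autoreceptor feedbacks on, and with both off.  The
#' autoreceptors-on curve spans a strictly narrower extracellular-5-HT
#' range, quantifying the homeostatic damping.
#'
#' @param p calibrated kinetic parameters.
#' @param vary which input to scale: `"fire"`, `"sert_vmax"` or
#'   `"tph_vmax"`.
#' @param grid scale factors (defaults: 0.1-2 for firing; 0.5-1.5 for SERT,
#'   spanning the s/s and l/l expression genotypes; 0.19-1 for TPH,
#'   spanning the R441H and P449R variants).
#' @return a `seroterm_experiment` with table `sweep` (columns `scale`,
#'   `e5ht_nM_on`, `e5ht_nM_off`, and percent-of-baseline versions) and
#'   range/damping summaries.
#' @export
homeostasis_sweep <- function(p, vary = c("fire", "sert_vmax", "tph_vmax"),
                              grid = NULL) {
  vary <- match.arg(vary)
  if (is.null(grid))
    grid <- switch(vary,
      fire = sort(unique(c(seq(0.1, 2, by = 0.1), 0.58))),
      sert_vmax = seq(0.5, 1.5, by = 0.1),
      tph_vmax = sort(unique(c(seq(0.19, 1, length.out = 10), 0.5, 0.65))))
  annotations <- switch(vary,
    fire = c(),
    sert_vmax = c(`s/s` = 0.5, `l/l` = 1.5),
    tph_vmax = c(R441H = 0.19, P449R = 0.65))
  base_e <- baseline_state(p)[["e5ht"]]
  solve_at <- function(s, cfg) {
    if (vary == "fire") {
      ss <- find_steady_state(p, cfg, fire = s)
    } else {
      ps <- p
      ps[[vary]] <- p[[vary]] * s
      ss <- find_steady_state(ps, cfg, seed = baseline_state(p))
    }
    ss$state[["e5ht"]]
  }
  on <- autoreceptor_config(TRUE, TRUE)
  off <- autoreceptor_config(FALSE, FALSE)
  e_on <- vapply(grid, solve_at, numeric(1), cfg = on)
  e_off <- vapply(grid, solve_at, numeric(1), cfg = off)
  tab <- data.frame(scale = grid,
                    e5ht_nM_on = e_on * 1000, e5ht_nM_off = e_off * 1000,
                    e5ht_pct_on = 100 * e_on / base_e,
                    e5ht_pct_off = 100 * e_off / base_e)
  .experiment_result(
    "homeostasis_sweep",
    list(vary = vary, grid = grid, annotations = as.list(annotations)),
    tables = list(sweep = tab),
    summary = list(range_on_nM = diff(range(tab$e5ht_nM_on)),
                   range_off_nM = diff(range(tab$e5ht_nM_off)),
                   damping_ratio = diff(range(tab$e5ht_nM_on)) /
                     diff(range(tab$e5ht_nM_off))))
}

#' SSRI dosing experiment
#'
#' A single SSRI dose at `dose_time`: the unblocked-SERT fraction follows
#' the dosing profile ([fluox_dose()]), and the raphe firing rate is
#' suppressed toward `f_min` in proportion to an occupancy profile with its
#' own recovery constant `fire_washout` (firing recovers faster than the
#' drug washes out of the tissue).  A 5-HT1B knockout pins both terminal
#' autoreceptor factors at 1.  Extracellular 5-HT is reported as percent of
#' the pre-dose baseline; the peak-percent values depend on the
#' firing-suppression time course, which is only loosely constrained, and
#' are flagged as soft in the result metadata, while the regional and
#' knockout orderings are robust.
#'
#' @param p calibrated kinetic parameters.
#' @param f_min firing at peak raphe blockade, fraction of tonic
#'   (0.58 hippocampus/MRN, 0.20 frontal cortex/DRN).
#' @param knockout_1b turn off both terminal autoreceptor feedbacks.
#' @param dose_time dose hour.
#' @param fire_washout recovery constant of the firing suppression, hours.
#' @param t_max simulated span, hours.
#' @return a `seroterm_experiment` with the percent-of-baseline trajectory
#'   and summary (`peak_rise_pct`, `trough_pct`, `t_peak_hr`).
#' @export
ssri_experiment <- function(p, f_min = 0.58, knockout_1b = FALSE,
                            dose_time = 1, fire_washout = 5, t_max = 72) {
  cfg <- autoreceptor_config(!knockout_1b, !knockout_1b)
  occ <- function(t) occupancy_profile(t, dose_time = dose_time,
                                       washout = fire_washout)
  occ_max <- max(occ(seq(dose_time, dose_time + 20 * fire_washout,
                         by = 0.01)))
  fire_fun <- function(t) suppressed_fire(t, f_min, occ, occ_max)
  fluox_fun <- function(t) fluox_dose(t, dose_time = dose_time)
  drv <- drivers(fire = fire_fun, fluox = fluox_fun, breakpoints = dose_time)
  times <- sort(unique(c(seq(0, dose_time, by = 0.1),
                         seq(dose_time, t_max, by = 0.02))))
  traj <- integrate_terminal(p, drv, times, cfg = cfg)
  base_e <- baseline_state(p)[["e5ht"]]
  pct <- data.frame(hour = traj$time_hr, e5ht_pct = 100 * traj$e5ht / base_e)
  .experiment_result(
    "ssri",
    list(f_min = f_min, knockout_1b = knockout_1b, dose_time = dose_time,
         fire_washout = fire_washout, t_max = t_max,
         note = paste("peak percentages depend on the firing-suppression",
                      "time course and are soft; orderings are robust")),
    tables = list(e5ht_percent = pct),
    trajectories = list(full = traj),
    summary = list(peak_rise_pct = max(pct$e5ht_pct) - 100,
                   trough_pct = min(pct$e5ht_pct),
                   t_peak_hr = pct$hour[which.max(pct$e5ht_pct)]))
}

#' 5-HT1A agonist experiment
#'
#' A somatodendritic 5-HT1A agonist suppresses raphe firing (no SERT
#' blockade): firing falls toward `f_min` following an occupancy profile
#' with a short washout and recovers as the agonist clears.  Extracellular
#' 5-HT initially declines toward the steady-state mapping of the firing
#' reduction and then recovers, helped by the terminal autoreceptors.
#'
#' @param p calibrated kinetic parameters.
#' @param f_min firing at peak agonist occupancy, fraction of tonic.
#' @param washout agonist occupancy washout constant, hours.
#' @param dose_time dose hour.
#' @param t_max simulated span, hours.
#' @return a `seroterm_experiment` with the percent-of-baseline trajectory
#'   and summary (`trough_pct`, `t_trough_hr`, `final_pct`).
#' @export
agonist_experiment <- function(p, f_min = 0.20, washout = 2, dose_time = 1,
                               t_max = 24) {
  cfg <- autoreceptor_config(TRUE, TRUE)
  occ <- function(t) occupancy_profile(t, dose_time = dose_time,
                                       washout = washout)
  occ_max <- max(occ(seq(dose_time, dose_time + 20 * washout, by = 0.005)))
  fire_fun <- function(t) suppressed_fire(t, f_min, occ, occ_max)
  drv <- drivers(fire = fire_fun, fluox = 1, breakpoints = dose_time)
  times <- sort(unique(c(seq(0, dose_time, by = 0.1),
                         seq(dose_time, t_max, by = 0.01))))
  traj <- integrate_terminal(p, drv, times, cfg = cfg)
  base_e <- baseline_state(p)[["e5ht"]]
  pct <- data.frame(hour = traj$time_hr, e5ht_pct = 100 * traj$e5ht / base_e)
  .experiment_result(
    "agonist",
    list(f_min = f_min, washout = washout, dose_time = dose_time,
         t_max = t_max),
    tables = list(e5ht_percent = pct),
    trajectories = list(full = traj),
    summary = list(trough_pct = min(pct$e5ht_pct),
                   t_trough_hr = pct$hour[which.min(pct$e5ht_pct)],
                   final_pct = pct$e5ht_pct[nrow(pct)]))
}
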