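# Calibration of the under-determined constants so that the baseline steady
# state reproduces the published concentrations and fluxes.
#
# Precedence: literature-anchored Km values are never altered; only the
# author-chosen maximal velocities / rate constants are eligible.

.seroterm_env <- new.env(parent = emptyenv())

#' Calibration targets
#'
#' The published baseline values the calibration pins the model to:
#' free tryptophan 20.6 uM with a 10x intracellular pool, serum tryptophan
#' 96 uM giving an uptake flux of ~158 uM/hr, synthesis flux 5.57 uM/hr,
#' cytosolic / vesicular / extracellular 5-HT of 0.5 / 21.45 / 0.000768 uM,
#' 5-HTP 2.26 uM and 5-HIAA 5.22 uM.
#'
#' @return named list of targets (uM, uM/hr, dimensionless ratio).
#' @export
calibration_targets <- function() {
  list(trp_star = 20.6, pool_ratio = 10, btrp_star = 96,
       synthesis_flux = 5.57,
       c5ht_star = 0.5, v5ht_star = 21.45, e5ht_star = 0.000768,
       htp5_star = 2.26, hiaa_star = 5.22)
}

# Steady-state pieces forced by flux closure at the target operating point
# (synthesis factor and release factor both equal 1 at e5ht = e*):
#   htp5*  from V_AADC = synthesis flux
#   v5ht*  from release*fire*v5ht = V_SERT + V_catab_e + V_rem at fire = 1
#   c5ht*  from V_catab_c = synthesis - V_catab_e - V_rem
.forced_closure <- function(p, targets) {
  e <- targets$e5ht_star
  syn <- targets$synthesis_flux
  if (syn >= p$aadc_vmax)
    stop("synthesis flux exceeds AADC Vmax", call. = FALSE)
  htp5 <- p$aadc_km * syn / (p$aadc_vmax - syn)
  vce <- p$catab_e_vmax * e / (p$catab_e_km + e)
  vrem <- p$k_rem * e
  v5ht <- v_sert(e, 1, p) + vce + vrem
  vcc <- syn - vce - vrem
  if (vcc <= 0 || vcc >= p$catab_c_vmax)
    stop("cytosolic catabolism flux infeasible", call. = FALSE)
  c5ht <- p$catab_c_km * vcc / (p$catab_c_vmax - vcc)
  list(htp5 = htp5, v5ht = v5ht, c5ht = c5ht,
       v_catab_c = vcc, v_catab_e = vce, v_rem = vrem,
       hiaa5 = (vcc + vce) / p$hiaa_k_catab)
}

#' Calibrate the biopterin pool
#'
#' Solves for the BH4 level at which the tryptophan hydroxylase velocity
#' (with synthesis factor 1) equals the target synthesis flux at the target
#' tryptophan concentration, then for the BH2 level at which the reductase
#' exactly regenerates that flux.  Their sum becomes the conserved total
#' biopterin of the model.
#'
#' @param p kinetic parameters (TPH and DRR entries used).
#' @param targets see [calibration_targets()].
#' @return named vector: `bh4_star`, `bh2_star`, `b_total` (uM).
#' @export
calibrate_biopterin <- function(p, targets = calibration_targets()) {
  syn <- targets$synthesis_flux
  if (syn == 0) return(c(bh4_star = 0, bh2_star = 0, b_total = 0))
  trp <- targets$trp_star
  mm_trp <- trp / (p$tph_k_trp + trp + trp^2 / p$tph_ki)
  f4 <- function(b) p$tph_vmax * mm_trp * b / (p$tph_k_bh4 + b) - syn
  if (f4(1e3) < 0)
    stop("no BH4 root in (0, 1e3] uM: TPH parameters cannot reach the ",
         "target synthesis flux", call. = FALSE)
  bh4 <- stats::uniroot(f4, c(1e-12, 1e3), tol = 1e-14)$root
  f2 <- function(b2) v_drr(b2, bh4, p) - syn
  if (f2(1e3) < 0)
    stop("no BH2 root in (0, 1e3] uM: DRR parameters cannot regenerate the ",
         "target flux", call. = FALSE)
  bh2 <- stats::uniroot(f2, c(1e-12, 1e3), tol = 1e-14)$root
  c(bh4_star = bh4, bh2_star = bh2, b_total = bh2 + bh4)
}

#' Calibrate the vesicular leak constant
#'
#' At steady state the net vesicular packaging flux must equal the release
#' flux, which at baseline equals the vesicular concentration itself
#' (fire = 1/hr, release factor 1).  Given the catabolism-forced cytosolic
#' level, the leak constant follows in closed form:
#' `k_out = (mat_vmax*c*/(mat_km + c*) - v5ht*) / v5ht*`.
#'
#' The default transporter Vmax of 3500 uM/hr yields `k_out` of about
#' 116/hr; the alternative consistent pair `mat_vmax = 1226` yields about
#' 40/hr.
#'
#' @inheritParams calibrate_biopterin
#' @return `mat_k_out`, /hr.
#' @export
calibrate_mat <- function(p, targets = calibration_targets()) {
  fc <- .forced_closure(p, targets)
  if (fc$c5ht <= 0) stop("degenerate cytosolic 5-HT level", call. = FALSE)
  k_out <- (p$mat_vmax * fc$c5ht / (p$mat_km + fc$c5ht) - fc$v5ht) / fc$v5ht
  if (k_out <= 0)
    stop("mat_vmax too small: calibrated vesicular leak would be negative",
         call. = FALSE)
  k_out
}

#' Calibrate the tryptophan-pool constants
#'
#' With the pool at `pool_ratio` times the free tryptophan level, the pool
#' catabolism constant must carry exactly the uptake flux not consumed by
#' synthesis, and the forward exchange constant follows from the pool
#' balance:
#' `k_catab = (uptake - synthesis)/pool`,
#' `k1 = (k_minus1 + k_catab) * pool / trp*`.
#'
#' @inheritParams calibrate_biopterin
#' @return named vector: `pool_k1`, `pool_k_catab` (/hr).
#' @export
calibrate_trp_pool <- function(p, targets = calibration_targets()) {
  uptake <- v_trpin(targets$btrp_star, p)
  pool <- targets$pool_ratio * targets$trp_star
  k_catab <- (uptake - targets$synthesis_flux) / pool
  if (k_catab <= 0)
    stop("uptake flux does not exceed synthesis flux: pool calibration ",
         "infeasible", call. = FALSE)
  k1 <- (p$pool_k_minus1 + k_catab) * pool / targets$trp_star
  c(pool_k1 = k1, pool_k_catab = k_catab)
}

#' Flux-balance check of the originally tabulated trp-pool constants
#'
#' The tabulated triple (k1 = 6, k-1 = 0.6, k_catab = 0.2 /hr) cannot
#' satisfy the steady state: the pool must dispose of the uptake flux not
#' consumed by synthesis (about 152 uM/hr at the target operating point),
#' but the maximum steady efflux from free tryptophan into the pool is
#' `k1 * trp* = 6 x 20.6 = 123.6` uM/hr.  This function performs that
#' arithmetic and raises a warning carrying it; the calibrated constants
#' replace the tabulated ones.
#'
#' @param p kinetic parameters.
#' @param targets see [calibration_targets()].
#' @param k1_printed,k_catab_printed the tabulated values.
#' @return invisibly, a list with `required_efflux`, `max_attainable`
#'   (uM/hr) and `feasible`.
#' @export
check_printed_pool_constants <- function(p, targets = calibration_targets(),
                                         k1_printed = 6,
                                         k_catab_printed = 0.2) {
  required <- v_trpin(targets$btrp_star, p) - targets$synthesis_flux
  attainable <- k1_printed * targets$trp_star
  feasible <- attainable >= required
  if (!feasible)
    warning(sprintf(
      paste0("tabulated trp-pool constants are flux-infeasible: steady ",
             "disposal of %.1f uM/hr is required (uptake %.1f - synthesis ",
             "%.2f uM/hr) but k1*trp = %g x %.1f = %.1f uM/hr is the most ",
             "the exchange can carry; using calibrated constants instead"),
      required, v_trpin(targets$btrp_star, p), targets$synthesis_flux,
      k1_printed, targets$trp_star, attainable),
      call. = FALSE)
  invisible(list(required_efflux = required, max_attainable = attainable,
                 feasible = feasible))
}

#' Calibrate a parameter set to the baseline targets
#'
#' Fills the three calibrated constants (`mat_k_out`, `pool_k1`,
#' `pool_k_catab`), attaches the analytic baseline steady state and the
#' conserved biopterin total, and tags provenance.  Idempotent: re-running
#' on an already-calibrated set reproduces it.
#'
#' The flux-balance warning about the originally tabulated trp-pool
#' constants (see [check_printed_pool_constants()]) is raised once per
#' session.
#'
#' @param p a `seroterm_params` object (calibrated entries may be `NA`).
#' @param targets see [calibration_targets()].
#' @return the calibrated `seroterm_params`.
#' @export
calibrate_parameters <- function(p, targets = calibration_targets()) {
  if (is.null(.seroterm_env$pool_warned)) {
    .seroterm_env$pool_warned <- TRUE
    check_printed_pool_constants(p, targets)
  }
  bio <- calibrate_biopterin(p, targets)
  p$mat_k_out <- unname(calibrate_mat(p, targets))
  pool <- calibrate_trp_pool(p, targets)
  p$pool_k1 <- unname(pool[["pool_k1"]])
  p$pool_k_catab <- unname(pool[["pool_k_catab"]])
  fc <- .forced_closure(p, targets)
  st <- terminal_state(
    bh2 = unname(bio[["bh2_star"]]), bh4 = unname(bio[["bh4_star"]]),
    trp = targets$trp_star, htp5 = fc$htp5, c5ht = fc$c5ht, v5ht = fc$v5ht,
    e5ht = targets$e5ht_star, hiaa5 = fc$hiaa5,
    trp_pool = targets$pool_ratio * targets$trp_star)
  attr(p, "baseline_state") <- st
  attr(p, "b_total") <- unname(bio[["b_total"]])
  prov <- attr(p, "provenance")
  prov[c("mat_k_out", "pool_k1", "pool_k_catab")] <- "calibrated"
  attr(p, "provenance") <- prov
  validate_parameters(p)
  p
}

#' Flux-closure report at a steady state
#'
#' Evaluates every reaction and transport velocity at a (purported) steady
#' state and the residuals of the five balance identities that must hold
#' there: synthesis = decarboxylation; net vesicular packaging = release;
#' release = reuptake + extracellular catabolism + removal; synthesis =
#' total catabolism + removal; uptake = pool disposal + synthesis.
#'
#' @param p kinetic parameters.
#' @param steady a terminal state.
#' @param cfg autoreceptor configuration.
#' @param fire,fluox,btrp constant driver values.
#' @param targets optional targets for relative-error reporting.
#' @return an object of class `seroterm_flux_report`: list with `state`,
#'   `velocities` (uM/hr), `identity_residuals` (uM/hr), `residual_norm`
#'   (infinity norm of the full right-hand side), and `targets_delta`
#'   (relative errors vs the calibration targets).
#' @export
verify_flux_closure <- function(p, steady, cfg = autoreceptor_config(),
                                fire = 1, fluox = 1, btrp = 96,
                                targets = calibration_targets()) {
  fx <- terminal_fluxes(steady, p, cfg, fire = fire, fluox = fluox, btrp = btrp)
  s <- unclass(steady)[.seroterm_state_names]
  ident <- c(
    tph_vs_aadc = fx$v_tph - fx$v_aadc,
    mat_vs_release = fx$v_mat_net - fx$v_release,
    release_vs_efflux = fx$v_release - (fx$v_sert + fx$v_catab_e + fx$v_rem),
    tph_vs_disposal = fx$v_tph - (fx$v_catab_c + fx$v_catab_e + fx$v_rem),
    uptake_vs_use = fx$v_trpin - (p$pool_k_catab * s[["trp_pool"]] + fx$v_tph))
  drv <- drivers(fire = fire, fluox = fluox, btrp = btrp)
  rhs <- terminal_rhs(0, s, p, drv, cfg)
  delta <- c(
    trp = s[["trp"]] / targets$trp_star - 1,
    htp5 = s[["htp5"]] / targets$htp5_star - 1,
    c5ht = s[["c5ht"]] / targets$c5ht_star - 1,
    v5ht = s[["v5ht"]] / targets$v5ht_star - 1,
    e5ht = s[["e5ht"]] / targets$e5ht_star - 1,
    hiaa5 = s[["hiaa5"]] / targets$hiaa_star - 1,
    pool_ratio = s[["trp_pool"]] / (targets$pool_ratio * s[["trp"]]) - 1)
  structure(list(state = s, velocities = fx, identity_residuals = ident,
                 residual_norm = max(abs(rhs)), targets_delta = delta),
            class = "seroterm_flux_report")
}

#' @export
print.seroterm_flux_report <- function(x, ...) {
  cat("<seroterm_flux_report>\n")
  cat("state (uM):\n")
  print(round(x$state, 6))
  cat("velocities (uM/hr):\n")
  v <- unlist(x$velocities)
  print(round(v, 4))
  cat("identity residuals (uM/hr):\n")
  print(signif(x$identity_residuals, 3))
  cat(sprintf("residual norm: %.3g uM/hr\n", x$residual_norm))
  invisible(x)
}
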