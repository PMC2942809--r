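# Rate laws.  All Michaelis-Menten denominators are Km + S with S >= 0, so
# every rate is 0 at zero substrate by construction and bounded by its Vmax.

#' Autoreceptor synthesis factor
#'
#' Multiplier on the tryptophan hydroxylase velocity from the terminal
#' 5-HT1B autoreceptors: `1.5 - e5ht^2 / (e*^2 + e5ht^2)` with
#' `e* = auto_e5ht_star`.  Equal to 1 at the baseline extracellular
#' concentration, rising to 1.5 as e5ht falls to 0 and approaching 0.5 as
#' e5ht grows.  Returns exactly 1 when the synthesis feedback is off.
#'
#' @param e5ht extracellular 5-HT, uM (vectorised).
#' @param p kinetic parameters.
#' @param cfg autoreceptor configuration.
#' @return dimensionless factor in `(auto_synth_lo, auto_synth_hi]`.
#' @export
synthesis_factor <- function(e5ht, p, cfg = autoreceptor_config()) {
  if (any(e5ht < 0)) stop("e5ht must be non-negative", call. = FALSE)
  if (!cfg$synthesis) return(rep(1, length(e5ht)))
  p$auto_synth_hi - e5ht^2 / (p$auto_e5ht_star^2 + e5ht^2)
}

#' Autoreceptor release factor
#'
#' Piecewise-linear multiplier on vesicular release: 1.5 at `e5ht = 0`,
#' descending to 1.0 at `auto_e5ht_star` (the baseline concentration) and to
#' 0.4 at `auto_release_break`, constant 0.4 beyond.  Continuous; returns
#' exactly 1 when the release feedback is off.
#'
#' @inheritParams synthesis_factor
#' @return dimensionless factor in `[auto_release_lo, auto_release_hi]`.
#' @export
release_factor <- function(e5ht, p, cfg = autoreceptor_config()) {
  if (any(e5ht < 0)) stop("e5ht must be non-negative", call. = FALSE)
  if (!cfg$release) return(rep(1, length(e5ht)))
  s <- p$auto_e5ht_star
  b <- p$auto_release_break
  hi <- p$auto_release_hi
  lo <- p$auto_release_lo
  ifelse(e5ht <= s,
         hi - (hi - 1) * e5ht / s,
         ifelse(e5ht <= b, 1 - (1 - lo) * (e5ht - s) / (b - s), lo))
}

#' Tryptophan hydroxylase velocity
#'
#' Two-substrate Michaelis-Menten law with weak substrate inhibition in
#' tryptophan (`trp^2/Ki` term in the denominator) multiplied by the
#' autoreceptor [synthesis_factor()].  The substrate-inhibition optimum lies
#' near `sqrt(K_trp * Ki)` = 200 uM, far above the ~21 uM operating point,
#' so synthesis is steeply sensitive to tryptophan availability.
#'
#' @param trp tryptophan, uM.
#' @param bh4 tetrahydrobiopterin, uM.
#' @inheritParams synthesis_factor
#' @return rate, uM/hr.
#' @export
v_tph <- function(trp, bh4, e5ht, p, cfg = autoreceptor_config()) {
  if (any(trp < 0) || any(bh4 < 0)) stop("concentrations must be non-negative",
                                         call. = FALSE)
  p$tph_vmax * trp * bh4 /
    ((p$tph_k_trp + trp + trp^2 / p$tph_ki) * (p$tph_k_bh4 + bh4)) *
    synthesis_factor(e5ht, p, cfg)
}

#' Aromatic amino acid decarboxylase velocity
#' @param htp5 5-HTP, uM.
#' @param p kinetic parameters.
#' @return rate, uM/hr.
#' @export
v_aadc <- function(htp5, p) {
  if (any(htp5 < 0)) stop("htp5 must be non-negative", call. = FALSE)
  p$aadc_vmax * htp5 / (p$aadc_km + htp5)
}

#' Dihydropteridine reductase net velocity
#'
#' Bidirectional two-substrate law recycling BH2 to BH4 at the expense of
#' NADPH; the NADPH and NADP levels are fixed parameters.  Positive values
#' regenerate BH4; the sign may be negative.
#'
#' @param bh2,bh4 biopterin concentrations, uM.
#' @param p kinetic parameters.
#' @return net rate, uM/hr.
#' @export
v_drr <- function(bh2, bh4, p) {
  if (any(bh2 < 0) || any(bh4 < 0)) stop("concentrations must be non-negative",
                                         call. = FALSE)
  p$drr_vmax_f * bh2 * p$nadph /
    ((p$drr_k_bh2 + bh2) * (p$drr_k_nadph + p$nadph)) -
    p$drr_vmax_b * bh4 * p$nadp /
      ((p$drr_k_bh4 + bh4) * (p$drr_k_nadp + p$nadp))
}

#' Tryptophan uptake across the blood-brain barrier
#'
#' Single effective Michaelis-Menten step (L-transporter kinetics with the
#' effective Km in the presence of competing amino acids).
#'
#' @param btrp serum tryptophan, uM.
#' @param p kinetic parameters.
#' @return rate, uM/hr.
#' @export
v_trpin <- function(btrp, p) {
  if (any(btrp < 0)) stop("btrp must be non-negative", call. = FALSE)
  p$trpin_vmax * btrp / (p$trpin_km + btrp)
}

#' Net vesicular packaging velocity
#'
#' Michaelis-Menten uptake of cytosolic 5-HT into vesicles minus a linear
#' leak `mat_k_out * v5ht` back to the cytosol.  Positive = into vesicles.
#'
#' @param c5ht cytosolic 5-HT, uM.
#' @param v5ht vesicular 5-HT, uM.
#' @param p kinetic parameters.
#' @return net rate, uM/hr.
#' @export
v_mat_net <- function(c5ht, v5ht, p) {
  if (any(c5ht < 0) || any(v5ht < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  p$mat_vmax * c5ht / (p$mat_km + c5ht) - p$mat_k_out * v5ht
}

#' Serotonin transporter (SERT) reuptake velocity
#'
#' @param e5ht extracellular 5-HT, uM.
#' @param unblocked_fraction fraction of SERTs left unblocked, in `[0, 1]`
#'   (1 = no SSRI, 0 = complete knockout).
#' @param p kinetic parameters.
#' @return rate, uM/hr.
#' @export
v_sert <- function(e5ht, unblocked_fraction, p) {
  if (any(e5ht < 0)) stop("e5ht must be non-negative", call. = FALSE)
  if (any(unblocked_fraction < 0) || any(unblocked_fraction > 1))
    stop("unblocked_fraction must lie in [0, 1]", call. = FALSE)
  unblocked_fraction * p$sert_vmax * e5ht / (p$sert_km + e5ht)
}

#' Catabolic, removal and pool-exchange fluxes
#'
#' The combined MAO/ALDH catabolism of cytosolic and extracellular 5-HT,
#' first-order removal of extracellular 5-HT (glial/blood uptake and
#' diffusion), 5-HIAA clearance, and the net tryptophan -> pool exchange
#' flux (positive = into the pool).
#'
#' @param state a terminal state (named vector, uM).
#' @param p kinetic parameters.
#' @return named list: `v_catab_c`, `v_catab_e`, `v_rem`, `v_hiaa_out`,
#'   `pool_flux`, all uM/hr.
#' @export
clearances <- function(state, p) {
  s <- pmax(unclass(state)[.seroterm_state_names], 0)
  list(
    v_catab_c = p$catab_c_vmax * s[["c5ht"]] / (p$catab_c_km + s[["c5ht"]]),
    v_catab_e = p$catab_e_vmax * s[["e5ht"]] / (p$catab_e_km + s[["e5ht"]]),
    v_rem = p$k_rem * s[["e5ht"]],
    v_hiaa_out = p$hiaa_k_catab * s[["hiaa5"]],
    pool_flux = p$pool_k1 * s[["trp"]] - p$pool_k_minus1 * s[["trp_pool"]])
}
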