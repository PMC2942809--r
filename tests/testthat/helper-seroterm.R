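# Shared fixtures: one calibrated parameter set reused across test files.
base_params <- suppressWarnings(kinetic_parameters())
base_state <- baseline_state(base_params)
base_targets <- calibration_targets()

# independent line-by-line recoding of the nine differential equations,
# kept free of the package's rate-law functions so it can act as an oracle
oracle_rhs <- function(s, q, fire, fluox, btrp, syn_on = TRUE, rel_on = TRUE) {
  bh2 <- s[["bh2"]]; bh4 <- s[["bh4"]]; trp <- s[["trp"]]
  htp5 <- s[["htp5"]]; c5 <- s[["c5ht"]]; v5 <- s[["v5ht"]]
  e5 <- s[["e5ht"]]; hi <- s[["hiaa5"]]; pool <- s[["trp_pool"]]
  synf <- if (syn_on) 1.5 - e5^2 / (0.000768^2 + e5^2) else 1
  relf <- if (!rel_on) 1 else if (e5 <= 0.000768) 1.5 - 0.5 * e5 / 0.000768
          else if (e5 <= 0.0023) 1 - 0.6 * (e5 - 0.000768) / (0.0023 - 0.000768)
          else 0.4
  VT <- q$tph_vmax * trp * bh4 /
    ((q$tph_k_trp + trp + trp^2 / q$tph_ki) * (q$tph_k_bh4 + bh4)) * synf
  VD <- q$drr_vmax_f * bh2 * q$nadph /
    ((q$drr_k_bh2 + bh2) * (q$drr_k_nadph + q$nadph)) -
    q$drr_vmax_b * bh4 * q$nadp /
      ((q$drr_k_bh4 + bh4) * (q$drr_k_nadp + q$nadp))
  VA <- q$aadc_vmax * htp5 / (q$aadc_km + htp5)
  VM <- q$mat_vmax * c5 / (q$mat_km + c5) - q$mat_k_out * v5
  VS <- fluox * q$sert_vmax * e5 / (q$sert_km + e5)
  Vin <- q$trpin_vmax * btrp / (q$trpin_km + btrp)
  rel <- relf * fire * v5
  vcc <- q$catab_c_vmax * c5 / (q$catab_c_km + c5)
  vce <- q$catab_e_vmax * e5 / (q$catab_e_km + e5)
  pf <- q$pool_k1 * trp - q$pool_k_minus1 * pool
  c(bh2 = VT - VD,
    bh4 = VD - VT,
    trp = Vin - VT - pf,
    htp5 = VT - VA,
    c5ht = VA - VM + VS - vcc,
    v5ht = VM - rel,
    e5ht = rel - VS - vce - q$k_rem * e5,
    hiaa5 = vcc + vce - q$hiaa_k_catab * hi,
    trp_pool = pf - q$pool_k_catab * pool)
}

# a small set of strictly positive states spread around the baseline
random_states <- function(n = 12, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    f <- exp(stats::runif(9, log(0.2), log(5)))
    s <- unclass(base_state) * f
    names(s) <- names(base_state)
    s
  })
}
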