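# Right-hand side of the nine ODEs.

#' All reaction and transport velocities at a state
#'
#' Evaluates every rate law at one state under given instantaneous driver
#' values.  Concentrations that have gone (marginally) negative through
#' solver round-off are clipped to 0 for rate evaluation only; the stored
#' state is never modified, so conservation checks stay honest.
#'
#' @param state terminal state, uM.
#' @param p kinetic parameters.
#' @param cfg autoreceptor configuration.
#' @param fire firing rate, /hr.
#' @param fluox fraction of SERTs unblocked, in `[0, 1]`.
#' @param btrp serum tryptophan, uM.
#' @return named list of velocities, uM/hr: `v_tph`, `v_drr`, `v_trpin`,
#'   `v_aadc`, `v_mat_net`, `v_sert` (already scaled by `fluox`),
#'   `v_release` (`release_factor * fire * v5ht`), plus the [clearances()].
#' @export
terminal_fluxes <- function(state, p, cfg = autoreceptor_config(),
                            fire = 1, fluox = 1, btrp = 96) {
  s <- pmax(unclass(state)[.seroterm_state_names], 0)
  cl <- clearances(s, p)
  c(list(
    v_tph = v_tph(s[["trp"]], s[["bh4"]], s[["e5ht"]], p, cfg),
    v_drr = v_drr(s[["bh2"]], s[["bh4"]], p),
    v_trpin = v_trpin(btrp, p),
    v_aadc = v_aadc(s[["htp5"]], p),
    v_mat_net = v_mat_net(s[["c5ht"]], s[["v5ht"]], p),
    v_sert = v_sert(s[["e5ht"]], fluox, p),
    v_release = release_factor(s[["e5ht"]], p, cfg) * fire * s[["v5ht"]]),
    cl)
}

#' Right-hand side of the nine model ODEs
#'
#' Time derivatives of the nine concentrations, uM/hr:
#' \preformatted{
#'   d(bh2)      = V_TPH - V_DRR
#'   d(bh4)      = V_DRR - V_TPH
#'   d(trp)      = V_trpin - V_TPH - pool_flux
#'   d(htp5)     = V_TPH - V_AADC
#'   d(c5ht)     = V_AADC - V_MATnet + fluox*V_SERT - V_catab_c
#'   d(v5ht)     = V_MATnet - release*fire*v5ht
#'   d(e5ht)     = release*fire*v5ht - fluox*V_SERT - V_catab_e - V_rem
#'   d(hiaa5)    = V_catab_c + V_catab_e - k_hiaa*hiaa5
#'   d(trp_pool) = pool_flux - k_pool_catab*trp_pool
#' }
#' The biopterin equations cancel exactly, so `bh2 + bh4` is conserved.
#'
#' @param t time, hours.
#' @param state terminal state, uM.
#' @param p kinetic parameters.
#' @param drv drivers, see [drivers()].
#' @param cfg autoreceptor configuration.
#' @return named numeric vector of nine derivatives, uM/hr.
#' @export
terminal_rhs <- function(t, state, p, drv = drivers(), cfg = autoreceptor_config()) {
  fire <- drv$fire(t)
  fluox <- drv$fluox(t)
  btrp <- drv$btrp(t)
  if (any(!is.finite(c(fire, fluox, btrp))))
    stop("drivers undefined or non-finite at t = ", t, call. = FALSE)
  fx <- terminal_fluxes(state, p, cfg, fire = fire, fluox = fluox, btrp = btrp)
  d <- c(
    bh2 = fx$v_tph - fx$v_drr,
    bh4 = fx$v_drr - fx$v_tph,
    trp = fx$v_trpin - fx$v_tph - fx$pool_flux,
    htp5 = fx$v_tph - fx$v_aadc,
    c5ht = fx$v_aadc - fx$v_mat_net + fx$v_sert - fx$v_catab_c,
    v5ht = fx$v_mat_net - fx$v_release,
    e5ht = fx$v_release - fx$v_sert - fx$v_catab_e - fx$v_rem,
    hiaa5 = fx$v_catab_c + fx$v_catab_e - fx$v_hiaa_out,
    trp_pool = fx$pool_flux - p$pool_k_catab * max(state[["trp_pool"]], 0))
  if (any(!is.finite(d)))
    stop("non-finite derivative at t = ", t, call. = FALSE)
  d
}

# deSolve-compatible wrapper
.rhs_desolve <- function(t, y, parms) {
  list(terminal_rhs(t, y, parms$p, parms$drv, parms$cfg))
}
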