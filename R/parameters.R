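# Parameter set, autoreceptor configuration, and state constructors.
#
# Units throughout the core: concentrations in uM, time in hours.
# Extracellular 5-HT is reported in nM at the presentation layer
# (baseline 0.768 nM = 0.000768 uM).

.seroterm_param_names <- c(
  "trpin_km", "trpin_vmax",
  "tph_k_trp", "tph_k_bh4", "tph_vmax", "tph_ki",
  "aadc_km", "aadc_vmax",
  "drr_k_bh2", "drr_k_nadph", "drr_vmax_f",
  "drr_k_bh4", "drr_k_nadp", "drr_vmax_b",
  "nadph", "nadp",
  "mat_km", "mat_vmax", "mat_k_out",
  "sert_km", "sert_vmax",
  "pool_k1", "pool_k_minus1", "pool_k_catab",
  "catab_c_vmax", "catab_c_km", "catab_e_vmax", "catab_e_km",
  "hiaa_k_catab", "k_rem",
  "auto_e5ht_star", "auto_release_break",
  "auto_synth_hi", "auto_synth_lo",
  "auto_release_hi", "auto_release_lo")

.seroterm_state_names <- c(
  "bh2", "bh4", "trp", "htp5", "c5ht", "v5ht", "e5ht", "hiaa5", "trp_pool")

#' Kinetic parameters of the serotonergic terminal model
#'
#' Builds the full parameter set of the model.  Defaults are the resolved
#' baseline values: literature-anchored Michaelis constants, the
#' Methods-text maximal velocities where they conflict with the tabulated
#' ones (`sert_vmax` 4700 uM/hr, `trpin_km` 330 uM, `trpin_vmax` 700 uM/hr),
#' and -- when `calibrate = TRUE`, the default -- three constants pinned by
#' [calibrate_parameters()] so that the baseline steady state reproduces the
#' published concentrations and fluxes: the vesicular leak `mat_k_out`, and
#' the tryptophan-pool constants `pool_k1` and `pool_k_catab`.
#'
#' Parameter overrides are given by name, e.g.
#' `kinetic_parameters(sert_vmax = 8000)`.  Unknown names are rejected.
#' Every parameter carries a provenance tag (`"table"`, `"methods-text"`,
#' `"assumed"`, `"calibrated"`, or `"user"`) in `attr(p, "provenance")`.
#'
#' @param ... named numeric overrides of individual parameters.
#' @param calibrate logical; run [calibrate_parameters()] to fill the three
#'   calibrated constants and attach the analytic baseline steady state.
#' @param targets calibration targets, see [calibration_targets()].
#' @return an object of class `seroterm_params`: a named list of rate
#'   constants (uM, uM/hr, /hr) with attributes `provenance` and, after
#'   calibration, `baseline_state` and `b_total` (conserved biopterin, uM).
#' @examples
#' p <- kinetic_parameters()
#' p$sert_vmax            # 4700 uM/hr
#' baseline_state(p)["e5ht"] * 1000  # 0.768 nM
#' @export
kinetic_parameters <- function(..., calibrate = TRUE,
                               targets = calibration_targets()) {
  p <- list(
    # blood-brain-barrier tryptophan uptake (effective L-transporter kinetics)
    trpin_km = 330, trpin_vmax = 700,
    # tryptophan hydroxylase, with weak substrate inhibition in trp
    tph_k_trp = 40, tph_k_bh4 = 20, tph_vmax = 400, tph_ki = 1000,
    # aromatic amino acid decarboxylase
    aadc_km = 160, aadc_vmax = 400,
    # dihydropteridine reductase (biopterin recycling); NADPH/NADP are held
    # as fixed cofactor levels, not state variables
    drr_k_bh2 = 100, drr_k_nadph = 75, drr_vmax_f = 5000,
    drr_k_bh4 = 10, drr_k_nadp = 75, drr_vmax_b = 3,
    nadph = 300, nadp = 300,
    # vesicular monoamine transporter with linear leak back to the cytosol
    mat_km = 0.198, mat_vmax = 3500, mat_k_out = NA_real_,
    # serotonin reuptake transporter
    sert_km = 0.17, sert_vmax = 4700,
    # exchange between free tryptophan and the intracellular trp pool
    pool_k1 = NA_real_, pool_k_minus1 = 0.6, pool_k_catab = NA_real_,
    # combined MAO/ALDH catabolism of cytosolic and extracellular 5-HT
    catab_c_vmax = 1000, catab_c_km = 95, catab_e_vmax = 1000, catab_e_km = 95,
    # 5-HIAA clearance and removal of extracellular 5-HT (glia, blood, diffusion)
    hiaa_k_catab = 1, k_rem = 400,
    # terminal (5-HT1B) autoreceptor constants
    auto_e5ht_star = 0.000768, auto_release_break = 0.0023,
    auto_synth_hi = 1.5, auto_synth_lo = 0.5,
    auto_release_hi = 1.5, auto_release_lo = 0.4)

  prov <- c(
    trpin_km = "methods-text", trpin_vmax = "methods-text",
    tph_k_trp = "table", tph_k_bh4 = "table", tph_vmax = "table",
    tph_ki = "table", aadc_km = "table", aadc_vmax = "table",
    drr_k_bh2 = "table", drr_k_nadph = "table", drr_vmax_f = "table",
    drr_k_bh4 = "table", drr_k_nadp = "table", drr_vmax_b = "table",
    nadph = "assumed", nadp = "assumed",
    mat_km = "table", mat_vmax = "table", mat_k_out = "calibrated",
    sert_km = "table", sert_vmax = "methods-text",
    pool_k1 = "calibrated", pool_k_minus1 = "table", pool_k_catab = "calibrated",
    catab_c_vmax = "table", catab_c_km = "table",
    catab_e_vmax = "table", catab_e_km = "table",
    hiaa_k_catab = "table", k_rem = "methods-text",
    auto_e5ht_star = "methods-text", auto_release_break = "methods-text",
    auto_synth_hi = "methods-text", auto_synth_lo = "methods-text",
    auto_release_hi = "methods-text", auto_release_lo = "methods-text")

  overrides <- list(...)
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == ""))
      stop("parameter overrides must be named", call. = FALSE)
    bad <- setdiff(nm, .seroterm_param_names)
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           .nearest_hint(bad[1], .seroterm_param_names), call. = FALSE)
    for (k in nm) {
      p[[k]] <- as.numeric(overrides[[k]])
      prov[[k]] <- "user"
    }
  }

  structure(p, class = "seroterm_params", provenance = prov) -> p
  validate_parameters(p, allow_na = TRUE)
  if (calibrate) p <- calibrate_parameters(p, targets = targets)
  p
}

# suggest the nearest known name for an unknown key
.nearest_hint <- function(key, known) {
  d <- utils::adist(key, known)
  near <- known[which.min(d)]
  if (min(d) <= 3) paste0(" (did you mean '", near, "'?)") else ""
}

#' @export
print.seroterm_params <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<seroterm_params> (uM, uM/hr, /hr)\n")
  for (k in names(x))
    cat(sprintf("  %-18s %12.6g  [%s]\n", k, x[[k]], prov[[k]]))
  bs <- attr(x, "baseline_state")
  if (!is.null(bs))
    cat("calibrated baseline attached; e5ht =", format(bs[["e5ht"]] * 1000),
        "nM\n")
  invisible(x)
}

#' Validate a parameter set
#'
#' Checks positivity of every rate constant and the ordering of the
#' autoreceptor breakpoints.
#'
#' @param p a `seroterm_params` object.
#' @param allow_na allow the calibrated constants to be `NA` (pre-calibration).
#' @return `p`, invisibly; errors on violation.
#' @export
validate_parameters <- function(p, allow_na = FALSE) {
  miss <- setdiff(.seroterm_param_names, names(p))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "), call. = FALSE)
  calibrated <- c("mat_k_out", "pool_k1", "pool_k_catab")
  for (k in .seroterm_param_names) {
    v <- p[[k]]
    if (is.na(v)) {
      if (allow_na && k %in% calibrated) next
      stop("parameter '", k, "' is NA", call. = FALSE)
    }
    if (!is.finite(v) || v <= 0)
      stop("parameter '", k, "' must be a positive number, got ", v,
           call. = FALSE)
  }
  if (!(p$auto_release_break > p$auto_e5ht_star))
    stop("auto_release_break must exceed auto_e5ht_star", call. = FALSE)
  invisible(p)
}

#' Autoreceptor feedback configuration
#'
#' Switches for the two terminal (5-HT1B) autoreceptor effects.  When a flag
#' is off the corresponding factor is pinned to exactly 1 for every
#' extracellular 5-HT level; turning both off emulates a 5-HT1B knockout.
#' Because both factors equal 1 at the baseline extracellular concentration
#' (0.768 nM), the baseline steady state is identical with and without the
#' autoreceptors.
#'
#' @param synthesis enable feedback on synthesis (the TPH factor).
#' @param release enable feedback on vesicular release.
#' @return an object of class `seroterm_autoconfig`.
#' @export
autoreceptor_config <- function(synthesis = TRUE, release = TRUE) {
  stopifnot(is.logical(synthesis), length(synthesis) == 1L, !is.na(synthesis),
            is.logical(release), length(release) == 1L, !is.na(release))
  structure(list(synthesis = synthesis, release = release),
            class = "seroterm_autoconfig")
}

#' Terminal state constructor
#'
#' The nine model concentrations at one instant, in uM: the biopterin pair
#' (`bh2`, `bh4`), free tryptophan `trp`, 5-HTP (`htp5`), cytosolic /
#' vesicular / extracellular serotonin (`c5ht`, `v5ht`, `e5ht`), 5-HIAA
#' (`hiaa5`), and the intracellular tryptophan pool (`trp_pool`).
#'
#' @param bh2,bh4,trp,htp5,c5ht,v5ht,e5ht,hiaa5,trp_pool concentrations, uM.
#' @return a named numeric vector of class `seroterm_state`.
#' @export
terminal_state <- function(bh2, bh4, trp, htp5, c5ht, v5ht, e5ht, hiaa5,
                           trp_pool) {
  s <- c(bh2 = bh2, bh4 = bh4, trp = trp, htp5 = htp5, c5ht = c5ht,
         v5ht = v5ht, e5ht = e5ht, hiaa5 = hiaa5, trp_pool = trp_pool)
  validate_state(s)
  class(s) <- "seroterm_state"
  s
}

#' @rdname terminal_state
#' @param s a candidate state vector.
#' @export
validate_state <- function(s) {
  if (!all(.seroterm_state_names %in% names(s)))
    stop("state must contain: ", paste(.seroterm_state_names, collapse = ", "),
         call. = FALSE)
  s <- s[.seroterm_state_names]
  if (any(!is.finite(s))) stop("state contains non-finite values", call. = FALSE)
  if (any(s < 0)) stop("state contains negative concentrations", call. = FALSE)
  invisible(s)
}

#' Calibrated baseline steady state
#'
#' @param p calibrated parameters from [kinetic_parameters()].
#' @return the baseline `seroterm_state` attached during calibration.
#' @export
baseline_state <- function(p) {
  bs <- attr(p, "baseline_state")
  if (is.null(bs))
    stop("parameters carry no baseline state; run calibrate_parameters()",
         call. = FALSE)
  bs
}
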