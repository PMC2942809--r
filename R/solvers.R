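# Steady-state solving, stiff time integration with discontinuous drivers,
# and trajectory metrics.

#' Stiff integration of the terminal model
#'
#' Integrates the nine ODEs with `deSolve` (default `lsoda`), restarting
#' the solver at every declared driver breakpoint so that discontinuous
#' forcing (pulse edges, dose times, meal knots) is handled as a hard
#' restart rather than left to step-size heuristics.
#'
#' @param p kinetic parameters.
#' @param drv drivers, see [drivers()].
#' @param times requested output times, hours, strictly increasing.
#' @param state0 initial state; defaults to the calibrated baseline.
#' @param cfg autoreceptor configuration.
#' @param rtol,atol solver tolerances.
#' @param method a `deSolve` method name.
#' @param hmax optional maximal step size, hours (applied in every segment).
#' @param fluxes also record all reaction velocities at each output time.
#' @return a `seroterm_trajectory`: data frame with `time_hr` and the nine
#'   state columns (uM), attributes `nsteps` (accepted solver steps per
#'   segment) and, if requested, `fluxes` (data frame of velocities).
#' @export
integrate_terminal <- function(p, drv, times, state0 = NULL,
                               cfg = autoreceptor_config(),
                               rtol = 1e-8, atol = 1e-10, method = "lsoda",
                               hmax = NULL, fluxes = FALSE) {
  if (is.null(state0)) state0 <- baseline_state(p)
  s <- validate_state(state0)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  t0 <- times[1]
  tf <- times[length(times)]
  bp <- drv$breakpoints
  bp <- bp[bp > t0 & bp < tf]
  edges <- unique(c(t0, bp, tf))
  parms <- list(p = p, drv = drv, cfg = cfg)
  rows <- list()
  nsteps <- numeric(0)
  cur <- s
  for (i in seq_len(length(edges) - 1)) {
    a <- edges[i]
    b <- edges[i + 1]
    tt <- unique(c(a, times[times > a & times < b], b))
    out <- tryCatch(
      deSolve::ode(y = cur, times = tt, func = .rhs_desolve, parms = parms,
                   method = method, rtol = rtol, atol = atol,
                   hmax = if (is.null(hmax)) NULL else hmax),
      warning = function(w)
        stop("integration trouble in segment [", a, ", ", b, "] hr: ",
             conditionMessage(w), call. = FALSE))
    nsteps <- c(nsteps, attr(out, "istate")[2])
    keep <- if (i < length(edges) - 1) -nrow(out) else TRUE
    rows[[i]] <- out[keep, , drop = FALSE]
    cur <- out[nrow(out), -1]
  }
  m <- do.call(rbind, rows)
  df <- as.data.frame(m)
  names(df)[1] <- "time_hr"
  # keep only the requested times plus segment edges (edges aid half-life
  # bracketing and restart bookkeeping)
  class(df) <- c("seroterm_trajectory", "data.frame")
  attr(df, "nsteps") <- nsteps
  if (fluxes) {
    fl <- t(vapply(seq_len(nrow(df)), function(i) {
      ti <- df$time_hr[i]
      unlist(terminal_fluxes(unlist(df[i, .seroterm_state_names]), p, cfg,
                             fire = drv$fire(ti), fluox = drv$fluox(ti),
                             btrp = drv$btrp(ti)))
    }, numeric(12)))
    attr(df, "fluxes") <- as.data.frame(fl)
  }
  df
}

# damped Newton on the 9 steady-state equations with the bh2 row replaced
# by the biopterin conservation constraint (the raw Jacobian is singular
# along the conserved direction)
.newton_steady <- function(p, cfg, fire, fluox, btrp, seed, b_total,
                           tol = 1e-10, maxit = 200) {
  drv <- drivers(fire = fire, fluox = fluox, btrp = btrp)
  Ffun <- function(x) {
    r <- terminal_rhs(0, x, p, drv, cfg)
    r[1] <- x[[1]] + x[[2]] - b_total
    r
  }
  x <- pmax(seed, 0)
  r <- Ffun(x)
  for (it in seq_len(maxit)) {
    if (max(abs(r)) < tol) break
    J <- matrix(0, 9, 9)
    for (j in 1:9) {
      h <- max(1e-9, 1e-6 * abs(x[[j]]))
      xp <- x
      xp[[j]] <- xp[[j]] + h
      J[, j] <- (Ffun(xp) - r) / h
    }
    dx <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(dx))
      stop("singular Jacobian in steady-state Newton iteration",
           call. = FALSE)
    lambda <- 1
    repeat {
      xn <- pmax(x + lambda * dx, 0)
      rn <- Ffun(xn)
      if (max(abs(rn)) < max(abs(r)) || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    x <- xn
    r <- rn
  }
  if (max(abs(r)) >= tol)
    stop("steady-state Newton iteration did not converge (residual ",
         format(max(abs(r))), " uM/hr)", call. = FALSE)
  names(x) <- .seroterm_state_names
  x
}

#' Steady state under constant drivers
#'
#' Finds the fixed point of the model two ways: a damped Newton iteration
#' (with the biopterin conservation constraint substituted for one of the
#' two redundant biopterin equations) seeded from the calibrated baseline,
#' and -- when `cross_check = TRUE` -- long stiff integration from the seed,
#' which must agree with the root to 0.1% per variable.
#'
#' @param p kinetic parameters.
#' @param cfg autoreceptor configuration.
#' @param fire,fluox,btrp constant driver values.
#' @param seed starting state; defaults to the calibrated baseline.
#' @param tol convergence tolerance on the infinity norm of the right-hand
#'   side, uM/hr.
#' @param cross_check verify the root against long integration.
#' @param t_long horizon for the long-integration route, hours.
#' @return an object of class `seroterm_steady`: list with `state`,
#'   `velocities`, `identity_residuals`, `residual_norm`, `converged`,
#'   `targets_delta`, and (if cross-checked) `route_disagreement`, the
#'   maximal per-variable relative difference between the two routes.
#' @export
find_steady_state <- function(p, cfg = autoreceptor_config(),
                              fire = 1, fluox = 1, btrp = 96, seed = NULL,
                              tol = 1e-8, cross_check = FALSE,
                              t_long = 400) {
  if (is.null(seed)) seed <- baseline_state(p)
  b_total <- seed[["bh2"]] + seed[["bh4"]]
  x <- .newton_steady(p, cfg, fire, fluox, btrp, unclass(seed), b_total,
                      tol = min(tol, 1e-10))
  rep <- verify_flux_closure(p, x, cfg, fire = fire, fluox = fluox,
                             btrp = btrp)
  out <- list(state = x, velocities = rep$velocities,
              identity_residuals = rep$identity_residuals,
              residual_norm = rep$residual_norm,
              converged = rep$residual_norm < tol,
              targets_delta = rep$targets_delta)
  if (cross_check) {
    drv <- drivers(fire = fire, fluox = fluox, btrp = btrp)
    traj <- integrate_terminal(p, drv, times = c(0, t_long / 2, t_long),
                               state0 = seed, cfg = cfg,
                               rtol = 1e-10, atol = 1e-12)
    xi <- unlist(traj[nrow(traj), .seroterm_state_names])
    out$route_disagreement <-
      max(abs(xi - x) / pmax(abs(x), 1e-9))
    if (out$route_disagreement > 1e-3)
      warning("root-finding and long-integration steady states disagree by ",
              format(out$route_disagreement), " (relative)", call. = FALSE)
  }
  class(out) <- "seroterm_steady"
  out
}

#' @export
print.seroterm_steady <- function(x, ...) {
  cat("<seroterm_steady>", if (x$converged) "(converged)" else "(NOT converged)",
      "\n")
  s <- x$state
  cat(sprintf("  e5ht %.4g nM | c5ht %.4g uM | v5ht %.4g uM | trp %.4g uM\n",
              s[["e5ht"]] * 1000, s[["c5ht"]], s[["v5ht"]], s[["trp"]]))
  cat(sprintf("  residual norm %.3g uM/hr", x$residual_norm))
  if (!is.null(x$route_disagreement))
    cat(sprintf(" | route disagreement %.3g", x$route_disagreement))
  cat("\n")
  invisible(x)
}

#' Decay half-life of a trajectory variable
#'
#' Time from the peak of `variable` until its elevation above `baseline`
#' first falls to half the peak elevation, computed on an interpolant of the
#' trajectory by bracketed root finding.  Defined on the elevation (not the
#' absolute concentration) because saturated reuptake makes the decay
#' near-linear rather than exponential.
#'
#' @param traj a `seroterm_trajectory`.
#' @param variable state column name (default `"e5ht"`).
#' @param baseline pre-stimulus level, uM.
#' @return half-life in hours.
#' @export
half_life <- function(traj, variable = "e5ht", baseline) {
  tt <- traj$time_hr
  y <- traj[[variable]]
  ipk <- which.max(y)
  peak <- y[ipk]
  if (peak <= baseline)
    stop("no peak above baseline in '", variable, "'", call. = FALSE)
  tpk <- tt[ipk]
  target <- baseline + (peak - baseline) / 2
  post_t <- tt[ipk:length(tt)]
  post_y <- y[ipk:length(y)]
  below <- which(post_y <= target)
  if (!length(below))
    stop("decay never reaches half the peak elevation", call. = FALSE)
  j <- below[1]
  if (j == 1) return(0)
  f <- stats::approxfun(post_t, post_y)
  th <- stats::uniroot(function(t) f(t) - target,
                       lower = post_t[j - 1], upper = post_t[j],
                       tol = 1e-12)$root
  th - tpk
}
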