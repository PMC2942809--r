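test_that("the calibrated steady state is a fixed point of the integrator", {
  traj <- integrate_terminal(base_params, drivers(), times = c(0, 50, 100))
  dev <- abs(unlist(traj[nrow(traj), -1]) - unclass(base_state)) /
    unclass(base_state)
  expect_lt(max(dev), 1e-6)
})

test_that("root finding and long integration deliver the same steady state", {
  ss <- find_steady_state(base_params, cross_check = TRUE)
  expect_true(ss$converged)
  expect_lt(ss$residual_norm, 1e-8)
  expect_lt(ss$route_disagreement, 1e-3)
  # and under a perturbed condition (half the SERTs blocked)
  ss5 <- find_steady_state(base_params, fluox = 0.5, cross_check = TRUE)
  expect_lt(ss5$route_disagreement, 1e-3)
})

test_that("the baseline fixed point is locally stable on the conservation manifold", {
  p <- base_params
  drv <- drivers()
  f <- function(x) terminal_rhs(0, x, p, drv)
  x0 <- unclass(base_state)
  J <- matrix(0, 9, 9)
  r0 <- f(x0)
  for (j in 1:9) {
    h <- max(1e-7, 1e-6 * x0[[j]])
    xp <- x0
    xp[[j]] <- xp[[j]] + h
    J[, j] <- (f(xp) - r0) / h
  }
  ev <- eigen(J, only.values = TRUE)$values
  re <- sort(Re(ev))
  # biopterin conservation contributes one exactly-zero eigenvalue; the
  # remaining eight must be strictly negative
  expect_lt(abs(re[9]), 1e-6)
  expect_true(all(re[1:8] < -1e-3))
})

test_that("steady extracellular 5-HT falls and vesicular 5-HT rises with SERT fraction", {
  fr <- c(0, 0.05, 0.2, 0.5, 1)
  e <- v <- numeric(length(fr))
  seed <- base_state
  for (i in rev(seq_along(fr))) {
    ss <- find_steady_state(base_params, fluox = fr[i], seed = seed)
    seed <- ss$state
    e[i] <- ss$state[["e5ht"]]
    v[i] <- ss$state[["v5ht"]]
  }
  expect_true(all(diff(e) < 0))
  expect_true(all(diff(v) > 0))
})

test_that("half-life recovers closed forms on synthetic decays", {
  # pure exponential elevation with k = ln 2 per second
  t_hr <- seq(0, 10 / 3600, length.out = 2001)
  base <- 0.000768
  expo <- data.frame(time_hr = t_hr,
                     e5ht = base + 2 * exp(-log(2) * t_hr * 3600))
  expect_equal(half_life(expo, "e5ht", base) * 3600, 1, tolerance = 1e-4)
  # linear decay from peak to baseline over T gives T/2
  lin <- data.frame(time_hr = t_hr,
                    e5ht = base + pmax(0, 2 * (1 - t_hr * 3600 / 5)))
  expect_equal(half_life(lin, "e5ht", base) * 3600, 2.5, tolerance = 1e-3)
  flat <- data.frame(time_hr = t_hr, e5ht = rep(base, length(t_hr)))
  expect_error(half_life(flat, "e5ht", base), "no peak")
  stuck <- data.frame(time_hr = t_hr,
                      e5ht = base + 2 - t_hr)  # barely declines
  expect_error(half_life(stuck, "e5ht", base), "never reaches")
})

test_that("pulse peak converges under tolerance refinement and conserves biopterin", {
  pr8 <- pulse_release(base_params)
  tr <- pr8$trajectories$e5ht
  b0 <- tr$bh2[1] + tr$bh4[1]
  expect_lt(max(abs(tr$bh2 + tr$bh4 - b0)), 1e-8)
  expect_gt(min(unlist(tr[-1])), -1e-9)  # non-negativity up to solver tolerance
  # the pulse window itself is resolved by a healthy number of accepted steps
  expect_gt(sum(attr(tr, "nsteps")), 50)
  drv <- drivers(fire = function(t) square_pulse_fire(t, t_on = 0.002),
                 breakpoints = c(0.002, 0.002 + 1 / 18000))
  times <- sort(unique(c(seq(0, 0.002, length.out = 5),
                         seq(0.002, 0.002 + 1 / 18000, length.out = 101),
                         0.002 + 1 / 18000 + seq(0, 10, by = 0.01) / 3600)))
  t10 <- integrate_terminal(base_params, drv, times, rtol = 1e-10,
                            atol = 1e-13, hmax = (1 / 18000) / 60)
  expect_equal(max(t10$e5ht), pr8$summary$peak_e5ht_uM, tolerance = 1e-6)
})
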