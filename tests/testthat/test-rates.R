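test_that("autoreceptor synthesis factor pins 1 at baseline and spans (0.5, 1.5]", {
  p <- base_params
  on <- autoreceptor_config()
  expect_equal(synthesis_factor(0.000768, p, on), 1)
  expect_equal(synthesis_factor(0, p, on), 1.5)
  expect_equal(synthesis_factor(0.000768, p, autoreceptor_config(FALSE, FALSE)), 1)
  e <- seq(0, 0.05, length.out = 400)
  f <- synthesis_factor(e, p, on)
  expect_true(all(diff(f) < 0))
  expect_true(all(f > 0.5 & f <= 1.5))
  expect_error(synthesis_factor(-1e-6, p, on), "non-negative")
})

test_that("release factor is the continuous piecewise-linear curve 1.5 -> 1.0 -> 0.4", {
  p <- base_params
  on <- autoreceptor_config()
  expect_equal(release_factor(0, p, on), 1.5)
  expect_equal(release_factor(0.000768, p, on), 1)
  expect_equal(release_factor(0.000384, p, on), 1.25)
  expect_equal(release_factor(0.0023, p, on), 0.4)
  expect_equal(release_factor(0.01, p, on), 0.4)
  # continuity at both breakpoints
  eps <- 1e-10
  expect_equal(release_factor(0.000768 - eps, p, on),
               release_factor(0.000768 + eps, p, on), tolerance = 1e-5)
  expect_equal(release_factor(0.0023 - eps, p, on),
               release_factor(0.0023 + eps, p, on), tolerance = 1e-5)
  e <- seq(0, 0.01, length.out = 500)
  f <- release_factor(e, p, on)
  expect_true(all(diff(f) <= 0))
  expect_true(all(f >= 0.4 & f <= 1.5))
  expect_equal(release_factor(0.01, p, autoreceptor_config(TRUE, FALSE)), 1)
})

test_that("TPH velocity shows weak substrate inhibition with optimum near sqrt(Ktrp*Ki)", {
  p <- base_params
  bh4 <- base_state[["bh4"]]
  expect_equal(v_tph(0, bh4, 0.000768, p), 0)
  expect_equal(v_tph(20.6, 0, 0.000768, p), 0)
  # at the calibrated operating point the velocity is the target synthesis flux
  expect_equal(v_tph(20.6, bh4, 0.000768, p), 5.57, tolerance = 1e-10)
  # brute-force grid: the maximum over trp sits near sqrt(40 * 1000) = 200 uM
  trp_grid <- seq(1, 1000, by = 1)
  v <- vapply(trp_grid, function(tr) v_tph(tr, bh4, 0.000768, p), numeric(1))
  opt <- trp_grid[which.max(v)]
  expect_gt(opt, 150)
  expect_lt(opt, 260)
  expect_lt(v_tph(1000, bh4, 0.000768, p), max(v))
})

test_that("single-substrate uptake and decarboxylation laws hit their printed fluxes", {
  p <- base_params
  expect_equal(v_aadc(2.26, p), 400 * 2.26 / 162.26)   # ~5.57 uM/hr
  expect_equal(v_aadc(0, p), 0)
  expect_equal(v_aadc(160, p), 200)                     # half-saturation
  expect_equal(v_trpin(96, p), 700 * 96 / 426)          # ~157.7 uM/hr
  expect_equal(v_trpin(0, p), 0)
  expect_equal(v_trpin(330, p), 350)
})

test_that("reductase, vesicular transport and SERT laws behave at the edges", {
  p <- base_params
  expect_equal(v_drr(0, 0, p), 0)
  expect_lt(v_drr(0, 1, p), 0)          # only the back reaction
  expect_equal(v_mat_net(0, 0, p), 0)
  expect_equal(v_mat_net(0, 10, p), -10 * p$mat_k_out)  # pure leak
  # calibrated: packaging flux at the baseline equals the release flux
  expect_equal(v_mat_net(base_state[["c5ht"]], base_state[["v5ht"]], p),
               base_state[["v5ht"]], tolerance = 1e-10)
  expect_equal(v_sert(0.000768, 1, p), 4700 * 0.000768 / 0.170768)
  expect_equal(v_sert(0.5, 0, p), 0)
  # near-saturated clearance at pulse-scale concentrations
  expect_equal(v_sert(2, 1, p), 9400 / 2.17)
  expect_error(v_sert(0.001, 1.5, p), "\\[0, 1\\]")
})

test_that("Michaelis-Menten rates are monotone in substrate and bounded by Vmax", {
  p <- base_params
  s <- seq(0, 5000, length.out = 300)
  for (law in list(
    list(f = function(x) v_aadc(x, p), vmax = p$aadc_vmax),
    list(f = function(x) v_trpin(x, p), vmax = p$trpin_vmax),
    list(f = function(x) v_sert(x, 1, p), vmax = p$sert_vmax))) {
    y <- vapply(s, law$f, numeric(1))
    expect_true(all(diff(y) > 0))
    expect_true(all(y < law$vmax))
  }
})

test_that("clearance fluxes match their first-order / MM forms", {
  p <- base_params
  cl <- clearances(base_state, p)
  expect_equal(cl$v_catab_c, 1000 * base_state[["c5ht"]] / (95 + base_state[["c5ht"]]))
  expect_equal(cl$v_rem, 400 * 0.000768)
  expect_equal(cl$pool_flux,
               p$pool_k1 * 20.6 - p$pool_k_minus1 * 206, tolerance = 1e-12)
  zero <- base_state * 0
  cl0 <- clearances(zero, p)
  expect_true(all(abs(unlist(cl0)) == 0))
})
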