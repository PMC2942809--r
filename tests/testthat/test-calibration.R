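test_that("biopterin calibration reproduces the target synthesis flux", {
  p <- base_params
  bio <- calibrate_biopterin(p, base_targets)
  # oracle: plain bisection of the TPH rate law, coded independently
  f <- function(b) 400 * 20.6 * b / ((40 + 20.6 + 20.6^2 / 1000) * (20 + b)) - 5.57
  lo <- 1e-9; hi <- 100
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  expect_equal(unname(bio[["bh4_star"]]), lo, tolerance = 1e-8)
  expect_equal(unname(bio[["bh4_star"]]), 0.86051, tolerance = 1e-4)
  expect_equal(unname(bio[["bh2_star"]]), 0.144212, tolerance = 1e-4)
  expect_equal(v_drr(bio[["bh2_star"]], bio[["bh4_star"]], p), 5.57,
               tolerance = 1e-8)
  tg0 <- base_targets
  tg0$synthesis_flux <- 0
  expect_equal(unname(calibrate_biopterin(p, tg0)[["bh4_star"]]), 0)
})

test_that("vesicular leak calibration offers both consistent pairs", {
  expect_equal(calibrate_mat(base_params, base_targets), 115.99, tolerance = 1e-3)
  p_alt <- suppressWarnings(kinetic_parameters(mat_vmax = 1226, calibrate = FALSE))
  expect_equal(calibrate_mat(p_alt, base_targets), 40, tolerance = 2e-3)
  p_small <- suppressWarnings(kinetic_parameters(mat_vmax = 25, calibrate = FALSE))
  expect_error(calibrate_mat(p_small, base_targets), "too small")
})

test_that("trp-pool calibration balances uptake against synthesis and pool disposal", {
  k <- calibrate_trp_pool(base_params, base_targets)
  uptake <- 700 * 96 / 426
  expect_equal(unname(k[["pool_k_catab"]]), (uptake - 5.57) / 206, tolerance = 1e-12)
  expect_equal(unname(k[["pool_k1"]]),
               (0.6 + (uptake - 5.57) / 206) * 206 / 20.6, tolerance = 1e-12)
  expect_equal(unname(k[["pool_k_catab"]]), 0.7387, tolerance = 1e-4)
  expect_equal(unname(k[["pool_k1"]]), 13.387, tolerance = 1e-4)
})

test_that("the tabulated trp-pool constants are provably flux-infeasible", {
  expect_warning(
    chk <- check_printed_pool_constants(base_params, base_targets),
    "flux-infeasible")
  expect_false(chk$feasible)
  expect_equal(chk$required_efflux, 700 * 96 / 426 - 5.57, tolerance = 1e-12)
  expect_equal(chk$max_attainable, 6 * 20.6)
  expect_gt(chk$required_efflux, chk$max_attainable)
})

test_that("calibration is idempotent and insensitive to the NADPH choice except bh2*", {
  p1 <- base_params
  p2 <- suppressWarnings(calibrate_parameters(p1, base_targets))
  expect_equal(unlist(p2[names(p2)]), unlist(p1[names(p1)]), tolerance = 1e-10)
  expect_equal(unclass(baseline_state(p2)), unclass(baseline_state(p1)),
               tolerance = 1e-10)
  p3 <- suppressWarnings(kinetic_parameters(nadph = 600))
  expect_equal(p3$mat_k_out, p1$mat_k_out, tolerance = 1e-12)
  expect_equal(p3$pool_k1, p1$pool_k1, tolerance = 1e-12)
  s3 <- baseline_state(p3)
  expect_equal(s3[["bh4"]], base_state[["bh4"]], tolerance = 1e-10)
  expect_false(isTRUE(all.equal(s3[["bh2"]], base_state[["bh2"]],
                                tolerance = 1e-3)))
})

test_that("flux closure holds at the calibrated baseline and reports targets honestly", {
  rep <- verify_flux_closure(base_params, base_state)
  expect_lt(max(abs(rep$identity_residuals)), 1e-6)
  expect_lt(rep$residual_norm, 1e-8)
  expect_equal(rep$velocities$v_sert, 21.14, tolerance = 1e-3)
  expect_equal(rep$velocities$v_rem, 0.3072, tolerance = 1e-6)
  expect_equal(rep$velocities$v_catab_e, 0.008, tolerance = 2e-2)
  # cytosolic 5-HT is forced by inverting the catabolism balance
  expect_equal(rep$state[["c5ht"]], 95 * 5.2547 / (1000 - 5.2547),
               tolerance = 1e-3)
  # every target matched within 2%
  expect_lt(max(abs(rep$targets_delta)), 0.02)
  zero <- base_state * 0
  rep0 <- verify_flux_closure(base_params, zero)
  v0 <- unlist(rep0$velocities)
  expect_true(all(v0[setdiff(names(v0), "v_trpin")] == 0))
  expect_equal(rep0$residual_norm, v_trpin(96, base_params))
})

test_that("parameter factory validates names and records provenance", {
  expect_error(suppressWarnings(kinetic_parameters(sert_vmx = 1)), "sert_vmax")
  p <- suppressWarnings(kinetic_parameters(sert_vmax = 8000))
  expect_equal(p$sert_vmax, 8000)
  expect_equal(attr(p, "provenance")[["sert_vmax"]], "user")
  expect_equal(attr(base_params, "provenance")[["mat_k_out"]], "calibrated")
  expect_error(suppressWarnings(kinetic_parameters(sert_km = -1)), "positive")
})
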