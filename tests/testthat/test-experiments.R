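test_that("SERT-fraction sweep is monotone and vanishes reuptake at knockout", {
  res <- table4_sweep(base_params)
  tab <- res$tables$sweep
  expect_equal(tab$f, c(1, 0.5, 0.2, 0.1, 0.05, 0))
  expect_true(all(diff(tab$e5ht_nM) > 0))   # e5ht rises as f falls
  expect_true(all(diff(tab$v5ht) < 0))      # vesicular store drains
  expect_true(all(diff(tab$v_tph) < 0))     # synthesis feedback throttles
  expect_identical(tab$v_sert[tab$f == 0], 0)
  # experiments are deterministic: identical re-run, bit for bit
  expect_identical(res$tables$sweep, table4_sweep(base_params)$tables$sweep)
})

test_that("a pulse at the tonic rate is no pulse at all", {
  res <- pulse_release(base_params, pulse = 1, follow_s = 5)
  expect_false(res$summary$peak_detected)
  expect_true(is.na(res$summary$half_life_s))
  tr <- res$trajectories$e5ht
  expect_lt(diff(range(tr$e5ht)) / base_state[["e5ht"]], 1e-4)
})

test_that("stimulation pulse releases ~10% of the vesicular store and decays linearly", {
  res <- pulse_release(base_params)
  expect_true(res$summary$peak_detected)
  expect_gt(res$summary$v5ht_released_frac, 0.05)
  expect_lt(res$summary$v5ht_released_frac, 0.2)
  expect_gt(res$summary$decay_linearity_r2, 0.99)
})

test_that("meals leave no trace when the peak factor is 1", {
  res <- meals_experiment(base_params, peak_factor = 1, warmup_days = 0)
  expect_lt(max(abs(unlist(res$summary))), 0.01)
  expect_equal(mean(res$tables$percent_of_baseline$e5ht), 100, tolerance = 1e-4)
})

test_that("meal responses: equal tryptophan peaks, synthesis swings more than e5ht", {
  res <- meals_experiment(base_params)
  pct <- res$tables$percent_of_baseline
  # three local maxima of cellular trp, all the same height (trp relaxes to
  # baseline between meals)
  y <- pct$trp
  ipk <- which(diff(sign(diff(y))) == -2) + 1
  pks <- y[ipk][y[ipk] > 110]
  expect_equal(length(pks), 3)
  expect_lt(diff(range(pks)) / mean(pks), 0.02)
  # autoreceptor damping: the synthesis-velocity swing strictly exceeds the
  # extracellular swing
  expect_gt(res$summary$v_tph_swing_pct, res$summary$e5ht_swing_pct)
  expect_gt(res$summary$e5ht_swing_pct, 1)
})

test_that("autoreceptors damp steady-state e5ht across all three swept inputs", {
  for (vary in c("fire", "sert_vmax", "tph_vmax")) {
    res <- homeostasis_sweep(base_params, vary)
    expect_lt(res$summary$range_on_nM, res$summary$range_off_nM)
    expect_true(all(res$tables$sweep$e5ht_nM_on > 0))
  }
})

test_that("SSRI dosing: regional and 5-HT1B-knockout orderings are robust", {
  wt_hip <- ssri_experiment(base_params, f_min = 0.58)
  wt_fc <- ssri_experiment(base_params, f_min = 0.20)
  ko_hip <- ssri_experiment(base_params, f_min = 0.58, knockout_1b = TRUE)
  ko_fc <- ssri_experiment(base_params, f_min = 0.20, knockout_1b = TRUE)
  # all four regions end up above baseline at some point after the dose
  expect_gt(wt_fc$summary$peak_rise_pct, 5)
  # hippocampus (milder firing suppression) rises more than frontal cortex
  expect_gt(wt_hip$summary$peak_rise_pct, wt_fc$summary$peak_rise_pct)
  expect_gt(ko_hip$summary$peak_rise_pct, ko_fc$summary$peak_rise_pct)
  # knockouts overshoot wild type in both regions
  expect_gt(ko_hip$summary$peak_rise_pct, wt_hip$summary$peak_rise_pct)
  expect_gt(ko_fc$summary$peak_rise_pct, wt_fc$summary$peak_rise_pct)
})

test_that("5-HT1A agonist troughs map to the steady-state firing curve", {
  fc <- agonist_experiment(base_params, f_min = 0.20)
  hip <- agonist_experiment(base_params, f_min = 0.58)
  expect_equal(fc$summary$trough_pct, 30, tolerance = 0.15)
  expect_equal(hip$summary$trough_pct, 70, tolerance = 0.05)
  expect_gt(fc$summary$final_pct, fc$summary$trough_pct)  # recovery
  none <- agonist_experiment(base_params, f_min = 1, t_max = 6)
  expect_equal(none$summary$trough_pct, 100, tolerance = 1e-4)
})
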