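test_that("cycle extraction returns one ordered window per cycle", {
  tr <- toy_trace(3)
  w <- extract_cycles(tr)
  expect_equal(nrow(w), 3)
  expect_equal(w$cycle_index, 1:3)
  expect_true(all(vapply(w$window, function(x) all(x$phase == "measure"),
                         logical(1))))
  expect_error(extract_cycles(dplyr::select(tr, -phase)), "phase")
  # a cycle with no measure phase is skipped with a warning
  tr2 <- tr[!(tr$cycle_index == 2 & tr$phase == "measure"), ]
  expect_warning(w2 <- extract_cycles(tr2), "no measure phase")
  expect_equal(nrow(w2), 2)
})

test_that("window count follows the configured cycle length", {
  traj <- trajectory_spec("constant", list(value = 100), 48 * 60)
  ch <- chamber_spec(fish_mass_kg = 0.017)
  tr <- synthesize_trace(traj, ch, cycle = cycle_config(77, 5, 78))
  expect_equal(nrow(extract_cycles(tr)), floor(48 * 3600 / 160))
})

test_that("slope fitting is exact on lines and defined on constants", {
  t <- 0:59
  w <- tibble::tibble(time_s = t, o2_mg_per_l = 9 - 5 * t / 3600,
                      o2_sat_pct = 90)
  f <- fit_slope(w)
  expect_equal(f$slope_mg_l_h, -5, tolerance = 1e-10)
  expect_equal(f$r2, 1)
  const <- tibble::tibble(time_s = t, o2_mg_per_l = 8.5)
  fc <- fit_slope(const)
  expect_equal(fc$slope_mg_l_h, 0)
  expect_equal(fc$r2, 0)
  expect_error(fit_slope(w[1:2, ]), "3 samples")
  expect_error(fit_slope(tibble::tibble(time_s = rep(1, 5),
                                        o2_mg_per_l = 1:5)), "variance")
})

test_that("slope fits agree with an independent normal-equations oracle", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(10:120, 1)
    t <- sort(runif(n, 0, 150))
    y <- 9 + rnorm(1, -0.005, 0.002) * t + rnorm(n, 0, 0.01)
    f <- fit_slope(tibble::tibble(time_s = t, o2_mg_per_l = y))
    o <- ols_oracle(t / 3600, y)
    expect_equal(f$slope_mg_l_h, unname(o["slope"]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(o["intercept"]), tolerance = 1e-10)
  }
})

test_that("the MO2 equation converts slopes with the chamber geometry", {
  ch <- chamber_spec(volume_l = 0.362, fish_mass_kg = 0.020,
                     fish_volume_l = 0.020)
  expect_equal(compute_mo2(0, ch), 0)
  expect_equal(compute_mo2(-10, ch), 0.342 * 10 / 0.020)  # 171.0
  expect_warning(mo2 <- compute_mo2(2, ch), "rising")
  expect_lt(mo2, 0)
})

test_that("noiseless end-to-end extraction recovers the trajectory", {
  ch <- chamber_spec(fish_mass_kg = 0.025)
  flat <- synthesize_trace(trajectory_spec("constant", list(value = 180), 120),
                           ch)
  m <- extract_mo2(flat, ch)
  expect_lt(max(abs(m$mo2 - 180)), 1e-6)
  expect_true(all(m$qc_pass))
  rhythm <- scenario_preset("daily_rhythm", noise_sd = 0,
                            background_fraction = 0)$trajectory
  tr <- synthesize_trace(rhythm, ch, duration_min = 600)
  m2 <- extract_mo2(tr, ch)
  truth <- make_trajectory(rhythm, time_min = m2$time_min)$mo2
  expect_lt(max(abs(m2$mo2 - truth)), 1e-6)
})

test_that("background respiration is recovered and corrected exactly", {
  ch <- chamber_spec(fish_mass_kg = 0.020)
  traj <- trajectory_spec("constant", list(value = 180), 120)
  f <- 0.02
  gross <- synthesize_trace(traj, ch, background_fraction = f)
  m_raw <- extract_mo2(gross, ch)
  expect_equal(mean(m_raw$mo2), 180 / (1 - f), tolerance = 1e-9)

  # empty-chamber traces reproducing that background rate
  fish_slope <- 180 * ch$fish_mass_kg / (ch$volume_l - ch$fish_volume_l)
  bg_rate <- f / (1 - f) * fish_slope
  empty_traj <- trajectory_spec("constant", list(value = 0), 25)
  empty <- synthesize_trace(empty_traj, ch,
                            background_rate_mg_l_h = bg_rate)
  msgs <- capture_warnings(
    bg <- estimate_background(before = empty,
                              gross_slope_mg_l_h = fish_slope / (1 - f)))
  expect_match(msgs, "one background segment", all = FALSE)
  expect_match(msgs, ">= 1%", all = FALSE, fixed = TRUE)
  expect_equal(bg$rate_mg_l_h, bg_rate, tolerance = 1e-9)
  expect_equal(bg$fraction, f, tolerance = 1e-9)
  expect_true(bg$significant)

  # correction reduces extracted MO2 by exactly (1 - f)
  m_cor <- extract_mo2(gross, ch, background = suppressWarnings(
    estimate_background(before = empty)))
  expect_equal(m_cor$mo2, m_raw$mo2 * (1 - f), tolerance = 1e-9)
  expect_equal(mean(m_cor$mo2), 180, tolerance = 1e-6)

  # a small background stays below the 1% insignificance flag
  empty_small <- synthesize_trace(empty_traj, ch,
                                  background_rate_mg_l_h = bg_rate / 4)
  bg_small <- estimate_background(before = empty_small, after = empty_small,
                                  gross_slope_mg_l_h = fish_slope / (1 - f))
  expect_lt(bg_small$fraction, 0.01)
  expect_false(bg_small$significant)
})

test_that("QC flags follow the R2 and saturation rules and are monotone", {
  fits <- tibble::tibble(
    r2 = c(rep(0.99, 7), 0.9, 0.8, 0.94),
    end_sat_pct = c(rep(95, 9), 90))
  out <- qc_filter(fits)
  expect_equal(sum(out$qc_pass), 7)
  low_sat <- tibble::tibble(r2 = 0.99, end_sat_pct = 75)
  expect_false(qc_filter(low_sat)$qc_pass)
  # raising r2_min never increases the number of passing points
  set.seed(5)
  rand <- tibble::tibble(r2 = runif(200), end_sat_pct = runif(200, 60, 100))
  passes <- vapply(seq(0.05, 0.95, by = 0.05),
                   function(r) sum(qc_filter(rand, r2_min = r)$qc_pass),
                   numeric(1))
  expect_true(all(diff(passes) <= 0))
  expect_error(qc_filter(fits, r2_min = 1.2), "r2_min")
})
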