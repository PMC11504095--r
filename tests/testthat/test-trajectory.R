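test_that("constant trajectories are flat at the requested value", {
  tr <- make_trajectory(trajectory_spec("constant", list(value = 180), 60))
  expect_equal(nrow(tr), 61)
  expect_true(all(tr$mo2 == 180))
})

test_that("cosinor trajectory evaluates the closed form", {
  spec <- trajectory_spec(
    "cosinor",
    list(mesor = 90.5, amplitude = 16.9, acrophase_h = 13.2,
         period_h = 24, t0_clock_h = 0),
    duration_min = 1440)
  tr <- make_trajectory(spec, time_min = 13.2 * 60)
  expect_equal(tr$mo2, 90.5 + 16.9)  # peak value at the acrophase
  trough <- make_trajectory(spec, time_min = (13.2 + 12) * 60)
  expect_equal(trough$mo2, 90.5 - 16.9)
})

test_that("piecewise trajectories are continuous and match hand evaluation", {
  spec <- trajectory_spec(
    "piecewise_linear",
    list(start = 180, slopes = c(1.26, -0.72, -0.0184),
         breaks_min = c(72, 185)),
    duration_min = 360)
  tr <- make_trajectory(spec)
  expect_equal(tr$mo2[tr$time_min == 72], 180 + 1.26 * 72)
  expect_equal(tr$mo2[tr$time_min == 185], 180 + 1.26 * 72 - 0.72 * 113)
  # continuity: no jump larger than the largest slope times the step
  expect_true(all(abs(diff(tr$mo2)) <= 1.26 + 1e-12))
  # approach from both sides of each break agrees
  for (b in c(72, 185)) {
    lhs <- make_trajectory(spec, time_min = b - 1e-9)$mo2
    rhs <- make_trajectory(spec, time_min = b + 1e-9)$mo2
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
})

test_that("SDA tent wave rises to its peak fraction and returns to baseline", {
  spec <- trajectory_spec(
    "sda_wave",
    list(baseline = 100, peak_frac = 0.35, start_time_min = 0,
         peak_time_min = 180, end_time_min = 420),
    duration_min = 1440)
  tr <- make_trajectory(spec)
  expect_equal(tr$mo2[tr$time_min == 0], 100)
  expect_equal(tr$mo2[tr$time_min == 180], 135)
  expect_equal(max(tr$mo2), 135)
  expect_true(all(tr$mo2[tr$time_min >= 420] == 100))
})

test_that("temperature-ramp trajectory hits the configured maximum and rates", {
  p <- scenario_preset("temperature", noise_sd = 0)
  tr <- make_trajectory(p$trajectory)
  expect_equal(tr$mo2[tr$time_min == 0], 112)
  expect_equal(max(tr$mo2), 352)
  expect_equal(tr$time_min[which.max(tr$mo2)], 154)
  # rise of 1.9 units per min during the ramp = 19 per degC at 0.1 degC/min
  ramp <- tr[tr$time_min <= 90, ]
  expect_equal(unique(round(diff(ramp$mo2), 9)), 1.9)
  post <- tr[tr$time_min >= 154, ]
  expect_equal(unique(round(diff(post$mo2), 9)), -0.16)
})

test_that("invalid specifications are rejected", {
  expect_error(trajectory_spec("sawtooth", list(), 60), "kind")
  expect_error(trajectory_spec("cosinor", list(mesor = 1), 60), "Missing")
  expect_error(
    trajectory_spec("piecewise_linear",
                    list(start = 0, slopes = c(1, 2), breaks_min = c(80)),
                    60),
    "inside")
  expect_error(
    trajectory_spec("piecewise_linear",
                    list(start = 0, slopes = c(1, 2, 3),
                         breaks_min = c(30, 20)), 60),
    "increasing")
  expect_error(trajectory_spec("constant", list(value = 1), -5), "duration")
})

test_that("all scenario presets validate and carry their study parameters", {
  names <- c("daily_rhythm", "feeding", "acute_stress", "temperature",
             "anesthetic_control", "anesthetic_2pe", "anesthetic_clove",
             "anesthetic_ms222")
  for (nm in names) {
    p <- scenario_preset(nm)
    expect_s3_class(p, "scenario_preset")
    expect_s3_class(p$trajectory, "trajectory_spec")
    expect_gte(p$n_fish, 1)
    expect_true(p$background_fraction >= 0 && p$background_fraction < 0.05)
  }
  expect_equal(scenario_preset("daily_rhythm")$trajectory$params$mesor, 90.5)
  expect_equal(scenario_preset("acute_stress")$trajectory$params$slopes,
               c(1.26, -0.72, -0.0184))
  expect_equal(scenario_preset("anesthetic_2pe")$trajectory$params$increase_rate,
               8.34)
  expect_error(scenario_preset("nope"), "Unknown")
  expect_error(scenario_preset("feeding", background_fraction = 0.2), "0.05")
})
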