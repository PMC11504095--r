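test_that("identical fed and fasted series give zero SDA everywhere", {
  p <- sda_pair(n_fish = 3)
  s <- sda_metrics(p$fasted, p$fasted)
  expect_true(all(s$table$pct_change == 0))
  expect_true(all(s$table$p_value == 1))
  expect_null(s$significant_window_min)
})

test_that("the noiseless postprandial wave peaks at +35% 180 min after feeding", {
  p <- sda_pair(n_fish = 4)
  s <- sda_metrics(p$fed, p$fasted)
  expect_equal(s$peak_pct, 35, tolerance = 1e-9)
  expect_equal(s$peak_time_min, 180)
  # the wave is over by 420 min and non-significance is sustained after it
  expect_equal(s$return_to_baseline_min, 420)
  expect_error(sda_metrics(p$fed,
                           dplyr::mutate(p$fasted,
                                         fish_id = paste0(fish_id, "x"))),
               "paired|share")
})

test_that("per-bin paired tests match the hand-computed t distribution", {
  # three fish, one bin, differences (1, 2, 3): t = 2 sqrt(3), df 2
  fed <- tibble::tibble(fish_id = c("a", "b", "c"), time_min = 0,
                        mo2 = c(101, 102, 103))
  fasted <- tibble::tibble(fish_id = c("a", "b", "c"), time_min = 0,
                           mo2 = c(100, 100, 100))
  s <- sda_metrics(fed, fasted)
  expect_equal(s$table$p_value, 2 * pt(-2 * sqrt(3), df = 2),
               tolerance = 1e-12)
})

test_that("SDA percent change is invariant to common rescaling", {
  p <- sda_pair(n_fish = 3, noise_sd = 1, seed = 4)
  s1 <- sda_metrics(p$fed, p$fasted)
  s2 <- sda_metrics(dplyr::mutate(p$fed, mo2 = mo2 * 3.7),
                    dplyr::mutate(p$fasted, mo2 = mo2 * 3.7))
  expect_equal(s1$table$pct_change, s2$table$pct_change, tolerance = 1e-9)
})

test_that("Q10 obeys its closed-form identities", {
  expect_equal(q10(100, 100, 21, 30), 1)
  expect_equal(q10(112, 278, 21, 30), (278 / 112)^(10 / 9), tolerance = 1e-12)
  # homogeneity: Q10(r, k r, T, T + 10) = k
  for (k in c(0.5, 2, 3.06)) expect_equal(q10(80, k * 80, 20, 30), k)
  expect_equal(q10(100, 2 * 250, 20, 30) / q10(100, 250, 20, 30), 2)
  expect_error(q10(0, 10, 20, 30), "positive")
  expect_error(q10(10, 10, 25, 25), "differ")
})

test_that("per-fish Q10 summarises with mean and SEM", {
  tab <- tibble::tibble(fish_id = c("a", "b", "c"),
                        r1 = c(100, 110, 120), r2 = c(250, 260, 300),
                        t1_c = 21, t2_c = 30)
  res <- q10_per_fish(tab)
  expect_equal(res$per_fish$q10, (tab$r2 / tab$r1)^(10 / 9))
  expect_equal(res$mean, mean(res$per_fish$q10))
  expect_equal(res$sem, sd(res$per_fish$q10) / sqrt(3))
})

test_that("temperature sensitivity is the per-degree regression slope", {
  d3 <- tibble::tibble(time_min = 0:2, temp_c = c(21, 22, 23),
                       mo2 = c(100, 102, 104))
  expect_equal(temperature_sensitivity(d3)$slope_per_degc, 2)
  flat <- tibble::tibble(time_min = 0:10, temp_c = 21:31, mo2 = 50)
  expect_equal(temperature_sensitivity(flat)$slope_per_degc, 0)
  expect_error(temperature_sensitivity(
    tibble::tibble(time_min = 0:5, temp_c = 21, mo2 = rnorm(6))), "constant")
  # noiseless ramp preset: 19 units per degree over any ramp subwindow
  tr <- make_trajectory(scenario_preset("temperature", noise_sd = 0)$trajectory)
  tr$temp_c <- temperature_profile(tr$time_min, 21, 30, 0.1)
  for (w in list(c(0, 90), c(10, 80), c(30, 60))) {
    expect_equal(temperature_sensitivity(tr, window = w)$slope_per_degc, 19,
                 tolerance = 1e-9)
  }
})

test_that("anesthetic metrics are read off a noiseless rise-and-fall profile", {
  tr <- make_trajectory(trajectory_spec(
    "piecewise_linear", list(start = 100, slopes = c(2, -1, 0),
                             breaks_min = c(30, 90)),
    duration_min = 180, dt_min = 2))
  d <- dplyr::mutate(tr, fish_id = "f1")
  prof <- anesthetic_profile(d)
  pf <- prof$per_fish
  expect_equal(pf$increase_rate, 2, tolerance = 0.02)
  expect_equal(pf$time_to_maximum, 30, tolerance = 2)
  expect_equal(pf$maximum, 160, tolerance = 1)
  expect_equal(pf$stabilization_time, 90, tolerance = 2)
  expect_equal(pf$base, 100, tolerance = 0.5)
  expect_equal(pf$raw_maximum, 160)
  # a flat profile has no rise: rates near zero, time-to-maximum 0
  flat <- tibble::tibble(fish_id = "f1", time_min = seq(0, 180, 2), mo2 = 120)
  pflat <- suppressWarnings(anesthetic_profile(flat))
  expect_equal(pflat$per_fish$increase_rate, 0, tolerance = 1e-9)
  expect_equal(pflat$per_fish$decrease_rate, 0, tolerance = 1e-9)
  expect_equal(pflat$per_fish$time_to_maximum, 0)
  expect_equal(pflat$per_fish$maximum, 120, tolerance = 1e-9)
})

test_that("the 2-phenoxyethanol preset returns its generating rise parameters", {
  traj <- scenario_preset("anesthetic_2pe", noise_sd = 0)$trajectory
  d <- dplyr::mutate(make_trajectory(traj), fish_id = "f1")
  prof <- anesthetic_profile(d)
  expect_equal(prof$per_fish$increase_rate, 8.34, tolerance = 0.01)
  expect_equal(prof$per_fish$time_to_maximum, 27, tolerance = 1)
  expect_equal(prof$per_fish$maximum, 415, tolerance = 1)
})

test_that("group metric tests flag only truly shifted groups", {
  set.seed(61)
  mk <- function(group, inc_shift = 0) {
    tibble::tibble(group = group,
                   fish_id = paste0(group, 1:10),
                   increase_rate = rnorm(10, 1 + inc_shift, 0.5),
                   time_to_maximum = rnorm(10, 38, 5))
  }
  null_prof <- dplyr::bind_rows(mk("a"), mk("b"), mk("c"))
  null_out <- group_metric_tests(null_prof,
                                 metrics = c("increase_rate",
                                             "time_to_maximum"))
  expect_true(all(null_out$p_adjusted > 0.05))
  shift_prof <- dplyr::bind_rows(mk("a"), mk("b"), mk("c"),
                                 mk("d", inc_shift = 4))
  out <- group_metric_tests(shift_prof, metrics = "increase_rate")
  has_d <- grepl("d", out$pair)
  expect_true(all(out$p_adjusted[has_d] < 0.01))
  expect_true(all(out$p_adjusted[!has_d] > 0.05))
  two <- group_metric_tests(dplyr::bind_rows(mk("a"), mk("b")),
                            metrics = "increase_rate")
  expect_equal(two$p_adjusted, two$p_raw)
  expect_error(group_metric_tests(mk("a")), "2 groups")
})
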