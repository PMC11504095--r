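# Shared fixtures built in code.

# Independent OLS oracle: explicit normal equations, no lm/cov shortcuts.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# Minimal hand-built 3-cycle trace (1 Hz, flush 3 s / wait 1 s / measure 4 s).
toy_trace <- function(n_cycles = 3, measure_slope_per_s = -0.001) {
  cyc <- 8
  time_s <- seq_len(n_cycles * cyc) - 1
  within <- time_s %% cyc
  phase <- ifelse(within < 3, "flush", ifelse(within < 4, "wait", "measure"))
  o2 <- 8.8 + ifelse(within >= 3, (within - 2) * measure_slope_per_s, 0)
  tibble::tibble(
    time_s = time_s,
    chamber_id = "toy",
    o2_mg_per_l = o2,
    o2_sat_pct = concentration_to_sat(o2, 21.5),
    temp_c = 21.5,
    phase = phase,
    cycle_index = time_s %/% cyc + 1L)
}

# Paired fed/fasted MO2 series for several identical fish on a 10-min grid.
sda_pair <- function(n_fish = 4, baseline = 90.5, noise_sd = 0, seed = 1) {
  traj <- trajectory_spec(
    "sda_wave",
    list(baseline = baseline, peak_frac = 0.35, start_time_min = 0,
         peak_time_min = 180, end_time_min = 420),
    duration_min = 1440, dt_min = 10)
  base <- make_trajectory(traj)
  set.seed(seed)
  fed <- purrr::map_dfr(seq_len(n_fish), function(i) {
    dplyr::mutate(base, fish_id = sprintf("f%02d", i),
                  mo2 = mo2 + rnorm(dplyr::n(), 0, noise_sd))
  })
  fasted <- purrr::map_dfr(seq_len(n_fish), function(i) {
    tibble::tibble(fish_id = sprintf("f%02d", i),
                   time_min = base$time_min,
                   mo2 = baseline + rnorm(nrow(base), 0, noise_sd))
  })
  list(fed = fed, fasted = fasted)
}
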