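#' Synthesize a raw intermittent-flow oxygen trace
#'
#' Generates a per-second chamber O2 record with flush/wait/measure cycle
#' structure from a ground-truth MO2 trajectory. During each closed (wait +
#' measure) phase the concentration declines linearly with slope
#' `-MO2 * M / V_eff` (mg O2 L-1 h-1), where MO2 is the trajectory value at the
#' midpoint of that cycle's measure phase, M the fish mass and V_eff the
#' chamber volume minus the fish volume. Microbial background respiration adds
#' a further decline so that it makes up `background_fraction` of the gross
#' slope; optode noise is additive Gaussian on the concentration. During the
#' flush the concentration relaxes exponentially back to air saturation with
#' time constant `V_eff / flow`. The saturation column is derived from the
#' freshwater solubility function at the (constant or ramped) water
#' temperature.
#'
#' @param trajectory A [trajectory_spec()] (evaluated exactly at measure-phase
#'   midpoints) or a data frame with `time_min` and `mo2` columns (linearly
#'   interpolated).
#' @param chamber A [chamber_spec()].
#' @param cycle A [cycle_config()].
#' @param duration_min Trace duration in minutes; defaults to the trajectory's
#'   span. Trailing seconds that do not complete a cycle are dropped.
#' @param noise_sd Gaussian optode noise SD on concentration, mg O2 L-1.
#' @param background_fraction Microbial respiration as a fraction of the gross
#'   measured slope, in `[0, 0.05)`.
#' @param background_rate_mg_l_h Absolute additional decline rate (mg O2 L-1
#'   h-1), used to build empty-chamber background traces.
#' @param temp_start_c,temp_end_c,temp_rate_c_per_min Water-temperature
#'   profile; see [temperature_profile()].
#' @param flow_l_h Flush pump flow for the relaxation time constant.
#' @param chamber_id Chamber label stored in the trace.
#' @param seed Integer seed; required whenever `noise_sd > 0`.
#'
#' @return A tibble (an O2 trace) with columns `time_s`, `chamber_id`,
#'   `o2_mg_per_l`, `o2_sat_pct`, `temp_c`, `phase` (flush/wait/measure) and
#'   `cycle_index`.
#' @export
#' @examples
#' traj <- trajectory_spec("constant", list(value = 180), 30)
#' tr <- synthesize_trace(traj, chamber_spec(fish_mass_kg = 0.020))
#' head(tr)
synthesize_trace <- function(trajectory, chamber, cycle = cycle_config(),
                             duration_min = NULL, noise_sd = 0,
                             background_fraction = 0,
                             background_rate_mg_l_h = 0,
                             temp_start_c = 21.5, temp_end_c = temp_start_c,
                             temp_rate_c_per_min = 0.1, flow_l_h = 300,
                             chamber_id = "ch1", seed = NULL) {
  stopifnot(inherits(chamber, "chamber_spec"), inherits(cycle, "cycle_config"))
  if (background_fraction < 0 || background_fraction >= 0.05) {
    abort("`background_fraction` must be in [0, 0.05).")
  }
  if (noise_sd > 0 && is.null(seed)) {
    abort("`seed` is required when `noise_sd` > 0.")
  }
  if (is.null(duration_min)) {
    duration_min <- if (inherits(trajectory, "trajectory_spec")) {
      trajectory$duration_min
    } else {
      max(trajectory$time_min)
    }
  }
  mo2_at <- function(t_min) {
    if (inherits(trajectory, "trajectory_spec")) {
      make_trajectory(trajectory, time_min = t_min)$mo2
    } else {
      stats::approx(trajectory$time_min, trajectory$mo2, xout = t_min,
                    rule = 2)$y
    }
  }

  v_eff <- chamber$volume_l - chamber$fish_volume_l
  cyc_s <- cycle_length_s(cycle)
  n_cycles <- floor(duration_min * 60 / cyc_s)
  if (n_cycles < 1) abort("Duration shorter than one cycle.")
  tau_s <- v_eff / flow_l_h * 3600

  time_s <- seq_len(n_cycles * cyc_s) - 1
  temp_c <- temperature_profile(time_s / 60, temp_start_c, temp_end_c,
                                temp_rate_c_per_min)
  sat_conc <- o2_solubility(temp_c)
  within <- time_s %% cyc_s
  phase <- ifelse(within < cycle$flush_s, "flush",
                  ifelse(within < cycle$flush_s + cycle$wait_s, "wait",
                         "measure"))
  cycle_index <- time_s %/% cyc_s + 1L

  # gross closed-phase slope (mg/L per hour) per cycle, from MO2 at the
  # measure-phase midpoint; background is a fraction of the gross slope
  mid_s <- (cycle_index - 1L) * cyc_s + cycle$flush_s + cycle$wait_s +
    cycle$measure_s / 2
  mo2_mid <- mo2_at(unique(mid_s) / 60)
  fish_slope <- mo2_mid * chamber$fish_mass_kg / v_eff
  gross_slope <- fish_slope / (1 - background_fraction) + background_rate_mg_l_h

  closed_start <- cycle$flush_s  # seconds within cycle where decline begins
  o2 <- numeric(length(time_s))
  c_end_prev <- sat_conc[1]
  for (k in seq_len(n_cycles)) {
    idx <- ((k - 1L) * cyc_s + 1L):(k * cyc_s)
    w <- within[idx]
    sat_k <- sat_conc[idx]
    fl <- w < closed_start
    # exponential approach to saturation during the flush
    c_fl <- sat_k[fl] + (c_end_prev - sat_k[fl]) * exp(-(w[fl] + 1) / tau_s)
    c_start <- if (any(fl)) c_fl[sum(fl)] else c_end_prev
    c_cl <- c_start - gross_slope[k] / 3600 * (w[!fl] - closed_start + 1)
    o2[idx] <- c(c_fl, c_cl)
    c_end_prev <- o2[idx[length(idx)]]
    if (any(o2[idx] < 0)) {
      abort("Trajectory drives oxygen concentration below zero; shorten the measure phase or lower MO2.")
    }
  }
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    o2 <- o2 + rnorm(length(o2), 0, noise_sd)
  }

  tibble::tibble(
    time_s = time_s,
    chamber_id = chamber_id,
    o2_mg_per_l = o2,
    o2_sat_pct = concentration_to_sat(o2, temp_c),
    temp_c = temp_c,
    phase = phase,
    cycle_index = cycle_index)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Synthesize a locomotor-activity series
#'
#' Sinusoidal 24 h activity intensity sampled on a fixed bin grid (10 min by
#' default, matching infrared-photocell actimetry). `mode = "intensity"`
#' returns the noiseless rate; `mode = "poisson"` draws counts with that
#' intensity, which requires `amplitude <= mesor` so the rate is nonnegative.
#'
#' @param mesor Mean level, counts per bin.
#' @param amplitude Mesor-to-peak distance, counts per bin.
#' @param acrophase_h Clock hour of peak activity.
#' @param n_days Number of days recorded.
#' @param mode `"intensity"` or `"poisson"`.
#' @param seed Integer seed, required for `"poisson"`.
#' @param bin_min Bin width in minutes (default 10).
#' @param t0_clock_h Clock hour of the first bin start (default 0, midnight).
#'
#' @return A tibble (an activity series) with columns `day`, `clock_h` (bin
#'   start, hours since midnight), `time_h` (hours since recording start) and
#'   `counts`.
#' @export
#' @examples
#' act <- synthesize_activity(27.83, 21.5, 12.7, n_days = 9)
#' head(act)
synthesize_activity <- function(mesor, amplitude, acrophase_h, n_days,
                                mode = c("intensity", "poisson"), seed = NULL,
                                bin_min = 10, t0_clock_h = 0) {
  mode <- match.arg(mode)
  if (mode == "poisson") {
    if (amplitude > mesor) {
      abort("Poisson mode needs `amplitude <= mesor` (nonnegative rate).")
    }
    if (is.null(seed)) abort("`seed` is required for poisson mode.")
  }
  bins_per_day <- 24 * 60 / bin_min
  if (bins_per_day != round(bins_per_day)) {
    abort("`bin_min` must divide 24 h.")
  }
  n <- n_days * bins_per_day
  time_h <- (seq_len(n) - 1) * bin_min / 60
  clock_h <- (t0_clock_h + time_h) %% 24
  rate <- mesor + amplitude * cos(2 * pi / 24 * (clock_h - acrophase_h))
  counts <- if (mode == "intensity") {
    rate
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    rpois(n, rate)
  }
  tibble::tibble(
    day = rep(seq_len(n_days), each = bins_per_day),
    clock_h = clock_h,
    time_h = time_h,
    counts = counts)
}

#' Simulate a full multi-fish scenario
#'
#' Draws per-fish masses, synthesizes one raw O2 trace per fish from the
#' scenario preset's ground-truth trajectory, and returns everything needed by
#' the extraction and analysis stages. Identical seeds give identical output.
#'
#' @param preset A [scenario_preset()].
#' @param seed Integer seed controlling mass draws and optode noise.
#'
#' @return A list with `preset`, `fish` (tibble of `fish_id`, `mass_kg`) and
#'   `traces` (named list of O2-trace tibbles, one per fish).
#' @export
simulate_scenario <- function(preset, seed = 1) {
  stopifnot(inherits(preset, "scenario_preset"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  mass_g <- if (preset$noise_sd > 0) {
    pmax(rnorm(preset$n_fish, preset$mass_g_mean, preset$mass_g_sd), 5)
  } else {
    rep(preset$mass_g_mean, preset$n_fish)
  }
  fish <- tibble::tibble(
    fish_id = sprintf("fish%02d", seq_len(preset$n_fish)),
    mass_kg = mass_g / 1000)
  traces <- purrr::map2(fish$fish_id, fish$mass_kg, function(id, m) {
    synthesize_trace(
      preset$trajectory,
      chamber_spec(preset$chamber_volume_l, fish_mass_kg = m),
      cycle = preset$cycle,
      noise_sd = preset$noise_sd,
      background_fraction = preset$background_fraction,
      temp_start_c = preset$temp_start_c,
      temp_end_c = preset$temp_end_c,
      temp_rate_c_per_min = preset$temp_rate_c_per_min,
      chamber_id = id,
      seed = if (preset$noise_sd > 0) seed + match(id, fish$fish_id) else NULL)
  })
  names(traces) <- fish$fish_id
  list(preset = preset, fish = fish, traces = traces)
}
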