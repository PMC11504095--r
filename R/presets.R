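#' Chamber and cycle configuration
#'
#' `chamber_spec()` records the respirometer geometry needed by the MO2
#' equation MO2 = V * M^-1 * d[O2]/dt: `volume_l` is the empty respirometer
#' volume and the effective water volume V is `volume_l - fish_volume_l`.
#' Fish volume defaults to body mass at a density of 1 g per mL.
#' `cycle_config()` records the intermittent-flow cycle timing: an open-system
#' flush, then a closed system with a short wait and a measurement period.
#'
#' @param volume_l Respirometer volume in litres (default 0.36229, a 362.29 mL
#'   chamber).
#' @param fish_mass_kg Fish body mass in kg.
#' @param fish_volume_l Fish body volume in litres; defaults to
#'   `fish_mass_kg` litres per kilogram (density 1 g per mL).
#' @return `chamber_spec()`: an object of class `chamber_spec`;
#'   `cycle_config()`: an object of class `cycle_config`.
#' @export
#' @examples
#' chamber_spec(fish_mass_kg = 0.020)
chamber_spec <- function(volume_l = 0.36229, fish_mass_kg,
                         fish_volume_l = fish_mass_kg) {
  if (!is.numeric(fish_mass_kg) || fish_mass_kg <= 0) {
    abort("`fish_mass_kg` must be > 0.")
  }
  if (fish_volume_l < 0 || volume_l <= fish_volume_l) {
    abort("`volume_l` must exceed `fish_volume_l`, and `fish_volume_l` >= 0.")
  }
  structure(list(volume_l = volume_l, fish_mass_kg = fish_mass_kg,
                 fish_volume_l = fish_volume_l),
            class = "chamber_spec")
}

#' @rdname chamber_spec
#' @param flush_s,wait_s,measure_s Phase durations in seconds. Defaults follow
#'   common practice for small cyprinids (flush 75-79 s, wait 1-10 s, measure
#'   75-150 s) but any positive values are accepted.
#' @export
cycle_config <- function(flush_s = 77, wait_s = 5, measure_s = 78) {
  if (any(c(flush_s, wait_s, measure_s) <= 0)) {
    abort("All cycle phase durations must be > 0 seconds.")
  }
  structure(list(flush_s = flush_s, wait_s = wait_s, measure_s = measure_s),
            class = "cycle_config")
}

cycle_length_s <- function(config) {
  config$flush_s + config$wait_s + config$measure_s
}

#' Scenario presets for the five respirometry experiments
#'
#' Returns the generative parameters of one of the study scenarios, each a
#' bundle of a ground-truth MO2 [trajectory_spec()], fish-group properties,
#' chamber/cycle configuration and noise levels:
#'
#' \describe{
#'   \item{daily_rhythm}{48 h in the chamber; MO2 follows a 24 h cosinor with
#'     mesor 90.5, amplitude 16.9 mg O2 kg-1 h-1 and acrophase 13.2 h (13:12),
#'     the fitted second-day rhythm of fasted goldfish; mean mass 17.1 g.}
#'   \item{feeding}{24 h post-meal; the fed trajectory is a flat fasted
#'     baseline carrying a postprandial wave peaking at +35% 180 min after
#'     feeding and returning to baseline at 420 min; mean mass 24.5 g.}
#'   \item{acute_stress}{6 h after a 5-min chase; three-segment piecewise
#'     course from a basal 180 mg O2 kg-1 h-1: +1.26 units min-1 to 72 min,
#'     -0.72 to 185 min, then -0.0184 (effectively stable); mean mass 25.2 g.}
#'   \item{temperature}{0.1 degC min-1 ramp from 21 to 30 degC (90 min) then
#'     5 h at 30 degC; MO2 rises at 19 units per degC during the ramp from a
#'     basal 112, keeps rising to a maximum of 352 at minute 154, then
#'     declines at 0.16 units min-1; mean mass 20.9 g.}
#'   \item{anesthetic_control, anesthetic_2pe, anesthetic_clove,
#'     anesthetic_ms222}{4 h recovery profiles: linear rise to a maximum, fall,
#'     then a stable base, parameterised per group by the fitted maximum,
#'     increase rate, time to maximum, decrease rate and stabilization time;
#'     mean mass 22.2 g.}
#' }
#'
#' @param name One of `"daily_rhythm"`, `"feeding"`, `"acute_stress"`,
#'   `"temperature"`, `"anesthetic_control"`, `"anesthetic_2pe"`,
#'   `"anesthetic_clove"`, `"anesthetic_ms222"`.
#' @param n_fish Number of fish; defaults to the scenario's group size.
#' @param noise_sd Optode noise standard deviation, mg O2 L-1 (default 0.01).
#'   Set 0 for noiseless ground truth.
#' @param background_fraction Microbial background respiration as a fraction of
#'   gross oxygen uptake, in `[0, 0.05)`; the study systems kept it below 0.01.
#' @param fasted_baseline For `feeding`: the flat fasted MO2 level
#'   (mg O2 kg-1 h-1) shared by both conditions.
#'
#' @return An object of class `scenario_preset`: a list with elements `name`,
#'   `trajectory` (a [trajectory_spec()]), `n_fish`, `mass_g_mean`,
#'   `mass_g_sd`, `chamber_volume_l`, `cycle` (a [cycle_config()]), `noise_sd`,
#'   `background_fraction`, `temp_start_c`, `temp_end_c`, `temp_rate_c_per_min`
#'   and `t0_clock_h` (clock hour at trajectory time 0).
#' @export
#' @examples
#' scenario_preset("acute_stress", noise_sd = 0)
scenario_preset <- function(name, n_fish = NULL, noise_sd = 0.01,
                            background_fraction = 0.005,
                            fasted_baseline = 90.5) {
  names_ok <- c("daily_rhythm", "feeding", "acute_stress", "temperature",
                "anesthetic_control", "anesthetic_2pe", "anesthetic_clove",
                "anesthetic_ms222")
  if (!name %in% names_ok) {
    abort(paste0("Unknown scenario '", name, "'."))
  }
  if (background_fraction < 0 || background_fraction >= 0.05) {
    abort("`background_fraction` must be in [0, 0.05).")
  }
  an_profile <- function(max, inc, tmax, dec, stab) {
    trajectory_spec("anesthetic_profile",
                    list(start = max - inc * tmax, increase_rate = inc,
                         time_to_max_min = tmax, decrease_rate = dec,
                         stabilization_min = stab),
                    duration_min = 240)
  }
  base <- switch(name,
    daily_rhythm = list(
      trajectory = trajectory_spec(
        "cosinor",
        list(mesor = 90.5, amplitude = 16.9, acrophase_h = 13.2,
             period_h = 24, t0_clock_h = 10),
        duration_min = 2880),
      n_fish = 8, mass_g_mean = 17.1, mass_g_sd = 3.1, t0_clock_h = 10),
    feeding = list(
      trajectory = trajectory_spec(
        "sda_wave",
        list(baseline = fasted_baseline, peak_frac = 0.35,
             start_time_min = 0, peak_time_min = 180, end_time_min = 420),
        duration_min = 1440, dt_min = 10),
      n_fish = 8, mass_g_mean = 24.5, mass_g_sd = 5.4, t0_clock_h = 10),
    acute_stress = list(
      trajectory = trajectory_spec(
        "piecewise_linear",
        list(start = 180, slopes = c(1.26, -0.72, -0.0184),
             breaks_min = c(72, 185)),
        duration_min = 360),
      n_fish = 8, mass_g_mean = 25.2, mass_g_sd = 1.9, t0_clock_h = 10.5),
    temperature = list(
      trajectory = trajectory_spec(
        "temperature_ramp",
        list(basal = 112, per_degree = 19, ramp_rate_c_per_min = 0.1,
             t_start_c = 21, t_end_c = 30, max_value = 352,
             max_time_min = 154, decline_per_min = 0.16),
        duration_min = 390),
      n_fish = 8, mass_g_mean = 20.9, mass_g_sd = 0.9, t0_clock_h = 10.5,
      temp_start_c = 21, temp_end_c = 30, temp_rate_c_per_min = 0.1),
    anesthetic_control = list(
      trajectory = an_profile(353, 0.87, 37.5, 0.025, 74.3),
      n_fish = 10, mass_g_mean = 22.2, mass_g_sd = 6.8, t0_clock_h = 10.5),
    anesthetic_2pe = list(
      trajectory = an_profile(415, 8.34, 27.0, 0.004, 139.6),
      n_fish = 10, mass_g_mean = 22.2, mass_g_sd = 6.8, t0_clock_h = 10.5),
    anesthetic_clove = list(
      trajectory = an_profile(359, 3.06, 38.6, 0.007, 118.5),
      n_fish = 10, mass_g_mean = 22.2, mass_g_sd = 6.8, t0_clock_h = 10.5),
    anesthetic_ms222 = list(
      trajectory = an_profile(355, 0.99, 52.2, 0.042, 93.9),
      n_fish = 10, mass_g_mean = 22.2, mass_g_sd = 6.8, t0_clock_h = 10.5))

  preset <- utils::modifyList(
    list(name = name, chamber_volume_l = 0.36229, cycle = cycle_config(),
         noise_sd = noise_sd, background_fraction = background_fraction,
         temp_start_c = 21.5, temp_end_c = 21.5, temp_rate_c_per_min = 0.1),
    base)
  if (!is.null(n_fish)) preset$n_fish <- n_fish
  if (preset$n_fish < 1) abort("`n_fish` must be >= 1.")
  structure(preset, class = "scenario_preset")
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat("<scenario_preset> ", x$name, "\n", sep = "")
  cat("  trajectory: ", x$trajectory$kind, " over ",
      x$trajectory$duration_min, " min\n", sep = "")
  cat("  fish: n = ", x$n_fish, ", mass ", x$mass_g_mean, " +/- ",
      x$mass_g_sd, " g\n", sep = "")
  cat("  noise_sd = ", x$noise_sd, " mg/L, background = ",
      x$background_fraction, "\n", sep = "")
  invisible(x)
}
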