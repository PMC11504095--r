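#' Configure an end-to-end pipeline run
#'
#' Bundles everything a full simulate-extract-analyse run needs: the scenario,
#' the mandatory seed, generator overrides and quality thresholds. Rerunning
#' [run_pipeline()] with an identical configuration gives identical output.
#'
#' @param scenario A [scenario_preset()] name.
#' @param seed Integer seed (mandatory; drives every stochastic step).
#' @param n_fish,noise_sd,background_fraction Generator overrides passed to
#'   [scenario_preset()].
#' @param r2_min,sat_min_pct Quality thresholds, see [qc_filter()].
#' @param window_min Optional length-2 analysis window (minutes from
#'   recording start) applied before the scenario analysis; the daily-rhythm
#'   scenario defaults to the second day, `c(1440, 2880)`.
#' @param out_dir Optional directory; when given, intermediate CSVs, a JSON
#'   report and a log file are written there.
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario, seed, n_fish = NULL, noise_sd = 0.01,
                       background_fraction = 0.005, r2_min = 0.95,
                       sat_min_pct = 80, window_min = NULL, out_dir = NULL) {
  if (missing(seed) || !is.numeric(seed)) {
    abort("`seed` is mandatory for a pipeline run.")
  }
  structure(list(scenario = scenario, seed = as.integer(seed),
                 n_fish = n_fish, noise_sd = noise_sd,
                 background_fraction = background_fraction,
                 r2_min = r2_min, sat_min_pct = sat_min_pct,
                 window_min = window_min, out_dir = out_dir),
            class = "run_config")
}

#' Run the full respirometry pipeline for a scenario
#'
#' Simulates the scenario's raw chamber traces, extracts quality-filtered MO2
#' series per fish, and runs the scenario-appropriate analysis: cosinor
#' rhythm for `daily_rhythm`, SDA metrics for `feeding` (a paired fasted run
#' is simulated alongside), segmented regression with stabilization for
#' `acute_stress`, temperature sensitivity, post-ramp breakpoint and Q10 for
#' `temperature`, and recovery-profile metrics for the anesthetic scenarios.
#' When `config$out_dir` is set, the MO2 series, analysis tables, a JSON
#' report of headline numbers and a log of QC counts are written there.
#'
#' @param config A [run_config()].
#'
#' @return A list (report bundle): `config`, `mo2` (pooled MO2 tibble),
#'   `qc` (per-fish rejected counts), `analysis` (scenario-specific objects)
#'   and `report` (named list of headline numbers).
#' @export
#' @examples
#' \donttest{
#' run_pipeline(run_config("acute_stress", seed = 1, noise_sd = 0))
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  preset <- scenario_preset(config$scenario, n_fish = config$n_fish,
                            noise_sd = config$noise_sd,
                            background_fraction = config$background_fraction)
  sim <- simulate_scenario(preset, seed = config$seed)
  mo2 <- extract_scenario_mo2(sim, config)
  qc <- mo2 |>
    dplyr::group_by(.data$fish_id) |>
    dplyr::summarise(n = dplyr::n(), n_rejected = sum(!.data$qc_pass),
                     .groups = "drop")

  window <- config$window_min %||%
    (if (config$scenario == "daily_rhythm") c(1440, 2880) else NULL)
  pooled <- mo2 |> dplyr::filter(.data$qc_pass)
  if (!is.null(window)) {
    pooled <- dplyr::filter(pooled, .data$time_min >= window[1],
                            .data$time_min <= window[2])
  }

  analysis <- list()
  report <- list(scenario = config$scenario, seed = config$seed,
                 n_fish = preset$n_fish,
                 n_points = nrow(mo2), n_rejected = sum(!mo2$qc_pass))

  if (config$scenario == "daily_rhythm") {
    pooled$clock_h <- preset$t0_clock_h + pooled$time_min / 60
    fit <- fit_cosinor(pooled, clock_h, mo2, period_h = 24)
    analysis$cosinor <- fit
    report <- c(report, list(
      mesor = fit$mesor, amplitude = fit$amplitude,
      acrophase_h = fit$acrophase_h, p_zero_amplitude = fit$p_zero_amplitude))
  } else if (config$scenario == "feeding") {
    fasted_preset <- preset
    fasted_preset$trajectory <- trajectory_spec(
      "constant", list(value = preset$trajectory$params$baseline),
      duration_min = preset$trajectory$duration_min)
    fasted_sim <- simulate_scenario(fasted_preset, seed = config$seed)
    fasted_mo2 <- extract_scenario_mo2(fasted_sim, config)
    sda <- sda_metrics(pooled, dplyr::filter(fasted_mo2, .data$qc_pass))
    analysis$sda <- sda
    analysis$fasted_mo2 <- fasted_mo2
    report <- c(report, list(
      peak_pct = sda$peak_pct, peak_time_min = sda$peak_time_min,
      return_to_baseline_min = sda$return_to_baseline_min))
  } else if (config$scenario == "acute_stress") {
    fit <- fit_segmented(pooled, time_min, mo2, n_breakpoints = 2)
    analysis$segmented <- fit
    stab <- stabilization_time(fit)
    report <- c(report, list(
      breakpoints_min = fit$breakpoints_min,
      segment_slopes = fit$segment_slopes,
      stabilization_min = stab,
      basal_mo2 = mean(pooled$mo2[pooled$time_min >= stab])))
  } else if (config$scenario == "temperature") {
    ramp_end <- (preset$temp_end_c - preset$temp_start_c) /
      preset$temp_rate_c_per_min
    sens <- temperature_sensitivity(pooled, window = c(0, ramp_end))
    post <- dplyr::filter(pooled, .data$time_min >= ramp_end)
    seg <- fit_segmented(post, time_min, mo2, n_breakpoints = 1)
    q10_tab <- pooled |>
      dplyr::group_by(.data$fish_id) |>
      dplyr::summarise(
        r1 = mean(.data$mo2[.data$time_min <= 10]),
        r2 = mean(.data$mo2[.data$time_min >=
                              max(.data$time_min) - 30]),
        .groups = "drop") |>
      dplyr::mutate(t1_c = preset$temp_start_c, t2_c = preset$temp_end_c)
    q10_res <- q10_per_fish(q10_tab)
    analysis$sensitivity <- sens
    analysis$post_ramp_segmented <- seg
    analysis$q10 <- q10_res
    report <- c(report, list(
      slope_per_degc = sens$slope_per_degc,
      peak_time_min = seg$breakpoints_min[1],
      q10_mean = q10_res$mean, q10_sem = q10_res$sem))
  } else {  # anesthetic groups
    prof <- anesthetic_profile(pooled)
    analysis$profile <- prof
    report <- c(report, as.list(setNames(prof$summary$mean,
                                         paste0(prof$summary$metric,
                                                "_mean"))))
  }

  bundle <- list(config = config, mo2 = mo2, qc = qc,
                 analysis = analysis, report = report)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

extract_scenario_mo2 <- function(sim, config) {
  preset <- sim$preset
  purrr::map2_dfr(sim$traces, sim$fish$mass_kg, function(tr, m) {
    extract_mo2(tr, chamber_spec(preset$chamber_volume_l, fish_mass_kg = m),
                r2_min = config$r2_min, sat_min_pct = config$sat_min_pct)
  })
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_mo2(bundle$mo2, file.path(out_dir, "mo2.csv"))
  readr::write_csv(bundle$qc, file.path(out_dir, "qc.csv"))
  jsonlite::write_json(bundle$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(
    paste0("scenario: ", bundle$config$scenario),
    paste0("seed: ", bundle$config$seed),
    paste0("points: ", nrow(bundle$mo2)),
    paste0("qc rejected: ", sum(!bundle$mo2$qc_pass)),
    sprintf("fish %s: %d points, %d rejected",
            bundle$qc$fish_id, bundle$qc$n, bundle$qc$n_rejected))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
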