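#' Extract closed-phase measurement windows from a raw trace
#'
#' Splits an intermittent-flow O2 trace into its per-cycle measure-phase
#' windows (the only samples used for slope fitting). Windows are returned in
#' cycle order and are non-overlapping; cycles without any measure-phase
#' samples are skipped with a warning.
#'
#' @param trace An O2-trace tibble as produced by [synthesize_trace()] or
#'   [read_trace()]: columns `time_s`, `o2_mg_per_l`, `o2_sat_pct`, `phase`,
#'   `cycle_index` (and optionally `temp_c`, `chamber_id`).
#'
#' @return A tibble with one row per cycle: `cycle_index` and a list-column
#'   `window` holding the measure-phase samples of that cycle.
#' @export
extract_cycles <- function(trace) {
  required <- c("time_s", "o2_mg_per_l", "phase", "cycle_index")
  missing <- setdiff(required, names(trace))
  if (length(missing)) {
    abort(paste0("Trace is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  if (is.unsorted(trace$time_s, strictly = TRUE)) {
    abort("`time_s` must be strictly increasing.")
  }
  all_cycles <- unique(trace$cycle_index)
  meas <- dplyr::filter(trace, .data$phase == "measure")
  skipped <- setdiff(all_cycles, unique(meas$cycle_index))
  if (length(skipped)) {
    warn(paste0("Skipping ", length(skipped),
                " cycle(s) with no measure phase: ",
                paste(utils::head(skipped, 5), collapse = ", "),
                if (length(skipped) > 5) ", ..." else ""))
  }
  meas |>
    dplyr::group_by(.data$cycle_index) |>
    tidyr::nest(window = !"cycle_index") |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$cycle_index)
}

#' Fit the oxygen-decline slope of one measurement window
#'
#' Ordinary least-squares line of concentration against time (converted to
#' hours), the quantity d[O2]/dt of the MO2 equation. `r2` is the squared
#' Pearson correlation; for a zero-variance (constant-concentration) window it
#' is defined as 0, so such windows fail the usual R2 > 0.95 quality rule.
#' `end_sat_pct` is the saturation of the final sample, the worst case for the
#' hypoxia criterion.
#'
#' @param window A tibble of measure-phase samples: `time_s`, `o2_mg_per_l`
#'   and optionally `o2_sat_pct`.
#'
#' @return A one-row tibble (a slope fit): `slope_mg_l_h`, `intercept`, `r2`,
#'   `n_points`, `end_sat_pct`, `time_mid_min`.
#' @export
fit_slope <- function(window) {
  n <- nrow(window)
  if (n < 3) abort("Slope fitting needs at least 3 samples.")
  t_h <- window$time_s / 3600
  y <- window$o2_mg_per_l
  st <- var(t_h)
  if (st == 0) abort("Zero time variance in window.")
  slope <- stats::cov(t_h, y) / st
  intercept <- mean(y) - slope * mean(t_h)
  sy <- var(y)
  r2 <- if (sy == 0) 0 else stats::cor(t_h, y)^2
  tibble::tibble(
    slope_mg_l_h = slope,
    intercept = intercept,
    r2 = r2,
    n_points = n,
    end_sat_pct = if ("o2_sat_pct" %in% names(window)) {
      window$o2_sat_pct[n]
    } else NA_real_,
    time_mid_min = (min(window$time_s) + max(window$time_s) + 1) / 2 / 60)
}

#' Convert an oxygen-decline slope to mass-specific MO2
#'
#' Applies the intermittent-flow respirometry equation
#' MO2 = V * M^-1 * d[O2]/dt, with V the respirometer volume minus the fish
#' volume (L) and M the fish body mass (kg). MO2 is reported positive for
#' declining oxygen; a rising (positive) slope yields a negative MO2 and a
#' warning, so apparent-production cycles stay visible in the QC report
#' rather than silently disappearing.
#'
#' @param slope_mg_l_h Oxygen slope(s), mg O2 L-1 h-1 (negative when O2
#'   declines). A slope-fit tibble from [fit_slope()] is also accepted.
#' @param chamber A [chamber_spec()].
#'
#' @return Numeric MO2 in mg O2 kg-1 h-1.
#' @export
#' @examples
#' compute_mo2(-10, chamber_spec(0.362, fish_mass_kg = 0.020))
compute_mo2 <- function(slope_mg_l_h, chamber) {
  stopifnot(inherits(chamber, "chamber_spec"))
  if (is.data.frame(slope_mg_l_h)) slope_mg_l_h <- slope_mg_l_h$slope_mg_l_h
  v_eff <- chamber$volume_l - chamber$fish_volume_l
  mo2 <- v_eff * (-slope_mg_l_h) / chamber$fish_mass_kg
  if (any(mo2 < 0)) {
    warn(paste0(sum(mo2 < 0), " window(s) had rising oxygen; reported as ",
                "negative MO2."))
  }
  mo2
}

#' Estimate microbial background respiration from empty-chamber traces
#'
#' Background (microbial) respiration is measured in the empty chamber before
#' and after an experiment; the background rate is the mean of the two
#' measure-phase decline rates. When only one segment is available it is used
#' alone, with a warning. If a mean gross experimental slope is supplied, the
#' background fraction is computed against it and flagged when it reaches 1%,
#' the conventional threshold below which background is considered
#' insignificant.
#'
#' @param before,after Empty-chamber O2-trace tibbles (either may be `NULL`).
#' @param gross_slope_mg_l_h Mean absolute measure-phase slope of the actual
#'   experiment, mg O2 L-1 h-1 (optional).
#'
#' @return A list: `rate_before`, `rate_after`, `rate_mg_l_h` (positive decline
#'   rates), `fraction` (or `NA`), `significant` (fraction >= 0.01).
#' @export
estimate_background <- function(before = NULL, after = NULL,
                                gross_slope_mg_l_h = NULL) {
  seg_rate <- function(trace) {
    if (is.null(trace)) return(NA_real_)
    fits <- dplyr::bind_rows(purrr::map(extract_cycles(trace)$window,
                                        fit_slope))
    mean(-fits$slope_mg_l_h)
  }
  rb <- seg_rate(before)
  ra <- seg_rate(after)
  if (is.na(rb) && is.na(ra)) {
    abort("At least one of `before` and `after` is required.")
  }
  if (is.na(rb) || is.na(ra)) {
    warn("Only one background segment available; using it alone.")
  }
  rate <- mean(c(rb, ra), na.rm = TRUE)
  fraction <- if (is.null(gross_slope_mg_l_h)) NA_real_ else {
    rate / abs(gross_slope_mg_l_h)
  }
  significant <- isTRUE(fraction >= 0.01)
  if (significant) {
    warn(sprintf("Background respiration is %.1f%% of gross uptake (>= 1%%).",
                 100 * fraction))
  }
  list(rate_before = rb, rate_after = ra, rate_mg_l_h = rate,
       fraction = fraction, significant = significant)
}

#' Quality-filter slope fits
#'
#' Flags each MO2 measurement against the standard intermittent-flow quality
#' rules: the coefficient of determination of the decline must exceed
#' `r2_min` (default 0.95) and the window must end above `sat_min_pct`
#' (default 80%) air saturation, avoiding hypoxic stress. Points failing
#' either rule get `qc_pass = FALSE`; nothing is dropped.
#'
#' @param fits A tibble of slope fits (from [fit_slope()] /
#'   [extract_mo2()]) with columns `r2` and `end_sat_pct`.
#' @param r2_min Minimum R2, in (0, 1].
#' @param sat_min_pct Minimum end-of-window saturation, in (0, 100].
#'
#' @return The input tibble with a logical `qc_pass` column; the number of
#'   rejected points is reported via a message attribute `n_rejected`.
#' @export
qc_filter <- function(fits, r2_min = 0.95, sat_min_pct = 80) {
  if (r2_min <= 0 || r2_min > 1) abort("`r2_min` must be in (0, 1].")
  if (sat_min_pct <= 0 || sat_min_pct > 100) {
    abort("`sat_min_pct` must be in (0, 100].")
  }
  sat_ok <- is.na(fits$end_sat_pct) | fits$end_sat_pct >= sat_min_pct
  out <- dplyr::mutate(fits,
                       qc_pass = .data$r2 > r2_min & sat_ok)
  attr(out, "n_rejected") <- sum(!out$qc_pass)
  out
}

#' Extract a quality-filtered MO2 series from a raw trace
#'
#' The full per-fish extraction stage: split the trace into measure windows,
#' fit each window's decline slope, optionally subtract background respiration
#' on the slope scale (linear interpolation over experiment time between the
#' before and after empty-chamber estimates), apply the MO2 equation, and flag
#' quality. Each cycle's MO2 is timestamped at the midpoint of its measure
#' phase.
#'
#' @param trace An O2-trace tibble.
#' @param chamber A [chamber_spec()].
#' @param background Optional result of [estimate_background()]; its rate is
#'   subtracted from the decline slope before the MO2 equation.
#' @param r2_min,sat_min_pct Quality thresholds, see [qc_filter()].
#' @param fish_id Label for the fish; defaults to the trace's `chamber_id`.
#'
#' @return A tibble (an MO2 series): `fish_id`, `time_min`, `mo2`
#'   (mg O2 kg-1 h-1), `r2`, `end_sat_pct`, `n_points`, `qc_pass`,
#'   `background_corrected`, plus `temp_c` (window mean) when the trace has a
#'   temperature column.
#' @export
#' @examples
#' traj <- trajectory_spec("constant", list(value = 180), 30)
#' ch <- chamber_spec(fish_mass_kg = 0.020)
#' extract_mo2(synthesize_trace(traj, ch), ch)
extract_mo2 <- function(trace, chamber, background = NULL,
                        r2_min = 0.95, sat_min_pct = 80, fish_id = NULL) {
  windows <- extract_cycles(trace)
  fits <- dplyr::bind_rows(purrr::map(windows$window, fit_slope))
  fits$cycle_index <- windows$cycle_index
  slope <- fits$slope_mg_l_h
  corrected <- !is.null(background)
  if (corrected) {
    tspan <- range(fits$time_mid_min)
    rb <- background$rate_before
    ra <- background$rate_after
    if (is.na(rb)) rb <- background$rate_mg_l_h
    if (is.na(ra)) ra <- background$rate_mg_l_h
    frac <- (fits$time_mid_min - tspan[1]) / max(tspan[2] - tspan[1], 1e-12)
    bg_rate <- rb + (ra - rb) * frac
    slope <- slope + bg_rate  # background makes slope more negative
  }
  mo2 <- compute_mo2(slope, chamber)
  out <- tibble::tibble(
    fish_id = fish_id %||% (if ("chamber_id" %in% names(trace)) {
      trace$chamber_id[1]
    } else "fish01"),
    time_min = fits$time_mid_min,
    mo2 = mo2,
    r2 = fits$r2,
    end_sat_pct = fits$end_sat_pct,
    n_points = fits$n_points,
    background_corrected = corrected)
  if ("temp_c" %in% names(trace)) {
    meas <- dplyr::filter(trace, .data$phase == "measure")
    out$temp_c <- as.numeric(tapply(meas$temp_c, meas$cycle_index, mean)[
      as.character(windows$cycle_index)])
  }
  qc_filter(out, r2_min = r2_min, sat_min_pct = sat_min_pct)
}
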