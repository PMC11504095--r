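#' Specify a ground-truth metabolic-rate trajectory
#'
#' A `trajectory_spec` describes the noiseless mass-specific oxygen consumption
#' (MO2, mg O2 kg-1 h-1) of a fish over an experiment, as one of the functional
#' forms that occur in respirometry challenge studies. It is the generative
#' counterpart of the analysis stages: cosinor rhythms, continuous
#' piecewise-linear (segmented) time courses, a postprandial
#' specific-dynamic-action wave, a temperature-ramp response, and an anesthetic
#' recovery profile.
#'
#' Parameter sets by `kind` (all MO2 values mg O2 kg-1 h-1, times minutes):
#' \describe{
#'   \item{constant}{`value`.}
#'   \item{cosinor}{`mesor`, `amplitude`, `acrophase_h` (clock hour of the
#'     fitted maximum), optional `period_h` (default 24) and `t0_clock_h`
#'     (clock hour corresponding to trajectory time 0, default 0).}
#'   \item{piecewise_linear}{`start` (value at time 0), `slopes` (units per
#'     minute, one per segment), `breaks_min` (strictly increasing, inside the
#'     duration; one fewer than slopes). Continuous across breaks.}
#'   \item{sda_wave}{`baseline`, `peak_frac` (peak fractional elevation, e.g.
#'     0.35), `peak_time_min`, `end_time_min`, optional `start_time_min`
#'     (default 0). Returns baseline * (1 + w(t)) where w is a piecewise-linear
#'     tent rising from 0 to `peak_frac` and back to 0.}
#'   \item{temperature_ramp}{`basal` (value at ramp start), `per_degree`
#'     (units per degree C during the ramp), `ramp_rate_c_per_min`,
#'     `t_start_c`, `t_end_c`, `max_value`, `max_time_min`, `decline_per_min`.
#'     Three linear phases: rise at `per_degree * ramp_rate` during the ramp,
#'     continued rise to `max_value` at `max_time_min`, then decline.}
#'   \item{anesthetic_profile}{`start`, `increase_rate`, `time_to_max_min`,
#'     `decrease_rate` (positive; applied as a negative slope),
#'     `stabilization_min`. Rise, fall, then flat.}
#' }
#'
#' @param kind One of `"constant"`, `"cosinor"`, `"piecewise_linear"`,
#'   `"sda_wave"`, `"temperature_ramp"`, `"anesthetic_profile"`.
#' @param params Named list of parameters for `kind` (see Details).
#' @param duration_min Total duration in minutes (> 0).
#' @param dt_min Sampling step of the evaluation grid in minutes (> 0).
#'
#' @return An object of class `trajectory_spec`.
#' @seealso [make_trajectory()]
#' @export
trajectory_spec <- function(kind, params, duration_min, dt_min = 1) {
  kinds <- c("constant", "cosinor", "piecewise_linear", "sda_wave",
             "temperature_ramp", "anesthetic_profile")
  if (!is.character(kind) || length(kind) != 1L || !kind %in% kinds) {
    abort(paste0("`kind` must be one of: ", paste(kinds, collapse = ", "), "."))
  }
  if (!is.numeric(duration_min) || duration_min <= 0) {
    abort("`duration_min` must be > 0.")
  }
  if (!is.numeric(dt_min) || dt_min <= 0) abort("`dt_min` must be > 0.")
  params <- as.list(params)

  need <- switch(kind,
    constant = "value",
    cosinor = c("mesor", "amplitude", "acrophase_h"),
    piecewise_linear = c("start", "slopes", "breaks_min"),
    sda_wave = c("baseline", "peak_frac", "peak_time_min", "end_time_min"),
    temperature_ramp = c("basal", "per_degree", "ramp_rate_c_per_min",
                         "t_start_c", "t_end_c", "max_value", "max_time_min",
                         "decline_per_min"),
    anesthetic_profile = c("start", "increase_rate", "time_to_max_min",
                           "decrease_rate", "stabilization_min"))
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    abort(paste0("Missing params for kind '", kind, "': ",
                 paste(missing, collapse = ", "), "."))
  }

  if (kind == "piecewise_linear") {
    b <- params$breaks_min
    if (length(params$slopes) != length(b) + 1L) {
      abort("`slopes` must have one more element than `breaks_min`.")
    }
    if (length(b) && (any(diff(b) <= 0) || any(b <= 0) || any(b >= duration_min))) {
      abort("`breaks_min` must be strictly increasing and inside (0, duration_min).")
    }
  }
  if (kind == "sda_wave" && params$peak_frac < 0) {
    abort("`peak_frac` must be >= 0.")
  }
  if (kind == "cosinor" && params$amplitude < 0) {
    abort("`amplitude` must be >= 0.")
  }

  structure(
    list(kind = kind, params = params,
         duration_min = duration_min, dt_min = dt_min),
    class = "trajectory_spec")
}

#' Evaluate a trajectory specification on its time grid
#'
#' Deterministic, noiseless evaluation of the functional form described by a
#' [trajectory_spec()] on the grid `seq(0, duration_min, by = dt_min)`.
#' Piecewise forms are continuous across breakpoints.
#'
#' @param spec A [trajectory_spec()].
#' @param time_min Optional explicit evaluation times in minutes; defaults to
#'   the spec's own grid.
#'
#' @return A tibble with columns `time_min` and `mo2` (mg O2 kg-1 h-1).
#' @export
#' @examples
#' make_trajectory(trajectory_spec("constant", list(value = 180), 60))
make_trajectory <- function(spec, time_min = NULL) {
  stopifnot(inherits(spec, "trajectory_spec"))
  t <- time_min %||% seq(0, spec$duration_min, by = spec$dt_min)
  p <- spec$params
  mo2 <- switch(spec$kind,
    constant = rep(p$value, length(t)),
    cosinor = {
      period <- p$period_h %||% 24
      t0 <- p$t0_clock_h %||% 0
      clock_h <- t0 + t / 60
      p$mesor + p$amplitude * cos(2 * pi / period * (clock_h - p$acrophase_h))
    },
    piecewise_linear = eval_piecewise(t, p$start, p$slopes, p$breaks_min),
    sda_wave = {
      t0 <- p$start_time_min %||% 0
      w <- tent_wave(t, t0, p$peak_time_min, p$end_time_min, p$peak_frac)
      p$baseline * (1 + w)
    },
    temperature_ramp = {
      ramp_min <- (p$t_end_c - p$t_start_c) / p$ramp_rate_c_per_min
      ramp_slope <- p$per_degree * p$ramp_rate_c_per_min
      at_ramp_end <- p$basal + ramp_slope * ramp_min
      mid_slope <- (p$max_value - at_ramp_end) / (p$max_time_min - ramp_min)
      eval_piecewise(t, p$basal,
                     c(ramp_slope, mid_slope, -p$decline_per_min),
                     c(ramp_min, p$max_time_min))
    },
    anesthetic_profile = eval_piecewise(
      t, p$start,
      c(p$increase_rate, -p$decrease_rate, 0),
      c(p$time_to_max_min, p$stabilization_min)))
  tibble::tibble(time_min = t, mo2 = mo2)
}

# continuous piecewise-linear evaluation: value at 0 plus integrated slope
eval_piecewise <- function(t, start, slopes, breaks) {
  knots <- c(0, breaks)
  knot_vals <- start + c(0, cumsum(slopes[-length(slopes)] * diff(knots)))
  seg <- findInterval(t, knots)
  seg[seg < 1L] <- 1L
  knot_vals[seg] + slopes[seg] * (t - knots[seg])
}

tent_wave <- function(t, t0, t_peak, t_end, peak) {
  w <- numeric(length(t))
  up <- t >= t0 & t <= t_peak
  dn <- t > t_peak & t <= t_end
  if (t_peak > t0) w[up] <- peak * (t[up] - t0) / (t_peak - t0)
  if (t_end > t_peak) w[dn] <- peak * (t_end - t[dn]) / (t_end - t_peak)
  w
}

#' Water-temperature profile for a scenario
#'
#' Temperature over experiment time: constant, or a linear ramp at
#' `rate_c_per_min` from `t_start_c` to `t_end_c` beginning at time 0, constant
#' thereafter (the heating protocol of acute warming trials).
#'
#' @param time_min Times in minutes.
#' @param t_start_c Starting (or constant) temperature, degrees C.
#' @param t_end_c Final temperature; equal to `t_start_c` for a constant
#'   profile.
#' @param rate_c_per_min Ramp rate in degrees C per minute.
#'
#' @return Numeric vector of temperatures.
#' @export
temperature_profile <- function(time_min, t_start_c = 21.5,
                                t_end_c = t_start_c, rate_c_per_min = 0.1) {
  if (t_end_c == t_start_c) return(rep(t_start_c, length(time_min)))
  pmin(t_start_c + rate_c_per_min * pmax(time_min, 0), t_end_c)
}
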