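#' Specific-dynamic-action metrics from paired fed/fasted series
#'
#' Quantifies the postprandial rise in metabolic rate. Both series are grouped
#' into time bins (10 min by default, times counted from feeding), the percent
#' change 100 * (fed - fasted) / fasted is computed per fish per bin and
#' averaged over fish, and a paired t-test per bin (same fish under both
#' conditions) defines the significant window. The peak percent change and
#' its time are reported, and the return to baseline is the first post-peak
#' bin from which the paired test stays non-significant to the end of the
#' record.
#'
#' @param fed,fasted MO2-series tibbles (`fish_id`, `time_min`, `mo2`, and
#'   optionally `qc_pass`, which is honoured) for the same fish under the two
#'   conditions; times are minutes post-feeding.
#' @param bin_min Bin width in minutes (default 10).
#' @param alpha Per-bin significance level (default 0.05).
#'
#' @return An object of class `sda_result`: `table` (tibble: `bin_min`,
#'   `pct_change`, `p_value`, `n_fish`), `peak_pct`, `peak_time_min`,
#'   `significant_window_min` (length-2 vector or `NULL`),
#'   `return_to_baseline_min`.
#' @export
sda_metrics <- function(fed, fasted, bin_min = 10, alpha = 0.05) {
  prep <- function(d, label) {
    if ("qc_pass" %in% names(d)) d <- dplyr::filter(d, .data$qc_pass)
    d |>
      dplyr::mutate(bin_min = floor(.data$time_min / bin_min) * bin_min) |>
      dplyr::group_by(.data$fish_id, .data$bin_min) |>
      dplyr::summarise(mo2 = mean(.data$mo2), .groups = "drop") |>
      dplyr::rename(!!label := "mo2")
  }
  joined <- dplyr::inner_join(prep(fed, "fed"), prep(fasted, "fasted"),
                              by = c("fish_id", "bin_min"))
  if (!nrow(joined)) abort("Fed and fasted series share no fish/time bins.")
  if (!setequal(unique(fed$fish_id), unique(fasted$fish_id))) {
    abort("Fed and fasted series must contain the same (paired) fish.")
  }
  # p-value of the per-bin paired test; degenerate zero-variance bins are
  # decided by whether the common difference is zero
  safe_p <- function(fed_v, fasted_v) {
    d <- fed_v - fasted_v
    if (length(d) < 2) return(NA_real_)
    if (sd(d) == 0) return(if (all(d == 0)) 1 else 0)
    t.test(fed_v, fasted_v, paired = TRUE)$p.value
  }
  table <- joined |>
    dplyr::group_by(.data$bin_min) |>
    dplyr::summarise(
      pct_change = mean(100 * (.data$fed - .data$fasted) / .data$fasted),
      p_value = safe_p(.data$fed, .data$fasted),
      n_fish = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$bin_min)

  peak_i <- which.max(table$pct_change)
  sig <- !is.na(table$p_value) & table$p_value < alpha
  window <- if (any(sig)) range(table$bin_min[sig]) else NULL
  after <- seq_len(nrow(table)) > peak_i
  nonsig_tail <- after & !sig
  # first post-peak bin from which non-significance is sustained to the end
  rtb <- NA_real_
  for (i in which(nonsig_tail)) {
    if (all(!sig[i:nrow(table)])) { rtb <- table$bin_min[i]; break }
  }
  structure(
    list(table = table,
         peak_pct = table$pct_change[peak_i],
         peak_time_min = table$bin_min[peak_i],
         significant_window_min = window,
         return_to_baseline_min = rtb),
    class = "sda_result")
}

#' @export
print.sda_result <- function(x, ...) {
  cat(sprintf("SDA: peak %+.1f%% at %g min post-feeding\n",
              x$peak_pct, x$peak_time_min))
  if (!is.null(x$significant_window_min)) {
    cat("  significant window:", x$significant_window_min[1], "-",
        x$significant_window_min[2], "min\n")
  }
  cat("  return to baseline:", x$return_to_baseline_min, "min\n")
  invisible(x)
}

#' Thermal coefficient Q10
#'
#' `q10()` evaluates the van 't Hoff form Q10 = (r2 / r1)^(10 / (t2 - t1))
#' for rates r1, r2 at temperatures t1, t2. `q10_per_fish()` applies it to
#' each fish's own initial and final rates and summarises as mean +/- SEM —
#' the per-animal-then-average convention, whose mean generally differs from
#' Q10 evaluated on the group-mean rates.
#'
#' @param r1,r2 Positive metabolic rates at `t1_c` and `t2_c`.
#' @param t1_c,t2_c Temperatures in degrees C (`t1_c != t2_c`).
#'
#' @return `q10()`: numeric Q10 value(s).
#' @export
#' @examples
#' q10(112, 278, 21, 30)
q10 <- function(r1, r2, t1_c, t2_c) {
  if (any(t1_c == t2_c)) abort("`t1_c` and `t2_c` must differ.")
  if (any(r1 <= 0 | r2 <= 0)) abort("Rates must be positive.")
  (r2 / r1)^(10 / (t2_c - t1_c))
}

#' @rdname q10
#' @param data A data frame with columns `fish_id`, `r1`, `r2`, `t1_c`,
#'   `t2_c`.
#' @return `q10_per_fish()`: an object of class `q10_result` with `per_fish`
#'   (tibble of `fish_id`, `q10`), `mean`, `sem`, `n`.
#' @export
q10_per_fish <- function(data) {
  per <- tibble::tibble(
    fish_id = data$fish_id,
    q10 = q10(data$r1, data$r2, data$t1_c, data$t2_c))
  structure(
    list(per_fish = per,
         mean = mean(per$q10),
         sem = sd(per$q10) / sqrt(nrow(per)),
         n = nrow(per)),
    class = "q10_result")
}

#' @export
print.q10_result <- function(x, ...) {
  cat(sprintf("Q10 = %.2f +/- %.2f (mean +/- SEM, n = %d fish)\n",
              x$mean, x$sem, x$n))
  invisible(x)
}

#' Metabolic sensitivity to temperature
#'
#' Least-squares slope of MO2 on water temperature over a stated time window
#' (typically the heating ramp), in mg O2 kg-1 h-1 per degree C, with its
#' standard error. For repeated-measures data a random-intercept variant is
#' available through [fit_random_intercept()] with temperature as the
#' covariate.
#'
#' @param series An MO2-series tibble with `time_min`, `mo2` and `temp_c`
#'   columns (`qc_pass` honoured if present).
#' @param window Length-2 time window in minutes (default the whole series).
#'
#' @return A tibble: `slope_per_degc`, `se`, `n`.
#' @export
temperature_sensitivity <- function(series, window = NULL) {
  d <- series
  if ("qc_pass" %in% names(d)) d <- dplyr::filter(d, .data$qc_pass)
  if (!is.null(window)) {
    d <- dplyr::filter(d, .data$time_min >= window[1],
                       .data$time_min <= window[2])
  }
  if (length(unique(d$temp_c)) < 2) {
    abort("Temperature is constant within the window.")
  }
  fit <- lm(mo2 ~ temp_c, data = d)
  sm <- suppressWarnings(summary(fit))$coefficients
  tibble::tibble(slope_per_degc = sm["temp_c", "Estimate"],
                 se = sm["temp_c", "Std. Error"],
                 n = nrow(d))
}

#' Anesthetic recovery-profile metrics
#'
#' Characterises each fish's post-anesthesia MO2 time course, which rises to
#' a maximum and then declines to a stable base: a one-breakpoint segmented
#' fit gives the increase rate (first-segment slope), time to maximum (the
#' breakpoint) and maximum (fitted value at the breakpoint) plus the decrease
#' rate (absolute second-segment slope); a two-breakpoint fit with the
#' [stabilization_time()] rule gives the stabilization time, and the base is
#' the mean fitted value over the post-stabilization segment. Metrics are
#' summarised per group as mean +/- SEM. Fish whose fits fail are excluded
#' and listed.
#'
#' @param series A long MO2 tibble with `fish_id`, `time_min`, `mo2`
#'   (`qc_pass` honoured) covering the recovery window (about 4 h).
#' @param slope_tol Flat-slope tolerance for stabilization, units per minute.
#' @param min_segment_points Passed to [fit_segmented()].
#'
#' @return An object of class `anesthetic_profile`: `per_fish` (tibble of
#'   `fish_id`, `maximum`, `increase_rate`, `time_to_maximum`,
#'   `decrease_rate`, `stabilization_time`, `base`, `raw_maximum`), `summary`
#'   (tibble of metric, mean, sem, n) and `failed` (character vector).
#' @export
anesthetic_profile <- function(series, slope_tol = 0.05,
                               min_segment_points = 5) {
  d <- series
  if ("qc_pass" %in% names(d)) d <- dplyr::filter(d, .data$qc_pass)
  one_fish <- function(df) {
    f1 <- fit_segmented(df, time_min, mo2, n_breakpoints = 1,
                        min_segment_points = min_segment_points)
    f2 <- tryCatch(
      fit_segmented(df, time_min, mo2, n_breakpoints = 2,
                    min_segment_points = min_segment_points),
      error = function(e) NULL)
    stab <- if (!is.null(f2)) stabilization_time(f2, slope_tol) else NA_real_
    base <- if (!is.null(f2) && !is.na(stab)) {
      fitted_vals <- fitted(f2$model)
      mean(fitted_vals[f2$data$time_min >= stab])
    } else NA_real_
    maximum <- f1$segment_intercepts[2]
    time_to_max <- f1$breakpoints_min[1]
    # a profile that never rose: no meaningful peak, report time 0
    if (all(abs(f1$segment_slopes) < slope_tol)) {
      time_to_max <- 0
      maximum <- f1$segment_intercepts[1]
    }
    if (!is.na(base) && maximum < base) {
      warn("Fitted maximum is below the fitted base for one fish.")
    }
    tibble::tibble(
      maximum = maximum,
      increase_rate = f1$segment_slopes[1],
      time_to_maximum = time_to_max,
      decrease_rate = abs(f1$segment_slopes[2]),
      stabilization_time = stab,
      base = base,
      raw_maximum = max(df$mo2))
  }
  ids <- unique(d$fish_id)
  res <- purrr::map(ids, function(id) {
    tryCatch(one_fish(d[d$fish_id == id, ]), error = function(e) NULL)
  })
  failed <- ids[vapply(res, is.null, logical(1))]
  if (length(failed)) {
    warn(paste0("Profile fit failed for: ", paste(failed, collapse = ", ")))
  }
  per_fish <- dplyr::bind_rows(
    purrr::map2(res[!ids %in% failed], ids[!ids %in% failed],
                function(r, id) dplyr::mutate(r, fish_id = id,
                                              .before = 1)))
  summary <- per_fish |>
    tidyr::pivot_longer(-"fish_id", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sem = sd(.data$value, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$value))),
      n = sum(!is.na(.data$value)), .groups = "drop")
  structure(list(per_fish = per_fish, summary = summary, failed = failed),
            class = "anesthetic_profile")
}

#' @export
print.anesthetic_profile <- function(x, ...) {
  cat("Anesthetic recovery profile (", nrow(x$per_fish), " fish)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Between-group tests of recovery-profile metrics
#'
#' For each recovery metric (increase rate, time to maximum, ...), all
#' pairwise group contrasts from a one-way linear model, adjusted with the
#' Benjamini-Hochberg FDR within that metric's pair family.
#'
#' @param profiles A tibble of per-fish metrics with a `group` column (e.g.
#'   row-bound `per_fish` tables from [anesthetic_profile()] runs).
#' @param metrics Character vector of metric columns to test; defaults to all
#'   numeric columns except identifiers.
#' @param adjust Adjustment method, `"BH"` or `"holm-sidak"`.
#'
#' @return A tibble: `metric`, `pair`, `estimate`, `se`, `p_raw`,
#'   `p_adjusted`, `method`.
#' @export
group_metric_tests <- function(profiles, metrics = NULL, adjust = "BH") {
  if (!"group" %in% names(profiles)) abort("`profiles` needs a `group` column.")
  grp <- factor(profiles$group)
  if (length(levels(grp)) < 2) abort("Need at least 2 groups.")
  if (any(table(grp) < 2)) abort("Every group needs at least 2 fish.")
  metrics <- metrics %||% setdiff(
    names(profiles)[vapply(profiles, is.numeric, logical(1))],
    c("fish_id"))
  purrr::map_dfr(metrics, function(m) {
    d <- data.frame(y = profiles[[m]], group = grp)
    d <- d[is.finite(d$y), ]
    fit <- lm(y ~ group, data = d)
    ct <- pairwise_contrasts(fit, "group", type = "mean", adjust = adjust)
    dplyr::mutate(ct, metric = m, .before = 1)
  })
}
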