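#' Sokolove-Bushell chi-square periodogram
#'
#' For each candidate period P the series is folded into K = P / bin columns
#' and the statistic Q_P = N * Var(column means) / Var(series) is computed
#' (variances as mean squared deviations), which is referenced to a
#' chi-square distribution with K - 1 degrees of freedom. Periods whose Q_P
#' exceeds the (1 - alpha) chi-square quantile are significant;
#' `peak_period_min` is the significant period with the largest Q_P (or `NA`
#' when none is significant). Candidate periods must be integer multiples of
#' the bin width; others are skipped with a warning.
#'
#' @param activity An activity tibble (see [synthesize_activity()] /
#'   [read_activity()]) with a `counts` column on a regular bin grid.
#' @param period_grid_min Candidate periods in minutes; defaults to the
#'   circadian range 1000-1700 min at the bin resolution.
#' @param alpha Significance level for the threshold line (default 0.05).
#' @param bin_min Bin width in minutes (default 10).
#'
#' @return An object of class `chisq_periodogram`: a list with `table`
#'   (tibble of `period_min`, `qp`, `df`, `threshold`, `significant`),
#'   `alpha`, `bin_min` and `peak_period_min`. `autoplot()` is provided.
#' @export
#' @examples
#' act <- synthesize_activity(27.83, 21.5, 12.7, n_days = 9)
#' chi_square_periodogram(act)$peak_period_min
chi_square_periodogram <- function(activity, period_grid_min = NULL,
                                   alpha = 0.05, bin_min = 10) {
  x <- activity$counts
  n_total <- length(x)
  period_grid_min <- period_grid_min %||% seq(1000, 1700, by = bin_min)
  bad <- period_grid_min %% bin_min != 0
  if (any(bad)) {
    warn(paste0("Skipping ", sum(bad),
                " candidate period(s) not a multiple of the bin width."))
    period_grid_min <- period_grid_min[!bad]
  }
  if (n_total * bin_min < 2 * max(period_grid_min)) {
    abort("Series must span at least twice the longest candidate period.")
  }
  rows <- purrr::map_dfr(period_grid_min, function(p) {
    k <- p %/% bin_min
    n_use <- (n_total %/% k) * k  # whole folds only
    xs <- x[seq_len(n_use)]
    col <- rep_len(seq_len(k), n_use)
    m_h <- as.numeric(tapply(xs, col, mean))
    m_bar <- mean(xs)
    denom <- mean((xs - m_bar)^2)
    qp <- if (denom == 0) 0 else {
      n_use * mean((m_h - m_bar)^2) / denom
    }
    tibble::tibble(period_min = p, qp = qp, df = k - 1L,
                   threshold = qchisq(1 - alpha, k - 1L))
  })
  rows$significant <- rows$qp > rows$threshold
  peak <- if (any(rows$significant)) {
    sig <- rows[rows$significant, ]
    sig$period_min[which.max(sig$qp)]
  } else NA_real_
  structure(list(table = rows, alpha = alpha, bin_min = bin_min,
                 peak_period_min = peak),
            class = "chisq_periodogram")
}

#' @export
print.chisq_periodogram <- function(x, ...) {
  cat("Chi-square periodogram (", nrow(x$table), " candidate periods, alpha ",
      x$alpha, ")\n", sep = "")
  if (is.na(x$peak_period_min)) {
    cat("  no significant period\n")
  } else {
    cat("  peak period:", x$peak_period_min, "min\n")
  }
  invisible(x)
}

#' @export
#' @method tidy chisq_periodogram
tidy.chisq_periodogram <- function(x, ...) x$table

#' @export
#' @rdname chi_square_periodogram
#' @param object A `chisq_periodogram`.
#' @param ... Unused.
#' @method autoplot chisq_periodogram
autoplot.chisq_periodogram <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(.data$period_min, .data$qp)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(ggplot2::aes(y = .data$threshold),
                       linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "Period (min)", y = expression(Q[P]),
                  title = "Chi-square periodogram") +
    ggplot2::theme_minimal()
}

#' Average daily waveform
#'
#' Mean and standard deviation per time-of-day bin across days: the averaged
#' daily profile conventionally plotted with photophase/scotophase shading.
#'
#' @param series A tibble with `clock_h` (hours since midnight) and a value
#'   column.
#' @param value Value column (default `counts`).
#' @param bin_min Bin width in minutes (default 10); bins tile 24 h exactly.
#'
#' @return A tibble with `clock_h` (bin start), `mean`, `sd`, `n_days`.
#' @export
daily_waveform <- function(series, value = counts, bin_min = 10) {
  v <- rlang::eval_tidy(rlang::enquo(value), series)
  if (24 * 60 %% bin_min != 0) abort("`bin_min` must tile 24 h exactly.")
  bin <- floor((series$clock_h * 60) / bin_min + 1e-9) * bin_min / 60
  out <- tibble::tibble(bin = bin, v = v) |>
    dplyr::group_by(clock_h = .data$bin) |>
    dplyr::summarise(mean = mean(.data$v),
                     sd = if (dplyr::n() > 1) sd(.data$v) else 0,
                     n_days = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$clock_h)
  out
}

#' Actogram matrix
#'
#' Arranges an activity series as a day-by-bin matrix for actogram display.
#' With `double_plot = TRUE` each row concatenates day i with day i + 1 (the
#' conventional 48 h double-plotted scale), giving `n_days - 1` rows. A
#' partial final day is padded with `NA`.
#'
#' @param series An activity tibble with `day` and `counts` columns on a
#'   regular bin grid.
#' @param double_plot Concatenate consecutive days per row.
#' @param bin_min Bin width in minutes (default 10).
#'
#' @return A numeric matrix (days x bins; days - 1 x 2 bins when
#'   double-plotted), with bin-start clock hours as column names.
#' @export
actogram_matrix <- function(series, double_plot = FALSE, bin_min = 10) {
  bins_per_day <- 24 * 60 / bin_min
  days <- sort(unique(series$day))
  m <- matrix(NA_real_, nrow = length(days), ncol = bins_per_day,
              dimnames = list(days, (seq_len(bins_per_day) - 1) * bin_min / 60))
  for (i in seq_along(days)) {
    v <- series$counts[series$day == days[i]]
    m[i, seq_along(v)] <- v
  }
  if (!double_plot) return(m)
  if (nrow(m) < 2) abort("Double plotting needs at least 2 days.")
  dd <- cbind(m[-nrow(m), , drop = FALSE], m[-1, , drop = FALSE])
  colnames(dd) <- c(colnames(m), as.numeric(colnames(m)) + 24)
  dd
}
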