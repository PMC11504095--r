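#' Continuous piecewise-linear (segmented) regression by exhaustive search
#'
#' Fits a continuous piecewise-linear model with `n_breakpoints` slope-change
#' points to a time course, as used to locate metabolic-rate breakpoints after
#' a challenge. Breakpoints are found by exhaustive search over the observed
#' time grid: every admissible combination of observed time points is tried
#' and the combination minimising the residual sum of squares is returned
#' (ties broken toward the earliest breakpoints). The result is therefore the
#' exact RSS minimiser on the grid, and recovery is exact on noiseless
#' piecewise input whose true breaks lie on the grid. For a given breakpoint
#' set the model is linear in {1, t, (t - b_j)+} and solved by least squares.
#'
#' @param data A data frame (e.g. a pooled MO2 series).
#' @param time,value Time (minutes) and response columns.
#' @param n_breakpoints Number of breakpoints, 1-3.
#' @param min_segment_points Minimum observations per segment (default 5).
#'
#' @return An object of class `segmented_fit`: `breakpoints_min`,
#'   `segment_slopes` (units per minute), `segment_intercepts` (fitted value
#'   at each segment start), `slope_se`, `rss`, `n`, `n_breakpoints`, `model`
#'   (the `lm` at the chosen breaks) and `data`. `tidy()`, `glance()` and
#'   `autoplot()` methods are provided.
#' @export
#' @examples
#' tr <- make_trajectory(trajectory_spec("piecewise_linear",
#'   list(start = 180, slopes = c(1.26, -0.72, -0.0184),
#'        breaks_min = c(72, 185)), 360))
#' fit_segmented(tr, time_min, mo2, n_breakpoints = 2)
fit_segmented <- function(data, time, value, n_breakpoints,
                          min_segment_points = 5) {
  t <- rlang::eval_tidy(rlang::enquo(time), data)
  y <- rlang::eval_tidy(rlang::enquo(value), data)
  ok <- complete.cases(t, y)
  t <- t[ok]; y <- y[ok]
  ord <- order(t)
  t <- t[ord]; y <- y[ord]
  n <- length(t)
  if (!n_breakpoints %in% 1:3) abort("`n_breakpoints` must be 1, 2 or 3.")
  if (n < (n_breakpoints + 1) * min_segment_points) {
    abort("Too few points for the requested number of segments.")
  }
  ut <- unique(t)
  # candidate breakpoints: observed times with enough points on both sides
  counts <- cumsum(tabulate(match(t, ut)))
  admissible <- function(b_idx) {
    # points strictly inside each segment boundary set
    cuts <- c(-Inf, ut[b_idx], Inf)
    seg <- findInterval(t, ut[b_idx], left.open = FALSE)
    all(tabulate(seg + 1L, nbins = n_breakpoints + 1L) >= min_segment_points)
  }
  cand <- seq_along(ut)[-c(1L, length(ut))]

  best <- list(rss = Inf, idx = NULL, fit = NULL)
  design <- function(b) {
    X <- cbind(1, t)
    for (bb in b) X <- cbind(X, pmax(t - bb, 0))
    X
  }
  consider <- function(b_idx) {
    if (!admissible(b_idx)) return()
    X <- design(ut[b_idx])
    f <- stats::lm.fit(X, y)
    rss <- sum(f$residuals^2)
    if (is.infinite(best$rss) ||
        rss < best$rss - .Machine$double.eps * max(1, best$rss)) {
      best <<- list(rss = rss, idx = b_idx, fit = f)
    }
  }
  if (n_breakpoints == 1) {
    for (i in cand) consider(i)
  } else if (n_breakpoints == 2) {
    for (i in cand) for (j in cand[cand > i]) consider(c(i, j))
  } else {
    for (i in cand) for (j in cand[cand > i]) for (k in cand[cand > j]) {
      consider(c(i, j, k))
    }
  }
  if (is.null(best$idx)) abort("No admissible breakpoint combination.")
  breaks <- ut[best$idx]

  # refit with lm for SEs at the chosen breakpoints
  df_fit <- as.data.frame(design(breaks)[, -1, drop = FALSE])
  names(df_fit) <- c("t", paste0("h", seq_along(breaks)))
  df_fit$y <- y
  model <- lm(y ~ ., data = df_fit)
  beta <- coef(model)
  vc <- suppressWarnings(vcov(model))
  k <- length(breaks)
  slope_contrasts <- lapply(0:k, function(j) {
    w <- c(0, 1, as.numeric(seq_len(k) <= j))
    w
  })
  slopes <- vapply(slope_contrasts, function(w) sum(w * beta), numeric(1))
  slope_se <- vapply(slope_contrasts,
                     function(w) sqrt(drop(t(w) %*% vc %*% w)), numeric(1))
  knots <- c(min(t), breaks)
  intercepts <- beta[1] + beta[2] * knots[1] +
    c(0, cumsum(slopes[-length(slopes)] * diff(knots)))

  # straight-line comparison: flag degenerate breakpoints
  rss0 <- sum(lm.fit(cbind(1, t), y)$residuals^2)
  if (rss0 - best$rss <= 1e-8 * max(rss0, 1)) {
    warn("Breakpoint(s) give no RSS improvement over a straight line; fit is degenerate.")
  }

  structure(
    list(n_breakpoints = k,
         breakpoints_min = unname(breaks),
         segment_slopes = unname(slopes),
         segment_intercepts = unname(intercepts),
         slope_se = unname(slope_se),
         rss = best$rss,
         n = n,
         model = model,
         data = tibble::tibble(time_min = t, value = y)),
    class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat("Segmented fit:", x$n_breakpoints, "breakpoint(s) at",
      paste(signif(x$breakpoints_min, 6), collapse = ", "), "min\n")
  cat("  slopes (units/min):",
      paste(signif(x$segment_slopes, 4), collapse = ", "), "\n")
  cat("  rss:", signif(x$rss, 6), " n:", x$n, "\n")
  invisible(x)
}

#' @export
#' @method tidy segmented_fit
tidy.segmented_fit <- function(x, ...) {
  k <- x$n_breakpoints
  tibble::tibble(
    segment = seq_len(k + 1),
    start_min = c(min(x$data$time_min), x$breakpoints_min),
    end_min = c(x$breakpoints_min, max(x$data$time_min)),
    slope = x$segment_slopes,
    slope_se = x$slope_se,
    value_at_start = x$segment_intercepts)
}

#' @export
#' @method glance segmented_fit
glance.segmented_fit <- function(x, ...) {
  tibble::tibble(n_breakpoints = x$n_breakpoints, rss = x$rss, n = x$n)
}

#' @export
#' @rdname fit_segmented
#' @param object A `segmented_fit`.
#' @param ... Unused.
#' @method autoplot segmented_fit
autoplot.segmented_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- fitted(object$model)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_min, .data$value)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::geom_vline(xintercept = object$breakpoints_min,
                        linetype = "dashed") +
    ggplot2::labs(x = "Time (min)", y = "Value",
                  title = "Segmented regression") +
    ggplot2::theme_minimal()
}

#' Stabilization time from a segmented fit
#'
#' The time at which the fitted profile becomes flat: the first breakpoint
#' whose following segment slope is within `slope_tol` of zero (default
#' |slope| < 0.05 units per minute). If the first segment is already flat the
#' stabilization time is 0; if no segment is flat, `NA`.
#'
#' @param fit A `segmented_fit`.
#' @param slope_tol Absolute slope tolerance, units per minute.
#'
#' @return Stabilization time in minutes (`NA` if the profile never
#'   stabilises).
#' @export
stabilization_time <- function(fit, slope_tol = 0.05) {
  stopifnot(inherits(fit, "segmented_fit"))
  flat <- abs(fit$segment_slopes) < slope_tol
  if (flat[1]) return(0)
  starts <- fit$breakpoints_min
  for (j in seq_along(starts)) {
    if (flat[j + 1]) return(starts[j])
  }
  NA_real_
}
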