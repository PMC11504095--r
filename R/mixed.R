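#' Random-intercept mixed model for repeated respirometry measures
#'
#' Fits a linear mixed-effects model with a random intercept per fish by
#' restricted maximum likelihood (REML), the standard model for per-fish
#' repeated MO2 measurements: fixed covariates (time, temperature, group)
#' plus a between-fish intercept variance. When the between-fish variance is
#' estimated at its zero boundary the fixed-effect estimates coincide with
#' pooled ordinary least squares.
#'
#' @param data A long data frame with one row per fish per time point.
#' @param formula Fixed-effects formula, e.g. `mo2 ~ time_min` or
#'   `mo2 ~ time_min * group`; the random intercept is added internally.
#' @param fish_id Column identifying fish (the grouping factor).
#'
#' @return An object of class `ri_fit`: `model` (the `lmerMod`),
#'   `fixed_coefficients` (tibble: term, estimate, se, statistic, p_value —
#'   Wald z tests), `var_between`, `var_resid`, `n_fish`, `reml_loglik`.
#'   `tidy()` and `glance()` methods are provided.
#' @export
#' @examples
#' d <- expand.grid(fish_id = paste0("f", 1:4), time_min = 1:10)
#' d$mo2 <- 100 + 1.2 * d$time_min + rnorm(40)
#' fit_random_intercept(d, mo2 ~ time_min, fish_id)
fit_random_intercept <- function(data, formula, fish_id) {
  fq <- rlang::enquo(fish_id)
  ids <- rlang::eval_tidy(fq, data)
  if (length(unique(ids)) < 2) abort("Need at least 2 fish.")
  if (min(table(ids)) < 2) abort("Need at least 2 points per fish.")
  data <- as.data.frame(data)
  data$.fish <- factor(ids)
  mm <- stats::model.matrix(formula, data)
  if (qr(mm)$rank < ncol(mm)) abort("Singular fixed-effects design.")
  f <- stats::update(formula, . ~ . + (1 | .fish))
  model <- tryCatch(
    lme4::lmer(f, data = data, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) abort(paste0("Mixed-model fit failed (singular design?): ",
                                     conditionMessage(e))))
  vc <- as.data.frame(lme4::VarCorr(model))
  var_between <- vc$vcov[vc$grp == ".fish"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  sm <- summary(model)$coefficients
  fixed <- tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    se = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p_value = unname(2 * pnorm(-abs(sm[, "t value"]))))
  structure(
    list(model = model,
         fixed_coefficients = fixed,
         var_between = var_between,
         var_resid = var_resid,
         n_fish = length(unique(ids)),
         reml_loglik = as.numeric(stats::logLik(model))),
    class = "ri_fit")
}

#' @export
print.ri_fit <- function(x, ...) {
  cat("Random-intercept model (REML), ", x$n_fish, " fish\n", sep = "")
  print(x$fixed_coefficients)
  cat(sprintf("  var(between) = %.4g, var(resid) = %.4g, REML logLik = %.4g\n",
              x$var_between, x$var_resid, x$reml_loglik))
  invisible(x)
}

#' @export
#' @method tidy ri_fit
tidy.ri_fit <- function(x, ...) x$fixed_coefficients

#' @export
#' @method glance ri_fit
glance.ri_fit <- function(x, ...) {
  tibble::tibble(var_between = x$var_between, var_resid = x$var_resid,
                 n_fish = x$n_fish, reml_loglik = x$reml_loglik)
}

#' Backward stepwise reduction of a mixed model
#'
#' Starting from a tentative full model, iteratively removes the fixed term
#' with the largest Wald p-value above `alpha` and refits, until every
#' remaining term is significant (the intercept is never dropped, and a term
#' is only dropped when no higher-order interaction containing it remains).
#' The random intercept is dropped only when its variance is estimated as
#' exactly zero, in which case the final refit is ordinary least squares.
#'
#' @param data,formula,fish_id As in [fit_random_intercept()].
#' @param alpha Retention threshold (default 0.05).
#'
#' @return A list: `fit` (an `ri_fit`, or an `lm` if the random intercept was
#'   dropped), `log` (tibble of drop steps: step, dropped, p_value),
#'   `formula` (the reduced fixed-effects formula).
#' @export
backward_select <- function(data, formula, fish_id, alpha = 0.05) {
  fq <- rlang::enquo(fish_id)
  current <- formula
  log <- tibble::tibble(step = integer(), dropped = character(),
                        p_value = numeric())
  step <- 0L
  repeat {
    fit <- fit_random_intercept(data, current, !!fq)
    tab <- fit$fixed_coefficients
    tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
    terms_obj <- stats::terms(current)
    labels <- attr(terms_obj, "term.labels")
    if (!nrow(tab) || !length(labels)) break
    # droppable terms: not marginal to any retained interaction
    droppable <- labels[vapply(labels, function(l) {
      !any(vapply(setdiff(labels, l), function(other) {
        all(strsplit(l, ":")[[1]] %in% strsplit(other, ":")[[1]])
      }, logical(1)))
    }, logical(1))]
    # map coefficient p-values to model terms (max p among a term's coefs)
    assign_idx <- attr(stats::model.matrix(current, data), "assign")
    coefs <- stats::model.matrix(current, data)
    term_p <- vapply(droppable, function(l) {
      cols <- colnames(coefs)[assign_idx == match(l, labels)]
      max(tab$p_value[tab$term %in% cols], na.rm = TRUE)
    }, numeric(1))
    worst <- which.max(term_p)
    if (!length(worst) || term_p[worst] <= alpha) break
    step <- step + 1L
    log <- dplyr::bind_rows(log, tibble::tibble(
      step = step, dropped = droppable[worst], p_value = term_p[worst]))
    current <- stats::update(current,
                             stats::as.formula(paste(". ~ . -",
                                                     droppable[worst])))
  }
  fit <- fit_random_intercept(data, current, !!fq)
  if (fit$var_between == 0) {
    data2 <- as.data.frame(data)
    fit <- lm(current, data = data2)
    log <- dplyr::bind_rows(log, tibble::tibble(
      step = step + 1L, dropped = "(random intercept)", p_value = NA_real_))
  }
  list(fit = fit, log = log, formula = current)
}

#' Pairwise group contrasts with FDR adjustment
#'
#' All pairwise Wald contrasts of group-specific slopes (time trends) or of
#' group means at a stated time, computed on the estimated-marginal-means
#' scale and adjusted across the pair set with the Benjamini-Hochberg false
#' discovery rate (Holm-Sidak available as an alternative). The fitted model
#' must contain a categorical group term; for slope contrasts it must
#' interact with the time covariate.
#'
#' @param model An `ri_fit`, `lmerMod` or `lm` whose formula contains the
#'   grouping factor.
#' @param group Name of the grouping factor (string).
#' @param type `"slope"` for time-trend contrasts (requires `time_var`) or
#'   `"mean"` for group-mean contrasts (optionally `at` a stated time).
#' @param time_var Name of the time covariate (for `type = "slope"` or `at`).
#' @param at Time value at which means are compared (for `type = "mean"`).
#' @param adjust `"BH"` (default) or `"holm-sidak"`.
#'
#' @return A tibble (a contrast table): `pair`, `estimate`, `se`, `p_raw`,
#'   `p_adjusted`, `method`.
#' @export
pairwise_contrasts <- function(model, group, type = c("slope", "mean"),
                               time_var = NULL, at = NULL, adjust = "BH") {
  type <- match.arg(type)
  if (inherits(model, "ri_fit")) model <- model$model
  spec <- stats::as.formula(paste("~", group))
  em <- if (type == "slope") {
    if (is.null(time_var)) abort("`time_var` is required for slope contrasts.")
    emmeans::emtrends(model, spec, var = time_var, lmer.df = "asymptotic")
  } else {
    at_list <- if (!is.null(at)) setNames(list(at), time_var) else NULL
    emmeans::emmeans(model, spec, at = at_list, lmer.df = "asymptotic")
  }
  ct <- summary(emmeans::contrast(em, method = "pairwise", adjust = "none"))
  n_groups <- nrow(summary(em))
  if (n_groups < 2) abort("Need at least 2 groups.")
  p_raw <- ct$p.value
  p_adjusted <- switch(tolower(adjust),
                       bh = p.adjust(p_raw, "BH"),
                       "holm-sidak" = holm_sidak(p_raw),
                       abort("`adjust` must be 'BH' or 'holm-sidak'."))
  tibble::tibble(
    pair = as.character(ct$contrast),
    estimate = ct$estimate,
    se = ct$SE,
    p_raw = p_raw,
    p_adjusted = p_adjusted,
    method = paste0(type, " contrast, ", adjust))
}

#' Holm-Sidak step-down adjusted p-values
#'
#' Step-down Sidak adjustment: with the m p-values sorted ascending, the i-th
#' is adjusted to 1 - (1 - p_(i))^(m - i + 1), then cumulative maxima enforce
#' monotonicity. Equivalent in spirit to Holm's method but using the Sidak
#' inequality, as in common biomedical ANOVA software.
#'
#' @param p Numeric vector of raw p-values.
#'
#' @return Adjusted p-values in the original order.
#' @export
#' @examples
#' holm_sidak(c(0.01, 0.04))
holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Two-way ANOVA with Holm-Sidak pairwise comparisons
#'
#' Type-II sums-of-squares F tests for two crossed factors and their
#' interaction (e.g. day x light phase for metabolic rate), followed by
#' Holm-Sidak-adjusted pairwise comparisons of the levels of each factor
#' within each level of the other, the conventional follow-up family.
#'
#' @param data A data frame.
#' @param value Response column.
#' @param factor_a,factor_b Factor columns.
#'
#' @return A list: `anova` (tibble: term, sumsq, df, statistic, p_value) and
#'   `comparisons` (tibble of within-level pairwise tests with `p_adjusted`).
#' @export
two_way_anova <- function(data, value, factor_a, factor_b) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  a <- factor(rlang::eval_tidy(rlang::enquo(factor_a), data))
  b <- factor(rlang::eval_tidy(rlang::enquo(factor_b), data))
  if (any(table(a, b) < 2)) {
    abort("Every factor-level cell needs at least 2 replicates.")
  }
  d <- data.frame(v = v, a = a, b = b)
  fit <- lm(v ~ a * b, data = d)
  an <- car::Anova(fit, type = 2)
  anova_tab <- tibble::tibble(
    term = rownames(an),
    sumsq = an[["Sum Sq"]],
    df = an[["Df"]],
    statistic = an[["F value"]],
    p_value = an[["Pr(>F)"]])

  # pairwise cell comparisons: levels of one factor within the other
  mse <- sum(resid(fit)^2) / fit$df.residual
  cells <- d |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(mean = mean(.data$v), n = dplyr::n(), .groups = "drop")
  cmp <- list()
  pair_rows <- function(within, lvls, get_cell, label) {
    purrr::map_dfr(within, function(w) {
      combs <- utils::combn(lvls, 2, simplify = FALSE)
      purrr::map_dfr(combs, function(pr) {
        c1 <- get_cell(w, pr[1]); c2 <- get_cell(w, pr[2])
        se <- sqrt(mse * (1 / c1$n + 1 / c2$n))
        tstat <- (c1$mean - c2$mean) / se
        tibble::tibble(
          family = label, within = as.character(w),
          pair = paste(pr, collapse = " vs "),
          estimate = c1$mean - c2$mean, se = se,
          statistic = tstat,
          p_raw = 2 * pt(-abs(tstat), fit$df.residual))
      })
    })
  }
  cmp_a <- pair_rows(levels(b), levels(a),
                     function(w, l) cells[cells$b == w & cells$a == l, ],
                     "factor_a within factor_b")
  cmp_b <- pair_rows(levels(a), levels(b),
                     function(w, l) cells[cells$a == w & cells$b == l, ],
                     "factor_b within factor_a")
  comparisons <- dplyr::bind_rows(cmp_a, cmp_b) |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(p_adjusted = holm_sidak(.data$p_raw)) |>
    dplyr::ungroup()
  list(anova = anova_tab, comparisons = comparisons)
}

#' Paired Student t-test
#'
#' Standard paired t-test on the within-pair differences, used to compare the
#' oxygen consumption of the same fish under two conditions (e.g. fed versus
#' fasted). Pairing is positional: `x[i]` and `y[i]` belong to the same fish.
#' Identical vectors give t = 0, p = 1; nonzero constant differences (zero
#' variance) are an error.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#'
#' @return A tibble: `t`, `df`, `p_value`, `mean_diff`.
#' @export
#' @examples
#' paired_t_test(c(5, 6, 7), c(4, 4, 4))
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 2) abort("Need at least 2 pairs.")
  d <- x - y
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(t = 0, df = length(d) - 1, p_value = 1,
                            mean_diff = 0))
    }
    abort("Zero-variance nonzero differences; the paired t-test is undefined.")
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_diff = unname(tt$estimate))
}
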