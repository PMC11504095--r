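test_that("with no between-fish variance the REML slope equals pooled OLS", {
  set.seed(51)
  d <- expand.grid(fish_id = paste0("f", 1:6), time_min = seq(0, 50, 5))
  d$mo2 <- 100 + 1.26 * d$time_min + rnorm(nrow(d), 0, 3)
  fit <- fit_random_intercept(d, mo2 ~ time_min, fish_id)
  ols <- coef(lm(mo2 ~ time_min, data = d))
  expect_equal(fit$fixed_coefficients$estimate[2], unname(ols[2]),
               tolerance = 1e-8)
  expect_gte(fit$var_between, 0)
})

test_that("REML recovers slope and variance components in simulation", {
  set.seed(52)
  n_fish <- 50
  d <- expand.grid(fish_id = seq_len(n_fish), time_min = seq(0, 95, 5))
  intercepts <- rnorm(n_fish, 100, 10)
  d$mo2 <- intercepts[d$fish_id] + 1.26 * d$time_min + rnorm(nrow(d), 0, 4)
  fit <- fit_random_intercept(d, mo2 ~ time_min, fish_id)
  est <- fit$fixed_coefficients
  slope <- est$estimate[est$term == "time_min"]
  se <- est$se[est$term == "time_min"]
  expect_lt(abs(slope - 1.26), 2 * se)
  expect_lt(abs(fit$var_between - 100) / 100, 0.25)
  expect_equal(glance(fit)$n_fish, n_fish)
})

test_that("singular designs are rejected", {
  d <- data.frame(fish_id = rep(c("a", "b"), each = 2),
                  time_min = rep(3, 4), mo2 = rnorm(4))
  expect_error(fit_random_intercept(d, mo2 ~ time_min, fish_id), "Singular")
  expect_error(fit_random_intercept(d[1:2, ], mo2 ~ 1, fish_id), "2 fish")
})

test_that("backward selection drops null slopes and keeps real ones", {
  set.seed(53)
  d <- expand.grid(fish_id = paste0("f", 1:10), time_min = seq(0, 90, 10))
  d$null_y <- rep(rnorm(10, 100, 5), times = 10) + rnorm(nrow(d), 0, 3)
  null_sel <- backward_select(d, null_y ~ time_min, fish_id)
  expect_true("time_min" %in% null_sel$log$dropped)
  d$strong_y <- rep(rnorm(10, 100, 5), times = 10) + 1.26 * d$time_min +
    rnorm(nrow(d), 0, 3)
  strong_sel <- backward_select(d, strong_y ~ time_min, fish_id)
  expect_false("time_min" %in% strong_sel$log$dropped)
  expect_true("time_min" %in%
                strong_sel$fit$fixed_coefficients$term)
  # intercept-only input: no fixed term can be dropped
  only <- backward_select(d, strong_y ~ 1, fish_id)
  expect_true(all(only$log$dropped %in% "(random intercept)"))
})

test_that("null-slope drop frequency approaches 1 - alpha at large n", {
  set.seed(54)
  dropped <- replicate(60, {
    d <- expand.grid(fish_id = paste0("f", 1:8), time_min = seq(0, 90, 10))
    d$y <- rep(rnorm(8, 100, 5), times = 10) + rnorm(nrow(d), 0, 3)
    sel <- backward_select(d, y ~ time_min, fish_id)
    "time_min" %in% sel$log$dropped
  })
  expect_gt(mean(dropped), 0.85)  # expect about 95%, allow simulation noise
})

test_that("pairwise contrasts collapse to the raw p with two groups", {
  set.seed(55)
  d <- expand.grid(fish_id = paste0("f", 1:6), time_min = seq(0, 50, 10))
  d$group <- ifelse(d$fish_id %in% paste0("f", 1:3), "a", "b")
  d$mo2 <- 100 + 1 * d$time_min + 2 * d$time_min * (d$group == "b") +
    rep(rnorm(6, 0, 4), times = 6) + rnorm(nrow(d), 0, 2)
  fit <- fit_random_intercept(d, mo2 ~ time_min * group, fish_id)
  ct <- pairwise_contrasts(fit, "group", type = "slope",
                           time_var = "time_min")
  expect_equal(nrow(ct), 1)
  expect_equal(ct$p_adjusted, ct$p_raw)
  expect_equal(ct$estimate, -2, tolerance = 3 * ct$se)
})

test_that("a deviant group's contrasts rank smallest; BH never lowers p", {
  set.seed(56)
  d <- expand.grid(fish_id = paste0("f", 1:12), time_min = seq(0, 60, 10))
  d$group <- c("a", "b", "c", "d")[ceiling(match(d$fish_id,
                                                 paste0("f", 1:12)) / 3)]
  slope_shift <- ifelse(d$group == "d", 5, 0)
  d$mo2 <- 100 + (1 + slope_shift) * d$time_min +
    rep(rnorm(12, 0, 3), times = 7) + rnorm(nrow(d), 0, 2)
  fit <- fit_random_intercept(d, mo2 ~ time_min * group, fish_id)
  ct <- pairwise_contrasts(fit, "group", type = "slope",
                           time_var = "time_min")
  expect_equal(nrow(ct), 6)
  has_d <- grepl("d", ct$pair)
  expect_true(max(ct$p_adjusted[has_d]) < min(ct$p_adjusted[!has_d]))
  expect_true(all(ct$p_adjusted >= ct$p_raw - 1e-15))
  expect_equal(order(ct$p_adjusted), order(ct$p_raw))
})

test_that("identical groups produce no significant contrasts", {
  set.seed(57)
  d <- expand.grid(fish_id = paste0("f", 1:12), time_min = seq(0, 60, 10))
  d$group <- c("a", "b", "c")[ceiling(match(d$fish_id,
                                            paste0("f", 1:12)) / 4)]
  d$mo2 <- 100 + 1 * d$time_min + rep(rnorm(12, 0, 3), times = 7) +
    rnorm(nrow(d), 0, 2)
  fit <- fit_random_intercept(d, mo2 ~ time_min * group, fish_id)
  ct <- pairwise_contrasts(fit, "group", type = "slope",
                           time_var = "time_min")
  expect_true(all(ct$p_adjusted > 0.05))
})

test_that("Holm-Sidak follows the step-down formula", {
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - (1 - 0.01)^2, 0.04))
  set.seed(58)
  p <- runif(8)
  adj <- holm_sidak(p)
  expect_true(all(adj >= p - 1e-15))
  # adjusted values are monotone in the order of the raw p-values
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("two-way ANOVA matches hand-computed sums of squares on a 2x2 toy", {
  d <- data.frame(
    a = rep(c("lo", "hi"), each = 4),
    b = rep(rep(c("x", "y"), each = 2), 2),
    v = c(10, 12, 20, 22, 14, 16, 24, 26))
  out <- two_way_anova(d, v, a, b)
  # balanced layout: SS_A = 2n (mean_hi - mean)^2 summed over levels
  gm <- mean(d$v)
  ss_a <- sum(tapply(d$v, d$a, function(x) length(x) * (mean(x) - gm)^2))
  ss_b <- sum(tapply(d$v, d$b, function(x) length(x) * (mean(x) - gm)^2))
  expect_equal(out$anova$sumsq[out$anova$term == "a"], ss_a)
  expect_equal(out$anova$sumsq[out$anova$term == "b"], ss_b)
  expect_equal(out$anova$sumsq[out$anova$term == "a:b"], 0, tolerance = 1e-12)
  expect_true(all(c("p_raw", "p_adjusted") %in% names(out$comparisons)))
  # identical cells: F of everything indistinguishable from 0
  d2 <- d; d2$v <- rep(c(1, 2), 4)
  out2 <- two_way_anova(d2, v, a, b)
  expect_lt(max(out2$anova$statistic, na.rm = TRUE), 1e-10)
  expect_error(two_way_anova(d[1:6, ], v, a, b), "2 replicates")
})

test_that("the paired t-test follows its textbook form and pairing matters", {
  expect_equal(paired_t_test(c(1, 2, 3), c(1, 2, 3)),
               tibble::tibble(t = 0, df = 2, p_value = 1, mean_diff = 0))
  out <- paired_t_test(c(2, 3, 4), c(1, 1, 1))
  expect_equal(out$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(out$df, 2)
  shuffled <- paired_t_test(c(2, 3, 4), c(1, 1, 1)[c(2, 3, 1)])
  expect_equal(out$t, shuffled$t)  # constant y: order cannot matter
  x <- c(5, 9, 7); y <- c(4, 10, 5)
  expect_false(isTRUE(all.equal(paired_t_test(x, y)$t,
                                paired_t_test(x, y[c(2, 1, 3)])$t)))
  expect_error(paired_t_test(c(2, 3), c(1, 2, 3)), "equal length")
  expect_error(paired_t_test(c(2, 3, 4), c(1, 2, 3)), "Zero-variance")
})
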