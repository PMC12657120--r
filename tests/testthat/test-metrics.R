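anchored_fit <- function(p_lo = 0.017, p_hi = 0.0003, x_min = 0, x_max = 300) {
  b0 <- qlogis(p_lo)
  b1 <- (qlogis(p_hi) - b0) / (x_max - x_min) # anchored at both endpoints
  structure(list(b0 = b0, b1 = b1, x_min = x_min, x_max = x_max,
                 floor = 0.001, fitted = TRUE, match_level = 0,
                 lambda = 0, active_constraints = character()),
            class = "dose_response_fit")
}

test_that("risk endpoints evaluate the fitted curve at the dose extremes", {
  fit <- anchored_fit()
  ep <- risk_endpoints(fit)
  expect_equal(ep[["p_min"]], 0.017, tolerance = 1e-12)
  expect_equal(ep[["p_max"]], 0.0003, tolerance = 1e-12)
  flat <- anchored_fit(p_lo = 0.05, p_hi = 0.05)
  epf <- risk_endpoints(flat)
  expect_equal(epf[["p_min"]], epf[["p_max"]])
  # a declining curve has p_min (low-dose risk) > p_max
  expect_true(ep[["p_min"]] > ep[["p_max"]] && fit$b1 < 0)
})

test_that("risk-reduction arithmetic matches its definitions", {
  expect_equal(arr(0.02, 0.01), 0.01)
  expect_equal(arr(0.3, 0.3), 0)
  expect_equal(arr(0.017, 0.0003), 0.0167, tolerance = 1e-12)
  expect_equal(rrr(0.02, 0.01), 0.5)
  expect_equal(rrr(0.4, 0), 1)
  expect_equal(rrr(0.017, 0.0003), 0.0167 / 0.017, tolerance = 1e-12)
  expect_warning(out <- rrr(0, 0), "undefined")
  expect_true(is.na(out))
  expect_equal(err(100, 0.005), 0.5)
  expect_equal(err(0, 0.9), 0)
  expect_equal(err(22, 0.0175), 0.385, tolerance = 1e-12)
  expect_equal(expected_rejections(100, 0.017), 1.7)
})

test_that("metric identities hold to 1e-12 across random endpoint pairs", {
  set.seed(14)
  for (i in 1:50) {
    p_min <- runif(1, 1e-3, 0.5)
    p_max <- runif(1, 1e-4, p_min)
    n <- sample(1:500, 1)
    a <- arr(p_min, p_max)
    expect_lt(abs(rrr(p_min, p_max) * p_min - a), 1e-12)
    expect_lt(abs(err(n, a) / n - a), 1e-12)
    # the gap between the expected-event curves equals the stratum ERR
    gap <- expected_rejections(n, p_min) - expected_rejections(n, p_max)
    expect_lt(abs(gap - err(n, a)), 1e-9)
  }
})

test_that("bootstrap intervals are deterministic and degenerate correctly", {
  same <- list(doses = rep(150, 40), outcomes = rep(1L, 40))
  ci0 <- bootstrap_ci(same$doses, same$outcomes, metric = "arr", B = 100,
                      seed = 2, lambda = 0.1, x_min = 20, x_max = 300)
  expect_equal(ci0$lower, ci0$upper)

  str <- make_stratum(120, -1, -0.004, seed = 77)
  a <- bootstrap_ci(str$doses, str$outcomes, metric = "arr", B = 120,
                    seed = 5, lambda = 1e-4, x_min = 20, x_max = 300)
  b <- bootstrap_ci(str$doses, str$outcomes, metric = "arr", B = 120,
                    seed = 5, lambda = 1e-4, x_min = 20, x_max = 300)
  expect_identical(a[c("lower", "upper")], b[c("lower", "upper")])
  expect_lte(a$lower, a$upper)
  expect_error(bootstrap_ci(str$doses, str$outcomes, B = 50), "B must be")
})

test_that("bootstrap interval width shrinks as the stratum grows", {
  med_width <- vapply(c(50, 200, 800), function(n) {
    widths <- vapply(1:5, function(r) {
      str <- make_stratum(n, -1, -0.004, seed = 7000 + 13 * n + r)
      ci <- bootstrap_ci(str$doses, str$outcomes, metric = "arr", B = 120,
                         seed = r, lambda = 1e-4, x_min = 20, x_max = 300)
      ci$upper - ci$lower
    }, numeric(1))
    median(widths)
  }, numeric(1))
  expect_true(all(diff(med_width) < 0))
})

test_that("delta-method intervals are sane and near the bootstrap at large n", {
  str <- make_stratum(2000, -1, -0.004, seed = 91)
  fit <- fit_constrained(str$doses, str$outcomes, lambda = 1e-4,
                         x_min = 20, x_max = 300)
  d <- delta_ci(str$doses, str$outcomes, fit, metric = "arr")
  expect_gt(d$se, 0)
  expect_lt(d$lower, d$estimate)
  expect_gt(d$upper, d$estimate)
  ci <- bootstrap_ci(str$doses, str$outcomes, metric = "arr", B = 300,
                     seed = 3, lambda = 1e-4, x_min = 20, x_max = 300)
  # same order of magnitude of uncertainty
  expect_lt(abs((d$upper - d$lower) / (ci$upper - ci$lower) - 1), 0.5)
})

test_that("cohort benefit aggregates ERR linearly and ranks strata by total", {
  one <- data.frame(match_level = 0.5, n = 80, err = 1.2)
  cb1 <- cohort_benefit(one)
  expect_equal(cb1$total, 1.2)
  expect_equal(cb1$best_levels, 0.5)

  tab <- data.frame(match_level = c(0.83, 0.33), n = c(22, 100),
                    err = c(err(22, 0.0175), err(100, 0.005)))
  cb <- cohort_benefit(tab)
  # a small high-ARR stratum ranks below a large moderate-ARR stratum
  expect_equal(cb$best_levels, 0.33)
  expect_equal(cb$total, 0.385 + 0.5, tolerance = 1e-12)

  doubled <- transform(tab, n = 2 * n, err = 2 * err)
  expect_equal(cohort_benefit(doubled)$total, 2 * cb$total)
})

test_that("ROC/AUC follows the Mann-Whitney oracle, with ties and symmetry", {
  # perfect separation
  roc <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(roc$auc, 1)
  expect_equal(roc$fpr[1], 0)
  expect_equal(utils::tail(roc$tpr, 1), 1)

  for (seed in 1:5) {
    set.seed(seed + 50)
    n <- sample(20:200, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    labels <- rbinom(n, 1, plogis(3 * scores - 1.5))
    if (length(unique(labels)) < 2) next
    roc <- roc_auc(scores, labels)
    expect_equal(roc$auc, pairwise_auc(scores, labels), tolerance = 1e-12)
    # curve is a proper staircase
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
    expect_equal(c(utils::tail(roc$fpr, 1), utils::tail(roc$tpr, 1)), c(1, 1))
    # negating scores reflects the AUC
    expect_equal(roc_auc(-scores, labels)$auc, 1 - roc$auc,
                 tolerance = 1e-12)
    # independent reference implementation
    expect_equal(roc$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }

  set.seed(4)
  null_auc <- roc_auc(runif(10000), rbinom(10000, 1, 0.5))$auc
  expect_lt(abs(null_auc - 0.5), 0.02)

  expect_warning(und <- roc_auc(runif(5), rep(1, 5)), "single class")
  expect_true(is.na(und$auc))
})

test_that("risk summaries carry consistent per-stratum metrics", {
  co <- generate_cohort(generator_config(
    stratum_sizes = rep(150L, 7L),
    true_params = data.frame(match_level = match_levels(),
                             b0 = qlogis(0.2), b1 = -0.005),
    seed = 29L))
  fits <- fit_all_levels(co, fit_control(lambda_grid = 1e-3, seed = 1L))
  rs <- risk_summary(co, fits, B = 120, seed = 9L)
  expect_identical(nrow(rs), 7L)
  expect_equal(rs$arr, rs$p_min - rs$p_max, tolerance = 1e-12)
  expect_equal(rs$err, rs$n * rs$arr, tolerance = 1e-12)
  expect_equal(rs$rrr_percent, 100 * rs$rrr, tolerance = 1e-12)
  expect_equal(rs$expected_rej_low - rs$expected_rej_high, rs$err,
               tolerance = 1e-9)
  expect_true(all(rs$arr_lo <= rs$arr_hi))
})
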