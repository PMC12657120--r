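test_that("the logistic risk curve is stable, symmetric and anchored", {
  expect_equal(sigmoid_risk(c(0, 150, 300), 0, 0), rep(0.5, 3))
  expect_equal(sigmoid_risk(0, qlogis(0.017), -0.2), 0.017, tolerance = 1e-14)
  # saturation without overflow at |linear predictor| = 700
  expect_equal(sigmoid_risk(700, 0, 1), 1)
  expect_equal(sigmoid_risk(700, 0, -1), 0)
  # symmetry under sign flip of both parameters
  x <- seq(20, 300, by = 35)
  expect_equal(sigmoid_risk(x, -1.3, 0.004) + sigmoid_risk(x, 1.3, -0.004),
               rep(1, length(x)), tolerance = 1e-12)
})

test_that("the penalized objective equals NLL plus ridge, via a naive loop", {
  expect_equal(penalized_nll(0, 0, 150, 1, lambda = 0), log(2),
               tolerance = 1e-12)
  set.seed(12)
  doses <- runif(25, 20, 300)
  outcomes <- rbinom(25, 1, 0.4)
  for (par in list(c(0.5, -0.01, 0), c(-2, 0.003, 0.7), c(1, 0, 10))) {
    naive <- 0
    for (i in seq_along(doses)) {
      p <- 1 / (1 + exp(-(par[1] + par[2] * doses[i])))
      naive <- naive - (outcomes[i] * log(p) + (1 - outcomes[i]) * log(1 - p))
    }
    naive <- naive + par[3] * (par[1]^2 + par[2]^2)
    expect_equal(penalized_nll(par[1], par[2], doses, outcomes, par[3]),
                 naive, tolerance = 1e-10)
    # lambda = 0 reduces exactly to the unpenalized NLL
    expect_equal(penalized_nll(par[1], par[2], doses, outcomes, 0),
                 naive - par[3] * (par[1]^2 + par[2]^2), tolerance = 1e-10)
  }
  expect_error(penalized_nll(0, 0, 1:3, 1:2), "length")
  expect_error(penalized_nll(0, 0, 1, 2), "0/1")
})

test_that("unpenalized slack-constraint fits match the IRLS (glm) oracle", {
  for (seed in 1:5) {
    str <- make_stratum(300, -0.5, -0.004, seed = seed + 40)
    fit <- fit_constrained(str$doses, str$outcomes, lambda = 0)
    ref <- glm(str$outcomes ~ str$doses, family = binomial)
    expect_equal(fit$b0, unname(coef(ref)[1]), tolerance = 1e-5)
    expect_equal(fit$b1, unname(coef(ref)[2]), tolerance = 1e-7)
    expect_length(fit$active_constraints, 0)
    expect_true(fit$converged)
  }
})

test_that("the probability floor binds exactly when data push risk below it", {
  set.seed(5)
  doses <- c(runif(30, 20, 100), runif(30, 200, 300))
  outcomes <- c(rep(1L, 30), rep(0L, 30))  # separable: risk collapses at high dose
  fit <- fit_constrained(doses, outcomes, lambda = 1e-8,
                         x_min = 20, x_max = 300)
  p_hi <- sigmoid_risk(300, fit$b0, fit$b1)
  expect_lt(abs(p_hi - fit$floor), 1e-6)
  expect_true("x_max" %in% fit$active_constraints)
  expect_gte(sigmoid_risk(20, fit$b0, fit$b1), fit$floor - 1e-9)
})

test_that("the constrained optimum is unique across starting points", {
  set.seed(6)
  str <- make_stratum(60, -1.5, -0.005, seed = 6)
  costs <- vapply(list(NULL, c(0, 0), c(2, -0.05), c(-5, 0.01)),
                  function(ini) fit_constrained(str$doses, str$outcomes,
                                                lambda = 0.01,
                                                init = ini)$cost,
                  numeric(1))
  expect_lt(max(costs) - min(costs), 1e-6)
})

test_that("ridge shrinkage is monotone along a lambda ladder", {
  str <- make_stratum(120, -1, -0.004, seed = 17)
  ladder <- 10^seq(-4, 2, by = 1)
  norms <- vapply(ladder, function(lam) {
    f <- fit_constrained(str$doses, str$outcomes, lambda = lam)
    f$b0^2 + f$b1^2
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("the fitted curve is monotone with the sign of the slope", {
  str <- make_stratum(200, -1, -0.006, seed = 23)
  fit <- fit_constrained(str$doses, str$outcomes, lambda = 1e-3)
  grid <- seq(20, 300, by = 5)
  curve <- sigmoid_risk(grid, fit$b0, fit$b1)
  expect_true(all(sign(diff(curve)) == sign(fit$b1)))
})

test_that("lambda selection is deterministic, honors singleton grids and ties", {
  str <- make_stratum(80, -1, -0.004, seed = 31)
  expect_equal(as.numeric(select_lambda(str$doses, str$outcomes,
                                        grid = 0.37, seed = 1)), 0.37)
  l1 <- select_lambda(str$doses, str$outcomes, seed = 99)
  l2 <- select_lambda(str$doses, str$outcomes, seed = 99)
  expect_identical(l1, l2)
  # a duplicated grid value cannot select the larger duplicate
  ld <- select_lambda(str$doses, str$outcomes, grid = c(0.1, 0.1), seed = 5)
  expect_equal(as.numeric(ld), 0.1)
  expect_error(select_lambda(str$doses[1:3], str$outcomes[1:3],
                             k_folds = 5), "k_folds")
})

test_that("separation drives the selected ridge weight off the grid minimum", {
  hits <- vapply(1:20, function(seed) {
    set.seed(seed + 600)
    doses <- runif(30, 20, 300)
    outcomes <- as.integer(doses < median(doses))
    lam <- suppressWarnings(select_lambda(doses, outcomes, seed = seed + 600,
                                          x_min = 20, x_max = 300))
    as.numeric(lam) > min(fit_control()$lambda_grid)
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("fit_all_levels returns one ordered fit per stratum", {
  co <- generate_cohort(generator_config(seed = 3L))
  ctrl <- fit_control(lambda_grid = 10^seq(-3, 1, by = 1), seed = 8L)
  fits <- suppressWarnings(fit_all_levels(co, ctrl))
  expect_length(fits, 7L)
  expect_equal(vapply(fits, function(f) f$match_level, numeric(1)),
               match_levels(), ignore_attr = TRUE)
  expect_true(all(vapply(fits, function(f) isTRUE(f$fitted), logical(1))))
  # floor respected at the cohort-wide dose bounds in every stratum
  for (f in fits) {
    expect_gte(sigmoid_risk(f$x_min, f$b0, f$b1), f$floor - 1e-9)
    expect_gte(sigmoid_risk(f$x_max, f$b0, f$b1), f$floor - 1e-9)
  }
})

test_that("an empty stratum yields a placeholder and the rest proceed", {
  cfg <- generator_config(stratum_sizes = c(60L, 95L, 0L, 105L, 95L, 22L, 42L),
                          seed = 4L)
  co <- generate_cohort(cfg)
  fits <- suppressWarnings(fit_all_levels(
    co, fit_control(lambda_grid = c(0.01, 1), seed = 2L)))
  fitted_flags <- vapply(fits, function(f) isTRUE(f$fitted), logical(1))
  expect_identical(sum(fitted_flags), 6L)
  expect_false(fits[["0.33"]]$fitted)
})

test_that("slope signs are stable across disjoint half-cohorts", {
  tp <- data.frame(match_level = match_levels(), b0 = qlogis(0.25),
                   b1 = -0.006)
  agree <- vapply(1:20, function(seed) {
    cfg <- generator_config(stratum_sizes = rep(400L, 7L), true_params = tp,
                            seed = seed + 300)
    co <- generate_cohort(cfg)
    set.seed(seed)
    half <- sample(nrow(co), nrow(co) / 2)
    ctrl <- fit_control(lambda_grid = 10^seq(-3, 1, by = 1), seed = seed)
    f1 <- fit_all_levels(co[half, ], ctrl)
    f2 <- fit_all_levels(co[-half, ], ctrl)
    all(vapply(1:7, function(g) sign(f1[[g]]$b1) == sign(f2[[g]]$b1),
               logical(1)))
  }, logical(1))
  expect_gt(mean(agree), 0.5)
})

test_that("quasi-separated strata are flagged but still fit within the floor", {
  doses <- runif(30, 20, 300)
  fit <- fit_constrained(doses, rep(0L, 30), lambda = 0.1,
                         x_min = 20, x_max = 300)
  expect_true(fit$quasi_separated)
  expect_gte(sigmoid_risk(20, fit$b0, fit$b1), fit$floor - 1e-9)
  expect_gte(sigmoid_risk(300, fit$b0, fit$b1), fit$floor - 1e-9)
})

test_that("standardized fitting reports coefficients back on the mg scale", {
  co <- generate_cohort(generator_config(
    stratum_sizes = rep(300L, 7L),
    true_params = data.frame(match_level = match_levels(),
                             b0 = qlogis(0.2), b1 = -0.005),
    seed = 19L))
  raw <- fit_all_levels(co, fit_control(lambda_grid = 1e-6, seed = 1L))
  std <- fit_all_levels(co, fit_control(lambda_grid = 1e-6, seed = 1L,
                                        standardize = TRUE))
  # with a negligible penalty the two parametrizations coincide
  for (g in 1:7) {
    expect_equal(std[[g]]$b0, raw[[g]]$b0, tolerance = 1e-4)
    expect_equal(std[[g]]$b1, raw[[g]]$b1, tolerance = 1e-4)
  }
})
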