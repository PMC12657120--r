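# Constrained, ridge-penalized logistic dose-response model.
#
# Per match stratum the rejection probability is p(x) = plogis(b0 + b1*x)
# with dose x in raw mg. The fit minimizes the penalized negative
# log-likelihood subject to probability-floor constraints
#   p(x_min) >= floor  and  p(x_max) >= floor,
# which keep predicted risks clinically plausible at the dose extremes.
# Each floor constraint is a half-plane in (b0, b1) (the logit is linear in
# the parameters), so the feasible region is convex and the penalized NLL
# is convex: the optimum is unique and lies either in the interior, on one
# constraint line, or at their intersection. The solver exploits exactly
# that geometry: a damped Newton step for the interior, a 1-D Newton search
# along each constraint line, and the vertex (qlogis(floor), 0); the
# feasible candidate with the lowest cost wins.

#' Logistic rejection-risk curve
#'
#' `1 / (1 + exp(-(b0 + b1 * dose)))`, numerically stable for linear
#' predictors of magnitude up to several hundred (it saturates smoothly at
#' 0 and 1).
#'
#' @param dose Dose in mg (any finite numeric vector).
#' @param b0 Intercept: log-odds of rejection at dose 0.
#' @param b1 Slope: change in log-odds per mg.
#' @return Probabilities in `(0, 1)` (possibly 0/1 at extreme saturation).
#' @export
#' @examples
#' sigmoid_risk(150, 0, 0)           # 0.5
#' sigmoid_risk(0, qlogis(0.017), -0.01)
sigmoid_risk <- function(dose, b0, b1) {
  if (any(!is.finite(dose)) || any(!is.finite(b0)) || any(!is.finite(b1))) {
    stop("inputs must be finite", call. = FALSE)
  }
  stats::plogis(b0 + b1 * dose)
}

#' Ridge-penalized negative log-likelihood
#'
#' The fitting objective: the Bernoulli negative log-likelihood of the
#' outcomes under the logistic dose-response curve, plus the ridge penalty
#' `lambda * (b0^2 + b1^2)` (optionally excluding the intercept).
#' Per-observation probabilities are clipped to `[eps, 1 - eps]` before
#' taking logs, so the cost stays finite under complete saturation.
#'
#' @param b0,b1 Curve parameters.
#' @param doses Numeric vector of doses (mg).
#' @param outcomes Binary vector (0/1), same length as `doses`.
#' @param lambda Ridge weight, `>= 0`.
#' @param eps Probability clip for the log terms.
#' @param penalize_intercept Include `b0^2` in the penalty (default TRUE,
#'   matching the written form of the objective).
#' @return The scalar cost.
#' @export
penalized_nll <- function(b0, b1, doses, outcomes, lambda = 0,
                          eps = 1e-12, penalize_intercept = TRUE) {
  if (length(doses) != length(outcomes)) {
    stop("doses and outcomes must have the same length", call. = FALSE)
  }
  if (!all(outcomes %in% c(0, 1))) {
    stop("outcomes must be 0/1", call. = FALSE)
  }
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  p <- stats::plogis(b0 + b1 * doses)
  p <- pmin(pmax(p, eps), 1 - eps)
  nll <- -sum(outcomes * log(p) + (1 - outcomes) * log(1 - p))
  nll + lambda * (b1^2 + if (penalize_intercept) b0^2 else 0)
}

#' Control parameters for dose-response fitting
#'
#' @param lambda_grid Candidate ridge weights for cross-validated selection
#'   (default: 13 log-spaced points from 1e-4 to 100).
#' @param k_folds Cross-validation folds.
#' @param floor Minimum admissible predicted risk at the dose extremes.
#' @param x_min,x_max Dose bounds used for the floor constraints and risk
#'   endpoints; `NULL` means use the cohort-wide observed dose range.
#' @param fallback_lambda Ridge weight used when a stratum cannot support
#'   cross-validation (too few events); default is the smallest grid value,
#'   so data-poor strata get a near-maximum-likelihood fit contained by the
#'   floor constraints rather than a shrinkage artifact (a heavy intercept
#'   penalty on the raw mg scale would drag the baseline risk toward 0.5
#'   while leaving the slope essentially free).
#' @param eps Probability clip in the likelihood.
#' @param tol Convergence tolerance on the cost.
#' @param max_iter Newton iteration cap.
#' @param penalize_intercept Include the intercept in the ridge penalty.
#' @param standardize Fit on doses centred and scaled by the cohort mean/sd
#'   (coefficients are reported back on the raw mg scale). Default off: the
#'   objective is written on the raw scale.
#' @param shared_lambda Select a single ridge weight on the pooled cohort
#'   instead of per stratum.
#' @param seed Seed for fold assignment (and per-stratum substreams in
#'   [fit_all_levels()]).
#' @return A `fit_control` list.
#' @export
fit_control <- function(lambda_grid = 10^seq(-4, 2, length.out = 13L),
                        k_folds = 5L, floor = 0.001,
                        x_min = NULL, x_max = NULL,
                        fallback_lambda = NULL,
                        eps = 1e-12, tol = 1e-10, max_iter = 100L,
                        penalize_intercept = TRUE, standardize = FALSE,
                        shared_lambda = FALSE, seed = 1L) {
  if (is.null(lambda_grid) || length(lambda_grid) == 0L) {
    stop("fit control field 'lambda_grid' must be a nonempty numeric vector",
         call. = FALSE)
  }
  if (any(lambda_grid < 0)) stop("lambda_grid must be >= 0", call. = FALSE)
  if (k_folds < 2L) stop("k_folds must be >= 2", call. = FALSE)
  if (!(floor > 0 && floor < 0.5)) {
    stop("floor must be in (0, 0.5)", call. = FALSE)
  }
  if (is.null(fallback_lambda)) {
    fallback_lambda <- min(lambda_grid)
  }
  structure(list(lambda_grid = sort(lambda_grid), k_folds = as.integer(k_folds),
                 floor = floor, x_min = x_min, x_max = x_max,
                 fallback_lambda = fallback_lambda, eps = eps, tol = tol,
                 max_iter = as.integer(max_iter),
                 penalize_intercept = penalize_intercept,
                 standardize = standardize, shared_lambda = shared_lambda,
                 seed = as.integer(seed)),
            class = "fit_control")
}

# Damped Newton minimization of the penalized NLL from a given start.
.newton_fit <- function(b, doses, outcomes, lambda, eps, tol, max_iter,
                        penalize_intercept) {
  X <- cbind(1, doses)
  pen <- 2 * lambda * c(if (penalize_intercept) 1 else 0, 1)
  cost <- function(b) penalized_nll(b[1L], b[2L], doses, outcomes, lambda,
                                    eps, penalize_intercept)
  cur <- cost(b)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- X %*% b
    p <- stats::plogis(eta)
    w <- as.numeric(p * (1 - p))
    grad <- crossprod(X, p - outcomes) + pen * b
    H <- crossprod(X, X * w) + diag(pen + 1e-12, 2L)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    if (sum(grad * step) < tol) {  # Newton decrement: at the optimum
      converged <- TRUE
      break
    }
    t <- 1
    repeat {
      cand <- b - t * as.numeric(step)
      new <- cost(cand)
      if (new <= cur + 1e-12 || t < 1e-10) break
      t <- t / 2
    }
    if (new > cur) break
    gain <- cur - new
    b <- cand
    cur <- new
    if (gain < tol) {
      converged <- TRUE
      break
    }
  }
  list(b = b, cost = cur, converged = converged)
}

# Minimize the penalized NLL restricted to the constraint line
# b0 + b1 * xc = qlogis(floor): a 1-D problem in b1, convex before the
# probability clip. The clip flattens the objective far from the data into
# plateaus that can strand a pure golden search, so a coarse scan (dense
# where the likelihood is informative) brackets the basin first; golden
# search plus Newton polish then sharpen the minimum.
.line_fit <- function(xc, L, doses, outcomes, lambda, eps,
                      penalize_intercept) {
  g <- function(b1) penalized_nll(L - b1 * xc, b1, doses, outcomes, lambda,
                                  eps, penalize_intercept)
  scan <- sort(unique(c(seq(-20, 20, by = 0.5), seq(-0.6, 0.6, by = 0.005))))
  eta <- outer(doses - xc, scan) + L
  p <- pmin(pmax(stats::plogis(eta), eps), 1 - eps)
  nll <- -colSums(outcomes * log(p) + (1 - outcomes) * log(1 - p))
  b0s <- L - scan * xc
  vals <- nll + lambda * (scan^2 + if (penalize_intercept) b0s^2 else 0)
  k <- which.min(vals)
  lo <- scan[max(1L, k - 1L)]
  hi <- scan[min(length(scan), k + 1L)]
  opt <- stats::optimize(g, lower = lo, upper = hi, tol = 1e-12)
  b1 <- opt$minimum
  # Newton polish along the line; direction d = (-xc, 1)
  X <- cbind(1, doses)
  pen <- 2 * lambda * c(if (penalize_intercept) 1 else 0, 1)
  d <- c(-xc, 1)
  for (i in 1:8) {
    b <- c(L - b1 * xc, b1)
    eta <- X %*% b
    p <- stats::plogis(eta)
    w <- as.numeric(p * (1 - p))
    grad <- as.numeric(crossprod(X, p - outcomes) + pen * b)
    H <- crossprod(X, X * w) + diag(pen + 1e-12, 2L)
    g1 <- sum(grad * d)
    g2 <- as.numeric(t(d) %*% H %*% d)
    if (!is.finite(g1) || !is.finite(g2) || g2 <= 0) break
    step <- g1 / g2
    b1_new <- b1 - step
    if (g(b1_new) <= g(b1)) b1 <- b1_new else break
    if (abs(step) < 1e-14) break
  }
  c(L - b1 * xc, b1)
}

#' Fit the constrained ridge-penalized logistic dose-response model
#'
#' Minimizes [penalized_nll()] over `(b0, b1)` subject to the probability
#' floor at both dose extremes: `sigmoid_risk(x_min) >= floor` and
#' `sigmoid_risk(x_max) >= floor`. The objective is convex and the feasible
#' region is an intersection of two half-planes, so the unique optimum is
#' found exactly by comparing the interior Newton solution (when feasible)
#' with the minima along each constraint boundary and the vertex where both
#' constraints meet.
#'
#' @param doses Numeric vector of doses (mg).
#' @param outcomes Binary 0/1 vector.
#' @param lambda Ridge weight `>= 0`.
#' @param floor Minimum admissible predicted risk at the extremes.
#' @param x_min,x_max Dose extremes for the constraints (default: observed
#'   range of `doses`).
#' @param control A [fit_control()] (supplies `eps`, `tol`, `max_iter`,
#'   `penalize_intercept`).
#' @param init Optional starting value `c(b0, b1)`; the default starts at
#'   the intercept-only fit `(qlogis(clamped mean outcome), 0)`.
#' @return A `dose_response_fit`: list with `b0`, `b1`, `lambda`, `floor`,
#'   `x_min`, `x_max`, `cost`, `converged`, `active_constraints` (subset of
#'   `c("x_min", "x_max")`), `quasi_separated`, `n`, `n_events`.
#' @export
fit_constrained <- function(doses, outcomes, lambda = 0, floor = 0.001,
                            x_min = min(doses), x_max = max(doses),
                            control = fit_control(), init = NULL) {
  if (length(doses) != length(outcomes)) {
    stop("doses and outcomes must have the same length", call. = FALSE)
  }
  if (length(doses) < 1L) stop("need at least one observation", call. = FALSE)
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be 0/1", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  L <- stats::qlogis(floor)
  eps <- control$eps
  pi_ <- control$penalize_intercept
  cost <- function(b) penalized_nll(b[1L], b[2L], doses, outcomes, lambda,
                                    eps, pi_)
  feasible <- function(b) {
    b[1L] + b[2L] * x_min >= L - 1e-9 && b[1L] + b[2L] * x_max >= L - 1e-9
  }
  if (is.null(init)) {
    ybar <- mean(outcomes)
    init <- c(stats::qlogis(min(max(ybar, floor), 1 - 1e-6)), 0)
  }

  interior <- .newton_fit(init, doses, outcomes, lambda, eps, control$tol,
                          control$max_iter, pi_)

  candidates <- list()
  if (feasible(interior$b)) {
    candidates[["interior"]] <- list(b = interior$b, cost = interior$cost,
                                     converged = interior$converged)
  }
  # a feasible unconstrained optimum is the constrained optimum (convexity);
  # the boundary search is needed only when the interior fails or escapes
  need_boundary <- !(feasible(interior$b) && interior$converged)
  for (side in if (need_boundary) c("x_min", "x_max") else character()) {
    xc <- if (side == "x_min") x_min else x_max
    b <- .line_fit(xc, L, doses, outcomes, lambda, eps, pi_)
    if (feasible(b)) {
      candidates[[side]] <- list(b = b, cost = cost(b), converged = TRUE)
    }
  }
  candidates[["vertex"]] <- list(b = c(L, 0), cost = cost(c(L, 0)),
                                 converged = TRUE)

  costs <- vapply(candidates, function(c.) c.$cost, numeric(1L))
  best <- candidates[[which.min(costs)]]
  converged <- best$converged
  if (!converged) {
    warning("dose-response fit did not converge (lambda = ", lambda, ")",
            call. = FALSE)
  }
  b <- best$b
  # active constraints: slack below ~1e-6 on the probability scale
  eta_tol <- 1e-6 / (floor * (1 - floor))
  active <- c("x_min", "x_max")[
    c(b[1L] + b[2L] * x_min - L, b[1L] + b[2L] * x_max - L) <= eta_tol]

  structure(list(match_level = NA_real_, b0 = b[1L], b1 = b[2L],
                 lambda = lambda, floor = floor,
                 x_min = x_min, x_max = x_max,
                 cost = best$cost, converged = converged,
                 active_constraints = active,
                 quasi_separated = length(unique(outcomes)) < 2L,
                 n = length(doses), n_events = sum(outcomes),
                 fitted = TRUE),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!isTRUE(x$fitted)) {
    cat("Dose-response fit (match level ", format(x$match_level),
        "): no data, not fitted\n", sep = "")
    return(invisible(x))
  }
  cat("Constrained ridge logistic dose-response fit\n")
  if (!is.na(x$match_level)) {
    cat("  match level:", format(x$match_level), "\n")
  }
  cat(sprintf("  b0 = %.6f, b1 = %.6g, lambda = %g\n", x$b0, x$b1, x$lambda))
  cat(sprintf("  n = %d (%d events); risk at [%g, %g] mg: %.5f -> %.5f\n",
              x$n, x$n_events, x$x_min, x$x_max,
              sigmoid_risk(x$x_min, x$b0, x$b1),
              sigmoid_risk(x$x_max, x$b0, x$b1)))
  if (length(x$active_constraints) > 0L) {
    cat("  active floor constraint(s):",
        paste(x$active_constraints, collapse = ", "), "\n")
  }
  if (x$quasi_separated) cat("  flag: quasi-separated (single-class outcomes)\n")
  if (!x$converged) cat("  flag: NOT converged\n")
  invisible(x)
}

#' Select the ridge weight by cross-validation
#'
#' For each candidate `lambda`, performs k-fold cross-validation with
#' outcome-stratified folds (shuffled by `seed`): the model is fit on the
#' training folds with the floor constraints, and scored by the mean
#' unpenalized negative log-likelihood per held-out observation. Returns
#' the `lambda` minimizing the mean held-out loss, breaking ties toward the
#' smaller value. Folds whose training part contains a single outcome class
#' are skipped with a warning.
#'
#' @inheritParams fit_constrained
#' @param grid Candidate ridge weights.
#' @param k_folds Number of folds.
#' @param seed Seed for the fold shuffle.
#' @return The selected `lambda`, with attribute `cv_loss` (named mean
#'   held-out loss per grid value).
#' @export
select_lambda <- function(doses, outcomes, grid = fit_control()$lambda_grid,
                          k_folds = 5L, seed = 1L, floor = 0.001,
                          x_min = min(doses), x_max = max(doses),
                          control = fit_control()) {
  n <- length(doses)
  if (length(grid) == 0L) stop("grid must be nonempty", call. = FALSE)
  if (k_folds < 2L) stop("k_folds must be >= 2", call. = FALSE)
  if (n < k_folds) stop("need at least k_folds observations", call. = FALSE)
  grid <- sort(grid)
  set.seed(seed)
  fold <- integer(n)
  for (cls in unique(outcomes)) {
    idx <- which(outcomes == cls)
    fold[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
  }
  loss <- matrix(NA_real_, nrow = k_folds, ncol = length(grid))
  for (k in seq_len(k_folds)) {
    test <- fold == k
    if (length(unique(outcomes[!test])) < 2L || !any(test)) {
      warning("fold ", k, " skipped: single outcome class in training data",
              call. = FALSE)
      next
    }
    for (j in seq_along(grid)) {
      fit <- fit_constrained(doses[!test], outcomes[!test], lambda = grid[j],
                             floor = floor, x_min = x_min, x_max = x_max,
                             control = control)
      loss[k, j] <- penalized_nll(fit$b0, fit$b1, doses[test],
                                  outcomes[test], lambda = 0,
                                  eps = control$eps) / sum(test)
    }
  }
  if (all(is.na(loss))) {
    stop("all cross-validation folds were skipped", call. = FALSE)
  }
  mean_loss <- colMeans(loss, na.rm = TRUE)
  out <- grid[which.min(mean_loss)]
  attr(out, "cv_loss") <- stats::setNames(mean_loss, format(grid))
  out
}

#' Fit the dose-response model for every match stratum
#'
#' One constrained ridge fit per encoded match level, each with its own
#' cross-validated ridge weight (or a single pooled weight when
#' `control$shared_lambda` is TRUE). Dose extremes default to the
#' cohort-wide observed range, so all strata are compared at common low-
#' and high-dose points. Strata that cannot support cross-validation
#' (fewer than two records of either outcome class, or fewer records than
#' folds) are fit with `control$fallback_lambda`; empty strata yield an
#' unfitted placeholder.
#'
#' @param cohort A `transplant_cohort` with complete `dose_mg` and
#'   `rejected` values.
#' @param control A [fit_control()].
#' @return List of 7 `dose_response_fit` objects ordered by match level.
#' @export
fit_all_levels <- function(cohort, control = fit_control()) {
  stopifnot(inherits(cohort, "transplant_cohort"),
            inherits(control, "fit_control"))
  if (anyNA(cohort$dose_mg) || anyNA(cohort$rejected)) {
    stop("cohort has missing dose or outcome values; ",
         "complete the data before fitting", call. = FALSE)
  }
  lv <- match_levels()
  idx <- cohort_strata(cohort)
  x_min <- if (is.null(control$x_min)) min(cohort$dose_mg) else control$x_min
  x_max <- if (is.null(control$x_max)) max(cohort$dose_mg) else control$x_max

  # internal standardization: fit on z = (x - m)/s, map back to raw mg
  std_m <- 0
  std_s <- 1
  if (isTRUE(control$standardize)) {
    std_m <- mean(cohort$dose_mg)
    std_s <- stats::sd(cohort$dose_mg)
    if (!is.finite(std_s) || std_s == 0) std_s <- 1
  }
  tr <- function(x) (x - std_m) / std_s
  z_min <- tr(x_min)
  z_max <- tr(x_max)

  set.seed(control$seed)
  substream <- sample.int(.Machine$integer.max - 1L, 8L)

  shared <- NULL
  if (isTRUE(control$shared_lambda)) {
    keep <- !is.na(cohort$match_fraction)
    shared <- select_lambda(tr(cohort$dose_mg[keep]), cohort$rejected[keep],
                            grid = control$lambda_grid,
                            k_folds = control$k_folds, seed = substream[8L],
                            floor = control$floor,
                            x_min = z_min, x_max = z_max, control = control)
  }

  fits <- vector("list", 7L)
  names(fits) <- as.character(lv)
  for (g in seq_len(7L)) {
    rows <- idx[[g]]
    if (length(rows) == 0L) {
      fits[[g]] <- structure(list(match_level = lv[g], b0 = NA_real_,
                                  b1 = NA_real_, lambda = NA_real_,
                                  floor = control$floor, x_min = x_min,
                                  x_max = x_max, cost = NA_real_,
                                  converged = NA, active_constraints = character(),
                                  quasi_separated = NA, n = 0L, n_events = 0L,
                                  fitted = FALSE),
                             class = "dose_response_fit")
      next
    }
    z <- tr(cohort$dose_mg[rows])
    y <- cohort$rejected[rows]
    cv_ok <- length(rows) >= control$k_folds && min(table(y)) >= 2L &&
      length(unique(y)) == 2L
    lam <- if (!is.null(shared)) {
      as.numeric(shared)
    } else if (cv_ok) {
      as.numeric(select_lambda(z, y, grid = control$lambda_grid,
                               k_folds = control$k_folds,
                               seed = substream[g], floor = control$floor,
                               x_min = z_min, x_max = z_max,
                               control = control))
    } else {
      control$fallback_lambda
    }
    fit <- fit_constrained(z, y, lambda = lam, floor = control$floor,
                           x_min = z_min, x_max = z_max, control = control)
    # back-transform to the raw mg scale
    fit$b1 <- fit$b1 / std_s
    fit$b0 <- fit$b0 - fit$b1 * std_m
    fit$x_min <- x_min
    fit$x_max <- x_max
    fit$match_level <- lv[g]
    fit$cv_used <- is.null(shared) && cv_ok
    fits[[g]] <- fit
  }
  fits
}
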