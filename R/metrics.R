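# Derived risk quantities: ARR, RRR, ERR, expected rejections at the dose
# bounds, bootstrap confidence intervals, cohort benefit, and ROC/AUC
# discrimination.
#
# Naming note: following field convention for these dose-response summaries,
# p_min is the fitted risk at the LOWER dose x_min and p_max the risk at the
# UPPER dose x_max. With a protective (negative-slope) curve p_min is the
# larger of the two probabilities, so the subscripts index the dose, not the
# magnitude of the risk.

#' Fitted risk at the dose extremes
#'
#' @param fit A `dose_response_fit`.
#' @param x_min,x_max Dose extremes (default: the fit's own bounds, at which
#'   the floor constraints guarantee both risks `>= floor - 1e-9`).
#' @return Named vector `c(p_min = ..., p_max = ...)`: fitted risk at the
#'   lower and upper dose.
#' @export
risk_endpoints <- function(fit, x_min = fit$x_min, x_max = fit$x_max) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (!isTRUE(fit$fitted)) {
    return(c(p_min = NA_real_, p_max = NA_real_))
  }
  c(p_min = sigmoid_risk(x_min, fit$b0, fit$b1),
    p_max = sigmoid_risk(x_max, fit$b0, fit$b1))
}

#' Absolute risk reduction
#'
#' `p_min - p_max`: the drop in fitted rejection risk when moving from the
#' lower to the upper dose. Negative if the fitted curve increases with
#' dose.
#'
#' @param p_min Fitted risk at the lower dose, in `[0, 1]`.
#' @param p_max Fitted risk at the upper dose, in `[0, 1]`.
#' @return The risk difference.
#' @export
arr <- function(p_min, p_max) {
  stopifnot(all(p_min >= 0 & p_min <= 1), all(p_max >= 0 & p_max <= 1))
  p_min - p_max
}

#' Relative risk reduction
#'
#' `(p_min - p_max) / p_min`: the fraction of the low-dose (baseline) risk
#' eliminated by the upper dose. Undefined when `p_min = 0` (which the
#' probability floor prevents in fitted curves); returned as `NA` with a
#' warning rather than an error so a pipeline run is never killed by one
#' degenerate stratum.
#'
#' @inheritParams arr
#' @return The fraction (multiply by 100 for the percent form).
#' @export
rrr <- function(p_min, p_max) {
  stopifnot(all(p_min >= 0 & p_min <= 1), all(p_max >= 0 & p_max <= 1))
  out <- ifelse(p_min > 0, (p_min - p_max) / p_min, NA_real_)
  if (anyNA(out)) {
    warning("relative risk reduction undefined where p_min = 0",
            call. = FALSE)
  }
  out
}

#' Expected rejection reduction
#'
#' `n * (p_min - p_max)`: the expected number of rejection events prevented
#' in a stratum of size `n` by using the upper rather than the lower dose.
#' Reported as a real number (fractional expected events).
#'
#' @param n Stratum size, `>= 0`.
#' @param arr_value Absolute risk reduction.
#' @return Expected prevented events.
#' @export
err <- function(n, arr_value) {
  stopifnot(all(n >= 0))
  n * arr_value
}

#' Expected rejection count at a fixed risk
#'
#' `n * p`: expected rejections in a stratum of size `n` at per-patient
#' risk `p`. Evaluated at `p_min` and `p_max` this gives the low- and
#' high-dose expected-event curves whose gap equals [err()].
#'
#' @param n Stratum size, `>= 0`.
#' @param p Rejection probability in `[0, 1]`.
#' @return Expected event count.
#' @export
expected_rejections <- function(n, p) {
  stopifnot(all(n >= 0), all(p >= 0 & p <= 1))
  n * p
}

# Recompute arr and rrr on B case-resamples of one stratum.
.boot_metrics <- function(doses, outcomes, lambda, floor, x_min, x_max,
                          control, B, seed) {
  n <- length(doses)
  set.seed(seed)
  out <- matrix(NA_real_, nrow = B, ncol = 2L,
                dimnames = list(NULL, c("arr", "rrr")))
  for (b in seq_len(B)) {
    take <- sample.int(n, n, replace = TRUE)
    fit <- fit_constrained(doses[take], outcomes[take], lambda = lambda,
                           floor = floor, x_min = x_min, x_max = x_max,
                           control = control)
    ep <- risk_endpoints(fit)
    out[b, "arr"] <- ep[["p_min"]] - ep[["p_max"]]
    out[b, "rrr"] <- if (ep[["p_min"]] > 0) {
      (ep[["p_min"]] - ep[["p_max"]]) / ep[["p_min"]]
    } else NA_real_
  }
  out
}

#' Bootstrap confidence interval for a stratum risk metric
#'
#' Nonparametric case-resampling bootstrap: `B` resamples of the stratum
#' records (with replacement, original size), a constrained refit on each
#' (at the same ridge weight as the full-data fit), and the percentile
#' interval of the recomputed metric. Resamples on which the metric is
#' undefined are dropped and counted; the interval is flagged unreliable if
#' more than half are dropped.
#'
#' @param doses,outcomes The stratum data.
#' @param metric `"arr"` or `"rrr"`.
#' @param B Number of resamples (`>= 100`).
#' @param seed Resampling seed.
#' @param level Interval level in `(0, 1)`.
#' @param lambda,floor,x_min,x_max,control Passed to [fit_constrained()].
#' @return A `bootstrap_ci`: list with `lower`, `upper`, `level`, `metric`,
#'   `B`, `n_undefined`, `unreliable`.
#' @export
bootstrap_ci <- function(doses, outcomes, metric = c("arr", "rrr"),
                         B = 1000L, seed = 1L, level = 0.95,
                         lambda = 0, floor = 0.001,
                         x_min = min(doses), x_max = max(doses),
                         control = fit_control()) {
  metric <- match.arg(metric)
  if (B < 100L) stop("B must be >= 100", call. = FALSE)
  if (!(level > 0 && level < 1)) stop("level must be in (0,1)", call. = FALSE)
  vals <- .boot_metrics(doses, outcomes, lambda, floor, x_min, x_max,
                        control, B, seed)[, metric]
  n_undef <- sum(is.na(vals))
  alpha <- (1 - level) / 2
  qs <- stats::quantile(vals, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  structure(list(lower = qs[1L], upper = qs[2L], level = level,
                 metric = metric, B = B, n_undefined = n_undef,
                 unreliable = n_undef > B / 2),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("%.0f%% percentile bootstrap CI for %s: [%.6g, %.6g] (B = %d%s)\n",
              100 * x$level, x$metric, x$lower, x$upper, x$B,
              if (x$unreliable) ", UNRELIABLE" else ""))
  invisible(x)
}

#' Delta-method confidence interval for a stratum risk metric
#'
#' Large-sample alternative to the bootstrap: the coefficient covariance is
#' the inverse penalized-likelihood Hessian at the fitted optimum and the
#' metric variance follows from its analytic gradient. Only valid when the
#' floor constraints are slack at the optimum; a warning is issued
#' otherwise, since the interval ignores the constraints.
#'
#' @inheritParams bootstrap_ci
#' @param fit The full-data `dose_response_fit` for this stratum.
#' @return List with `lower`, `upper`, `se`, `estimate`, `level`.
#' @export
delta_ci <- function(doses, outcomes, fit, metric = c("arr", "rrr"),
                     level = 0.95) {
  metric <- match.arg(metric)
  stopifnot(inherits(fit, "dose_response_fit"), isTRUE(fit$fitted))
  if (length(fit$active_constraints) > 0L) {
    warning("floor constraint active: delta-method interval ignores it",
            call. = FALSE)
  }
  X <- cbind(1, doses)
  p <- stats::plogis(fit$b0 + fit$b1 * doses)
  H <- crossprod(X, X * (p * (1 - p))) + diag(2 * fit$lambda, 2L)
  V <- solve(H)
  pmin_ <- sigmoid_risk(fit$x_min, fit$b0, fit$b1)
  pmax_ <- sigmoid_risk(fit$x_max, fit$b0, fit$b1)
  dmin <- pmin_ * (1 - pmin_) * c(1, fit$x_min)
  dmax <- pmax_ * (1 - pmax_) * c(1, fit$x_max)
  if (metric == "arr") {
    est <- pmin_ - pmax_
    grad <- dmin - dmax
  } else {
    est <- (pmin_ - pmax_) / pmin_
    grad <- (pmax_ / pmin_^2) * dmin - dmax / pmin_
  }
  se <- sqrt(as.numeric(t(grad) %*% V %*% grad))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(lower = est - z * se, upper = est + z * se, se = se,
       estimate = est, level = level)
}

#' Per-stratum risk summary table
#'
#' Combines the fitted dose-response curves with the stratum sizes into the
#' headline risk table: fitted risks at the dose extremes, absolute and
#' relative risk reduction, expected rejection reduction, expected event
#' counts at each dose, and (optionally) bootstrap confidence intervals for
#' ARR and RRR computed from shared resamples.
#'
#' @param cohort The `transplant_cohort` the fits came from.
#' @param fits List of 7 `dose_response_fit` objects from
#'   [fit_all_levels()].
#' @param B Bootstrap resamples per stratum (used when `ci = TRUE`).
#' @param seed Master bootstrap seed (spawns one substream per stratum).
#' @param level CI level.
#' @param ci Compute bootstrap intervals (set FALSE to skip the resampling).
#' @param control A [fit_control()] for the bootstrap refits.
#' @return A `risk_summary` data frame, one row per match level.
#' @export
risk_summary <- function(cohort, fits, B = 1000L, seed = 1L, level = 0.95,
                         ci = TRUE, control = fit_control()) {
  stopifnot(inherits(cohort, "transplant_cohort"), length(fits) == 7L)
  idx <- cohort_strata(cohort)
  lv <- match_levels()
  set.seed(seed)
  substream <- sample.int(.Machine$integer.max - 1L, 7L)
  rows <- vector("list", 7L)
  for (g in seq_len(7L)) {
    fit <- fits[[g]]
    n_g <- length(idx[[g]])
    if (!isTRUE(fit$fitted)) {
      rows[[g]] <- data.frame(match_level = lv[g], n = n_g,
                              p_min = NA_real_, p_max = NA_real_,
                              arr = NA_real_, rrr = NA_real_,
                              rrr_percent = NA_real_, err = NA_real_,
                              expected_rej_low = NA_real_,
                              expected_rej_high = NA_real_,
                              arr_lo = NA_real_, arr_hi = NA_real_,
                              rrr_lo = NA_real_, rrr_hi = NA_real_)
      next
    }
    ep <- risk_endpoints(fit)
    a <- arr(ep[["p_min"]], ep[["p_max"]])
    r <- if (ep[["p_min"]] > 0) a / ep[["p_min"]] else NA_real_
    cis <- c(arr_lo = NA_real_, arr_hi = NA_real_,
             rrr_lo = NA_real_, rrr_hi = NA_real_)
    if (ci && n_g > 0L) {
      vals <- .boot_metrics(cohort$dose_mg[idx[[g]]],
                            cohort$rejected[idx[[g]]],
                            lambda = fit$lambda, floor = fit$floor,
                            x_min = fit$x_min, x_max = fit$x_max,
                            control = control, B = B, seed = substream[g])
      alpha <- (1 - level) / 2
      qa <- stats::quantile(vals[, "arr"], c(alpha, 1 - alpha),
                            na.rm = TRUE, names = FALSE)
      qr <- stats::quantile(vals[, "rrr"], c(alpha, 1 - alpha),
                            na.rm = TRUE, names = FALSE)
      cis <- c(arr_lo = qa[1L], arr_hi = qa[2L],
               rrr_lo = qr[1L], rrr_hi = qr[2L])
    }
    rows[[g]] <- data.frame(match_level = lv[g], n = n_g,
                            p_min = ep[["p_min"]], p_max = ep[["p_max"]],
                            arr = a, rrr = r, rrr_percent = 100 * r,
                            err = err(n_g, a),
                            expected_rej_low = expected_rejections(
                              n_g, ep[["p_min"]]),
                            expected_rej_high = expected_rejections(
                              n_g, ep[["p_max"]]),
                            arr_lo = cis[["arr_lo"]], arr_hi = cis[["arr_hi"]],
                            rrr_lo = cis[["rrr_lo"]], rrr_hi = cis[["rrr_hi"]])
  }
  out <- do.call(rbind, rows)
  attr(out, "ci_level") <- level
  class(out) <- c("risk_summary", "data.frame")
  out
}

#' Aggregate cohort benefit of high-dose therapy
#'
#' Brings together per-patient risk reduction and stratum size: the
#' expected rejection reduction (ERR) per match level, their grand total,
#' and the level(s) where switching the whole stratum to the upper dose
#' prevents the most events.
#'
#' @param summaries A `risk_summary` (or data frame with `match_level`,
#'   `n`, `err`).
#' @return A `cohort_benefit`: list with `table` (match_level, n, err),
#'   `total`, `best_levels`.
#' @export
cohort_benefit <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("match_level", "n", "err") %in% names(summaries)))
  tab <- data.frame(match_level = summaries$match_level, n = summaries$n,
                    err = summaries$err)
  total <- sum(tab$err, na.rm = TRUE)
  ok <- !is.na(tab$err)
  best <- tab$match_level[ok][tab$err[ok] == max(tab$err[ok])]
  structure(list(table = tab, total = total, best_levels = best),
            class = "cohort_benefit")
}

#' @export
print.cohort_benefit <- function(x, ...) {
  cat("Cohort benefit of high-dose therapy (expected rejections prevented)\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("Total: %.4g; largest benefit at match level(s): %s\n",
              x$total, paste(format(x$best_levels), collapse = ", ")))
  invisible(x)
}

#' ROC curve and AUC of fitted risks against observed outcomes
#'
#' Sweeps a threshold over the unique score values in descending order
#' (tied scores grouped at one threshold), accumulating the stepwise
#' false-positive and true-positive rates from `(0, 0)` to `(1, 1)`, and
#' integrates the area under the curve by the trapezoidal rule (equivalent
#' to the Mann-Whitney probability that a random positive outscores a
#' random negative, counting ties as one half).
#'
#' @param scores Numeric risk scores (e.g. pooled per-patient fitted
#'   risks).
#' @param labels Binary 0/1 outcomes.
#' @return A `roc_curve`: list with `thresholds`, `fpr`, `tpr`, `auc`. With
#'   single-class labels the AUC is `NA` (undefined) and the curve empty.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    warning("AUC undefined: labels contain a single class", call. = FALSE)
    return(structure(list(thresholds = numeric(), fpr = numeric(),
                          tpr = numeric(), auc = NA_real_),
                     class = "roc_curve"))
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  n <- length(s)
  last_of_tie <- c(s[-n] != s[-1L], TRUE)
  tp <- cumsum(y)[last_of_tie]
  fp <- cumsum(1 - y)[last_of_tie]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(thresholds = c(Inf, s[last_of_tie]), fpr = fpr, tpr = tpr,
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  if (is.na(x$auc)) {
    cat("ROC curve: AUC undefined (single-class labels)\n")
  } else {
    cat(sprintf("ROC curve: %d thresholds, AUC = %.4f\n",
                length(x$thresholds), x$auc))
  }
  invisible(x)
}
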