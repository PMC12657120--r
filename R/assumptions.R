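# Validation stage: per-stratum normality, variance homogeneity, and the
# one-way ANOVA of mean dose across match strata. All tests are advisory:
# the pipeline reports and flags but never aborts on them.

#' Upper-tail probability of the F distribution
#'
#' `P(F(df1, df2) > f)`, the p-value of an observed F statistic.
#'
#' @param f Observed statistic, `>= 0`.
#' @param df1,df2 Numerator and denominator degrees of freedom, `>= 1`.
#' @return Upper-tail probability in `[0, 1]`.
#' @export
#' @examples
#' f_survival(0.932969, 6, 512)
f_survival <- function(f, df1, df2) {
  if (any(!is.finite(f)) || any(f < 0)) {
    stop("f must be finite and >= 0", call. = FALSE)
  }
  if (any(df1 < 1) || any(df2 < 1)) {
    stop("degrees of freedom must be >= 1", call. = FALSE)
  }
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

.new_anova_table <- function(ss_between, ss_within, df_between, df_within) {
  if (df_within < 1L) {
    stop("degenerate input: no within-group degrees of freedom", call. = FALSE)
  }
  ms_between <- ss_between / df_between
  ms_within <- ss_within / df_within
  if (ms_within <= 0) {
    stop("degenerate input: within-group mean square is zero ",
         "(all observations identical within groups)", call. = FALSE)
  }
  f_stat <- ms_between / ms_within
  structure(list(
    ss_between = ss_between, ss_within = ss_within,
    ss_total = ss_between + ss_within,
    df_between = as.integer(df_between), df_within = as.integer(df_within),
    df_total = as.integer(df_between + df_within),
    ms_between = ms_between, ms_within = ms_within,
    f_stat = f_stat,
    p_value = f_survival(f_stat, df_between, df_within)
  ), class = "anova_table")
}

#' One-way analysis of variance on dose groups
#'
#' Decomposes the total sum of squares of the pooled observations into
#' between-group and within-group components by the definitional two-pass
#' formula (group means first, then squared deviations), and returns the F
#' statistic `MS_between / MS_within` with its upper-tail p-value.
#'
#' @param groups List of numeric vectors, one per group (at least two
#'   groups, each nonempty, at least one with two or more observations).
#' @return An `anova_table` with fields `ss_between`, `ss_within`,
#'   `ss_total`, `df_between`, `df_within`, `df_total`, `ms_between`,
#'   `ms_within`, `f_stat`, `p_value`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  n_g <- vapply(groups, length, integer(1L))
  if (any(n_g < 1L)) stop("every group must be nonempty", call. = FALSE)
  all_x <- unlist(groups, use.names = FALSE)
  if (anyNA(all_x)) stop("groups must not contain NA", call. = FALSE)
  k <- length(groups)
  n <- length(all_x)
  grand <- mean(all_x)
  means <- vapply(groups, mean, numeric(1L))
  ss_between <- sum(n_g * (means - grand)^2)
  ss_within <- sum(vapply(seq_len(k),
                          function(g) sum((groups[[g]] - means[g])^2),
                          numeric(1L)))
  .new_anova_table(ss_between, ss_within, k - 1L, n - k)
}

#' Complete an ANOVA table from its sum-of-squares decomposition
#'
#' Given the between- and within-group sums of squares and their degrees of
#' freedom (as printed in a standard ANOVA table), fills in the mean
#' squares, F statistic and p-value. Useful for re-deriving published table
#' entries without the underlying data.
#'
#' @param ss_between,ss_within Sums of squares.
#' @param df_between,df_within Degrees of freedom.
#' @return An `anova_table`.
#' @export
#' @examples
#' anova_from_ss(12391.47, 1133377, df_between = 6, df_within = 512)
anova_from_ss <- function(ss_between, ss_within, df_between, df_within) {
  stopifnot(ss_between >= 0, ss_within >= 0,
            df_between >= 1, df_within >= 1)
  .new_anova_table(ss_between, ss_within, df_between, df_within)
}

#' @export
print.anova_table <- function(x, ...) {
  df <- as.data.frame(x)
  cat("One-way ANOVA\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.anova_table <- function(x, ...) {
  data.frame(
    Source = c("Between groups", "Within groups", "Total"),
    SS = c(x$ss_between, x$ss_within, x$ss_total),
    df = c(x$df_between, x$df_within, x$df_total),
    MS = c(x$ms_between, x$ms_within, NA_real_),
    F = c(x$f_stat, NA_real_, NA_real_),
    p = c(x$p_value, NA_real_, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA applied to the absolute deviations of each observation
#' from its group's center. The classic test centers on the group mean;
#' `center = "median"` gives the Brown-Forsythe variant.
#'
#' @param groups List of numeric vectors, one per group, each with at least
#'   two observations.
#' @param center `"mean"` (default) or `"median"`.
#' @return A `group_test` with `statistic` (F), `df` (df1, df2), `p_value`.
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  n_g <- vapply(groups, length, integer(1L))
  if (any(n_g < 2L)) {
    stop("every group must have at least two observations", call. = FALSE)
  }
  cfun <- if (center == "mean") mean else stats::median
  dev <- lapply(groups, function(x) abs(x - cfun(x)))
  at <- one_way_anova(dev)
  structure(list(test = "Levene", center = center,
                 statistic = at$f_stat,
                 df = c(at$df_between, at$df_within),
                 p_value = at$p_value),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(x$test, " test: statistic = ", format(x$statistic),
      ", df = (", x$df[1L], ", ", x$df[2L], "), p = ",
      format(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Shapiro-Wilk normality test per match stratum
#'
#' Applies the Shapiro-Wilk test to the doses of each match stratum. The
#' test supports group sizes 3--5000; strata outside that range are marked
#' not-applicable rather than aborting, and results are always advisory
#' (ANOVA is robust to non-normality at these group sizes, so the pipeline
#' proceeds regardless).
#'
#' @param cohort A `transplant_cohort`.
#' @return Data frame with one row per match level: `match_level`, `n`,
#'   `W`, `p_value`, `applicable`.
#' @export
shapiro_wilk_by_stratum <- function(cohort) {
  stopifnot(inherits(cohort, "transplant_cohort"))
  idx <- cohort_strata(cohort)
  lv <- match_levels()
  rows <- lapply(seq_along(lv), function(g) {
    dose <- cohort$dose_mg[idx[[g]]]
    dose <- dose[!is.na(dose)]
    n <- length(dose)
    if (n < 3L || n > 5000L || length(unique(dose)) == 1L) {
      data.frame(match_level = lv[g], n = n, W = NA_real_,
                 p_value = NA_real_, applicable = FALSE)
    } else {
      sw <- stats::shapiro.test(dose)
      data.frame(match_level = lv[g], n = n, W = unname(sw$statistic),
                 p_value = sw$p.value, applicable = TRUE)
    }
  })
  do.call(rbind, rows)
}
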