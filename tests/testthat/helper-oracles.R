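# Independent oracles used across the suite. Each recomputes a quantity by
# a route disjoint from the implementation it checks.

# Exhaustive-grid oracle for the constrained penalized fit. The search runs
# over (eta_lo, eta_hi), the linear predictor at the two dose extremes -- an
# affine reparametrization of (b0, b1) in which the cost stays convex, the
# floor constraints become the box eta >= qlogis(floor), and the surface is
# well conditioned. Coarse scan, then local refinement down to step < 1e-6.
grid_oracle_cost <- function(doses, outcomes, lambda, floor = 0.001,
                             x_min = 20, x_max = 300) {
  L <- qlogis(floor)
  span <- x_max - x_min
  n <- length(doses)
  eval_grid <- function(los, his) {
    g <- expand.grid(lo = los, hi = his)
    b1 <- (g$hi - g$lo) / span
    b0 <- g$lo - b1 * x_min
    eta <- matrix(b0, nrow = n, ncol = nrow(g), byrow = TRUE) +
      doses %*% t(b1)
    p <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
    nll <- -colSums(outcomes * log(p) + (1 - outcomes) * log(1 - p))
    list(g = g, cost = nll + lambda * (b0^2 + b1^2))
  }
  res <- eval_grid(seq(L, 20, by = 0.1), seq(L, 20, by = 0.1))
  best <- res$g[which.min(res$cost), ]
  step <- 0.1
  while (step > 1e-7) {
    step <- step / 8
    los <- unique(pmax(L, seq(best$lo - 20 * step, best$lo + 20 * step,
                              by = step)))
    his <- unique(pmax(L, seq(best$hi - 20 * step, best$hi + 20 * step,
                              by = step)))
    res <- eval_grid(los, his)
    best <- res$g[which.min(res$cost), ]
  }
  min(res$cost)
}

# Mann-Whitney pairwise-comparison oracle for the AUC: the probability that
# a random positive outscores a random negative, ties counting one half.
pairwise_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Small random stratum with a logistic dose-response outcome.
make_stratum <- function(n, b0, b1, seed, lo = 20, hi = 300) {
  set.seed(seed)
  doses <- runif(n, lo, hi)
  list(doses = doses,
       outcomes = rbinom(n, 1, plogis(b0 + b1 * doses)))
}
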