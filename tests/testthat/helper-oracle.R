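# Independent Clopper-Pearson oracle: invert the exact binomial tail
# probabilities by bisection, never touching the beta quantile route the
# package uses. lower solves P(X >= k | p) = alpha/2, upper solves
# P(X <= k | p) = alpha/2.
cp_bisect <- function(k, n, conf_level = 0.95, tol = 1e-12) {
  alpha <- 1 - conf_level
  bisect <- function(f, lo, hi) {
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (k == 0) 0 else {
    # P(X >= k | p) increases in p; find p with tail = alpha/2
    bisect(function(p) (1 - pbinom(k - 1, n, p)) - alpha / 2, 0, 1)
  }
  upper <- if (k == n) 1 else {
    # P(X <= k | p) decreases in p
    bisect(function(p) (alpha / 2) - pbinom(k, n, p), 0, 1)
  }
  c(lower = lower, upper = upper)
}

# brute-force predictive values: evaluate expected counts on a large
# deterministic population instead of the Bayes formula
pv_brute <- function(se, sp, prev, pop = 1e6) {
  d <- prev * pop
  nd <- pop - d
  tp <- d * se; fn <- d * (1 - se)
  tn <- nd * sp; fp <- nd * (1 - sp)
  c(ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}
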