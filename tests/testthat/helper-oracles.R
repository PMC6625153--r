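# Independent oracles used to cross-check the implementation paths.

# Two-sided Fisher p by direct hypergeometric enumeration over all tables
# with the observed margins (probability-mass rule).
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Grid-search maximizer of the grouped binomial log-likelihood for the
# per-allele logistic model, refined iteratively; independent of glm.
logistic_grid_oracle <- function(cases, controls, dose = 0:2) {
  loglik <- function(al, be) {
    eta <- al + be * dose
    sum(cases * eta - (cases + controls) * log1p(exp(eta)))
  }
  center <- c(0, 0); width <- 8
  for (iter in 1:14) {
    al_grid <- seq(center[1] - width, center[1] + width, length.out = 31)
    be_grid <- seq(center[2] - width, center[2] + width, length.out = 31)
    ll <- outer(al_grid, be_grid, Vectorize(loglik))
    best <- arrayInd(which.max(ll), dim(ll))
    center <- c(al_grid[best[1]], be_grid[best[2]])
    width <- width * 0.25
  }
  c(alpha = center[1], beta = center[2])
}

# Direct product-limit estimate by explicit risk-set enumeration; censored
# subjects at a tied time remain at risk for the events at that time.
km_oracle <- function(times, events) {
  ev_times <- sort(unique(times[as.logical(events)]))
  surv <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_i <- sum(times >= t)
    d_i <- sum(times == t & as.logical(events))
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  data.frame(time = ev_times, surv = surv)
}

# absolute-difference comparison against a printed (possibly truncated) value
expect_close <- function(actual, printed, tol) {
  testthat::expect_lt(abs(unname(actual) - printed), tol)
}

# small toy cohort for I/O and aggregation tests
toy_cohort <- function() {
  cohort(
    subject_id = sprintf("t%02d", 1:10),
    group = rep(c("case", "control"), 5),
    gstm1 = c("null", "present", "null", "null", "present",
              "null", "present", "missing", "null", "present"),
    smoking = c("smoker", "nonsmoker", "missing", "smoker", "nonsmoker",
                "missing", "smoker", "nonsmoker", "missing", "smoker"),
    age = c(40, 50, NA, 61, 38, 45, 52, 47, 59, 44))
}
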