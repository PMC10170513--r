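test_that("acceleration factor matches closed forms", {
  ## null bias: alpha is identically 1
  tr0 <- fake_traj(rep(0, 50))
  a0 <- acceleration_factor(tr0)
  expect_equal(a0$alpha, rep(1, 50))

  ## constant bias c: alpha = exp(beta c) at every record
  beta <- 1.2; cc <- 2.5
  trc <- fake_traj(rep(cc, 30))
  ac <- acceleration_factor(trc, beta = beta)
  expect_equal(ac$alpha, rep(exp(beta * cc), 30), tolerance = 1e-12)

  ## linear ramp V_j = j delta (j = 0, 1, ...): geometric-series oracle
  beta <- 1; delta <- 0.05
  n <- 150
  trl <- fake_traj((seq_len(n) - 1) * delta)
  al <- acceleration_factor(trl, beta = beta)
  for (k in c(11, 101)) {   # records covering j = 0..10 and j = 0..100
    expected <- (exp(beta * delta * k) - 1) / (exp(beta * delta) - 1) / k
    expect_equal(al$alpha[k], expected, tolerance = 1e-10)
  }

  expect_error(acceleration_factor(fake_traj(numeric(0))), "invalid input")
  expect_error(acceleration_factor(fake_traj(c(1, -0.5))), "invalid input")
})

test_that("alpha accumulates stably in log space for huge beta V", {
  tr <- fake_traj(seq(0, 1000, length.out = 20))
  a <- acceleration_factor(tr, beta = 1)
  expect_true(all(is.finite(a$log_alpha)))
  ## the running mean is dominated by the last (largest) term
  expect_equal(a$log_alpha[20], 1000 - log(20), tolerance = 1e-6)
})

test_that("alpha is non-decreasing while the bias is non-decreasing", {
  set.seed(14)
  for (rep in 1:10) {
    v <- cumsum(runif(80, 0, 0.4))
    a <- acceleration_factor(fake_traj(v), beta = 1.68)
    expect_true(all(diff(a$log_alpha) >= -1e-12))
  }
})

test_that("transition time is the alpha maximum with boundary semantics", {
  mk <- function(la) {
    structure(data.frame(time = seq_along(la), log_alpha = la,
                         alpha = exp(la), bound = TRUE),
              class = c("alpha_series", "data.frame"))
  }
  rising <- mk(seq(0, 2, length.out = 60))
  tt <- transition_time(rising)
  expect_false(tt$converged)
  expect_equal(tt$t_star, 60)

  peak <- mk(c(seq(0, 3, length.out = 50), seq(2.9, 1, length.out = 30)))
  tt2 <- transition_time(peak)
  expect_true(tt2$converged)
  expect_equal(tt2$t_star, 50)

  tie <- mk(c(0, 2, 1, 2, 0))
  expect_equal(transition_time(tie)$t_star, 2)   # earliest of equal maxima
})

test_that("RT_calcd multiplies alpha by the transition time with units", {
  ## unbiased limit: alpha = 1 recovers the transition time itself
  e1 <- rt_calcd(1, 123)
  expect_equal(e1$rt_ps, 123)
  expect_equal(e1$rt_min, 123 / 6e13)

  e2 <- rt_calcd(1e6, 100)
  expect_equal(e2$rt_ps, 1e8)
  expect_equal(e2$log10_rt_min, log10(1e8 / 6e13))

  expect_error(rt_calcd(0.5, 100), "invalid input")
  expect_error(rt_calcd(2, 0), "invalid input")

  ## zeroed bias end to end: RT_calcd equals t*
  tr <- fake_traj(rep(0, 40))
  a <- acceleration_factor(tr)
  ## alpha flat at 1: maximum at the first record by the earliest-tie rule
  tt <- transition_time(a)
  est <- rt_calcd(tt$alpha_max, tt$t_star, converged = tt$converged)
  expect_equal(est$rt_ps, tt$t_star)
})

test_that("t_metad reads the first unbound record and flags censoring", {
  tr1 <- fake_traj(rep(0.1, 5), unbound = c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(t_metad(tr1)$time_ps, 1)

  tr2 <- fake_traj(rep(0.1, 5), status = "max_time_reached")
  res2 <- t_metad(tr2)
  expect_true(res2$censored)
  expect_true(is.na(res2$t_metad_ns))

  tr3 <- fake_traj(rep(0.1, 8), times = seq(2, 16, by = 2),
                   unbound = c(rep(FALSE, 5), TRUE, FALSE, TRUE))
  expect_equal(t_metad(tr3)$time_ps, 12)
  expect_equal(t_metad(tr3)$t_metad_ns, 0.012)
})

test_that("replica aggregation uses the geometric mean and log-scale SEM", {
  same <- aggregate_replicas(rep(7, 6))
  expect_equal(same$tau, 7)
  expect_equal(same$sem, 0)

  two <- aggregate_replicas(c(10, 1000))
  expect_equal(two$mean, 2)
  expect_equal(two$tau, 100)
  expect_equal(two$sem, sd(c(1, 3)) / sqrt(2))

  arith <- aggregate_replicas(c(10, 1000), kind = "arithmetic")
  expect_equal(arith$tau, 505)

  expect_error(aggregate_replicas(c(1, -2)), "invalid input")
  expect_error(aggregate_replicas(numeric(0)), "invalid input")

  ## lognormal draws: tau estimates the distribution median
  set.seed(77)
  v <- stats::rlnorm(10, meanlog = log(50), sdlog = 0.8)
  ag <- aggregate_replicas(v)
  expect_lt(abs(log10(ag$tau) - log10(50)), 3 * ag$sem)
})

test_that("ECD and the Poisson curve follow their definitions", {
  e1 <- ecd(5)
  expect_equal(e1$value, 5)
  expect_equal(e1$prob, 1)

  e4 <- ecd(c(3, 1, 4, 2))
  expect_equal(e4$value, 1:4)
  expect_equal(e4$prob, c(0.25, 0.5, 0.75, 1))

  edup <- ecd(c(2, 2, 1))
  expect_equal(edup$value, c(1, 2, 2))
  expect_equal(edup$prob, c(1, 2, 3) / 3)

  expect_equal(as.numeric(poisson_cdf(0, 3)), 0)
  expect_equal(as.numeric(poisson_cdf(3 * log(2), 3)), 0.5)
  expect_equal(as.numeric(poisson_cdf(1e6, 3)), 1)
  expect_equal(attr(poisson_cdf(1, 2, mode = "as_printed"), "mode"),
               "as_printed")
})

test_that("the exponentiality check behaves across regimes", {
  ## near-perfect exponential quantiles
  q <- stats::qexp((1:20 - 0.5) / 20, rate = 2)
  res <- exponentiality_check(q)
  expect_lt(res$statistic, 0.1)
  expect_gt(res$p_value, 0.9)

  ## degenerate constant sample is maximally non-exponential
  resc <- exponentiality_check(rep(1, 10))
  expect_gt(resc$statistic, 0.6)
  expect_lt(resc$p_value, 0.01)

  ## with the rate fitted from the sample the asymptotic p-value is
  ## conservative: the nominal-level rejection rate stays below 5%
  set.seed(123)
  rej <- vapply(seq_len(200), function(i) {
    exponentiality_check(stats::rexp(10, rate = 0.3))$p_value < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.05)
})

test_that("the unpaired t-test matches the pooled-variance formula", {
  same <- unpaired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  a <- c(1, 2, 3); b <- c(2, 4, 6)
  res <- unpaired_t_test(a, b)
  ## hand calculation: sp2 = (2*1 + 2*4)/4 = 2.5,
  ## t = -2 / sqrt(2.5 * 2/3) = -sqrt(12/5)
  expect_equal(res$t, -sqrt(12 / 5), tolerance = 1e-10)
  expect_equal(res$dof, 4)
  ## independent cross-check against the reference implementation
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)

  swapped <- unpaired_t_test(b, a)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p_value, res$p_value)

  ## degenerate: zero variance, unequal means
  degen <- unpaired_t_test(c(1, 1), c(2, 2))
  expect_true(is.infinite(degen$t))
  expect_equal(degen$p_value, 0)
  expect_equal(degen$stars, "***")
  expect_equal(unpaired_t_test(c(1, 2), c(1.1, 2.1))$stars, "ns")
})
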