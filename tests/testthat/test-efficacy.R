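test_that("partial likelihood matches the risk-set enumeration oracle", {
  # one treated event at day 1, one control at day 2: L(psi) = psi/(psi+1)
  ll <- cox_partial_loglik(c(1, 2), c(1, 1), c(1, 0), c(1, 1.75))
  expect_equal(exp(ll), c(0.5, 1.75 / 2.75), tolerance = 1e-12)

  set.seed(11)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    time <- round(rexp(n, 0.1), 3) + 0.001
    event <- rbinom(n, 1, 0.8)
    group <- rbinom(n, 1, 0.5)
    if (!any(event == 1) || length(unique(group)) < 2) next
    for (psi in c(1, 1.75)) {
      expect_equal(cox_partial_loglik(time, event, group, psi),
                   log(oracle_partial_lik(time, event, group, psi)),
                   tolerance = 1e-8)
    }
  }
})

test_that("partial likelihood agrees with the survival package at fixed hazard ratios", {
  skip_if_not_installed("survival")
  set.seed(21)
  for (i in 1:50) {
    n <- sample(6:20, 1)
    time <- rexp(n, 0.05)
    event <- rbinom(n, 1, 0.7)
    group <- rbinom(n, 1, 0.5)
    if (sum(event) == 0 || length(unique(group)) < 2) next
    for (psi in c(1, 1.75)) {
      fit <- survival::coxph(survival::Surv(time, event) ~ group,
                             init = log(psi),
                             control = survival::coxph.control(iter.max = 0))
      expect_equal(cox_partial_loglik(time, event, group, psi),
                   fit$loglik[2], tolerance = 1e-8)
    }
  }
})

test_that("partial likelihood is rank-invariant and flat without contrasts", {
  set.seed(5)
  time <- rexp(10, 0.1); event <- rbinom(10, 1, 0.8)
  group <- rep(0:1, 5)
  base <- cox_partial_loglik(time, event, group, 1.75)
  for (f in list(function(t) t^2, function(t) 3 * t + 1, sqrt)) {
    expect_equal(cox_partial_loglik(f(time), event, group, 1.75), base)
  }
  # single-group data carries no information about the hazard ratio
  flat <- cox_partial_loglik(time, event, rep(1, 10), c(1, 2, 5))
  expect_equal(as.numeric(flat), c(0, 0, 0))
  expect_true(attr(flat, "flat"))
})

test_that("posterior efficacy follows the two-point-prior formula", {
  # treated event before control event: L(1.75) = 1.75/2.75, L(1) = 1/2,
  # so pi = 0.63636/(0.63636 + 0.5) = 0.560
  expect_equal(posterior_efficacy(c(1, 2), c(1, 1), c(1, 0),
                                  two_point_prior(1.75, 0.5)),
               0.560, tolerance = 1e-3)
  # control event first: L(1.75) = 1/2.75, pi = 0.36364/0.86364 = 0.421
  expect_equal(posterior_efficacy(c(1, 2), c(1, 1), c(0, 1),
                                  two_point_prior(1.75, 0.5)),
               0.42105, tolerance = 1e-4)
  # equal likelihoods return the prior
  expect_equal(posterior_efficacy(c(1, 2), c(1, 0), c(1, 1),
                                  two_point_prior(1.75, 0.5)), 0.5)
})

test_that("changing the prior shifts the posterior log-odds exactly", {
  set.seed(3)
  time <- rexp(20, 0.1); event <- rbinom(20, 1, 0.7); group <- rep(0:1, 10)
  for (pi_new in c(0.25, 0.5, 0.75)) {
    p1 <- posterior_efficacy(time, event, group, two_point_prior(1.75, 0.5))
    p2 <- posterior_efficacy(time, event, group,
                             two_point_prior(1.75, pi_new))
    expect_equal(log(p2 / (1 - p2)) - log(p1 / (1 - p1)),
                 log(pi_new / (1 - pi_new)) - log(0.5 / 0.5),
                 tolerance = 1e-10)
  }
})

test_that("boundary translation under a prior change is the exact logit shift", {
  b <- boundaries(0.224, 0.839, 11)
  expect_equal(shift_boundaries_for_prior(b, 0.5, 0.5)[c("l", "u")],
               b[c("l", "u")])
  b2 <- shift_boundaries_for_prior(b, 0.5, 0.75)
  expect_equal(b2$l, 0.464, tolerance = 1e-3)
  expect_equal(b2$u, 0.940, tolerance = 1e-3)
})

test_that("stage-wise stopping applies the boundaries with a forced final decision", {
  b <- boundaries(0.224, 0.839, 11)
  expect_equal(stopping_decision(0.90, 1, b), "efficacy")
  expect_equal(stopping_decision(0.10, 1, b), "futility")
  expect_equal(stopping_decision(0.50, 1, b), "continue")
  expect_equal(stopping_decision(0.50, 11, b), "futility")
  expect_equal(stopping_decision(0.85, 11, b), "efficacy")
  expect_error(boundaries(0.9, 0.2), "l < u")
})

test_that("trajectories are reproducible, null-centred and ordered by effect", {
  t1 <- simulate_likelihood_trajectories(1, reps = 400, seed = 99)
  t2 <- simulate_likelihood_trajectories(1, reps = 400, seed = 99)
  expect_identical(t1, t2)
  ta <- simulate_likelihood_trajectories(1.75, reps = 400, seed = 100)
  # the posterior is a martingale over the 50/50 prior mixture of the
  # null and the desirable effect, so the mixture mean stays at pi_e
  # (under the null alone the mean falls below the prior)
  expect_equal(mean(c(t1[, 1], ta[, 1])), 0.5, tolerance = 0.05)
  expect_lt(mean(t1[, 1]), 0.5)
  # under the alternative posteriors are stochastically larger
  for (k in c(1, 5, 11)) {
    expect_gt(mean(ta[, k]), mean(t1[, k]) + 0.05)
  }
})

test_that("boundary operating characteristics respect limiting boundaries and monotonicity", {
  tn <- simulate_likelihood_trajectories(1, reps = 500, seed = 31)
  ta <- simulate_likelihood_trajectories(1.75, reps = 500, seed = 32)
  eps <- boundary_operating_chars(tn, ta, 0.001, 0.999)
  expect_lt(eps$type1, 0.01)
  expect_equal(eps$EN0, max(attr(tn, "n_stage")), tolerance = 0.05)
  expect_error(boundary_operating_chars(tn, ta, 0.9, 0.2))
  # type I error decreases as the efficacy boundary rises (common draws)
  t1s <- vapply(c(0.6, 0.75, 0.9),
                function(u) boundary_operating_chars(tn, ta, 0.2, u)$type1,
                0)
  expect_true(all(diff(t1s) <= 0))
})

test_that("boundary stopping rules are invariant to the survival distribution at fixed 28-day recovery", {
  # two different shapes with identical 28-day recovery probability give
  # the same stage-1 posterior distribution (rank-based statistic)
  m1 <- outcome_model()                      # shape 0.797
  rate2 <- -log(0.30) / 28^1.4               # shape 1.4, same S(28) = 0.30
  m2 <- outcome_model(weibull_rate = rate2, weibull_shape = 1.4)
  s1 <- simulate_likelihood_trajectories(1.75, reps = 1000, seed = 77,
                                         model = m1)
  s2 <- simulate_likelihood_trajectories(1.75, reps = 1000, seed = 78,
                                         model = m2)
  ks <- suppressWarnings(stats::ks.test(s1[, 1], s2[, 1]))
  expect_gt(ks$p.value, 0.01)
})
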