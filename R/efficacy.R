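#' Cox partial log-likelihood at a fixed hazard ratio
#'
#' Evaluates the log partial likelihood of a two-group proportional
#' hazards model at a *given* hazard ratio `psi` for the treated group
#' (`group = 1`).  Only the ordering of the improvement events enters;
#' administratively censored observations contribute to risk sets only.
#' Tied event times are handled with the Breslow approximation (exact
#' for the continuous generators used here, where ties have measure
#' zero).
#'
#' @param time observed times (event or censoring), days.
#' @param event 1 if improvement was observed at `time`, 0 if censored.
#' @param group 1 for treated, 0 for control.
#' @param psi hazard ratio at which to evaluate (positive, vectorized).
#' @return log partial likelihood value(s); if the data contain no
#'   events (or only one group), the partial likelihood is constant and
#'   0 is returned with attribute `flat = TRUE`.
#' @export
cox_partial_loglik <- function(time, event, group, psi) {
  stopifnot(length(time) == length(event), length(time) == length(group),
            all(psi > 0), all(event %in% c(0, 1)), all(group %in% c(0, 1)))
  if (!any(event == 1) || length(unique(group)) < 2L) {
    return(structure(rep(0, length(psi)), flat = TRUE))
  }
  o <- order(time)
  e_o <- event[o]
  z_o <- group[o]
  n1 <- rev(cumsum(rev(z_o)))       # treated at risk at each sorted time
  n0 <- rev(cumsum(rev(1 - z_o)))   # controls at risk
  if (anyDuplicated(time[o])) {     # Breslow: tied events share the risk set
    first <- match(time[o], time[o])
    n1 <- n1[first]
    n0 <- n0[first]
  }
  ev <- e_o == 1
  s1 <- sum(z_o[ev])
  n1e <- n1[ev]
  n0e <- n0[ev]
  vapply(psi, function(p) s1 * log(p) - sum(log(n1e * p + n0e)), 0)
}

#' Two-point prior on the hazard ratio
#'
#' Prior mass `pi_e` on the desirable hazard ratio `psi_star` and
#' `1 - pi_e` on the null `psi = 1`.
#'
#' @param psi_star desirable hazard ratio (> 1).
#' @param pi_e prior probability of efficacy.
#' @return an object of class `two_point_prior`.
#' @export
two_point_prior <- function(psi_star = 1.75, pi_e = 0.5) {
  stopifnot(psi_star > 1, pi_e > 0, pi_e < 1)
  structure(list(psi_star = psi_star, pi_e = pi_e),
            class = "two_point_prior")
}

#' Posterior probability of efficacy under the two-point prior
#'
#' Combines the Cox partial likelihoods at the null and desirable hazard
#' ratios:
#' `pi = pi_e L(psi*) / (pi_e L(psi*) + (1 - pi_e) L(1))`.
#' Equivalently, the posterior log-odds are the prior log-odds plus the
#' partial log-likelihood ratio, so a change of `pi_e` translates the
#' posterior log-odds by a constant.
#'
#' @param time,event,group efficacy data as in [cox_partial_loglik()].
#' @param prior a [two_point_prior()].
#' @return posterior probability that `psi = psi_star`.
#' @export
posterior_efficacy <- function(time, event, group, prior = two_point_prior()) {
  ll <- cox_partial_loglik(time, event, group, c(1, prior$psi_star))
  expit(logit(prior$pi_e) + (ll[2] - ll[1]))
}

#' Sequential stopping boundaries
#'
#' @param l futility boundary (posterior probability scale).
#' @param u efficacy boundary; `0 < l < u < 1`.
#' @param K maximum number of analysis stages.
#' @return an object of class `boundaries`.
#' @export
boundaries <- function(l, u, K = 11L) {
  stopifnot(l > 0, u < 1, l < u, K >= 1)
  structure(list(l = l, u = u, K = as.integer(K)), class = "boundaries")
}

#' @export
print.boundaries <- function(x, ...) {
  cat(sprintf("Sequential boundaries: l = %.3f, u = %.3f, K = %d stages\n",
              x$l, x$u, x$K))
  invisible(x)
}

#' Stage-wise stopping decision
#'
#' Before the final stage, stop for efficacy if the posterior probability
#' exceeds `u`, for futility if below `l`, otherwise continue.  At the
#' final stage `k = K` the boundaries coincide: efficacy if above `u`,
#' futility otherwise.
#'
#' @param pi_post posterior probability of efficacy.
#' @param k current stage (1-based).
#' @param b a [boundaries()] object.
#' @return one of `"efficacy"`, `"futility"`, `"continue"`.
#' @export
stopping_decision <- function(pi_post, k, b) {
  stopifnot(k >= 1, k <= b$K)
  if (pi_post > b$u) return("efficacy")
  if (k >= b$K || pi_post < b$l) return("futility")
  "continue"
}

#' Translate boundaries to a different prior probability of efficacy
#'
#' Because changing the two-point prior only shifts the posterior
#' log-odds by the prior log-odds difference, boundaries calibrated
#' under `pi_old` are exactly equivalent, under `pi_new`, to the
#' logit-translated pair returned here; operating characteristics are
#' unchanged.
#'
#' @param b a [boundaries()] object calibrated under `pi_old`.
#' @param pi_old,pi_new old and new prior probabilities of efficacy.
#' @return the translated [boundaries()].
#' @export
shift_boundaries_for_prior <- function(b, pi_old, pi_new) {
  xi <- logit(pi_new) - logit(pi_old)
  boundaries(expit(logit(b$l) + xi), expit(logit(b$u) + xi), b$K)
}

# Stage composition of the calibration design: stage 1 holds the two
# graduation cohorts; every later stage adds one cohort.
stage_sizes <- function(c1, c2, K) {
  list(treated = c(2 * c1, rep(c1, K - 1L)),
       control = c(2 * c2, rep(c2, K - 1L)))
}

#' Simulate stage-wise likelihood-pair trajectories
#'
#' Simulates the accumulating efficacy data of one dose evaluation and
#' records, at every stage, the Cox partial log-likelihoods at the null
#' (`psi = 1`) and desirable (`psi = psi_star`) hazard ratios.  Stage 1
#' comprises the two graduation cohorts (`2*c1` treated, `2*c2`
#' concurrent controls) plus `n_shared` shared platform controls; each
#' later stage adds one cohort of `c1 + c2`.  Only the 28-day recovery
#' probability under the null and the true hazard ratio matter: the
#' stopping rule is rank-based, so results are invariant to the precise
#' survival distribution.
#'
#' @param hr_true true hazard ratio generating the treated arm.
#' @param K number of stages.
#' @param c1,c2 per-cohort counts on active dose and control.
#' @param n_shared shared controls available from stage 1.
#' @param reps number of simulated trajectories.
#' @param prior a [two_point_prior()]; `psi_star` sets the alternative.
#' @param model an [outcome_model()]; its Weibull (with 70% recovery by
#'   `t_eff` under the null) generates the times.
#' @param seed integer seed.
#' @return a `reps x K` matrix of posterior efficacy probabilities, with
#'   attributes `n_stage` (cumulative charged sample size per stage,
#'   shared controls excluded) and `llr` (the log-likelihood-ratio
#'   matrix).
#' @export
simulate_likelihood_trajectories <- function(hr_true, K = 11L, c1 = 4L,
                                             c2 = 2L, n_shared = 30L,
                                             reps = 1000L,
                                             prior = two_point_prior(),
                                             model = outcome_model(),
                                             seed = 1L) {
  stopifnot(reps >= 1, K >= 1)
  sz <- stage_sizes(c1, c2, K)
  stage <- c(rep(1L, n_shared),
             rep(seq_len(K), sz$treated), rep(seq_len(K), sz$control))
  z <- c(rep(0L, n_shared),
         rep(1L, sum(sz$treated)), rep(0L, sum(sz$control)))
  hr <- ifelse(z == 1L, hr_true, 1)
  n_tot <- length(z)
  n_stage <- cumsum(sz$treated + sz$control)  # charged EN, shared excluded
  llr <- matrix(NA_real_, reps, K)
  psis <- c(1, prior$psi_star)
  set.seed(seed)
  umat <- matrix(runif(reps * n_tot), reps, n_tot)
  for (r in seq_len(reps)) {
    tt <- recovery_quantile(umat[r, ], hr, model)
    ev <- as.integer(tt <= model$t_eff)
    tobs <- pmin(tt, model$t_eff)
    o <- order(tobs)
    e_o <- ev[o]; z_o <- z[o]; s_o <- stage[o]
    for (k in seq_len(K)) {
      sel <- s_o <= k
      zk <- z_o[sel]; ek <- e_o[sel]
      n1 <- rev(cumsum(rev(zk)))
      n0 <- rev(cumsum(rev(1 - zk)))
      evk <- ek == 1L
      s1 <- sum(zk[evk])
      llr[r, k] <- s1 * log(psis[2]) -
        sum(log(n1[evk] * psis[2] + n0[evk])) + sum(log(n1[evk] + n0[evk]))
    }
  }
  post <- expit(logit(prior$pi_e) + llr)
  attr(post, "n_stage") <- n_stage
  attr(post, "llr") <- llr
  post
}

# first stage at which the running max exceeds u / running min drops
# below l; K+1 encodes "never".  P is a reps x K posterior matrix.
first_crossings <- function(P, l, u) {
  K <- ncol(P)
  M <- P
  m <- P
  for (k in seq_len(K)[-1]) {
    M[, k] <- pmax(M[, k - 1L], M[, k])
    m[, k] <- pmin(m[, k - 1L], m[, k])
  }
  list(e = K + 1L - rowSums(M > u), f = K + 1L - rowSums(m < l), K = K)
}

decide_trajectories <- function(P, l, u) {
  fc <- first_crossings(P, l, u)
  eff <- fc$e <= fc$K & fc$e < fc$f
  stop_stage <- pmin(fc$e, fc$f, fc$K)
  list(efficacy = eff, stop_stage = stop_stage)
}

#' Operating characteristics of a boundary pair
#'
#' Applies the stopping rule along pre-simulated posterior trajectories
#' under the null and the alternative and reports error rates and
#' expected charged sample sizes (active dose plus that evaluation's own
#' randomized controls; shared controls are not charged).
#'
#' @param traj_null,traj_alt posterior matrices from
#'   [simulate_likelihood_trajectories()] under `hr_true = 1` and the
#'   desirable hazard ratio.
#' @param l,u candidate boundaries (`l < u`).
#' @return a list with `type1`, `power`, `EN0`, `EN1`, and the stage-stop
#'   distributions `stop_null`, `stop_alt`.
#' @export
boundary_operating_chars <- function(traj_null, traj_alt, l, u) {
  stopifnot(l < u, l > 0, u < 1)
  n_stage <- attr(traj_null, "n_stage")
  d0 <- decide_trajectories(traj_null, l, u)
  d1 <- decide_trajectories(traj_alt, l, u)
  K <- ncol(traj_null)
  list(type1 = mean(d0$efficacy), power = mean(d1$efficacy),
       EN0 = mean(n_stage[d0$stop_stage]),
       EN1 = mean(n_stage[d1$stop_stage]),
       stop_null = tabulate(d0$stop_stage, K) / nrow(traj_null),
       stop_alt = tabulate(d1$stop_stage, K) / nrow(traj_alt))
}

#' Calibrate sequential stopping boundaries
#'
#' Grid search over boundary pairs `(l, u)` maximizing
#' `power - lambda * (EN0 + EN1) / (2 * max_n)` subject to a one-sided
#' type I error cap, using common simulated trajectories for every cell.
#' A coarse pass at step 0.005 is refined locally at step 0.001.
#'
#' @param traj_null,traj_alt trajectory matrices from
#'   [simulate_likelihood_trajectories()].
#' @param lambda sample-size weight in the criterion.
#' @param alpha_max type I error cap.
#' @param max_n maximum total sample size normalizing the criterion.
#' @param coarse,fine grid steps of the two passes.
#' @return a [boundaries()] object with attribute `oc` (the operating
#'   characteristics at the optimum) and `criterion`.
#' @export
calibrate_boundaries <- function(traj_null, traj_alt, lambda = 1.35,
                                 alpha_max = 0.10, max_n = 216,
                                 coarse = 0.005, fine = 0.001) {
  K <- ncol(traj_null)
  n_stage <- attr(traj_null, "n_stage")
  search <- function(lgrid, ugrid) {
    # precompute crossing stages per candidate threshold
    cmax0 <- run_extreme(traj_null, "max"); cmin0 <- run_extreme(traj_null, "min")
    cmax1 <- run_extreme(traj_alt, "max");  cmin1 <- run_extreme(traj_alt, "min")
    E0 <- cross_stages(cmax0, ugrid, above = TRUE)
    F0 <- cross_stages(cmin0, lgrid, above = FALSE)
    E1 <- cross_stages(cmax1, ugrid, above = TRUE)
    F1 <- cross_stages(cmin1, lgrid, above = FALSE)
    best <- list(crit = -Inf)
    for (iu in seq_along(ugrid)) {
      e0 <- E0[, iu]; e1 <- E1[, iu]
      for (il in seq_along(lgrid)) {
        if (lgrid[il] >= ugrid[iu]) next
        f0 <- F0[, il]; f1 <- F1[, il]
        type1 <- mean(e0 <= K & e0 < f0)
        if (type1 > alpha_max) next
        power <- mean(e1 <= K & e1 < f1)
        EN0 <- mean(n_stage[pmin(e0, f0, K)])
        EN1 <- mean(n_stage[pmin(e1, f1, K)])
        crit <- power - lambda * (EN0 + EN1) / (2 * max_n)
        if (crit > best$crit) {
          best <- list(crit = crit, l = lgrid[il], u = ugrid[iu],
                       type1 = type1, power = power, EN0 = EN0, EN1 = EN1)
        }
      }
    }
    best
  }
  g <- function(step) seq(step, 1 - step, by = step)
  b1 <- search(g(coarse), g(coarse))
  lg <- seq(max(fine, b1$l - coarse), min(1 - fine, b1$l + coarse), by = fine)
  ug <- seq(max(fine, b1$u - coarse), min(1 - fine, b1$u + coarse), by = fine)
  b2 <- search(lg, ug)
  out <- boundaries(b2$l, b2$u, K)
  attr(out, "criterion") <- b2$crit
  attr(out, "oc") <- b2[c("type1", "power", "EN0", "EN1")]
  out
}

# running row-wise extrema of a reps x K matrix
run_extreme <- function(P, which = c("max", "min")) {
  which <- match.arg(which)
  f <- if (which == "max") pmax else pmin
  M <- P
  for (k in seq_len(ncol(P))[-1]) M[, k] <- f(M[, k - 1L], M[, k])
  M
}

# first stage the running extreme crosses each threshold; K+1 = never
cross_stages <- function(cext, thresholds, above) {
  K <- ncol(cext)
  out <- matrix(NA_integer_, nrow(cext), length(thresholds))
  for (i in seq_along(thresholds)) {
    cnt <- if (above) rowSums(cext > thresholds[i]) else
      rowSums(cext < thresholds[i])
    out[, i] <- K + 1L - cnt
  }
  out
}
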