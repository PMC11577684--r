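#' Prior for the dual-agent combination toxicity model
#'
#' The combination model has parameters
#' `theta = (theta1, log theta21, log theta22, eta)`: a shared intercept
#' tied to the control DLE risk, one logistic slope per agent, and an
#' interaction coefficient `eta` acting multiplicatively on the odds
#' (positive = synergistic DLE risk).  Independent normal priors;
#' `mu1 = logit(p0_prior / 2)` because the control combination stacks
#' the two agent margins: `1 - (1 - p)^2 ~ p0` for small `p0`.
#' Calibrated defaults: `mu21 = mu22 = 0`, `var1 = 0.6`,
#' `var21 = var22 = 0.25`, `mu_eta = 0`, `var_eta = 0.10`.
#'
#' @param mu1 prior mean of the shared intercept.
#' @param mu21,mu22 prior means of the log-slopes of agents A and B.
#' @param mu_eta prior mean of the interaction coefficient.
#' @param var1,var21,var22,var_eta prior variances.
#' @return an object of class `combo_prior`.
#' @export
combo_prior <- function(mu1 = logit(0.10 / 2), mu21 = 0, mu22 = 0,
                        mu_eta = 0, var1 = 0.6, var21 = 0.25,
                        var22 = 0.25, var_eta = 0.10) {
  stopifnot(var1 > 0, var21 > 0, var22 > 0, var_eta > 0)
  structure(list(mu1 = mu1, mu21 = mu21, mu22 = mu22, mu_eta = mu_eta,
                 var1 = var1, var21 = var21, var22 = var22,
                 var_eta = var_eta), class = "combo_prior")
}

#' Combination DLE probability
#'
#' Per-agent marginal DLE probabilities follow the two-parameter
#' logistic model with a shared intercept,
#' `p(d_j) = expit(theta1 + theta21 * dtilde_j)` and
#' `p(s_l) = expit(theta1 + theta22 * stilde_l)`; under independence the
#' combination risk is `p0 = 1 - (1 - p(d_j)) (1 - p(s_l))`, and the
#' interaction multiplies the odds:
#' `odds(p) = odds(p0) * exp(eta * dtilde_j * stilde_l)`.
#'
#' @param theta numeric length-4 vector
#'   `(theta1, log theta21, log theta22, eta)`.
#' @param dtilde_j,stilde_l standardized dose levels of the two agents
#'   (0 = agent absent).
#' @return DLE probability in (0, 1).
#' @export
combo_dle_probability <- function(theta, dtilde_j, stilde_l) {
  stopifnot(length(theta) == 4)
  pa <- expit(theta[1] + exp(theta[2]) * dtilde_j)
  pb <- expit(theta[1] + exp(theta[3]) * stilde_l)
  p0 <- 1 - (1 - pa) * (1 - pb)
  o <- p0 / (1 - p0) * exp(theta[4] * dtilde_j * stilde_l)
  o / (1 + o)
}

#' Build the standardized dose grid for a combination
#'
#' Prior DLE guesses for one agent given alone increase by `nu_d`
#' (`nu_s`) per level from the control risk `p0_prior` (level 0 of
#' either agent is the control).  Because each guess already contains
#' the control contribution of the absent agent, the single-agent
#' margin is first recovered by factoring out `expit(mu1)` and the
#' standardized level then inverts the logistic margin at the prior
#' point estimates (intercept `mu1 = logit(p0_prior/2)`, slopes
#' `exp(mu2x)`); level 0 maps to 0.
#'
#' @param J,L numbers of dose levels of agents A and B.
#' @param p0_prior prior control DLE probability.
#' @param nu_d,nu_s per-level prior risk increments.
#' @param prior a [combo_prior()] supplying the point estimates.
#' @return an object of class `combo_grid` with `dtilde` (length
#'   `J + 1`), `stilde` (length `L + 1`) and the prior marginal
#'   probabilities.
#' @export
build_combo_skeleton <- function(J = 2L, L = 3L, p0_prior = 0.10,
                                 nu_d = 0.075, nu_s = 0.075,
                                 prior = combo_prior()) {
  pd <- p0_prior + nu_d * (0:J)
  ps <- p0_prior + nu_s * (0:L)
  stopifnot(all(pd < 1), all(ps < 1))
  # The prior guesses are combination-level risks of one agent given
  # alone (level 0 recovers the control risk p0).  The single-agent
  # margin is recovered by removing the other agent's control
  # contribution q0 = expit(mu1): 1 - (1-p_margin)(1-q0) = p_guess.
  q0 <- expit(prior$mu1)
  pa_marg <- 1 - (1 - pd[-1]) / (1 - q0)
  pb_marg <- 1 - (1 - ps[-1]) / (1 - q0)
  stopifnot(all(pa_marg > 0), all(pb_marg > 0))
  dtilde <- c(0, (logit(pa_marg) - prior$mu1) / exp(prior$mu21))
  stilde <- c(0, (logit(pb_marg) - prior$mu1) / exp(prior$mu22))
  if (any(diff(dtilde) <= 0) || any(diff(stilde) <= 0)) {
    stop("skeleton inversion produced non-increasing standardized doses")
  }
  structure(list(J = as.integer(J), L = as.integer(L),
                 dtilde = dtilde, stilde = stilde,
                 prior_probs_a = pd, prior_probs_b = ps),
            class = "combo_grid")
}

# Latin-hypercube stratified standard normal sample, n x k, seeded
lhs_normal <- function(n, k, seed) {
  set.seed(seed)
  q <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    q[, j] <- qnorm((sample.int(n) - runif(n)) / n)
  }
  q
}

#' Weighted support for the 4-parameter combination posterior
#'
#' A seeded stratified (Latin hypercube) normal sample of the prior on
#' `(theta1, log theta21, log theta22, eta)` with equal base weights;
#' posterior updates re-weight the fixed support by the likelihood
#' (deterministic given the seed).  DLE probabilities at every active
#' combination and the control are precomputed.
#'
#' @param prior a [combo_prior()].
#' @param grid a [build_combo_skeleton()] result.
#' @param n number of support points.
#' @param seed seed of the stratified sample.
#' @param cfg a [safety_config()] whose overdose/target-interval event
#'   indicators are precomputed for fast repeated evaluation.
#' @return an object of class `combo_support`.  Column 1 of the
#'   probability matrix is the control combination; active combinations
#'   follow in column-major `(j, l)` order (`j` fastest).
#' @export
combo_support <- function(prior, grid, n = 2^13, seed = 20L,
                          cfg = safety_config()) {
  zn <- lhs_normal(n, 4L, seed)
  th1 <- prior$mu1 + sqrt(prior$var1) * zn[, 1]
  lt21 <- prior$mu21 + sqrt(prior$var21) * zn[, 2]
  lt22 <- prior$mu22 + sqrt(prior$var22) * zn[, 3]
  eta <- prior$mu_eta + sqrt(prior$var_eta) * zn[, 4]
  combos <- rbind(c(0L, 0L),
                  as.matrix(expand.grid(j = seq_len(grid$J),
                                        l = seq_len(grid$L))))
  p <- matrix(NA_real_, n, nrow(combos))
  for (i in seq_len(nrow(combos))) {
    dt <- grid$dtilde[combos[i, 1] + 1L]
    st <- grid$stilde[combos[i, 2] + 1L]
    pa <- expit(th1 + exp(lt21) * dt)
    pb <- expit(th1 + exp(lt22) * st)
    p0 <- 1 - (1 - pa) * (1 - pb)
    o <- p0 / (1 - p0) * exp(eta * dt * st)
    p[, i] <- o / (1 + o)
  }
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  adle <- p[, -1, drop = FALSE] - p[, 1]
  A <- ncol(adle)
  summ <- cbind(p, 1 * (adle >= cfg$gamma + 2 * cfg$delta),
                1 * (adle >= cfg$gamma - cfg$delta &
                       adle <= cfg$gamma + cfg$delta))
  structure(list(summ = summ, n_arms = A,
                 theta = cbind(theta1 = th1, log_theta21 = lt21,
                               log_theta22 = lt22, eta = eta),
                 combos = combos, p = p, logp = log(p), log1mp = log1p(-p),
                 combo_names = c("control",
                                 sprintf("(%d,%d)", combos[-1, 1],
                                         combos[-1, 2])),
                 cfg = cfg, grid = grid, n = n, seed = seed),
            class = "combo_support")
}

#' Update the combination-toxicity posterior
#'
#' Re-weights the fixed prior support by the Bernoulli likelihood of
#' per-combination DLE counts.
#'
#' @param support a [combo_support()].
#' @param events,n per-combination DLE and patient counts in the column
#'   order of `support$combos` (control first).
#' @return an object of class `combo_posterior` with weights `w` and
#'   posterior mean DLE probabilities `p_mean` (named by combination).
#' @export
update_combo_posterior <- function(support, events, n) {
  stopifnot(inherits(support, "combo_support"),
            length(events) == ncol(support$p), length(n) == length(events),
            all(events >= 0), all(events <= n))
  logw <- drop(support$logp %*% events + support$log1mp %*% (n - events))
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  s <- drop(crossprod(support$summ, w))
  A <- support$n_arms
  pm <- s[seq_len(A + 1L)]
  names(pm) <- support$combo_names
  structure(list(support = support, w = w, p_mean = pm,
                 over = s[A + 1L + seq_len(A)],
                 target = s[2L * A + 1L + seq_len(A)]),
            class = "combo_posterior")
}

# per-combination posterior probabilities of overdose / target interval
combo_event_probs <- function(post, cfg = post$support$cfg) {
  if (identical(cfg$gamma, post$support$cfg$gamma) &&
      identical(cfg$delta, post$support$cfg$delta)) {
    return(list(overdose = post$over, target = post$target))
  }
  p <- post$support$p
  adle <- p[, -1, drop = FALSE] - p[, 1]
  over <- drop(crossprod(adle >= cfg$gamma + 2 * cfg$delta, post$w))
  targ <- drop(crossprod(adle >= cfg$gamma - cfg$delta &
                           adle <= cfg$gamma + cfg$delta, post$w))
  list(overdose = over, target = targ)
}

#' Safe combinations under overdose control
#'
#' Applies the single-agent overdose-control rule per combination with
#' the combination posterior.
#'
#' @param post a [update_combo_posterior()] result.
#' @param cfg a [safety_config()].
#' @return integer matrix of safe combinations, one `(j, l)` row each.
#' @export
safe_combo_set <- function(post, cfg = post$support$cfg) {
  over <- combo_event_probs(post, cfg)$overdose
  post$support$combos[-1, , drop = FALSE][over < cfg$c_overdose, ,
                                          drop = FALSE]
}

#' Admissible escalation moves between combinations
#'
#' From the current combination, only staying put or changing *one*
#' agent by *one* level is allowed (no skipping, no diagonal moves),
#' restricted to safe combinations.
#'
#' @param current integer pair `(j, l)`.
#' @param safe_combos integer matrix of safe combinations (rows).
#' @return integer matrix of admissible combinations (possibly 0 rows).
#' @export
admissible_moves <- function(current, safe_combos) {
  j <- current[1]; l <- current[2]
  cand <- rbind(c(j, l), c(j - 1L, l), c(j + 1L, l),
                c(j, l - 1L), c(j, l + 1L))
  cand <- cand[cand[, 1] >= 1L & cand[, 2] >= 1L, , drop = FALSE]
  if (nrow(safe_combos) == 0L) return(cand[0, , drop = FALSE])
  keep <- paste(cand[, 1], cand[, 2]) %in%
    paste(safe_combos[, 1], safe_combos[, 2])
  cand[keep, , drop = FALSE]
}

#' Choose the next combination for the escalation cohort
#'
#' Maximizes the target-interval probability over the admissible moves;
#' ties are broken by fair randomization.  Returns `NULL` when no safe
#' combination is reachable (safety stop).
#'
#' @param current integer pair `(j, l)`.
#' @param post a [update_combo_posterior()] result.
#' @param cfg a [safety_config()].
#' @return integer pair, or `NULL` to stop for safety.
#' @export
select_next_combo <- function(current, post, cfg) {
  safe <- safe_combo_set(post, cfg)
  moves <- admissible_moves(current, safe)
  if (nrow(moves) == 0L) return(NULL)
  targ <- combo_event_probs(post, cfg)$target
  key <- paste(post$support$combos[-1, 1], post$support$combos[-1, 2])
  pr <- targ[match(paste(moves[, 1], moves[, 2]), key)]
  best <- which(pr == max(pr))
  if (length(best) > 1L) best <- best[sample.int(length(best), 1L)]
  moves[best, ]
}
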