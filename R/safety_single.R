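#' Safety (dose-escalation) configuration
#'
#' Parameters of the additional-DLE-risk (ADLE) escalation target: the
#' design seeks the dose whose DLE probability exceeds the control arm's
#' by `gamma`, accepts doses within `gamma +/- delta`, and excludes
#' doses whose posterior probability of ADLE `>= gamma + 2*delta`
#' reaches `c_overdose`.
#'
#' @param m number of active doses.
#' @param gamma target additional DLE risk over control.
#' @param delta half-width of the acceptable ADLE interval.
#' @param c_overdose overdose-control probability threshold.
#' @param p0_prior prior DLE probability on the control arm.
#' @return an object of class `safety_config`.
#' @export
safety_config <- function(m = 3L, gamma = 0.20, delta = 0.05,
                          c_overdose = 0.25, p0_prior = 0.10) {
  stopifnot(m >= 1, gamma > 0, gamma < 1, delta > 0, gamma + 2 * delta < 1,
            c_overdose > 0, c_overdose < 1, p0_prior > 0, p0_prior < 1)
  structure(list(m = as.integer(m), gamma = gamma, delta = delta,
                 c_overdose = c_overdose, p0_prior = p0_prior),
            class = "safety_config")
}

#' Normal prior on the dose-toxicity model parameters
#'
#' The model parameters are `(theta1, log(theta2))` with independent
#' normal priors; the log parameterization of the slope enforces
#' `theta2 > 0` (monotone dose-toxicity).  The intercept mean is tied to
#' the prior control DLE probability, `mu1 = logit(p0_prior)`, so that
#' the control standardized dose is 0.  Calibrated defaults:
#' `mu2 = -0.25`, `var1 = 1.40`, `var2 = 0.35`.
#'
#' @param mu1 prior mean of the intercept `theta1`.
#' @param mu2 prior mean of `log(theta2)`.
#' @param var1,var2 prior variances.
#' @return an object of class `safety_prior`.
#' @export
safety_prior <- function(mu1 = logit(0.10), mu2 = -0.25,
                         var1 = 1.40, var2 = 0.35) {
  stopifnot(var1 > 0, var2 > 0)
  structure(list(mu1 = mu1, mu2 = mu2, var1 = var1, var2 = var2),
            class = "safety_prior")
}

#' Dose-toxicity probability of the two-parameter logistic model
#'
#' `p = expit(theta1 + theta2 * dtilde)`.  The control arm has
#' standardized dose 0, so its DLE probability depends on the intercept
#' only.
#'
#' @param theta1 intercept.
#' @param theta2 slope (must be positive).
#' @param dtilde standardized dose level.
#' @return DLE probability in (0, 1).
#' @export
dle_probability <- function(theta1, theta2, dtilde) {
  if (any(theta2 <= 0)) stop("theta2 must be positive")
  expit(theta1 + theta2 * dtilde)
}

#' Build the standardized dose grid (skeleton)
#'
#' Standardized dose levels are chosen so the prior toxicity curve
#' passes through the prior DLE guesses:
#' `dtilde_j = (logit(p_j) - theta1_hat) / theta2_hat`, with the control
#' fixed at 0 (which requires `logit(p_0) = theta1_hat`).
#'
#' @param prior_probs prior DLE probabilities, control first, strictly
#'   increasing.
#' @param theta1_hat,theta2_hat prior point estimates of the model
#'   parameters (`theta2_hat > 0`).
#' @return an object of class `dose_grid` with fields `prior_probs` and
#'   `dtilde`.
#' @export
build_skeleton <- function(prior_probs, theta1_hat = logit(prior_probs[1]),
                           theta2_hat = exp(-0.25)) {
  stopifnot(all(diff(prior_probs) > 0), all(prior_probs > 0),
            all(prior_probs < 1), theta2_hat > 0)
  if (abs(logit(prior_probs[1]) - theta1_hat) > 1e-10) {
    stop("theta1_hat must equal logit of the control prior probability ",
         "(control standardized dose must be 0)")
  }
  dtilde <- (logit(prior_probs) - theta1_hat) / theta2_hat
  dtilde[1] <- 0
  structure(list(prior_probs = prior_probs, dtilde = dtilde),
            class = "dose_grid")
}

#' Equally-spaced prior DLE guesses
#'
#' The calibrated skeleton uses `p_j = p0 + nu * j`: prior DLE risk
#' increasing by `nu` per dose level.
#'
#' @param p0 prior control DLE probability.
#' @param nu per-level increment (calibrated value 0.125).
#' @param m number of active doses.
#' @return numeric vector of length `m + 1` (control first).
#' @export
skeleton_probs <- function(p0 = 0.10, nu = 0.125, m = 3L) {
  p0 + nu * (0:m)
}

#' Discretized representation of the parameter posterior
#'
#' Builds the fixed quadrature support over `(theta1, log theta2)`: a
#' tensor grid of `nodes x nodes` equally spaced points spanning
#' `span` prior standard deviations around the prior means, with prior
#' log-density precomputed, together with the per-arm DLE probabilities
#' at every support point.  The same support is reused for every update
#' (deterministic, no sequential re-weighting).
#'
#' @param prior a [safety_prior()].
#' @param grid a [dose_grid()].
#' @param nodes nodes per dimension.
#' @param span half-width of the support in prior standard deviations.
#' @param cfg a [safety_config()] whose overdose/target-interval event
#'   indicators are precomputed for fast repeated evaluation.
#' @return an object of class `safety_support`.
#' @export
safety_support <- function(prior, grid, nodes = 101L, span = 6,
                           cfg = safety_config()) {
  s1 <- sqrt(prior$var1)
  s2 <- sqrt(prior$var2)
  t1 <- seq(prior$mu1 - span * s1, prior$mu1 + span * s1, length.out = nodes)
  lt2 <- seq(prior$mu2 - span * s2, prior$mu2 + span * s2, length.out = nodes)
  th1 <- rep(t1, times = nodes)
  lth2 <- rep(lt2, each = nodes)
  logprior <- dnorm(th1, prior$mu1, s1, log = TRUE) +
    dnorm(lth2, prior$mu2, s2, log = TRUE)
  p <- expit(matrix(th1, length(th1), length(grid$dtilde)) +
               outer(exp(lth2), grid$dtilde))
  # keep log-likelihood finite at the extreme support corners
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  adle <- p[, -1, drop = FALSE] - p[, 1]
  summ <- cbind(p, 1 * (adle >= cfg$gamma + 2 * cfg$delta),
                1 * (adle >= cfg$gamma - cfg$delta &
                       adle <= cfg$gamma + cfg$delta))
  structure(list(theta1 = th1, log_theta2 = lth2, logprior = logprior,
                 p = p, logp = log(p), log1mp = log1p(-p),
                 summ = summ, n_arms = ncol(adle),
                 cfg = cfg, grid = grid, nodes = nodes, span = span),
            class = "safety_support")
}

#' Update the posterior of the dose-toxicity parameters
#'
#' Bayes update of the discretized prior with the Bernoulli DLE
#' likelihood.  Data enter only through per-arm event and patient
#' counts; all arms (including pooled controls) inform the shared
#' parameters.
#'
#' @param support a [safety_support()] (or a [safety_prior()] plus
#'   `grid`, in which case the support is built with defaults).
#' @param events per-arm DLE counts, control first (length `m + 1`).
#' @param n per-arm patient counts, control first.
#' @param grid a [dose_grid()], only needed when `support` is a prior.
#' @return an object of class `safety_posterior`: the support plus
#'   normalized weights `w` and posterior mean DLE probabilities
#'   `p_mean`.
#' @export
update_posterior <- function(support, events, n, grid = NULL) {
  if (inherits(support, "safety_prior")) {
    stopifnot(!is.null(grid))
    support <- safety_support(support, grid)
  }
  stopifnot(inherits(support, "safety_support"),
            length(events) == ncol(support$p), length(n) == length(events),
            all(events >= 0), all(events <= n))
  logw <- support$logprior +
    drop(support$logp %*% events + support$log1mp %*% (n - events))
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  s <- drop(crossprod(support$summ, w))
  m <- support$n_arms
  structure(list(support = support, w = w,
                 p_mean = s[seq_len(m + 1L)],
                 over = s[m + 1L + seq_len(m)],
                 target = s[2L * m + 1L + seq_len(m)]),
            class = "safety_posterior")
}

#' @export
print.safety_posterior <- function(x, ...) {
  cat("Dose-toxicity posterior on", length(x$w), "support points\n")
  cat("  posterior mean P(DLE):",
      paste(sprintf("%.3f", x$p_mean), collapse = " "), "\n")
  invisible(x)
}

#' Posterior probability of overdosing at a dose
#'
#' Posterior mass of the event `p_j - p_0 >= gamma + 2*delta` (the dose
#' carries an unacceptably high additional DLE risk).
#'
#' @param post a [update_posterior()] result.
#' @param j active dose index (1-based; control is never assessed).
#' @param cfg a [safety_config()].
#' @return posterior probability.
#' @export
prob_overdose <- function(post, j, cfg = post$support$cfg) {
  stopifnot(j >= 1, j <= ncol(post$support$p) - 1L)
  if (identical(cfg$gamma, post$support$cfg$gamma) &&
      identical(cfg$delta, post$support$cfg$delta)) {
    return(post$over[j])
  }
  adle <- post$support$p[, j + 1L] - post$support$p[, 1L]
  sum(post$w[adle >= cfg$gamma + 2 * cfg$delta])
}

#' Set of safe doses under overdose control
#'
#' Doses whose posterior overdose probability is below `c_overdose`.
#' Because the model is monotone in dose at every support point, the
#' set is downward closed.
#'
#' @inheritParams prob_overdose
#' @return integer vector of safe dose indices (possibly empty).
#' @export
safe_dose_set <- function(post, cfg = post$support$cfg) {
  m <- ncol(post$support$p) - 1L
  over <- vapply(seq_len(m), prob_overdose, 0, post = post, cfg = cfg)
  which(over < cfg$c_overdose)
}

#' Posterior probability that a dose hits the target ADLE interval
#'
#' Posterior mass of `p_j - p_0` falling in
#' `[gamma - delta, gamma + delta]`; the safe dose maximizing this is
#' the escalation target.
#'
#' @inheritParams prob_overdose
#' @return posterior probability.
#' @export
target_interval_prob <- function(post, j, cfg = post$support$cfg) {
  stopifnot(j >= 1, j <= ncol(post$support$p) - 1L)
  if (identical(cfg$gamma, post$support$cfg$gamma) &&
      identical(cfg$delta, post$support$cfg$delta)) {
    return(post$target[j])
  }
  adle <- post$support$p[, j + 1L] - post$support$p[, 1L]
  sum(post$w[adle >= cfg$gamma - cfg$delta & adle <= cfg$gamma + cfg$delta])
}

#' Choose the next dose for the escalation cohort
#'
#' Among safe doses no more than one level from the current dose, pick
#' the one maximizing the target-interval probability; no level skipping
#' is allowed.  An empty safe set stops the trial for safety; if only
#' the current dose is safe the cohort stays.  Ties are broken by fair
#' randomization.
#'
#' @param current current dose level (1-based).
#' @param safe integer vector of safe doses.
#' @param probs per-dose target-interval probabilities (length `m`).
#' @return the next dose index, or `NA_integer_` for a safety stop.
#' @export
select_next_dose <- function(current, safe, probs) {
  if (length(safe) == 0L) return(NA_integer_)
  cand <- intersect(safe, (current - 1L):(current + 1L))
  if (length(cand) == 0L) return(NA_integer_)
  if (length(cand) == 1L) return(cand)
  best <- cand[probs[cand] == max(probs[cand])]
  if (length(best) > 1L) best <- best[sample.int(length(best), 1L)]
  best
}
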