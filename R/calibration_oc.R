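#' Classify an arm by true safety and efficacy
#'
#' An arm is *incorrect* if unsafe (true additional DLE risk above 0.30)
#' or null (hazard ratio 1); safe arms are *undesirable* at hazard ratio
#' 1.25, *acceptable* at 1.5 and *desirable* at 1.75 or above.
#'
#' @param safe logical: true additional DLE risk at most `adle_max`.
#' @param hr true hazard ratio of the arm.
#' @return one of `"incorrect"`, `"undesirable"`, `"acceptable"`,
#'   `"desirable"`.
#' @export
classify_arm <- function(safe, hr) {
  stopifnot(is.logical(safe), hr > 0)
  if (!safe || hr <= 1) return("incorrect")
  if (hr >= 1.75) return("desirable")
  if (hr >= 1.5) return("acceptable")
  "undesirable"
}

#' Classify every active arm of a scenario
#'
#' @param scn a [scenario()] or [combo_scenario()].
#' @param adle_max largest acceptable additional DLE risk.
#' @return character vector of classes for the active arms (scenario
#'   order; combo scenarios in `j`-fastest order matching the engine).
#' @export
classify_scenario <- function(scn, adle_max = 0.30) {
  if (inherits(scn, "combo_scenario")) {
    combos <- as.matrix(expand.grid(j = seq_len(ncol(scn$p_dle)),
                                    l = seq_len(nrow(scn$p_dle))))
    p <- scn$p_dle[cbind(combos[, 2], combos[, 1])]
    hr <- scn$hr[cbind(combos[, 2], combos[, 1])]
    p0 <- scn$p0
  } else {
    p <- scn$p_dle[-1]
    hr <- scn$hr[-1]
    p0 <- scn$p_dle[1]
  }
  vapply(seq_along(p),
         function(i) classify_arm(p[i] - p0 <= adle_max, hr[i]), "")
}

#' Geometric mean of selection proportions
#'
#' Used by the hyperparameter calibration: the geometric mean across
#' scenarios of the proportion of correct target selections (0 if any
#' proportion is 0).
#'
#' @param rates vector of proportions in `[0, 1]`.
#' @return the geometric mean.
#' @export
geometric_mean_selection <- function(rates) {
  stopifnot(all(rates >= 0), all(rates <= 1))
  if (any(rates == 0)) return(0)
  exp(mean(log(rates)))
}

#' Replicate platform trial simulations under one scenario
#'
#' @param tc a [trial_config()].
#' @param scn a [scenario()] or [combo_scenario()].
#' @param reps number of replicates.
#' @param seed root seed; replicate `i` uses an independent substream.
#' @param cprior a [combo_prior()] for combo scenarios.
#' @return list of `trial_result` objects.
#' @export
simulate_trials <- function(tc, scn, reps = 1000L, seed = 1L,
                            cprior = combo_prior()) {
  if (inherits(scn, "combo_scenario")) {
    grid <- build_combo_skeleton(J = ncol(scn$p_dle), L = nrow(scn$p_dle),
                                 p0_prior = tc$cfg$p0_prior, prior = cprior)
    support <- combo_support(cprior, grid, cfg = tc$cfg)
    lapply(seq_len(reps), function(i) {
      run_combo_trial(tc, scn, cprior,
                      seed = substream_seed(seed, paste0("rep", i)),
                      support = support)
    })
  } else {
    grid <- build_skeleton(skeleton_probs(tc$cfg$p0_prior, tc$nu, tc$cfg$m),
                           theta2_hat = exp(tc$prior$mu2))
    support <- safety_support(tc$prior, grid, cfg = tc$cfg)
    lapply(seq_len(reps), function(i) {
      run_single_agent_trial(tc, scn,
                             seed = substream_seed(seed, paste0("rep", i)),
                             support = support)
    })
  }
}

#' Summarize operating characteristics of replicated simulations
#'
#' Per-arm recommendation percentages are non-exclusive (several arms
#' can be recommended in one replicate) and may sum to more than 100%.
#'
#' @param results list of `trial_result` objects from [simulate_trials()].
#' @param scn the scenario they were simulated under.
#' @return a one-row data frame: per-arm recommendation `%`, `any_rec`,
#'   `any_desirable`, `all_desirable` (`NA` when the scenario has no
#'   desirable arm), mean/median total sample size, mean duration in
#'   days, and stop-reason percentages.
#' @export
summarize_oc <- function(results, scn) {
  cls <- classify_scenario(scn)
  A <- length(cls)
  rec <- vapply(seq_len(A), function(a) {
    100 * mean(vapply(results, function(r) a %in% r$recommended, TRUE))
  }, 0)
  des <- which(cls == "desirable")
  any_rec <- 100 * mean(vapply(results,
                               function(r) length(r$recommended) > 0, TRUE))
  any_des <- if (length(des)) {
    100 * mean(vapply(results,
                      function(r) any(des %in% r$recommended), TRUE))
  } else NA_real_
  all_des <- if (length(des)) {
    100 * mean(vapply(results,
                      function(r) all(des %in% r$recommended), TRUE))
  } else NA_real_
  ntot <- vapply(results, function(r) r$n_total, 0L)
  safety_stop <- vapply(results, function(r) {
    all(r$reason %in% c("safety", "not_graduated"))
  }, TRUE)
  out <- data.frame(label = scn$label, t(rec), any_rec = any_rec,
                    any_desirable = any_des, all_desirable = all_des,
                    mean_n = mean(ntot), median_n = median(ntot),
                    mean_duration = mean(vapply(results,
                                                function(r) 1 * r$duration,
                                                0)),
                    pct_safety_stop = 100 * mean(safety_stop),
                    mean_n_safety_stop = if (any(safety_stop))
                      mean(ntot[safety_stop]) else NA_real_)
  names(out)[1 + seq_len(A)] <- paste0("rec_", seq_len(A))
  out
}

#' Escalation-only trial for safety-model calibration
#'
#' Runs the dose-escalation component alone (no graduation or efficacy):
#' cohorts of `c1 + c2` every safety readout, up to `n_cohorts`, with
#' the usual overdose-controlled dose selection.  The selected dose is
#' the safe dose maximizing the target-interval probability at the final
#' posterior, or none after a safety stop.
#'
#' @param prior a [safety_prior()].
#' @param nu skeleton increment.
#' @param p_dle true per-arm DLE probabilities (control first).
#' @param cfg a [safety_config()].
#' @param n_cohorts maximum number of cohorts.
#' @param c1,c2 cohort split.
#' @param seed integer seed.
#' @param support optional precomputed [safety_support()].
#' @return list with `selected` (dose index or `NA`), `n` (patients).
#' @export
run_safety_trial <- function(prior, nu, p_dle, cfg = safety_config(),
                             n_cohorts = 12L, c1 = 4L, c2 = 2L, seed = 1L,
                             support = NULL) {
  m <- cfg$m
  stopifnot(length(p_dle) == m + 1L)
  if (is.null(support)) {
    grid <- build_skeleton(skeleton_probs(cfg$p0_prior, nu, m),
                           theta2_hat = exp(prior$mu2))
    support <- safety_support(prior, grid, cfg = cfg)
  }
  set.seed(seed)
  ev <- numeric(m + 1L)
  nn <- numeric(m + 1L)
  current <- 1L
  post <- NULL
  for (co in seq_len(n_cohorts)) {
    ya <- rbinom(1L, c1, p_dle[current + 1L])
    yc <- rbinom(1L, c2, p_dle[1L])
    ev[current + 1L] <- ev[current + 1L] + ya
    nn[current + 1L] <- nn[current + 1L] + c1
    ev[1L] <- ev[1L] + yc
    nn[1L] <- nn[1L] + c2
    post <- update_posterior(support, ev, nn)
    safe <- safe_dose_set(post, cfg)
    if (length(safe) == 0L) {
      return(list(selected = NA_integer_, n = sum(nn)))
    }
    probs <- vapply(seq_len(m), target_interval_prob, 0,
                    post = post, cfg = cfg)
    nxt <- select_next_dose(current, safe, probs)
    if (is.na(nxt)) return(list(selected = NA_integer_, n = sum(nn)))
    current <- nxt
  }
  safe <- safe_dose_set(post, cfg)
  if (length(safe) == 0L) return(list(selected = NA_integer_, n = sum(nn)))
  probs <- vapply(seq_len(m), target_interval_prob, 0,
                  post = post, cfg = cfg)
  sel <- safe[which.max(probs[safe])]
  list(selected = sel, n = sum(nn))
}

#' Grid-search calibration of the safety-model hyperparameters
#'
#' For every hyperparameter cell, escalation-only trials are simulated
#' under each calibration scenario and the proportion of correct target
#' selections recorded; the selected cell maximizes the geometric mean
#' across scenarios (ties resolved by grid order).  The target dose of
#' a scenario is the dose whose true additional DLE risk is closest to
#' the target `gamma`.
#'
#' @param grid data frame of candidate cells with columns `nu`, `mu2`,
#'   `var1`, `var2`.
#' @param scenarios list of true DLE probability vectors (control
#'   first).
#' @param cfg a [safety_config()].
#' @param sims simulations per cell and scenario.
#' @param seed root seed (common random numbers across cells).
#' @return the grid with per-scenario selection proportions and
#'   `geo_mean`, sorted as supplied, with the selected cell in attribute
#'   `selected` (a one-row data frame).
#' @export
calibrate_safety_hyperparams <- function(grid, scenarios,
                                         cfg = safety_config(),
                                         sims = 100L, seed = 1L) {
  stopifnot(nrow(grid) >= 1, all(c("nu", "mu2", "var1", "var2") %in%
                                   names(grid)))
  targets <- vapply(scenarios, function(p) {
    which.min(abs((p[-1] - p[1]) - cfg$gamma))
  }, 0L)
  sel_mat <- matrix(NA_real_, nrow(grid), length(scenarios))
  for (g in seq_len(nrow(grid))) {
    pr <- safety_prior(mu1 = logit(cfg$p0_prior), mu2 = grid$mu2[g],
                       var1 = grid$var1[g], var2 = grid$var2[g])
    sgrid <- build_skeleton(skeleton_probs(cfg$p0_prior, grid$nu[g], cfg$m),
                            theta2_hat = exp(pr$mu2))
    support <- safety_support(pr, sgrid, cfg = cfg)
    for (s in seq_along(scenarios)) {
      hits <- vapply(seq_len(sims), function(i) {
        r <- run_safety_trial(pr, grid$nu[g], scenarios[[s]], cfg,
                              seed = substream_seed(seed,
                                                    paste0("cal", s, "_", i)),
                              support = support)
        identical(r$selected, targets[s])
      }, TRUE)
      sel_mat[g, s] <- mean(hits)
    }
  }
  out <- cbind(grid, sel_mat)
  names(out)[ncol(grid) + seq_along(scenarios)] <-
    paste0("sel_", seq_along(scenarios))
  out$geo_mean <- apply(sel_mat, 1, geometric_mean_selection)
  attr(out, "selected") <- out[which.max(out$geo_mean), , drop = FALSE]
  out
}
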