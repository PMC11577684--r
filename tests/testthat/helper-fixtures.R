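# shared fixtures: baseline configuration pieces, built once per test run

baseline_cfg <- safety_config()
baseline_prior <- safety_prior()
baseline_grid <- build_skeleton(skeleton_probs())
baseline_support <- safety_support(baseline_prior, baseline_grid,
                                   cfg = baseline_cfg)

baseline_combo_prior <- combo_prior()
baseline_combo_grid <- build_combo_skeleton()
baseline_combo_support <- combo_support(baseline_combo_prior,
                                        baseline_combo_grid,
                                        n = 2^12, seed = 42,
                                        cfg = baseline_cfg)

# a degenerate (point-mass-like) single-agent posterior at given per-arm
# DLE probabilities, for testing decision rules against known truths
point_mass_posterior <- function(p_arms) {
  sup <- list(p = matrix(p_arms, nrow = 1),
              cfg = baseline_cfg)
  class(sup) <- "safety_support"
  structure(list(support = sup, w = 1,
                 p_mean = p_arms,
                 over = as.numeric(p_arms[-1] - p_arms[1] >=
                                     baseline_cfg$gamma +
                                       2 * baseline_cfg$delta),
                 target = as.numeric(abs(p_arms[-1] - p_arms[1] -
                                           baseline_cfg$gamma) <=
                                       baseline_cfg$delta)),
            class = "safety_posterior")
}

# brute-force Cox partial likelihood by risk-set enumeration (oracle)
oracle_partial_lik <- function(time, event, group, psi) {
  o <- order(time)
  time <- time[o]; event <- event[o]; group <- group[o]
  lik <- 1
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      at_risk <- time >= time[i]
      num <- psi^group[i]
      den <- sum(psi^group[at_risk])
      lik <- lik * num / den
    }
  }
  lik
}
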