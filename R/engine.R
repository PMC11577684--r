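#' Platform trial configuration
#'
#' Bundles the design constants of one compound evaluation: cohort
#' split, shared-control cap, per-dose intake cap, readout times,
#' stopping boundaries and the safety model settings.  The maximum
#' number of efficacy stages `K` is derived from the per-dose cap
#' (stage 1 holds two cohorts, every later stage one), so that active
#' plus own-control intake on a dose never exceeds the cap.
#'
#' @param c1,c2 per-cohort patients on the active dose and on control.
#' @param nc maximum number of shared concurrent controls added to an
#'   efficacy analysis (0 disables sharing).
#' @param per_dose_cap maximum intake (active + own controls) per dose.
#' @param bounds a [boundaries()] object; its `K` is overridden by the
#'   cap-derived stage count.
#' @param cfg a [safety_config()].
#' @param prior a [safety_prior()] (single-agent) — combo runs take a
#'   [combo_prior()] via `run_combo_trial()`.
#' @param nu per-level increment of the skeleton prior DLE guesses.
#' @param eff_prior a [two_point_prior()].
#' @param model an [outcome_model()].
#' @param share_controls_safety should pooled platform controls enter
#'   the safety posterior (default yes).
#' @return an object of class `trial_config`.
#' @export
trial_config <- function(c1 = 4L, c2 = 2L, nc = 30L, per_dose_cap = 72L,
                         bounds = boundaries(0.224, 0.839),
                         cfg = safety_config(), prior = safety_prior(),
                         nu = 0.125, eff_prior = two_point_prior(),
                         model = outcome_model(),
                         share_controls_safety = TRUE) {
  stopifnot(c1 >= 1, c2 >= 1, nc >= 0, per_dose_cap %% (c1 + c2) == 0)
  K <- as.integer(per_dose_cap / (c1 + c2)) - 1L
  bounds$K <- K
  structure(list(c1 = as.integer(c1), c2 = as.integer(c2),
                 nc = as.integer(nc), per_dose_cap = as.integer(per_dose_cap),
                 bounds = bounds, cfg = cfg, prior = prior, nu = nu,
                 eff_prior = eff_prior, model = model,
                 share_controls_safety = share_controls_safety),
            class = "trial_config")
}

#' @export
print.trial_config <- function(x, ...) {
  cat(sprintf(
    "Platform trial config: cohorts %d+%d, up to %d shared controls,\n",
    x$c1, x$c2, x$nc))
  cat(sprintf("  per-dose cap %d (K = %d stages), boundaries l=%.3f u=%.3f\n",
              x$per_dose_cap, x$bounds$K, x$bounds$l, x$bounds$u))
  invisible(x)
}

#' Select shared concurrent controls
#'
#' Among pooled platform control patients concurrent with an analysis
#' (enrolled early enough for full efficacy follow-up by `now`), returns
#' the indices of the most recent `nc` by enrolment day.
#'
#' @param enrol_day enrolment days of the candidate control records.
#' @param now analysis calendar day.
#' @param nc maximum number to return.
#' @param t_eff required follow-up in days.
#' @return integer indices into `enrol_day` (possibly empty).
#' @export
shared_controls <- function(enrol_day, now, nc, t_eff = 28) {
  ok <- which(enrol_day <= now - t_eff)
  if (length(ok) == 0L || nc == 0L) return(integer())
  ok[order(enrol_day[ok], decreasing = TRUE)][seq_len(min(nc, length(ok)))]
}

#' Default pool of previous platform controls
#'
#' A steady-state platform supplies up to `nc` concurrent control
#' patients recruited by other compound evaluations before this one
#' enters; the pool is drawn from the control-arm outcome distribution
#' with enrolment days running back at `c2` per week from day 0.
#' Set `nc = 0` (or pass an explicit empty pool) for a first-in-platform
#' evaluation.
#'
#' @param tc a [trial_config()].
#' @param p0 true control-arm DLE probability.
#' @return a list with fields `enrol`, `y_dle`, `time`, `event`, or
#'   `NULL` when `tc$nc == 0`.
#' @export
default_control_pool <- function(tc, p0) {
  if (tc$nc == 0L) return(NULL)
  d <- draw_patients_raw(tc$nc, p0, 1, tc$model)
  list(enrol = -7L * ceiling(seq_len(tc$nc) / tc$c2),
       y_dle = d$y_dle, time = d$time, event = d$event)
}

# internal: run one platform evaluation of a compound over generic
# "arms" 1..A with a safety driver abstracting single-agent vs combo.
# driver: list(update(events, n) -> post, safe(post) -> arm ids,
#              next_arm(current, post) -> arm id or NA)
run_platform <- function(tc, p_dle, hr, driver, seed, control_pool = NULL,
                         max_day = 2100) {
  A <- length(p_dle) - 1L          # active arms; entry 1 is control
  c1 <- tc$c1; c2 <- tc$c2; csz <- c1 + c2
  K <- tc$bounds$K
  t_safe <- tc$model$t_safe; t_eff <- tc$model$t_eff
  set.seed(seed)

  if (is.null(control_pool)) {
    control_pool <- default_control_pool(tc, p_dle[1L])
  }
  n_pool <- if (is.null(control_pool)) 0L else length(control_pool$enrol)
  cap_n <- A * tc$per_dose_cap + 3L * csz + n_pool
  pat <- list(arm = integer(cap_n), owner = integer(cap_n),
              enrol = integer(cap_n), y = integer(cap_n),
              time = numeric(cap_n), event = integer(cap_n))
  np <- 0L
  if (n_pool > 0L) {
    idx <- seq_len(n_pool)
    pat$arm[idx] <- 0L
    pat$owner[idx] <- 0L           # owner 0: previous-compound controls
    pat$enrol[idx] <- as.integer(control_pool$enrol)
    pat$y[idx] <- as.integer(control_pool$y_dle)
    pat$time[idx] <- control_pool$time
    pat$event[idx] <- as.integer(control_pool$event)
    np <- n_pool
  }
  recruit <- function(arm_id, day) {
    dr_a <- draw_patients_raw(c1, p_dle[arm_id + 1L], hr[arm_id + 1L],
                              tc$model)
    dr_c <- draw_patients_raw(c2, p_dle[1L], 1, tc$model)
    idx <- np + seq_len(csz)
    pat$arm[idx] <<- c(rep(arm_id, c1), rep(0L, c2))
    pat$owner[idx] <<- arm_id
    pat$enrol[idx] <<- day
    pat$y[idx] <<- c(dr_a$y_dle, dr_c$y_dle)
    pat$time[idx] <<- c(dr_a$time, dr_c$time)
    pat$event[idx] <<- c(dr_a$event, dr_c$event)
    np <<- np + csz
  }

  # Dose-finding assigns one cohort per safety readout to the currently
  # targeted safe dose (no level skipping) and ends once the posterior
  # target dose — the safe dose maximizing the target-interval
  # probability — has graduated or stopped.  Each graduated dose runs
  # its own sequential efficacy evaluation: an analysis 28 days after
  # the last cohort of the stage, recruiting one further cohort per
  # continue decision, so each stage adds one cohort as the boundary
  # calibration assumes.  Dose safety is re-checked at analysis times.
  status <- rep("untested", A)      # untested/escal/evaluating/stopped
  reason <- rep(NA_character_, A)   # safety/futility/efficacy/not_graduated
  n_coh <- integer(A)               # cohorts recruited on the arm
  coh2_day <- rep(NA_integer_, A)   # enrolment day of the 2nd cohort
  intake <- integer(A)              # active + own-control intake
  kstage <- integer(A)
  next_analysis <- rep(NA_integer_, A)
  pi_last <- rep(NA_real_, A)
  escal_active <- TRUE
  current <- 1L
  end_day <- 0L
  post_cache <- NULL
  safe_cache <- NULL
  nn_cache <- NULL
  ev_cache <- NULL

  # first cohort on the first arm at day 0
  recruit(current, 0L)
  status[current] <- "escal"
  n_coh[current] <- 1L
  intake[current] <- csz

  analyse_arm <- function(a, day) {
    seen <- pat$enrol[seq_len(np)] <= day - t_eff
    tre <- which(seen & pat$arm[seq_len(np)] == a)
    own <- which(seen & pat$arm[seq_len(np)] == 0L &
                   pat$owner[seq_len(np)] == a)
    oth <- which(pat$arm[seq_len(np)] == 0L & pat$owner[seq_len(np)] != a)
    sh <- oth[shared_controls(pat$enrol[oth], day, tc$nc, t_eff)]
    ii <- c(tre, own, sh)
    posterior_efficacy(pat$time[ii], pat$event[ii],
                       as.integer(pat$arm[ii] == a), tc$eff_prior)
  }

  for (day in seq(7L, max_day, by = 7L)) {
    if (!any(status == "evaluating") && !escal_active) break

    # --- safety posterior on all DLE readouts available today
    seen <- which(pat$enrol[seq_len(np)] <= day - t_safe)
    if (!tc$share_controls_safety) {
      seen <- seen[pat$arm[seen] != 0L | pat$owner[seen] == current]
    }
    arm1 <- pat$arm[seen] + 1L
    nn <- tabulate(arm1, A + 1L)
    ev <- tabulate(arm1[pat$y[seen] == 1L], A + 1L)
    if (is.null(post_cache) || !identical(nn, nn_cache) ||
        !identical(ev, ev_cache)) {
      post_cache <- driver$update(ev, nn)
      safe_cache <- driver$safe(post_cache)
      nn_cache <- nn; ev_cache <- ev
    }
    post <- post_cache
    safe <- safe_cache

    # --- graduation of safe arms with two followed-up cohorts
    for (a in which(status == "escal")) {
      if (n_coh[a] >= 2L && !is.na(coh2_day[a]) &&
          coh2_day[a] <= day - t_eff) {
        if (a %in% safe) {
          status[a] <- "evaluating"
          next_analysis[a] <- day
        } else if (!escal_active) {
          status[a] <- "stopped"; reason[a] <- "safety"
          end_day <- max(end_day, day)
        }
      }
    }

    # --- efficacy analyses due today (dose safety re-checked here)
    for (a in which(status == "evaluating")) {
      if (is.na(next_analysis[a]) || next_analysis[a] > day) next
      if (!(a %in% safe)) {
        status[a] <- "stopped"; reason[a] <- "safety"
        next_analysis[a] <- NA_integer_
        end_day <- max(end_day, day)
        next
      }
      kstage[a] <- kstage[a] + 1L
      pi_post <- analyse_arm(a, day)
      pi_last[a] <- pi_post
      k_eff <- if (kstage[a] >= K || intake[a] + csz > tc$per_dose_cap)
        K else kstage[a]
      dec <- stopping_decision(pi_post, k_eff, tc$bounds)
      if (dec == "continue") {
        recruit(a, day)
        n_coh[a] <- n_coh[a] + 1L
        intake[a] <- intake[a] + csz
        next_analysis[a] <- day + t_eff
      } else {
        status[a] <- "stopped"; reason[a] <- dec
        next_analysis[a] <- NA_integer_
        end_day <- max(end_day, day)
      }
    }

    # --- dose-finding cohort assignment
    if (escal_active) {
      if (length(safe) == 0L) {
        escal_active <- FALSE
        for (a in which(status %in% c("untested", "escal"))) {
          status[a] <- "stopped"; reason[a] <- "safety"
        }
        end_day <- max(end_day, day)
      } else {
        # dose-finding ends once the posterior target dose has entered
        # (or finished) its efficacy evaluation
        tp <- driver$target_probs(post)
        best <- safe[tp[safe] == max(tp[safe])]
        if (length(best) > 1L) best <- best[sample.int(length(best), 1L)]
        cand <- driver$adjacent(current)
        cand <- cand[cand %in% safe & status[cand] %in%
                       c("untested", "escal") &
                       intake[cand] + csz <= tc$per_dose_cap]
        if (!status[best] %in% c("untested", "escal") ||
            length(cand) == 0L) {
          escal_active <- FALSE
          end_day <- max(end_day, day)
        } else {
          current <- driver$next_arm(current, post, cand)
          recruit(current, day)
          if (status[current] == "untested") status[current] <- "escal"
          n_coh[current] <- n_coh[current] + 1L
          if (n_coh[current] == 2L) coh2_day[current] <- day
          intake[current] <- intake[current] + csz
        }
      }
    }
  }

  # arms still awaiting graduation when everything else ended
  for (a in which(status %in% c("untested", "escal"))) {
    status[a] <- "stopped"
    reason[a] <- if (n_coh[a] >= 2L) "safety" else "not_graduated"
  }

  idx <- seq_len(np)
  structure(list(
    recommended = which(reason == "efficacy"),
    reason = reason,
    n_total = np - n_pool,         # pool patients belong to the platform
    n_per_arm = tabulate(pat$arm[idx][-seq_len(n_pool)] + 1L, A + 1L),
    intake = intake,
    duration = end_day,
    pi_last = pi_last,
    stages = kstage,
    patients = data.frame(arm = pat$arm[idx], owner = pat$owner[idx],
                          enrol_day = pat$enrol[idx], y_dle = pat$y[idx],
                          time = pat$time[idx], event = pat$event[idx])),
    class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("Platform evaluation result\n")
  cat("  recommended arms:",
      if (length(x$recommended)) paste(x$recommended, collapse = ", ")
      else "none", "\n")
  cat("  stop reasons:", paste(x$reason, collapse = ", "), "\n")
  cat(sprintf("  total n = %d, duration = %d days\n", x$n_total, x$duration))
  invisible(x)
}

# driver for the single-agent safety model
single_agent_driver <- function(tc, support) {
  cfg <- tc$cfg
  m <- cfg$m
  list(
    update = function(events, n) update_posterior(support, events, n),
    safe = function(post) safe_dose_set(post, cfg),
    target_probs = function(post) {
      vapply(seq_len(m), target_interval_prob, 0, post = post, cfg = cfg)
    },
    adjacent = function(current) {
      seq_len(m)[abs(seq_len(m) - current) <= 1L]
    },
    next_arm = function(current, post, cand) {
      probs <- vapply(seq_len(m), target_interval_prob, 0,
                      post = post, cfg = cfg)
      sel <- select_next_dose(current, cand, probs)
      if (is.na(sel)) NA_integer_ else sel
    })
}

#' Simulate one single-agent platform evaluation
#'
#' Runs the full seamless design for one compound with three (or `m`)
#' active doses against randomized control: cohort-wise Bayesian dose
#' escalation with overdose control at a 7-day DLE readout, graduation
#' of safe doses with two followed-up cohorts into independent
#' sequential efficacy evaluations at a 28-day time-to-improvement
#' readout, with shared concurrent controls augmenting each analysis.
#'
#' @param tc a [trial_config()].
#' @param scn a [scenario()] (truth).
#' @param seed integer seed (one replicate is fully determined by
#'   `(tc, scn, seed)`).
#' @param control_pool previous concurrent platform controls: a list or
#'   data frame with fields `enrol` (days, typically negative), `y_dle`,
#'   `time`, `event`.  Defaults to [default_control_pool()] (a
#'   steady-state platform); pass a zero-row pool for a
#'   first-in-platform compound.
#' @param support optional precomputed [safety_support()] (rebuilt from
#'   `tc` when omitted; pass one when replicating).
#' @return a `trial_result`: recommended doses, per-arm stop reasons
#'   (`efficacy`, `futility`, `safety`, `not_graduated`), sample sizes,
#'   calendar duration and the patient-level ledger.
#' @export
run_single_agent_trial <- function(tc, scn, seed = 1L, control_pool = NULL,
                                   support = NULL) {
  stopifnot(inherits(tc, "trial_config"), inherits(scn, "scenario"),
            length(scn$p_dle) == tc$cfg$m + 1L)
  if (is.null(support)) {
    grid <- build_skeleton(skeleton_probs(tc$cfg$p0_prior, tc$nu, tc$cfg$m),
                           theta2_hat = exp(tc$prior$mu2))
    support <- safety_support(tc$prior, grid, cfg = tc$cfg)
  }
  run_platform(tc, scn$p_dle, scn$hr, single_agent_driver(tc, support),
               seed = seed, control_pool = control_pool)
}

# driver for the dual-agent combination safety model; arms are rows of
# support$combos[-1, ] (j fastest)
combo_driver <- function(tc, support) {
  cfg <- tc$cfg
  combos <- support$combos[-1, , drop = FALSE]
  list(
    update = function(events, n) update_combo_posterior(support, events, n),
    safe = function(post) {
      which(combo_event_probs(post, cfg)$overdose < cfg$c_overdose)
    },
    target_probs = function(post) combo_event_probs(post, cfg)$target,
    adjacent = function(current) {
      cur <- combos[current, ]
      which(abs(combos[, 1] - cur[1]) + abs(combos[, 2] - cur[2]) <= 1L)
    },
    next_arm = function(current, post, cand) {
      tp <- combo_event_probs(post, cfg)$target
      sel <- cand[tp[cand] == max(tp[cand])]
      if (length(sel) > 1L) sel <- sel[sample.int(length(sel), 1L)]
      sel
    })
}

#' Simulate one dual-agent combination platform evaluation
#'
#' As [run_single_agent_trial()], but escalation moves over the grid of
#' dose combinations of two agents using the four-parameter interaction
#' model: from the current combination only one agent may change, by
#' one level.  Each combination graduates into its own sequential
#' efficacy evaluation.
#'
#' @param tc a [trial_config()] (its single-agent prior is ignored).
#' @param scn a [combo_scenario()].
#' @param cprior a [combo_prior()].
#' @param seed integer seed.
#' @param control_pool previous platform controls as in
#'   [run_single_agent_trial()].
#' @param support optional precomputed [combo_support()].
#' @return a `trial_result`; arms are indexed in the row order of the
#'   support's combination table (`j` fastest), recorded in attribute
#'   `combos`.
#' @export
run_combo_trial <- function(tc, scn, cprior = combo_prior(), seed = 1L,
                            control_pool = NULL, support = NULL) {
  stopifnot(inherits(tc, "trial_config"), inherits(scn, "combo_scenario"))
  if (is.null(support)) {
    grid <- build_combo_skeleton(J = ncol(scn$p_dle), L = nrow(scn$p_dle),
                                 p0_prior = tc$cfg$p0_prior, prior = cprior)
    support <- combo_support(cprior, grid, cfg = tc$cfg)
  }
  combos <- support$combos[-1, , drop = FALSE]
  p_dle <- c(scn$p0, scn$p_dle[cbind(combos[, 2], combos[, 1])])
  hr <- c(1, scn$hr[cbind(combos[, 2], combos[, 1])])
  res <- run_platform(tc, p_dle, hr, combo_driver(tc, support),
                      seed = seed, control_pool = control_pool)
  attr(res, "combos") <- combos
  res
}
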