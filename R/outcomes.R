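#' Outcome model for correlated safety and efficacy responses
#'
#' Patient-level outcomes are a binary dose-limiting event (DLE) observed
#' by `t_safe` days and a time-to-improvement following a proportional
#' hazards Weibull distribution, administratively censored at `t_eff`
#' days.  The two outcomes are coupled through a Gaussian copula with
#' latent correlation `rho`; the marginals are preserved exactly.
#'
#' The default Weibull parameters (`S(t) = exp(-rate * t^shape)` with
#' rate 0.085 per day^shape and shape 0.797) give a median recovery time
#' of 14 days and a 70% recovery rate within 28 days on the control arm.
#' A dose's hazard ratio multiplies the rate.
#'
#' @param weibull_rate,weibull_shape Weibull rate and shape of the control
#'   arm time-to-improvement distribution.
#' @param t_safe days after which the DLE indicator is read out.
#' @param t_eff administrative censoring time for time-to-improvement.
#' @param rho latent Gaussian correlation between the DLE indicator and
#'   the recovery time (`0 <= rho < 1`).
#' @return an object of class `outcome_model`.
#' @export
outcome_model <- function(weibull_rate = 0.085, weibull_shape = 0.797,
                          t_safe = 7, t_eff = 28, rho = 0.8) {
  stopifnot(weibull_rate > 0, weibull_shape > 0,
            rho >= 0, rho < 1, t_safe < t_eff)
  structure(list(weibull_rate = weibull_rate, weibull_shape = weibull_shape,
                 t_safe = t_safe, t_eff = t_eff, rho = rho),
            class = "outcome_model")
}

#' Survival function of the time-to-improvement distribution
#'
#' `S(t) = exp(-hr * rate * t^shape)`: a proportional-hazards Weibull in
#' which the hazard ratio `hr` multiplies the rate parameter.  Note that
#' larger hazard ratios mean *faster improvement* (recovery is the
#' event).
#'
#' @param t time in days (vectorized).
#' @param hr hazard ratio versus control (positive).
#' @param model an [outcome_model()].
#' @return survival probabilities `S(t)`.
#' @export
recovery_survival <- function(t, hr = 1, model = outcome_model()) {
  stopifnot(all(hr > 0), all(t >= 0))
  exp(-hr * model$weibull_rate * t^model$weibull_shape)
}

# inverse CDF of the PH-Weibull: u in (0,1) -> time
recovery_quantile <- function(u, hr, model) {
  (-log(1 - u) / (hr * model$weibull_rate))^(1 / model$weibull_shape)
}

#' Draw correlated (DLE, time-to-improvement) outcomes for one arm
#'
#' Gaussian copula construction: a bivariate standard normal pair with
#' correlation `rho` is drawn; the first coordinate is thresholded at
#' `qnorm(p_dle)` to give the binary DLE, the second is mapped through
#' the probability integral transform to the arm's Weibull recovery
#' time.  Positive `rho` associates DLEs with slower recovery.
#'
#' @param n number of patients.
#' @param p_dle true DLE probability of the arm.
#' @param hr true hazard ratio of the arm versus control.
#' @param model an [outcome_model()].
#' @return a data frame with columns `y_dle` (0/1), `time` (days, censored
#'   at `t_eff`), `event` (1 if improvement observed by `t_eff`), and
#'   `time_true` (uncensored latent recovery time).
#' @export
draw_patients <- function(n, p_dle, hr, model = outcome_model()) {
  d <- draw_patients_raw(n, p_dle, hr, model)
  data.frame(y_dle = d$y_dle, time = d$time, event = d$event,
             time_true = d$time_true)
}

# list-returning fast path used inside the simulation engine
draw_patients_raw <- function(n, p_dle, hr, model) {
  stopifnot(n >= 0, p_dle > 0, p_dle < 1, hr > 0)
  if (n == 0L) {
    return(list(y_dle = integer(), time = numeric(),
                event = integer(), time_true = numeric()))
  }
  z1 <- rnorm(n)
  z2 <- model$rho * z1 + sqrt(1 - model$rho^2) * rnorm(n)
  y <- as.integer(z1 <= qnorm(p_dle))
  tt <- recovery_quantile(pnorm(z2), hr, model)
  list(y_dle = y, time = pmin(tt, model$t_eff),
       event = as.integer(tt <= model$t_eff), time_true = tt)
}

#' Single-agent truth scenarios
#'
#' The built-in scenario grid pairs five dose-DLE curves with five
#' dose-efficacy curves over a control arm and three active doses.
#' Safety scenario 0 is benign (all doses safe), scenario 4 has no safe
#' active dose; efficacy scenario 0 is global null, scenario 4 makes all
#' doses desirable.
#'
#' @param safety integer 0..4 selecting the dose-DLE curve.
#' @param efficacy integer 0..4 selecting the dose-hazard-ratio curve.
#' @return an object of class `scenario` with fields `p_dle` (length 4,
#'   control first), `hr` (length 4, control first) and `label`.
#' @export
single_agent_scenario <- function(safety, efficacy) {
  p_tab <- list(`0` = c(0.10, 0.12, 0.13, 0.15),
                `1` = c(0.10, 0.12, 0.15, 0.30),
                `2` = c(0.10, 0.15, 0.30, 0.45),
                `3` = c(0.10, 0.30, 0.45, 0.60),
                `4` = c(0.10, 0.45, 0.60, 0.60))
  hr_tab <- list(`0` = c(1.00, 1.00, 1.00, 1.00),
                 `1` = c(1.00, 1.00, 1.75, 1.75),
                 `2` = c(1.00, 1.50, 1.75, 1.75),
                 `3` = c(1.00, 1.50, 1.75, 2.00),
                 `4` = c(1.00, 1.75, 2.00, 2.00))
  stopifnot(as.character(safety) %in% names(p_tab),
            as.character(efficacy) %in% names(hr_tab))
  scenario(p_dle = p_tab[[as.character(safety)]],
           hr = hr_tab[[as.character(efficacy)]],
           label = sprintf("S%d-E%d", safety, efficacy))
}

#' Construct a truth scenario
#'
#' @param p_dle per-arm true DLE probabilities, control first.
#' @param hr per-arm true hazard ratios versus control, control first
#'   (control entry must be 1).
#' @param label scenario label.
#' @return an object of class `scenario`.
#' @export
scenario <- function(p_dle, hr, label = "") {
  stopifnot(length(p_dle) == length(hr),
            all(p_dle > 0), all(p_dle < 1), all(hr > 0), hr[1] == 1)
  structure(list(p_dle = as.numeric(p_dle), hr = as.numeric(hr),
                 label = label), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("Trial truth scenario", x$label, "\n")
  cat("  P(DLE):", paste(sprintf("%.2f", x$p_dle), collapse = " "), "\n")
  cat("  HR    :", paste(sprintf("%.2f", x$hr), collapse = " "), "\n")
  invisible(x)
}

#' Dual-agent truth scenarios
#'
#' Scenario grid for combinations of 2 doses of agent A and 3 doses of
#' agent B.  The control arm keeps DLE probability 0.10 and hazard ratio
#' 1.  Matrices are indexed `[l, j]` = (dose of B, dose of A), matching
#' the layout B-dose down the rows.
#'
#' @param safety integer 0..3 selecting the combination-DLE surface.
#' @param efficacy integer 0..3 selecting the combination-HR surface.
#' @return an object of class `combo_scenario` with fields `p_dle` and
#'   `hr` (3x2 matrices over active combinations), `p0`, `label`.
#' @export
combo_scenario <- function(safety, efficacy) {
  p_tab <- list(
    `0` = matrix(c(0.10, 0.13, 0.15, 0.12, 0.15, 0.18), nrow = 3),
    `1` = matrix(c(0.10, 0.25, 0.50, 0.12, 0.30, 0.55), nrow = 3),
    `2` = matrix(c(0.15, 0.25, 0.30, 0.30, 0.35, 0.45), nrow = 3),
    `3` = matrix(c(0.40, 0.45, 0.50, 0.45, 0.50, 0.55), nrow = 3))
  hr_tab <- list(
    `0` = matrix(1, nrow = 3, ncol = 2),
    `1` = matrix(c(1.00, 1.25, 1.50, 1.25, 1.50, 1.75), nrow = 3),
    `2` = matrix(c(1.00, 1.25, 1.50, 1.50, 1.75, 2.00), nrow = 3),
    `3` = matrix(c(1.00, 1.50, 1.75, 1.50, 1.75, 1.75), nrow = 3))
  stopifnot(as.character(safety) %in% names(p_tab),
            as.character(efficacy) %in% names(hr_tab))
  structure(list(p_dle = p_tab[[as.character(safety)]],
                 hr = hr_tab[[as.character(efficacy)]],
                 p0 = 0.10,
                 label = sprintf("C%d-E%d", safety, efficacy)),
            class = "combo_scenario")
}
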