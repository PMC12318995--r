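#' First-phase response-selection drift
#'
#' In the first phase of response selection both the task-relevant target
#' colour and the task-irrelevant colour word drive evidence accumulation.
#' On congruent trials the two pull in the same (correct) direction; on
#' incongruent trials the word pulls toward the error boundary.
#'
#' @param params A [dstp_params()] object.
#' @param congruency `"congruent"` or `"incongruent"`.
#' @return Signed drift rate (evidence units / s); positive is toward the
#'   correct response.
#' @examples
#' p <- dstp_params(0.10, 0.05, 0.35, 0.9, 0.18, 0.22, 0.3)
#' phase1_drift(p, "congruent")    # 0.15
#' phase1_drift(p, "incongruent")  # 0.05
#' @export
phase1_drift <- function(params, congruency = c("congruent", "incongruent")) {
  validate_dstp_params(params)
  congruency <- match.arg(congruency)
  p <- unclass(params)
  if (congruency == "congruent") {
    unname(p[["mu_target_color"]] + p[["mu_color_word"]])
  } else {
    unname(p[["mu_target_color"]] - p[["mu_color_word"]])
  }
}

#' Simulate DSTP trials for one condition
#'
#' Runs the trial-level DSTP race: a response-selection (RS) accumulator with
#' boundaries at `+/- crit_a` (upper = correct) and a stimulus-selection (SS)
#' accumulator with boundaries at `+/- crit_c`, both starting at 0, advanced
#' in lockstep by an Euler-Maruyama scheme with independent noise. If RS hits
#' a boundary first the trial ends there (phase winner `"RS1"`). If SS
#' finishes first, the RS drift is replaced -- `+mu_rs2` when the target was
#' selected; when the word was selected, `+mu_rs2` on congruent and `-mu_rs2`
#' on incongruent trials -- and RS continues from its accumulated value until
#' a response boundary is reached (phase winner `"SS"`).
#'
#' A continuity correction (barrier shifted inward by 0.5826 * sigma *
#' sqrt(dt)) compensates for discrete boundary monitoring, so accuracy and
#' mean decision time converge to the continuous-time diffusion; see
#' [wiener_stats()] for the single-stage closed forms used to validate this.
#'
#' @param params A [dstp_params()] object.
#' @param congruency `"congruent"` or `"incongruent"`.
#' @param n_trials Number of trials (>= 1).
#' @param config A [sim_config()] object.
#' @return A data frame with one row per trial and columns `rt_s` (decision
#'   time plus `ter`, s), `correct` (logical), `phase_winner` (`"RS1"` or
#'   `"SS"`), `selected_stimulus` (`"none"`, `"target"` or `"word"`), and
#'   `censored` (logical; trials undecided at `max_decision_time`, responded
#'   by RS accumulator sign).
#' @examples
#' p <- dstp_params(0.08, 0.12, 0.35, 0.9, 0.18, 0.22, 0.3)
#' sim <- simulate_dstp(p, "incongruent", 1000, sim_config(seed = 1))
#' mean(sim$correct); mean(sim$rt_s[sim$correct])
#' @export
simulate_dstp <- function(params, congruency = c("congruent", "incongruent"),
                          n_trials, config = sim_config()) {
  validate_dstp_params(params)
  congruency <- match.arg(congruency)
  if (!inherits(config, "dstp_sim_config")) stop("config must come from sim_config()", call. = FALSE)
  if (!is.numeric(n_trials) || length(n_trials) != 1L || is.na(n_trials) ||
      n_trials < 1 || n_trials != round(n_trials)) {
    stop("n_trials must be a positive integer", call. = FALSE)
  }
  p <- unclass(params)
  out <- .dstp_simulate_cpp(as.integer(n_trials),
                            p[["mu_target_color"]], p[["mu_color_word"]],
                            p[["mu_ss"]], p[["mu_rs2"]],
                            p[["crit_a"]], p[["crit_c"]], p[["ter"]],
                            congruency == "congruent",
                            config$dt, config$sigma, config$max_decision_time,
                            resolve_seed(config))
  data.frame(rt_s = out$rt_s,
             correct = out$correct,
             phase_winner = c("RS1", "SS")[out$phase_winner],
             selected_stimulus = c("none", "target", "word")[out$selected + 1L],
             censored = out$censored,
             stringsAsFactors = FALSE)
}

#' Simulate a single DSTP trial
#'
#' Convenience wrapper around [simulate_dstp()] with `n_trials = 1`.
#'
#' @inheritParams simulate_dstp
#' @return A one-row data frame (see [simulate_dstp()]).
#' @export
simulate_trial <- function(params, congruency = c("congruent", "incongruent"),
                           config = sim_config()) {
  simulate_dstp(params, congruency, 1L, config)
}

#' Closed-form two-boundary Wiener statistics
#'
#' Choice probability and mean decision time of a single Wiener diffusion
#' starting at 0 between absorbing boundaries at `+/- a`:
#' `p_upper = 1 / (1 + exp(-2 v a / sigma^2))` and
#' `E[T] = (a / v) * tanh(a v / sigma^2)` (for `v = 0`, `a^2 / sigma^2`).
#' Used as the analytic oracle for the simulator in the single-stage regime
#' (stimulus selection disabled by a very large `crit_c`).
#'
#' @param v Drift rate (evidence units / s).
#' @param a Boundary height (> 0).
#' @param sigma Diffusion noise standard deviation (> 0).
#' @return A list with `p_upper` and `mean_decision_time` (s).
#' @examples
#' wiener_stats(v = 0, a = 0.1, sigma = 0.1)    # p 0.5, mean 1 s
#' wiener_stats(v = 0.1, a = 0.1, sigma = 0.1)  # p ~0.8808, mean tanh(1)
#' @export
wiener_stats <- function(v, a, sigma) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("a must be a single positive number", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be a single positive number", call. = FALSE)
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
    stop("v must be a single finite number", call. = FALSE)
  s2 <- sigma^2
  if (v == 0) {
    list(p_upper = 0.5, mean_decision_time = a^2 / s2)
  } else {
    list(p_upper = 1 / (1 + exp(-2 * v * a / s2)),
         mean_decision_time = (a / v) * tanh(a * v / s2))
  }
}
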