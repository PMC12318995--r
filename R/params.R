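#' DSTP parameter set
#'
#' Construct and validate the seven free parameters of the dual-stage
#' two-phase (DSTP) model of selective attention. Two diffusion processes
#' race: an early response-selection accumulator whose drift combines the
#' target colour and the (task-irrelevant) colour word, and a stimulus
#' selection accumulator; when stimulus selection finishes first, response
#' selection enters a second, cleaner phase.
#'
#' Drift magnitudes are stored unsigned; the sign is applied by congruency
#' (first phase) or by the outcome of stimulus selection (second phase).
#'
#' @param mu_target_color Drift magnitude for the target colour during the
#'   first response-selection phase (evidence units / s).
#' @param mu_color_word Drift magnitude contributed by the colour word during
#'   the first response-selection phase (evidence units / s).
#' @param mu_ss Drift magnitude of the late stimulus-selection process
#'   (evidence units / s).
#' @param mu_rs2 Drift magnitude of the second response-selection phase
#'   (evidence units / s).
#' @param crit_a Height of the response-selection boundary (evidence units).
#' @param crit_c Height of the stimulus-selection boundary (evidence units).
#' @param ter Non-decision time: encoding plus motor latency (s).
#'
#' @return An object of class `dstp_params`: a named numeric vector of the
#'   seven parameters.
#' @examples
#' p <- dstp_params(mu_target_color = 0.08, mu_color_word = 0.12,
#'                  mu_ss = 0.35, mu_rs2 = 0.9, crit_a = 0.18,
#'                  crit_c = 0.22, ter = 0.30)
#' p
#' @seealso [simulate_dstp()], [dstp_fit()], [interference_ratio()]
#' @export
dstp_params <- function(mu_target_color, mu_color_word, mu_ss, mu_rs2,
                        crit_a, crit_c, ter) {
  p <- c(mu_target_color = as.numeric(mu_target_color),
         mu_color_word = as.numeric(mu_color_word),
         mu_ss = as.numeric(mu_ss),
         mu_rs2 = as.numeric(mu_rs2),
         crit_a = as.numeric(crit_a),
         crit_c = as.numeric(crit_c),
         ter = as.numeric(ter))
  validate_dstp_params(p)
  class(p) <- "dstp_params"
  p
}

#' Names of the seven DSTP parameters, in canonical order
#' @return Character vector of length 7.
#' @export
dstp_param_names <- function() {
  c("mu_target_color", "mu_color_word", "mu_ss", "mu_rs2",
    "crit_a", "crit_c", "ter")
}

validate_dstp_params <- function(p) {
  nm <- dstp_param_names()
  if (!all(nm %in% names(p))) {
    stop("dstp_params requires fields: ", paste(setdiff(nm, names(p)), collapse = ", "),
         call. = FALSE)
  }
  p <- unclass(p)[nm]
  if (any(!is.finite(p))) stop("all DSTP parameters must be finite", call. = FALSE)
  drifts <- p[c("mu_target_color", "mu_color_word", "mu_ss", "mu_rs2")]
  if (any(drifts < 0)) {
    stop("drift magnitudes must be >= 0 (sign is applied by congruency, not stored)",
         call. = FALSE)
  }
  if (p[["crit_a"]] <= 0) stop("crit_a must be > 0", call. = FALSE)
  if (p[["crit_c"]] <= 0) stop("crit_c must be > 0", call. = FALSE)
  if (p[["ter"]] < 0) stop("ter must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Coerce a named vector or list to `dstp_params`
#' @param x Named numeric vector, list, or one-row data frame holding the
#'   seven parameter fields.
#' @return A `dstp_params` object.
#' @export
as_dstp_params <- function(x) {
  if (inherits(x, "dstp_params")) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- as.list(x)
  }
  x <- unlist(x[dstp_param_names()])
  do.call(dstp_params, as.list(x))
}

#' @export
print.dstp_params <- function(x, digits = 4, ...) {
  cat("DSTP parameters (7 free parameters):\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Simulation settings for the DSTP integrator
#'
#' Numerical settings of the Euler-Maruyama scheme. The defaults follow the
#' scaling convention of the DSTP fitting literature: step `dt` = 1 ms and
#' within-trial diffusion noise `sigma` = 0.1 per sqrt(s) for every
#' accumulator. `max_decision_time` reflects the 5,000 ms response window of
#' the Shape Stroop task; trials still undecided at the deadline are returned
#' censored (responding by accumulator sign), never dropped.
#'
#' @param dt Integration step (s). Must be > 0.
#' @param sigma Diffusion noise standard deviation per unit sqrt(s). Must be > 0.
#' @param max_decision_time Censoring cap on the decision time (s).
#' @param seed Optional integer seed for the simulator's own random stream.
#'   When `NULL`, a seed is drawn from R's RNG (so `set.seed()` upstream
#'   still yields reproducible runs).
#' @return An object of class `dstp_sim_config` (a named list).
#' @examples
#' sim_config()
#' sim_config(dt = 0.0005, seed = 42)
#' @export
sim_config <- function(dt = 0.001, sigma = 0.1, max_decision_time = 5.0,
                       seed = NULL) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be a single positive number", call. = FALSE)
  if (!is.numeric(max_decision_time) || length(max_decision_time) != 1L ||
      !is.finite(max_decision_time) || max_decision_time <= 0)
    stop("max_decision_time must be a single positive number", call. = FALSE)
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("seed must be an integer or NULL", call. = FALSE)
  }
  structure(list(dt = dt, sigma = sigma,
                 max_decision_time = max_decision_time, seed = seed),
            class = "dstp_sim_config")
}

#' @export
print.dstp_sim_config <- function(x, ...) {
  cat(sprintf("DSTP simulation settings: dt = %g s, sigma = %g, max decision time = %g s, seed = %s\n",
              x$dt, x$sigma, x$max_decision_time,
              if (is.null(x$seed)) "from R RNG" else x$seed))
  invisible(x)
}

# draw a scalar seed for the C++ stream, tied to R's RNG when unset
resolve_seed <- function(config) {
  if (!is.null(config$seed)) return(as.double(config$seed))
  as.double(sample.int(.Machine$integer.max, 1L))
}
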