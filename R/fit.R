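#' Default parameter bounds for fitting
#'
#' Start values are drawn uniformly within these bounds and out-of-bounds
#' proposals are penalised during optimisation. The ranges bracket, with wide
#' margins, the magnitudes typically estimated for Stroop-type conflict
#' tasks.
#'
#' @return A 7 x 2 matrix with rows in [dstp_param_names()] order and columns
#'   `lower`, `upper`.
#' @export
dstp_bounds <- function() {
  b <- rbind(mu_target_color = c(0, 0.6),
             mu_color_word = c(0, 0.6),
             mu_ss = c(0.01, 2.0),
             mu_rs2 = c(0.05, 2.5),
             crit_a = c(0.03, 0.4),
             crit_c = c(0.03, 0.6),
             ter = c(0.1, 0.6))
  colnames(b) <- c("lower", "upper")
  b[dstp_param_names(), , drop = FALSE]
}

check_bounds <- function(bounds) {
  nm <- dstp_param_names()
  if (!is.matrix(bounds) || !all(nm %in% rownames(bounds)) || ncol(bounds) != 2L)
    stop("bounds must be a 7 x 2 matrix with the DSTP parameter names as rows",
         call. = FALSE)
  bounds <- bounds[nm, , drop = FALSE]
  if (any(bounds[, 1] >= bounds[, 2]))
    stop("each lower bound must be below its upper bound", call. = FALSE)
  bounds
}

# G2 objective over both congruency conditions with common random numbers:
# the two simulator seeds are fixed for the whole fit, so the stochastic
# objective is deterministic given the parameters and Nelder-Mead does not
# stall on Monte-Carlo noise.
make_g2_objective <- function(bins, n_sim, config, bounds, crn_seeds) {
  lower <- bounds[, 1]
  span <- bounds[, 2] - bounds[, 1]
  conds <- c("incongruent", "congruent")
  function(z) {
    viol <- sum(pmax(-z, 0) + pmax(z - 1, 0))
    if (viol > 0) return(1e6 + 1e7 * viol)
    theta <- lower + z * span
    total <- 0
    for (i in seq_along(conds)) {
      cond <- conds[i]
      b <- bins[[cond]]
      counts <- .dstp_bin_counts_cpp(as.integer(n_sim),
                                     theta[["mu_target_color"]],
                                     theta[["mu_color_word"]],
                                     theta[["mu_ss"]], theta[["mu_rs2"]],
                                     theta[["crit_a"]], theta[["crit_c"]],
                                     theta[["ter"]],
                                     cond == "congruent",
                                     config$dt, config$sigma,
                                     config$max_decision_time,
                                     crn_seeds[i],
                                     b$correct_edges, b$error_edges)
      pred <- pmax(c(counts$correct_counts, counts$error_counts) / n_sim, 1e-5)
      obs <- c(b$correct_counts, b$error_counts)
      total <- total + g2_stat(obs, pred)
    }
    total
  }
}

# Data-anchored start grid: the fastest observed response bounds ter from
# above (min RT = ter + fastest decision), so a ladder of ter offsets below
# min RT, crossed with a low and a high response boundary, places starts on
# both sides of the ter/crit_a tradeoff valley. Remaining starts are uniform.
anchored_starts <- function(data, bounds, n_starts) {
  nm <- dstp_param_names()
  lower <- bounds[, 1]
  span <- bounds[, 2] - bounds[, 1]
  minrt <- min(data$rt_s)
  grid <- expand.grid(dter = c(0.42, 0.22), a0 = c(0.13, 0.20, 0.28))
  z <- matrix(runif(n_starts * 7L), nrow = n_starts,
              dimnames = list(NULL, nm))
  for (i in seq_len(min(nrow(grid), n_starts))) {
    th <- c(mu_target_color = 0.10, mu_color_word = 0.10, mu_ss = 0.40,
            mu_rs2 = 1.0, crit_a = grid$a0[i], crit_c = 0.25,
            ter = min(max(minrt - grid$dter[i], bounds["ter", 1]),
                      bounds["ter", 2]))
    z[i, ] <- (th[nm] - lower) / span
  }
  z
}

check_fit_data <- function(data) {
  need <- c("congruency", "correct", "rt_s")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("trial data lack required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  data$congruency <- as.character(data$congruency)
  for (cond in c("congruent", "incongruent")) {
    sel <- data$congruency == cond
    if (!any(sel))
      stop("trial data contain no ", cond, " trials", call. = FALSE)
    if (!any(data$correct[sel]))
      stop("trial data contain no correct ", cond, " trials", call. = FALSE)
  }
  data
}

#' Fit the DSTP model to one participant's trials
#'
#' Simulation-based estimation of the seven DSTP parameters from the trials
#' of one participant in one word location, with congruency as a within-fit
#' factor: a single parameter set jointly fits congruent and incongruent
#' trials, the two conditions differing only in the sign of the colour-word
#' drift. The objective is the likelihood-ratio chi-square ([g2_stat()])
#' over RT quantile bins ([make_rt_bins()]), summed over the two congruency
#' conditions, each evaluation simulating `n_sim` trials per condition.
#' `n_starts` Nelder-Mead runs (default 50) are launched from start values
#' drawn uniformly within `bounds`, each evaluation simulating `n_sim`
#' (default 5,000) trials per condition, and the run with the smallest G2 is
#' returned. Common random numbers are reused across objective evaluations
#' within the fit. Follow with [dstp_refit()] to polish the winner at higher
#' simulation precision (default 100,000 trials per evaluation).
#'
#' @param data Data frame of one participant x location with columns
#'   `congruency` (`"congruent"`/`"incongruent"`), `correct` (logical) and
#'   `rt_s` (seconds). Both conditions must contain at least one correct
#'   trial.
#' @param n_starts Number of random starts (each a Nelder-Mead run).
#' @param n_sim Simulated trials per congruency condition per objective
#'   evaluation.
#' @param quantile_probs,error_bin_threshold Passed to [make_rt_bins()].
#' @param bounds Parameter bounds as in [dstp_bounds()].
#' @param maxit Nelder-Mead iteration cap per start.
#' @param starts `"uniform"` (all starts drawn uniformly within bounds, the
#'   default protocol) or `"anchored"` (the first six starts form a
#'   data-anchored grid over the non-decision time, laddered below the
#'   fastest observed RT, crossed with a low and a high response boundary;
#'   any remaining starts are uniform). Anchored starts make small
#'   multi-start budgets far more reliable; see the methods vignette.
#' @param config A [sim_config()]; its `seed` field is ignored here (see
#'   `seed`).
#' @param seed Optional integer seed controlling start draws and the common
#'   random numbers.
#' @return An object of class `dstp_fit` with components `params`
#'   ([dstp_params()]), `g2`, `n_starts`, `start_table` (one row per start:
#'   fitted parameters, G2, convergence flag, evaluation count),
#'   `n_sim_per_eval`, `n_sim_final` (`NA` until [dstp_refit()]),
#'   `converged`, `bins`, and the fit settings. Supports `coef()`, `print()`,
#'   `summary()`, `predict()`, `residuals()`, `simulate()` and `plot()`.
#' @examples
#' \donttest{
#' truth <- dstp_params(0.08, 0.12, 0.35, 0.9, 0.18, 0.22, 0.30)
#' dat <- rbind(
#'   cbind(simulate_dstp(truth, "incongruent", 324, sim_config(seed = 1)),
#'         congruency = "incongruent"),
#'   cbind(simulate_dstp(truth, "congruent", 108, sim_config(seed = 2)),
#'         congruency = "congruent"))
#' fit <- dstp_fit(dat, n_starts = 2, n_sim = 500, maxit = 20, seed = 9)
#' coef(fit)
#' }
#' @export
dstp_fit <- function(data, n_starts = 50, n_sim = 5000,
                     quantile_probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                     error_bin_threshold = 11, bounds = dstp_bounds(),
                     maxit = 200, starts = c("uniform", "anchored"),
                     config = sim_config(), seed = NULL) {
  data <- check_fit_data(data)
  bounds <- check_bounds(bounds)
  starts <- match.arg(starts)
  if (n_starts < 1) stop("n_starts must be >= 1", call. = FALSE)
  if (n_sim < 1) stop("n_sim must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  bins <- make_rt_bins(data$rt_s, data$correct,
                       quantile_probs = quantile_probs,
                       congruency = data$congruency,
                       error_bin_threshold = error_bin_threshold)
  crn_seeds <- as.double(sample.int(2147483646L, 2L))
  objective <- make_g2_objective(bins, n_sim, config, bounds, crn_seeds)

  nm <- dstp_param_names()
  lower <- bounds[, 1]
  span <- bounds[, 2] - bounds[, 1]
  start_z <- if (starts == "anchored") anchored_starts(data, bounds, n_starts)
             else matrix(runif(n_starts * 7L), nrow = n_starts,
                         dimnames = list(NULL, nm))

  rows <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    opt <- optim(start_z[s, ], objective, method = "Nelder-Mead",
                 control = list(maxit = maxit))
    theta <- lower + pmin(pmax(opt$par, 0), 1) * span
    rows[[s]] <- data.frame(start = s, as.list(setNames(theta, nm)),
                            g2 = opt$value, convergence = opt$convergence,
                            fevals = unname(opt$counts[1]))
  }
  start_table <- do.call(rbind, rows)
  best <- which.min(start_table$g2)
  params <- as_dstp_params(start_table[best, nm])

  structure(list(params = params,
                 g2 = start_table$g2[best],
                 n_starts = n_starts,
                 start_table = start_table,
                 n_sim_per_eval = n_sim,
                 n_sim_final = NA_integer_,
                 converged = start_table$convergence[best] == 0,
                 bins = bins,
                 bounds = bounds,
                 quantile_probs = quantile_probs,
                 error_bin_threshold = error_bin_threshold,
                 config = config,
                 crn_seeds = crn_seeds,
                 n_trials = vapply(bins, `[[`, 0, "n"),
                 call = match.call()),
            class = "dstp_fit")
}

#' Final refit at higher simulation precision
#'
#' One additional Nelder-Mead pass started from the parameters of a
#' [dstp_fit()], each objective evaluation simulating `n_sim` trials per
#' congruency condition (default 100,000). The returned G2 is computed at
#' this precision, so its Monte-Carlo variance is much smaller than during
#' the multi-start screen.
#'
#' @param object A `dstp_fit`.
#' @param n_sim Simulated trials per condition per evaluation for the final
#'   pass. A value below the screening precision triggers a warning.
#' @param maxit Nelder-Mead iteration cap per pass.
#' @param restarts Number of Nelder-Mead passes: each pass restarts the
#'   simplex at the previous pass's solution, which lets the optimiser
#'   recover from a collapsed simplex.
#' @param top Number of leading screen starts (ranked by screen G2) to
#'   polish; when `top > 1` the polished candidates are compared by a single
#'   high-precision G2 evaluation at `n_sim_select` simulated trials per
#'   condition and the best is returned.
#' @param n_sim_select Simulation precision of the candidate comparison
#'   (only used when `top > 1`).
#' @param seed Optional integer seed for the final pass's common random
#'   numbers.
#' @return The updated `dstp_fit`, with `params`, `g2`, `n_sim_final` and
#'   `converged` replaced by the final pass.
#' @export
dstp_refit <- function(object, n_sim = 100000, maxit = 200, restarts = 1,
                       top = 1, n_sim_select = 20000, seed = NULL) {
  if (!inherits(object, "dstp_fit")) stop("object must be a dstp_fit", call. = FALSE)
  if (n_sim < object$n_sim_per_eval)
    warning("final-pass n_sim (", n_sim, ") is below the screening precision (",
            object$n_sim_per_eval, ")", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  bounds <- object$bounds
  lower <- bounds[, 1]
  span <- bounds[, 2] - bounds[, 1]
  crn_seeds <- as.double(sample.int(2147483646L, 2L))
  objective <- make_g2_objective(object$bins, n_sim, object$config, bounds,
                                 crn_seeds)
  nm <- dstp_param_names()
  st <- object$start_table
  top <- min(max(1, top), nrow(st))
  cand_params <- if (top == 1) {
    list(unclass(object$params)[nm])
  } else {
    ord <- order(st$g2)[seq_len(top)]
    lapply(ord, function(i) unlist(st[i, nm]))
  }

  polish <- function(theta0) {
    z0 <- (theta0 - lower) / span
    opt <- NULL
    for (r in seq_len(max(1, restarts))) {
      opt <- optim(z0, objective, method = "Nelder-Mead",
                   control = list(maxit = maxit))
      z0 <- opt$par
    }
    opt
  }
  opts <- lapply(cand_params, polish)

  if (top > 1) {
    sel_seeds <- as.double(sample.int(2147483646L, 2L))
    sel_obj <- make_g2_objective(object$bins, n_sim_select, object$config,
                                 bounds, sel_seeds)
    sel_g2 <- vapply(opts, function(o) sel_obj(o$par), 0)
    best <- which.min(sel_g2)
  } else {
    best <- which.min(vapply(opts, `[[`, 0, "value"))
  }
  opt <- opts[[best]]

  theta <- lower + pmin(pmax(opt$par, 0), 1) * span
  object$params <- as_dstp_params(theta)
  object$g2 <- opt$value
  object$n_sim_final <- n_sim
  object$converged <- opt$convergence == 0
  object$crn_seeds_final <- crn_seeds
  object
}

#' Interference ratio
#'
#' The colour-word drift relative to the speed of late stimulus selection,
#' `mu_color_word / mu_ss`: an index of how strongly the irrelevant word
#' pulls on response selection before attention can select the target.
#'
#' @param params A [dstp_params()] object or a fitted [dstp_fit()].
#' @return The dimensionless ratio.
#' @examples
#' interference_ratio(dstp_params(0.1, 0.2, 0.4, 1, 0.2, 0.2, 0.3))  # 0.5
#' @export
interference_ratio <- function(params) {
  if (inherits(params, "dstp_fit")) params <- params$params
  validate_dstp_params(params)
  p <- unclass(params)
  if (p[["mu_ss"]] == 0)
    stop("interference ratio undefined: mu_ss is 0", call. = FALSE)
  unname(p[["mu_color_word"]] / p[["mu_ss"]])
}

#' @export
coef.dstp_fit <- function(object, ...) {
  unclass(object$params)[dstp_param_names()]
}

#' @export
print.dstp_fit <- function(x, digits = 4, ...) {
  cat("DSTP fit (", x$n_starts, " starts, ", x$n_sim_per_eval,
      " simulated trials per evaluation", sep = "")
  if (!is.na(x$n_sim_final))
    cat("; final pass at ", x$n_sim_final, sep = "")
  cat(")\n")
  print(round(coef(x), digits))
  cat(sprintf("G2 = %.3f  interference ratio = %.3f  converged: %s\n",
              x$g2, interference_ratio(x$params), x$converged))
  invisible(x)
}

#' @export
summary.dstp_fit <- function(object, ...) {
  st <- object$start_table
  out <- list(coefficients = coef(object),
              interference_ratio = interference_ratio(object$params),
              g2 = object$g2,
              n_starts = object$n_starts,
              n_sim_per_eval = object$n_sim_per_eval,
              n_sim_final = object$n_sim_final,
              converged = object$converged,
              n_trials = object$n_trials,
              g2_range = range(st$g2),
              start_table = st)
  class(out) <- "summary.dstp_fit"
  out
}

#' @export
print.summary.dstp_fit <- function(x, digits = 4, ...) {
  cat("DSTP model fit by multi-start simulation-based G2 minimisation\n\n")
  cat("Parameters:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nInterference ratio (mu_color_word / mu_ss): %.*f\n",
              digits, x$interference_ratio))
  cat(sprintf("G2 = %.3f (best of %d starts; start-table range %.3f-%.3f)\n",
              x$g2, x$n_starts, x$g2_range[1], x$g2_range[2]))
  cat(sprintf("Trials: %s\n",
              paste(sprintf("%s = %d", names(x$n_trials), x$n_trials),
                    collapse = ", ")))
  cat(sprintf("Simulated trials per evaluation: %d (screen)%s\n",
              x$n_sim_per_eval,
              if (is.na(x$n_sim_final)) "" else
                sprintf(", %d (final)", x$n_sim_final)))
  cat("Converged:", x$converged, "\n")
  invisible(x)
}

#' Predicted versus observed bin proportions of a DSTP fit
#'
#' @param object A `dstp_fit`.
#' @param n_sim Simulated trials per condition used to estimate the
#'   predicted proportions.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame with one row per bin: `condition`, `outcome`
#'   (`correct`/`error`), `bin`, `observed` (proportion) and `predicted`.
#' @export
predict.dstp_fit <- function(object, n_sim = 20000, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(names(object$bins), function(cond) {
    b <- object$bins[[cond]]
    pred <- predicted_bin_proportions(object$params, object$bins, cond, n_sim,
                                      object$config)
    data.frame(condition = cond,
               outcome = rep(c("correct", "error"),
                             c(length(b$correct_counts), length(b$error_counts))),
               bin = c(seq_along(b$correct_counts), seq_along(b$error_counts)),
               observed = c(b$correct_counts, b$error_counts) / b$n,
               predicted = c(pred$correct, pred$error))
  })
  do.call(rbind, out)
}

#' @export
residuals.dstp_fit <- function(object, n_sim = 20000, seed = NULL, ...) {
  pr <- predict(object, n_sim = n_sim, seed = seed)
  setNames(pr$observed - pr$predicted,
           paste(pr$condition, pr$outcome, pr$bin, sep = "."))
}

#' Simulate trials from a fitted DSTP model
#'
#' Each replicate simulates the fitted model at the observed per-condition
#' trial counts, returning data in the same layout [dstp_fit()] accepts.
#'
#' @param object A `dstp_fit`.
#' @param nsim Number of replicate datasets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` data frames (`congruency`, `correct`, `rt_s`,
#'   plus simulator metadata columns).
#' @export
simulate.dstp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  reps <- lapply(seq_len(nsim), function(r) {
    out <- lapply(names(object$bins), function(cond) {
      n <- object$bins[[cond]]$n
      sim <- simulate_dstp(object$params, cond, n, object$config)
      cbind(congruency = cond, sim)
    })
    do.call(rbind, out)
  })
  if (nsim == 1) reps[[1]] else reps
}

#' Diagnostic plot of a DSTP fit
#'
#' Observed versus model-predicted cumulative bin proportions per congruency
#' condition, correct and error trials side by side.
#'
#' @param x A `dstp_fit`.
#' @param n_sim Simulated trials per condition for the predicted proportions.
#' @param seed Optional integer seed.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the data frame from [predict.dstp_fit()].
#' @export
plot.dstp_fit <- function(x, n_sim = 20000, seed = NULL, ...) {
  pr <- predict(x, n_sim = n_sim, seed = seed)
  conds <- unique(pr$condition)
  oldpar <- graphics::par(mfrow = c(1, length(conds)))
  on.exit(graphics::par(oldpar))
  for (cond in conds) {
    sub <- pr[pr$condition == cond & pr$outcome == "correct", ]
    graphics::plot(cumsum(sub$observed), cumsum(sub$predicted),
                   xlab = "observed cumulative proportion",
                   ylab = "predicted cumulative proportion",
                   main = cond, xlim = c(0, 1), ylim = c(0, 1), ...)
    graphics::abline(0, 1, lty = 2)
    sub_e <- pr[pr$condition == cond & pr$outcome == "error", ]
    graphics::points(cumsum(sub_e$observed), cumsum(sub_e$predicted), pch = 4)
  }
  invisible(pr)
}
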