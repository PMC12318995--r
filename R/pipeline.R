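#' Fit the DSTP model to every participant and word location
#'
#' Runs the two-stage estimation protocol over a trial table: for each
#' participant, three independent fits (one per word location), each a
#' multi-start screen ([dstp_fit()]) optionally followed by a final pass at
#' higher simulation precision ([dstp_refit()]). Per-fit seeds are derived
#' deterministically from `seed`, so the whole table is reproducible.
#'
#' @param trials Trial-level data frame with `participant_id`,
#'   `word_location`, `congruency`, `correct`, `rt_s` (and `age_group`, kept
#'   in the output when present).
#' @param n_starts,n_sim,maxit,quantile_probs,error_bin_threshold,bounds,config
#'   Passed to [dstp_fit()].
#' @param n_sim_final Simulated trials per evaluation of the final pass;
#'   `NULL` skips the final pass.
#' @param refit_maxit Iteration cap of the final pass.
#' @param seed Integer seed for the whole table.
#' @param progress Print one line per completed fit.
#' @return A data frame, one row per participant x location:
#'   `participant_id`, `age_group`, `location`, the seven parameters,
#'   `interference_ratio`, `g2`, `n_starts`, `converged`.
#' @export
fit_cohort <- function(trials, n_starts = 50, n_sim = 5000,
                       n_sim_final = 100000, maxit = 200, refit_maxit = maxit,
                       quantile_probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                       error_bin_threshold = 11, bounds = dstp_bounds(),
                       config = sim_config(), seed = 1, progress = FALSE) {
  need <- c("participant_id", "word_location", "congruency", "correct", "rt_s")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trials lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)

  ids <- unique(trials$participant_id)
  locs <- unique(trials$word_location)
  rows <- list()
  counter <- 0L
  for (id in ids) {
    for (loc in locs) {
      counter <- counter + 1L
      sub <- trials[trials$participant_id == id & trials$word_location == loc, ]
      fit_seed <- (as.integer(seed) + 7919L * counter) %% 2147483647L
      fit <- dstp_fit(sub, n_starts = n_starts, n_sim = n_sim,
                      quantile_probs = quantile_probs,
                      error_bin_threshold = error_bin_threshold,
                      bounds = bounds, maxit = maxit, config = config,
                      seed = fit_seed)
      if (!is.null(n_sim_final))
        fit <- dstp_refit(fit, n_sim = n_sim_final, maxit = refit_maxit)
      age <- if ("age_group" %in% names(sub)) sub$age_group[1] else NA_character_
      rows[[counter]] <- data.frame(
        participant_id = id, age_group = age, location = loc,
        as.list(coef(fit)),
        interference_ratio = interference_ratio(fit),
        g2 = fit$g2, n_starts = fit$n_starts, converged = fit$converged)
      if (progress)
        message(sprintf("fit %s / %s: G2 = %.2f", id, loc, fit$g2))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-level ANOVA of fitted parameters
#'
#' The inferential stage for a fitted-parameter table: for each parameter
#' (and the interference ratio), outliers are screened with 1.5-IQR fences
#' ([filter_param_outliers()]), participants left without a complete set of
#' locations for that parameter are dropped listwise, and a mixed ANOVA with
#' age group as the between-subject factor and word location as the
#' within-subject factor is computed ([mixed_anova()]).
#'
#' @param param_table Data frame from [fit_cohort()] (or [read_params()]).
#' @param parameters Parameter columns to analyse; defaults to the seven
#'   DSTP parameters plus `interference_ratio`.
#' @param outlier_k Fence multiplier; `NULL` disables the outlier screen.
#' @param outlier_scope `"pooled"` (fences over the full sample per
#'   parameter, the default) or `"by_group"`.
#' @return A list with `anova` (named list of [mixed_anova()] tables),
#'   `exclusions` (the outlier log) and `dropped` (named list of participant
#'   ids dropped listwise per parameter).
#' @export
analyze_params <- function(param_table, parameters = NULL, outlier_k = 1.5,
                           outlier_scope = c("pooled", "by_group")) {
  outlier_scope <- match.arg(outlier_scope)
  if (is.null(parameters)) {
    parameters <- intersect(c(dstp_param_names(), "interference_ratio"),
                            names(param_table))
  }
  if (!is.null(outlier_k)) {
    scr <- filter_param_outliers(param_table, parameters = parameters,
                                 k = outlier_k,
                                 scope_by = if (outlier_scope == "by_group")
                                   "age_group" else NULL)
    filtered <- scr$filtered
    exclusions <- scr$exclusions
  } else {
    filtered <- param_table
    exclusions <- NULL
  }
  n_loc <- length(unique(param_table$location))
  tables <- list()
  dropped <- list()
  for (par in parameters) {
    ok_tab <- tapply(!is.na(filtered[[par]]), filtered$participant_id, sum)
    keep <- names(ok_tab)[ok_tab == n_loc]
    dropped[[par]] <- setdiff(names(ok_tab), keep)
    sub <- filtered[filtered$participant_id %in% keep,
                    c("participant_id", "age_group", "location", par)]
    tables[[par]] <- mixed_anova(sub, dv = par, between = "age_group",
                                 within = "location",
                                 subject = "participant_id")
  }
  list(anova = tables, exclusions = exclusions, dropped = dropped)
}

#' Group-level ANOVA of behavioural summaries
#'
#' Accuracy (all trials) and correct-trial mean RT are summarised per
#' participant and condition cell ([summarize_behavior()]), participants
#' with an unusable RT cell are dropped listwise from the RT analysis, and
#' each summary is submitted to a mixed ANOVA with age group between
#' subjects and congruency and word location within subjects.
#'
#' @param trials Trial-level data frame (see [summarize_behavior()]).
#' @return A list with `summary` (the per-participant cell table),
#'   `accuracy` and `rt` ([mixed_anova()] tables), and `dropped_rt`
#'   (participants excluded from the RT ANOVA).
#' @export
analyze_behavior <- function(trials) {
  s <- summarize_behavior(trials)
  acc <- mixed_anova(s, dv = "accuracy", between = "age_group",
                     within = c("congruency", "word_location"),
                     subject = "participant_id")
  bad <- tapply(is.na(s$mean_rt), s$participant_id, any)
  dropped <- names(bad)[bad]
  s_rt <- s[!s$participant_id %in% dropped, ]
  rt <- mixed_anova(s_rt, dv = "mean_rt", between = "age_group",
                    within = c("congruency", "word_location"),
                    subject = "participant_id")
  list(summary = s, accuracy = acc, rt = rt, dropped_rt = dropped)
}

#' Parameter-recovery study
#'
#' The end-to-end validation loop for the estimation machinery: draw
#' per-participant DSTP parameters from the two age-group distributions
#' (target-location generative structure), simulate each participant's
#' session at those parameters (default: the session's trial mix, 324
#' incongruent + 108 congruent trials), fit every participant with the
#' multi-start G2 procedure at a configurable budget, and compare true with
#' fitted parameters: cohort-level Pearson correlations, biases, and the
#' ordering of group means.
#'
#' @param n_per_group Synthetic participants per age group.
#' @param n_starts,n_sim,maxit,starts Multi-start screening budget per fit
#'   (see [dstp_fit()]; the recovery protocol uses data-anchored starts by
#'   default).
#' @param n_sim_final Simulated trials per evaluation of the final polish
#'   pass (`NULL` skips it).
#' @param refit_maxit,refit_restarts,refit_top Iteration cap, restart count
#'   and number of polished screen candidates of the final pass (see
#'   [dstp_refit()]).
#' @param n_incongruent,n_congruent Trials per participant and condition.
#' @param cohort A [cohort_config()] providing the generative distributions.
#' @param config A [sim_config()].
#' @param seed Integer seed for the whole study.
#' @return An object of class `dstp_recovery`: a list with `results` (one
#'   row per participant: true and fitted parameters, G2), `correlations`
#'   (named vector of true-vs-fitted Pearson correlations), `bias` (mean
#'   fitted minus true), and `group_means` (true and fitted means per age
#'   group).
#' @export
recover_study <- function(n_per_group = 20, n_starts = 10, n_sim = 600,
                          maxit = 60, n_sim_final = 1500, refit_maxit = 150,
                          refit_restarts = 1, refit_top = 2,
                          starts = "anchored",
                          n_incongruent = 324, n_congruent = 108,
                          cohort = cohort_config(), config = sim_config(),
                          seed = 1) {
  set.seed(seed)
  groups <- rep(c("young", "old"), each = n_per_group)
  rows <- list()
  for (i in seq_along(groups)) {
    truth <- draw_participant_params(cohort, groups[i])[["target"]]
    dat <- rbind(
      cbind(congruency = "incongruent",
            simulate_dstp(truth, "incongruent", n_incongruent, config)),
      cbind(congruency = "congruent",
            simulate_dstp(truth, "congruent", n_congruent, config)))
    fit <- dstp_fit(dat, n_starts = n_starts, n_sim = n_sim, maxit = maxit,
                    starts = starts, config = config)
    if (!is.null(n_sim_final))
      fit <- dstp_refit(fit, n_sim = n_sim_final, maxit = refit_maxit,
                        restarts = refit_restarts, top = refit_top)
    tr <- unclass(truth)
    rows[[i]] <- data.frame(
      participant = i, age_group = groups[i],
      as.list(setNames(tr, paste0("true_", names(tr)))),
      as.list(setNames(coef(fit), paste0("fit_", dstp_param_names()))),
      g2 = fit$g2)
  }
  results <- do.call(rbind, rows)
  nm <- dstp_param_names()
  correlations <- vapply(nm, function(p) {
    stats::cor(results[[paste0("true_", p)]], results[[paste0("fit_", p)]])
  }, 0)
  bias <- vapply(nm, function(p) {
    mean(results[[paste0("fit_", p)]] - results[[paste0("true_", p)]])
  }, 0)
  group_means <- do.call(rbind, lapply(split(results, results$age_group),
    function(d) {
      data.frame(age_group = d$age_group[1],
                 as.list(colMeans(d[paste0("true_", nm)])),
                 as.list(colMeans(d[paste0("fit_", nm)])))
    }))
  rownames(group_means) <- NULL
  structure(list(results = results, correlations = correlations, bias = bias,
                 group_means = group_means,
                 settings = list(n_per_group = n_per_group,
                                 n_starts = n_starts, n_sim = n_sim,
                                 maxit = maxit, n_sim_final = n_sim_final,
                                 n_incongruent = n_incongruent,
                                 n_congruent = n_congruent, seed = seed)),
            class = "dstp_recovery")
}

#' @export
print.dstp_recovery <- function(x, digits = 3, ...) {
  s <- x$settings
  cat(sprintf("DSTP parameter recovery: %d participants/group, %d starts x %d simulated trials\n",
              s$n_per_group, s$n_starts, s$n_sim))
  cat("True-vs-fitted correlations:\n")
  print(round(x$correlations, digits))
  cat("Mean bias (fitted - true):\n")
  print(round(x$bias, digits))
  invisible(x)
}
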