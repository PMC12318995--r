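#' Generative settings for a synthetic cohort
#'
#' Defines the cohort sizes and the group-level distributions the
#' per-participant DSTP parameters are drawn from. The default structure
#' encodes the age effects reported for this task family: relative to the
#' young group, the old group's generative means are shifted up for the two
#' boundaries and the non-decision time (more cautious, slower encoding) and
#' down for the second-phase drift (slower late response selection), while
#' the first-phase drifts and the stimulus-selection drift are age-invariant.
#' The colour-word drift is substantial only in the target location, so the
#' congruency effect on RT is confined to words inside the target shape.
#'
#' Per-participant parameters are drawn independently as normal deviates
#' around the group x location means with standard deviation
#' `sd_frac` x mean, then clamped to the fitting bounds ([dstp_bounds()]).
#'
#' @param n_young,n_old Participants per age group (defaults 75 and 72).
#' @param means Data frame of generative means: columns `age_group`,
#'   `word_location` and the seven parameter names. Defaults to
#'   `default_cohort_means()`.
#' @param sd_frac Between-participant standard deviation as a fraction of
#'   each mean.
#' @param seed Optional integer seed stored for [simulate_cohort()].
#' @return An object of class `dstp_cohort_config`.
#' @export
cohort_config <- function(n_young = 75, n_old = 72,
                          means = default_cohort_means(),
                          sd_frac = 0.15, seed = NULL) {
  if (n_young < 1 || n_old < 1) stop("group sizes must be >= 1", call. = FALSE)
  need <- c("age_group", "word_location", dstp_param_names())
  miss <- setdiff(need, names(means))
  if (length(miss))
    stop("means lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (sd_frac < 0) stop("sd_frac must be >= 0", call. = FALSE)
  b <- dstp_bounds()
  for (nm in dstp_param_names()) {
    if (any(means[[nm]] < b[nm, 1] | means[[nm]] > b[nm, 2]))
      stop("generative mean for ", nm, " lies outside the fitting bounds",
           call. = FALSE)
  }
  structure(list(n_young = n_young, n_old = n_old, means = means,
                 sd_frac = sd_frac, seed = seed),
            class = "dstp_cohort_config")
}

#' Default generative means per age group and word location
#'
#' Young target-location values: `mu_target_color` 0.08, `mu_color_word`
#' 0.12, `mu_ss` 0.35, `mu_rs2` 0.9, `crit_a` 0.18, `crit_c` 0.22, `ter`
#' 0.30 s. Old-group shifts: `crit_a` +0.07, `crit_c` +0.05, `ter` +0.05 s,
#' `mu_rs2` -0.3. In the distractor and background locations the colour-word
#' drift drops to 0.03 (words outside the target shape barely feed response
#' selection); all other parameters are location-invariant.
#'
#' @return A data frame with one row per age group x word location.
#' @export
default_cohort_means <- function() {
  grid <- expand.grid(age_group = c("young", "old"),
                      word_location = c("target", "distractor", "background"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$mu_target_color <- 0.08
  grid$mu_color_word <- ifelse(grid$word_location == "target", 0.12, 0.03)
  grid$mu_ss <- 0.35
  grid$mu_rs2 <- ifelse(grid$age_group == "old", 0.9 - 0.3, 0.9)
  grid$crit_a <- ifelse(grid$age_group == "old", 0.18 + 0.07, 0.18)
  grid$crit_c <- ifelse(grid$age_group == "old", 0.22 + 0.05, 0.22)
  grid$ter <- ifelse(grid$age_group == "old", 0.30 + 0.05, 0.30)
  grid
}

# draw one participant's parameters for every location; clamped to bounds
draw_participant_params <- function(config, age_group) {
  b <- dstp_bounds()
  means <- config$means[config$means$age_group == age_group, , drop = FALSE]
  out <- lapply(seq_len(nrow(means)), function(i) {
    mu <- unlist(means[i, dstp_param_names()])
    th <- rnorm(7, mean = mu, sd = config$sd_frac * mu)
    th <- pmin(pmax(th, b[, 1]), b[, 2])
    as_dstp_params(setNames(th, dstp_param_names()))
  })
  names(out) <- means$word_location
  out
}

#' Simulate one participant's session
#'
#' Runs the DSTP simulator over every trial of a session design, using the
#' participant's parameter set for the trial's word location and the sign
#' convention for its congruency. Error trials are assigned a uniformly
#' random wrong colour as the response.
#'
#' @param participant_id Scalar identifier.
#' @param params_by_location Named list of [dstp_params()], one per word
#'   location appearing in `design`.
#' @param design A [session_design()] data frame.
#' @param config A [sim_config()].
#' @return A data frame with one row per design trial: the design columns
#'   plus `participant_id`, `response_color`, `correct`, `rt_s`, `censored`.
#' @export
simulate_participant <- function(participant_id, params_by_location, design,
                                 config = sim_config()) {
  locs <- unique(design$word_location)
  miss <- setdiff(locs, names(params_by_location))
  if (length(miss))
    stop("missing parameters for location(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  colors <- attr(design, "colors")
  if (is.null(colors)) colors <- unique(design$target_color)

  out <- design
  out$response_color <- NA_character_
  out$correct <- NA
  out$rt_s <- NA_real_
  out$censored <- NA

  for (loc in locs) {
    for (cond in c("congruent", "incongruent")) {
      idx <- which(design$word_location == loc & design$congruency == cond)
      if (!length(idx)) next
      sim <- simulate_dstp(params_by_location[[loc]], cond, length(idx), config)
      out$correct[idx] <- sim$correct
      out$rt_s[idx] <- sim$rt_s
      out$censored[idx] <- sim$censored
    }
  }
  wrong <- !out$correct
  out$response_color[!wrong] <- out$target_color[!wrong]
  if (any(wrong)) {
    out$response_color[wrong] <- vapply(out$target_color[wrong], function(tc) {
      sample(setdiff(colors, tc), 1L)
    }, character(1))
  }
  cbind(participant_id = participant_id, out)
}

#' Simulate a synthetic Shape Stroop cohort
#'
#' Generates a full synthetic study: per participant, a freshly randomised
#' session design, DSTP parameters drawn from the group distributions in
#' `config`, and simulated trial-level behaviour. The ground-truth parameter
#' table is returned alongside the trials so parameter recovery can be
#' evaluated without any external data.
#'
#' @param config A [cohort_config()].
#' @param sim A [sim_config()] (its `seed` field should stay `NULL` here;
#'   use `config$seed` to seed the whole cohort).
#' @param ... Passed to [session_design()] (block counts).
#' @return An object of class `dstp_cohort`: a list with `trials` (one row
#'   per trial, all participants) and `true_params` (one row per participant
#'   x location; parameter columns prefixed `true_`, plus
#'   `true_interference_ratio`).
#' @examples
#' \donttest{
#' co <- simulate_cohort(cohort_config(n_young = 2, n_old = 2, seed = 1))
#' nrow(co$trials)  # 4 * 432
#' }
#' @export
simulate_cohort <- function(config = cohort_config(), sim = sim_config(), ...) {
  if (!inherits(config, "dstp_cohort_config"))
    stop("config must come from cohort_config()", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)

  groups <- rep(c("young", "old"), c(config$n_young, config$n_old))
  ids <- sprintf("p%03d", seq_along(groups))

  trial_list <- vector("list", length(ids))
  truth_list <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    design <- session_design(...)
    params <- draw_participant_params(config, groups[i])
    tr <- simulate_participant(ids[i], params, design, sim)
    tr <- cbind(tr[, "participant_id", drop = FALSE], age_group = groups[i],
                tr[, setdiff(names(tr), "participant_id")])
    trial_list[[i]] <- tr
    truth_list[[i]] <- do.call(rbind, lapply(names(params), function(loc) {
      th <- unclass(params[[loc]])
      data.frame(participant_id = ids[i], age_group = groups[i],
                 word_location = loc,
                 as.list(setNames(th, paste0("true_", names(th)))),
                 true_interference_ratio = interference_ratio(params[[loc]]))
    }))
  }
  structure(list(trials = do.call(rbind, trial_list),
                 true_params = do.call(rbind, truth_list),
                 config = config),
            class = "dstp_cohort")
}

#' @export
print.dstp_cohort <- function(x, ...) {
  cat(sprintf("Synthetic Shape Stroop cohort: %d young + %d old participants, %d trials\n",
              x$config$n_young, x$config$n_old, nrow(x$trials)))
  invisible(x)
}
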