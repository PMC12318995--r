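trial_columns <- function() {
  c("participant_id", "age_group", "block", "trial", "word_location",
    "congruency", "target_color", "color_word", "target_shape", "orientation",
    "response_color", "correct", "rt_s", "censored")
}

param_columns <- function() {
  c("participant_id", "age_group", "location", dstp_param_names(),
    "interference_ratio", "g2", "n_starts", "converged")
}

parse_logical_col <- function(x) {
  v <- rep(NA, length(x))
  v[tolower(x) %in% c("true", "t", "1")] <- TRUE
  v[tolower(x) %in% c("false", "f", "0")] <- FALSE
  v
}

#' Read trial-level behavioural data
#'
#' Reads a comma-delimited trial table (UTF-8, `.` decimal) with the columns
#' written by [write_trials()]; column order is matched by name. Reaction
#' times are parsed as seconds. Malformed rows are reported with their file
#' line numbers.
#'
#' @param path Path to the CSV file.
#' @return A typed data frame, one row per trial.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0) stop("empty trial file: ", path, call. = FALSE)
  miss <- setdiff(trial_columns(), names(raw))
  if (length(miss))
    stop("trial file lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  raw <- raw[trial_columns()]

  # +1 for the header row so reported numbers are file line numbers
  report_bad <- function(bad, what) {
    if (any(bad))
      stop("malformed ", what, " on line(s): ",
           paste(utils::head(which(bad) + 1L, 10), collapse = ", "),
           call. = FALSE)
  }
  rt <- suppressWarnings(as.numeric(raw$rt_s))
  report_bad(is.na(rt) | rt <= 0, "rt_s")
  blk <- suppressWarnings(as.integer(raw$block))
  report_bad(is.na(blk), "block")
  tri <- suppressWarnings(as.integer(raw$trial))
  report_bad(is.na(tri), "trial")
  corr <- parse_logical_col(raw$correct)
  report_bad(is.na(corr), "correct")
  cens <- parse_logical_col(raw$censored)
  report_bad(is.na(cens), "censored")

  out <- raw
  out$block <- blk
  out$trial <- tri
  out$rt_s <- rt
  out$correct <- corr
  out$censored <- cens
  out
}

#' Write trial-level behavioural data
#'
#' @param trials Trial-level data frame (see [read_trials()] for the schema).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(trial_columns(), names(trials))
  if (length(miss))
    stop("trials lack required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  write.csv(trials[trial_columns()], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fitted-parameter table
#'
#' One row per participant x word location, in the fixed column order
#' `participant_id, age_group, location, <seven parameters>,
#' interference_ratio, g2, n_starts, converged`.
#'
#' @param params Data frame as returned by [fit_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  miss <- setdiff(param_columns(), names(params))
  if (length(miss))
    stop("parameter table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  write.csv(params[param_columns()], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a fitted-parameter table
#' @param path CSV path written by [write_params()].
#' @return A typed data frame, one row per participant x location.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- read.csv(path, check.names = FALSE)
  miss <- setdiff(param_columns(), names(out))
  if (length(miss))
    stop("parameter file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out
}

pipeline_defaults <- function() {
  list(
    design = list(n_blocks = 18, trials_per_block = 24,
                  congruent_per_block = 6),
    cohort = list(n_young = 75, n_old = 72, sd_frac = 0.15),
    sim = list(dt = 0.001, sigma = 0.1, max_decision_time = 5.0),
    fit = list(n_starts = 50, n_sim_per_eval = 5000, n_sim_final = 100000,
               quantile_probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
               error_bin_threshold = 11, maxit = 200, refit = TRUE),
    analysis = list(outlier_k = 1.5, outlier_scope = "pooled"),
    out_dir = ".",
    seed = 1L
  )
}

#' Read a pipeline configuration file
#'
#' Reads a YAML or JSON configuration (chosen by file extension) and merges
#' it over the package defaults. Keys are validated: an unknown top-level or
#' nested key is an error, so typos cannot silently fall back to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file; `NULL` returns the
#'   defaults.
#' @return A nested list with components `design`, `cohort`, `sim`, `fit`,
#'   `analysis`, `out_dir`, `seed`.
#' @export
read_pipeline_config <- function(path = NULL) {
  base <- pipeline_defaults()
  if (is.null(path)) return(base)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
                 yaml = ,
                 yml = yaml::read_yaml(path),
                 json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                 stop("config must be .yaml, .yml or .json", call. = FALSE))
  if (!is.list(user)) stop("config must be a mapping of settings", call. = FALSE)

  merge_level <- function(base, user, prefix = "") {
    unknown <- setdiff(names(user), names(base))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste0(prefix, unknown, collapse = ", "), call. = FALSE)
    for (k in names(user)) {
      if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
        if (!is.list(user[[k]]))
          stop("config key ", prefix, k, " must be a mapping", call. = FALSE)
        base[[k]] <- merge_level(base[[k]], user[[k]], paste0(prefix, k, "."))
      } else {
        base[[k]] <- user[[k]]
      }
    }
    base
  }
  cfg <- merge_level(base, user)
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(cfg$design$n_blocks >= 1,
            cfg$cohort$n_young >= 1, cfg$cohort$n_old >= 1,
            cfg$cohort$sd_frac >= 0,
            cfg$sim$dt > 0, cfg$sim$sigma > 0, cfg$sim$max_decision_time > 0,
            cfg$fit$n_starts >= 1, cfg$fit$n_sim_per_eval >= 1,
            cfg$fit$n_sim_final >= 1, cfg$fit$error_bin_threshold >= 1,
            cfg$fit$maxit >= 1, cfg$analysis$outlier_k >= 0)
  if (!cfg$analysis$outlier_scope %in% c("pooled", "by_group"))
    stop("analysis.outlier_scope must be 'pooled' or 'by_group'", call. = FALSE)
  invisible(cfg)
}
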