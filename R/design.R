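#' Generate one Shape Stroop session design
#'
#' Builds the trial list of one experimental session: `n_blocks` blocks of
#' `trials_per_block` trials. Within every block the colour word is
#' incongruent with the target colour on 18 trials and congruent on 6 (by
#' default), appears equally often in each of the three locations (target
#' shape, distractor shape, background), each of the four colours is the
#' target on exactly 6 trials, and target shape (rectangle/oval) and
#' orientation (horizontal/vertical) are balanced. Trial order is randomised
#' within block, and block composition is re-randomised per call, so each
#' participant receives a different ordering.
#'
#' Task timing (500 ms fixation, 100 ms blank, 5,000 ms stimulus display) and
#' the 12-trial colour-key practice block are recorded as attributes; they
#' are design metadata and do not enter the trial-level simulation except
#' through the response deadline (`max_decision_time` in [sim_config()]).
#'
#' @param n_blocks Number of experimental blocks.
#' @param trials_per_block Trials per block; must be divisible by the number
#'   of colours and of locations.
#' @param congruent_per_block Congruent trials per block; must be divisible
#'   by the number of locations.
#' @param seed Optional integer seed.
#' @return A data frame of class `dstp_design` with columns `block`, `trial`,
#'   `word_location`, `congruency`, `target_color`, `color_word`,
#'   `target_shape`, `orientation`.
#' @examples
#' d <- session_design(seed = 1)
#' nrow(d)                       # 432
#' table(d$block, d$congruency)  # 6 congruent / 18 incongruent per block
#' @export
session_design <- function(n_blocks = 18, trials_per_block = 24,
                           congruent_per_block = 6, seed = NULL) {
  colors <- c("red", "green", "blue", "yellow")
  locations <- c("target", "distractor", "background")
  if (n_blocks < 1) stop("n_blocks must be >= 1", call. = FALSE)
  if (trials_per_block %% length(colors) != 0)
    stop("trials_per_block must be divisible by the number of colours (4)",
         call. = FALSE)
  if (trials_per_block %% length(locations) != 0)
    stop("trials_per_block must be divisible by the number of locations (3)",
         call. = FALSE)
  if (congruent_per_block %% length(locations) != 0)
    stop("congruent_per_block must be divisible by the number of locations (3)",
         call. = FALSE)
  if (congruent_per_block >= trials_per_block)
    stop("congruent_per_block must be below trials_per_block", call. = FALSE)
  if (trials_per_block %% 2 != 0)
    stop("trials_per_block must be even to balance shape and orientation",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  per_loc <- trials_per_block / length(locations)
  cong_per_loc <- congruent_per_block / length(locations)

  blocks <- lapply(seq_len(n_blocks), function(b) {
    loc <- rep(locations, each = per_loc)
    cong <- rep(rep(c("congruent", "incongruent"),
                    c(cong_per_loc, per_loc - cong_per_loc)),
                times = length(locations))
    target_color <- sample(rep(colors, each = trials_per_block / length(colors)))
    color_word <- ifelse(cong == "congruent", target_color,
                         vapply(target_color,
                                function(tc) sample(setdiff(colors, tc), 1L),
                                character(1)))
    shape <- sample(rep(c("rectangle", "oval"), each = trials_per_block / 2))
    orientation <- sample(rep(c("horizontal", "vertical"),
                              each = trials_per_block / 2))
    ord <- sample.int(trials_per_block)
    data.frame(block = b, trial = seq_len(trials_per_block),
               word_location = loc[ord], congruency = cong[ord],
               target_color = target_color[ord], color_word = color_word[ord],
               target_shape = shape[ord], orientation = orientation[ord],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  structure(out,
            class = c("dstp_design", "data.frame"),
            colors = colors, locations = locations,
            fixation_ms = 500, blank_ms = 100, display_ms = 5000,
            practice_trials = 12)
}

#' Check the invariants of a session design
#'
#' Verifies every structural constraint of the Shape Stroop session: block
#' and trial counts, the per-block congruency split, per-block colour
#' counts, shape/orientation balance, and the congruent/incongruent
#' colour-word rule.
#'
#' @param design A [session_design()] data frame.
#' @param n_blocks,trials_per_block,congruent_per_block Expected counts.
#' @return `TRUE` invisibly; otherwise an error describing the violated
#'   constraint.
#' @export
check_session_design <- function(design, n_blocks = 18, trials_per_block = 24,
                                 congruent_per_block = 6) {
  need <- c("block", "trial", "word_location", "congruency", "target_color",
            "color_word", "target_shape", "orientation")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (length(unique(design$block)) != n_blocks)
    stop("expected ", n_blocks, " blocks", call. = FALSE)
  for (b in unique(design$block)) {
    d <- design[design$block == b, ]
    if (nrow(d) != trials_per_block)
      stop("block ", b, " has ", nrow(d), " trials, expected ",
           trials_per_block, call. = FALSE)
    if (sum(d$congruency == "congruent") != congruent_per_block)
      stop("block ", b, ": wrong congruent count", call. = FALSE)
    if (any(table(d$target_color) != trials_per_block / 4))
      stop("block ", b, ": target colours not balanced", call. = FALSE)
    if (any(table(d$word_location) != trials_per_block / 3))
      stop("block ", b, ": word locations not balanced", call. = FALSE)
    if (any(table(d$target_shape) != trials_per_block / 2))
      stop("block ", b, ": target shapes not balanced", call. = FALSE)
    if (any(table(d$orientation) != trials_per_block / 2))
      stop("block ", b, ": orientations not balanced", call. = FALSE)
  }
  cong <- design$congruency == "congruent"
  if (!all(design$color_word[cong] == design$target_color[cong]))
    stop("congruent trials must have color_word equal to target_color",
         call. = FALSE)
  if (any(design$color_word[!cong] == design$target_color[!cong]))
    stop("incongruent trials must have color_word different from target_color",
         call. = FALSE)
  invisible(TRUE)
}
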