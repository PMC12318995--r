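#' Reaction-time quantile bins for the G2 objective
#'
#' Builds the observed bin structure the simulation-based fit is scored
#' against. Correct-trial RTs are cut at the stated quantiles (defaults 0.1,
#' 0.3, 0.5, 0.7, 0.9, giving six bins); error RTs are binned the same way
#' when there are at least `error_bin_threshold` errors, otherwise all errors
#' are pooled into a single bin (standard practice for sparse error
#' distributions). Quantiles use linear interpolation (type 7) throughout the
#' package. Bins are right-closed: a trial falls in bin `b` when
#' `edge[b-1] < rt <= edge[b]`.
#'
#' When `congruency` is supplied, one bin set is built per congruency
#' condition (the structure the joint fit uses); otherwise a single set is
#' built from all trials.
#'
#' @param rts Numeric vector of reaction times (s), one per trial.
#' @param correct_flags Logical vector, same length as `rts`.
#' @param quantile_probs Ordered probabilities for the bin edges.
#' @param congruency Optional character/factor vector of
#'   `"congruent"`/`"incongruent"` labels, same length as `rts`.
#' @param error_bin_threshold Minimum error count for quantile-binned error
#'   RTs; below it a single pooled error bin is used.
#' @return An object of class `dstp_bins`: a list with one element per
#'   condition, each holding `correct_edges`, `error_edges` (length 0 means
#'   one pooled bin), `correct_counts`, `error_counts` and `n`, plus the
#'   binning settings as attributes.
#' @examples
#' set.seed(1)
#' rt <- runif(100, 0.5, 1.5)
#' make_rt_bins(rt, rep(TRUE, 100))
#' @export
make_rt_bins <- function(rts, correct_flags,
                         quantile_probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                         congruency = NULL, error_bin_threshold = 11) {
  if (length(rts) == 0L) stop("no trials supplied", call. = FALSE)
  if (length(correct_flags) != length(rts))
    stop("rts and correct_flags must have equal length", call. = FALSE)
  if (any(!is.finite(rts)) || any(rts <= 0))
    stop("all reaction times must be finite and positive", call. = FALSE)
  if (is.unsorted(quantile_probs, strictly = TRUE) ||
      any(quantile_probs <= 0) || any(quantile_probs >= 1))
    stop("quantile_probs must be strictly increasing within (0, 1)", call. = FALSE)
  correct_flags <- as.logical(correct_flags)

  if (is.null(congruency)) {
    groups <- list(all = seq_along(rts))
  } else {
    if (length(congruency) != length(rts))
      stop("congruency must have the same length as rts", call. = FALSE)
    congruency <- as.character(congruency)
    bad <- setdiff(unique(congruency), c("congruent", "incongruent"))
    if (length(bad))
      stop("unknown congruency labels: ", paste(bad, collapse = ", "), call. = FALSE)
    groups <- split(seq_along(rts), congruency)
  }

  bins <- lapply(groups, function(idx) {
    rt <- rts[idx]
    ok <- correct_flags[idx]
    if (!any(ok)) stop("no correct trials in a condition; cannot place quantile bins",
                       call. = FALSE)
    correct_edges <- unname(quantile(rt[ok], probs = quantile_probs, type = 7))
    n_err <- sum(!ok)
    error_edges <- if (n_err >= error_bin_threshold) {
      unname(quantile(rt[!ok], probs = quantile_probs, type = 7))
    } else {
      numeric(0)
    }
    list(correct_edges = correct_edges,
         error_edges = error_edges,
         correct_counts = bin_counts(rt[ok], correct_edges),
         error_counts = bin_counts(rt[!ok], error_edges),
         n = length(idx))
  })

  structure(bins, class = "dstp_bins",
            quantile_probs = quantile_probs,
            error_bin_threshold = error_bin_threshold)
}

# tally values into right-closed bins defined by inner edges
bin_counts <- function(x, edges) {
  k <- length(edges) + 1L
  if (length(x) == 0L) return(integer(k))
  idx <- findInterval(x, edges, left.open = TRUE) + 1L
  tabulate(idx, nbins = k)
}

#' @export
print.dstp_bins <- function(x, ...) {
  cat("RT quantile bins (probs:",
      paste(attr(x, "quantile_probs"), collapse = ", "), ")\n")
  for (nm in names(x)) {
    b <- x[[nm]]
    cat(sprintf("  %s: n = %d, correct counts [%s], error counts [%s]\n",
                nm, b$n, paste(b$correct_counts, collapse = ", "),
                paste(b$error_counts, collapse = ", ")))
  }
  invisible(x)
}

#' Model-predicted bin proportions by simulation
#'
#' Simulates `n_sim` DSTP trials for one congruency condition and classifies
#' each by correctness and the observed bin edges in `binspec`. Proportions
#' are counts / `n_sim`, floored at `1e-5` (never exactly zero, so the G2
#' statistic stays finite) and not renormalised.
#'
#' @param params A [dstp_params()] object.
#' @param binspec A [make_rt_bins()] object.
#' @param congruency Which condition of `binspec` to predict
#'   (`"congruent"`, `"incongruent"`, or `"all"` for a single-condition spec).
#' @param n_sim Number of simulated trials (>= 1).
#' @param config A [sim_config()] object; set its `seed` for reproducible
#'   proportions.
#' @return A list with `correct` and `error` proportion vectors (aligned with
#'   the bin counts in `binspec`).
#' @export
predicted_bin_proportions <- function(params, binspec, congruency, n_sim,
                                      config = sim_config()) {
  validate_dstp_params(params)
  if (!inherits(binspec, "dstp_bins")) stop("binspec must come from make_rt_bins()", call. = FALSE)
  if (!congruency %in% names(binspec))
    stop("binspec has no condition named '", congruency, "'", call. = FALSE)
  if (!is.numeric(n_sim) || length(n_sim) != 1L || n_sim < 1)
    stop("n_sim must be a positive integer", call. = FALSE)
  cong_flag <- identical(congruency, "congruent")
  b <- binspec[[congruency]]
  p <- unclass(params)
  counts <- .dstp_bin_counts_cpp(as.integer(n_sim),
                                 p[["mu_target_color"]], p[["mu_color_word"]],
                                 p[["mu_ss"]], p[["mu_rs2"]],
                                 p[["crit_a"]], p[["crit_c"]], p[["ter"]],
                                 cong_flag, config$dt, config$sigma,
                                 config$max_decision_time, resolve_seed(config),
                                 b$correct_edges, b$error_edges)
  list(correct = pmax(counts$correct_counts / n_sim, 1e-5),
       error = pmax(counts$error_counts / n_sim, 1e-5))
}

#' Likelihood-ratio chi-square (G2) statistic
#'
#' `G2 = 2 * sum_b O_b * log(O_b / (N * p_b))` with `N = sum(O)`, the
#' likelihood-ratio statistic comparing observed multinomial bin counts with
#' model-predicted bin proportions. Bins with zero observed count contribute
#' zero. The fit minimises the sum of this statistic over the two congruency
#' conditions.
#'
#' @param observed_counts Non-negative counts per bin.
#' @param predicted_proportions Strictly positive predicted proportions per
#'   bin, aligned with `observed_counts`.
#' @return The (non-negative, up to proportion-flooring slack) statistic.
#' @examples
#' g2_stat(c(30, 70), c(0.5, 0.5))  # ~16.46
#' @export
g2_stat <- function(observed_counts, predicted_proportions) {
  if (length(observed_counts) != length(predicted_proportions))
    stop("observed_counts and predicted_proportions must have equal length", call. = FALSE)
  if (any(observed_counts < 0) || any(!is.finite(observed_counts)))
    stop("observed counts must be finite and non-negative", call. = FALSE)
  if (any(predicted_proportions <= 0) || any(!is.finite(predicted_proportions)))
    stop("predicted proportions must be finite and > 0", call. = FALSE)
  n <- sum(observed_counts)
  pos <- observed_counts > 0
  2 * sum(observed_counts[pos] *
            log(observed_counts[pos] / (n * predicted_proportions[pos])))
}
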