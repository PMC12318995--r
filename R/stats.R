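#' Interquartile-range outlier fences
#'
#' Computes the 25th and 75th percentiles (linear-interpolation quantiles,
#' the package-wide convention), their difference (IQR), and the fences
#' `q25 - k * IQR` and `q75 + k * IQR`. Values outside the fences are
#' treated as outliers by [filter_param_outliers()].
#'
#' @param values At least four finite numbers.
#' @param k Fence multiplier (default 1.5).
#' @return An object of class `dstp_outlier_bounds`: a list with `q25`,
#'   `q75`, `iqr`, `lower`, `upper`, `k` and `n_flagged`.
#' @examples
#' iqr_bounds(c(1, 2, 3, 4, 100))  # fences -1 and 7; 100 flagged
#' @export
iqr_bounds <- function(values, k = 1.5) {
  values <- values[is.finite(values)]
  if (length(values) < 4)
    stop("need at least 4 finite values to place IQR fences", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k < 0)
    stop("k must be a single non-negative number", call. = FALSE)
  q <- unname(quantile(values, c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  lower <- q[1] - k * iqr
  upper <- q[2] + k * iqr
  structure(list(q25 = q[1], q75 = q[2], iqr = iqr,
                 lower = lower, upper = upper, k = k,
                 n_flagged = sum(values < lower | values > upper)),
            class = "dstp_outlier_bounds")
}

#' @export
print.dstp_outlier_bounds <- function(x, digits = 4, ...) {
  cat(sprintf("IQR outlier fences (k = %g): q25 = %.*f, q75 = %.*f, IQR = %.*f\n",
              x$k, digits, x$q25, digits, x$q75, digits, x$iqr))
  cat(sprintf("  fences: [%.*f, %.*f]; %d value(s) flagged\n",
              digits, x$lower, digits, x$upper, x$n_flagged))
  invisible(x)
}

#' Screen fitted parameters for outliers
#'
#' For each parameter column, fences are computed with [iqr_bounds()] over
#' the pooled sample (or within groups defined by `scope_by`), and values
#' outside the fences are flagged. Flagged cells are set to `NA` in the
#' returned table -- the exclusion is scoped to that parameter's analysis
#' only; the row's other parameters remain available -- and every exclusion
#' is logged.
#'
#' @param param_table Data frame with `participant_id`, `word_location` and
#'   one column per parameter.
#' @param parameters Character vector of parameter columns to screen
#'   (default: the seven DSTP parameters plus `interference_ratio`,
#'   intersected with the available columns).
#' @param k Fence multiplier.
#' @param scope_by Optional character vector of grouping columns (e.g.
#'   `"age_group"`) within which fences are computed; `NULL` (default)
#'   pools the full sample per parameter.
#' @return A list with `filtered` (the table with flagged cells `NA`),
#'   `exclusions` (one row per flagged cell: participant, location,
#'   parameter, value, violated fence) and `bounds` (the fences per
#'   parameter).
#' @export
filter_param_outliers <- function(param_table,
                                  parameters = NULL, k = 1.5,
                                  scope_by = NULL) {
  if (is.null(parameters)) {
    parameters <- intersect(c(dstp_param_names(), "interference_ratio"),
                            names(param_table))
  }
  miss <- setdiff(parameters, names(param_table))
  if (length(miss))
    stop("param_table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  groups <- if (is.null(scope_by)) {
    list(seq_len(nrow(param_table)))
  } else {
    split(seq_len(nrow(param_table)),
          interaction(param_table[scope_by], drop = TRUE))
  }
  filtered <- param_table
  logs <- list()
  bounds <- list()
  for (par in parameters) {
    for (gi in seq_along(groups)) {
      idx <- groups[[gi]]
      bnd <- iqr_bounds(param_table[[par]][idx], k = k)
      bounds[[paste(par, gi, sep = ".")]] <- bnd
      vals <- param_table[[par]][idx]
      out <- which(vals < bnd$lower | vals > bnd$upper)
      if (length(out)) {
        rows <- idx[out]
        loc_col <- intersect(c("word_location", "location"), names(param_table))
        logs[[length(logs) + 1L]] <- data.frame(
          participant_id = param_table$participant_id[rows],
          word_location = if (length(loc_col))
            param_table[[loc_col[1]]][rows] else NA_character_,
          parameter = par,
          value = vals[out],
          fence = ifelse(vals[out] < bnd$lower, "lower", "upper"),
          bound = ifelse(vals[out] < bnd$lower, bnd$lower, bnd$upper))
        filtered[[par]][rows] <- NA_real_
      }
    }
  }
  exclusions <- if (length(logs)) do.call(rbind, logs) else
    data.frame(participant_id = character(0), word_location = character(0),
               parameter = character(0), value = numeric(0),
               fence = character(0), bound = numeric(0))
  list(filtered = filtered, exclusions = exclusions, bounds = bounds)
}

# orthonormal contrast matrix (q x k) spanning deviations from the mean
orthonormal_contrasts <- function(k) {
  C <- t(stats::contr.helmert(k))
  C / sqrt(rowSums(C^2))
}

# epsilon from a covariance matrix and an orthonormal contrast matrix
eps_from_cov <- function(S, C) {
  M <- C %*% S %*% t(C)
  q <- nrow(C)
  tr2 <- sum(M * M)
  if (tr2 <= 0) stop("contrast covariance is degenerate (rank-deficient input)",
                     call. = FALSE)
  eps <- sum(diag(M))^2 / (q * tr2)
  min(max(eps, 1 / q), 1)
}

#' Greenhouse-Geisser epsilon
#'
#' Box's sphericity index estimated from the sample covariance of the
#' within-subject condition means:
#' `epsilon = tr(M)^2 / ((k - 1) * tr(M^2))` with `M = C S C'`, `S` the
#' sample covariance of the `subjects x k` matrix and `C` a set of
#' normalised orthogonal contrasts. Clamped to `[1/(k-1), 1]`; equals 1
#' exactly when `k = 2` or when sphericity holds (e.g. compound symmetry).
#'
#' @param condition_matrix Numeric matrix, subjects in rows, the `k >= 2`
#'   within-subject conditions in columns; needs at least `k + 1` subjects.
#' @return The epsilon estimate.
#' @export
gg_epsilon <- function(condition_matrix) {
  x <- as.matrix(condition_matrix)
  k <- ncol(x)
  if (k < 2) stop("need at least 2 within-subject conditions", call. = FALSE)
  if (nrow(x) < k + 1)
    stop("need at least k + 1 subjects to estimate the covariance", call. = FALSE)
  if (any(!is.finite(x))) stop("condition_matrix must be finite", call. = FALSE)
  eps_from_cov(var(x), orthonormal_contrasts(k))
}

#' Mixed (split-plot) ANOVA with Greenhouse-Geisser correction
#'
#' Sums-of-squares decomposition for one between-subject factor and one or
#' two within-subject factors, each within effect (and its interaction with
#' the between factor) tested against its own effect-by-subject error term.
#' Degrees of freedom of within effects are multiplied by the
#' Greenhouse-Geisser epsilon estimated from the pooled within-group
#' covariance of the subject-by-cell matrix; the reported p-values use the
#' adjusted degrees of freedom. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` with the error term of the effect's
#' stratum. The design must be complete (every subject observed exactly once
#' in every within-cell); incomplete data raise an error rather than being
#' imputed. Group sizes may differ.
#'
#' @param data Long-format data frame.
#' @param dv,between,subject Column names (strings): the dependent variable,
#'   the between-subject factor, the subject identifier.
#' @param within Character vector of one or two within-subject factor column
#'   names.
#' @return An object of class `dstp_anova`: a data frame with one row per
#'   effect (`effect`, `df_num`, `df_den`, `ss_effect`, `ss_error`, `F`,
#'   `gg_epsilon`, `df_num_adj`, `df_den_adj`, `p`, `partial_eta_sq`).
#' @examples
#' d <- expand.grid(subject = paste0("s", 1:8),
#'                  congruency = c("congruent", "incongruent"))
#' d$group <- rep(c("young", "old"), each = 4)[match(d$subject, paste0("s", 1:8))]
#' set.seed(1); d$rt <- rnorm(nrow(d), 1, 0.1)
#' mixed_anova(d, dv = "rt", between = "group", within = "congruency",
#'             subject = "subject")
#' @export
mixed_anova <- function(data, dv, between, within, subject) {
  for (col in c(dv, between, within, subject)) {
    if (!col %in% names(data)) stop("column not found: ", col, call. = FALSE)
  }
  if (length(within) < 1 || length(within) > 2)
    stop("within must name 1 or 2 factors", call. = FALSE)
  if (any(!is.finite(data[[dv]])))
    stop("dependent variable contains non-finite values", call. = FALSE)

  subj <- as.character(data[[subject]])
  grp_by_subj <- tapply(as.character(data[[between]]), subj,
                        function(v) unique(v))
  if (any(lengths(grp_by_subj) != 1))
    stop("each subject must belong to exactly one level of the between factor",
         call. = FALSE)

  wlv <- lapply(within, function(w) sort(unique(as.character(data[[w]]))))
  names(wlv) <- within
  cell <- do.call(paste, c(lapply(within, function(w) as.character(data[[w]])),
                           sep = "\r"))
  cell_levels <- do.call(paste,
    c(rev(expand.grid(rev(wlv), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)), sep = "\r"))
  tab <- table(subj, factor(cell, levels = cell_levels))
  if (any(tab != 1))
    stop("design is incomplete or unbalanced: every subject must be observed ",
         "exactly once in every within-cell (aggregate to cell means first)",
         call. = FALSE)

  subjects <- rownames(tab)
  m <- length(cell_levels)
  Y <- matrix(NA_real_, nrow = length(subjects), ncol = m,
              dimnames = list(subjects, cell_levels))
  Y[cbind(match(subj, subjects), match(cell, cell_levels))] <- data[[dv]]

  grp <- factor(unlist(grp_by_subj[subjects]))
  glev <- levels(grp)
  g <- length(glev)
  n_g <- as.integer(table(grp))
  N <- length(subjects)
  if (g < 2) stop("between factor needs at least 2 levels", call. = FALSE)
  if (any(n_g < 2)) stop("each group needs at least 2 subjects", call. = FALSE)

  gm <- mean(Y)
  subj_means <- rowMeans(Y)
  grp_means <- tapply(subj_means, grp, mean)

  ss_between <- m * sum(n_g * (grp_means - gm)^2)
  ss_subj_err <- m * sum((subj_means - grp_means[grp])^2)

  # pooled within-group covariance of the subject x cell matrix
  S_pool <- matrix(0, m, m)
  for (lv in glev) {
    Yg <- Y[grp == lv, , drop = FALSE]
    S_pool <- S_pool + (nrow(Yg) - 1) * var(Yg)
  }
  S_pool <- S_pool / (N - g)

  # orthonormal contrast rows per within effect (kronecker over factors)
  kfacs <- vapply(within, function(w) length(wlv[[w]]), 0L)
  effect_C <- function(involved) {
    mats <- lapply(seq_along(within), function(i) {
      k <- kfacs[i]
      if (within[i] %in% involved) orthonormal_contrasts(k)
      else matrix(1 / sqrt(k), nrow = 1, ncol = k)
    })
    Reduce(kronecker, mats)
  }
  within_effects <- c(as.list(within),
                      if (length(within) == 2) list(within))

  rows <- list()
  add_row <- function(effect, ss_eff, df_num, ss_err, df_den, eps = NA_real_) {
    ms_eff <- ss_eff / df_num
    ms_err <- ss_err / df_den
    Fv <- if (ss_eff <= 0) 0 else ms_eff / ms_err
    adj <- if (is.na(eps)) 1 else eps
    p <- if (ss_eff <= 0) 1 else
      stats::pf(Fv, df_num * adj, df_den * adj, lower.tail = FALSE)
    etap <- if (ss_eff <= 0) 0 else ss_eff / (ss_eff + ss_err)
    rows[[length(rows) + 1L]] <<- data.frame(
      effect = effect, df_num = df_num, df_den = df_den,
      ss_effect = ss_eff, ss_error = ss_err, F = Fv,
      gg_epsilon = eps, df_num_adj = df_num * adj, df_den_adj = df_den * adj,
      p = p, partial_eta_sq = etap)
  }

  add_row(between, ss_between, g - 1, ss_subj_err, N - g)

  for (eff in within_effects) {
    C <- effect_C(eff)
    q <- nrow(C)
    Z <- Y %*% t(C)                         # subject contrast scores
    zbar <- colMeans(Z)
    zbar_g <- apply(Z, 2, function(col) tapply(col, grp, mean))
    if (q == 1) zbar_g <- matrix(zbar_g, nrow = g)
    ss_eff <- N * sum(zbar^2)
    # group deviations of the contrast means: sum_g n_g (zbar_gj - zbar_j)^2
    ss_int <- sum(n_g * rowSums((zbar_g - matrix(zbar, g, q, byrow = TRUE))^2))
    ss_err <- sum((Z - zbar_g[grp, , drop = FALSE])^2)
    eps <- tryCatch(eps_from_cov(S_pool, C), error = function(e) 1)
    nm <- paste(eff, collapse = ":")
    add_row(nm, ss_eff, q, ss_err, (N - g) * q, eps)
    add_row(paste(between, nm, sep = ":"), ss_int, (g - 1) * q, ss_err,
            (N - g) * q, eps)
  }

  out <- do.call(rbind, rows)
  attr(out, "n_subjects") <- N
  attr(out, "groups") <- setNames(n_g, glev)
  attr(out, "ss_total") <- sum((Y - gm)^2)
  class(out) <- c("dstp_anova", "data.frame")
  out
}

#' @export
print.dstp_anova <- function(x, digits = 3, ...) {
  cat("Mixed ANOVA (Greenhouse-Geisser corrected within effects)\n")
  df <- as.data.frame(x)
  df$F <- round(df$F, digits)
  df$gg_epsilon <- round(df$gg_epsilon, digits)
  df$df_num_adj <- round(df$df_num_adj, 1)
  df$df_den_adj <- round(df$df_den_adj, 1)
  df$p <- signif(df$p, digits)
  df$partial_eta_sq <- round(df$partial_eta_sq, digits)
  print(df[, c("effect", "df_num_adj", "df_den_adj", "F", "gg_epsilon",
               "p", "partial_eta_sq")], row.names = FALSE)
  invisible(x)
}

#' Tukey-corrected pairwise comparisons
#'
#' All-pairs comparisons of a family of cell means using the studentized
#' range distribution: `q = |m_i - m_j| / sqrt(MSE / n)` (Tukey-Kramer with
#' the harmonic term when cell sizes differ), with the adjusted p-value
#' `ptukey(q, k, df)` for a family of `k` means and `error_df` error degrees
#' of freedom. For `k = 2` the adjusted p equals the two-sided pooled
#' t-test p.
#'
#' @param cell_means Named numeric vector of cell means (>= 2 cells).
#' @param error_mean_square Positive error mean square from the ANOVA
#'   stratum the family belongs to.
#' @param error_df Error degrees of freedom (>= 1).
#' @param n_per_cell Observations per cell mean; scalar or one value per
#'   cell.
#' @return An object of class `dstp_pairwise`: a data frame with one row per
#'   pair (`level_1`, `level_2`, `mean_diff`, `se`, `q`, `p_adj`).
#' @export
tukey_pairwise <- function(cell_means, error_mean_square, error_df,
                           n_per_cell) {
  k <- length(cell_means)
  if (k < 2) stop("need at least 2 cell means", call. = FALSE)
  if (!is.numeric(error_mean_square) || error_mean_square <= 0)
    stop("error_mean_square must be positive", call. = FALSE)
  if (error_df < 1) stop("error_df must be >= 1", call. = FALSE)
  if (is.null(names(cell_means))) names(cell_means) <- seq_len(k)
  n_per_cell <- rep_len(n_per_cell, k)
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    diff <- cell_means[i] - cell_means[j]
    se <- sqrt(error_mean_square * (1 / n_per_cell[i] + 1 / n_per_cell[j]))
    q <- abs(diff) / (se / sqrt(2))
    p <- ptukey(q, nmeans = k, df = error_df, lower.tail = FALSE)
    data.frame(level_1 = names(cell_means)[i], level_2 = names(cell_means)[j],
               mean_diff = unname(diff), se = unname(se), q = unname(q),
               p_adj = unname(p))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("dstp_pairwise", "data.frame")
  out
}

#' @export
print.dstp_pairwise <- function(x, digits = 4, ...) {
  cat("Tukey-corrected pairwise comparisons\n")
  df <- as.data.frame(x)
  df$mean_diff <- round(df$mean_diff, digits)
  df$se <- round(df$se, digits)
  df$q <- round(df$q, 3)
  df$p_adj <- signif(df$p_adj, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Per-participant condition summaries of trial-level behaviour
#'
#' Accuracy per cell uses all trials; mean RT per cell uses correct,
#' non-censored trials only. Cells without a usable correct trial get `NA`
#' mean RT and are reported with a warning so the RT ANOVA can drop the
#' participant listwise.
#'
#' @param trials Trial-level data frame with `participant_id`, `age_group`,
#'   `word_location`, `congruency`, `correct`, `rt_s` and (optionally)
#'   `censored`.
#' @return A data frame with one row per participant x location x
#'   congruency: `accuracy`, `mean_rt`, `n_trials`, `n_rt_trials`.
#' @export
summarize_behavior <- function(trials) {
  need <- c("participant_id", "age_group", "word_location", "congruency",
            "correct", "rt_s")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trials lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"censored" %in% names(trials)) trials$censored <- FALSE

  key <- list(participant_id = trials$participant_id,
              age_group = trials$age_group,
              word_location = trials$word_location,
              congruency = trials$congruency)
  acc <- aggregate(trials$correct, key, mean)
  names(acc)[5] <- "accuracy"
  ntr <- aggregate(trials$correct, key, length)
  names(ntr)[5] <- "n_trials"

  usable <- trials$correct & !trials$censored
  rt <- trials$rt_s
  rt[!usable] <- NA_real_
  mrt <- aggregate(rt, key, function(v) mean(v, na.rm = TRUE))
  names(mrt)[5] <- "mean_rt"
  nrt <- aggregate(usable, key, sum)
  names(nrt)[5] <- "n_rt_trials"

  out <- Reduce(function(a, b) merge(a, b, sort = FALSE),
                list(acc, ntr, mrt, nrt))
  out$mean_rt[out$n_rt_trials == 0] <- NA_real_
  bad <- out$n_rt_trials == 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) without usable correct trials; mean RT set NA (",
            paste(unique(out$participant_id[bad]), collapse = ", "), ")",
            call. = FALSE)
  }
  out[order(out$participant_id, out$word_location, out$congruency), ]
}

#' @importFrom stats aggregate
NULL
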