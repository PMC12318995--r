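test_that("IQR fences follow the 1.5-IQR rule under type-7 quantiles", {
  b <- iqr_bounds(c(1, 2, 3, 4, 100))
  expect_equal(b$q25, 2)
  expect_equal(b$q75, 4)
  expect_equal(b$iqr, 2)
  expect_equal(b$lower, -1)
  expect_equal(b$upper, 7)
  expect_equal(b$n_flagged, 1L)

  same <- iqr_bounds(rep(3, 10))
  expect_equal(same$iqr, 0)
  expect_equal(same$lower, 3)
  expect_equal(same$upper, 3)
  expect_equal(same$n_flagged, 0L)

  k0 <- iqr_bounds(c(1, 2, 3, 4, 100), k = 0)
  expect_equal(k0$lower, k0$q25)
  expect_equal(k0$upper, k0$q75)

  expect_error(iqr_bounds(c(1, 2, 3)), "at least 4")
})

test_that("outlier screening is scoped per parameter and matches a brute-force scan", {
  set.seed(21)
  tab <- expand.grid(participant_id = sprintf("p%02d", 1:20),
                     location = c("target", "distractor", "background"),
                     stringsAsFactors = FALSE)
  # bounded draws: no natural fence outliers besides the injected one
  tab$crit_a <- runif(60, 0.18, 0.22)
  tab$ter <- runif(60, 0.28, 0.32)
  tab$crit_a[7] <- 5  # one wild boundary estimate

  scr <- filter_param_outliers(tab, parameters = c("crit_a", "ter"))
  expect_true(is.na(scr$filtered$crit_a[7]))
  expect_false(any(is.na(scr$filtered$ter)))  # scoped to crit_a only
  expect_equal(nrow(scr$exclusions), 1L)
  expect_equal(scr$exclusions$parameter, "crit_a")

  # brute-force scan agreement on exclusion counts
  for (par in c("crit_a", "ter")) {
    q <- quantile(tab[[par]], c(0.25, 0.75), type = 7)
    fence <- c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q))
    n_manual <- sum(tab[[par]] < fence[1] | tab[[par]] > fence[2])
    expect_equal(sum(scr$exclusions$parameter == par), n_manual)
  }

  clean <- filter_param_outliers(tab[-7, ], parameters = "ter")
  expect_equal(clean$filtered, tab[-7, ])
  expect_equal(nrow(clean$exclusions), 0L)
})

test_that("Greenhouse-Geisser epsilon has its exact special cases", {
  set.seed(22)
  # k = 2: a single contrast dimension, epsilon is identically 1
  x2 <- matrix(rnorm(20), ncol = 2)
  expect_equal(gg_epsilon(x2), 1)

  # exact compound symmetry: colour whitened data by a CS covariance root
  k <- 3; n <- 12
  x <- matrix(rnorm(n * k), ncol = k)
  x <- scale(x, center = TRUE, scale = FALSE)
  W <- chol(var(x))
  S_cs <- matrix(0.3, k, k); diag(S_cs) <- 1
  xc <- x %*% solve(W) %*% chol(S_cs)  # sample covariance is exactly S_cs
  expect_equal(gg_epsilon(xc), 1, tolerance = 1e-10)

  expect_error(gg_epsilon(matrix(1, 5, 3)), "degenerate")
  expect_error(gg_epsilon(matrix(rnorm(4), 2, 2)), "subjects")
})

test_that("epsilon matches an independent eigenvalue computation", {
  set.seed(23)
  for (k in c(3, 4)) {
    x <- matrix(rnorm(9 * k, sd = rep(1:k, each = 9)), ncol = k)
    C <- t(stats::contr.helmert(k)); C <- C / sqrt(rowSums(C^2))
    lam <- eigen(C %*% var(x) %*% t(C), symmetric = TRUE,
                 only.values = TRUE)$values
    eps_eig <- sum(lam)^2 / ((k - 1) * sum(lam^2))
    expect_equal(gg_epsilon(x), max(min(eps_eig, 1), 1 / (k - 1)),
                 tolerance = 1e-10)
  }
})

make_split_plot_data <- function(n_per_group = 4, k = 2, seed = 24,
                                 effects = TRUE) {
  set.seed(seed)
  d <- expand.grid(participant_id = sprintf("s%02d", seq_len(2 * n_per_group)),
                   w = paste0("c", seq_len(k)), stringsAsFactors = FALSE)
  d$age_group <- rep(c("young", "old"),
                     each = n_per_group)[match(d$participant_id,
                                               unique(d$participant_id))]
  d$y <- rnorm(nrow(d), 1, 0.1)
  if (effects) {
    d$y <- d$y + 0.3 * (d$age_group == "old") + 0.2 * (d$w == "c1") +
      0.15 * (d$age_group == "old") * (d$w == "c1")
  }
  d
}

test_that("mixed ANOVA F values match brute-force sums of squares on a 2x2 design", {
  d <- make_split_plot_data(n_per_group = 4, k = 2)
  out <- mixed_anova(d, dv = "y", between = "age_group", within = "w",
                     subject = "participant_id")

  # brute-force split-plot decomposition from cell/subject means
  Y <- tapply(d$y, list(d$participant_id, d$w), mean)
  grp <- tapply(d$age_group, d$participant_id, unique)[rownames(Y)]
  gm <- mean(Y)
  sm <- rowMeans(Y)
  ss_A <- 2 * sum(tapply(sm, grp, function(v) length(v) * (mean(v) - gm)^2))
  ss_S <- 2 * sum((sm - ave(sm, grp))^2)
  cmeans <- colMeans(Y)
  ss_W <- nrow(Y) * sum((cmeans - gm)^2)
  cell <- matrix(0, 2, 2, dimnames = list(unique(grp), colnames(Y)))
  for (g in rownames(cell)) cell[g, ] <- colMeans(Y[grp == g, ])
  ng <- table(grp)[rownames(cell)]
  ss_AW <- sum(ng * rowSums((cell - outer(rowMeans(cell), cmeans - gm, "+"))^2))
  ss_tot <- sum((Y - gm)^2)
  ss_WS <- ss_tot - ss_A - ss_S - ss_W - ss_AW

  expect_equal(out$ss_effect[out$effect == "age_group"], ss_A)
  expect_equal(out$ss_error[out$effect == "age_group"], ss_S)
  expect_equal(out$ss_effect[out$effect == "w"], ss_W)
  expect_equal(out$ss_effect[out$effect == "age_group:w"], ss_AW)
  expect_equal(out$ss_error[out$effect == "w"], ss_WS)
  expect_equal(out$F[out$effect == "age_group"], (ss_A / 1) / (ss_S / 6))
  expect_equal(out$F[out$effect == "w"], (ss_W / 1) / (ss_WS / 6))
  # k = 2 within effects need no sphericity correction
  expect_equal(out$gg_epsilon[out$effect == "w"], 1)
  expect_equal(attr(out, "ss_total"),
               sum(out$ss_effect) + ss_S + ss_WS)
})

test_that("mixed ANOVA agrees with car's Greenhouse-Geisser machinery", {
  skip_if_not_installed("car")
  d <- make_split_plot_data(n_per_group = 6, k = 3, seed = 25)
  ours <- mixed_anova(d, dv = "y", between = "age_group", within = "w",
                      subject = "participant_id")

  wide <- reshape(d, idvar = c("participant_id", "age_group"),
                  timevar = "w", direction = "wide")
  mod <- lm(cbind(y.c1, y.c2, y.c3) ~ age_group, data = wide,
            contrasts = list(age_group = "contr.sum"))
  idata <- data.frame(w = factor(paste0("c", 1:3)))
  aa <- suppressWarnings(car::Anova(mod, idata = idata, idesign = ~w,
                                    type = 3))
  sm <- summary(aa, multivariate = FALSE)
  uni <- sm$univariate.tests
  expect_equal(ours$F[ours$effect == "w"], uni["w", "F value"],
               tolerance = 1e-8)
  expect_equal(ours$F[ours$effect == "age_group:w"],
               uni["age_group:w", "F value"], tolerance = 1e-8)
  expect_equal(ours$gg_epsilon[ours$effect == "w"],
               unname(sm$pval.adjustments["w", "GG eps"]), tolerance = 1e-8)
  expect_equal(ours$p[ours$effect == "w"],
               unname(sm$pval.adjustments["w", "Pr(>F[GG])"]),
               tolerance = 1e-8)
})

test_that("two within factors decompose fully and exactly", {
  set.seed(26)
  d <- expand.grid(participant_id = sprintf("s%02d", 1:10),
                   congruency = c("congruent", "incongruent"),
                   word_location = c("target", "distractor", "background"),
                   stringsAsFactors = FALSE)
  d$age_group <- rep(c("young", "old"), c(5, 5))[match(d$participant_id,
                                                       unique(d$participant_id))]
  d$y <- rnorm(nrow(d), 1, 0.2)
  out <- mixed_anova(d, dv = "y", between = "age_group",
                     within = c("congruency", "word_location"),
                     subject = "participant_id")
  expect_setequal(out$effect,
                  c("age_group", "congruency", "age_group:congruency",
                    "word_location", "age_group:word_location",
                    "congruency:word_location",
                    "age_group:congruency:word_location"))
  # complete decomposition: SS_total = sum of effect SS + unique error SS
  err_unique <- sum(out$ss_error[!duplicated(out$ss_error)])
  expect_equal(sum(out$ss_effect) + err_unique, attr(out, "ss_total"),
               tolerance = 1e-8)
  expect_true(all(out$partial_eta_sq >= 0 & out$partial_eta_sq <= 1))
  # epsilon bounds per effect: 1/(k-1) <= eps <= 1
  expect_true(out$gg_epsilon[out$effect == "word_location"] >= 0.5)
  expect_equal(out$gg_epsilon[out$effect == "congruency"], 1)
})

test_that("mixed ANOVA rejects incomplete designs and flags constant data", {
  d <- make_split_plot_data()
  expect_error(mixed_anova(d[-1, ], dv = "y", between = "age_group",
                           within = "w", subject = "participant_id"),
               "incomplete|unbalanced")
  dc <- d; dc$y <- 1
  out <- mixed_anova(dc, dv = "y", between = "age_group", within = "w",
                     subject = "participant_id")
  expect_true(all(out$F == 0))
  expect_true(all(out$partial_eta_sq == 0))
})

test_that("relabelling subjects within group leaves the ANOVA unchanged", {
  d <- make_split_plot_data(seed = 27)
  out1 <- mixed_anova(d, dv = "y", between = "age_group", within = "w",
                      subject = "participant_id")
  d2 <- d
  # swap the ids of two subjects in the same group
  d2$participant_id[d$participant_id == "s01"] <- "zz"
  d2$participant_id[d$participant_id == "s02"] <- "s01"
  d2$participant_id[d2$participant_id == "zz"] <- "s02"
  out2 <- mixed_anova(d2, dv = "y", between = "age_group", within = "w",
                      subject = "participant_id")
  expect_equal(as.data.frame(out1), as.data.frame(out2))
})

test_that("Tukey comparisons reduce to the pooled t-test for two cells and match TukeyHSD", {
  set.seed(28)
  # k = 2 equivalence
  g <- rep(c("a", "b"), each = 8)
  y <- rnorm(16, mean = c(1, 1.4)[as.integer(factor(g))])
  fit <- aov(y ~ g)
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  means <- tapply(y, g, mean)
  tk <- tukey_pairwise(means, mse, df.residual(fit), 8)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-10)

  # identical means: adjusted p is 1
  same <- tukey_pairwise(c(a = 1, b = 1, c = 1), 0.5, 12, 5)
  expect_true(all(same$p_adj > 0.9999))

  # k = 3 against TukeyHSD on a one-way fit
  g3 <- rep(c("a", "b", "c"), each = 7)
  y3 <- rnorm(21, mean = c(1, 1.3, 1.8)[as.integer(factor(g3))])
  fit3 <- aov(y3 ~ g3)
  mse3 <- summary(fit3)[[1]]["Residuals", "Mean Sq"]
  tk3 <- tukey_pairwise(tapply(y3, g3, mean), mse3, df.residual(fit3), 7)
  ref <- TukeyHSD(fit3)$g3
  for (i in seq_len(nrow(tk3))) {
    pair <- paste(tk3$level_2[i], tk3$level_1[i], sep = "-")
    expect_equal(tk3$p_adj[i], ref[pair, "p adj"], tolerance = 1e-8)
    expect_equal(-tk3$mean_diff[i], ref[pair, "diff"], tolerance = 1e-10)
  }

  expect_error(tukey_pairwise(c(1, 2), -1, 10, 5), "positive")
  expect_error(tukey_pairwise(c(a = 1), 1, 10, 5), "at least 2")
})

test_that("behavioural summaries aggregate correctly and handle empty cells", {
  co <- simulate_cohort(cohort_config(n_young = 2, n_old = 2, seed = 31))
  s <- summarize_behavior(co$trials)
  expect_equal(nrow(s), 4 * 3 * 2)

  # oracle aggregation for one cell
  tr <- co$trials
  cellsel <- tr$participant_id == "p001" & tr$word_location == "target" &
    tr$congruency == "incongruent"
  expect_equal(s$accuracy[s$participant_id == "p001" &
                            s$word_location == "target" &
                            s$congruency == "incongruent"],
               mean(tr$correct[cellsel]))
  ok <- cellsel & tr$correct & !tr$censored
  expect_equal(s$mean_rt[s$participant_id == "p001" &
                           s$word_location == "target" &
                           s$congruency == "incongruent"],
               mean(tr$rt_s[ok]))

  # all-correct input gives accuracy 1 everywhere
  tr2 <- tr
  tr2$correct <- TRUE
  s2 <- summarize_behavior(tr2)
  expect_true(all(s2$accuracy == 1))

  # a participant with no correct trials in one cell is flagged
  tr3 <- tr
  kill <- tr3$participant_id == "p002" & tr3$word_location == "background" &
    tr3$congruency == "congruent"
  tr3$correct[kill] <- FALSE
  expect_warning(s3 <- summarize_behavior(tr3), "p002")
  expect_true(is.na(s3$mean_rt[s3$participant_id == "p002" &
                                 s3$word_location == "background" &
                                 s3$congruency == "congruent"]))
})
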