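test_that("interference ratio is the word drift over the selection drift", {
  expect_equal(interference_ratio(dstp_params(0.1, 0.2, 0.4, 1, 0.2, 0.2, 0.3)),
               0.5)
  expect_equal(interference_ratio(dstp_params(0.1, 0, 0.4, 1, 0.2, 0.2, 0.3)),
               0)
  p0 <- dstp_params(0.1, 0.2, 0.01, 1, 0.2, 0.2, 0.3)
  p0 <- unclass(p0); p0["mu_ss"] <- 0
  class(p0) <- "dstp_params"
  expect_error(interference_ratio(p0), "mu_ss")
})

test_that("fitting validates its inputs and names the missing condition", {
  dat <- make_fit_data(seed = 71)
  expect_error(dstp_fit(dat[dat$congruency == "incongruent", ]),
               "no congruent trials")
  dat2 <- dat
  dat2$correct[dat2$congruency == "congruent"] <- FALSE
  expect_error(dstp_fit(dat2), "no correct congruent")
  expect_error(dstp_fit(dat[, c("congruency", "correct")]), "rt_s")
})

test_that("a small multi-start fit returns a complete, reproducible result", {
  dat <- make_fit_data(seed = 72)
  fit <- dstp_fit(dat, n_starts = 2, n_sim = 300, maxit = 15, seed = 7)
  expect_s3_class(fit, "dstp_fit")
  expect_equal(nrow(fit$start_table), 2L)
  expect_equal(fit$n_starts, 2L)
  expect_equal(fit$n_sim_per_eval, 300)
  expect_true(is.finite(fit$g2) && fit$g2 >= 0)
  expect_equal(fit$g2, min(fit$start_table$g2))
  b <- dstp_bounds()
  expect_true(all(coef(fit) >= b[, 1] & coef(fit) <= b[, 2]))

  # identical seed reproduces the fit; trial order is irrelevant
  fit2 <- dstp_fit(dat, n_starts = 2, n_sim = 300, maxit = 15, seed = 7)
  expect_equal(coef(fit), coef(fit2))
  perm <- sample(nrow(dat))
  fit3 <- dstp_fit(dat[perm, ], n_starts = 2, n_sim = 300, maxit = 15,
                   seed = 7)
  expect_equal(coef(fit), coef(fit3))
})

test_that("the best fitted G2 does not exceed the generating parameters' G2", {
  truth <- default_test_params()
  dat <- make_fit_data(truth, seed = 73)
  fit <- dstp_fit(dat, n_starts = 6, n_sim = 1000, maxit = 80,
                  starts = "anchored", seed = 8)
  # evaluate the generating parameters on the same bins with the same
  # common random numbers (argmin dominance up to Monte-Carlo slack)
  obj <- dstp:::make_g2_objective(fit$bins, fit$n_sim_per_eval, fit$config,
                                  fit$bounds, fit$crn_seeds)
  b <- fit$bounds
  z_truth <- (unclass(truth)[dstp_param_names()] - b[, 1]) / (b[, 2] - b[, 1])
  expect_lte(fit$g2, obj(z_truth) + 3)
})

test_that("the final pass polishes at higher precision and warns when lower", {
  dat <- make_fit_data(seed = 74)
  fit <- dstp_fit(dat, n_starts = 2, n_sim = 400, maxit = 15, seed = 9)
  out <- dstp_refit(fit, n_sim = 800, maxit = 30)
  expect_equal(out$n_sim_final, 800)
  expect_true(is.finite(out$g2))
  expect_warning(dstp_refit(fit, n_sim = 100, maxit = 5), "below the screening")
})

test_that("fit methods expose the usual modelling interface", {
  dat <- make_fit_data(seed = 75)
  fit <- dstp_fit(dat, n_starts = 2, n_sim = 400, maxit = 15, seed = 10)
  expect_length(coef(fit), 7L)
  expect_named(coef(fit), dstp_param_names())
  expect_output(print(fit), "DSTP fit")
  expect_output(print(summary(fit)), "Interference ratio")

  pr <- predict(fit, n_sim = 2000, seed = 11)
  expect_true(all(c("condition", "outcome", "observed", "predicted") %in%
                    names(pr)))
  # observed proportions per condition sum to one
  for (cond in c("congruent", "incongruent")) {
    expect_equal(sum(pr$observed[pr$condition == cond]), 1)
  }
  r <- residuals(fit, n_sim = 2000, seed = 11)
  expect_equal(unname(r), pr$observed - pr$predicted)

  sim <- simulate(fit, nsim = 1, seed = 12)
  expect_equal(nrow(sim), nrow(dat))
  expect_setequal(unique(sim$congruency), c("congruent", "incongruent"))
})

test_that("synthetic groups differing in boundary yield ordered fitted boundaries", {
  # group-level monotone diagnostic at a deliberately small budget
  cfg <- sim_config()
  set.seed(80)
  fit_a <- function(a, seed) {
    truth <- dstp_params(0.08, 0.12, 0.35, 0.9, a, 0.22, 0.30)
    dat <- make_fit_data(truth, n_incongruent = 216, n_congruent = 72,
                         seed = seed)
    fit <- dstp_fit(dat, n_starts = 6, n_sim = 500, maxit = 60,
                    starts = "anchored", seed = seed)
    coef(dstp_refit(fit, n_sim = 1000, maxit = 100, top = 2,
                    n_sim_select = 5000))[["crit_a"]]
  }
  low <- vapply(1:3, function(i) fit_a(0.12, 100 + i), 0)
  high <- vapply(1:3, function(i) fit_a(0.26, 200 + i), 0)
  expect_gt(mean(high), mean(low))
})
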