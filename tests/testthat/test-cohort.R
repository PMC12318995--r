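test_that("cohort defaults encode the intended group structure", {
  cc <- cohort_config()
  expect_equal(cc$n_young, 75)
  expect_equal(cc$n_old, 72)
  m <- cc$means
  young_t <- m[m$age_group == "young" & m$word_location == "target", ]
  old_t <- m[m$age_group == "old" & m$word_location == "target", ]
  # old group: wider boundaries, longer encoding, slower second phase
  expect_gt(old_t$crit_a, young_t$crit_a)
  expect_gt(old_t$crit_c, young_t$crit_c)
  expect_gt(old_t$ter, young_t$ter)
  expect_lt(old_t$mu_rs2, young_t$mu_rs2)
  # word drift concentrated in the target location
  young_d <- m[m$age_group == "young" & m$word_location == "distractor", ]
  expect_gt(young_t$mu_color_word, young_d$mu_color_word)

  expect_error(cohort_config(n_young = 0), "group sizes")
  bad <- default_cohort_means()
  bad$crit_a <- 5
  expect_error(cohort_config(means = bad), "bounds")
})

test_that("a participant's session yields one record per design trial", {
  design <- session_design(seed = 51)
  cc <- cohort_config(seed = 52)
  set.seed(52)
  params <- dstp:::draw_participant_params(cc, "young")
  tr <- simulate_participant("p01", params, design, sim_config())
  expect_equal(nrow(tr), nrow(design))
  expect_true(all(tr$rt_s > 0))
  # response colour is the target colour iff the response was correct
  expect_true(all((tr$response_color == tr$target_color) == tr$correct))
  expect_true(all(tr$response_color %in% c("red", "green", "blue", "yellow")))

  expect_error(simulate_participant("p01", params["target"], design,
                                    sim_config()),
               "distractor")
})

test_that("word drift of zero abolishes the congruency effect", {
  p_null <- dstp_params(0.08, 0, 0.35, 0.9, 0.18, 0.22, 0.30)
  cfg <- sim_config(seed = 53)
  si <- simulate_dstp(p_null, "incongruent", 20000, cfg)
  sc <- simulate_dstp(p_null, "congruent", 20000, sim_config(seed = 54))
  d <- mean(si$rt_s[si$correct]) - mean(sc$rt_s[sc$correct])
  se <- sqrt(var(si$rt_s[si$correct]) / sum(si$correct) +
               var(sc$rt_s[sc$correct]) / sum(sc$correct))
  expect_lt(abs(d), 3 * se)
})

test_that("synthetic cohorts return trials plus ground truth and honour counts", {
  co <- simulate_cohort(cohort_config(n_young = 3, n_old = 2, seed = 55))
  expect_equal(nrow(co$trials), 5 * 432)
  expect_equal(nrow(co$true_params), 5 * 3)
  expect_setequal(unique(co$trials$age_group), c("young", "old"))
  expect_equal(sum(table(unique(co$trials[c("participant_id", "age_group")])$age_group)), 5)
  # every participant's design satisfies the session invariants
  for (id in unique(co$trials$participant_id)) {
    check_session_design(co$trials[co$trials$participant_id == id, ])
  }
  # reproducible per seed
  co2 <- simulate_cohort(cohort_config(n_young = 3, n_old = 2, seed = 55))
  expect_identical(co$trials, co2$trials)
  # true old-young differences have the configured sign
  tp <- co$true_params
  expect_gt(mean(tp$true_crit_a[tp$age_group == "old"]),
            mean(tp$true_crit_a[tp$age_group == "young"]) - 0.02)
})

test_that("the default cohort reproduces the headline behavioural pattern", {
  co <- simulate_cohort(cohort_config(n_young = 25, n_old = 25, seed = 56))
  s <- summarize_behavior(co$trials)
  agg <- aggregate(mean_rt ~ word_location + congruency + age_group, s, mean)
  g <- function(loc, cong, grp)
    agg$mean_rt[agg$word_location == loc & agg$congruency == cong &
                  agg$age_group == grp]
  # congruency slowing is concentrated in the target location, in both groups
  for (grp in c("young", "old")) {
    eff <- vapply(c("target", "distractor", "background"), function(loc)
      g(loc, "incongruent", grp) - g(loc, "congruent", grp), 0)
    expect_gt(eff[["target"]], 0.05)
    expect_gt(eff[["target"]], 2 * eff[["distractor"]])
    expect_gt(eff[["target"]], 2 * eff[["background"]])
  }
  # synthetic old adults are slower overall
  expect_gt(mean(s$mean_rt[s$age_group == "old"]),
            mean(s$mean_rt[s$age_group == "young"]))
  # and more accurate (wider boundaries)
  expect_gt(mean(s$accuracy[s$age_group == "old"]),
            mean(s$accuracy[s$age_group == "young"]))
})
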