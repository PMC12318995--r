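# shared fixtures, built in code at test time

default_test_params <- function() {
  dstp_params(mu_target_color = 0.08, mu_color_word = 0.12, mu_ss = 0.35,
              mu_rs2 = 0.9, crit_a = 0.18, crit_c = 0.22, ter = 0.30)
}

# one participant's worth of trials at the session's congruency mix
make_fit_data <- function(params = default_test_params(),
                          n_incongruent = 324, n_congruent = 108, seed = 1) {
  rbind(
    cbind(congruency = "incongruent",
          simulate_dstp(params, "incongruent", n_incongruent,
                        sim_config(seed = seed))),
    cbind(congruency = "congruent",
          simulate_dstp(params, "congruent", n_congruent,
                        sim_config(seed = seed + 1000))))
}

# independent brute-force multinomial log-likelihood-ratio for G2 checks
g2_oracle <- function(obs, prop) {
  n <- sum(obs)
  ll_sat <- sum(ifelse(obs > 0, obs * log(obs / n), 0))
  ll_mod <- sum(ifelse(obs > 0, obs * log(prop), 0))
  2 * (ll_sat - ll_mod)
}
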