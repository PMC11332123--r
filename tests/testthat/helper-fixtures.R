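# Shared fixtures: tiny deterministic trial tables and analytic force traces.

# 20-trial fixture with a fixed, reproducible choice pattern
fixture_trials_20 <- function(seed = 123) {
  session <- build_session("thunderstorm", n_blocks = 1, seed = seed)
  session <- session[1:16, ]
  extra <- session[1:4, ]
  extra$trial_index <- 17:20
  trials <- rbind(session, extra)
  withr::with_seed(seed, {
    trials$choice <- as.integer(stats::runif(20) <
                                  stats::plogis(trials$incentive_level -
                                                  trials$effort_level))
  })
  trials
}

# one synthetic subject's full 80-trial session
fixture_subject <- function(family = "linear", k = 0.5, beta = 3, c = -1,
                            seed = 7) {
  session <- build_session("thunderstorm", n_blocks = 5, seed = seed)
  tr <- simulate_choices(session, family, k, beta, c, seed = seed + 1)
  tr$subject_id <- "s1"
  tr
}

# analytic force trace: baseline, exact linear ramp, exact plateau, no noise
fixture_trace <- function(threshold = 60, delta = 5, baseline_s = 0.5,
                          ramp_s = 0.5, hold_s = 2) {
  fs <- 60
  n_base <- round(baseline_s * fs)
  n_ramp <- round(ramp_s * fs)
  n_hold <- round(hold_s * fs)
  force <- c(rep(0, n_base),
             seq(0, threshold + delta, length.out = n_ramp),
             rep(threshold + delta, n_hold))
  tibble::tibble(
    subject_id = "s1", trial_index = 1L,
    t = (seq_along(force) - 1) / fs,
    force = force, required_threshold = threshold
  )
}
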