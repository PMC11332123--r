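test_that("rolling average is symmetric, line-preserving, and local", {
  fs <- 60
  const <- tibble::tibble(t = (0:99) / fs, force = rep(7, 100))
  expect_equal(rolling_average(const)$force, const$force)
  # interior of a linear ramp passes through unchanged (symmetric filter)
  ramp <- tibble::tibble(t = (0:99) / fs, force = 2 * (0:99))
  sm <- rolling_average(ramp)$force
  expect_equal(sm[5:96], ramp$force[5:96], tolerance = 1e-9)
  # unit impulse spreads 1/6 over the window core (half-weight end taps)
  imp <- tibble::tibble(t = (0:99) / fs, force = c(rep(0, 50), 1, rep(0, 49)))
  smi <- rolling_average(imp)$force
  expect_equal(smi[51], 1 / 6)
  expect_equal(smi[49:53], rep(1 / 6, 5))
  expect_equal(smi[48], 1 / 12)
  expect_equal(smi[54], 1 / 12)
  expect_equal(sum(smi), 1, tolerance = 1e-9) # mass (mean) preserved
  expect_error(rolling_average(tibble::tibble(t = c(0, 0.5, 0.6),
                                              force = 1:3)), "60 Hz")
})

test_that("rolling average is linear and shift-equivariant", {
  fs <- 60
  x <- withr::with_seed(3, tibble::tibble(t = (0:199) / fs,
                                          force = rnorm(200)))
  y <- withr::with_seed(4, tibble::tibble(t = (0:199) / fs,
                                          force = rnorm(200)))
  lin <- rolling_average(dplyr::mutate(x, force = 2 * x$force + 3 * y$force))
  expect_equal(lin$force,
               2 * rolling_average(x)$force + 3 * rolling_average(y)$force,
               tolerance = 1e-10)
  shifted <- dplyr::mutate(x, force = dplyr::lag(force, 10, default = 0))
  expect_equal(rolling_average(shifted)$force[20:190],
               dplyr::lag(rolling_average(x)$force, 10)[20:190],
               tolerance = 1e-10)
})

test_that("success epochs end at the 90th consecutive above-threshold sample", {
  tr <- fixture_trace(threshold = 60, delta = 5, baseline_s = 1,
                      ramp_s = 0.5, hold_s = 2)
  ep <- find_success_epoch(tr, epoch_len = 2.5)
  above <- tr$force >= 60
  first_above <- which(above)[1]
  expect_equal(ep$end, first_above + 89)
  expect_equal(ep$end - ep$start + 1, round(2.5 * 60))
  expect_false(is.null(ep))
  # failure trace (never holds 1.5 s) yields no epoch
  fail <- tr
  fail$force[seq(first_above + 30, nrow(fail), by = 60)] <- 0
  expect_null(find_success_epoch(fail))
})

test_that("epochs anchor to the final completion after a failed attempt", {
  fs <- 60
  thr <- 50
  # 1 s above threshold (60 samples < 90), a dip, then a clean 2 s hold
  force <- c(rep(0, 30), rep(thr + 4, 60), rep(thr - 5, 30),
             rep(thr + 6, 150))
  tr <- tibble::tibble(t = (seq_along(force) - 1) / fs, force = force,
                       required_threshold = thr)
  ep25 <- find_success_epoch(tr, epoch_len = 2.5)
  ep20 <- find_success_epoch(tr, epoch_len = 2.0)
  completion <- 120 + 90 # dip ends at sample 120; 90 consecutive follow
  expect_equal(ep25$end, completion)
  expect_equal(ep20$end, completion)
  # the shorter epoch excludes more of the failed attempt
  expect_gt(ep20$start, ep25$start)
  expect_true(ep25$start <= 61) # 2.5 s epoch reaches back into the attempt
})

test_that("overexertion averages above-threshold excess force", {
  tr <- fixture_trace(threshold = 60, delta = 5)
  ep <- find_success_epoch(tr, 2.5)
  plateau_only <- tibble::tibble(force = rep(65, 150))
  expect_equal(overexertion(plateau_only,
                            tibble::tibble(start = 1, end = 150),
                            threshold = 60), 5)
  at_thr <- tibble::tibble(force = rep(60, 150))
  expect_equal(overexertion(at_thr, tibble::tibble(start = 1, end = 150),
                            threshold = 60), 0)
  # noisy epoch equals the masked-mean oracle
  noisy <- withr::with_seed(6, tibble::tibble(
    force = 60 + rnorm(150, 2, 3), required_threshold = 60))
  epn <- tibble::tibble(start = 1, end = 150)
  keep <- noisy$force >= 60
  expect_equal(overexertion(noisy, epn), mean(noisy$force[keep] - 60))
  expect_equal(overexertion(noisy, epn, all_samples = TRUE),
               mean(noisy$force - 60))
  # translation covariance: shifting trace and threshold together is a no-op
  shifted <- dplyr::mutate(noisy, force = force + 10)
  expect_equal(overexertion(shifted, epn, threshold = 70),
               overexertion(noisy, epn))
  expect_error(overexertion(tibble::tibble(force = rep(1, 10)),
                            tibble::tibble(start = 1, end = 10),
                            threshold = 50), "above-threshold")
})

test_that("yank peak is the maximal forward difference times 60", {
  fs <- 60
  ramp <- tibble::tibble(force = 40 / fs * (0:149)) # slope 40 %MGF/s
  ep <- tibble::tibble(start = 1, end = 150)
  expect_equal(yank_peak(ramp, ep), 40, tolerance = 1e-9)
  expect_equal(yank_peak(tibble::tibble(force = rep(5, 150)), ep), 0)
  # piecewise slopes 20 then 50 -> 50
  pw <- tibble::tibble(force = c(20 / fs * (0:74),
                                 20 / fs * 74 + 50 / fs * (1:75)))
  expect_equal(yank_peak(pw, ep), 50, tolerance = 1e-9)
  # invariant to constant offsets
  expect_equal(yank_peak(dplyr::mutate(pw, force = force + 30), ep),
               yank_peak(pw, ep))
  expect_error(yank_peak(pw, tibble::tibble(start = 1, end = 1)), "2 samples")
})

test_that("cohort vigor extraction finds epochs only for completed trials", {
  co <- generate_cohort(cohort_spec(n_per_group = 2, seed = 12))
  forces <- generate_force_traces(co$trials, seed = 3)
  v <- compute_vigor(forces, epoch_len = 2.5)
  acc <- co$trials[co$trials$choice == 1, ]
  succ <- acc[acc$success == 1, c("subject_id", "trial_index")]
  got <- v[, c("subject_id", "trial_index")]
  expect_equal(dplyr::arrange(got, subject_id, trial_index),
               dplyr::arrange(succ, subject_id, trial_index),
               ignore_attr = TRUE)
  expect_true(all(is.finite(v$overexertion)))
  expect_true(all(is.finite(v$yank_peak)))
  expect_true(all(v$epoch_len == 2.5))
})
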