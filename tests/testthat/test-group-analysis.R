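test_that("inflexible responders are exactly the zero-variation subjects", {
  tr <- fixture_subject(seed = 2)
  expect_false(detect_inflexible(tr)$inflexible)
  up <- dplyr::mutate(tr, choice = 1L)
  expect_true(detect_inflexible(up)$inflexible)
  down <- dplyr::mutate(tr, choice = 0L)
  expect_true(detect_inflexible(down)$inflexible)
  almost <- dplyr::mutate(tr, choice = c(0L, rep(1L, 79)))
  expect_false(detect_inflexible(almost)$inflexible)
})

test_that("acceptance heatmaps tally cell proportions", {
  tr <- fixture_subject(seed = 3)
  tr$group <- "MAST_PLC"
  all_in <- dplyr::mutate(tr, choice = 1L)
  h <- acceptance_heatmap(all_in, by = "subject")
  expect_true(all(h$acceptance == 1))
  # deterministic agent accepting only SV > 0 (linear k = 1, huge beta):
  # cell (E, T) accepted iff T > E
  det <- simulate_choices(build_session(seed = 5), "linear", 1, 1e4, 0,
                          seed = 6)
  det$subject_id <- "d"
  hd <- acceptance_heatmap(det, by = "subject")
  off_diag <- hd$incentive_level != hd$effort_level # SV = 0 cells are coin flips
  expect_equal(hd$acceptance[off_diag],
               as.numeric(hd$incentive_level > hd$effort_level)[off_diag])
  # hand-tallied 32-trial fixture: two blocks, accepts exactly on block 1
  two <- build_session(n_blocks = 2, seed = 9)
  two$subject_id <- "s"
  two$choice <- as.integer(two$block == 1)
  ht <- acceptance_heatmap(two, by = "subject")
  expect_true(all(ht$acceptance == 0.5))
  expect_true(all(ht$n_trials == 2))
})

test_that("group heatmaps include the stress-minus-control difference", {
  co <- generate_cohort(cohort_spec(n_per_group = 4, seed = 10))
  h <- acceptance_heatmap(co$trials, by = "group")
  expect_equal(nrow(h), 16)
  expect_true(all(c("MAST_PLC", "MAST_EXP", "diff") %in% names(h)))
  expect_equal(h$diff, h$MAST_EXP - h$MAST_PLC)
})

test_that("quadrant summaries aggregate consistently to overall acceptance", {
  co <- generate_cohort(cohort_spec(n_per_group = 3, seed = 14))
  qs <- quadrant_summary(co$trials)
  expect_true(all(qs$n_trials == 20))
  per_subject <- dplyr::summarise(qs, q_mean = mean(acceptance),
                                  .by = subject_id)
  overall <- dplyr::summarise(co$trials, acc = mean(choice),
                              .by = subject_id)
  cmp <- dplyr::left_join(per_subject, overall, by = "subject_id")
  expect_equal(cmp$q_mean, cmp$acc, tolerance = 1e-12)
})

test_that("permutation test matches exhaustive enumeration for 3 vs 3", {
  d <- tibble::tibble(value = c(1.2, 0.8, 1.5, 2.1, 2.4, 1.9),
                      group = rep(c("MAST_PLC", "MAST_EXP"), each = 3))
  res <- permutation_group_test(d, "value", n_perm = 5000, seed = 1)
  expect_true(res$exact)
  obs <- mean(d$value[4:6]) - mean(d$value[1:3])
  expect_equal(res$observed, obs)
  # independent enumeration of all 20 splits
  idx <- utils::combn(6, 3)
  diffs <- apply(idx, 2, function(i) mean(d$value[i]) - mean(d$value[-i]))
  expect_equal(res$p_value, mean(abs(diffs) >= abs(obs) - 1e-12))
})

test_that("permutation test degenerate and null behavior", {
  same <- tibble::tibble(value = rep(1, 8),
                         group = rep(c("MAST_PLC", "MAST_EXP"), 4))
  expect_warning(res <- permutation_group_test(same, "value"), "zero-variance")
  expect_equal(res$observed, 0)
  expect_equal(res$p_value, 1)
  expect_error(permutation_group_test(
    tibble::tibble(value = 1:3, group = c("a", "a", "b")), "value"),
    "at least 2")
  expect_error(permutation_group_test(
    tibble::tibble(value = 1:4, group = rep("a", 4)), "value"), "two levels")
})

test_that("permutation p-values are super-uniform under the null", {
  hits <- withr::with_seed(77, {
    vapply(1:200, function(i) {
      d <- tibble::tibble(value = rnorm(16),
                          group = rep(c("MAST_PLC", "MAST_EXP"), each = 8))
      permutation_group_test(d, "value", n_perm = 1000, seed = i,
                             exact = FALSE)$p_value < 0.05
    }, logical(1))
  })
  expect_lte(mean(hits), 0.08)
})

test_that("failed-trial summaries count choice = 1, success = 0 events", {
  co <- generate_cohort(cohort_spec(n_per_group = 4,
                                    failure_prob_by_effort = rep(0, 4),
                                    seed = 19))
  zero <- failed_trial_summary(co$trials)
  expect_true(all(zero$n_failed == 0))
  tr <- co$trials
  idx <- which(tr$choice == 1)[1:3]
  tr$success[idx] <- 0L
  three <- failed_trial_summary(tr)
  expect_equal(sum(three$n_failed), 3)
  # oracle on a cohort with failures enabled
  co2 <- generate_cohort(cohort_spec(n_per_group = 5, seed = 20))
  s <- failed_trial_summary(co2$trials)
  oracle <- co2$trials |>
    dplyr::filter(choice == 1, success == 0) |>
    dplyr::count(group, name = "n_failed")
  cmp <- dplyr::left_join(s, oracle, by = "group")
  expect_equal(cmp$n_failed.x,
               ifelse(is.na(cmp$n_failed.y), 0L, cmp$n_failed.y))
  oracle4 <- co2$trials |>
    dplyr::filter(choice == 1, success == 0, effort_level == 4) |>
    nrow()
  expect_equal(sum(s$n_failed_max_effort), oracle4)
})
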