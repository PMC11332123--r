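test_that("evidence matrix is -AIC/2 with one cell per subject and family", {
  fits <- tidyr::expand_grid(subject_id = c("a", "b"),
                             family = model_families()) |>
    dplyr::mutate(stage = "map", aic = 26)
  ev <- evidence_from_fits(fits)
  expect_true(all(as.matrix(ev[, model_families()]) == -13))
  # equal AICs give identical row entries
  expect_equal(unname(unlist(ev[1, model_families()])), rep(-13, 4))
  expect_error(evidence_from_fits(fits[-1, ]), "exactly one")
})

test_that("BMS respects symmetry, dominance, and relabeling", {
  # identical evidence rows, K = 2: everything splits evenly and the null
  # (equal frequencies) model is favored over random effects
  lme <- matrix(0, 10, 2, dimnames = list(NULL, c("linear", "hyperbolic")))
  b <- run_bms(lme, n_samples = 2e5, seed = 1)
  expect_equal(unname(b$r_expected), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(unname(b$xp), c(0.5, 0.5), tolerance = 0.01)
  expect_gt(b$bor, 0.5)
  expect_equal(unname(b$pxp), c(0.5, 0.5), tolerance = 0.01)
  expect_equal(sum(b$alpha - 1), 10, tolerance = 1e-6) # alpha conservation

  # one family 10 log-units ahead for all of 40 subjects
  lme2 <- cbind(linear = rep(10, 40), hyperbolic = rep(0, 40))
  b2 <- run_bms(lme2, n_samples = 2e5, seed = 1)
  expect_gt(b2$xp[["linear"]], 0.999)
  expect_lt(b2$bor, 1e-6)
  expect_gt(b2$pxp[["linear"]], 0.999)
  expect_gt(b$bor, b2$bor) # exchangeable evidence raises omnibus risk

  # permuting family columns permutes every output identically
  lme3 <- withr::with_seed(4, matrix(rnorm(30, sd = 2), 10, 3,
                                     dimnames = list(NULL, c("a", "b", "c"))))
  b3 <- run_bms(lme3, n_samples = 2e5, seed = 9)
  perm <- c(3, 1, 2)
  b3p <- run_bms(lme3[, perm], n_samples = 2e5, seed = 9)
  expect_equal(unname(b3p$alpha), unname(b3$alpha[perm]), tolerance = 1e-8)
  expect_equal(unname(b3p$r_expected), unname(b3$r_expected[perm]),
               tolerance = 1e-8)
  expect_equal(unname(b3p$xp), unname(b3$xp[perm]), tolerance = 0.01)
  expect_equal(b3p$bor, b3$bor, tolerance = 1e-8)

  # adding a constant to one subject's whole row changes nothing
  lme4 <- lme3
  lme4[3, ] <- lme4[3, ] + 50
  b4 <- run_bms(lme4, n_samples = 2e5, seed = 9)
  expect_equal(b4$alpha, b3$alpha, tolerance = 1e-8)
  expect_equal(b4$bor, b3$bor, tolerance = 1e-8)

  expect_error(run_bms(matrix(c(1, NA), 1, 2)), "finite")
  expect_warning(run_bms(lme, n_samples = 10, seed = 1), "noisy")
})

test_that("BMS alpha matches an independent fixed-point iteration", {
  # 3 subjects, 2 families; naive reference implementation written directly
  # from the update equations
  lme <- matrix(c(1.2, -0.3,
                  0.4, 0.9,
                  -1.0, 0.5), 3, 2, byrow = TRUE,
                dimnames = list(NULL, c("m1", "m2")))
  alpha <- c(1, 1)
  for (iter in 1:5000) {
    u <- matrix(0, 3, 2)
    for (n in 1:3) {
      logu <- lme[n, ] + digamma(alpha) - digamma(sum(alpha))
      u[n, ] <- exp(logu - max(logu))
      u[n, ] <- u[n, ] / sum(u[n, ])
    }
    alpha_new <- 1 + colSums(u)
    if (max(abs(alpha_new - alpha)) < 1e-12) break
    alpha <- alpha_new
  }
  b <- run_bms(lme, n_samples = 1e5, seed = 1)
  expect_equal(unname(b$alpha), unname(alpha), tolerance = 1e-5)
  expect_equal(unname(b$r_expected), unname(alpha / sum(alpha)),
               tolerance = 1e-5)
  # pxp identity holds elementwise
  expect_equal(unname(b$pxp),
               unname(b$xp * (1 - b$bor) + b$bor / 2), tolerance = 1e-12)
})

test_that("xp Monte-Carlo error at 1e6 samples is below 0.005", {
  lme <- withr::with_seed(2, matrix(rnorm(20), 10, 2,
                                    dimnames = list(NULL, c("a", "b"))))
  x1 <- run_bms(lme, n_samples = 1e6, seed = 1)$xp
  x2 <- run_bms(lme, n_samples = 1e6, seed = 99)$xp
  expect_lt(max(abs(x1 - x2)), 0.005)
})

test_that("group model selection handles degenerate and tied cases", {
  fits <- tidyr::expand_grid(subject_id = "s1", family = model_families()) |>
    dplyr::mutate(stage = "map", group = "G",
                  aic = c(10, 20, 30, 40))
  sel <- select_group_model(fits, "G", n_samples = 5e4, seed = 1)
  expect_equal(sel$family, fits$family[which.min(fits$aic)])
  expect_equal(sel$bms$n_subjects, 1)
  expect_error(select_group_model(fits, "H"), "no fits")
})

test_that("predicted SV tables agree with elementwise evaluation", {
  fits <- tibble::tibble(subject_id = c("a", "b"), group = "G",
                         family = "linear", stage = "map",
                         k = c(0, 0.5), beta = 3, c = -1, aic = 10)
  sv <- predicted_sv(fits, "linear")
  expect_equal(nrow(sv), 32)
  # k = 0 subject: SV equals the incentive level everywhere
  a <- dplyr::filter(sv, subject_id == "a")
  expect_equal(a$sv, a$incentive_level)
  # k > 0: strictly decreasing in effort within each incentive row
  b <- dplyr::filter(sv, subject_id == "b") |>
    dplyr::arrange(incentive_level, effort_level)
  for (t in 1:4) {
    expect_true(all(diff(b$sv[b$incentive_level == t]) < 0))
  }
  # elementwise oracle
  expect_equal(b$sv, b$incentive_level - 0.5 * b$effort_level)
  expect_true(all(sv$quadrant %in% c("low_eff_low_inc", "low_eff_high_inc",
                                     "high_eff_low_inc", "high_eff_high_inc")))
  expect_error(predicted_sv(fits, "exponential"), "no fits")
})
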