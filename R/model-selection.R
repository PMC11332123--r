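# Random-effects Bayesian model selection over the four discounting
# families, using -AIC/2 as the approximate log model evidence, plus
# extraction of model-predicted subjective values from the winning family.

#' Approximate log-evidence matrix from a fit table
#'
#' Converts per-subject AICs into approximate log model evidences
#' (`-AIC / 2`), one row per subject, one column per family.
#'
#' @param fits Fit table (e.g. `fit_cohort()$fits`); must contain exactly one
#'   row per subject and family at the chosen stage.
#' @param stage Which stage's AICs to use (default `"map"`, falling back to
#'   `"mle"` when no MAP rows exist).
#'
#' @return A tibble with `subject_id`, optional `group`, and one numeric
#'   column per family.
#' @export
evidence_from_fits <- function(fits, stage = c("map", "mle")) {
  assert_cols(fits, c("subject_id", "family", "aic"), "`fits`")
  stage <- match.arg(stage)
  if ("stage" %in% names(fits)) {
    if (!stage %in% fits$stage) stage <- setdiff(c("map", "mle"), stage)
    fits <- dplyr::filter(fits, .data$stage == !!stage)
  }
  counts <- dplyr::count(fits, .data$subject_id, .data$family)
  if (any(counts$n != 1) ||
      !all(table(counts$subject_id) == length(unique(fits$family)))) {
    stop("`fits` must contain exactly one fit per subject and family",
         call. = FALSE)
  }
  keys <- intersect(c("subject_id", "group"), names(fits))
  fits |>
    dplyr::mutate(log_evidence = -.data$aic / 2) |>
    dplyr::select(dplyr::all_of(keys), "family", "log_evidence") |>
    tidyr::pivot_wider(names_from = "family", values_from = "log_evidence")
}

evidence_matrix <- function(evidence) {
  fam_cols <- intersect(model_families(), names(evidence))
  if (length(fam_cols) < 2) fam_cols <- names(evidence)[vapply(evidence, is.numeric, TRUE)]
  m <- as.matrix(evidence[, fam_cols])
  rownames(m) <- evidence$subject_id %||% NULL
  m
}

#' Random-effects Bayesian model selection
#'
#' Variational inference on a Dirichlet model of population model
#' frequencies: responsibilities `u_nk` proportional to
#' `exp(logE_nk + psi(alpha_k) - psi(sum alpha))` and Dirichlet updates
#' `alpha_k = alpha0 + sum_n u_nk`, iterated to convergence. Exceedance
#' probabilities (`xp`, the posterior probability that each family is the
#' most frequent) are estimated by Monte-Carlo argmax frequency over
#' Dirichlet samples. The Bayes omnibus risk (`bor`) compares the free energy
#' of the random-effects model with the null model in which all families are
#' equally frequent, and the protected exceedance probability is
#' `pxp = xp * (1 - bor) + bor / K`.
#'
#' @param evidence Evidence table from [evidence_from_fits()], or a numeric
#'   matrix (subjects x families) of log evidences.
#' @param alpha0 Dirichlet prior count per family (default 1).
#' @param n_samples Monte-Carlo samples for `xp` (default `1e6`; below 1000 a
#'   warning is issued).
#' @param seed Integer seed for the Monte-Carlo step.
#' @param tol Convergence tolerance on `max |delta alpha|` (default `1e-6`).
#' @param max_iter Maximum variational iterations (default 500).
#'
#' @return An object of class `bms_result`: a list with `alpha`,
#'   `r_expected`, `xp`, `bor`, `pxp` (named per family), `families`,
#'   `n_subjects`, `n_samples`, `seed`, and the free energies `F_rfx`,
#'   `F_null`.
#' @export
run_bms <- function(evidence, alpha0 = 1, n_samples = 1e6, seed = 1,
                    tol = 1e-6, max_iter = 500) {
  lme <- if (is.matrix(evidence)) evidence else evidence_matrix(evidence)
  if (!all(is.finite(lme))) stop("log evidences must be finite", call. = FALSE)
  n <- nrow(lme)
  K <- ncol(lme)
  if (n < 1 || K < 2) stop("need >= 1 subject and >= 2 families", call. = FALSE)
  if (n_samples < 1000) warning("`n_samples` < 1000: xp will be noisy")

  alpha <- rep(alpha0, K)
  u <- matrix(1 / K, n, K)
  for (it in seq_len(max_iter)) {
    elog_r <- digamma(alpha) - digamma(sum(alpha))
    lu <- sweep(lme, 2, elog_r, `+`)
    lu <- lu - apply(lu, 1, max)
    u <- exp(lu) / rowSums(exp(lu))
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }

  # free energy (ELBO) of the random-effects model at the converged posterior
  elog_r <- digamma(alpha) - digamma(sum(alpha))
  u_safe <- pmax(u, 1e-300)
  kl_dir <- lgamma(sum(alpha)) - sum(lgamma(alpha)) -
    lgamma(K * alpha0) + K * lgamma(alpha0) +
    sum((alpha - alpha0) * (digamma(alpha) - digamma(sum(alpha))))
  f_rfx <- sum(u * lme) + sum(u %*% elog_r) - sum(u * log(u_safe)) - kl_dir
  # null model: every subject's data averaged over an equal-frequency prior
  f_null <- sum(apply(lme, 1, logsumexp) - log(K))
  bor <- 1 / (1 + exp(f_rfx - f_null))

  r_expected <- alpha / sum(alpha)
  xp <- withr::with_seed(as.integer(seed) %% 2147483647L, {
    g <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                n_samples, K)
    tabulate(max.col(g, ties.method = "first"), K) / n_samples
  })
  pxp <- xp * (1 - bor) + bor / K

  fam <- colnames(lme) %||% paste0("family", seq_len(K))
  structure(
    list(alpha = stats::setNames(alpha, fam),
         r_expected = stats::setNames(r_expected, fam),
         xp = stats::setNames(xp, fam),
         bor = bor,
         pxp = stats::setNames(pxp, fam),
         families = fam, n_subjects = n, n_samples = n_samples, seed = seed,
         F_rfx = f_rfx, F_null = f_null),
    class = "bms_result"
  )
}

#' @export
print.bms_result <- function(x, ...) {
  cat(sprintf("Random-effects BMS over %d famil%s, %d subjects\n",
              length(x$families), ifelse(length(x$families) == 1, "y", "ies"),
              x$n_subjects))
  tab <- data.frame(alpha = round(x$alpha, 3),
                    r_expected = round(x$r_expected, 3),
                    xp = round(x$xp, 4), pxp = round(x$pxp, 4))
  print(tab)
  cat(sprintf("Bayes omnibus risk: %.4f\n", x$bor))
  invisible(x)
}

#' Select the best-fitting family for one group
#'
#' Runs [run_bms()] on the evidence of a single group's subjects; the winner
#' is the family with the highest exceedance probability (ties broken
#' lexicographically with a warning).
#'
#' @param fits Fit table covering the group's subjects (all families).
#' @param group Group label to select on (uses the `group` column).
#' @param stage Stage whose AICs enter the evidence (default `"map"`).
#' @inheritParams run_bms
#'
#' @return A list with `family` (the winner) and `bms` (the `bms_result`).
#' @export
select_group_model <- function(fits, group, stage = "map", alpha0 = 1,
                               n_samples = 1e6, seed = 1) {
  assert_cols(fits, "group", "`fits`")
  sub <- dplyr::filter(fits, .data$group == !!group)
  if (nrow(sub) == 0) stop(sprintf("no fits for group '%s'", group),
                           call. = FALSE)
  ev <- evidence_from_fits(sub, stage = stage)
  bms <- run_bms(ev, alpha0 = alpha0, n_samples = n_samples, seed = seed)
  top <- which(bms$xp == max(bms$xp))
  if (length(top) > 1) {
    warning("tie in exceedance probability; reporting lexicographic winner")
    top <- top[order(bms$families[top])][1]
  }
  list(family = bms$families[top], bms = bms)
}

#' Model-predicted subjective values over the offer grid
#'
#' Evaluates each subject's fitted discounting curve (their own `k` under the
#' given family, normally the group's BMS winner) on all 16 offers, tagging
#' each with its quadrant.
#'
#' @param fits Fit table containing the family's fits for every subject in
#'   scope (stage `"map"` rows are used when present).
#' @param family Family whose fits to evaluate.
#' @param paradigm Offer grid to evaluate on (default `"thunderstorm"`).
#'
#' @return Tibble: `subject_id`, `group`, `family`, offer columns, `quadrant`
#'   and `sv`.
#' @export
predicted_sv <- function(fits, family, paradigm = "thunderstorm") {
  check_family(family)
  rows <- dplyr::filter(fits, .data$family == !!family)
  if ("stage" %in% names(rows) && "map" %in% rows$stage) {
    rows <- dplyr::filter(rows, .data$stage == "map")
  }
  if (nrow(rows) == 0) stop("no fits available for this family", call. = FALSE)
  fam <- family
  grid <- classify_quadrant(build_offer_grid(paradigm))
  tidyr::crossing(rows[, intersect(c("subject_id", "group", "family", "k"),
                                   names(rows))], grid) |>
    dplyr::mutate(sv = subjective_value(fam, .data$incentive_level,
                                        .data$effort_level, .data$k)) |>
    dplyr::select(-"k")
}
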