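# Synthetic cohort generator: subjects with group-dependent discounting
# families and parameters, simulated sessions with effort failures and
# outcomes, optional inflexible responders, and trial-linked force traces.

#' Default generating parameter distributions per family
#'
#' Means and SDs of truncated-normal distributions for (`k`, `beta`, `c`)
#' used when simulating agents of a given family. The `k` locations are
#' calibrated so that the four families' effort-cost curves span a comparable
#' range over effort levels 1-4 (placing indifference points inside the offer
#' grid), and so that the linear and hyperbolic cost curves nearly coincide at
#' high effort — which keeps baseline group differences small and lets the
#' configured quadrant effect carry the group contrast.
#'
#' @param family One of [model_families()].
#' @return A list with elements `k`, `beta`, `c`, each `c(mean, sd)`, plus
#'   `k_bounds` for truncation.
#' @export
default_family_params <- function(family) {
  check_family(family)
  k <- switch(family,
    linear      = c(0.60, 0.20),
    parabolic   = c(0.15, 0.04),
    hyperbolic  = c(0.18, 0.05),
    exponential = c(0.50, 0.08)
  )
  list(
    k = k,
    beta = c(3, 1.5),
    c = c(-1.5, 0.75),
    k_bounds = if (family == "hyperbolic") c(0, 0.2499) else c(0, 5)
  )
}

#' Specify a synthetic cohort
#'
#' Bundles every setting of the synthetic-data generator: group sizes, the
#' discounting family generating each group's choices (control group linear,
#' stress group hyperbolic by default, mirroring the group-level model
#' structure the paradigms were designed to detect), generating parameter
#' distributions, effort-failure probabilities, the rate of "inflexible"
#' all-accept/all-decline responders, and the subjective-value bonus
#' injected for the stress group on high-effort/low-incentive offers.
#'
#' @param n_per_group Subjects per group (default 40, the study's group size).
#' @param paradigm `"thunderstorm"` or `"highstriker"`.
#' @param group_family Named character vector mapping each group to a family.
#' @param param_distributions Named list (per group) of lists with elements
#'   `k`, `beta`, `c` (each `c(mean, sd)`); defaults come from
#'   [default_family_params()] of the group's family.
#' @param failure_prob_by_effort Probability that an accepted trial fails, per
#'   effort level 1-4 (default `c(0, 0, 0, 0.05)`).
#' @param inflexible_rate Probability that a subject is an inflexible
#'   responder (all-accept or all-decline, equiprobable).
#' @param quadrant_sv_bonus Named numeric per group: subjective-value bonus on
#'   high-effort/low-incentive offers (default +2 SV units for `MAST_EXP`),
#'   injecting the selective stress effect on uneconomical offers.
#' @param n_blocks Blocks per session (default 5; 16 offers per block).
#' @param seed Root integer seed.
#'
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 40,
                        paradigm = "thunderstorm",
                        group_family = c(MAST_PLC = "linear",
                                         MAST_EXP = "hyperbolic"),
                        param_distributions = NULL,
                        failure_prob_by_effort = c(0, 0, 0, 0.05),
                        inflexible_rate = 0.05,
                        quadrant_sv_bonus = c(MAST_PLC = 0, MAST_EXP = 2),
                        n_blocks = 5,
                        seed = 1) {
  check_paradigm(paradigm)
  stopifnot(n_per_group >= 1,
            length(failure_prob_by_effort) == 4,
            all(failure_prob_by_effort >= 0 & failure_prob_by_effort <= 1),
            inflexible_rate >= 0, inflexible_rate <= 1)
  groups <- names(group_family)
  if (is.null(groups) || any(!nzchar(groups))) {
    stop("`group_family` must be a named character vector", call. = FALSE)
  }
  for (f in group_family) check_family(f)
  if (is.null(param_distributions)) {
    param_distributions <- lapply(group_family, function(f) {
      default_family_params(f)[c("k", "beta", "c")]
    })
  }
  structure(
    list(
      n_per_group = as.integer(n_per_group),
      paradigm = paradigm,
      group_family = group_family,
      param_distributions = param_distributions,
      failure_prob_by_effort = failure_prob_by_effort,
      inflexible_rate = inflexible_rate,
      quadrant_sv_bonus = quadrant_sv_bonus,
      n_blocks = as.integer(n_blocks),
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

k_bounds_for <- function(family) {
  if (family == "hyperbolic") c(0, 0.2499) else c(0, 5)
}

draw_agent_params <- function(group, spec) {
  family <- spec$group_family[[group]]
  d <- spec$param_distributions[[group]]
  kb <- k_bounds_for(family)
  tibble::tibble(
    family = family,
    k = rtruncnorm(1, d$k[1], d$k[2], kb[1], kb[2]),
    beta = rtruncnorm(1, d$beta[1], d$beta[2], 0, 30),
    c = stats::rnorm(1, d$c[1], d$c[2])
  )
}

# Outcome sampling given choices. Thunderstorm: neutralized threats yield
# "none"; declined or failed trials draw a shock with the offer probability.
# High striker: successful trials earn the reward; failures earn nothing;
# declined trials have no outcome.
simulate_outcomes <- function(trials, failure_prob_by_effort, seed) {
  n <- nrow(trials)
  withr::with_seed(as.integer(seed) %% 2147483647L, {
    fail_p <- failure_prob_by_effort[trials$effort_level]
    success <- ifelse(trials$choice == 1L,
                      as.integer(stats::runif(n) >= fail_p), NA_integer_)
    u <- stats::runif(n)
    if (trials$paradigm[1] == "thunderstorm") {
      at_risk <- trials$choice == 0L | (!is.na(success) & success == 0L)
      outcome <- ifelse(at_risk,
                        ifelse(u < trials$incentive_value / 100,
                               "shock_delivered", "no_shock"),
                        "none")
    } else {
      outcome <- dplyr::case_when(
        trials$choice == 1L & success == 1L ~ "reward_earned",
        trials$choice == 1L & success == 0L ~ "no_reward",
        .default = "none"
      )
    }
    # direct assignment: mutate()'s data mask would resolve `success` to an
    # existing column when re-simulating already-annotated trials
    trials$success <- success
    trials$outcome <- outcome
    trials
  })
}

#' Generate a complete synthetic cohort
#'
#' Draws `n_per_group` agents per group from the spec's parameter
#' distributions, simulates an 80-trial session per agent (choices from the
#' group's discounting family, effort failures by effort level, outcomes per
#' paradigm rules), and overwrites a random subset of subjects as inflexible
#' responders. Choice, outcome, and inflexibility randomness use separate
#' substreams of the root seed, so e.g. outcome settings never perturb
#' choices.
#'
#' @param spec A [cohort_spec()].
#'
#' @return A list with `subjects` (one row per subject incl. the true
#'   generating parameters) and `trials` (one row per trial).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_per_group = 4, seed = 42))
#' dplyr::count(cohort$trials, subject_id)
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- names(spec$group_family)
  ids <- unlist(lapply(groups, function(g) {
    sprintf("%s_%02d", g, seq_len(spec$n_per_group))
  }))
  grp <- rep(groups, each = spec$n_per_group)

  subjects <- withr::with_seed(derive_seed(spec$seed, "agents"), {
    purrr::map2_dfr(ids, grp, function(id, g) {
      dplyr::bind_cols(tibble::tibble(subject_id = id, group = g),
                       draw_agent_params(g, spec))
    })
  })

  # inflexible-responder assignment from its own stream
  subjects <- withr::with_seed(derive_seed(spec$seed, "inflexible"), {
    infl <- stats::runif(nrow(subjects)) < spec$inflexible_rate
    mode <- ifelse(stats::runif(nrow(subjects)) < 0.5, "all_accept",
                   "all_decline")
    dplyr::mutate(subjects,
                  inflexible_mode = ifelse(infl, mode, NA_character_))
  })

  trials <- purrr::pmap_dfr(
    list(subjects$subject_id, subjects$group, seq_len(nrow(subjects))),
    function(id, g, i) {
      row <- subjects[i, ]
      session <- build_session(spec$paradigm, spec$n_blocks,
                               seed = derive_seed(spec$seed, "session", i))
      tr <- simulate_choices(session, row$family, row$k, row$beta, row$c,
                             seed = derive_seed(spec$seed, "choice", i),
                             quadrant_sv_bonus =
                               spec$quadrant_sv_bonus[[g]] %||% 0)
      if (!is.na(row$inflexible_mode)) {
        tr$choice <- if (row$inflexible_mode == "all_accept") 1L else 0L
      }
      tr <- simulate_outcomes(tr, spec$failure_prob_by_effort,
                              seed = derive_seed(spec$seed, "outcome", i))
      dplyr::bind_cols(tibble::tibble(subject_id = id, group = g), tr)
    }
  )
  list(subjects = subjects, trials = dplyr::select(trials, -"p_accept"))
}

#' Force an existing subject's trials to an inflexible response pattern
#'
#' Sets every choice to accept (or decline) and resamples success/outcome
#' accordingly; used both by the generator and to construct exclusion-rule
#' test cases.
#'
#' @param trials One subject's trials.
#' @param mode `"all_accept"` or `"all_decline"`.
#' @param failure_prob_by_effort As in [cohort_spec()].
#' @param seed Integer seed for outcome resampling.
#'
#' @return The modified trials table.
#' @export
inject_inflexible <- function(trials, mode = c("all_accept", "all_decline"),
                              failure_prob_by_effort = c(0, 0, 0, 0.05),
                              seed = 1) {
  mode <- match.arg(mode)
  if (length(unique(trials$subject_id %||% "s")) > 1) {
    stop("`trials` must belong to a single subject", call. = FALSE)
  }
  trials$choice <- if (mode == "all_accept") 1L else 0L
  simulate_outcomes(trials, failure_prob_by_effort, seed)
}
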