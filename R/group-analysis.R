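# Descriptive tables, exclusion rules, and permutation-based group
# contrasts on choices, predicted subjective values, and vigor.

#' Flag inflexible responders
#'
#' A subject is an inflexible responder when their choices show no variation
#' across all offers (all-accept or all-decline); such subjects are flagged
#' and analyses are typically reported both with and without them.
#'
#' @param trials Trial table with `subject_id` and `choice`.
#' @return Tibble: `subject_id`, `inflexible` (logical), `n_trials`.
#' @export
detect_inflexible <- function(trials) {
  assert_cols(trials, c("subject_id", "choice"), "`trials`")
  trials |>
    dplyr::summarise(
      inflexible = dplyr::n_distinct(.data$choice) < 2,
      n_trials = dplyr::n(),
      .by = "subject_id"
    )
}

#' Acceptance heatmap over the 16 offers
#'
#' Proportion of accepted offers per (effort level, incentive level) cell.
#' With `by = "group"` the cell value is the mean of subject-level
#' proportions and a stress-minus-control difference column is added; with
#' `by = "subject"` one long row per subject and cell is returned.
#'
#' @param trials Trial table.
#' @param by `"group"` (default) or `"subject"`.
#' @return A tibble; for `by = "group"` columns `effort_level`,
#'   `incentive_level`, one column per group, and `diff`
#'   (`MAST_EXP - MAST_PLC`) when both study groups are present.
#' @export
acceptance_heatmap <- function(trials, by = c("group", "subject")) {
  by <- match.arg(by)
  assert_cols(trials, c("subject_id", "effort_level", "incentive_level",
                        "choice"), "`trials`")
  per_subject <- trials |>
    dplyr::summarise(
      acceptance = mean(.data$choice),
      n_trials = dplyr::n(),
      .by = dplyr::all_of(intersect(
        c("subject_id", "group", "effort_level", "incentive_level"),
        names(trials)
      ))
    )
  if (by == "subject") return(per_subject)
  assert_cols(trials, "group", "`trials` (for by = \"group\")")
  wide <- per_subject |>
    dplyr::summarise(acceptance = mean(.data$acceptance),
                     .by = c("group", "effort_level", "incentive_level")) |>
    tidyr::pivot_wider(names_from = "group", values_from = "acceptance") |>
    dplyr::arrange(.data$incentive_level, .data$effort_level)
  if (all(study_groups() %in% names(wide))) {
    wide$diff <- wide$MAST_EXP - wide$MAST_PLC
  }
  wide
}

#' Per-subject quadrant acceptance summary
#'
#' Acceptance proportions within the four low/high effort-by-incentive
#' quadrants (20 trials per quadrant in a complete 80-trial session).
#'
#' @param trials Trial table.
#' @return Tibble: `subject_id`, optional `group`, `quadrant`, `acceptance`,
#'   `n_trials`.
#' @export
quadrant_summary <- function(trials) {
  assert_cols(trials, c("subject_id", "effort_level", "incentive_level",
                        "choice"), "`trials`")
  tr <- classify_quadrant(trials)
  keys <- intersect(c("subject_id", "group", "quadrant"), names(tr))
  dplyr::summarise(tr,
                   acceptance = mean(.data$choice),
                   n_trials = dplyr::n(),
                   .by = dplyr::all_of(keys))
}

#' Permutation test for a between-group difference in subject-level values
#'
#' Tests `mean(MAST_EXP) - mean(MAST_PLC)` (more generally, second group
#' minus first) of one scalar per subject against the label-permutation null.
#' With `exact = TRUE` (or automatically when the number of distinct splits
#' is at most `n_perm`) every split is enumerated and the p-value is the
#' exact tail proportion; otherwise `n_perm` random permutations are drawn
#' and the `+1`-corrected two-sided Monte-Carlo p-value is returned.
#'
#' @param data Data frame with one row per subject.
#' @param value Name of the numeric column to compare.
#' @param group Name of the two-level group column (default `"group"`; the
#'   reference level is the first sorted level unless the columns holds
#'   `MAST_PLC`/`MAST_EXP`, in which case `MAST_PLC` is the reference).
#' @param n_perm Number of random permutations (default 5000, minimum 1000).
#' @param seed Integer seed.
#' @param exact `TRUE`, `FALSE`, or `"auto"` (default).
#'
#' @return One-row tibble: `observed`, `p_value`, `n_perm`, `exact`, `seed`.
#' @export
permutation_group_test <- function(data, value = "value", group = "group",
                                   n_perm = 5000, seed = 1, exact = "auto") {
  assert_cols(data, c(value, group), "`data`")
  x <- data[[value]]
  g <- as.character(data[[group]])
  levels <- sort(unique(g))
  if (length(levels) != 2) stop("`group` must have exactly two levels",
                                call. = FALSE)
  if (all(study_groups() %in% levels)) levels <- study_groups()
  if (min(table(g)) < 2) stop("each group needs at least 2 subjects",
                              call. = FALSE)
  if (n_perm < 1000) stop("`n_perm` must be >= 1000", call. = FALSE)
  obs <- mean(x[g == levels[2]]) - mean(x[g == levels[1]])
  if (stats::var(x) == 0) {
    warning("zero-variance values; p = 1")
    return(tibble::tibble(observed = obs, p_value = 1, n_perm = 0L,
                          exact = TRUE, seed = seed))
  }
  n <- length(x)
  n2 <- sum(g == levels[2])
  n_splits <- choose(n, n2)
  use_exact <- isTRUE(exact) || (identical(exact, "auto") && n_splits <= n_perm)
  if (use_exact) {
    idx2 <- utils::combn(n, n2)
    diffs <- apply(idx2, 2, function(id) mean(x[id]) - mean(x[-id]))
    p <- mean(abs(diffs) >= abs(obs) - 1e-12)
    return(tibble::tibble(observed = obs, p_value = p,
                          n_perm = as.integer(n_splits), exact = TRUE,
                          seed = seed))
  }
  diffs <- withr::with_seed(as.integer(seed) %% 2147483647L, {
    vapply(seq_len(n_perm), function(i) {
      id <- sample.int(n, n2)
      mean(x[id]) - mean(x[-id])
    }, numeric(1))
  })
  p <- (1 + sum(abs(diffs) >= abs(obs) - 1e-12)) / (1 + n_perm)
  tibble::tibble(observed = obs, p_value = p, n_perm = as.integer(n_perm),
                 exact = FALSE, seed = seed)
}

#' Failed-trial summary per group
#'
#' Counts accepted trials that failed (choice = 1, success = 0), overall and
#' at the maximum effort level.
#'
#' @param trials Trial table with `group`, `choice`, `success`,
#'   `effort_level`.
#' @return Tibble: `group`, `n_failed`, `n_failed_max_effort`, `n_accepted`.
#' @export
failed_trial_summary <- function(trials) {
  assert_cols(trials, c("group", "choice", "success", "effort_level"),
              "`trials`")
  trials |>
    dplyr::summarise(
      n_failed = sum(.data$choice == 1 & .data$success == 0, na.rm = TRUE),
      n_failed_max_effort = sum(.data$choice == 1 & .data$success == 0 &
                                  .data$effort_level == 4, na.rm = TRUE),
      n_accepted = sum(.data$choice == 1),
      .by = "group"
    )
}
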