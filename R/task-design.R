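# Task design: offer grids, session construction, quadrant classification,
# and objective value for the two forced-choice paradigms.

#' Paradigm and group labels
#'
#' `paradigms()` returns the two supported forced-choice paradigms:
#' `"thunderstorm"` (physical effort traded against a probability of an
#' aversive electric shock) and `"highstriker"` (physical effort traded
#' against a small monetary reward). `study_groups()` returns the two
#' between-subject conditions: a no-stress control group (`"MAST_PLC"`) and an
#' acute-stress group (`"MAST_EXP"`).
#'
#' @return A character vector.
#' @export
paradigms <- function() c("thunderstorm", "highstriker")

#' @rdname paradigms
#' @export
study_groups <- function() c("MAST_PLC", "MAST_EXP")

incentive_values_for <- function(paradigm) {
  switch(paradigm,
    thunderstorm = c(20, 30, 40, 50), # % threat-of-shock
    highstriker  = c(1, 5, 10, 15),   # Eurocents
    stop(sprintf("unknown paradigm: '%s'", paradigm), call. = FALSE)
  )
}

check_paradigm <- function(paradigm) {
  if (!is.character(paradigm) || length(paradigm) != 1L ||
      !paradigm %in% paradigms()) {
    stop("`paradigm` must be one of: ", paste(paradigms(), collapse = ", "),
         call. = FALSE)
  }
  paradigm
}

#' Build the full 4x4 offer grid of a paradigm
#'
#' Each paradigm crosses four effort levels (40/60/80/100% of the
#' participant's maximum sustainable grip force, MGF) with four incentive
#' levels: shock probabilities 20/30/40/50% in the thunderstorm paradigm, or
#' rewards of 1/5/10/15 Eurocents in the high-striker paradigm. The crossing
#' yields the 16 unique offers presented in every trial block.
#'
#' @param paradigm `"thunderstorm"` or `"highstriker"`.
#'
#' @return A tibble with 16 rows and columns `paradigm`, `effort_level` (1-4),
#'   `effort_pct_mgf` (40/60/80/100), `incentive_level` (1-4) and
#'   `incentive_value` (shock % or Eurocents).
#' @export
#' @examples
#' build_offer_grid("thunderstorm")
build_offer_grid <- function(paradigm = "thunderstorm") {
  check_paradigm(paradigm)
  vals <- incentive_values_for(paradigm)
  tidyr::expand_grid(effort_level = 1:4, incentive_level = 1:4) |>
    dplyr::mutate(
      paradigm = paradigm,
      effort_pct_mgf = 20 * (.data$effort_level + 1),
      incentive_value = vals[.data$incentive_level]
    ) |>
    dplyr::select("paradigm", "effort_level", "effort_pct_mgf",
                  "incentive_level", "incentive_value")
}

#' Build a randomized session (trial template)
#'
#' A session consists of `n_blocks` blocks; by default each block is an
#' independent random permutation of the 16-offer grid, so the default
#' five-block session has 80 trials with every offer appearing exactly five
#' times. Set `shuffle = "session"` for a single unconstrained shuffle of all
#' `16 * n_blocks` trials instead.
#'
#' @param paradigm `"thunderstorm"` or `"highstriker"`.
#' @param n_blocks Number of blocks (default 5).
#' @param seed Integer seed; identical seeds reproduce identical orders.
#' @param shuffle `"block"` (each block a permutation of the grid; default) or
#'   `"session"` (one shuffle of all trials).
#'
#' @return A tibble of `16 * n_blocks` rows with `block`, `trial_index` and
#'   the offer columns of [build_offer_grid()].
#' @export
build_session <- function(paradigm = "thunderstorm", n_blocks = 5, seed = 1,
                          shuffle = c("block", "session")) {
  check_paradigm(paradigm)
  shuffle <- match.arg(shuffle)
  if (!is.numeric(n_blocks) || length(n_blocks) != 1L || n_blocks < 1) {
    stop("`n_blocks` must be a single integer >= 1", call. = FALSE)
  }
  n_blocks <- as.integer(n_blocks)
  grid <- build_offer_grid(paradigm)
  ord <- withr::with_seed(as.integer(seed) %% 2147483647L, {
    if (shuffle == "block") {
      unlist(lapply(seq_len(n_blocks), function(b) sample.int(16L)))
    } else {
      sample(rep(seq_len(16L), n_blocks))
    }
  })
  session <- grid[ord, ]
  session$block <- rep(seq_len(n_blocks), each = 16L)
  session$trial_index <- seq_len(16L * n_blocks)
  dplyr::select(session, "paradigm", "block", "trial_index",
                dplyr::everything())
}

#' Classify an offer into a low/high effort-by-incentive quadrant
#'
#' Offers are median-split on both axes: levels 1-2 are "low", levels 3-4
#' "high". The four resulting quadrants (each holding 4 of the 16 offers) are
#' the cells used for post-hoc group contrasts; the high-effort/low-incentive
#' quadrant contains the offers with the most negative objective value.
#'
#' @param effort_level Integer vector of effort levels (1-4), or a data frame
#'   holding `effort_level` and `incentive_level` columns.
#' @param incentive_level Integer vector of incentive levels (1-4); ignored
#'   when `effort_level` is a data frame.
#'
#' @return A character vector (or, for data-frame input, the data frame with a
#'   `quadrant` column added) with values `low_eff_low_inc`,
#'   `low_eff_high_inc`, `high_eff_low_inc`, `high_eff_high_inc`.
#' @export
#' @examples
#' classify_quadrant(4, 1)
#' build_offer_grid() |> classify_quadrant()
classify_quadrant <- function(effort_level, incentive_level = NULL) {
  if (is.data.frame(effort_level)) {
    data <- assert_cols(effort_level, c("effort_level", "incentive_level"))
    data$quadrant <- classify_quadrant(data$effort_level, data$incentive_level)
    return(data)
  }
  stopifnot(all(effort_level %in% 1:4), all(incentive_level %in% 1:4))
  eff <- ifelse(effort_level >= 3, "high_eff", "low_eff")
  inc <- ifelse(incentive_level >= 3, "high_inc", "low_inc")
  paste(eff, inc, sep = "_")
}

#' Objective value of an offer
#'
#' Assuming 1:1 correspondence between effort and incentive levels, the
#' objective value of exerting effort is `incentive_level - effort_level`;
#' offers with negative values are "uneconomical" (effort outweighs the
#' incentive on a common level scale).
#'
#' @inheritParams classify_quadrant
#' @return A numeric vector (or the input data frame with an
#'   `objective_value` column).
#' @export
objective_value <- function(effort_level, incentive_level = NULL) {
  if (is.data.frame(effort_level)) {
    data <- assert_cols(effort_level, c("effort_level", "incentive_level"))
    data$objective_value <- data$incentive_level - data$effort_level
    return(data)
  }
  stopifnot(all(effort_level %in% 1:4), all(incentive_level %in% 1:4))
  incentive_level - effort_level
}
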