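# Effort-discounting subjective-value families, softmax choice rule,
# Bernoulli likelihood and choice simulation.

#' The four effort-discounting model families
#'
#' Each family maps an offer (incentive level `T`, effort level `E`, both on
#' the rescaled 1-4 scale) and a subject-level discounting coefficient `k` to
#' a subjective value (SV) of exerting effort:
#' linear `T - k*E`, parabolic `T - k*E^2`, hyperbolic `T - 1/(1 - k*E)`
#' (requires `k*E < 1`), exponential `T - exp(k*E)`.
#'
#' @return Character vector of family names.
#' @export
model_families <- function() c("linear", "parabolic", "hyperbolic", "exponential")

check_family <- function(family) {
  if (!is.character(family) || length(family) != 1L ||
      !family %in% model_families()) {
    stop("`family` must be one of: ", paste(model_families(), collapse = ", "),
         call. = FALSE)
  }
  family
}

# effort-cost component of SV and its derivative in k (both vectorized in E)
effort_cost <- function(family, effort_level, k) {
  switch(family,
    linear      = k * effort_level,
    parabolic   = k * effort_level^2,
    hyperbolic  = {
      if (any(k * effort_level >= 1)) {
        stop("hyperbolic family requires k * effort_level < 1", call. = FALSE)
      }
      1 / (1 - k * effort_level)
    },
    exponential = exp(k * effort_level)
  )
}

effort_cost_dk <- function(family, effort_level, k) {
  switch(family,
    linear      = effort_level,
    parabolic   = effort_level^2,
    hyperbolic  = effort_level / (1 - k * effort_level)^2,
    exponential = effort_level * exp(k * effort_level)
  )
}

#' Subjective value of exerting effort
#'
#' @param family One of [model_families()].
#' @param incentive_level Incentive (threat-of-shock or reward) level, 1-4.
#' @param effort_level Effort level, 1-4.
#' @param k Discounting coefficient; for the hyperbolic family `k * E` must be
#'   below 1 (so `k < 0.25` over the full grid).
#'
#' @return Numeric vector of subjective values.
#' @export
#' @examples
#' subjective_value("hyperbolic", incentive_level = 3, effort_level = 4, k = 0)
subjective_value <- function(family, incentive_level, effort_level, k) {
  check_family(family)
  stopifnot(all(incentive_level %in% 1:4), all(effort_level %in% 1:4))
  incentive_level - effort_cost(family, effort_level, k)
}

#' Softmax acceptance probability
#'
#' Maps subjective value to the probability of accepting the effort option via
#' a logistic (softmax) rule `p = 1 / (1 + exp(-beta * (sv + c_bias)))`, so
#' higher subjective value of exerting effort raises acceptance. `beta` is the
#' choice sensitivity (inverse temperature) and `c_bias` a general bias toward
#' accepting effort, expressed in SV units.
#'
#' @param sv Subjective value(s).
#' @param beta Choice sensitivity, `beta >= 0`.
#' @param c_bias Choice bias (SV units).
#'
#' @return Probabilities in the open interval (0, 1).
#' @export
#' @examples
#' accept_probability(sv = 1, beta = 1, c_bias = 0) # 1 / (1 + exp(-1))
accept_probability <- function(sv, beta, c_bias = 0) {
  if (any(beta < 0)) stop("`beta` must be >= 0", call. = FALSE)
  # clamp to the open interval so downstream logs stay finite
  pmin(pmax(sigmoid(beta * (sv + c_bias)), 1e-12), 1 - 1e-12)
}

#' Negative log-likelihood of observed choices
#'
#' Bernoulli negative log-likelihood of binary accept/decline choices under a
#' discounting family and softmax rule. Probabilities are floored at `eps`
#' (and capped at `1 - eps`) so the result is always finite.
#'
#' @param trials Data frame with columns `incentive_level`, `effort_level` and
#'   `choice` (1 = accept effort, 0 = decline).
#' @param family One of [model_families()].
#' @param k,beta,c_bias Model parameters (see [subjective_value()] and
#'   [accept_probability()]).
#' @param eps Floor applied to `p` and `1 - p` (default `1e-12`).
#'
#' @return A single non-negative number.
#' @export
choice_nll <- function(trials, family, k, beta, c_bias, eps = 1e-12) {
  assert_cols(trials, c("incentive_level", "effort_level", "choice"),
              "`trials`")
  if (nrow(trials) == 0L) stop("`trials` must contain at least one trial",
                               call. = FALSE)
  sv <- subjective_value(family, trials$incentive_level, trials$effort_level, k)
  p <- pmin(pmax(accept_probability(sv, beta, c_bias), eps), 1 - eps)
  -sum(trials$choice * log(p) + (1 - trials$choice) * log(1 - p))
}

# gradient of choice_nll in (k, beta, c_bias); clamping ignored (measure-zero)
choice_nll_grad <- function(trials, family, k, beta, c_bias) {
  sv <- subjective_value(family, trials$incentive_level, trials$effort_level, k)
  z <- beta * (sv + c_bias)
  p <- sigmoid(z)
  resid <- p - trials$choice        # d nll / d z
  dsv_dk <- -effort_cost_dk(family, trials$effort_level, k)
  c(
    k    = sum(resid * beta * dsv_dk),
    beta = sum(resid * (sv + c_bias)),
    c    = sum(resid * beta)
  )
}

#' Simulate choices for a trial template
#'
#' Draws one Bernoulli choice per trial from the discounting + softmax model.
#'
#' @param session Trial template, e.g. from [build_session()].
#' @inheritParams choice_nll
#' @param seed Integer seed (choices are reproducible given the seed).
#' @param quadrant_sv_bonus Optional subjective-value bonus added on
#'   high-effort/low-incentive offers before the softmax (used by the
#'   synthetic-cohort generator to inject a selective, graded group effect:
#'   the bonus expresses most strongly on the least uneconomical offers of
#'   the quadrant).
#'
#' @return The session with columns `p_accept` and `choice` added.
#' @export
simulate_choices <- function(session, family, k, beta, c_bias, seed = 1,
                             quadrant_sv_bonus = 0) {
  assert_cols(session, c("incentive_level", "effort_level"), "`session`")
  sv <- subjective_value(family, session$incentive_level, session$effort_level, k)
  if (quadrant_sv_bonus != 0) {
    target <- classify_quadrant(session$effort_level,
                                session$incentive_level) == "high_eff_low_inc"
    sv <- sv + quadrant_sv_bonus * target
  }
  p <- accept_probability(sv, beta, c_bias)
  choice <- withr::with_seed(as.integer(seed) %% 2147483647L,
                             as.integer(stats::runif(length(p)) < p))
  dplyr::mutate(session, p_accept = p, choice = choice)
}
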