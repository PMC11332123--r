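# Synthetic 60 Hz grip-force traces linked to accepted trials.

#' Specify synthetic force-trace generation
#'
#' Traces emulate the dynamometer recordings of accepted trials: a flat
#' baseline, a ramp up to a plateau held above the required force threshold
#' (percent of maximum sustainable grip force, %MGF), Gaussian sample noise,
#' and — for successful trials — at least 1.5 s of consecutive at-or-above
#' threshold force inside the 5 s response window. Failure traces repeatedly
#' dip below threshold so that no 1.5 s consecutive hold accumulates.
#'
#' @param sample_rate Fixed at 60 Hz.
#' @param baseline_duration Seconds of near-zero force before the ramp.
#' @param ramp_duration Seconds of the linear ramp to plateau.
#' @param hold_duration Seconds the plateau is held (must be >= 1.5 for
#'   success traces).
#' @param plateau_overexertion Named list (per group) of `c(mean, sd)` of the
#'   plateau's overshoot delta above threshold, in %MGF (draw truncated below
#'   at 0.5). Defaults inject a 2 %MGF group difference (control 3, stress 5).
#' @param noise_sd SD of Gaussian sample noise (%MGF).
#' @param window Response window in seconds (5 s in the paradigms).
#'
#' @return A list of class `force_trace_spec`.
#' @export
force_trace_spec <- function(sample_rate = 60,
                             baseline_duration = 0.5,
                             ramp_duration = 0.7,
                             hold_duration = 2,
                             plateau_overexertion = list(
                               MAST_PLC = c(3, 1.5),
                               MAST_EXP = c(5, 1.5)
                             ),
                             noise_sd = 1,
                             window = 5) {
  if (sample_rate != 60) stop("`sample_rate` is fixed at 60 Hz", call. = FALSE)
  stopifnot(hold_duration >= 1.5, baseline_duration >= 0, ramp_duration > 0,
            noise_sd >= 0, window > 0)
  structure(
    list(sample_rate = 60, baseline_duration = baseline_duration,
         ramp_duration = ramp_duration, hold_duration = hold_duration,
         plateau_overexertion = plateau_overexertion, noise_sd = noise_sd,
         window = window),
    class = "force_trace_spec"
  )
}

# deterministic trace skeleton; delta = plateau overshoot above threshold
build_trace_samples <- function(threshold, delta, success, spec, noise) {
  fs <- spec$sample_rate
  n_base <- round(spec$baseline_duration * fs)
  n_ramp <- round(spec$ramp_duration * fs)
  plateau <- threshold + delta
  if (success) {
    n_hold <- round(spec$hold_duration * fs)
    force <- c(rep(0, n_base),
               seq(0, plateau, length.out = n_ramp),
               rep(plateau, n_hold))
  } else {
    # dip below threshold every 1.2 s so no 90-sample run can accumulate
    n_total <- round(spec$window * fs)
    force <- c(rep(0, n_base), seq(0, plateau, length.out = n_ramp))
    force <- c(force, rep(plateau, max(0, n_total - length(force))))
    dip_at <- seq(n_base + n_ramp, n_total, by = round(1.2 * fs))
    dip_idx <- unlist(lapply(dip_at, function(d) {
      d:min(d + round(0.1 * fs), n_total)
    }))
    force[dip_idx] <- threshold - 2
  }
  force <- force + noise[seq_along(force)]
  if (success) {
    # keep the above-threshold hold intact despite noise
    above <- seq(n_base + n_ramp, length(force))
    force[above] <- pmax(force[above], threshold + 0.1)
  } else {
    # and keep failure dips strictly below threshold despite noise
    force[dip_idx] <- pmin(force[dip_idx], threshold - 0.5)
  }
  pmax(force, 0)
}

#' Generate a force trace for one accepted trial
#'
#' @param trial A one-row trial record with `choice == 1`, `success`,
#'   `effort_pct_mgf` and (optionally) `group`, `subject_id`, `trial_index`.
#' @param spec A [force_trace_spec()].
#' @param seed Integer seed.
#'
#' @return A tibble with `subject_id`, `trial_index`, `t` (seconds, 1/60
#'   steps), `force` (%MGF) and `required_threshold`.
#' @export
generate_force_trace <- function(trial, spec = force_trace_spec(), seed = 1) {
  stopifnot(inherits(spec, "force_trace_spec"), nrow(trial) == 1)
  if (is.na(trial$choice) || trial$choice != 1L) {
    stop("force traces exist only for accepted trials (choice == 1)",
         call. = FALSE)
  }
  threshold <- trial$effort_pct_mgf
  grp <- trial$group %||% "MAST_PLC"
  ov <- spec$plateau_overexertion[[grp]] %||% c(3, 1.5)
  success <- !is.na(trial$success) && trial$success == 1L
  withr::with_seed(as.integer(seed) %% 2147483647L, {
    delta <- rtruncnorm(1, ov[1], ov[2], lower = 0.5)
    n_max <- round(spec$window * spec$sample_rate) + 1L
    noise <- stats::rnorm(n_max, 0, spec$noise_sd)
    force <- build_trace_samples(threshold, delta, success, spec, noise)
    tibble::tibble(
      subject_id = trial$subject_id %||% "s1",
      trial_index = trial$trial_index %||% 1L,
      t = (seq_along(force) - 1) / spec$sample_rate,
      force = force,
      required_threshold = threshold
    )
  })
}

#' Generate force traces for all accepted trials of a cohort
#'
#' @param trials Trial table (e.g. from [generate_cohort()]).
#' @param spec A [force_trace_spec()].
#' @param seed Root seed; each trial uses a derived substream.
#'
#' @return Long-format tibble: `subject_id`, `trial_index`, `t`, `force`,
#'   `required_threshold`.
#' @export
generate_force_traces <- function(trials, spec = force_trace_spec(), seed = 1) {
  accepted <- dplyr::filter(trials, .data$choice == 1L)
  if (nrow(accepted) == 0) {
    return(tibble::tibble(subject_id = character(), trial_index = integer(),
                          t = numeric(), force = numeric(),
                          required_threshold = numeric()))
  }
  purrr::map_dfr(seq_len(nrow(accepted)), function(i) {
    generate_force_trace(accepted[i, ], spec,
                         seed = derive_seed(seed, "force", i))
  })
}
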