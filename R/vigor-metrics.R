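# Force-trace processing: smoothing, success-epoch extraction, overexertion
# and yank peak.

check_uniform_60hz <- function(t, sample_rate = 60) {
  if (length(t) > 1 && any(abs(diff(t) - 1 / sample_rate) > 1e-6)) {
    stop("force trace must be uniformly sampled at 60 Hz", call. = FALSE)
  }
  invisible(t)
}

# Symmetric moving mean. For odd sample counts this is the ordinary centered
# mean; for even counts (the default 100 ms window at 60 Hz spans 6 samples)
# the two outermost taps carry half weight, which keeps the filter symmetric
# (so straight-line segments pass through unchanged) while preserving the
# 6-sample bandwidth. Edges use the available (shrunken) window.
moving_mean <- function(x, w, align = c("center", "trailing")) {
  align <- match.arg(align)
  n <- length(x)
  if (w <= 1 || n == 0) return(x)
  if (align == "trailing") {
    cs <- cumsum(x)
    lead <- c(rep(0, w), cs[seq_len(n - w)])
    counts <- pmin(seq_len(n), w)
    return((cs - lead) / counts)
  }
  if (w %% 2 == 1) {
    weights <- rep(1, w)
    half <- (w - 1) / 2
  } else {
    weights <- c(0.5, rep(1, w - 1), 0.5)
    half <- w / 2
  }
  lags <- -half:half
  num <- numeric(n)
  den <- numeric(n)
  for (j in seq_along(lags)) {
    idx <- seq_len(n) + lags[j]
    ok <- idx >= 1 & idx <= n
    num[ok] <- num[ok] + weights[j] * x[idx[ok]]
    den[ok] <- den[ok] + weights[j]
  }
  num / den
}

#' Rolling average of a force trace
#'
#' Applies the 100 ms rolling mean used to denoise 60 Hz force data before
#' vigor metrics are computed. The window is centered (see `align`); edges
#' use the available shrunken window, so the output has the input's length.
#'
#' @param trace Tibble with columns `t` (seconds, uniform 1/60 s steps) and
#'   `force` (%MGF). Grouping columns (`subject_id`, `trial_index`) may be
#'   present; the filter is applied per trace.
#' @param window Window length in seconds (default 0.1).
#' @param align `"center"` (default) or `"trailing"`.
#'
#' @return The input with `force` replaced by its rolling average.
#' @export
rolling_average <- function(trace, window = 0.1,
                            align = c("center", "trailing")) {
  align <- match.arg(align)
  assert_cols(trace, c("t", "force"), "`trace`")
  w <- round(window * 60)
  keys <- intersect(c("subject_id", "trial_index"), names(trace))
  if (length(keys) == 0) {
    check_uniform_60hz(trace$t)
    trace$force <- moving_mean(trace$force, w, align)
    return(trace)
  }
  trace |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, key) {
      check_uniform_60hz(d$t)
      d$force <- moving_mean(d$force, w, align)
      d
    }) |>
    dplyr::ungroup()
}

#' Locate the successful-effort epoch of a trace
#'
#' Completion is the first sample at which 90 consecutive samples (1.5 s at
#' 60 Hz) at-or-above the required threshold have just been achieved. The
#' epoch is the `epoch_len`-second stretch ending at completion; when the
#' epoch would start before the trace begins it is truncated and flagged.
#'
#' @param trace A single trial's trace (`t`, `force`, and optionally
#'   `required_threshold`).
#' @param epoch_len Epoch length in seconds (2.5 default; 2.0 is the variant
#'   less contaminated by earlier failed attempts).
#' @param threshold Required force (%MGF); taken from `required_threshold`
#'   when omitted.
#' @param hold Consecutive hold needed for completion, seconds (1.5).
#'
#' @return A one-row tibble (`start`, `end` sample indices, `t_complete`,
#'   `truncated`) or `NULL` when the trace never completes.
#' @export
find_success_epoch <- function(trace, epoch_len = 2.5, threshold = NULL,
                               hold = 1.5) {
  assert_cols(trace, c("t", "force"), "`trace`")
  check_uniform_60hz(trace$t)
  threshold <- threshold %||% trace$required_threshold[1]
  if (is.null(threshold) || is.na(threshold)) {
    stop("`threshold` is required (no `required_threshold` column)",
         call. = FALSE)
  }
  need <- round(hold * 60)
  above <- trace$force >= threshold
  run <- 0L
  end <- NA_integer_
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= need) {
      end <- i
      break
    }
  }
  if (is.na(end)) return(NULL)
  start <- end - round(epoch_len * 60) + 1L
  truncated <- start < 1L
  tibble::tibble(start = max(start, 1L), end = end,
                 t_complete = trace$t[end], truncated = truncated)
}

#' Average overexertion within an epoch
#'
#' Mean force above the required threshold (%MGF) over the epoch's
#' at-or-above-threshold samples; below-threshold ramp samples are excluded
#' by default so they cannot produce negative "overexertion".
#'
#' @inheritParams find_success_epoch
#' @param epoch An epoch row from [find_success_epoch()].
#' @param all_samples If `TRUE`, average `force - threshold` over every epoch
#'   sample instead.
#'
#' @return Overexertion in %MGF.
#' @export
overexertion <- function(trace, epoch, threshold = NULL,
                         all_samples = FALSE) {
  threshold <- threshold %||% trace$required_threshold[1]
  f <- trace$force[epoch$start:epoch$end]
  if (all_samples) return(mean(f - threshold))
  keep <- f >= threshold
  if (!any(keep)) {
    stop("epoch contains no at-or-above-threshold samples", call. = FALSE)
  }
  mean(f[keep] - threshold)
}

#' Yank peak within an epoch
#'
#' Maximum first derivative of (smoothed) force over the epoch, computed as
#' the largest forward difference times the 60 Hz sampling rate.
#'
#' @inheritParams overexertion
#' @return Yank peak in %MGF per second.
#' @export
yank_peak <- function(trace, epoch) {
  f <- trace$force[epoch$start:epoch$end]
  if (length(f) < 2) stop("epoch must span at least 2 samples", call. = FALSE)
  max(diff(f)) * 60
}

#' Vigor metrics for every successful trace of a cohort
#'
#' Smooths each trace (100 ms rolling average), locates its success epoch,
#' and computes overexertion and yank peak. Traces without a completed
#' 1.5 s hold yield no row.
#'
#' @param forces Long force table: `subject_id`, `trial_index`, `t`, `force`,
#'   `required_threshold`.
#' @param epoch_len Epoch length in seconds (2.5 or 2.0).
#' @param window Rolling-average window (seconds).
#'
#' @return Tibble: `subject_id`, `trial_index`, `epoch_len`, `t_complete`,
#'   `truncated`, `overexertion`, `yank_peak`.
#' @export
compute_vigor <- function(forces, epoch_len = 2.5, window = 0.1) {
  assert_cols(forces, c("subject_id", "trial_index", "t", "force",
                        "required_threshold"), "`forces`")
  forces |>
    dplyr::group_by(.data$subject_id, .data$trial_index) |>
    dplyr::group_modify(function(d, key) {
      d$force <- moving_mean(d$force, round(window * 60))
      ep <- find_success_epoch(d, epoch_len)
      if (is.null(ep)) return(tibble::tibble())
      tibble::tibble(
        epoch_len = epoch_len,
        t_complete = ep$t_complete,
        truncated = ep$truncated,
        overexertion = overexertion(d, ep),
        yank_peak = yank_peak(d, ep)
      )
    }) |>
    dplyr::ungroup()
}
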