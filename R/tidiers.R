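# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a BMS result
#'
#' One row per model family with the Dirichlet parameter, expected model
#' frequency, exceedance probability and protected exceedance probability.
#'
#' @param x A `bms_result` from [run_bms()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bms_result
#' @export
tidy.bms_result <- function(x, ...) {
  tibble::tibble(
    family = x$families,
    alpha = unname(x$alpha),
    r_expected = unname(x$r_expected),
    xp = unname(x$xp),
    pxp = unname(x$pxp)
  )
}

#' @rdname tidy.bms_result
#' @method glance bms_result
#' @export
glance.bms_result <- function(x, ...) {
  winner <- x$families[which.max(x$xp)]
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_families = length(x$families),
    winner = winner,
    xp_winner = max(x$xp),
    pxp_winner = unname(x$pxp[winner]),
    bor = x$bor
  )
}

#' Tidy a recovery report
#'
#' @param x A `recovery_report` from [recovery_suite()].
#' @param ... Unused.
#' @return A tibble: parameter-recovery correlations and/or confusion counts
#'   stacked with a `component` column.
#' @method tidy recovery_report
#' @export
tidy.recovery_report <- function(x, ...) {
  parts <- list()
  if (!is.null(x$param_recovery)) {
    parts$parameters <- dplyr::mutate(x$param_recovery,
                                      component = "parameters")
  }
  if (!is.null(x$confusion)) {
    parts$models <- dplyr::mutate(x$confusion, component = "models")
  }
  dplyr::bind_rows(parts)
}

#' @rdname tidy.recovery_report
#' @method glance recovery_report
#' @export
glance.recovery_report <- function(x, ...) {
  out <- tibble::tibble(.rows = 1)
  if (!is.null(x$param_recovery)) {
    k_rows <- dplyr::filter(x$param_recovery, .data$parameter == "k")
    out$r_k_min <- min(k_rows$r)
  }
  if (!is.null(x$confusion)) {
    acc <- confusion_accuracy(x)
    out$prop_correct_min <- min(acc$prop_correct)
    out$n_replicates <- sum(acc$n_groups)
  }
  out
}
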