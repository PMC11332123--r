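# Parameter- and model-recovery harness: simulate agents with known
# parameters, re-fit them, and summarize how well truth is recovered.

#' Parameter and model recovery suite
#'
#' Two validation components:
#'
#' * `"parameters"` — generate one cohort from `spec`, re-fit each subject's
#'   generating family with the two-step procedure, and report the Pearson
#'   correlation between true and recovered `k`, `beta`, `c` per group.
#' * `"models"` — generate `n_replicates` single-family groups (cycling
#'   through `families`), fit all four families per subject, run per-group
#'   BMS, and tabulate the generating-vs-selected confusion matrix.
#'
#' @param spec A [cohort_spec()] for the parameter-recovery cohort.
#' @param components Which components to run (default both).
#' @param families Generating families for the confusion matrix.
#' @param n_replicates Total number of replicate groups for the confusion
#'   matrix (default 20).
#' @param n_subjects_confusion Subjects per replicate group (default 40,
#'   the study's group size; parabolic-vs-hyperbolic discrimination needs
#'   group-level evidence pooling).
#' @param n_starts Optimizer starts per fit (default 5 here; recovery fits
#'   are numerous).
#' @param confusion_stage Fitting stage used for confusion-matrix evidence:
#'   `"mle"` (default; model identity is driven by the likelihood and AIC is
#'   equal-dimensional across families) or `"map"` for the full two-step.
#' @param seed Root seed.
#'
#' @return An object of class `recovery_report`: list with
#'   `param_recovery` (tibble: `group`, `family`, `parameter`, `r`, `n`),
#'   `confusion` (tibble: `generating`, `selected`, `n`, `xp`),
#'   and `settings`.
#' @export
recovery_suite <- function(spec = cohort_spec(),
                           components = c("parameters", "models"),
                           families = model_families(),
                           n_replicates = 20,
                           n_subjects_confusion = 40,
                           n_starts = 5,
                           confusion_stage = c("mle", "map"),
                           seed = 1) {
  components <- match.arg(components, several.ok = TRUE)
  confusion_stage <- match.arg(confusion_stage)
  param_recovery <- NULL
  confusion <- NULL

  if ("parameters" %in% components) {
    # recovery validates estimation under the generative model families, so
    # the task-level quadrant margin (outside every family) is switched off
    pure_spec <- spec
    pure_spec$quadrant_sv_bonus[] <- 0
    cohort <- generate_cohort(pure_spec)
    param_recovery <- purrr::map_dfr(names(spec$group_family), function(g) {
      fam <- spec$group_family[[g]]
      tr <- dplyr::filter(cohort$trials, .data$group == g)
      # the inflexible-responder exclusion applies here as everywhere: a
      # subject with invariant choices carries no parameter information
      infl <- detect_inflexible(tr)
      keep <- infl$subject_id[!infl$inflexible]
      truth <- dplyr::filter(cohort$subjects, .data$group == g,
                             .data$subject_id %in% keep)
      tr <- dplyr::filter(tr, .data$subject_id %in% keep)
      fit <- fit_cohort(tr, families = fam, n_starts = n_starts,
                        seed = derive_seed(seed, "param_recovery"))
      est <- dplyr::filter(fit$fits, .data$stage == "map") |>
        dplyr::arrange(.data$subject_id)
      truth <- dplyr::arrange(truth, .data$subject_id)
      purrr::map_dfr(c("k", "beta", "c"), function(p) {
        tibble::tibble(
          group = g, family = fam, parameter = p,
          r = suppressWarnings(stats::cor(truth[[p]], est[[p]])),
          n = nrow(truth)
        )
      })
    })
  }

  if ("models" %in% components) {
    gen <- rep(families, length.out = n_replicates)
    runs <- purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
      fam <- gen[rep_i]
      rep_spec <- cohort_spec(
        n_per_group = n_subjects_confusion,
        paradigm = spec$paradigm,
        group_family = stats::setNames(fam, "SIM"),
        failure_prob_by_effort = spec$failure_prob_by_effort,
        inflexible_rate = 0,
        quadrant_sv_bonus = c(SIM = 0),
        seed = derive_seed(seed, "confusion", rep_i)
      )
      cohort <- generate_cohort(rep_spec)
      stages <- if (confusion_stage == "mle") "mle" else c("mle", "map")
      fit <- fit_cohort(cohort$trials, families = model_families(),
                        n_starts = n_starts,
                        seed = derive_seed(seed, "confusion_fit", rep_i),
                        stages = stages)
      sel <- select_group_model(fit$fits, "SIM", stage = confusion_stage,
                                n_samples = 1e5,
                                seed = derive_seed(seed, "confusion_bms",
                                                   rep_i))
      tibble::tibble(generating = fam, selected = sel$family,
                     xp = max(sel$bms$xp))
    })
    confusion <- runs |>
      dplyr::summarise(n = dplyr::n(), xp = mean(.data$xp),
                       .by = c("generating", "selected"))
  }

  structure(
    list(param_recovery = param_recovery, confusion = confusion,
         settings = list(spec = spec, n_replicates = n_replicates,
                         n_subjects_confusion = n_subjects_confusion,
                         n_starts = n_starts,
                         confusion_stage = confusion_stage, seed = seed)),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery report\n")
  if (!is.null(x$param_recovery)) {
    cat("\nParameter recovery (Pearson r, true vs MAP):\n")
    print(as.data.frame(x$param_recovery))
  }
  if (!is.null(x$confusion)) {
    cat("\nModel confusion (generating vs selected, group counts):\n")
    print(as.data.frame(x$confusion))
  }
  invisible(x)
}

#' Diagonal dominance of a recovery confusion matrix
#'
#' Fraction of replicate groups whose selected family equals the generating
#' family, per generating family.
#'
#' @param report A `recovery_report` with a confusion component.
#' @return Tibble: `generating`, `n_groups`, `prop_correct`.
#' @export
confusion_accuracy <- function(report) {
  stopifnot(inherits(report, "recovery_report"), !is.null(report$confusion))
  report$confusion |>
    dplyr::summarise(
      n_groups = sum(.data$n),
      prop_correct = sum(.data$n[.data$selected == .data$generating]) /
        sum(.data$n),
      .by = "generating"
    )
}
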