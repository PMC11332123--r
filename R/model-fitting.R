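# Two-step hierarchical fitting: subject-level bounded maximum likelihood,
# whole-sample empirical priors, and prior-shrunk MAP re-fitting, with AIC.

#' Default optimization bounds for a family
#'
#' `k` bounds are family-specific (hyperbolic needs `k < 0.25` so that
#' `k * E < 1` over the grid); `beta` in \[0, 30\]; `c` in \[-10, 10\].
#'
#' @param family One of [model_families()].
#' @return A list with numeric vectors `lower` and `upper`, named
#'   `(k, beta, c)`.
#' @export
default_bounds <- function(family) {
  check_family(family)
  kb <- k_bounds_for(family)
  list(lower = c(k = kb[1], beta = 0, c = -10),
       upper = c(k = kb[2], beta = 30, c = 10))
}

#' Akaike Information Criterion from a negative log-likelihood
#'
#' `AIC = 2 * n_params + 2 * nll`. All four families have the same three free
#' parameters (`k`, `beta`, `c`), so AIC comparison reduces to likelihood
#' comparison.
#'
#' @param nll Negative log-likelihood, `>= 0`.
#' @param n_params Number of free parameters (default 3).
#' @return A number.
#' @export
compute_aic <- function(nll, n_params = 3) {
  if (any(nll < 0)) stop("`nll` must be >= 0", call. = FALSE)
  2 * n_params + 2 * nll
}

# Latin-hypercube start points over the box
make_starts <- function(n_starts, bounds, seed) {
  u <- withr::with_seed(as.integer(seed) %% 2147483647L,
                        lhs::randomLHS(n_starts, 3))
  lo <- bounds$lower
  hi <- bounds$upper
  sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
}

# shared multi-start bounded minimizer; penalty(theta) and its gradient are
# added to the likelihood objective for MAP fitting (NULL for plain MLE)
optimize_subject <- function(trials, family, bounds, n_starts, seed,
                             penalty = NULL, penalty_grad = NULL,
                             extra_starts = NULL, reltol = 1e-6) {
  eps <- 1e-9 # keep hyperbolic strictly inside its domain
  lo <- bounds$lower
  hi <- bounds$upper
  if (family == "hyperbolic") hi["k"] <- min(hi["k"], 0.25 - eps)
  obj <- function(theta) {
    v <- choice_nll(trials, family, theta[1], theta[2], theta[3])
    if (!is.null(penalty)) v <- v + penalty(theta)
    v
  }
  grad <- function(theta) {
    g <- choice_nll_grad(trials, family, theta[1], theta[2], theta[3])
    if (!is.null(penalty_grad)) g <- g + penalty_grad(theta)
    g
  }
  starts <- make_starts(n_starts, list(lower = lo, upper = hi), seed)
  # always include a moderate deterministic start: LHS draws alone can all
  # land on the cliff-like part of the surface when beta is near its bound
  mid <- (lo + hi) / 2
  starts <- rbind(starts, c(mid[["k"]], min(3, hi[["beta"]]), 0))
  if (!is.null(extra_starts)) {
    extra_starts <- matrix(pmin(pmax(t(extra_starts), lo), hi), ncol = 3,
                           byrow = TRUE)
    starts <- rbind(starts, extra_starts)
  }
  n_starts <- nrow(starts)
  best <- NULL
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::nlminb(starts[i, ], obj, gradient = grad,
                    lower = lo, upper = hi,
                    control = list(rel.tol = reltol, iter.max = 300)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stop("optimization failed from every start point",
                          call. = FALSE)
  best
}

subject_fit_row <- function(trials, family, best, n_starts, stage,
                            inflexible) {
  theta <- best$par
  nll <- choice_nll(trials, family, theta[1], theta[2], theta[3])
  tibble::tibble(
    family = family,
    k = unname(theta[1]), beta = unname(theta[2]), c = unname(theta[3]),
    nll = nll, aic = compute_aic(nll),
    n_starts = n_starts,
    converged = best$convergence == 0 && !inflexible,
    inflexible = inflexible,
    stage = stage
  )
}

#' Stage-1 subject-level maximum-likelihood fit
#'
#' Multi-start bounded minimization of the Bernoulli negative log-likelihood
#' (Latin-hypercube start points, `nlminb` with analytic gradients). Subjects
#' whose choices show no variation are still fit but flagged
#' (`inflexible = TRUE`, `converged = FALSE`); the caller decides exclusion.
#'
#' @param trials One subject's trials (`incentive_level`, `effort_level`,
#'   `choice`).
#' @param family One of [model_families()].
#' @param bounds As from [default_bounds()].
#' @param n_starts Number of start points (default 10).
#' @param seed Integer seed (start points are reproducible).
#'
#' @return A one-row tibble: `family`, `k`, `beta`, `c`, `nll`, `aic`,
#'   `n_starts`, `converged`, `inflexible`, `stage`.
#' @export
fit_mle <- function(trials, family, bounds = default_bounds(family),
                    n_starts = 10, seed = 1) {
  check_family(family)
  if (nrow(trials) == 0) stop("`trials` is empty", call. = FALSE)
  inflexible <- length(unique(trials$choice)) < 2
  best <- optimize_subject(trials, family, bounds, n_starts, seed)
  subject_fit_row(trials, family, best, n_starts, "mle", inflexible)
}

#' Empirical prior from stage-1 fits
#'
#' Pools the whole sample (both groups, per the two-step procedure) and
#' returns the mean vector and ridge-regularized covariance of `(k, beta, c)`
#' for one family.
#'
#' @param fits Fit table containing at least columns `family`, `stage`, `k`,
#'   `beta`, `c`.
#' @param family One of [model_families()].
#' @param ridge Diagonal regularizer added to the sample covariance
#'   (default `1e-4`).
#'
#' @return A list of class `empirical_prior` with `family`, `mu` (length-3),
#'   `sigma` (3x3) and `ridge`.
#' @export
estimate_empirical_prior <- function(fits, family, ridge = 1e-4) {
  check_family(family)
  rows <- fits
  if ("stage" %in% names(rows)) {
    rows <- dplyr::filter(rows, .data$stage == "mle")
  }
  rows <- dplyr::filter(rows, .data$family == !!family)
  if (nrow(rows) < 2) {
    stop("need at least 2 stage-1 fits to estimate an empirical prior",
         call. = FALSE)
  }
  theta <- as.matrix(rows[, c("k", "beta", "c")])
  mu <- colMeans(theta)
  sigma <- stats::cov(theta) + diag(ridge, 3)
  structure(list(family = family, mu = mu, sigma = sigma, ridge = ridge),
            class = "empirical_prior")
}

#' Stage-2 MAP fit under an empirical prior
#'
#' Minimizes `nll(theta) + 0.5 * (theta - mu)' sigma^-1 (theta - mu)`, i.e.
#' the parameter search is shrunk toward the whole-sample mean with strength
#' given by the whole-sample covariance (empirical-Bayes reading of the
#' two-step procedure). The reported `nll`/`aic` are likelihood-only,
#' evaluated at the MAP point.
#'
#' @inheritParams fit_mle
#' @param prior An [estimate_empirical_prior()] result for the same family.
#' @param extra_start Optional additional start point (e.g. the subject's
#'   stage-1 estimate), length-3 `(k, beta, c)`.
#'
#' @return A one-row tibble as in [fit_mle()] with `stage = "map"`.
#' @export
fit_map <- function(trials, family, prior, bounds = default_bounds(family),
                    n_starts = 10, seed = 1, extra_start = NULL) {
  check_family(family)
  stopifnot(inherits(prior, "empirical_prior"))
  if (prior$family != family) {
    stop("prior family does not match `family`", call. = FALSE)
  }
  sigma_inv <- tryCatch(solve(prior$sigma), error = function(e) {
    stop("prior covariance is singular; increase `ridge`", call. = FALSE)
  })
  mu <- prior$mu
  penalty <- function(theta) 0.5 * drop(t(theta - mu) %*% sigma_inv %*%
                                          (theta - mu))
  penalty_grad <- function(theta) drop(sigma_inv %*% (theta - mu))
  inflexible <- length(unique(trials$choice)) < 2
  # the prior mean and (when supplied) the subject's stage-1 estimate join
  # the start set: the penalized surface can be badly conditioned when a
  # prior variance collapses (e.g. every stage-1 beta at the same bound)
  extra <- rbind(unname(prior$mu),
                 if (!is.null(extra_start)) unname(extra_start))
  best <- optimize_subject(trials, family, bounds, n_starts, seed,
                           penalty, penalty_grad, extra_starts = extra)
  subject_fit_row(trials, family, best, n_starts, "map", inflexible)
}

#' Two-step hierarchical fit of a whole cohort
#'
#' Runs the full fitting procedure on a trial table covering many subjects:
#' stage-1 MLE per subject and family, an empirical prior per family pooled
#' over the entire sample, then stage-2 MAP re-fits under that prior. Start
#' points use per-subject seeds derived from `seed`.
#'
#' @param trials Trial table with `subject_id`, `group`, `incentive_level`,
#'   `effort_level`, `choice`.
#' @param families Families to fit (default all four).
#' @param n_starts Start points per subject and family.
#' @param seed Root seed.
#' @param stages `c("mle", "map")` (default) or `"mle"` to stop after
#'   stage 1.
#' @param ridge Prior ridge, see [estimate_empirical_prior()].
#'
#' @return A list with `fits` (tibble over subjects x families x stages) and
#'   `priors` (named list of `empirical_prior`, when stage 2 ran).
#' @export
fit_cohort <- function(trials, families = model_families(), n_starts = 10,
                       seed = 1, stages = c("mle", "map"), ridge = 1e-4) {
  assert_cols(trials, c("subject_id", "incentive_level", "effort_level",
                        "choice"), "`trials`")
  stages <- match.arg(stages, c("mle", "map"), several.ok = TRUE)
  by_subject <- split(trials, trials$subject_id)
  ids <- names(by_subject)

  fit_stage <- function(stage, priors = NULL, stage1 = NULL) {
    purrr::imap_dfr(by_subject, function(tr, id) {
      grp <- if ("group" %in% names(tr)) tr$group[1] else NA_character_
      i <- match(id, ids)
      purrr::map_dfr(families, function(fam) {
        s <- derive_seed(seed, paste0(stage, "_", fam), i)
        row <- if (stage == "mle") {
          fit_mle(tr, fam, n_starts = n_starts, seed = s)
        } else {
          mle_row <- stage1[stage1$subject_id == id & stage1$family == fam, ]
          fit_map(tr, fam, priors[[fam]], n_starts = n_starts, seed = s,
                  extra_start = c(mle_row$k, mle_row$beta, mle_row$c))
        }
        dplyr::bind_cols(tibble::tibble(subject_id = id, group = grp), row)
      })
    })
  }

  fits <- fit_stage("mle")
  priors <- NULL
  if ("map" %in% stages) {
    priors <- purrr::set_names(
      lapply(families, function(fam) {
        estimate_empirical_prior(fits, fam, ridge = ridge)
      }),
      families
    )
    fits <- dplyr::bind_rows(fits, fit_stage("map", priors, stage1 = fits))
  }
  list(fits = fits, priors = priors)
}
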