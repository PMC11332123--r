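# Internal helpers: deterministic seed derivation, truncated-normal draws,
# small assertions shared across modules.

# Deterministic 32-bit-safe sub-seed: every stage of the pipeline draws its
# randomness from a named substream of the root seed so that, e.g., changing
# force-trace settings can never perturb simulated choices.
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483629 # prime below 2^31
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  s <- (abs(seed) %% m)
  s <- (s * 48271 + h * 1103 + 12345) %% m
  s <- (s * 16807 + (index %% m) * 7919 + 1) %% m
  as.integer(s)
}

# Inverse-CDF truncated-normal sampler (no dedicated package needed; the
# quantile transform is exact for one-sided and two-sided truncation).
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, lower < upper)
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("degenerate truncated normal: point mass outside bounds")
    }
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo < 1e-12) {
    stop("infeasible truncated normal: no probability mass between bounds")
  }
  u <- stats::runif(n, plo, phi)
  pmin(pmax(stats::qnorm(u, mean, sd), lower), upper)
}

# logistic and log-sum-exp, numerically stable
sigmoid <- function(x) stats::plogis(x)

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_cols <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(data)
}
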