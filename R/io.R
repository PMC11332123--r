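# Delimited-table I/O: provenance headers, schema validation for trial
# tables, and lossless round-trips.

PKG_STAGE_VERSION <- "1"

# tiny FNV-1a content hash for provenance lines (hex string)
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write / read a pipeline table with a provenance header
#'
#' Tables are comma-separated UTF-8 with `.` decimals; a `#`-prefixed header
#' records the producing stage, its version, the seed, and a content hash of
#' the column schema, so every artifact is self-describing.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @param stage Stage label recorded in the header.
#' @param seed Seed recorded in the header.
#' @return `write_study_table()` returns `path` invisibly;
#'   `read_study_table()` returns a tibble (header lines are skipped).
#' @export
write_study_table <- function(x, path, stage = "table", seed = NA) {
  header <- sprintf("# effortmob stage=%s version=%s seed=%s schema=%s",
                    stage, PKG_STAGE_VERSION, as.character(seed),
                    fnv1a(names(x)))
  writeLines(header, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_study_table
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

trial_required_cols <- c("subject_id", "paradigm", "block", "trial_index",
                         "effort_level", "incentive_level", "choice")

#' Validate a trial table against the schema invariants
#'
#' Checks required columns, level ranges (effort/incentive in 1-4, choice in
#' 0/1), that `success` is absent (NA) on declined trials, and that
#' `trial_index` is unique within subject. Violations are reported with the
#' offending row numbers.
#'
#' @param trials Data frame of trials.
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_trials <- function(trials) {
  assert_cols(trials, trial_required_cols, "trial table")
  problems <- character()
  bad_rows <- function(cond, msg) {
    rows <- which(cond)
    if (length(rows) > 0) {
      problems <<- c(problems, sprintf("%s (rows %s)", msg,
                                       paste(utils::head(rows, 5),
                                             collapse = ", ")))
    }
  }
  bad_rows(!trials$effort_level %in% 1:4, "effort_level outside 1-4")
  bad_rows(!trials$incentive_level %in% 1:4, "incentive_level outside 1-4")
  bad_rows(!trials$choice %in% c(0, 1), "choice must be 0 or 1")
  bad_rows(!trials$paradigm %in% paradigms(), "unknown paradigm")
  if ("success" %in% names(trials)) {
    bad_rows(trials$choice == 0 & !is.na(trials$success),
             "success must be absent (NA) on declined trials")
    bad_rows(trials$choice == 1 & !is.na(trials$success) &
               !trials$success %in% c(0, 1), "success must be 0/1")
  }
  dup <- trials |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::filter(duplicated(paste(.data$subject_id, .data$trial_index)))
  if (nrow(dup) > 0) {
    problems <- c(problems,
                  sprintf("duplicate trial_index within subject (rows %s)",
                          paste(utils::head(dup$.row, 5), collapse = ", ")))
  }
  if (length(problems) > 0) {
    stop("invalid trial table:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(tibble::as_tibble(trials))
}

#' Write / read trial tables
#'
#' Thin wrappers around [write_study_table()] / [read_study_table()] that
#' validate the schema on both ends, so invalid files are rejected with row
#' diagnostics rather than silently propagated.
#'
#' @param trials Trial table.
#' @param path File path.
#' @param seed Seed recorded in the provenance header.
#' @return `read_trials()` returns the validated tibble.
#' @export
write_trials <- function(trials, path, seed = NA) {
  validate_trials(trials)
  write_study_table(trials, path, stage = "trials", seed = seed)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- read_study_table(path)
  validate_trials(trials)
  trials
}
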