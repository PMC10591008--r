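# Follow-up design enumeration, classification and subsampling.
#
# A design is a baseline-anchored subset of the acquisition sessions.
# The full schedule is the reference design D_R; a tested design such as
# D_014 keeps sessions 0, 1 and 4. Designs are classified by duration (week
# of the last retained session) and by whether the nominal gaps between
# retained sessions are equal (balanced) or not (unbalanced, split into
# short-first and long-first by the first gap).

#' Construct a design specification
#'
#' @param session_indices strictly increasing 0-based session indices;
#'   must include 0 (the baseline is always retained).
#' @param name optional design name; derived from the indices
#'   (`"D_014"`) when omitted. The all-session design of a schedule is
#'   conventionally named `"D_R"` by [enumerate_designs()].
#' @return object of class `design_spec` with fields `name` and
#'   `session_indices` (and, after [classify_design()], `duration_weeks`
#'   and `interval_type`).
#' @export
design_spec <- function(session_indices, name = NULL) {
  idx <- as.integer(session_indices)
  if (length(idx) < 2 || any(diff(idx) <= 0)) {
    stop_config("session_indices must be strictly increasing with >= 2 entries")
  }
  if (idx[1] != 0) {
    stop_config("designs must retain the baseline session (index 0)")
  }
  if (is.null(name)) name <- paste0("D_", paste(idx, collapse = ""))
  structure(list(name = name, session_indices = idx,
                 duration_weeks = NA_real_,
                 interval_type = NA_character_),
            class = "design_spec")
}

#' Parse a design name back into a specification
#'
#' Inverse of the naming convention: `"D_014"` gives sessions 0, 1, 4.
#' `"D_R"` needs `n_sessions` to recover the full schedule.
#'
#' @param name design name such as `"D_024"` or `"D_R"`.
#' @param n_sessions total sessions in the schedule (required for `"D_R"`).
#' @export
parse_design_name <- function(name, n_sessions = NULL) {
  if (identical(name, "D_R")) {
    if (is.null(n_sessions)) {
      stop_config("parsing 'D_R' requires n_sessions")
    }
    d <- design_spec(seq_len(n_sessions) - 1L, name = "D_R")
    return(d)
  }
  digits <- sub("^D_?", "", name)
  if (!grepl("^[0-9]+$", digits)) {
    stop_config("cannot parse design name '%s'", name)
  }
  design_spec(as.integer(strsplit(digits, "")[[1]]), name = name)
}

#' Enumerate candidate follow-up designs
#'
#' Returns the reference design (all `n_sessions` sessions, named `D_R`)
#' followed by every baseline-anchored subset of size `k`: the baseline plus
#' each choice of `k - 1` follow-ups. For a 5-session schedule and `k = 3`
#' this is the standard menu of six tested designs (D_012, D_013, D_014,
#' D_023, D_024, D_034).
#'
#' @param n_sessions number of sessions in the full schedule.
#' @param k number of sessions retained by each tested design.
#' @param session_weeks optional nominal week offsets; when given, each
#'   design is also classified via [classify_design()].
#' @return list of `design_spec` objects, reference first.
#' @export
enumerate_designs <- function(n_sessions, k = 3, session_weeks = NULL) {
  if (!is_count(n_sessions) || n_sessions < 2) {
    stop_config("'n_sessions' must be an integer >= 2")
  }
  if (!is_count(k) || k < 2 || k > n_sessions) {
    stop_config("'k' must satisfy 2 <= k <= n_sessions")
  }
  ref <- design_spec(seq_len(n_sessions) - 1L, name = "D_R")
  followups <- seq_len(n_sessions - 1L)
  subs <- utils::combn(followups, k - 1L, simplify = FALSE)
  tested <- lapply(subs, function(s) design_spec(c(0L, s)))
  # Drop a tested design identical to the reference (k == n_sessions).
  tested <- Filter(function(d) length(d$session_indices) < n_sessions, tested)
  designs <- c(list(ref), tested)
  if (!is.null(session_weeks)) {
    designs <- lapply(designs, classify_design, session_weeks = session_weeks)
  }
  designs
}

#' Classify a design by duration and interval balance
#'
#' Fills `duration_weeks` (nominal week of the last retained session) and
#' `interval_type`: `"reference"` for the full schedule, `"balanced"` when
#' all successive nominal gaps are equal, otherwise
#' `"unbalanced_short_first"` or `"unbalanced_long_first"` depending on
#' whether the first gap is shorter or longer than the mean of the
#' remaining gaps. Classification uses the nominal schedule, not jittered
#' acquisition times.
#'
#' @param d a `design_spec`.
#' @param session_weeks nominal week offsets of the full schedule.
#' @export
classify_design <- function(d, session_weeks) {
  stopifnot(inherits(d, "design_spec"))
  if (max(d$session_indices) + 1L > length(session_weeks)) {
    stop_config("design '%s' references a session beyond the schedule",
                d$name)
  }
  w <- session_weeks[d$session_indices + 1L]
  d$duration_weeks <- w[length(w)]
  gaps <- diff(w)
  d$interval_type <- if (length(d$session_indices) == length(session_weeks)) {
    "reference"
  } else if (max(gaps) - min(gaps) < 1e-9) {
    "balanced"
  } else if (gaps[1] < mean(gaps[-1])) {
    "unbalanced_short_first"
  } else {
    "unbalanced_long_first"
  }
  d
}

#' Restrict a dataset to the sessions of a design
#'
#' Keeps only records whose session index belongs to the design; the
#' covariate, clinical and truth tables are unchanged (clinical change is
#' always anchored at the study's first and last clinical visits, whatever
#' the MRI design).
#'
#' @param dataset a `longitudinal_dataset`.
#' @param d a `design_spec`.
#' @return a `longitudinal_dataset` restricted to the design's sessions.
#' @export
subsample <- function(dataset, d) {
  stopifnot(inherits(dataset, "longitudinal_dataset"),
            inherits(d, "design_spec"))
  have <- sort(unique(dataset$records$session_index))
  missing <- setdiff(d$session_indices, have)
  if (length(missing) > 0) {
    stop_config("design '%s' needs session(s) %s absent from the dataset",
                d$name, paste(missing, collapse = ", "))
  }
  out <- dataset
  out$records <- dataset$records[
    dataset$records$session_index %in% d$session_indices, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("<design %s> sessions {%s}", x$name,
              paste(x$session_indices, collapse = ",")))
  if (!is.na(x$interval_type)) {
    cat(sprintf(" | %s, %g weeks", x$interval_type, x$duration_weeks))
  }
  cat("\n")
  invisible(x)
}

#' Serialize designs to and from JSON
#'
#' @param designs list of `design_spec`.
#' @param path JSON file path.
#' @export
write_designs <- function(designs, path) {
  jsonlite::write_json(
    lapply(designs, function(d) list(name = d$name,
                                     session_indices = d$session_indices)),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_designs
#' @export
read_designs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(x) design_spec(unlist(x$session_indices),
                                      name = x$name))
}
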