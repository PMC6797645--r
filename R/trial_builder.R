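#' @name trial_builder
#' @title Segmenting streams into trials and quality control
#'
#' @description
#' A subject's coordinate recordings arrive as one concatenated stream
#' spanning all trials; the per-trial onset (`on_ready`) and button-click
#' times define closed time windows that cut the stream into trials. Window
#' boundaries belong to the trial (the boundary sample is the click itself).
#' Defective data — missing trajectories, unequal stream lengths,
#' non-monotone timestamps, wrong trial counts — are flagged, never fatal:
#' flagging subjects for exclusion is the point of this stage.
NULL

.defect_codes <- c("missing_trajectory", "stream_length_mismatch",
                   "nonmonotone_time", "wrong_trial_count")

new_trial <- function(subject_id, presented_index, stimulus_id, samples,
                      on_ready, button_click, chosen_category = NA_character_,
                      alert_codes = integer(0), latency_recorded = NA_real_,
                      window_width = NA_real_, window_height = NA_real_) {
  structure(
    list(subject_id = subject_id,
         presented_index = as.integer(presented_index),
         stimulus_id = stimulus_id,
         samples = samples,
         on_ready = on_ready,
         button_click = button_click,
         chosen_category = chosen_category,
         alert_codes = as.integer(alert_codes),
         latency_recorded = latency_recorded,
         window_width = window_width,
         window_height = window_height),
    class = "mt_trial"
  )
}

#' @export
print.mt_trial <- function(x, ...) {
  cat("<mt_trial> subject ", x$subject_id, ", stimulus ", x$stimulus_id,
      " (presented #", x$presented_index, "): ", nrow(x$samples),
      " samples over ", x$button_click - x$on_ready, " ms\n", sep = "")
  invisible(x)
}

# "23" -> c(2L, 3L); "0" -> integer(0)
parse_alert_token <- function(token) {
  if (is.na(token) || !nzchar(token)) return(integer(0))
  codes <- as.integer(strsplit(token, "", fixed = TRUE)[[1L]])
  codes[codes != 0L]
}

# pad or truncate a per-trial vector to n (absent -> NA)
fit_to_trials <- function(v, n) {
  if (is.null(v)) v <- rep(NA_real_, n)
  length(v) <- n
  v
}

#' Segment one subject's streams into trials
#'
#' Parses the subject's delimited streams and assigns every (x, y, t) triplet
#' to the unique trial whose closed window `[on_ready, button_click]`
#' contains `t`; samples falling outside every window are dropped and
#' counted. Data defects set subject-level defect codes instead of raising.
#'
#' @param record One row of an `mt_raw` data frame (as a list or one-row
#'   data frame).
#' @param dialect An [export_dialect()].
#' @return An object of class `mt_subject`: fields `subject_id`, `trials`
#'   (list of `mt_trial` in presented order), `defects` (subset of
#'   `missing_trajectory`, `stream_length_mismatch`, `nonmonotone_time`,
#'   `wrong_trial_count`), `n_dropped_samples`, `n_parsed_samples`, and the
#'   browser metadata fields.
#' @export
segment_subject <- function(record, dialect = export_dialect()) {
  stopifnot(inherits(dialect, "mt_dialect"))
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  sid <- record$subject_id
  ctx <- function(col) sprintf("subject %s, column %s", sid, col)
  defects <- character(0)

  on_ready <- parse_separated_stream(record$on_ready_times, dialect,
                                     ctx("onReadyTime"))
  click <- parse_separated_stream(record$button_click_times, dialect,
                                  ctx("buttonClickTime"))
  n_expected <- dialect$n_trials
  n_trials <- length(on_ready)
  if (is.null(on_ready) || is.null(click) ||
      n_trials != n_expected || length(click) != n_trials) {
    defects <- c(defects, "wrong_trial_count")
    n_trials <- min(length(on_ready), length(click))
  }

  xs <- parse_separated_stream(record$x_stream, dialect, ctx("xPos"))
  ys <- parse_separated_stream(record$y_stream, dialect, ctx("yPos"))
  ts <- parse_separated_stream(record$t_stream, dialect, ctx("time"))
  if (is.null(xs) || is.null(ys) || is.null(ts)) {
    defects <- c(defects, "missing_trajectory")
    xs <- ys <- ts <- numeric(0)
  }
  lens <- c(length(xs), length(ys), length(ts))
  if (length(unique(lens)) > 1L) {
    defects <- c(defects, "stream_length_mismatch")
    m <- min(lens)
    xs <- xs[seq_len(m)]; ys <- ys[seq_len(m)]; ts <- ts[seq_len(m)]
  }
  n_parsed <- length(ts)

  latency <- fit_to_trials(
    parse_separated_stream(record$latency_stream, dialect, ctx("latency")),
    n_trials)
  ww <- fit_to_trials(
    parse_separated_stream(record$window_widths, dialect, ctx("windowWidth")),
    n_trials)
  wh <- fit_to_trials(
    parse_separated_stream(record$window_heights, dialect,
                           ctx("windowHeight")),
    n_trials)
  alert_tokens <- split_stream(record$alerts_stream, dialect)
  if (is.null(alert_tokens)) alert_tokens <- character(0)
  length(alert_tokens) <- n_trials
  stim <- split_stream(record$stimulus_order, dialect)
  if (is.null(stim)) stim <- rep(NA_character_, n_trials)
  length(stim) <- n_trials
  chosen <- split_stream(record$chosen_categories, dialect)
  if (is.null(chosen)) chosen <- rep(NA_character_, n_trials)
  length(chosen) <- n_trials

  trials <- vector("list", n_trials)
  assigned <- 0L
  for (j in seq_len(n_trials)) {
    idx <- which(ts >= on_ready[j] & ts <= click[j])
    assigned <- assigned + length(idx)
    samples <- data.frame(x = xs[idx], y = ys[idx], t = ts[idx])
    if (nrow(samples) == 0L) {
      defects <- c(defects, "missing_trajectory")
    } else if (is.unsorted(samples$t)) {
      # re-sorting would fabricate dynamics; flag instead
      defects <- c(defects, "nonmonotone_time")
    }
    trials[[j]] <- new_trial(
      subject_id = sid, presented_index = j, stimulus_id = stim[j],
      samples = samples, on_ready = on_ready[j], button_click = click[j],
      chosen_category = chosen[j],
      alert_codes = parse_alert_token(alert_tokens[j]),
      latency_recorded = latency[j],
      window_width = ww[j], window_height = wh[j])
  }

  structure(
    list(subject_id = sid,
         trials = trials,
         defects = unique(defects),
         n_parsed_samples = n_parsed,
         n_dropped_samples = n_parsed - assigned,
         browser = record$browser %||% NA_character_,
         browser_version = record$browser_version %||% NA_character_,
         operating_system = record$operating_system %||% NA_character_,
         resolution = record$resolution %||% NA_character_),
    class = "mt_subject"
  )
}

#' Segment a whole cohort
#'
#' @param raw An `mt_raw` data frame from [read_raw_export()].
#' @param dialect An [export_dialect()].
#' @return List of `mt_subject`, one per row of `raw`.
#' @export
segment_trials <- function(raw, dialect = attr(raw, "dialect") %||% export_dialect()) {
  lapply(seq_len(nrow(raw)), function(i) {
    segment_subject(as.list(as.data.frame(raw)[i, , drop = FALSE]), dialect)
  })
}

#' @export
print.mt_subject <- function(x, ...) {
  cat("<mt_subject> ", x$subject_id, ": ", length(x$trials), " trial(s)",
      sep = "")
  if (length(x$defects)) cat(" [defects: ", paste(x$defects, collapse = ", "),
                             "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Undo stimulus-order randomization
#'
#' Stimuli are presented in randomized order; analysis wants them in a fixed
#' canonical order. Each trial keeps its `presented_index`, so the
#' presentation order remains recoverable.
#'
#' @param trials List of `mt_trial` for one subject, in presented order.
#' @param canonical_order Character vector of stimulus IDs; must match the
#'   trials' stimulus IDs one-to-one as a set.
#' @return The trials reordered to match `canonical_order`.
#' @export
reorder_by_stimulus <- function(trials, canonical_order) {
  ids <- vapply(trials, function(tr) tr$stimulus_id, character(1))
  sid <- if (length(trials)) trials[[1L]]$subject_id else "<none>"
  if (anyDuplicated(ids)) {
    stop("subject ", sid, ": duplicate stimulus IDs in presented order: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (length(ids) != length(canonical_order) ||
      !setequal(ids, canonical_order)) {
    stop("subject ", sid, ": presented stimuli do not match the canonical ",
         "set (unknown or missing IDs)", call. = FALSE)
  }
  trials[match(canonical_order, ids)]
}

#' Latency: time to first cursor movement
#'
#' Time from trial onset to the first sample whose position differs from the
#' trial's initial cursor position. `NA` if the cursor never moves.
#'
#' @param trial An `mt_trial`.
#' @return Latency in ms, or `NA_real_`.
#' @export
compute_latency <- function(trial) {
  s <- trial$samples
  if (nrow(s) < 1L) return(NA_real_)
  moved <- which(s$x != s$x[1L] | s$y != s$y[1L])
  if (!length(moved)) return(NA_real_)
  s$t[moved[1L]] - trial$on_ready
}

#' Quality-control flags for one subject
#'
#' Never raises on bad data — surfacing bad data is its purpose. Two flags
#' are covariates rather than exclusion reasons: `weird_scaling` (some
#' trial's start-to-end horizontal displacement falls outside the tolerance
#' band around the expected half button separation, indicating browser zoom
#' or unusual pixel scaling) and `wts` (window too small on some trial, by
#' reported dimensions or alert code 4).
#'
#' Recorded latencies are cross-checked against recomputed ones; a
#' discrepancy larger than 50 ms is reported via [message()] (browser event
#' timing jitters) but is not a defect.
#'
#' @param subject An `mt_subject` from [segment_subject()].
#' @param geom An [geometry()].
#' @param dialect An [export_dialect()].
#' @return An object of class `mt_qcflags`: `subject_id`, `exclude`,
#'   `reasons`, `weird_scaling`, `wts`, `alert_counts` (named counts for
#'   codes 1-4), `n_intact_trials`, `n_dropped_samples`.
#' @export
flag_subject <- function(subject, geom = geometry(),
                         dialect = export_dialect()) {
  stopifnot(inherits(subject, "mt_subject"), inherits(geom, "mt_geometry"))
  reasons <- intersect(.defect_codes, subject$defects)

  expected_dx <- geom$button_separation_x / 2
  lo <- expected_dx * (1 - geom$scaling_tolerance)
  hi <- expected_dx * (1 + geom$scaling_tolerance)
  weird <- FALSE
  wts <- FALSE
  counts <- c(`1` = 0L, `2` = 0L, `3` = 0L, `4` = 0L)
  n_intact <- 0L
  n_latency_mismatch <- 0L

  for (tr in subject$trials) {
    s <- tr$samples
    if (nrow(s) >= 2L && !is.unsorted(s$t)) n_intact <- n_intact + 1L
    if (nrow(s) >= 2L) {
      dx <- abs(s$x[nrow(s)] - s$x[1L])
      if (dx < lo || dx > hi) weird <- TRUE
    }
    if ((!is.na(tr$window_width) && tr$window_width < geom$min_window_width) ||
        (!is.na(tr$window_height) && tr$window_height < geom$min_window_height) ||
        4L %in% tr$alert_codes) {
      wts <- TRUE
    }
    for (code in tr$alert_codes) {
      k <- as.character(code)
      if (k %in% names(counts)) counts[k] <- counts[k] + 1L
    }
    lat <- compute_latency(tr)
    if (!is.na(lat) && !is.na(tr$latency_recorded) &&
        abs(lat - tr$latency_recorded) > 50) {
      n_latency_mismatch <- n_latency_mismatch + 1L
    }
  }
  if (n_latency_mismatch > 0L) {
    message("subject ", subject$subject_id, ": recorded and recomputed ",
            "latency disagree by > 50 ms on ", n_latency_mismatch,
            " trial(s)")
  }

  structure(
    list(subject_id = subject$subject_id,
         exclude = length(reasons) > 0L,
         reasons = reasons,
         weird_scaling = weird,
         wts = wts,
         alert_counts = counts,
         n_intact_trials = n_intact,
         n_dropped_samples = subject$n_dropped_samples),
    class = "mt_qcflags"
  )
}

#' @export
print.mt_qcflags <- function(x, ...) {
  cat("<mt_qcflags> ", x$subject_id,
      if (x$exclude) " EXCLUDE" else " keep",
      if (length(x$reasons)) paste0(" (", paste(x$reasons, collapse = ", "), ")"),
      "; weird_scaling=", x$weird_scaling, ", wts=", x$wts, "\n", sep = "")
  invisible(x)
}

#' Apply the exclusion policy to a flagged cohort
#'
#' The conservative policy drops every subject with any defect on any trial;
#' the permissive policy drops only subjects with no intact trials at all.
#'
#' @param flags List of `mt_qcflags`, one per subject.
#' @param policy `"conservative"` (default) or `"permissive"`.
#' @return A list with `kept` (character vector of subject IDs) and `report`
#'   (data frame: subject_id, excluded, reasons, weird_scaling, wts,
#'   n_intact_trials).
#' @export
apply_exclusions <- function(flags, policy = c("conservative", "permissive")) {
  policy <- match.arg(policy)
  excluded <- vapply(flags, function(f) {
    if (policy == "conservative") length(f$reasons) > 0L
    else f$n_intact_trials == 0L
  }, logical(1))
  report <- data.frame(
    subject_id = vapply(flags, `[[`, character(1), "subject_id"),
    excluded = excluded,
    reasons = vapply(flags, function(f) paste(f$reasons, collapse = ";"),
                     character(1)),
    weird_scaling = vapply(flags, `[[`, logical(1), "weird_scaling"),
    wts = vapply(flags, `[[`, logical(1), "wts"),
    n_intact_trials = vapply(flags, `[[`, integer(1), "n_intact_trials"),
    stringsAsFactors = FALSE
  )
  list(kept = report$subject_id[!excluded], report = report, policy = policy)
}

#' Quality-control report as a JSON-ready list
#'
#' @param flags List of `mt_qcflags`.
#' @param exclusions Result of [apply_exclusions()] on the same flags.
#' @return A list with `summary` (totals, alert counts, percent of trials
#'   with no alerts) and `subjects` (per-subject flags and reasons), suitable
#'   for `jsonlite::write_json()`.
#' @export
qc_report <- function(flags, exclusions = apply_exclusions(flags)) {
  alert_totals <- Reduce(`+`, lapply(flags, `[[`, "alert_counts"))
  list(
    summary = list(
      n_subjects = length(flags),
      n_excluded = sum(exclusions$report$excluded),
      policy = exclusions$policy,
      n_weird_scaling = sum(exclusions$report$weird_scaling),
      n_wts = sum(exclusions$report$wts),
      alert_counts = as.list(alert_totals)
    ),
    subjects = lapply(flags, function(f) {
      list(subject_id = f$subject_id, exclude = f$exclude,
           reasons = f$reasons, weird_scaling = f$weird_scaling,
           wts = f$wts, alert_counts = as.list(f$alert_counts),
           n_intact_trials = f$n_intact_trials,
           n_dropped_samples = f$n_dropped_samples)
    })
  )
}
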