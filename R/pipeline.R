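#' Run the full processing pipeline on a raw export
#'
#' read -> segment -> QC flags -> exclusion policy -> reorder -> measures.
#' The long-format measures table contains only subjects kept by the
#' exclusion policy; the QC report covers everyone.
#'
#' @param raw An `mt_raw` data frame from [read_raw_export()], or a path to
#'   a raw export CSV.
#' @param dialect An [export_dialect()].
#' @param geom An [geometry()].
#' @param stimuli Optional data frame (`stimulus_id`, `ambiguous`) labelling
#'   the canonical stimulus set.
#' @param canonical_order Optional canonical stimulus order; defaults to
#'   `stimuli$stimulus_id` when given, else the sorted stimulus IDs observed
#'   in the data.
#' @param policy Exclusion policy, `"conservative"` or `"permissive"`.
#' @param options A [metric_options()].
#' @return List: `measures` (long table), `qc` (JSON-ready report),
#'   `exclusions`, `flags`, `subjects`, `alert_summary`.
#' @export
process_raw_export <- function(raw, dialect = export_dialect(),
                               geom = geometry(), stimuli = NULL,
                               canonical_order = NULL,
                               policy = c("conservative", "permissive"),
                               options = metric_options()) {
  policy <- match.arg(policy)
  if (is.character(raw)) raw <- read_raw_export(raw, dialect)
  subjects <- segment_trials(raw, dialect)
  flags <- lapply(subjects, flag_subject, geom = geom, dialect = dialect)
  excl <- apply_exclusions(flags, policy)
  keep <- vapply(subjects, function(s) s$subject_id %in% excl$kept, logical(1))

  if (is.null(canonical_order)) {
    canonical_order <- if (!is.null(stimuli)) stimuli$stimulus_id else {
      ids <- unique(unlist(lapply(subjects[keep], function(s)
        vapply(s$trials, `[[`, character(1), "stimulus_id"))))
      sort(ids)
    }
  }
  measures <- measures_long_table(subjects[keep], flags[keep],
                                  stimuli = stimuli,
                                  canonical_order = canonical_order,
                                  options = options)
  list(measures = measures,
       qc = qc_report(flags, excl),
       exclusions = excl,
       flags = flags,
       subjects = subjects,
       alert_summary = alert_summary(subjects))
}

#' Summarize alert messages across a cohort
#'
#' @param subjects List of `mt_subject`.
#' @return List: `n_trials`, `pct_no_alerts` (percent of trials with no
#'   alert), `counts` (total alerts by code 1-4), `pct_of_alerts` (each
#'   code's share of all alerts, percent).
#' @export
alert_summary <- function(subjects) {
  counts <- c(`1` = 0L, `2` = 0L, `3` = 0L, `4` = 0L)
  n_trials <- 0L
  n_clean <- 0L
  for (sub in subjects) {
    for (tr in sub$trials) {
      n_trials <- n_trials + 1L
      if (!length(tr$alert_codes)) n_clean <- n_clean + 1L
      for (code in tr$alert_codes) {
        k <- as.character(code)
        if (k %in% names(counts)) counts[k] <- counts[k] + 1L
      }
    }
  }
  total <- sum(counts)
  list(n_trials = n_trials,
       pct_no_alerts = if (n_trials) 100 * n_clean / n_trials else NA_real_,
       counts = counts,
       pct_of_alerts = if (total) 100 * counts / total else counts * NA_real_)
}

#' @rdname alert_summary
#' @param x Result of [alert_summary()].
#' @export
print_alert_summary <- function(x) {
  cat(sprintf("alerts: %.0f%% of %d trials received none\n",
              x$pct_no_alerts, x$n_trials))
  labels <- c("started too early", "started too late",
              "surpassed time limit", "window too small")
  for (k in 1:4) {
    cat(sprintf("  code %d (%s): %d\n", k, labels[k], x$counts[[k]]))
  }
  invisible(x)
}
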