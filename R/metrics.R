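#' @name metrics
#' @title Category-competition outcome measures
#'
#' @description
#' Five trial-level measures operationalize category competition. Three are
#' computed on trajectories rescaled to unit length per axis, so they are
#' unitless and comparable across display sizes: `xflips` (horizontal
#' direction reversals), `xdev` (maximum horizontal deviation from the ideal
#' straight-line trajectory), and `area` (Riemann-integrated horizontal gap
#' between actual and ideal trajectories). Two stay in raw units: `maxspeed`
#' (peak cursor speed, px/ms) and `rt` (trial onset to category click, ms).
#'
#' The ideal trajectory is the straight line from the trial's first to last
#' cursor position. Deviations are measured horizontally at matched vertical
#' progress: at each sample the ideal x is the line evaluated at that
#' sample's rescaled y (a time-parametrized variant is available via
#' [metric_options()]). Deviations are unsigned, so excursions on opposite
#' sides of the ideal line accumulate rather than cancel.
NULL

#' Options controlling metric computation
#'
#' @param jitter_threshold Differences with absolute value at or below this
#'   (on unit-scaled x) are discarded before counting x-flips; 0 means every
#'   strict sign reversal counts and exact zero steps are skipped.
#' @param riemann `"trapezoid"` (default) or `"left"` endpoint rule for the
#'   area integral.
#' @param parametrize `"y"` (default): deviations taken at matched vertical
#'   progress; `"time"`: at matched normalized time.
#' @return An object of class `mt_metric_options`.
#' @export
metric_options <- function(jitter_threshold = 0,
                           riemann = c("trapezoid", "left"),
                           parametrize = c("y", "time")) {
  stopifnot(jitter_threshold >= 0)
  structure(list(jitter_threshold = jitter_threshold,
                 riemann = match.arg(riemann),
                 parametrize = match.arg(parametrize)),
            class = "mt_metric_options")
}

new_norm <- function(x, y, t = NULL, tt = NULL, undefined = FALSE) {
  structure(list(x = x, y = y, t = t, tt = tt, undefined = undefined),
            class = "mt_norm")
}

rescale_axis <- function(v) {
  r <- range(v)
  if (r[1L] == r[2L]) return(rep(0, length(v)))  # degenerate axis
  (v - r[1L]) / (r[2L] - r[1L])
}

#' Rescale a trajectory to the unit square
#'
#' Per-axis affine min-max map onto [0, 1]. A degenerate axis (no movement)
#' maps to constant 0. Rescaling is idempotent and invariant to any uniform
#' zoom and translation of the raw coordinates.
#'
#' @param trial An `mt_trial`, or a data frame with columns `x`, `y` (and
#'   optionally `t`).
#' @return An object of class `mt_norm` with fields `x`, `y` in [0, 1] and
#'   raw `t` carried along; `undefined` is `TRUE` when there are fewer than
#'   2 samples (all measures on it become `NA`).
#' @export
rescale_space <- function(trial) {
  s <- if (inherits(trial, "mt_trial")) trial$samples else trial
  if (!is.data.frame(s) || nrow(s) < 2L) {
    return(new_norm(numeric(0), numeric(0), undefined = TRUE))
  }
  new_norm(rescale_axis(s$x), rescale_axis(s$y), t = s$t)
}

#' Rescale a trajectory in space and time
#'
#' As [rescale_space()], plus normalized time
#' `(t - on_ready) / (button_click - on_ready)` clipped to [0, 1], so
#' trajectories of different durations can be averaged or compared at
#' matched relative time.
#'
#' @param trial An `mt_trial`.
#' @return An `mt_norm` with additional field `tt`; `undefined` when the
#'   trial duration is not positive or there are fewer than 2 samples.
#' @export
rescale_time <- function(trial) {
  stopifnot(inherits(trial, "mt_trial"))
  norm <- rescale_space(trial)
  dur <- trial$button_click - trial$on_ready
  if (norm$undefined || is.na(dur) || dur <= 0) {
    norm$undefined <- TRUE
    return(norm)
  }
  norm$tt <- pmin(1, pmax(0, (trial$samples$t - trial$on_ready) / dur))
  norm
}

#' Count horizontal direction reversals (x-flips)
#'
#' Number of sign reversals in the successive differences of the x sequence,
#' after discarding differences no larger in absolute value than
#' `jitter_threshold`. Zero differences are skipped, never counted as
#' reversals.
#'
#' @param xs Numeric vector of (unit-scaled) x positions, length >= 2.
#' @param jitter_threshold See [metric_options()].
#' @return Integer count >= 0 (`NA_integer_` for fewer than 2 values).
#' @examples
#' count_xflips(c(0, 2, 1, 3))  # 2
#' @export
count_xflips <- function(xs, jitter_threshold = 0) {
  if (length(xs) < 2L) return(NA_integer_)
  d <- diff(xs)
  d <- d[abs(d) > jitter_threshold]
  if (length(d) < 2L) return(0L)
  s <- sign(d)
  sum(s[-1L] != s[-length(s)])
}

# unsigned horizontal deviations from the ideal line, parametrized by the
# chosen progress coordinate; NULL when the parametrization is degenerate
ideal_deviations <- function(norm, parametrize = "y") {
  if (norm$undefined) return(NULL)
  u <- if (parametrize == "time") norm$tt else norm$y
  if (is.null(u)) return(NULL)
  n <- length(norm$x)
  u1 <- u[1L]; un <- u[n]
  if (un == u1) return(NULL)  # no progress: line cannot be parametrized
  x1 <- norm$x[1L]; xn <- norm$x[n]
  ideal <- x1 + (xn - x1) * (u - u1) / (un - u1)
  list(d = abs(norm$x - ideal), u = u)
}

#' Maximum horizontal deviation from the ideal trajectory
#'
#' Largest unsigned horizontal distance between the unit-scaled trajectory
#' and the straight line from its start to its end, evaluated at each
#' sample's vertical progress (the line is extended beyond its endpoints for
#' out-of-range progress values).
#'
#' @param norm An `mt_norm` from [rescale_space()].
#' @param options A [metric_options()].
#' @return Unitless deviation >= 0, or `NA_real_` when undefined (fewer than
#'   2 samples, or start and end share the same progress coordinate).
#' @export
max_x_deviation <- function(norm, options = metric_options()) {
  dev <- ideal_deviations(norm, options$parametrize)
  if (is.null(dev)) return(NA_real_)
  max(dev$d)
}

#' Area between actual and ideal trajectories
#'
#' Riemann sum of the unsigned horizontal deviation over vertical progress:
#' the trapezoidal rule sums `((d_i + d_{i+1}) / 2) * |u_{i+1} - u_i|` over
#' successive samples (a left-endpoint rule is available via
#' [metric_options()]). Unsigned deviations make excursions on both sides of
#' the ideal line add up.
#'
#' @inheritParams max_x_deviation
#' @return Unitless area >= 0, or `NA_real_` when undefined.
#' @export
riemann_area <- function(norm, options = metric_options()) {
  dev <- ideal_deviations(norm, options$parametrize)
  if (is.null(dev)) return(NA_real_)
  d <- dev$d
  du <- abs(diff(dev$u))
  n <- length(d)
  if (options$riemann == "trapezoid") {
    sum((d[-n] + d[-1L]) / 2 * du)
  } else {
    sum(d[-n] * du)
  }
}

#' Peak cursor speed
#'
#' Maximum over consecutive sample pairs of Euclidean displacement divided
#' by the time increment, in raw pixel coordinates (px/ms). Pairs with zero
#' time increment are skipped.
#'
#' @param trial An `mt_trial`.
#' @return Speed in px/ms, or `NA_real_` when no positive time increment
#'   exists.
#' @export
max_speed <- function(trial) {
  s <- trial$samples
  if (nrow(s) < 2L) return(NA_real_)
  dt <- diff(s$t)
  keep <- dt > 0
  if (!any(keep)) return(NA_real_)
  disp <- sqrt(diff(s$x)^2 + diff(s$y)^2)
  max(disp[keep] / dt[keep])
}

#' Reaction time
#'
#' Time from trial onset (page fully loaded) to the category-button click.
#'
#' @param trial An `mt_trial`.
#' @return Duration in ms (>= 0).
#' @export
reaction_time <- function(trial) {
  rt <- trial$button_click - trial$on_ready
  if (is.na(rt)) return(NA_real_)
  if (rt < 0) {
    stop("subject ", trial$subject_id, ", stimulus ", trial$stimulus_id,
         ": button click precedes trial onset", call. = FALSE)
  }
  rt
}

#' All five measures for one trial
#'
#' @param trial An `mt_trial`.
#' @param options A [metric_options()].
#' @return One-row data frame with columns `xflips`, `xdev`, `area`,
#'   `maxspeed`, `rt`, `latency`; undefined measures are `NA`.
#' @export
trial_measures <- function(trial, options = metric_options()) {
  norm <- if (options$parametrize == "time") rescale_time(trial)
          else rescale_space(trial)
  data.frame(
    xflips = if (norm$undefined) NA_integer_
             else count_xflips(norm$x, options$jitter_threshold),
    xdev = max_x_deviation(norm, options),
    area = riemann_area(norm, options),
    maxspeed = max_speed(trial),
    rt = reaction_time(trial),
    latency = compute_latency(trial)
  )
}

#' Long-format trial-level measures table
#'
#' One row per subject x stimulus, carrying the five outcome measures, the
#' stimulus-ambiguity indicator, the subject-wide QC covariates
#' (`weird_scaling`, `wts`), alert codes, and browser metadata. Rows for
#' measure-undefined trials carry explicit `NA`s.
#'
#' @param subjects List of `mt_subject` (already filtered by the exclusion
#'   policy if desired).
#' @param flags List of `mt_qcflags` aligned with `subjects`; computed with
#'   default geometry when omitted.
#' @param stimuli Optional data frame with columns `stimulus_id` and
#'   `ambiguous` (0/1); when omitted `ambiguous` is `NA`.
#' @param canonical_order Optional stimulus ID vector; when supplied each
#'   subject's trials are reordered to it via [reorder_by_stimulus()].
#' @param options A [metric_options()].
#' @return Data frame with one row per trial: `subject_id`, `stimulus_id`,
#'   `presented_index`, `ambiguous`, `xflips`, `xdev`, `area`, `maxspeed`,
#'   `rt`, `latency`, `weird_scaling`, `wts`, `alerts`, `browser`,
#'   `operating_system`.
#' @export
measures_long_table <- function(subjects, flags = NULL, stimuli = NULL,
                                canonical_order = NULL,
                                options = metric_options()) {
  if (is.null(flags)) flags <- lapply(subjects, flag_subject)
  stopifnot(length(flags) == length(subjects))
  rows <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    sub <- subjects[[i]]
    fl <- flags[[i]]
    trials <- sub$trials
    if (!is.null(canonical_order)) {
      trials <- reorder_by_stimulus(trials, canonical_order)
    }
    if (!length(trials)) next
    meas <- do.call(rbind, lapply(trials, trial_measures, options = options))
    rows[[i]] <- cbind(
      data.frame(
        subject_id = sub$subject_id,
        stimulus_id = vapply(trials, `[[`, character(1), "stimulus_id"),
        presented_index = vapply(trials, `[[`, integer(1), "presented_index"),
        stringsAsFactors = FALSE
      ),
      meas,
      data.frame(
        weird_scaling = as.integer(fl$weird_scaling),
        wts = as.integer(fl$wts),
        alerts = vapply(trials, function(tr)
          paste(tr$alert_codes, collapse = ";"), character(1)),
        browser = sub$browser,
        operating_system = sub$operating_system,
        stringsAsFactors = FALSE
      )
    )
  }
  out <- do.call(rbind, compact(rows))
  if (is.null(out)) {
    out <- data.frame(subject_id = character(0), stimulus_id = character(0),
                      presented_index = integer(0))
  }
  if (!is.null(stimuli)) {
    stopifnot(all(c("stimulus_id", "ambiguous") %in% names(stimuli)))
    out$ambiguous <- stimuli$ambiguous[match(out$stimulus_id,
                                             stimuli$stimulus_id)]
  } else if (!"ambiguous" %in% names(out)) {
    out$ambiguous <- NA_integer_
  }
  amb_first <- c("subject_id", "stimulus_id", "presented_index", "ambiguous")
  out <- out[, c(amb_first, setdiff(names(out), amb_first)), drop = FALSE]
  rownames(out) <- NULL
  out
}
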