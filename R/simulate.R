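#' @name simulate
#' @title Synthetic cohorts for pipeline validation
#'
#' @description
#' Generates cursor trajectories from a two-attractor dynamics model: the
#' cursor starts on the Next button, and after a planted latency moves
#' toward the currently active category button at constant speed with
#' Gaussian positional noise. On ambiguous trials the active attractor
#' switches between the two buttons as a Poisson process until a commit
#' time, after which the cursor heads to the finally chosen button; on
#' unambiguous trials the attractor is fixed from the start. This
#' reproduces the qualitative signatures of category competition — more
#' direction reversals, larger deviation and area, higher peak speed, and
#' longer reaction times on ambiguous trials — with interpretable knobs.
#'
#' [simulate_dataset()] additionally serializes cohorts into the raw export
#' dialect (separator-joined streams, per-trial timing fields, randomized
#' stimulus order) and injects the idiosyncrasies seen in online data
#' collection: browser zoom (non-standard pixel scaling), too-small windows,
#' spurious "started too early" alerts, and wholesale coordinate-stream
#' loss. Alert codes are assigned by applying the interface's rules to the
#' generated timings: code 2 when latency exceeds 700 ms, code 3 when the
#' trial exceeds 5000 ms, code 4 when the window is too small.
NULL

#' Simulation configuration
#'
#' Defaults describe a realistic crowdsourced cohort: 10 recorded trials
#' (half ambiguous), cursor sampling every 16-18 ms, mean first-move latency
#' 442 ms, and idiosyncrasy rates of about 10% too-small windows, 40%
#' non-standard scaling, and 10% coordinate data loss.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials Recorded trials per subject (default 10).
#' @param n_practice Practice trials (not recorded; default 6).
#' @param ambiguous_fraction Fraction of stimuli that are ambiguous
#'   (default 0.5).
#' @param geometry An [geometry()]; button positions derive from it, with
#'   the Next button at (`next_x`, `next_y`).
#' @param next_x,next_y Pixel position of the Next button (cursor start).
#' @param dt_ms,dt_jitter_ms Mean sampling interval and uniform jitter
#'   (default 17 +/- 1 ms).
#' @param speed_px_per_ms Baseline cursor speed toward the active attractor.
#' @param time_pressure Linear growth rate of cursor speed per second of
#'   elapsed movement time (subjects speed up as a trial drags on, so late
#'   — post-deliberation — movements are faster; this is what makes peak
#'   speed sensitive to ambiguity).
#' @param noise_sd_px Gaussian positional noise per step (px, per axis).
#' @param switch_hazard_per_ms Attractor-switch rate on ambiguous trials
#'   (0 on unambiguous trials).
#' @param commit_mean_ms,commit_sd_ms Normal (truncated at 0) distribution
#'   of the additional deliberation time before an ambiguous trial commits
#'   to a category.
#' @param latency_mean_ms Mean of the (exponential, truncated at
#'   `latency_max_ms`) planted first-move latency.
#' @param latency_max_ms Upper truncation for latency draws.
#' @param alert_latency_ms Latency threshold above which a trial receives
#'   the "started too late" alert, code 2 (default 700 ms).
#' @param alert_rt_ms Answer-time limit above which a trial receives the
#'   "took too long" alert, code 3 (default 5000 ms).
#' @param p_alert1 Per-trial probability of a spurious "started too early"
#'   alert (code 1), independent of the dynamics.
#' @param p_small_window Per-subject probability of a too-small browser
#'   window (alert code 4 on the first trial, undersized reported window).
#' @param p_zoom Per-subject probability of non-standard pixel scaling; a
#'   zoom factor is drawn from `zoom_factors` and applied to all
#'   coordinates.
#' @param zoom_factors Candidate zoom factors (all far enough from 1 to be
#'   detectable).
#' @param p_data_loss Per-subject probability that the coordinate streams
#'   are lost entirely (absent cells in the export).
#' @param click_radius_px Distance from the button center at which the
#'   click registers.
#' @param max_trial_ms Guard against non-terminating trials; generation
#'   fails with an error if a cursor cannot reach a button in this time.
#' @param intertrial_gap_ms Pause between a trial's page submit and the
#'   next trial's onset.
#' @param time_origin_ms Epoch origin for absolute timestamps (arbitrary;
#'   only differences matter downstream).
#' @param seed Integer seed; fully determines the generated cohort.
#' @return An object of class `mt_sim_config`.
#' @export
sim_config <- function(n_subjects = 188,
                       n_trials = 10,
                       n_practice = 6,
                       ambiguous_fraction = 0.5,
                       geometry = mousetrackr::geometry(),
                       next_x = 683, next_y = 700,
                       dt_ms = 17, dt_jitter_ms = 1,
                       speed_px_per_ms = 0.8,
                       time_pressure = 0.3,
                       noise_sd_px = 3,
                       switch_hazard_per_ms = 0.004,
                       commit_mean_ms = 900, commit_sd_ms = 300,
                       latency_mean_ms = 442,
                       latency_max_ms = 2500,
                       alert_latency_ms = 700,
                       alert_rt_ms = 5000,
                       p_alert1 = 0.1,
                       p_small_window = 0.10,
                       p_zoom = 0.40,
                       zoom_factors = c(0.6, 0.7, 1.4, 1.6),
                       p_data_loss = 0.10,
                       click_radius_px = 15,
                       max_trial_ms = 20000,
                       intertrial_gap_ms = 800,
                       time_origin_ms = 1.5e12,
                       seed = NULL) {
  stopifnot(all(c(p_alert1, p_small_window, p_zoom, p_data_loss,
                  ambiguous_fraction) >= 0),
            all(c(p_alert1, p_small_window, p_zoom, p_data_loss,
                  ambiguous_fraction) <= 1),
            dt_ms > 0, speed_px_per_ms > 0, n_trials >= 1,
            click_radius_px > 0)
  structure(as.list(environment()), class = "mt_sim_config")
}

#' @export
print.mt_sim_config <- function(x, ...) {
  cat("<mt_sim_config> ", x$n_subjects, " subjects x ", x$n_trials,
      " trials; hazard ", x$switch_hazard_per_ms, "/ms; idiosyncrasies: ",
      "zoom ", x$p_zoom, ", small window ", x$p_small_window,
      ", data loss ", x$p_data_loss, "\n", sep = "")
  invisible(x)
}

button_positions <- function(config) {
  half <- config$geometry$button_separation_x / 2
  by <- config$next_y - config$geometry$next_to_buttons_y
  list(left = c(config$next_x - half, by),
       right = c(config$next_x + half, by),
       next_btn = c(config$next_x, config$next_y))
}

#' Simulate one trial's cursor trajectory
#'
#' Uses the calling environment's RNG stream; callers seed it.
#'
#' @param ambiguous Logical; switches the attractor dynamics on.
#' @param config An [sim_config()].
#' @param on_ready Trial onset time (ms since epoch).
#' @return List: `samples` (data frame x, y, t, integer px/ms),
#'   `button_click`, `chosen` ("left"/"right"), `latency` (observable
#'   first-move latency on the sampling grid), `n_switches`.
#' @export
simulate_trajectory <- function(ambiguous, config, on_ready = config$time_origin_ms) {
  btn <- button_positions(config)
  pos <- btn$next_btn
  side <- if (stats::runif(1) < 0.5) "left" else "right"
  latency <- min(stats::rexp(1, 1 / config$latency_mean_ms),
                 config$latency_max_ms)
  commit_after <- if (ambiguous) {
    latency + max(0, stats::rnorm(1, config$commit_mean_ms,
                                  config$commit_sd_ms))
  } else {
    latency
  }
  hazard <- if (ambiguous) config$switch_hazard_per_ms else 0

  # preallocate sample arrays and pre-draw per-step randomness in chunks;
  # the dynamics loop itself is then scalar arithmetic only
  cap <- 512L
  xs <- ys <- ts <- numeric(cap)
  draw_chunk <- function(m) {
    jit <- if (config$dt_jitter_ms > 0) {
      sample.int(2L * config$dt_jitter_ms + 1L, m, replace = TRUE) -
        config$dt_jitter_ms - 1L
    } else integer(m)
    list(jit = jit,
         nx = stats::rnorm(m, 0, config$noise_sd_px),
         ny = stats::rnorm(m, 0, config$noise_sd_px),
         u = stats::runif(m))
  }
  rnd <- draw_chunk(cap)

  t <- 0
  xs[1L] <- pos[1L]; ys[1L] <- pos[2L]; ts[1L] <- 0
  k <- 1L
  n_switches <- 0L
  first_move_t <- NA_real_
  speed <- config$speed_px_per_ms
  radius <- config$click_radius_px
  repeat {
    if (k >= length(rnd$jit)) {
      more <- draw_chunk(length(rnd$jit))
      rnd <- Map(c, rnd, more)
      length(xs) <- length(ys) <- length(ts) <- length(rnd$jit) + 1L
    }
    dt <- config$dt_ms + rnd$jit[k]
    t <- t + dt
    if (t > config$max_trial_ms) {
      stop("simulated trial failed to reach a button within ",
           config$max_trial_ms, " ms; check speed/noise/geometry settings",
           call. = FALSE)
    }
    if (t >= latency) {
      if (hazard > 0 && t < commit_after &&
          rnd$u[k] < 1 - exp(-hazard * dt)) {
        side <- if (side == "left") "right" else "left"
        n_switches <- n_switches + 1L
      }
      target <- btn[[side]]
      gx <- target[1L] - pos[1L]; gy <- target[2L] - pos[2L]
      dist <- sqrt(gx * gx + gy * gy)
      step <- speed * (1 + config$time_pressure * (t - latency) / 1000) * dt
      if (dist <= step) {
        pos <- target
      } else {
        pos <- c(pos[1L] + gx / dist * step, pos[2L] + gy / dist * step)
      }
      pos <- c(pos[1L] + rnd$nx[k], pos[2L] + rnd$ny[k])
      if (is.na(first_move_t)) first_move_t <- t
    }
    k <- k + 1L
    xs[k] <- pos[1L]; ys[k] <- pos[2L]; ts[k] <- t
    if (t >= commit_after) {
      endg <- btn[[side]]
      dx <- pos[1L] - endg[1L]; dy <- pos[2L] - endg[2L]
      if (sqrt(dx * dx + dy * dy) <= radius) break
    }
  }
  samples <- data.frame(x = round(xs[seq_len(k)]), y = round(ys[seq_len(k)]),
                        t = on_ready + ts[seq_len(k)])
  list(samples = samples,
       button_click = on_ready + t,
       chosen = side,
       latency = first_move_t,
       n_switches = n_switches)
}

#' Simulate a full cohort and serialize it as a raw export
#'
#' Generates every subject's trials, assigns alert codes from the generated
#' timings (code 2: latency > 700 ms; code 3: duration > 5000 ms; code 4:
#' too-small window; code 1: independent Bernoulli), applies per-subject
#' zoom factors to all coordinates, deletes coordinate streams for
#' data-loss subjects, and serializes everything into the wide export
#' dialect with a randomized stimulus order per subject.
#'
#' @param config An [sim_config()].
#' @param dialect An [export_dialect()] (its `n_trials` should match the
#'   config).
#' @return List with `records` (an `mt_raw` data frame, ready for
#'   [write_raw_export()]), and `truth`: `trials` (per-trial ground truth:
#'   ambiguity, chosen side, sample count, latency, duration, switch count,
#'   alert codes), `subjects` (per-subject zoom / small-window / data-loss
#'   assignments and browser metadata), and `stimuli` (canonical stimulus
#'   set with ambiguity labels).
#' @export
simulate_dataset <- function(config = sim_config(),
                             dialect = export_dialect(n_trials = config$n_trials)) {
  stopifnot(inherits(config, "mt_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  n_amb <- round(config$ambiguous_fraction * config$n_trials)
  stimuli <- data.frame(
    stimulus_id = sprintf("S%02d", seq_len(config$n_trials)),
    ambiguous = rep(c(0L, 1L),
                    c(config$n_trials - n_amb, n_amb)),
    stringsAsFactors = FALSE
  )

  alert_threshold_latency <- config$alert_latency_ms
  alert_threshold_rt <- config$alert_rt_ms

  rec_rows <- vector("list", config$n_subjects)
  truth_rows <- vector("list", config$n_subjects)
  subj_rows <- vector("list", config$n_subjects)

  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("P%04d", i)
    zoom <- if (stats::runif(1) < config$p_zoom)
      sample(config$zoom_factors, 1L) else 1
    small_window <- stats::runif(1) < config$p_small_window
    data_loss <- stats::runif(1) < config$p_data_loss
    browser <- sample(c("Chrome", "Firefox", "Edge"), 1L,
                      prob = c(0.81, 0.18, 0.01))
    os <- sample(c("Windows", "Macintosh", "Linux", "Chrome OS"), 1L,
                 prob = c(0.82, 0.10, 0.04, 0.04))
    if (small_window) {
      ww <- 640; wh <- 480
    } else {
      ww <- sample(c(1366, 1532, 1846), 1L)
      wh <- sample(c(726, 775, 938), 1L)
    }

    order_idx <- sample.int(config$n_trials)
    presented <- stimuli[order_idx, ]

    t_cursor <- config$time_origin_ms + (i - 1) * 3.6e6
    on_load <- on_ready <- click <- submit <- numeric(config$n_trials)
    lat_rec <- numeric(config$n_trials)
    alert_tokens <- character(config$n_trials)
    chosen <- character(config$n_trials)
    all_x <- all_y <- all_t <- numeric(0)
    tr_truth <- vector("list", config$n_trials)

    for (j in seq_len(config$n_trials)) {
      on_load[j] <- t_cursor
      on_ready[j] <- t_cursor + round(stats::runif(1, 150, 400))
      tr <- simulate_trajectory(presented$ambiguous[j] == 1L, config,
                                on_ready = on_ready[j])
      click[j] <- tr$button_click
      submit[j] <- click[j] + round(stats::runif(1, 300, 900))
      t_cursor <- submit[j] + config$intertrial_gap_ms
      lat_rec[j] <- tr$latency
      chosen[j] <- tr$chosen

      codes <- integer(0)
      if (stats::runif(1) < config$p_alert1) codes <- c(codes, 1L)
      if (tr$latency > alert_threshold_latency) codes <- c(codes, 2L)
      if (click[j] - on_ready[j] > alert_threshold_rt) codes <- c(codes, 3L)
      if (small_window && j == 1L) codes <- c(codes, 4L)
      alert_tokens[j] <- if (length(codes)) paste(codes, collapse = "")
                         else "0"

      s <- tr$samples
      if (zoom != 1) {
        s$x <- round(s$x * zoom)
        s$y <- round(s$y * zoom)
      }
      all_x <- c(all_x, s$x); all_y <- c(all_y, s$y); all_t <- c(all_t, s$t)

      tr_truth[[j]] <- data.frame(
        subject_id = sid, presented_index = j,
        stimulus_id = presented$stimulus_id[j],
        ambiguous = presented$ambiguous[j],
        chosen = tr$chosen,
        n_samples = nrow(s),
        latency_ms = tr$latency,
        duration_ms = click[j] - on_ready[j],
        n_switches = tr$n_switches,
        alerts = alert_tokens[j],
        zoom = zoom, small_window = small_window, data_loss = data_loss,
        stringsAsFactors = FALSE
      )
    }

    rec_rows[[i]] <- data.frame(
      subject_id = sid,
      x_stream = if (data_loss) NA_character_ else join_stream(all_x, dialect),
      y_stream = if (data_loss) NA_character_ else join_stream(all_y, dialect),
      t_stream = if (data_loss) NA_character_ else join_stream(all_t, dialect),
      on_load_times = join_stream(on_load, dialect),
      on_ready_times = join_stream(on_ready, dialect),
      button_click_times = join_stream(click, dialect),
      page_submit_times = join_stream(submit, dialect),
      window_widths = join_stream(rep(ww, config$n_trials), dialect),
      window_heights = join_stream(rep(wh, config$n_trials), dialect),
      alerts_stream = join_stream(alert_tokens, dialect),
      latency_stream = join_stream(lat_rec, dialect),
      stimulus_order = join_stream(presented$stimulus_id, dialect),
      chosen_categories = join_stream(chosen, dialect),
      browser = browser,
      browser_version = "100.0",
      operating_system = os,
      resolution = paste0(ww, "x", wh),
      stringsAsFactors = FALSE
    )
    truth_rows[[i]] <- do.call(rbind, tr_truth)
    subj_rows[[i]] <- data.frame(
      subject_id = sid, zoom = zoom, small_window = small_window,
      data_loss = data_loss, browser = browser, operating_system = os,
      stringsAsFactors = FALSE
    )
  }

  records <- do.call(rbind, rec_rows)
  if (is.null(records)) {
    records <- data.frame(matrix(character(0), nrow = 0,
                                 ncol = length(default_column_map()),
                                 dimnames = list(NULL,
                                                 names(default_column_map()))),
                          stringsAsFactors = FALSE)
  }
  structure(
    list(records = structure(records, class = c("mt_raw", "data.frame"),
                             dialect = dialect),
         truth = list(trials = do.call(rbind, truth_rows),
                      subjects = do.call(rbind, subj_rows),
                      stimuli = stimuli)),
    class = "mt_simulation"
  )
}

#' @export
print.mt_simulation <- function(x, ...) {
  cat("<mt_simulation> ", nrow(x$truth$subjects), " subjects, ",
      nrow(x$truth$trials), " trials\n", sep = "")
  invisible(x)
}
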