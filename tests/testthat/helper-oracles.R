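# Brute-force reference implementations of the outcome measures, written as
# plain loops directly from the definitions. They are deliberately
# independent of the package's vectorized code paths.

oracle_xflips <- function(xs, thr = 0) {
  d <- diff(xs)
  d <- d[abs(d) > thr]
  if (length(d) < 2L) return(0L)
  flips <- 0L
  for (i in 2:length(d)) {
    if (sign(d[i]) != sign(d[i - 1L])) flips <- flips + 1L
  }
  flips
}

# ideal x at progress u, line through first and last sample
oracle_ideal <- function(x, y, u) {
  n <- length(x)
  x[1L] + (x[n] - x[1L]) * (u - y[1L]) / (y[n] - y[1L])
}

oracle_xdev <- function(x, y) {
  best <- 0
  for (i in seq_along(x)) {
    d <- abs(x[i] - oracle_ideal(x, y, y[i]))
    if (d > best) best <- d
  }
  best
}

oracle_area <- function(x, y) {
  total <- 0
  for (i in seq_len(length(x) - 1L)) {
    d1 <- abs(x[i] - oracle_ideal(x, y, y[i]))
    d2 <- abs(x[i + 1L] - oracle_ideal(x, y, y[i + 1L]))
    total <- total + (d1 + d2) / 2 * abs(y[i + 1L] - y[i])
  }
  total
}

oracle_maxspeed <- function(x, y, t) {
  best <- -Inf
  for (i in seq_len(length(x) - 1L)) {
    dt <- t[i + 1L] - t[i]
    if (dt > 0) {
      v <- sqrt((x[i + 1L] - x[i])^2 + (y[i + 1L] - y[i])^2) / dt
      if (v > best) best <- v
    }
  }
  best
}

# random raw trajectory with distinct first/last y after normalization
random_trajectory <- function(n = 25) {
  repeat {
    x <- cumsum(stats::rnorm(n, 0, 20)) + 500
    y <- cumsum(stats::rnorm(n, -10, 15)) + 700
    if (diff(range(y)) > 0 && y[1L] != y[n]) break
  }
  t <- 1.5e12 + cumsum(sample(16:18, n, replace = TRUE))
  data.frame(x = x, y = y, t = t)
}

make_trial <- function(samples, on_ready = samples$t[1L],
                       button_click = samples$t[nrow(samples)],
                       stimulus_id = "S01", subject_id = "P0001",
                       presented_index = 1L, ...) {
  mousetrackr:::new_trial(subject_id = subject_id,
                          presented_index = presented_index,
                          stimulus_id = stimulus_id, samples = samples,
                          on_ready = on_ready, button_click = button_click,
                          ...)
}

# hand-built raw record with two trials for segmentation tests
make_two_trial_record <- function(extra_t = numeric(0)) {
  d <- export_dialect(n_trials = 2)
  t1 <- seq(1000, 2000, by = 100)
  t2 <- seq(3000, 4000, by = 100)
  ts <- c(t1, extra_t, t2)
  n <- length(ts)
  list(
    subject_id = "P0001",
    x_stream = join_stream(seq(500, by = 10, length.out = n), d),
    y_stream = join_stream(seq(700, by = -20, length.out = n), d),
    t_stream = join_stream(ts, d),
    on_ready_times = join_stream(c(1000, 3000), d),
    button_click_times = join_stream(c(2000, 4000), d),
    window_widths = join_stream(c(1500, 1500), d),
    window_heights = join_stream(c(800, 800), d),
    alerts_stream = join_stream(c("0", "2"), d),
    latency_stream = join_stream(c(100, 100), d),
    stimulus_order = join_stream(c("S02", "S01"), d),
    chosen_categories = join_stream(c("left", "right"), d),
    browser = "Chrome", browser_version = "100",
    operating_system = "Windows", resolution = "1500x800"
  )
}

clean_sim_config <- function(n_subjects, seed, ...) {
  sim_config(n_subjects = n_subjects, p_zoom = 0, p_small_window = 0,
             p_data_loss = 0, p_alert1 = 0, seed = seed, ...)
}
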