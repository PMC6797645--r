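test_that("spatial rescaling maps each axis onto the unit interval", {
  s <- data.frame(x = c(100, 385, 670), y = c(700, 500, 300),
                  t = c(0, 17, 34))
  norm <- rescale_space(s)
  expect_equal(norm$x, c(0, 0.5, 1))
  expect_equal(norm$y, c(1, 0.5, 0))
  # idempotence
  twice <- rescale_space(data.frame(x = norm$x, y = norm$y, t = s$t))
  expect_equal(twice$x, norm$x)
  expect_equal(twice$y, norm$y)
  # degenerate axis maps to 0
  flat <- rescale_space(data.frame(x = c(5, 5, 5), y = c(0, 1, 2),
                                   t = c(0, 1, 2)))
  expect_equal(flat$x, c(0, 0, 0))
  # fewer than 2 samples is undefined
  expect_true(rescale_space(data.frame(x = 1, y = 1, t = 1))$undefined)
})

test_that("rescaled space is invariant to zoom and translation", {
  set.seed(61)
  for (i in 1:30) {
    s <- random_trajectory(20)
    zoom <- stats::runif(1, 0.2, 4)
    shift <- stats::rnorm(2, 0, 300)
    z <- data.frame(x = s$x * zoom + shift[1], y = s$y * zoom + shift[2],
                    t = s$t)
    expect_equal(rescale_space(z)$x, rescale_space(s)$x, tolerance = 1e-9)
    expect_equal(rescale_space(z)$y, rescale_space(s)$y, tolerance = 1e-9)
  }
})

test_that("time rescaling fixes endpoints and preserves order", {
  s <- data.frame(x = c(0, 1, 2), y = c(0, 1, 2), t = c(1000, 1500, 2000))
  tr <- make_trial(s, on_ready = 1000, button_click = 2000)
  norm <- rescale_time(tr)
  expect_equal(norm$tt, c(0, 0.5, 1))
  set.seed(62)
  for (i in 1:20) {
    s <- random_trajectory(15)
    tr <- make_trial(s)
    tt <- rescale_time(tr)$tt
    expect_true(all(diff(tt) >= 0))
    expect_equal(tt[1], 0)
    expect_equal(tt[length(tt)], 1)
  }
  # zero duration is undefined
  flat <- make_trial(s, on_ready = s$t[1], button_click = s$t[1])
  expect_true(rescale_time(flat)$undefined)
})

test_that("x-flip counting matches hand-worked cases", {
  expect_identical(count_xflips(c(0, 1, 2, 3)), 0L)
  expect_identical(count_xflips(c(0, 2, 1, 3)), 2L)
  expect_identical(count_xflips(c(0, 1, 1, 2)), 0L)
  expect_identical(count_xflips(c(3, 2, 1)), 0L)
  expect_identical(count_xflips(c(0, 1, 0, 1, 0)), 3L)
  expect_identical(count_xflips(c(5, 5, 5)), 0L)
  # jitter threshold discards small wiggles
  expect_identical(count_xflips(c(0, 0.5, 0.45, 1), jitter_threshold = 0.1),
                   0L)
  expect_identical(count_xflips(c(0, 0.5, 0.45, 1)), 2L)
})

test_that("maximum deviation matches hand-worked cases", {
  # trajectory on the ideal line deviates by zero
  on_line <- rescale_space(data.frame(x = c(0, 0.25, 0.5, 1),
                                      y = c(0, 0.25, 0.5, 1), t = 1:4))
  expect_equal(max_x_deviation(on_line), 0)
  # start (0,0), end (1,1), sample (0.8, 0.5): ideal x at y=0.5 is 0.5
  tri <- rescale_space(data.frame(x = c(0, 0.8, 1), y = c(0, 0.5, 1),
                                  t = 1:3))
  expect_equal(max_x_deviation(tri), 0.3, tolerance = 1e-12)
  # no vertical progress between endpoints is undefined
  loop <- rescale_space(data.frame(x = c(0, 1, 0.5), y = c(0, 1, 0),
                                   t = 1:3))
  expect_true(is.na(max_x_deviation(loop)))
})

test_that("Riemann area matches the hand-worked trapezoid sum", {
  on_line <- rescale_space(data.frame(x = c(0, 0.5, 1), y = c(0, 0.5, 1),
                                      t = 1:3))
  expect_equal(riemann_area(on_line), 0)
  five <- rescale_space(data.frame(x = c(0, 0.45, 0.7, 0.95, 1),
                                   y = c(0, 0.25, 0.5, 0.75, 1), t = 1:5))
  expect_equal(riemann_area(five), 0.15, tolerance = 1e-12)
  # asymmetric spacing separates the trapezoid rule from the left rule:
  # deviations (0, 0.65, 0) at y = (0, 0.25, 1)
  asym <- rescale_space(data.frame(x = c(0, 0.9, 1), y = c(0, 0.25, 1),
                                   t = 1:3))
  expect_equal(riemann_area(asym), 0.65 / 2 * 0.25 + 0.65 / 2 * 0.75,
               tolerance = 1e-12)
  expect_equal(riemann_area(asym, metric_options(riemann = "left")),
               0 * 0.25 + 0.65 * 0.75, tolerance = 1e-12)
})

test_that("area refines stably under denser sampling of a smooth path", {
  path <- function(n) {
    y <- seq(0, 1, length.out = n)
    data.frame(x = y + 0.3 * sin(pi * y), y = y, t = seq_len(n))
  }
  a200 <- riemann_area(rescale_space(path(200)))
  a400 <- riemann_area(rescale_space(path(400)))
  # deviations from the diagonal are 0.3 sin(pi y); the integral is 0.6/pi
  expect_equal(a200, 0.6 / pi, tolerance = 1e-3)
  expect_lt(abs(a400 - a200), 1e-4)
})

test_that("peak speed matches hand-worked cases and skips zero intervals", {
  tr <- make_trial(data.frame(x = c(0, 30), y = c(0, 40), t = c(0, 10)))
  expect_equal(max_speed(tr), 5)
  still <- make_trial(data.frame(x = c(7, 7, 7), y = c(7, 7, 7),
                                 t = c(0, 10, 20)))
  expect_equal(max_speed(still), 0)
  dup <- make_trial(data.frame(x = c(0, 5, 30), y = c(0, 5, 40),
                               t = c(0, 0, 10)))
  expect_equal(max_speed(dup), sqrt(25^2 + 35^2) / 10)
  all_dup <- make_trial(data.frame(x = c(0, 5), y = c(0, 5), t = c(5, 5)))
  expect_true(is.na(max_speed(all_dup)))
})

test_that("reaction time is the onset-to-click difference", {
  tr <- make_trial(data.frame(x = c(0, 1), y = c(0, 1),
                              t = c(1e9, 1e9 + 1500)),
                   on_ready = 1e9, button_click = 1e9 + 1500)
  expect_equal(reaction_time(tr), 1500)
  boundary <- make_trial(data.frame(x = 0, y = 0, t = 1e9),
                         on_ready = 1e9, button_click = 1e9)
  expect_equal(reaction_time(boundary), 0)
  bad <- make_trial(data.frame(x = 0, y = 0, t = 1e9),
                    on_ready = 1e9, button_click = 1e9 - 1)
  expect_error(reaction_time(bad), "precedes")
})

test_that("normalized measures equal brute-force references on random paths", {
  set.seed(71)
  for (i in 1:200) {
    s <- random_trajectory(sample(5:40, 1))
    norm <- rescale_space(s)
    expect_identical(count_xflips(norm$x), oracle_xflips(norm$x))
    if (norm$y[1] != norm$y[length(norm$y)]) {
      expect_equal(max_x_deviation(norm), oracle_xdev(norm$x, norm$y),
                   tolerance = 1e-12)
      expect_equal(riemann_area(norm), oracle_area(norm$x, norm$y),
                   tolerance = 1e-12)
    }
    tr <- make_trial(s)
    expect_equal(max_speed(tr), oracle_maxspeed(s$x, s$y, s$t),
                 tolerance = 1e-12)
  }
})

test_that("area is bounded by max deviation times total y variation", {
  set.seed(72)
  for (i in 1:50) {
    norm <- rescale_space(random_trajectory(sample(5:30, 1)))
    if (norm$y[1] == norm$y[length(norm$y)]) next
    tv <- sum(abs(diff(norm$y)))
    expect_lte(riemann_area(norm), max_x_deviation(norm) * tv + 1e-12)
  }
})

test_that("the long table has one row per subject-stimulus with QC attached", {
  sim <- simulate_dataset(clean_sim_config(6, seed = 81))
  subs <- segment_trials(sim$records)
  tab <- measures_long_table(subs, stimuli = sim$truth$stimuli,
                             canonical_order = sim$truth$stimuli$stimulus_id)
  expect_identical(nrow(tab), 60L)
  expect_identical(tab$stimulus_id,
                   rep(sim$truth$stimuli$stimulus_id, 6))
  expect_true(all(tab$ambiguous %in% 0:1))
  expect_true(all(!is.na(tab$xdev)))
  expect_true(all(tab$rt > 0))

  # single subject, single trial
  one <- make_trial(data.frame(x = c(0, 1), y = c(0, 2), t = c(0, 17)))
  sub <- structure(list(subject_id = "P0001", trials = list(one),
                        defects = character(0), n_parsed_samples = 2L,
                        n_dropped_samples = 0L, browser = NA,
                        browser_version = NA, operating_system = NA,
                        resolution = NA),
                   class = "mt_subject")
  expect_identical(nrow(measures_long_table(list(sub))), 1L)
})

test_that("row counts equal the number of intact trials on defective cohorts", {
  sim <- simulate_dataset(sim_config(n_subjects = 25, p_data_loss = 0.2,
                                     seed = 82))
  subs <- segment_trials(sim$records)
  flags <- lapply(subs, flag_subject)
  tab <- measures_long_table(subs, flags, stimuli = sim$truth$stimuli)
  expect_identical(nrow(tab), nrow(sim$truth$trials))
  # data-loss subjects contribute rows with missing trajectory measures
  lost <- sim$truth$subjects$subject_id[sim$truth$subjects$data_loss]
  expect_true(length(lost) > 0)
  expect_true(all(is.na(tab$xdev[tab$subject_id %in% lost])))
  expect_false(anyNA(tab$xdev[!tab$subject_id %in% lost]))
})

test_that("measures are zoom- and translation-invariant where they must be", {
  set.seed(91)
  for (i in 1:25) {
    s <- random_trajectory(20)
    tr <- make_trial(s)
    zoom <- stats::runif(1, 0.3, 3)
    shift <- stats::rnorm(2, 0, 500)
    z <- make_trial(data.frame(x = s$x * zoom + shift[1],
                               y = s$y * zoom + shift[2], t = s$t))
    m1 <- trial_measures(tr)
    m2 <- trial_measures(z)
    expect_identical(m1$xflips, m2$xflips)
    expect_equal(m1$xdev, m2$xdev, tolerance = 1e-9)
    expect_equal(m1$area, m2$area, tolerance = 1e-9)
    expect_equal(m2$maxspeed, m1$maxspeed * zoom, tolerance = 1e-12)
    expect_identical(m1$rt, m2$rt)
  }
})
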