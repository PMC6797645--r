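test_that("samples are assigned to trials by closed time windows", {
  d <- export_dialect(n_trials = 2)
  sub <- segment_subject(make_two_trial_record(), d)
  expect_length(sub$trials, 2L)
  expect_identical(sub$defects, character(0))
  expect_equal(nrow(sub$trials[[1]]$samples), 11L)
  expect_equal(nrow(sub$trials[[2]]$samples), 11L)
  expect_equal(sub$n_dropped_samples, 0L)
  # boundary samples belong to the trial
  expect_equal(sub$trials[[1]]$samples$t[1], 1000)
  expect_equal(sub$trials[[1]]$samples$t[11], 2000)
  expect_identical(sub$trials[[1]]$alert_codes, integer(0))
  expect_identical(sub$trials[[2]]$alert_codes, 2L)
})

test_that("samples outside every window are dropped and counted", {
  d <- export_dialect(n_trials = 2)
  sub <- segment_subject(make_two_trial_record(extra_t = 2500), d)
  expect_equal(sub$n_dropped_samples, 1L)
  expect_equal(sub$n_parsed_samples, 23L)
  expect_equal(sum(vapply(sub$trials, function(tr) nrow(tr$samples),
                          integer(1))), 22L)
})

test_that("segmentation conserves samples on simulated cohorts", {
  sim <- simulate_dataset(clean_sim_config(10, seed = 31))
  subs <- segment_trials(sim$records)
  for (sub in subs) {
    assigned <- sum(vapply(sub$trials, function(tr) nrow(tr$samples),
                           integer(1)))
    expect_identical(assigned + sub$n_dropped_samples, sub$n_parsed_samples)
  }
})

test_that("stream defects are flagged, never fatal", {
  d <- export_dialect(n_trials = 2)
  rec <- make_two_trial_record()

  r1 <- rec; r1$x_stream <- NA_character_
  expect_identical(segment_subject(r1, d)$defects, "missing_trajectory")

  r2 <- rec
  r2$x_stream <- join_stream(1:5, d)  # shorter than y/t
  expect_true("stream_length_mismatch" %in% segment_subject(r2, d)$defects)

  r3 <- rec
  ts <- parse_separated_stream(rec$t_stream, d)
  ts[3:4] <- ts[4:3]
  r3$t_stream <- join_stream(ts, d)
  expect_true("nonmonotone_time" %in% segment_subject(r3, d)$defects)

  r4 <- rec
  r4$on_ready_times <- join_stream(1000, d)
  r4$button_click_times <- join_stream(2000, d)
  expect_true("wrong_trial_count" %in% segment_subject(r4, d)$defects)
})

test_that("reordering inverts the presentation permutation", {
  d <- export_dialect(n_trials = 2)
  sub <- segment_subject(make_two_trial_record(), d)  # presented S02, S01
  out <- reorder_by_stimulus(sub$trials, c("S01", "S02"))
  expect_identical(vapply(out, `[[`, character(1), "stimulus_id"),
                   c("S01", "S02"))
  expect_identical(vapply(out, `[[`, integer(1), "presented_index"),
                   c(2L, 1L))
  # identity order is a no-op
  same <- reorder_by_stimulus(sub$trials, c("S02", "S01"))
  expect_identical(same, sub$trials)
})

test_that("reordering is a pure permutation over random orders", {
  set.seed(41)
  canonical <- sprintf("S%02d", 1:8)
  for (i in 1:20) {
    perm <- sample(canonical)
    trials <- lapply(seq_along(perm), function(j) {
      make_trial(data.frame(x = c(0, 1), y = c(0, 1), t = c(0, 17)),
                 stimulus_id = perm[j], presented_index = j)
    })
    out <- reorder_by_stimulus(trials, canonical)
    expect_identical(vapply(out, `[[`, character(1), "stimulus_id"),
                     canonical)
    # multiset of trials unchanged: sort back by presented_index
    back <- out[order(vapply(out, `[[`, integer(1), "presented_index"))]
    expect_identical(back, trials)
  }
})

test_that("reordering rejects unknown and duplicate stimuli by subject", {
  trials <- lapply(1:2, function(j) {
    make_trial(data.frame(x = c(0, 1), y = c(0, 1), t = c(0, 17)),
               stimulus_id = "S01", presented_index = j,
               subject_id = "P0099")
  })
  expect_error(reorder_by_stimulus(trials, c("S01", "S02")),
               "P0099.*duplicate")
  trials[[2]]$stimulus_id <- "WAT"
  expect_error(reorder_by_stimulus(trials, c("S01", "S02")), "P0099")
})

test_that("latency is the first position change relative to onset", {
  still <- make_trial(data.frame(x = rep(5, 4), y = rep(5, 4),
                                 t = c(1000, 1017, 1034, 1051)),
                      on_ready = 1000, button_click = 1051)
  expect_true(is.na(compute_latency(still)))

  moving <- make_trial(data.frame(x = c(5, 5, 9, 12), y = c(5, 5, 5, 8),
                                  t = c(1000, 1425, 1442, 1459)),
                       on_ready = 1000, button_click = 1459)
  expect_equal(compute_latency(moving), 442)
})

test_that("weird_scaling flags displacements outside the tolerance band", {
  g <- geometry()  # expected half-separation 285, tolerance 0.25
  mk <- function(dx) {
    samples <- data.frame(x = c(100, 100 + dx), y = c(700, 228),
                          t = c(1000, 2000))
    structure(list(subject_id = "P1",
                   trials = list(make_trial(samples)),
                   defects = character(0), n_parsed_samples = 2L,
                   n_dropped_samples = 0L, browser = NA, browser_version = NA,
                   operating_system = NA, resolution = NA),
              class = "mt_subject")
  }
  expect_false(flag_subject(mk(285), g)$weird_scaling)
  expect_false(flag_subject(mk(-285), g)$weird_scaling)
  expect_true(flag_subject(mk(100), g)$weird_scaling)
  expect_true(flag_subject(mk(500), g)$weird_scaling)
  # band edges are inclusive
  expect_false(flag_subject(mk(285 * 0.75), g)$weird_scaling)
  expect_false(flag_subject(mk(285 * 1.25), g)$weird_scaling)
  expect_true(flag_subject(mk(285 * 0.7499), g)$weird_scaling)
})

test_that("wts flags small windows and alert code 4", {
  g <- geometry()
  base <- make_two_trial_record()
  d <- export_dialect(n_trials = 2)
  expect_false(flag_subject(segment_subject(base, d), g)$wts)

  small <- base
  small$window_widths <- join_stream(c(640, 640), d)
  expect_true(flag_subject(segment_subject(small, d), g)$wts)

  alerted <- base
  alerted$alerts_stream <- join_stream(c("4", "0"), d)
  fl <- flag_subject(segment_subject(alerted, d), g)
  expect_true(fl$wts)
  expect_equal(fl$alert_counts[["4"]], 1L)
})

test_that("defects imply exclusion under the conservative policy only", {
  d <- export_dialect(n_trials = 2)
  clean <- segment_subject(make_two_trial_record(), d)
  broken <- make_two_trial_record()
  broken$x_stream <- NA_character_
  broken$subject_id <- "P0002"
  broken_sub <- segment_subject(broken, d)

  flags <- list(flag_subject(clean), flag_subject(broken_sub))
  expect_false(flags[[1]]$exclude)
  expect_true(flags[[2]]$exclude)
  expect_identical(flags[[2]]$reasons, "missing_trajectory")

  cons <- apply_exclusions(flags, "conservative")
  expect_identical(cons$kept, "P0001")
  # the broken subject still has zero intact trials, so permissive also drops
  perm <- apply_exclusions(flags, "permissive")
  expect_identical(perm$kept, "P0001")

  # a subject with one bad and one good trial survives permissive only
  half <- make_two_trial_record()
  half$subject_id <- "P0003"
  ts <- parse_separated_stream(half$t_stream, d)
  keep <- ts <= 2000
  half$t_stream <- join_stream(ts[keep], d)
  half$x_stream <- join_stream(parse_separated_stream(half$x_stream, d)[keep], d)
  half$y_stream <- join_stream(parse_separated_stream(half$y_stream, d)[keep], d)
  half_fl <- flag_subject(segment_subject(half, d))
  expect_true(half_fl$exclude)
  expect_identical(apply_exclusions(list(half_fl), "conservative")$kept,
                   character(0))
  expect_identical(apply_exclusions(list(half_fl), "permissive")$kept,
                   "P0003")
})

test_that("QC flags are monotone: corrupting a trial never clears a flag", {
  d <- export_dialect(n_trials = 2)
  rec <- make_two_trial_record()
  base_reasons <- flag_subject(segment_subject(rec, d))$reasons
  worse <- rec
  worse$x_stream <- join_stream(
    parse_separated_stream(rec$x_stream, d)[1:15], d)
  worse_reasons <- flag_subject(segment_subject(worse, d))$reasons
  expect_true(all(base_reasons %in% worse_reasons))
  expect_gt(length(worse_reasons), length(base_reasons))
})

test_that("clean simulated cohorts produce no flags at all", {
  sim <- simulate_dataset(clean_sim_config(15, seed = 51))
  res <- process_raw_export(sim$records, stimuli = sim$truth$stimuli)
  rep <- res$exclusions$report
  expect_identical(sum(rep$excluded), 0L)
  expect_identical(sum(rep$weird_scaling), 0L)
  expect_identical(sum(rep$wts), 0L)
})

test_that("latency mismatches beyond 50 ms are reported as messages", {
  d <- export_dialect(n_trials = 2)
  rec <- make_two_trial_record()
  rec$latency_stream <- join_stream(c(5000, 5000), d)
  expect_message(flag_subject(segment_subject(rec, d)), "latency disagree")
})
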