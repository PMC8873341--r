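test_that("default schedule reproduces the paradigm's timeline", {
  s <- build_schedule()
  expect_equal(nrow(s$series), 9)
  expect_equal(unique(s$series$instruction_s + s$series$task_s +
                        s$series$rest_s), 62)
  expect_equal(s$total_duration_s, 558)
  expect_equal(s$n_trials, 180)
  expect_equal(length(s$label_track), 5580)  # 558 s x 10 Hz
  # fixed order within every session
  expect_equal(s$series$label,
               rep(c("0-back", "2-back", "3-back"), 3))
})

test_that("single-series schedule and validation errors behave", {
  s <- build_schedule(sessions = 1, series_per_session = 1)
  expect_equal(s$total_duration_s, 62)
  expect_equal(s$n_trials, 20)
  expect_error(build_schedule(task_s = -1), "positive")
  expect_error(build_schedule(sessions = 0), "integer")
})

test_that("label track partitions time with no overlap", {
  for (fs in c(10, 10.4)) {
    s <- build_schedule(sampling_rate = fs)
    expect_equal(length(s$label_track), round(558 * fs))
    counts <- table(s$label_track)
    expect_equal(sum(counts), length(s$label_track))
    # per-class task samples: 3 series x 40 s each (to grid resolution)
    for (cls in c("0-back", "2-back", "3-back")) {
      expect_lt(abs(counts[[cls]] - 3 * 40 * fs), 3)
    }
    expect_lt(abs(counts[["rest"]] - 9 * 20 * fs), 9)
    expect_lt(abs(counts[["instruction"]] - 9 * 2 * fs), 9)
  }
  # at the default 10 Hz grid the segmentation is exact
  s10 <- build_schedule()
  counts <- table(s10$label_track)
  expect_equal(unname(counts[c("0-back", "2-back", "3-back")]),
               rep(1200L, 3), ignore_attr = TRUE)
  expect_equal(counts[["rest"]], 1800L)
  expect_equal(counts[["instruction"]], 180L)
})

test_that("zero amplitudes and zero noise give an identically zero series", {
  prof <- subject_profile("z", amplitudes = c("0-back" = 0, "2-back" = 0,
                                              "3-back" = 0),
                          channel_gains = rep(1, 3),
                          noise = list(mayer = 0, respiratory = 0,
                                       cardiac = 0, white = 0),
                          rng_seed = 1)
  hemo <- hemodynamic_forward(tiny_schedule(), prof)
  expect_equal(max(abs(hemo$data)), 0)
})

test_that("a single task block peaks near the configured amplitude, where the HRF puts it", {
  sched <- build_schedule(sessions = 1, series_per_session = 1,
                          series_labels = "2-back")
  prof <- subject_profile("p", amplitudes = c("2-back" = 0.8),
                          channel_gains = 1,
                          noise = list(white = 0), rng_seed = 1,
                          enforce_monotone = FALSE)
  hemo <- hemodynamic_forward(sched, prof)
  hbo <- hemo$data[1, 1, ]
  # independent oracle: direct discrete convolution of the boxcar
  box <- ifelse(sched$label_track == "2-back", 0.8, 0)
  kern <- hrf_kernel(10)
  n <- length(box)
  oracle <- vapply(seq_len(n), function(i) {
    j <- seq_len(min(i, length(kern)))
    sum(kern[j] * box[i - j + 1])
  }, numeric(1))
  expect_equal(hbo, oracle, tolerance = 1e-10)
  expect_equal(max(hbo), 0.8, tolerance = 1e-6)  # unit-peak step response
  # peak falls inside the block-plus-delay interval
  peak_t <- (which.max(hbo) - 1) / 10
  expect_gt(peak_t, 2)
  expect_lt(peak_t, 2 + 40 + 15)
  # HbR is the scaled negative of HbO
  expect_equal(hemo$data[1, 2, ], -hbo / 3, tolerance = 1e-10)
})

test_that("same profile and seed give bitwise-identical realizations", {
  p <- clean_profile(4, seed = 11)
  a <- hemodynamic_forward(tiny_schedule(), p)
  b <- hemodynamic_forward(tiny_schedule(), p)
  expect_identical(a$data, b$data)
})

test_that("raising a class amplitude raises its task-window variance", {
  sched <- tiny_schedule()
  mk <- function(a3) {
    p <- subject_profile("m", amplitudes = c("0-back" = 0.2, "2-back" = 0.4,
                                             "3-back" = a3),
                         channel_gains = rep(1, 2),
                         noise = list(mayer = 0.1, white = 0.1),
                         rng_seed = 5)
    hemodynamic_forward(sched, p)
  }
  v <- vapply(c(0.5, 1.0, 2.0), function(a3) {
    h <- mk(a3)
    var(h$data[1, 1, sched$label_track == "3-back"])
  }, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("cohorts are reproducible and have the advertised geometry", {
  a <- make_cohort(n_subjects = 3, schedule = tiny_schedule(),
                   n_channels = 6, master_seed = 42)
  b <- make_cohort(n_subjects = 3, schedule = tiny_schedule(),
                   n_channels = 6, master_seed = 42)
  expect_identical(a$subjects[[2]]$optical$data, b$subjects[[2]]$optical$data)
  expect_equal(dim(a$subjects[[1]]$optical$data), c(6, 2, 3720))
  expect_error(make_cohort(n_subjects = 0), "integer")
  # degenerate population: zero spread means shared class amplitudes
  pop <- default_population()
  pop$amplitude_sd <- 0
  cc <- make_cohort(n_subjects = 2, schedule = tiny_schedule(),
                    n_channels = 4, population = pop, master_seed = 9)
  expect_equal(cc$subjects[[1]]$profile$amplitudes,
               cc$subjects[[2]]$profile$amplitudes)
})

test_that("default cohort matches the emulated acquisition", {
  cohort <- make_cohort(n_subjects = 26, master_seed = 1)
  expect_length(cohort$subjects, 26)
  dims <- vapply(cohort$subjects, function(s) dim(s$optical$data),
                 integer(3))
  expect_true(all(dims[1, ] == 36))
  expect_true(all(dims[2, ] == 2))
  expect_true(all(dims[3, ] == 5580))
})
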