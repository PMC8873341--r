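sine_hemo <- function(freq, n = 4000, fs = 10, amp = 1) {
  t <- (seq_len(n) - 1) / fs
  structure(list(data = array(rep(amp * sin(2 * pi * freq * t), each = 2),
                              dim = c(1, 2, n)),
                 sampling_rate = fs, subject_id = "x", filtered = FALSE,
                 schedule = NULL),
            class = "hemo_recording")
}

mid_amplitude <- function(x) {
  core <- x[seq(round(length(x) * 0.25), round(length(x) * 0.75))]
  (max(core) - min(core)) / 2
}

# amplitude of the f-Hz component over the middle half (integer periods),
# extracted by projection onto the quadrature pair
projected_amplitude <- function(x, f, fs) {
  per <- round(fs / f)
  start <- round(length(x) * 0.25)
  len <- (round(length(x) * 0.5) %/% per) * per
  core <- x[start + seq_len(len) - 1]
  t <- (start + seq_len(len) - 2) / fs
  2 * sqrt(mean(core * sin(2 * pi * f * t))^2 +
             mean(core * cos(2 * pi * f * t))^2)
}

test_that("a constant signal passes the low-pass unchanged", {
  h <- sine_hemo(0)  # zero signal
  h$data[] <- 3.7
  out <- lowpass_filter(h)
  expect_true(out$filtered)
  expect_equal(dim(out$data), dim(h$data))
  expect_lt(max(abs(out$data - 3.7)), 1e-9)
})

test_that("stopband attenuation matches the analytic two-pass magnitude", {
  filt <- design_lowpass(0.2, 10, 4)
  for (f in c(0.5, 1)) {
    h <- sine_hemo(f)
    out <- lowpass_filter(h, 0.2)
    measured <- projected_amplitude(out$data[1, 1, ], f, 10)
    expected <- filter_magnitude(filt, f)^2  # forward + backward pass
    expect_equal(measured, expected, tolerance = 0.01)
  }
})

test_that("the 0.05 Hz passband is preserved and filtering is idempotent there", {
  h <- sine_hemo(0.05)
  once <- lowpass_filter(h, 0.2)
  a1 <- mid_amplitude(once$data[1, 1, ])
  expect_equal(a1, 1, tolerance = 0.01)
  twice <- lowpass_filter(once, 0.2)
  a2 <- mid_amplitude(twice$data[1, 1, ])
  expect_lt(abs(a2 - a1) / a1, 0.02)
})

test_that("cutoffs at or above Nyquist are rejected", {
  expect_error(lowpass_filter(sine_hemo(0.05), cutoff_hz = 5), "Nyquist")
  expect_error(design_lowpass(-1, 10), "positive")
})

test_that("window counts follow floor((segment - window)/step) + 1", {
  sched <- tiny_schedule()
  hemo <- hemodynamic_forward(sched, clean_profile(2))
  ep <- segment_epochs(hemo, window_s = 10, step_s = 5)
  # 6 task segments of 40 s -> 7 windows each
  expect_equal(dim(ep$x)[1], 6 * 7)
  expect_equal(as.vector(table(ep$labels)), c(14, 14, 14))
  # window = segment length -> exactly one window per segment
  ep1 <- segment_epochs(hemo, window_s = 40, step_s = 5)
  expect_equal(dim(ep1$x)[1], 6)
  # 4-class mode adds the 20 s rest segments: floor((20-10)/5)+1 = 3 each
  ep4 <- segment_epochs(hemo, window_s = 10, step_s = 5,
                        class_mode = "4class")
  expect_equal(dim(ep4$x)[1], 6 * 7 + 6 * 3)
  expect_true("rest" %in% levels(ep4$labels))
  # exhaustive epoch-count law over a parameter grid
  for (w in c(5, 10, 20)) {
    for (st in c(2, 5, 10)) {
      e <- segment_epochs(hemo, window_s = w, step_s = st)
      expect_equal(dim(e$x)[1], 6 * (floor((40 - w) / st) + 1))
    }
  }
})

test_that("no window straddles a segment boundary", {
  sched <- tiny_schedule()
  hemo <- hemodynamic_forward(sched, clean_profile(2))
  ep <- segment_epochs(hemo, window_s = 10, step_s = 5,
                       class_mode = "4class")
  wlen <- 10 * sched$sampling_rate
  for (e in seq_along(ep$labels)) {
    span <- sched$label_track[ep$onset_sample[e] + seq_len(wlen) - 1]
    expect_equal(unique(span), as.character(ep$labels[e]))
  }
})

test_that("3-class mode contains no rest windows and errors when nothing fits", {
  hemo <- hemodynamic_forward(tiny_schedule(), clean_profile(2))
  ep <- segment_epochs(hemo, window_s = 10, step_s = 5)
  expect_setequal(levels(ep$labels), c("0-back", "2-back", "3-back"))
  expect_error(segment_epochs(hemo, window_s = 50, step_s = 5), "no epochs")
})

test_that("windows inherit the recording's values and decimation subsamples", {
  hemo <- hemodynamic_forward(tiny_schedule(), clean_profile(2))
  ep <- segment_epochs(hemo, window_s = 10, step_s = 5, decimate = 5)
  expect_equal(dim(ep$x)[4], 20)
  e1 <- ep$x[1, , , ]
  manual <- hemo$data[, , ep$onset_sample[1] + seq(1, 100, by = 5) - 1]
  expect_equal(e1, manual, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ep$sampling_rate, 2)
})

test_that("z-scoring uses training statistics only", {
  ep <- tiny_epochs()
  n <- dim(ep$x)[1]
  tr <- seq_len(floor(n / 2))
  normed <- normalize_examples(ep, "zscore", train_idx = tr)
  xt <- normed$x[tr, , , ]
  expect_lt(max(abs(apply(xt, 2:3, mean))), 1e-10)
  expect_lt(max(abs(apply(xt, 2:3, sd) - 1)), 1e-6)
  # applying train statistics to a shifted set leaves the shift visible
  shifted <- ep
  shifted$x <- shifted$x + 5
  out <- normalize_examples(shifted, "zscore", stats = normed$norm_stats)
  expect_gt(mean(out$x), 1)
  # identity scheme
  same <- normalize_examples(ep, "none")
  expect_equal(same$x, ep$x)
})

test_that("zero-variance channels are epsilon-guarded with a warning", {
  ep <- tiny_epochs()
  ep$x[, 1, 1, ] <- 2
  expect_warning(normalize_examples(ep, "zscore"), "zero-variance")
})
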