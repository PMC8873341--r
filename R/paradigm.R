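#' Build an n-back block schedule
#'
#' Constructs the session/series/trial timeline of the n-back working-memory
#' paradigm: each series starts with a short instruction screen, continues
#' with a block of trials at one workload level, and ends with rest. With the
#' defaults (3 sessions of 3 series; 2 s instruction + 40 s task + 20 s rest;
#' 20 trials per series) a subject performs 9 series of 62 s each, 180 trials
#' in total. Within a session the series always run in the fixed order
#' 0-back, 2-back, 3-back.
#'
#' @param sessions Number of recording sessions.
#' @param series_per_session Number of series per session.
#' @param sampling_rate Sampling rate in Hz used for the per-sample label
#'   track.
#' @param instruction_s,task_s,rest_s Durations of the three segments of a
#'   series, in seconds.
#' @param trials_per_series Number of trials inside the task segment.
#' @param series_labels Workload labels cycled over the series of a session,
#'   in presentation order.
#' @return A `block_schedule` object: the per-series table (`series`), the
#'   per-sample label track (`label_track`, one of the workload labels,
#'   `"rest"`, or `"instruction"`), the total duration and trial count.
#' @examples
#' sched <- build_schedule()
#' sched$total_duration_s  # 558
#' table(sched$label_track)
#' @export
build_schedule <- function(sessions = 3,
                           series_per_session = 3,
                           sampling_rate = 10,
                           instruction_s = 2,
                           task_s = 40,
                           rest_s = 20,
                           trials_per_series = 20,
                           series_labels = c("0-back", "2-back", "3-back")) {
  sessions <- stop_if_not_count(sessions, "sessions")
  series_per_session <- stop_if_not_count(series_per_session,
                                          "series_per_session")
  trials_per_series <- stop_if_not_count(trials_per_series,
                                         "trials_per_series")
  stop_if_not_positive(sampling_rate, "sampling_rate")
  stop_if_not_positive(instruction_s, "instruction_s")
  stop_if_not_positive(task_s, "task_s")
  stop_if_not_positive(rest_s, "rest_s")
  if (length(series_labels) < 1) stop("`series_labels` must be non-empty")

  n_series <- sessions * series_per_session
  series_duration <- instruction_s + task_s + rest_s
  labels <- rep_len(series_labels, series_per_session)
  series <- data.frame(
    series_index = seq_len(n_series),
    session = rep(seq_len(sessions), each = series_per_session),
    series_in_session = rep(seq_len(series_per_session), sessions),
    label = rep(labels, sessions),
    instruction_s = instruction_s,
    task_s = task_s,
    rest_s = rest_s,
    n_trials = trials_per_series,
    onset_s = (seq_len(n_series) - 1) * series_duration,
    stringsAsFactors = FALSE
  )

  # per-sample labels on a global time grid: sample i covers time
  # ((i-0.5)/fs), so the track has exactly round(total * fs) samples and
  # the segments partition it without overlap at any sampling rate
  seg_labels <- as.vector(rbind("instruction", series$label, "rest"))
  seg_series <- rep(series$series_index, each = 3)
  seg_ends <- cumsum(rep(c(instruction_s, task_s, rest_s), n_series))
  n_samples <- round(n_series * series_duration * sampling_rate)
  t_mid <- (seq_len(n_samples) - 0.5) / sampling_rate
  seg_of <- findInterval(t_mid, c(0, seg_ends), rightmost.closed = TRUE)
  label_track <- seg_labels[seg_of]

  out <- list(
    sampling_rate = sampling_rate,
    sessions = sessions,
    series_per_session = series_per_session,
    series = series,
    series_labels = unique(labels),
    label_track = label_track,
    series_track = seg_series[seg_of],
    total_duration_s = n_series * series_duration,
    n_trials = n_series * trials_per_series
  )
  class(out) <- "block_schedule"
  out
}

#' @export
print.block_schedule <- function(x, ...) {
  cat(sprintf(
    "n-back block schedule: %d sessions x %d series (%g s each), %g s total\n",
    x$sessions, x$series_per_session,
    x$series$instruction_s[1] + x$series$task_s[1] + x$series$rest_s[1],
    x$total_duration_s))
  cat(sprintf("  %d trials; labels: %s; label track of %d samples at %g Hz\n",
              x$n_trials, paste(x$series_labels, collapse = ", "),
              length(x$label_track), x$sampling_rate))
  invisible(x)
}

#' Canonical double-gamma haemodynamic response kernel
#'
#' Difference of two gamma densities (peak and late undershoot), sampled at
#' the given rate and scaled so that the peak of its step response is one:
#' a sustained activation of amplitude A therefore produces a response that
#' peaks at A.
#'
#' @param sampling_rate Hz.
#' @param peak_delay_s Delay of the response peak (gamma shape, seconds).
#' @param undershoot_delay_s Delay of the undershoot (seconds).
#' @param undershoot_ratio Relative amplitude of the undershoot.
#' @param duration_s Length of the sampled kernel in seconds.
#' @return Numeric vector of kernel weights.
#' @export
hrf_kernel <- function(sampling_rate,
                       peak_delay_s = 6,
                       undershoot_delay_s = 16,
                       undershoot_ratio = 1 / 6,
                       duration_s = 32) {
  t <- seq(0, duration_s, by = 1 / sampling_rate)
  h <- dgamma(t, shape = peak_delay_s, rate = 1) -
    undershoot_ratio * dgamma(t, shape = undershoot_delay_s, rate = 1)
  h / max(cumsum(h))
}

#' Describe one synthetic subject
#'
#' Bundles everything subject-specific in the forward model: per-class peak
#' HbO amplitudes (in micromolar), haemodynamic response timing, per-channel
#' gains, physiological noise amplitudes, and the RNG seed that fixes the
#' whole realization.
#'
#' @param subject_id Identifier string or integer.
#' @param amplitudes Named numeric vector of peak HbO amplitudes (uM) per
#'   workload class; rest contributes no activation.
#' @param channel_gains Positive multiplier per channel on the activation
#'   signal (spatial sensitivity profile).
#' @param systemic_gains Per-channel sensitivity to the channel-coherent
#'   systemic physiology (superficial scalp contribution); defaults to 1.
#' @param noise Named list of amplitudes: `mayer`, `respiratory`, `cardiac`
#'   (sinusoid amplitudes, uM) and `white` (white-noise sd, uM).
#' @param noise_freqs Subject-specific frequencies (Hz) of the sinusoidal
#'   components.
#' @param hrf_peak_delay_s,hrf_undershoot_delay_s,hrf_undershoot_ratio
#'   Haemodynamic response parameters (see [hrf_kernel()]).
#' @param hbr_ratio HbR is modelled as `-hbr_ratio * HbO`.
#' @param rng_seed Integer seed fixing noise phases and white noise.
#' @param enforce_monotone If `TRUE` (default), amplitudes are sorted so that
#'   a higher workload class never has a smaller amplitude.
#' @return A `subject_profile` object.
#' @export
subject_profile <- function(subject_id,
                            amplitudes = c("0-back" = 0.3, "2-back" = 0.45,
                                           "3-back" = 0.6),
                            channel_gains = rep(1, 36),
                            systemic_gains = rep(1, length(channel_gains)),
                            noise = list(mayer = 0.5, respiratory = 0.2,
                                         cardiac = 0.2, white = 0.3),
                            noise_freqs = c(mayer = 0.1, respiratory = 0.3,
                                            cardiac = 1.1),
                            hrf_peak_delay_s = 6,
                            hrf_undershoot_delay_s = 16,
                            hrf_undershoot_ratio = 1 / 6,
                            hbr_ratio = 1 / 3,
                            rng_seed = 1L,
                            enforce_monotone = TRUE) {
  if (is.null(names(amplitudes)) || any(!nzchar(names(amplitudes)))) {
    stop("`amplitudes` must be a named vector (one entry per class)")
  }
  if (enforce_monotone) {
    amplitudes[] <- sort(amplitudes)
  }
  noise <- lapply(noise, as.numeric)
  if (any(unlist(noise) < 0)) stop("noise amplitudes must be >= 0")
  if (any(channel_gains < 0)) stop("channel gains must be >= 0")
  if (length(systemic_gains) != length(channel_gains)) {
    stop("`systemic_gains` must have one entry per channel")
  }
  out <- list(subject_id = subject_id,
              amplitudes = amplitudes,
              channel_gains = channel_gains,
              systemic_gains = systemic_gains,
              noise = noise,
              noise_freqs = noise_freqs,
              hrf_peak_delay_s = hrf_peak_delay_s,
              hrf_undershoot_delay_s = hrf_undershoot_delay_s,
              hrf_undershoot_ratio = hrf_undershoot_ratio,
              hbr_ratio = hbr_ratio,
              rng_seed = as.integer(rng_seed))
  class(out) <- "subject_profile"
  out
}

#' Simulate haemoglobin concentration time series for one subject
#'
#' Forward haemodynamic model: a per-class boxcar over the task blocks
#' (amplitude set by the subject's class amplitudes, scaled per channel by
#' the gain vector) convolved with the double-gamma haemodynamic response
#' kernel gives the HbO activation; HbR activation is its scaled negative.
#' On top of the activation, every channel receives systemic physiological
#' noise — Mayer waves, respiration and cardiac pulsation as sinusoids at
#' the profile's subject-specific frequencies with one shared random phase
#' per component, scaled per channel by the systemic gain vector (systemic
#' physiology is coherent across the optode array, so it cannot be averaged
#' away over channels) — plus independent white noise per channel and
#' chromophore. HbR noise is the HbO systemic noise scaled by the HbR
#' ratio, with its own white noise. The realization is a pure function of
#' the profile's seed.
#'
#' @param schedule A [build_schedule()] object.
#' @param profile A [subject_profile()] object.
#' @return A `hemo_recording`: `data` is a channels x 2 (HbO, HbR) x samples
#'   array in uM, plus sampling rate and provenance.
#' @export
hemodynamic_forward <- function(schedule, profile) {
  stopifnot(inherits(schedule, "block_schedule"),
            inherits(profile, "subject_profile"))
  fs <- schedule$sampling_rate
  n <- length(schedule$label_track)
  n_ch <- length(profile$channel_gains)

  box <- rep(0, n)
  for (cls in names(profile$amplitudes)) {
    box[schedule$label_track == cls] <- profile$amplitudes[[cls]]
  }
  kern <- hrf_kernel(fs,
                     peak_delay_s = profile$hrf_peak_delay_s,
                     undershoot_delay_s = profile$hrf_undershoot_delay_s,
                     undershoot_ratio = profile$hrf_undershoot_ratio)
  resp <- convolve(box, rev(kern), type = "open")[seq_len(n)]

  data <- array(0, dim = c(n_ch, 2, n),
                dimnames = list(NULL, c("HbO", "HbR"), NULL))
  t <- (seq_len(n) - 1) / fs
  with_seed(profile$rng_seed, {
    systemic <- rep(0, n)
    for (comp in names(profile$noise_freqs)) {
      amp <- profile$noise[[comp]]
      if (is.null(amp) || amp == 0) next
      phase <- runif(1, 0, 2 * pi)
      systemic <- systemic +
        amp * sin(2 * pi * profile$noise_freqs[[comp]] * t + phase)
    }
    wsd <- profile$noise$white %||% 0
    for (ch in seq_len(n_ch)) {
      act <- profile$channel_gains[ch] * resp
      sys_ch <- profile$systemic_gains[ch] * systemic
      hbo <- act + sys_ch
      hbr <- -profile$hbr_ratio * act + profile$hbr_ratio * sys_ch
      if (wsd > 0) {
        hbo <- hbo + rnorm(n, 0, wsd)
        hbr <- hbr + rnorm(n, 0, profile$hbr_ratio * wsd)
      }
      data[ch, 1, ] <- hbo
      data[ch, 2, ] <- hbr
    }
  })

  out <- list(data = data,
              sampling_rate = fs,
              subject_id = profile$subject_id,
              filtered = FALSE,
              schedule = schedule)
  class(out) <- "hemo_recording"
  out
}

#' Frontal-weighted activation topography
#'
#' Base channel-gain pattern shared by the cohort, mirroring the optode
#' montage it emulates: most channels over the prefrontal cortex (strong
#' n-back activation), small groups over motor, parietal and occipital
#' regions (weak task response).
#'
#' @param n_channels Number of channels.
#' @export
default_base_gains <- function(n_channels = 36) {
  base <- rep(0.25, n_channels)
  n_front <- min(n_channels, 24)
  base[seq_len(n_front)] <- 1
  if (n_channels >= 28) base[25:28] <- 0.35
  if (n_channels >= 32) base[29:32] <- 0.3
  base
}

#' Population defaults for cohort simulation
#'
#' Between-subject distributions from which [make_cohort()] draws each
#' subject's profile: per-class mean peak amplitudes with a common sd
#' (truncated at a small positive floor); a shared frontal-weighted base
#' topography with log-normal per-channel jitter (the common spatial
#' structure is what makes subject transfer possible); uniform ranges for
#' the systemic-noise amplitudes, their subject-specific frequencies, the
#' per-channel systemic sensitivity, and the white-noise level.
#'
#' @export
default_population <- function() {
  list(
    amplitude_mean = c("0-back" = 0.3, "2-back" = 0.45, "3-back" = 0.6),
    amplitude_sd = 0.08,
    amplitude_floor = 0.05,
    base_gains = NULL,          # default_base_gains(n_channels) when NULL
    gain_jitter_sd = 0.3,       # log-normal sd around the base topography
    systemic_gain_range = c(0.5, 1.5),
    mayer_range = c(0.3, 0.7),
    respiratory_range = c(0.1, 0.3),
    cardiac_range = c(0.1, 0.3),
    white_range = c(0.2, 0.4),
    mayer_freq_range = c(0.07, 0.13),
    respiratory_freq_range = c(0.25, 0.35),
    cardiac_freq_range = c(0.9, 1.3),
    hbr_ratio = 1 / 3
  )
}

#' Draw one subject profile from a population
#' @noRd
draw_profile <- function(subject_id, n_channels, population, seed) {
  with_seed(seed, {
    amp <- population$amplitude_mean +
      rnorm(length(population$amplitude_mean), 0, population$amplitude_sd)
    amp <- pmax(amp, population$amplitude_floor)
    names(amp) <- names(population$amplitude_mean)
    base <- population$base_gains %||% default_base_gains(n_channels)
    gains <- base * exp(rnorm(n_channels, 0, population$gain_jitter_sd))
    sysg <- runif(n_channels, population$systemic_gain_range[1],
                  population$systemic_gain_range[2])
    noise <- list(
      mayer = runif(1, population$mayer_range[1], population$mayer_range[2]),
      respiratory = runif(1, population$respiratory_range[1],
                          population$respiratory_range[2]),
      cardiac = runif(1, population$cardiac_range[1],
                      population$cardiac_range[2]),
      white = runif(1, population$white_range[1], population$white_range[2])
    )
    freqs <- c(
      mayer = runif(1, population$mayer_freq_range[1],
                    population$mayer_freq_range[2]),
      respiratory = runif(1, population$respiratory_freq_range[1],
                          population$respiratory_freq_range[2]),
      cardiac = runif(1, population$cardiac_freq_range[1],
                      population$cardiac_freq_range[2])
    )
    subject_profile(subject_id, amplitudes = amp, channel_gains = gains,
                    systemic_gains = sysg, noise = noise,
                    noise_freqs = freqs, hbr_ratio = population$hbr_ratio,
                    rng_seed = derive_seed(seed, 2))
  })
}

#' Simulate a multi-subject fNIRS cohort
#'
#' Draws per-subject profiles from the population distributions, runs the
#' haemodynamic forward model, and maps concentrations to dual-wavelength
#' optical-density changes with the modified Beer-Lambert law, emulating a
#' 26-subject, 36-channel, 10 Hz n-back acquisition. Child seeds are derived
#' deterministically from `master_seed`, so the whole cohort is reproducible
#' bit for bit.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param schedule Block schedule shared by all subjects.
#' @param n_channels Number of measurement channels.
#' @param population Population distributions, see [default_population()].
#' @param mbll Optical constants, see [default_mbll_config()].
#' @param master_seed Integer master seed.
#' @return An `fnirs_cohort`: a list of subjects, each holding the subject's
#'   `optical` recording ([mbll_forward()] output) and ground-truth `profile`,
#'   plus the shared schedule and configuration.
#' @export
make_cohort <- function(n_subjects = 26,
                        schedule = build_schedule(),
                        n_channels = 36,
                        population = default_population(),
                        mbll = default_mbll_config(),
                        master_seed = 1L) {
  n_subjects <- stop_if_not_count(n_subjects, "n_subjects")
  subjects <- lapply(seq_len(n_subjects), function(i) {
    prof <- draw_profile(sprintf("S%02d", i), n_channels, population,
                         derive_seed(master_seed, i, 1))
    hemo <- hemodynamic_forward(schedule, prof)
    optical <- mbll_forward(hemo, mbll = mbll)
    list(subject_id = prof$subject_id, profile = prof, optical = optical)
  })
  out <- list(subjects = subjects,
              schedule = schedule,
              n_channels = n_channels,
              population = population,
              mbll = mbll,
              master_seed = as.integer(master_seed))
  class(out) <- "fnirs_cohort"
  out
}

#' @export
print.fnirs_cohort <- function(x, ...) {
  d <- dim(x$subjects[[1]]$optical$data)
  cat(sprintf(
    "synthetic fNIRS cohort: %d subjects, %d channels x %d wavelengths x %d samples at %g Hz (seed %d)\n",
    length(x$subjects), d[1], d[2], d[3],
    x$schedule$sampling_rate, x$master_seed))
  invisible(x)
}
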