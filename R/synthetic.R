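# Synthetic pulse-like recordings and canonical reference processes. The
# generator stands in for a pressure-pulse study cohort: quasi-periodic
# beats at a resting heart rate, beat-to-beat (RR) interval jitter,
# low-frequency baseline wander and broadband sensor noise, with a
# two-group design whose "complexity difference" is a single knob.

#' Specification for a synthetic two-group pulse cohort
#'
#' Defaults emulate a resting young-adult recording session: 10 s records at
#' 200 Hz (2000 samples), 72 bpm mean heart rate, 30 ms beat-to-beat jitter,
#' broadband noise at 5% of the percussion-wave amplitude, and visible
#' baseline wander. `effect` multiplies the jitter and noise SDs of group B
#' (labelled female) by `(1 + effect)`; `effect = 0` makes the two groups
#' exchangeable.
#'
#' @param n_per_group Records per group, `>= 1`.
#' @param fs Sampling rate (Hz).
#' @param duration_s Record duration (seconds); `fs * duration_s >= 64`.
#' @param heart_rate_bpm Mean beat rate (beats/min).
#' @param rr_jitter_sd SD of the beat-to-beat interval (seconds).
#' @param noise_sd SD of additive white Gaussian noise (amplitude units,
#'   relative to a unit percussion wave).
#' @param drift_amp Baseline-wander amplitude (same units).
#' @param effect Multiplicative inflation (`>= 0`) of `rr_jitter_sd` and
#'   `noise_sd` applied to group B only.
#' @param seed Root seed; per-record seeds are derived from it via a counter.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 100L, fs = 200, duration_s = 10,
                        heart_rate_bpm = 72, rr_jitter_sd = 0.03,
                        noise_sd = 0.05, drift_amp = 0.5,
                        effect = 0, seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  stopifnot(n_per_group >= 1L, is_scalar_number(fs), fs > 0,
            is_scalar_number(duration_s), duration_s > 0,
            fs * duration_s >= 64,
            is_scalar_number(heart_rate_bpm), heart_rate_bpm > 0,
            is_scalar_number(rr_jitter_sd), rr_jitter_sd >= 0,
            is_scalar_number(noise_sd), noise_sd >= 0,
            is_scalar_number(drift_amp), drift_amp >= 0,
            is_scalar_number(effect), effect >= 0)
  structure(list(n_per_group = n_per_group, fs = fs, duration_s = duration_s,
                 heart_rate_bpm = heart_rate_bpm, rr_jitter_sd = rr_jitter_sd,
                 noise_sd = noise_sd, drift_amp = drift_amp, effect = effect,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Default beat morphology: three positive Gaussian lobes per cardiac cycle
# (percussion, tidal and dicrotic waves). Amplitudes relative to the
# percussion wave; centers and widths as fractions of the RR interval.
default_lobes <- function() {
  data.frame(amplitude = c(1, 0.4, 0.25),
             center = c(0.15, 0.40, 0.65),
             width = c(0.05, 0.07, 0.08))
}

#' Generate one synthetic pulse recording
#'
#' Each beat is a sum of three positive Gaussian lobes (percussion, tidal,
#' dicrotic) placed on the cardiac cycle; beat onsets follow
#' `RR_i = 60/heart_rate_bpm + e_i` with `e_i ~ N(0, rr_jitter_sd^2)`
#' truncated so every interval exceeds 0.3 s. White Gaussian noise and a
#' sinusoidal baseline wander (frequency drawn in 0.05-0.5 Hz, random phase)
#' are added. Deterministic given `seed`.
#'
#' @param fs,duration_s,heart_rate_bpm,rr_jitter_sd,noise_sd,drift_amp
#'   As in [cohort_spec()].
#' @param seed Integer seed, or `NULL` to draw from the current RNG state.
#' @param lobes Data frame with columns `amplitude`, `center`, `width`
#'   describing the beat morphology (defaults to the three-lobe shape).
#' @param subject_id,sex,hand Metadata for the returned record.
#' @return A [pulse_record] with `fs * duration_s` samples.
#' @examples
#' rec <- generate_pulse(duration_s = 5, seed = 7)
#' rec
#' @export
generate_pulse <- function(fs = 200, duration_s = 10, heart_rate_bpm = 72,
                           rr_jitter_sd = 0.03, noise_sd = 0.05,
                           drift_amp = 0.5, seed = NULL,
                           lobes = default_lobes(),
                           subject_id = "synthetic", sex = "unknown",
                           hand = "unknown") {
  stopifnot(is_scalar_number(fs), fs > 0, is_scalar_number(duration_s),
            duration_s > 0)
  with_local_seed(seed, {
    rr_mean <- 60 / heart_rate_bpm
    n <- as.integer(round(fs * duration_s))
    t <- (seq_len(n) - 1L) / fs
    # beat onsets covering [ -RR, duration + RR ] so edge beats are complete
    onsets <- -rr_mean
    repeat {
      rr <- rr_mean + rnorm(1L, 0, rr_jitter_sd)
      rr <- max(rr, 0.3)
      onsets <- c(onsets, onsets[length(onsets)] + rr)
      if (onsets[length(onsets)] > duration_s + rr_mean) break
    }
    rr_of_beat <- diff(c(onsets, onsets[length(onsets)] + rr_mean))
    x <- numeric(n)
    for (b in seq_along(onsets)) {
      rr_b <- rr_of_beat[b]
      for (l in seq_len(nrow(lobes))) {
        mu <- onsets[b] + lobes$center[l] * rr_b
        sg <- lobes$width[l] * rr_b
        # only evaluate where the lobe is non-negligible
        lo <- max(1L, as.integer(floor((mu - 5 * sg) * fs)) + 1L)
        hi <- min(n, as.integer(ceiling((mu + 5 * sg) * fs)) + 1L)
        if (lo > hi) next
        idx <- lo:hi
        x[idx] <- x[idx] + lobes$amplitude[l] * exp(-((t[idx] - mu)^2) / (2 * sg^2))
      }
    }
    if (drift_amp > 0) {
      f_b <- runif(1L, 0.05, 0.5)
      phi <- runif(1L, 0, 2 * pi)
      x <- x + drift_amp * sin(2 * pi * f_b * t + phi)
    }
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    pulse_record(x, fs = fs, subject_id = subject_id, sex = sex, hand = hand)
  })
}

#' Generate a canonical reference process
#'
#' Standard validation signals for multiscale entropy analysis: white noise,
#' 1/f noise, the fully chaotic logistic map, a constant and a ramp.
#'
#' @param process One of `"white_noise"`, `"one_over_f"`, `"logistic_map"`,
#'   `"constant"`, `"ramp"`.
#' @param n Number of samples, `>= 16`.
#' @param seed Integer seed, or `NULL`.
#' @param fs Sampling rate attached to the returned record (cosmetic for
#'   these processes).
#' @return A [pulse_record].
#' @details 1/f noise is synthesized in the frequency domain with amplitude
#'   proportional to `1/sqrt(f)` and uniform random phases, then standardized
#'   to zero mean and unit variance. The logistic map iterates
#'   `x <- 4 x (1 - x)` from a seeded start in (0, 1) after a 1000-step
#'   burn-in.
#' @export
generate_reference <- function(process = c("white_noise", "one_over_f",
                                           "logistic_map", "constant", "ramp"),
                               n, seed = NULL, fs = 200) {
  process <- match.arg(process)
  n <- as.integer(n)
  if (n < 16L) stop("reference processes need n >= 16")
  x <- with_local_seed(seed, switch(process,
    white_noise = rnorm(n),
    one_over_f = {
      nf <- n %/% 2L
      f <- seq_len(nf)
      amp <- 1 / sqrt(f)
      phase <- runif(nf, 0, 2 * pi)
      half <- amp * exp(1i * phase)
      # Hermitian-symmetric spectrum -> real signal
      spec <- complex(n)
      spec[2:(nf + 1L)] <- half
      if (n %% 2L == 0L) spec[nf + 1L] <- Re(half[nf])  # Nyquist bin must be real
      idx <- 2:(nf + 1L)
      mir <- n - idx + 2L
      keep <- mir > nf + 1L
      spec[mir[keep]] <- Conj(spec[idx[keep]])
      y <- Re(fft(spec, inverse = TRUE)) / n
      (y - mean(y)) / sd(y)
    },
    logistic_map = {
      x0 <- runif(1L, 0.05, 0.95)
      for (i in 1:1000) x0 <- 4 * x0 * (1 - x0)
      out <- numeric(n)
      for (i in seq_len(n)) {
        x0 <- 4 * x0 * (1 - x0)
        out[i] <- x0
      }
      out
    },
    constant = rep(1, n),
    ramp = as.numeric(seq_len(n))
  ))
  pulse_record(x, fs = fs, subject_id = process)
}

#' Generate a two-group synthetic cohort
#'
#' Group A (labelled male) uses the baseline parameters; group B (labelled
#' female) has `rr_jitter_sd` and `noise_sd` multiplied by
#' `(1 + spec$effect)`. Per-record seeds are derived deterministically from
#' `spec$seed` via a counter, so the cohort is reproducible and extending it
#' never reshuffles existing records.
#'
#' @param spec A [cohort_spec()].
#' @param hand Hand label attached to every record (cohorts are generated
#'   per hand).
#' @return A list with `manifest` (data frame: record_path left blank,
#'   subject_id, sex, hand) and `records` (list of [pulse_record]s in
#'   manifest order).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_per_group = 3, duration_s = 5, seed = 1))
#' cohort$manifest
#' @export
generate_cohort <- function(spec, hand = "left") {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_per_group
  sexes <- rep(c("male", "female"), each = n)
  ids <- c(sprintf("M%03d", seq_len(n)), sprintf("F%03d", seq_len(n)))
  records <- vector("list", 2L * n)
  for (i in seq_len(2L * n)) {
    inflate <- if (sexes[i] == "female") 1 + spec$effect else 1
    records[[i]] <- generate_pulse(
      fs = spec$fs, duration_s = spec$duration_s,
      heart_rate_bpm = spec$heart_rate_bpm,
      rr_jitter_sd = spec$rr_jitter_sd * inflate,
      noise_sd = spec$noise_sd * inflate,
      drift_amp = spec$drift_amp,
      seed = spawn_seed(spec$seed, i),
      subject_id = ids[i], sex = sexes[i], hand = hand)
  }
  manifest <- data.frame(record_path = "", subject_id = ids, sex = sexes,
                         hand = hand, stringsAsFactors = FALSE)
  list(manifest = manifest, records = records)
}

#' Write a synthetic cohort to disk
#'
#' Writes one sample CSV per record plus a manifest CSV, the on-disk form
#' consumed by [read_manifest()] / [read_pulse_csv()].
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort$manifest
  for (i in seq_len(nrow(manifest))) {
    fname <- sprintf("%s_%s.csv", manifest$subject_id[i], manifest$hand[i])
    write_pulse_csv(cohort$records[[i]], file.path(dir, fname))
    manifest$record_path[i] <- fname
  }
  path <- file.path(dir, "manifest.csv")
  write_manifest(manifest, path)
  invisible(path)
}
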