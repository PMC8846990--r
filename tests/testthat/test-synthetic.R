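test_that("noise-free pulse is periodic at the beat lag", {
  # 75 bpm -> RR = 0.8 s = 160 samples at 200 Hz, an integer lag
  rec <- generate_pulse(fs = 200, duration_s = 10, heart_rate_bpm = 75,
                        rr_jitter_sd = 0, noise_sd = 0, drift_amp = 0, seed = 1)
  x <- rec$samples
  lag <- 160L
  mid <- 201:1600
  expect_gt(cor(x[mid], x[mid + lag]), 0.999)
})

test_that("pulse generation is deterministic given a seed", {
  a <- generate_pulse(seed = 7)
  b <- generate_pulse(seed = 7)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, generate_pulse(seed = 8)$samples))
})

test_that("default pulse concentrates spectral power below 10 Hz", {
  fracs <- vapply(1:5, function(s)
    power_fraction_below(generate_pulse(seed = s)$samples, 200, 10), numeric(1))
  expect_true(all(fracs >= 0.95))
})

test_that("pulse generator validates inputs", {
  expect_error(generate_pulse(fs = -1), "fs")
  expect_error(generate_pulse(duration_s = 0))
})

test_that("reference processes match their defining statistics", {
  expect_equal(generate_reference("constant", 100)$samples, rep(1, 100))
  expect_equal(generate_reference("ramp", 50)$samples, as.numeric(1:50))

  wn <- generate_reference("white_noise", 10000, seed = 3)$samples
  expect_lt(abs(mean(wn)), 4 / sqrt(10000))
  expect_lt(abs(var(wn) - 1), 0.1)

  # 1/f noise: least-squares log-log periodogram slope near -1
  pf <- generate_reference("one_over_f", 4096, seed = 4)$samples
  p <- Mod(fft(pf))^2
  f <- seq_len(2047) / 4096
  fit <- stats::lm(log(p[2:2048]) ~ log(f))
  expect_gt(coef(fit)[2], -1.3)
  expect_lt(coef(fit)[2], -0.7)

  lm_x <- generate_reference("logistic_map", 1000, seed = 5)$samples
  expect_true(all(lm_x > 0 & lm_x < 1))
  # iterates satisfy the map exactly
  expect_equal(lm_x[-1], 4 * head(lm_x, -1) * (1 - head(lm_x, -1)),
               tolerance = 1e-12)

  expect_error(generate_reference("pink", 100))
  expect_error(generate_reference("white_noise", 8))
})

test_that("cohort generation is deterministic, balanced and extendable", {
  spec <- cohort_spec(n_per_group = 3, duration_s = 5, seed = 9)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(lapply(a$records, `[[`, "samples"),
                   lapply(b$records, `[[`, "samples"))
  expect_equal(nrow(a$manifest), 6)
  expect_equal(sum(a$manifest$sex == "male"), 3)

  # growing the cohort never reshuffles existing records
  bigger <- generate_cohort(cohort_spec(n_per_group = 4, duration_s = 5, seed = 9))
  expect_identical(bigger$records[[1]]$samples, a$records[[1]]$samples)
  expect_identical(bigger$records[[3]]$samples, a$records[[3]]$samples)
})

test_that("effect = 0 makes groups exchangeable by construction", {
  spec <- cohort_spec(n_per_group = 2, duration_s = 5, effect = 0, seed = 11)
  coh <- generate_cohort(spec)
  # group B record i is generated with the same parameters as group A's,
  # differing only through its derived seed
  expect_equal(sd(coh$records[[3]]$samples), sd(coh$records[[1]]$samples),
               tolerance = 0.5)
})

test_that("positive effect inflates group B variability", {
  sds <- replicate(50, {
    spec <- cohort_spec(n_per_group = 1, duration_s = 4, effect = 0.5,
                        seed = sample.int(1e6, 1))
    coh <- generate_cohort(spec)
    c(a = sd(coh$records[[1]]$samples), b = sd(coh$records[[2]]$samples))
  })
  expect_gt(mean(sds["b", ]), mean(sds["a", ]))
})

test_that("group B broadband noise power is nondecreasing in effect", {
  hf_power <- function(effect) {
    mean(vapply(1:20, function(i) {
      spec <- cohort_spec(n_per_group = 1, duration_s = 4, effect = effect,
                          seed = 500 + i)
      x <- generate_cohort(spec)$records[[2]]$samples  # group B record
      1 - power_fraction_below(x, 200, 15)
    }, numeric(1)))
  }
  p <- vapply(c(0, 0.5, 1), hf_power, numeric(1))
  expect_true(all(diff(p) >= 0))
})

test_that("cohorts write to disk and reload through the manifest", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(cohort_spec(n_per_group = 2, duration_s = 5, seed = 3))
  write_cohort(coh, dir)
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(m), 4)
  rec <- read_pulse_csv(file.path(dir, m$record_path[1]), fs = 200)
  expect_identical(rec$samples, coh$records[[1]]$samples)
})
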