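test_that("the sonar call is a downward 70-15 kHz sweep at 500 kHz", {
  cl <- synthesize_call(2)
  expect_length(cl$waveform, 1000L)
  ## instantaneous frequency from the analytic phase: starts at 70 kHz,
  ## ends at 15 kHz
  n <- length(cl$waveform)
  t <- (seq_len(n) - 1) / cl$fs
  dur <- n / cl$fs
  finst <- function(frac) 70e3 + (15e3 - 70e3) * frac
  ## zero-crossing density over the first/last tenth approximates f
  f_measured <- function(idx) {
    x <- cl$waveform[idx]
    sum(abs(diff(sign(x))) > 0) / (2 * length(idx) / cl$fs)
  }
  expect_equal(f_measured(1:100), finst(0.1 / 2), tolerance = 0.05)
  expect_equal(f_measured(901:1000), finst(1 - 0.1 / 2), tolerance = 0.05)
  expect_error(synthesize_call(-1), "positive")
})

test_that("call durations follow the gamma(8, 0.3) law", {
  d <- sample_call_durations(2e5, seed = 1)
  expect_equal(mean(d), 2.4, tolerance = 0.01)
  expect_equal(stats::sd(d), sqrt(8) * 0.3, tolerance = 0.02)
})

test_that("the synthetic HRTF has the Woodworth ITD and symmetric median plane", {
  h <- synthetic_hrtf()
  expect_equal(hrtf_itd(h, 90), 0.007 * (pi / 2 + 1) / 343, tolerance = 1e-12)
  ir <- interpolate_hrtf(h, 0, 0)
  expect_equal(ir$left, ir$right)
  ## mirror symmetry about the median plane
  irl <- interpolate_hrtf(h, -30, 10)
  irr <- interpolate_hrtf(h, 30, 10)
  expect_equal(irl$left, irr$right, tolerance = 1e-12)
  expect_error(synthetic_hrtf(head_radius = 0), "positive")
})

test_that("HRTF interpolation is exact at nodes and continuous between", {
  h <- synthetic_hrtf(alpha_grid = seq(-60, 60, 20), phi_grid = seq(-40, 40, 20))
  node <- interpolate_hrtf(h, 20, 0)
  expect_equal(node$mag[, 1], h$mag[match(20, h$alpha), match(0, h$phi), , 1])
  ## midpoint along alpha equals the mean of the node representations
  a <- interpolate_hrtf(h, 20, 0); b <- interpolate_hrtf(h, 40, 0)
  mid <- interpolate_hrtf(h, 30, 0)
  expect_equal(mid$mag, (a$mag + b$mag) / 2, tolerance = 1e-12)
  expect_equal(mid$phase, (a$phase + b$phase) / 2, tolerance = 1e-12)
  expect_error(interpolate_hrtf(h, 75, 0), "out of range")
  ## rendered ITD varies continuously over 1-degree steps
  cl <- synthesize_call(1.5)
  itds <- vapply(seq(10, 20, 1), function(al) {
    measure_echo_cues(render_echo(cl, h, al, 0))$itd
  }, 0)
  expect_lt(max(abs(diff(itds))), 5e-6)
})

test_that("rendered echoes obey joint normalization and carry the model cues", {
  cl <- synthesize_call(2)
  h <- synthetic_hrtf()
  e0 <- render_echo(cl, h, 0, 0)
  expect_equal(e0$left, e0$right)
  expect_equal(sqrt(mean(c(e0$left, e0$right)^2)), 1, tolerance = 1e-9)
  ## joint normalization preserves the left/right RMS ratio
  ir <- interpolate_hrtf(h, 40, 0)
  lraw <- batroll:::fft_convolve(cl$waveform, ir$left)
  rraw <- batroll:::fft_convolve(cl$waveform, ir$right)
  e <- render_echo(cl, h, 40, 0)
  expect_equal(sqrt(mean(e$left^2)) / sqrt(mean(e$right^2)),
               sqrt(mean(lraw^2)) / sqrt(mean(rraw^2)), tolerance = 1e-12)
  ## measured ITD matches the generating Woodworth value across the grid
  for (al in c(-60, -20, 20, 60)) {
    cues <- measure_echo_cues(render_echo(cl, h, al, 0))
    expect_lt(abs(cues$itd - hrtf_itd(h, al)), 2e-6)
    expect_equal(sign(cues$ild), sign(al))
  }
  ## ILD monotone over alpha in [0, 60]
  ilds <- vapply(seq(0, 60, 10), function(al) {
    measure_echo_cues(render_echo(cl, h, al, 0))$ild
  }, 0)
  expect_true(all(diff(ilds) > 0))
})

test_that("cochlear features are 810-dimensional, tonotopic and non-negative", {
  cl <- synthesize_call(1.5)
  h <- synthetic_hrtf()
  e <- render_echo(cl, h, 10, 0)
  cf <- cochlear_features(e)
  expect_equal(ncol(cf), 810L)
  expect_gte(min(cf), -1e-9)
  ## pure 50 kHz tone peaks within one channel spacing of 50 kHz
  t <- (0:999) / 5e5
  tone <- structure(list(left = sin(2 * pi * 50e3 * t),
                         right = sin(2 * pi * 50e3 * t), fs = 5e5),
                    class = "binaural_echo")
  cf_tone <- cochlear_features(tone)
  centers <- seq(20e3, 100e3, length.out = 81)
  best <- centers[ceiling(which.max(colMeans(cf_tone)) / 5)]
  expect_lte(abs(best - 50e3), diff(centers)[1])
  ## silence gives all-zero features
  silent <- structure(list(left = numeric(1000), right = numeric(1000),
                           fs = 5e5), class = "binaural_echo")
  expect_equal(max(abs(cochlear_features(silent))), 0)
  ## too-short echo: empty output with a warning
  short <- structure(list(left = numeric(10), right = numeric(10), fs = 5e5),
                     class = "binaural_echo")
  expect_warning(out <- cochlear_features(short), "short")
  expect_equal(nrow(out), 0L)
})
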