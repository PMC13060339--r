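test_that("band noise confines energy to the geometric passband", {
  ## unramped realization exposes the raw synthesis spectrum
  spec <- stimulus_spec("band_noise", center_freq = 1000,
                        bandwidth_oct = 0.25, level = 60, ramp = 0,
                        seed = 3)
  w <- synthesize(spec)
  n <- length(w$samples)
  pw <- Mod(stats::fft(w$samples))^2
  freqs <- (0:(n %/% 2)) * w$sample_rate / n
  edges <- band_edges(1000, 0.25)
  expect_equal(edges, c(1000 * 2^(-1 / 8), 1000 * 2^(1 / 8)))
  out_band <- which(freqs < edges[1] | freqs > edges[2])
  expect_equal(sum(pw[out_band]), 0)

  ## ramped version still keeps >= 99% of power in the band
  wr <- synthesize(stimulus_spec("band_noise", center_freq = 1000,
                                 bandwidth_oct = 0.25, level = 60, seed = 3))
  pwr <- Mod(stats::fft(wr$samples))^2
  in_band <- which(freqs >= edges[1] & freqs <= edges[2])
  expect_gt(sum(pwr[in_band]) / sum(pwr[seq_along(freqs)]), 0.99)
})

test_that("every stimulus class hits its target level exactly", {
  specs <- list(
    stimulus_spec("tone", level = 60),
    stimulus_spec("band_noise", bandwidth_oct = 0.25, level = 40, seed = 1),
    stimulus_spec("five_tone", bandwidth_oct = 0.25, level = 75),
    stimulus_spec("low_noise_noise", bandwidth_oct = 0.25, level = 55, seed = 2),
    stimulus_spec("sam_tone", level = 65))
  for (sp in specs) {
    w <- synthesize(sp)
    expect_equal(steady_rms(w) / spl_to_pa(sp$level), 1, tolerance = 1e-6)
    expect_true(all(is.finite(w$samples)))
    expect_length(w$samples, round(sp$duration * sp$sample_rate))
  }
  ## dB SPL convention: 60 dB SPL tone has RMS pressure 0.02 Pa
  expect_equal(steady_rms(synthesize(stimulus_spec("tone", level = 60))),
               0.02, tolerance = 1e-6)
})

test_that("generators are pure functions of (spec, seed) and level-linear", {
  s1 <- stimulus_spec("band_noise", bandwidth_oct = 0.25, level = 60, seed = 11)
  expect_identical(synthesize(s1)$samples, synthesize(s1)$samples)
  s2 <- s1
  s2$level <- 80
  expect_equal(synthesize(s2)$samples, synthesize(s1)$samples * 10)
  s3 <- s1
  s3$seed <- 12
  expect_false(identical(synthesize(s3)$samples, synthesize(s1)$samples))
})

test_that("five-tone components sit at the log-spaced frequencies", {
  expect_equal(five_tone_freqs(1000, 0.25), 1000 * 2^((-2:2) / 16))
  expect_equal(round(five_tone_freqs(1000, 0.25), 1),
               c(917.0, 957.6, 1000.0, 1044.3, 1090.5))
  ## spectrum of the unramped complex peaks exactly at those bins
  w <- synthesize(stimulus_spec("five_tone", bandwidth_oct = 0.25,
                                level = 60, ramp = 0))
  n <- length(w$samples)
  mag <- Mod(stats::fft(w$samples))[1:(n %/% 2)]
  peaks <- sort(order(mag, decreasing = TRUE)[1:5] - 1)  # bin -> Hz (1 Hz bins)
  expect_equal(peaks, round(five_tone_freqs(1000, 0.25)), tolerance = 1)
})

test_that("raised-cosine ramps gate the waveform as specified", {
  fs <- 1000
  w <- structure(list(samples = rep(1, fs), sample_rate = fs,
                      spec = stimulus_spec("tone", center_freq = 100,
                                           duration = 1, ramp = 0.2,
                                           sample_rate = fs)),
                 class = "waveform")
  r <- apply_ramps(w, 0.2)
  nr <- 0.2 * fs
  expect_equal(r$samples[1], 0)              # onset starts at zero
  expect_equal(r$samples[nr + 1], 1)          # gain 1 at t = ramp
  expect_equal(r$samples[nr / 2 + 1], 0.5)    # cos^2 midpoint
  expect_equal(r$samples[fs - nr], 1)         # steady segment untouched
  expect_lt(sum(r$samples^2), sum(w$samples^2))
  expect_error(apply_ramps(w, 0.6), "invalid-spec")
})

test_that("envelope fluctuation orders the stimulus classes", {
  fl <- function(st, seed = NULL) {
    env_fluctuation(synthesize(stimulus_spec(st, bandwidth_oct = 0.25,
                                             level = 60, seed = seed)))
  }
  noise_fl <- vapply(1:20, function(s) fl("band_noise", s), numeric(1))
  five_fl <- fl("five_tone")
  sam_fl <- fl("sam_tone")
  lnn_fl <- vapply(1:5, function(s) fl("low_noise_noise", s), numeric(1))
  expect_true(all(five_fl < noise_fl))       # five-tone below every noise draw
  expect_gt(sam_fl, max(noise_fl))           # SAM fluctuates most
  expect_true(all(lnn_fl < 0.2))             # flattening works
  expect_true(all(lnn_fl < five_fl))
  ## SAM with depth 1 has envelope minima near zero
  wsam <- synthesize(stimulus_spec("sam_tone", level = 60))
  env <- loudsim:::hilbert_envelope(wsam$samples)[8821:35280]
  expect_lt(min(env) / max(env), 0.02)
})

test_that("the expected band-noise spectrum is flat across the band", {
  ## average in-band bin power over many seeds; compare band halves
  spec0 <- stimulus_spec("band_noise", center_freq = 1000,
                         bandwidth_oct = 0.25, level = 60, ramp = 0,
                         duration = 0.5, seed = 1)
  edges <- band_edges(1000, 0.25)
  n <- round(spec0$duration * spec0$sample_rate)
  freqs <- (0:(n %/% 2)) * spec0$sample_rate / n
  in_band <- which(freqs > edges[1] & freqs < edges[2])
  acc <- numeric(length(in_band))
  for (s in 1:200) {
    sp <- spec0
    sp$seed <- s
    w <- synthesize(sp)
    acc <- acc + Mod(stats::fft(w$samples))[in_band]^2
  }
  half <- length(acc) %/% 2
  lower <- mean(acc[1:half])
  upper <- mean(acc[(half + 1):length(acc)])
  expect_lt(abs(lower / upper - 1), 0.1)
})

test_that("invalid stimulus requests raise the documented errors", {
  expect_error(stimulus_spec("tone", center_freq = 30000), "Nyquist")
  expect_error(stimulus_spec("band_noise", bandwidth_oct = -0.5), "negative")
  expect_error(stimulus_spec("tone", duration = 0.3, ramp = 0.2),
               "twice the ramp")
  ## a band narrower than two 1-Hz bins is degenerate
  expect_error(synthesize(stimulus_spec("band_noise", center_freq = 1000,
                                        bandwidth_oct = 1e-6, level = 60,
                                        seed = 1)),
               "degenerate-band")
})
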