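#' Describe a test stimulus
#'
#' Constructs a parametric description of a narrow-band test sound. Five
#' stimulus classes are supported: pure tones, band-limited Rayleigh-spectrum
#' noise, five-tone complexes, low-noise noise (envelope-flattened band
#' noise), and sinusoidally amplitude-modulated (SAM) tones. Conventions
#' follow the measurement protocol the package emulates: 1-s stimuli at
#' 44.1 kHz with 200-ms raised-cosine onset/offset ramps, levels on a
#' 0-100 dB SPL range, and quarter- or one-octave bandwidths with geometric
#' band edges `fc * 2^(+/- bw/2)`.
#'
#' @param stim_type One of `"tone"`, `"band_noise"`, `"five_tone"`,
#'   `"low_noise_noise"`, `"sam_tone"`.
#' @param center_freq Center frequency in Hz.
#' @param bandwidth_oct Bandwidth in octaves (0 for tones and SAM tones'
#'   carrier; the modulated band of a SAM tone is set by `sam_rate`).
#' @param level Presentation level in dB SPL.
#' @param duration Duration in seconds (including ramps).
#' @param ramp Raised-cosine ramp duration in seconds (each end).
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed for stochastic stimulus classes.
#' @param sam_rate Modulation rate in Hz for SAM tones. Default: half the
#'   equivalent quarter-octave bandwidth at `center_freq`.
#' @param lnn_iterations Envelope-flattening iterations for low-noise noise.
#' @param phases Optional component phases (radians) for five-tone
#'   complexes; default is zero phase for every component, a deterministic
#'   choice whose envelope fluctuates less than Rayleigh band noise.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(stim_type = c("tone", "band_noise", "five_tone",
                                        "low_noise_noise", "sam_tone"),
                          center_freq = 1000, bandwidth_oct = 0, level = 60,
                          duration = 1, ramp = 0.2, sample_rate = 44100,
                          seed = NULL, sam_rate = NULL, lnn_iterations = 10,
                          phases = NULL) {
  stim_type <- match.arg(stim_type)
  if (!is.finite(center_freq) || center_freq <= 0) {
    stop("invalid-spec: center_freq must be positive", call. = FALSE)
  }
  if (center_freq >= sample_rate / 2) {
    stop("invalid-spec: center_freq at or above Nyquist", call. = FALSE)
  }
  if (bandwidth_oct < 0) {
    stop("invalid-spec: negative bandwidth", call. = FALSE)
  }
  if (duration < 2 * ramp) {
    stop("invalid-spec: duration must be at least twice the ramp", call. = FALSE)
  }
  if (stim_type %in% c("band_noise", "low_noise_noise") && bandwidth_oct <= 0) {
    stop("invalid-spec: noise stimuli need bandwidth_oct > 0", call. = FALSE)
  }
  if (is.null(sam_rate)) {
    ## half the equivalent quarter-octave bandwidth in Hz at fc
    sam_rate <- center_freq * (2^(1 / 8) - 2^(-1 / 8)) / 2
  }
  structure(list(stim_type = stim_type, center_freq = center_freq,
                 bandwidth_oct = bandwidth_oct, level = level,
                 duration = duration, ramp = ramp, sample_rate = sample_rate,
                 seed = seed, sam_rate = sam_rate,
                 lnn_iterations = lnn_iterations, phases = phases),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec> %s: fc = %g Hz, bw = %g oct, %g dB SPL, %g s (ramp %g s) @ %g Hz\n",
              x$stim_type, x$center_freq, x$bandwidth_oct, x$level,
              x$duration, x$ramp, x$sample_rate))
  invisible(x)
}

#' Geometric band edges of a stimulus
#'
#' @param center_freq Center frequency in Hz.
#' @param bandwidth_oct Bandwidth in octaves.
#' @return Numeric vector `c(lower, upper)` in Hz.
#' @export
band_edges <- function(center_freq, bandwidth_oct) {
  center_freq * 2^(c(-1, 1) * bandwidth_oct / 2)
}

## indices of the steady-state (unramped) segment of a spec
steady_index <- function(spec) {
  n <- round(spec$duration * spec$sample_rate)
  nr <- round(spec$ramp * spec$sample_rate)
  seq.int(nr + 1L, n - nr)
}

## Normalize to unit RMS over the central steady-state segment, then scale
## to the spec level (pascals), then gate with raised-cosine ramps.
finalize_waveform <- function(x, spec) {
  idx <- steady_index(spec)
  r <- sqrt(mean(x[idx]^2))
  if (!is.finite(r) || r <= 0) stop("degenerate waveform: zero RMS", call. = FALSE)
  x <- x / r * spl_to_pa(spec$level)
  w <- structure(list(samples = x, sample_rate = spec$sample_rate, spec = spec),
                 class = "waveform")
  apply_ramps(w, spec$ramp)
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %s, %d samples @ %g Hz, steady RMS %.2f dB SPL\n",
              x$spec$stim_type, length(x$samples), x$sample_rate,
              pa_to_spl(steady_rms(x))))
  invisible(x)
}

#' Steady-state RMS pressure of a waveform
#'
#' RMS over the central segment between the onset and offset ramps, i.e.
#' the portion unaffected by gating.
#'
#' @param w A `waveform`.
#' @return RMS pressure in pascals.
#' @export
steady_rms <- function(w) {
  sqrt(mean(w$samples[steady_index(w$spec)]^2))
}

#' Synthesize the waveform described by a stimulus spec
#'
#' Dispatches to the class-specific generator. All generators share the
#' same pipeline: construct the raw waveform, normalize to unit RMS over
#' the steady-state segment, scale to the target level in pascals
#' (`rms = 20e-6 * 10^(level/20)` Pa), and gate with raised-cosine ramps.
#'
#' @param spec A `stimulus_spec`.
#' @return A `waveform` with fields `samples` (pascals), `sample_rate`, `spec`.
#' @export
synthesize <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  switch(spec$stim_type,
         tone = make_pure_tone(spec),
         band_noise = make_band_noise(spec),
         five_tone = make_five_tone(spec),
         low_noise_noise = make_low_noise_noise(spec),
         sam_tone = make_sam_tone(spec))
}

#' Pure-tone generator
#'
#' @param spec A `stimulus_spec` with `stim_type = "tone"`.
#' @return A `waveform`.
#' @export
make_pure_tone <- function(spec) {
  stopifnot(spec$stim_type == "tone")
  n <- round(spec$duration * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  finalize_waveform(sin(2 * pi * spec$center_freq * t), spec)
}

## Frequency-domain band-noise core: Rayleigh magnitudes and uniform
## phases on the bins strictly inside the geometric band edges, zeros
## elsewhere, real signal by construction (inverse FFT with enforced
## conjugate symmetry). Returns the unnormalized time series.
band_noise_core <- function(spec) {
  n <- round(spec$duration * spec$sample_rate)
  edges <- band_edges(spec$center_freq, spec$bandwidth_oct)
  if (edges[2] >= spec$sample_rate / 2) {
    stop("invalid-spec: passband reaches Nyquist", call. = FALSE)
  }
  freqs <- (0:(n %/% 2)) * spec$sample_rate / n
  in_band <- which(freqs > edges[1] & freqs < edges[2])
  in_band <- setdiff(in_band, c(1L, n %/% 2 + 1L))  # never DC or Nyquist
  if (length(in_band) < 2) {
    stop("degenerate-band: fewer than 2 spectrum bins in passband", call. = FALSE)
  }
  mags <- sqrt(stats::rexp(length(in_band), rate = 1 / 2))  # Rayleigh(1)
  phis <- stats::runif(length(in_band), 0, 2 * pi)
  spec_full <- complex(length.out = n)
  spec_full[in_band] <- mags * exp(1i * phis)
  spec_full[n - in_band + 2L] <- Conj(spec_full[in_band])
  Re(stats::fft(spec_full, inverse = TRUE)) / n
}

#' Band-limited Rayleigh-spectrum noise generator
#'
#' Noise is synthesized in the frequency domain: bins strictly inside the
#' geometric passband carry independent Rayleigh magnitudes and uniform
#' phases; all other bins are exactly zero before the inverse transform
#' and ramping. The expected spectrum is flat across the band.
#'
#' @param spec A `stimulus_spec` with `stim_type = "band_noise"` and a
#'   positive bandwidth; `seed` controls the draw.
#' @return A `waveform`.
#' @export
make_band_noise <- function(spec) {
  stopifnot(spec$stim_type == "band_noise")
  x <- with_seed(spec$seed, band_noise_core(spec))
  finalize_waveform(x, spec)
}

#' Component frequencies of a five-tone complex
#'
#' Log-spaced at `fc * 2^(k * bw/4)`, k = -2..2, so the five components
#' span the geometric band edges `fc * 2^(+/- bw/2)`.
#' @param center_freq Center frequency in Hz.
#' @param bandwidth_oct Bandwidth in octaves.
#' @return Numeric vector of five frequencies in Hz.
#' @export
five_tone_freqs <- function(center_freq, bandwidth_oct) {
  center_freq * 2^((-2:2) * bandwidth_oct / 4)
}

#' Five-tone complex generator
#'
#' Five equal-amplitude components log-spaced across the geometric band
#' edges. Default component phases are all zero (cosine phase), a
#' deterministic choice; because the geometric spacing is slightly
#' non-uniform in Hz, the envelope drifts through beating configurations
#' and fluctuates less than Rayleigh band noise of the same bandwidth.
#'
#' @param spec A `stimulus_spec` with `stim_type = "five_tone"`.
#' @return A `waveform`.
#' @export
make_five_tone <- function(spec) {
  stopifnot(spec$stim_type == "five_tone")
  n <- round(spec$duration * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  f <- five_tone_freqs(spec$center_freq, spec$bandwidth_oct)
  ph <- spec$phases
  if (is.null(ph)) ph <- rep(0, 5)
  stopifnot(length(ph) == 5)
  x <- rowSums(vapply(1:5, function(k) cos(2 * pi * f[k] * t + ph[k]),
                      numeric(n)))
  finalize_waveform(x, spec)
}

#' Low-noise-noise generator
#'
#' Band noise whose envelope is iteratively flattened: each iteration
#' divides the waveform by its Hilbert envelope, re-band-limits it, and
#' renormalizes. If the envelope fluctuation has not converged below
#' `tol` after `spec$lnn_iterations` iterations, the best iterate is
#' returned with a warning.
#'
#' @param spec A `stimulus_spec` with `stim_type = "low_noise_noise"`.
#' @param tol Convergence tolerance on the envelope std/mean.
#' @return A `waveform`.
#' @export
make_low_noise_noise <- function(spec, tol = 0.1) {
  stopifnot(spec$stim_type == "low_noise_noise")
  n <- round(spec$duration * spec$sample_rate)
  edges <- band_edges(spec$center_freq, spec$bandwidth_oct)
  freqs <- (0:(n %/% 2)) * spec$sample_rate / n
  in_band <- which(freqs > edges[1] & freqs < edges[2])
  in_band <- setdiff(in_band, c(1L, n %/% 2 + 1L))
  keep <- logical(n)
  keep[in_band] <- TRUE
  keep[n - in_band + 2L] <- TRUE
  x <- with_seed(spec$seed, band_noise_core(spec))
  best <- x
  best_fl <- env_fluctuation_raw(x, spec$sample_rate)
  converged <- FALSE
  for (i in seq_len(spec$lnn_iterations)) {
    env <- hilbert_envelope(x)
    env <- pmax(env, 1e-12 * max(env))
    x <- x / env
    X <- stats::fft(x)
    X[!keep] <- 0
    x <- Re(stats::fft(X, inverse = TRUE)) / n
    x <- x / sqrt(mean(x^2))
    fl <- env_fluctuation_raw(x, spec$sample_rate)
    if (fl < best_fl) {
      best <- x
      best_fl <- fl
    }
    if (fl < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && best_fl >= tol) {
    warning("low-noise-noise envelope flattening did not converge; returning best iterate")
  }
  finalize_waveform(best, spec)
}

#' SAM-tone generator
#'
#' Sinusoidal amplitude modulation of a pure-tone carrier with modulation
#' depth 1 (envelope minima at zero) at rate `spec$sam_rate`.
#'
#' @param spec A `stimulus_spec` with `stim_type = "sam_tone"`.
#' @return A `waveform`.
#' @export
make_sam_tone <- function(spec) {
  stopifnot(spec$stim_type == "sam_tone")
  n <- round(spec$duration * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  x <- (1 - cos(2 * pi * spec$sam_rate * t)) * sin(2 * pi * spec$center_freq * t)
  finalize_waveform(x, spec)
}

#' Apply raised-cosine onset/offset ramps
#'
#' Multiplies the first and last `ramp * sample_rate` samples by
#' raised-cosine (Hann half-window) gates; the central segment is
#' untouched. Gain is 0 at the first sample and reaches 1 at `t = ramp`.
#'
#' @param w A `waveform`.
#' @param ramp Ramp duration in seconds.
#' @return The ramped `waveform`.
#' @export
apply_ramps <- function(w, ramp) {
  n <- length(w$samples)
  nr <- round(ramp * w$sample_rate)
  if (2 * nr > n) stop("invalid-spec: ramp longer than half the duration", call. = FALSE)
  if (nr > 0) {
    g <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1) / nr))
    w$samples[seq_len(nr)] <- w$samples[seq_len(nr)] * g
    w$samples[n - seq_len(nr) + 1L] <- w$samples[n - seq_len(nr) + 1L] * g
  }
  w
}

## Hilbert envelope via the analytic signal (FFT method).
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

env_fluctuation_raw <- function(x, sample_rate, trim = 0.05) {
  env <- hilbert_envelope(x)
  nt <- round(trim * sample_rate)
  env <- env[(nt + 1):(length(env) - nt)]
  stats::sd(env) / mean(env)
}

#' Envelope-fluctuation index of a waveform
#'
#' Standard deviation over mean of the Hilbert envelope, computed on the
#' steady-state (unramped) segment. Used to order stimulus classes by the
#' amount of temporal envelope fluctuation they carry.
#'
#' @param w A `waveform`.
#' @return Unitless fluctuation index.
#' @export
env_fluctuation <- function(w) {
  idx <- steady_index(w$spec)
  env <- hilbert_envelope(w$samples)[idx]
  stats::sd(env) / mean(env)
}
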