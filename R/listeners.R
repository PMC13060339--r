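#' Default parameters of the synthetic loudness surfaces
#'
#' Central container for the generator's study conditions: group loudness
#' slopes, the bandwidth-dependent equivalent-level offset surface, and
#' response noise. Defaults encode the cohort-level effects the package
#' is built to reproduce:
#'
#' * group mean loudness-growth slopes of 0.10 (NH) and 0.12 (HL)
#'   categorical units per dB, with between-subject jitter;
#' * a quarter-octave bandwidth offset (equivalent-level reduction)
#'   peaking at 7 dB at 1 kHz and 60 dB SPL for NH listeners, falling off
#'   smoothly in log-frequency and level; the one-octave offset is 4/7 of
#'   the quarter-octave offset (so quarter vs one-octave differ by 3 dB
#'   at the peak); HL surfaces carry 0.6 of the NH offset;
#' * `offset_spread_level` calibrated so the population expectation, over
#'   the NH cohort-sampling distribution, of the offset averaged over a
#'   listener's ten 1-kHz category boundaries equals 4.08 dB — the pooled
#'   mixed-model quarter-octave-vs-tone contrast the generator is meant to
#'   reproduce — while the 60-dB point offset stays 7 dB;
#' * trial-to-trial categorical response noise of 0.8 CU.
#'
#' @param slope_nh,slope_hl Group mean slopes, cat/dB.
#' @param slope_sd Between-subject SD of the slope, cat/dB.
#' @param anchor_slope_sd Within-listener across-frequency slope jitter.
#' @param knee_cu Categorical unit at which the two growth segments join.
#' @param segment_ratio Ratio of upper- to lower-segment slope.
#' @param offset_peak_db Peak quarter-octave offset, dB (NH).
#' @param offset_peak_freq,offset_peak_level Location of the peak (Hz, dB SPL).
#' @param offset_spread_logf Log-frequency spread of the offset, octaves.
#' @param offset_spread_level Level spread of the offset, dB.
#' @param octave_fraction One-octave offset as a fraction of quarter-octave.
#' @param hl_scale Multiplier on the offset surface for HL listeners.
#' @param mbld_scale_sd SD of the listener-specific log offset multiplier.
#' @param response_sd Response noise, categorical units.
#' @return A list of class `cls_params`.
#' @export
cls_params <- function(slope_nh = 0.10, slope_hl = 0.12,
                       slope_sd = 0.025, anchor_slope_sd = 0.005,
                       knee_cu = 2.5, segment_ratio = 2,
                       offset_peak_db = 7, offset_peak_freq = 1000,
                       offset_peak_level = 60, offset_spread_logf = 1.5,
                       offset_spread_level = 27.42,
                       octave_fraction = 4 / 7, hl_scale = 0.6,
                       mbld_scale_sd = 0.1, response_sd = 0.8) {
  p <- list(slope_nh = slope_nh, slope_hl = slope_hl, slope_sd = slope_sd,
            anchor_slope_sd = anchor_slope_sd, knee_cu = knee_cu,
            segment_ratio = segment_ratio, offset_peak_db = offset_peak_db,
            offset_peak_freq = offset_peak_freq,
            offset_peak_level = offset_peak_level,
            offset_spread_logf = offset_spread_logf,
            offset_spread_level = offset_spread_level,
            octave_fraction = octave_fraction, hl_scale = hl_scale,
            mbld_scale_sd = mbld_scale_sd, response_sd = response_sd)
  class(p) <- "cls_params"
  p
}

ANCHOR_FREQS <- c(500, 1000, 4000)

## Scaling constant relating the nominal slope s to the two segment
## slopes (m_lo = k*s, m_hi = ratio*k*s) such that the least-squares
## regression of CU on level over boundaries 2..9 of the *noise-free*
## loudness function returns exactly s. Homogeneity in (m_lo, m_hi)
## makes k independent of s.
slope_scale <- function(knee_cu = 2.5, segment_ratio = 2) {
  cu <- (2:9) - 0.5
  lv <- ifelse(cu <= knee_cu, cu, knee_cu + (cu - knee_cu) / segment_ratio)
  s_unit <- stats::cov(cu, lv) / stats::var(lv)  # LS slope with m_lo = 1
  1 / s_unit
}

## Two-segment piecewise-linear categorical loudness growth, clamped to
## [0, 10]. `t` is the level (dB) at CU = 0.5; `s` the nominal slope.
twoseg_cu <- function(level, t, s, knee_cu = 2.5, segment_ratio = 2) {
  k <- slope_scale(knee_cu, segment_ratio)
  m_lo <- k * s
  m_hi <- segment_ratio * m_lo
  t0 <- t - 0.5 / m_lo
  lk <- t0 + knee_cu / m_lo
  ## convex piecewise-linear (m_hi > m_lo): max of the two segments
  pmin(pmax(pmax(m_lo * (level - t0), knee_cu + m_hi * (level - lk)), 0), 10)
}

## Inverse of the (unclamped) two-segment growth.
twoseg_level <- function(cu, t, s, knee_cu = 2.5, segment_ratio = 2) {
  k <- slope_scale(knee_cu, segment_ratio)
  m_lo <- k * s
  m_hi <- segment_ratio * m_lo
  t0 <- t - 0.5 / m_lo
  lk <- t0 + knee_cu / m_lo
  ## inverse of a convex piecewise-linear map: min of the two inverses
  pmin(t0 + cu / m_lo, lk + (cu - knee_cu) / m_hi)
}

#' Construct a synthetic listener
#'
#' A listener is defined by anchor thresholds and slopes at 0.5, 1 and
#' 4 kHz (log-frequency interpolation in between, straight-line
#' extrapolation beyond), a two-segment categorical loudness growth at
#' each frequency, a listener-specific multiplier on the bandwidth-offset
#' surface, and Gaussian response noise on the categorical scale.
#'
#' @param group `"NH"` or `"HL"`.
#' @param anchor_thresholds Levels (dB SPL) at which CU = 0.5, at 0.5, 1
#'   and 4 kHz. Audiometric threshold (dB HL) is taken numerically equal.
#' @param anchor_slopes Nominal slopes (cat/dB) at the anchors.
#' @param mbld_scale Listener multiplier on the bandwidth-offset surface.
#' @param params A `cls_params` object.
#' @param id Listener identifier.
#' @param seed Integer seed for the listener's response stream.
#' @return An object of class `listener`.
#' @export
make_listener <- function(group = c("NH", "HL"), anchor_thresholds,
                          anchor_slopes, mbld_scale = 1,
                          params = cls_params(), id = "L1", seed = 1) {
  group <- match.arg(group)
  stopifnot(length(anchor_thresholds) == 3, length(anchor_slopes) == 3,
            all(anchor_slopes > 0))
  audiogram <- interp_logf(ANCHOR_FREQS, anchor_thresholds,
                           c(250, 500, 750, 1000, 1500, 2000, 3000, 4000,
                             6000, 8000))
  names(audiogram) <- c("250", "500", "750", "1000", "1500", "2000", "3000",
                        "4000", "6000", "8000")
  pta <- mean(audiogram[c("500", "1000", "2000")])
  if (group == "NH" && pta > 15) {
    stop("invalid-config: NH listener requires PTA <= 15 dB HL", call. = FALSE)
  }
  if (group == "HL" && (pta < 16 || pta > 55)) {
    stop("invalid-config: HL listener requires PTA in [16, 55] dB HL",
         call. = FALSE)
  }
  structure(list(group = group, id = id,
                 anchor_freqs = ANCHOR_FREQS,
                 anchor_thresholds = anchor_thresholds,
                 anchor_slopes = anchor_slopes,
                 audiogram = audiogram, pta = pta,
                 mbld_scale = mbld_scale, params = params,
                 response_sd = params$response_sd, seed = seed),
            class = "listener")
}

#' @export
print.listener <- function(x, ...) {
  cat(sprintf("<listener %s> group %s, PTA %.1f dB HL, slope at 1 kHz %.3f cat/dB\n",
              x$id, x$group, x$pta, x$anchor_slopes[2]))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Samples `n_nh` normal-hearing and `n_hl` hearing-impaired listeners.
#' Audiograms are flat-to-sloping random profiles constrained to the
#' group PTA bounds (NH <= 15 dB HL; HL in 16..55 dB HL); slopes are
#' drawn around the group means (0.10 / 0.12 cat/dB by default); HL
#' surfaces sit at elevated thresholds with steeper growth, so the
#' "very loud" boundary stays near normal (recruitment).
#'
#' @param n_nh,n_hl Group sizes.
#' @param params A `cls_params` object.
#' @param seed Integer seed.
#' @return A list of `listener` objects, classed `cohort`.
#' @export
make_cohort <- function(n_nh = 32, n_hl = 68, params = cls_params(), seed = 1) {
  stopifnot(n_nh >= 0, n_hl >= 0)
  if (params$slope_nh <= 0 || params$slope_hl <= 0) {
    stop("invalid-config: group slopes must be positive", call. = FALSE)
  }
  listeners <- with_seed(seed, {
    out <- vector("list", n_nh + n_hl)
    draw_one <- function(group, id, lseed) {
      for (i in 1:200) {
        if (group == "NH") {
          th <- c(stats::rnorm(2, 5, 3), stats::rnorm(1, 8, 5))
          th <- pmin(pmax(th, -5), c(15, 15, 20))
          s_base <- stats::rnorm(1, params$slope_nh, params$slope_sd)
        } else {
          b <- stats::runif(1, 18, 50)
          th <- c(b - stats::runif(1, 0, 10), b, b + stats::runif(1, 0, 25))
          th <- pmin(pmax(th, 0), 80)
          s_base <- stats::rnorm(1, params$slope_hl, params$slope_sd)
        }
        s <- s_base + stats::rnorm(3, 0, params$anchor_slope_sd)
        pta <- (th[1] + th[2] + (th[2] + th[3]) / 2) / 3
        ok <- if (group == "NH") pta <= 15 else (pta >= 16 && pta <= 55)
        if (ok && all(s > 0.02)) break
      }
      make_listener(group, th, s,
                    mbld_scale = exp(stats::rnorm(1, 0, params$mbld_scale_sd)),
                    params = params, id = id, seed = lseed)
    }
    for (i in seq_len(n_nh)) {
      out[[i]] <- draw_one("NH", sprintf("NH%02d", i), derive_seed(seed, i))
    }
    for (j in seq_len(n_hl)) {
      out[[n_nh + j]] <- draw_one("HL", sprintf("HL%02d", j),
                                  derive_seed(seed, n_nh + j))
    }
    out
  })
  structure(listeners, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  gr <- vapply(x, `[[`, character(1), "group")
  cat(sprintf("<cohort> %d listeners (%d NH, %d HL)\n",
              length(x), sum(gr == "NH"), sum(gr == "HL")))
  invisible(x)
}

#' Bandwidth-dependent equivalent-level offset
#'
#' The equivalent-level reduction (dB) a narrow-band stimulus suffers
#' relative to a tone of the same level: a smooth bump over frequency and
#' level, zero for tones, peaking (by default) at 7 dB at 1 kHz and
#' 60 dB SPL for NH quarter-octave noise; the one-octave offset is
#' `octave_fraction` of the quarter-octave offset, and HL listeners carry
#' `hl_scale` of the NH offset.
#'
#' @param freq Frequency, Hz.
#' @param level Level, dB SPL.
#' @param bandwidth_oct Bandwidth in octaves: 0, 0.25 or 1.
#' @param group `"NH"` or `"HL"`.
#' @param params A `cls_params` object.
#' @param mbld_scale Optional listener-specific multiplier.
#' @return Offset in dB (>= 0).
#' @export
bandwidth_offset <- function(freq, level, bandwidth_oct, group = "NH",
                             params = cls_params(), mbld_scale = 1) {
  frac <- if (isTRUE(all.equal(bandwidth_oct, 0))) {
    0
  } else if (isTRUE(all.equal(bandwidth_oct, 0.25))) {
    1
  } else if (isTRUE(all.equal(bandwidth_oct, 1))) {
    params$octave_fraction
  } else {
    stop("invalid-spec: bandwidth_oct must be 0, 0.25 or 1", call. = FALSE)
  }
  if (frac == 0) return(0 * freq * level)
  g <- if (group == "HL") params$hl_scale else 1
  params$offset_peak_db * frac * g * mbld_scale *
    exp(-(log2(freq / params$offset_peak_freq))^2 /
          (2 * params$offset_spread_logf^2)) *
    exp(-(level - params$offset_peak_level)^2 /
          (2 * params$offset_spread_level^2))
}

#' Ground-truth categorical loudness of a listener
#'
#' Evaluates the listener's CU(f, L) surface at an effective level
#' `level - bandwidth_offset(...)`; continuous, non-decreasing in level,
#' clamped to the 0-10 categorical scale.
#'
#' @param listener A `listener`.
#' @param freq Frequency, Hz.
#' @param level Level, dB SPL (vectorized).
#' @param bandwidth_oct Stimulus bandwidth in octaves (0, 0.25, 1).
#' @return Categorical units in \[0, 10\].
#' @export
cu <- function(listener, freq, level, bandwidth_oct = 0) {
  p <- listener$params
  off <- bandwidth_offset(freq, level, bandwidth_oct, listener$group, p,
                          listener$mbld_scale)
  t <- interp_logf(listener$anchor_freqs, listener$anchor_thresholds, freq)
  s <- interp_logf(listener$anchor_freqs, listener$anchor_slopes, freq)
  twoseg_cu(level - off, t, s, p$knee_cu, p$segment_ratio)
}

#' Analytic category-response probabilities
#'
#' Probabilities of the 11 response categories given an underlying
#' categorical loudness `cu_val`: the response is `round(cu + e)` with
#' Gaussian `e`, clamped to 0..10, so the masses are differences of
#' normal CDFs at the half-integer cut points with the tails absorbed
#' into categories 0 and 10.
#'
#' @param cu_val Underlying categorical loudness (vectorized).
#' @param sd Response noise SD in categorical units.
#' @return A matrix with 11 columns (categories 0..10) summing to 1 per row.
#' @export
category_probs <- function(cu_val, sd) {
  if (sd <= 0) {
    k <- pmin(pmax(round(cu_val), 0), 10)
    m <- matrix(0, length(cu_val), 11)
    m[cbind(seq_along(cu_val), k + 1L)] <- 1
    return(m)
  }
  cuts <- c(-Inf, (0:9) + 0.5, Inf)
  cdf <- vapply(cuts, function(cc) stats::pnorm((cc - cu_val) / sd),
                numeric(length(cu_val)))
  if (length(cu_val) == 1) cdf <- matrix(cdf, nrow = 1)
  cdf[, 2:12, drop = FALSE] - cdf[, 1:11, drop = FALSE]
}

#' Simulate a categorical response
#'
#' @param listener A `listener`.
#' @param freq Frequency, Hz.
#' @param level Level, dB SPL.
#' @param bandwidth_oct Bandwidth in octaves.
#' @param trial_seed Integer seed for this trial's response noise.
#' @return Integer category 0..10 (0 = "Can't Hear", 10 = "Too Loud").
#' @export
respond <- function(listener, freq, level, bandwidth_oct = 0,
                    trial_seed = NULL) {
  cu_val <- cu(listener, freq, level, bandwidth_oct)
  eps <- with_seed(trial_seed, stats::rnorm(1, 0, listener$response_sd))
  as.integer(pmin(pmax(round(cu_val + eps), 0), 10))
}

#' Ground-truth category-boundary levels of a listener
#'
#' The level at each frequency where the noiseless CU surface crosses
#' `k - 0.5`, for boundaries k = 1..10. For noise bandwidths the
#' bandwidth offset enters through the fixed point
#' `L = L_tone(k - 0.5) + offset(f, L)`.
#'
#' @param listener A `listener`.
#' @param bandwidth_oct Bandwidth in octaves.
#' @param freqs Frequencies, Hz.
#' @return A 10 x length(freqs) matrix of levels (dB SPL).
#' @export
true_boundaries <- function(listener, bandwidth_oct = 0,
                            freqs = PROFILE_FREQS) {
  p <- listener$params
  t <- interp_logf(listener$anchor_freqs, listener$anchor_thresholds, freqs)
  s <- interp_logf(listener$anchor_freqs, listener$anchor_slopes, freqs)
  b <- matrix(NA_real_, 10, length(freqs),
              dimnames = list(paste0("b", 1:10), as.character(freqs)))
  for (j in seq_along(freqs)) {
    lt <- twoseg_level((1:10) - 0.5, t[j], s[j], p$knee_cu, p$segment_ratio)
    lv <- lt
    for (it in 1:25) {
      lv <- lt + bandwidth_offset(freqs[j], lv, bandwidth_oct,
                                  listener$group, p, listener$mbld_scale)
    }
    b[, j] <- lv
  }
  b
}
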