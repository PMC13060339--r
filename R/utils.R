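#' @keywords internal
#' @useDynLib loudsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

## Reference pressure for dB SPL (20 micropascal).
P_REF <- 20e-6

#' Convert a sound pressure level to RMS pressure
#'
#' @param level_db Level in dB SPL.
#' @return RMS pressure in pascals.
#' @export
spl_to_pa <- function(level_db) P_REF * 10^(level_db / 20)

#' Convert an RMS pressure to sound pressure level
#'
#' @param pa RMS pressure in pascals.
#' @return Level in dB SPL.
#' @export
pa_to_spl <- function(pa) 20 * log10(pa / P_REF)

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's state afterwards. Makes generators pure
## functions of (args, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

## Deterministic derived seeds for sub-streams (kept below 2^31).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 104729 * as.numeric(k)) %% 2147483629L)
}

## Shannon entropy of a probability vector (nats); 0 * log 0 := 0.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

## Piecewise-linear interpolation on log2 frequency with straight-line
## extrapolation beyond the end anchors (used for threshold and slope
## surfaces and for the 8-kHz boundary extrapolation).
interp_logf <- function(anchor_freq, anchor_val, freq) {
  x <- log2(anchor_freq)
  xf <- log2(freq)
  n <- length(x)
  out <- stats::approx(x, anchor_val, xout = xf, rule = 2)$y
  lo <- xf < x[1]
  hi <- xf > x[n]
  if (any(lo)) {
    s <- (anchor_val[2] - anchor_val[1]) / (x[2] - x[1])
    out[lo] <- anchor_val[1] + s * (xf[lo] - x[1])
  }
  if (any(hi)) {
    s <- (anchor_val[n] - anchor_val[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- anchor_val[n] + s * (xf[hi] - x[n])
  }
  out
}

#' Standard profile frequencies
#'
#' The ten standard audiometric frequencies (Hz) at which loudness
#' profiles report category boundaries.
#' @export
PROFILE_FREQS <- c(250, 500, 750, 1000, 1500, 2000, 3000, 4000, 6000, 8000)

#' Frequencies sampled by the adaptive procedure
#'
#' The nine frequencies (Hz) at which stimuli are presented; 8 kHz is
#' never presented and its profile column is produced by extrapolation.
#' @export
SAMPLED_FREQS <- c(250, 500, 750, 1000, 1500, 2000, 3000, 4000, 6000)

## ISO-style category labels for the 0-10 categorical-unit scale.
#' Loudness category labels
#'
#' Labels for the 11 response categories on the 0-10 categorical-unit
#' scale. Even categories carry the named labels; odd categories are the
#' unnamed intermediate bars. The top category is labelled "Too Loud"
#' (the historical variant of "Extremely Loud").
#'
#' @param category Integer vector of categories in 0..10.
#' @return Character vector of labels.
#' @export
category_label <- function(category) {
  stopifnot(all(category %in% 0:10))
  labs <- c("Can't Hear", "(1)", "Very Soft", "(3)", "Soft", "Medium",
            "Loud", "(7)", "Very Loud", "(9)", "Too Loud")
  labs[category + 1L]
}
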