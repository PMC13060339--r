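#' Fit a loudness profile to trial records
#'
#' Maximum-a-posteriori fit of the correlated loudness surface to the
#' trial-by-trial stimuli and categorical responses of one adaptive run.
#' The fitted family matches the adaptive procedure's hypothesis space —
#' threshold and nominal slope at the 0.5/1/4-kHz anchor frequencies with
#' log-frequency interpolation (slopes free per anchor in the continuous
#' fit) — plus, for noise runs, a single amplitude on the canonical
#' bandwidth-offset bump (fixed peak location and spreads), which lets the
#' fitted surface express the level-dependent equivalent-level reduction
#' of narrow-band stimuli. A weak smoothness penalty ties the anchor
#' slopes together.
#'
#' The profile itself is the 10 x 10 matrix of category-boundary levels:
#' the level at which the fitted noiseless surface crosses `k - 0.5` CU,
#' for boundaries k = 1..10 and the ten standard frequencies 0.25-8 kHz.
#' The 8-kHz column is produced by the surface's log-frequency
#' extrapolation (stimuli are never presented at 8 kHz) and is flagged in
#' the diagnostics.
#'
#' @param trials A `qcls_trials` data frame (columns `freq`, `level`,
#'   `category`, `bandwidth_oct`); at least 20 trials over >= 2 frequencies.
#' @param config A `qcls_config` (supplies the response SD, growth-segment
#'   shape and the starting grid).
#' @param params A `cls_params` (supplies the canonical offset-bump shape).
#' @param slope_penalty_sd Scale (cat/dB) of the Gaussian smoothness
#'   penalty on anchor-slope differences.
#' @param bump_prior_mean,bump_prior_sd Weakly-informative Gaussian prior
#'   on the bandwidth-offset amplitude (dB, on the quarter-octave scale;
#'   both are multiplied by the bandwidth's offset fraction). The
#'   amplitude is only weakly separated from a uniform threshold shift by
#'   a single 100-trial run, and the mid-single-digit-dB prior resolves
#'   that ridge without overriding informative data.
#' @return An object of class `loudness_profile`.
#' @export
fit_profile <- function(trials, config = qcls_config(), params = cls_params(),
                        slope_penalty_sd = 0.03, bump_prior_mean = 5,
                        bump_prior_sd = 3) {
  if (nrow(trials) < 20) {
    stop("too-few-trials: need at least 20 trials", call. = FALSE)
  }
  if (length(unique(trials$freq)) < 2) {
    stop("too-few-trials: need trials at >= 2 frequencies", call. = FALSE)
  }
  bw <- unique(trials$bandwidth_oct)
  if (length(bw) != 1) {
    stop("trials must come from a single stimulus condition", call. = FALSE)
  }
  has_bump <- bw > 0
  frac <- if (!has_bump) 0 else if (isTRUE(all.equal(bw, 0.25))) 1 else
    params$octave_fraction

  ## canonical bump shape (unit amplitude at its own peak for this bandwidth)
  bump <- function(freq, level) {
    if (!has_bump) return(0)
    exp(-(log2(freq / params$offset_peak_freq))^2 /
          (2 * params$offset_spread_logf^2)) *
      exp(-(level - params$offset_peak_level)^2 /
            (2 * params$offset_spread_level^2))
  }

  wmat <- t(vapply(trials$freq, anchor_weights, numeric(3)))
  sd <- config$response_sd
  cat_lo <- ifelse(trials$category == 0, -Inf, trials$category - 0.5)
  cat_hi <- ifelse(trials$category == 10, Inf, trials$category + 0.5)
  bshape <- bump(trials$freq, trials$level)

  nll <- function(theta) {
    t_anchor <- theta[1:3]
    s_anchor <- theta[4:6]
    a <- if (has_bump) theta[7] else 0
    t_f <- as.numeric(wmat %*% t_anchor)
    s_f <- as.numeric(wmat %*% s_anchor)
    le <- trials$level - a * bshape
    cu_f <- twoseg_cu(le, t_f, s_f, config$knee_cu, config$segment_ratio)
    p <- stats::pnorm((cat_hi - cu_f) / sd) - stats::pnorm((cat_lo - cu_f) / sd)
    nl <- -sum(log(pmax(p, config$lik_floor))) +
      0.5 * sum((s_anchor - mean(s_anchor))^2) / slope_penalty_sd^2
    if (has_bump) {
      nl <- nl + 0.5 * ((a - bump_prior_mean * frac) /
                          (bump_prior_sd * frac))^2
    }
    nl
  }

  ## start at the discrete posterior mode from a batch update
  post <- init_posterior(config)
  for (i in seq_len(nrow(trials))) {
    post <- update_posterior(post, trials[i, ])
  }
  m <- posterior_mode(post)
  w_post <- exp(post$log_mass)
  pm <- as.numeric(crossprod(w_post, post$grid))  # posterior-mean parameters
  base_starts <- list(c(m[["t1"]], m[["t2"]], m[["t3"]], rep(m[["s"]], 3)),
                      c(pm[1:3], rep(pm[4], 3)))
  lower <- c(rep(-30, 3), rep(0.02, 3))
  upper <- c(rep(95, 3), rep(0.40, 3))
  pscale <- c(5, 5, 5, 0.02, 0.02, 0.02)
  if (has_bump) {
    starts <- c(lapply(c(2, 5, 8) * frac,
                       function(a0) c(base_starts[[1]], a0)),
                list(c(base_starts[[2]], 5 * frac)))
    lower <- c(lower, 0)
    upper <- c(upper, 15 * frac)
    pscale <- c(pscale, 1)
  } else {
    starts <- base_starts
  }
  fits <- lapply(starts, function(st) {
    stats::optim(st, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 500, parscale = pscale))
  })
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  theta <- fit$par
  est <- list(anchor_thresholds = theta[1:3], anchor_slopes = theta[4:6],
              bump_amplitude = if (has_bump) theta[7] else 0,
              bump_fraction = frac)

  boundaries <- profile_boundaries(est, bw, config, params)
  mono <- apply(boundaries, 2, function(b) all(diff(b) > 0))
  if (!all(mono)) {
    warning("fitted surface non-monotone at some frequencies; projected onto the monotone cone")
    boundaries <- apply(boundaries, 2, function(b) cummax(b) + 1e-6 * (seq_along(b) - 1))
  }
  structure(list(boundaries = boundaries,
                 bandwidth_oct = bw,
                 stim_type = if (bw == 0) "tone" else if (bw == 0.25)
                   "quarter_octave" else "one_octave",
                 listener_id = attr(trials, "listener_id"),
                 group = attr(trials, "group"),
                 estimates = est, config = config, params = params,
                 diagnostics = list(logLik = -fit$value,
                                    n_trials = nrow(trials),
                                    convergence = fit$convergence,
                                    extrapolated_freqs = 8000)),
            class = "loudness_profile")
}

#' Fit one listener's condition runs jointly
#'
#' Fits the runs of a single listener (tone, quarter-octave, one-octave —
#' any subset containing the tone run) with *shared* anchor thresholds
#' and slopes and one bandwidth-offset amplitude per noise condition.
#' Sharing the anchors resolves the ambiguity that limits single-run
#' noise fits: within one noise run, a uniform threshold shift and the
#' level-dependent offset amplitude are nearly exchangeable, whereas the
#' listener's tone run pins the thresholds and slopes, leaving the
#' amplitude cleanly identified. The per-condition boundary matrices and
#' everything downstream (contours, reductions, boundary tables) are
#' computed exactly as for [fit_profile()].
#'
#' @param trials_list A list of `qcls_trials`, one per stimulus
#'   condition (distinct bandwidths; one of them 0).
#' @param config A `qcls_config`.
#' @param params A `cls_params`.
#' @param slope_penalty_sd Smoothness penalty on anchor slopes (cat/dB).
#' @param bump_prior_mean,bump_prior_sd Optional Gaussian prior on the
#'   offset amplitudes (quarter-octave scale, scaled by each bandwidth's
#'   fraction). The default `bump_prior_sd = Inf` fits the amplitudes by
#'   maximum likelihood: the tone run already pins the anchors, so unlike
#'   the single-run case no regularization is needed, and a finite prior
#'   centered away from a listener's amplitude shrinks the estimate along
#'   the residual amplitude-threshold ridge (a bias that propagates to
#'   cohort medians). Supply a finite SD only to regularize deliberately.
#' @return A named list of `loudness_profile` objects, one per condition.
#' @export
fit_profiles_joint <- function(trials_list, config = qcls_config(),
                               params = cls_params(),
                               slope_penalty_sd = 0.03,
                               bump_prior_mean = 5, bump_prior_sd = Inf) {
  bws <- vapply(trials_list, function(tr) {
    b <- unique(tr$bandwidth_oct)
    if (length(b) != 1) {
      stop("each element must come from a single stimulus condition",
           call. = FALSE)
    }
    b
  }, numeric(1))
  if (anyDuplicated(bws)) stop("conditions must be distinct", call. = FALSE)
  if (!any(bws == 0)) stop("a tone run is required to anchor the joint fit",
                           call. = FALSE)
  trials_list <- trials_list[order(bws)]
  bws <- sort(bws)
  noise_idx <- which(bws > 0)
  fracs <- vapply(bws[noise_idx], function(b) {
    if (isTRUE(all.equal(b, 0.25))) 1 else if (isTRUE(all.equal(b, 1))) {
      params$octave_fraction
    } else stop("invalid-spec: bandwidth must be 0, 0.25 or 1", call. = FALSE)
  }, numeric(1))

  all_tr <- do.call(rbind, lapply(trials_list, function(tr) {
    tr[, c("freq", "level", "category", "bandwidth_oct")]
  }))
  cond_of <- rep(seq_along(trials_list),
                 vapply(trials_list, nrow, integer(1)))
  wmat <- t(vapply(all_tr$freq, anchor_weights, numeric(3)))
  sd <- config$response_sd
  cat_lo <- ifelse(all_tr$category == 0, -Inf, all_tr$category - 0.5)
  cat_hi <- ifelse(all_tr$category == 10, Inf, all_tr$category + 0.5)
  bshape <- exp(-(log2(all_tr$freq / params$offset_peak_freq))^2 /
                  (2 * params$offset_spread_logf^2)) *
    exp(-(all_tr$level - params$offset_peak_level)^2 /
          (2 * params$offset_spread_level^2))
  na <- length(noise_idx)

  nll <- function(theta) {
    t_f <- as.numeric(wmat %*% theta[1:3])
    s_f <- as.numeric(wmat %*% theta[4:6])
    a_of_cond <- numeric(length(trials_list))
    if (na > 0) a_of_cond[noise_idx] <- theta[6 + seq_len(na)]
    le <- all_tr$level - a_of_cond[cond_of] * bshape
    cu_f <- twoseg_cu(le, t_f, s_f, config$knee_cu, config$segment_ratio)
    p <- stats::pnorm((cat_hi - cu_f) / sd) -
      stats::pnorm((cat_lo - cu_f) / sd)
    nl <- -sum(log(pmax(p, config$lik_floor))) +
      0.5 * sum((theta[4:6] - mean(theta[4:6]))^2) / slope_penalty_sd^2
    if (na > 0 && is.finite(bump_prior_sd)) {
      nl <- nl + sum(0.5 * ((theta[6 + seq_len(na)] -
                               bump_prior_mean * fracs) /
                              (bump_prior_sd * fracs))^2)
    }
    nl
  }

  ## anchor start: grid posterior mode from the tone run
  post <- init_posterior(config)
  tone_tr <- trials_list[[which(bws == 0)]]
  for (i in seq_len(nrow(tone_tr))) post <- update_posterior(post, tone_tr[i, ])
  m <- posterior_mode(post)
  anchor_start <- c(m[["t1"]], m[["t2"]], m[["t3"]], rep(m[["s"]], 3))
  starts <- if (na > 0) {
    lapply(c(2, 5, 8), function(a0) c(anchor_start, a0 * fracs))
  } else {
    list(anchor_start)
  }
  lower <- c(rep(-30, 3), rep(0.02, 3), rep(0, na))
  upper <- c(rep(95, 3), rep(0.40, 3), 15 * fracs)
  pscale <- c(5, 5, 5, 0.02, 0.02, 0.02, rep(1, na))
  fits <- lapply(starts, function(st) {
    stats::optim(st, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 500, parscale = pscale))
  })
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  theta <- fit$par

  out <- lapply(seq_along(trials_list), function(k) {
    bw <- bws[k]
    a_k <- if (bw > 0) theta[6 + match(k, noise_idx)] else 0
    frac_k <- if (bw > 0) fracs[match(k, noise_idx)] else 0
    est <- list(anchor_thresholds = theta[1:3], anchor_slopes = theta[4:6],
                bump_amplitude = a_k, bump_fraction = frac_k)
    boundaries <- profile_boundaries(est, bw, config, params)
    structure(list(boundaries = boundaries, bandwidth_oct = bw,
                   stim_type = if (bw == 0) "tone" else if (bw == 0.25)
                     "quarter_octave" else "one_octave",
                   listener_id = attr(trials_list[[k]], "listener_id"),
                   group = attr(trials_list[[k]], "group"),
                   estimates = est, config = config, params = params,
                   diagnostics = list(logLik = -fit$value,
                                      n_trials = nrow(trials_list[[k]]),
                                      convergence = fit$convergence,
                                      joint = TRUE,
                                      extrapolated_freqs = 8000)),
              class = "loudness_profile")
  })
  names(out) <- vapply(out, `[[`, character(1), "stim_type")
  out
}

## Boundary levels implied by fitted surface parameters: fixed point
## L = L_tone(k - 0.5) + a * bump(f, L).
profile_boundaries <- function(est, bw, config, params) {
  freqs <- PROFILE_FREQS
  t_f <- interp_logf(ANCHOR_FREQS, est$anchor_thresholds, freqs)
  s_f <- interp_logf(ANCHOR_FREQS, est$anchor_slopes, freqs)
  b <- matrix(NA_real_, 10, length(freqs),
              dimnames = list(paste0("b", 1:10), as.character(freqs)))
  for (j in seq_along(freqs)) {
    lt <- twoseg_level((1:10) - 0.5, t_f[j], s_f[j], config$knee_cu,
                       config$segment_ratio)
    lv <- lt
    if (est$bump_amplitude > 0) {
      sh <- function(level) {
        exp(-(log2(freqs[j] / params$offset_peak_freq))^2 /
              (2 * params$offset_spread_logf^2)) *
          exp(-(level - params$offset_peak_level)^2 /
                (2 * params$offset_spread_level^2))
      }
      for (it in 1:25) lv <- lt + est$bump_amplitude * sh(lv)
    }
    b[, j] <- lv
  }
  b
}

#' @export
print.loudness_profile <- function(x, ...) {
  cat(sprintf("<loudness_profile> %s%s, %d trials, logLik %.1f\n",
              x$stim_type,
              if (!is.null(x$listener_id)) paste0(", listener ", x$listener_id) else "",
              x$diagnostics$n_trials, x$diagnostics$logLik))
  cat("Category-boundary levels (dB SPL), boundaries 1..10 x frequency:\n")
  print(round(x$boundaries, 1))
  invisible(x)
}

#' @export
coef.loudness_profile <- function(object, ...) object$boundaries

#' @export
summary.loudness_profile <- function(object, ...) {
  cat(sprintf("Loudness profile (%s condition)\n", object$stim_type))
  print(round(object$boundaries, 1))
  cat(sprintf("\n1-kHz loudness-growth slope: %.3f cat/dB\n",
              loudness_slope(object, 1000)))
  if (object$bandwidth_oct > 0) {
    cat(sprintf("Fitted bandwidth-offset amplitude: %.2f dB\n",
                object$estimates$bump_amplitude * object$estimates$bump_fraction))
  }
  invisible(object)
}

#' Expected categorical loudness under a fitted profile
#'
#' Interpolates the boundary levels at one of the profile frequencies:
#' piecewise-linear in level through the points (boundary level, k - 0.5),
#' extended linearly beyond the outer boundaries and clamped to \[0, 10\].
#'
#' @param object A `loudness_profile`.
#' @param freq One of the profile frequencies, Hz.
#' @param level Level(s), dB SPL.
#' @param ... Unused.
#' @return Expected CU values.
#' @export
predict.loudness_profile <- function(object, freq, level, ...) {
  b <- profile_column(object, freq)
  cu_k <- (1:10) - 0.5
  sl_lo <- (cu_k[2] - cu_k[1]) / (b[2] - b[1])
  sl_hi <- (cu_k[10] - cu_k[9]) / (b[10] - b[9])
  out <- stats::approx(b, cu_k, xout = level, rule = 2)$y
  lo <- level < b[1]
  hi <- level > b[10]
  out[lo] <- cu_k[1] + sl_lo * (level[lo] - b[1])
  out[hi] <- cu_k[10] + sl_hi * (level[hi] - b[10])
  pmin(pmax(out, 0), 10)
}

## boundary column at a profile frequency (exact match required)
profile_column <- function(profile, freq) {
  j <- which(abs(PROFILE_FREQS - freq) < 1e-6)
  if (length(j) != 1) {
    stop("freq must be one of the profile frequencies: ",
         paste(PROFILE_FREQS, collapse = ", "), call. = FALSE)
  }
  profile$boundaries[, j]
}

#' Level at a given categorical loudness under a fitted profile
#'
#' Inverse of [predict.loudness_profile()]: interpolates level as a
#' function of CU through the ten boundary points, extending linearly
#' beyond the outer boundaries (with a warning outside the fitted range).
#'
#' @param profile A `loudness_profile`.
#' @param freq One of the profile frequencies, Hz.
#' @param cu_val Categorical loudness value(s).
#' @param warn Warn when extrapolating beyond the outer boundaries?
#' @return Level(s), dB SPL.
#' @export
profile_level <- function(profile, freq, cu_val, warn = TRUE) {
  b <- profile_column(profile, freq)
  cu_k <- (1:10) - 0.5
  if (warn && any(cu_val < cu_k[1] | cu_val > cu_k[10])) {
    warning("categorical loudness outside the fitted dynamic range; extrapolating")
  }
  out <- stats::approx(cu_k, b, xout = cu_val, rule = 2)$y
  sl_lo <- (b[2] - b[1]) / (cu_k[2] - cu_k[1])
  sl_hi <- (b[10] - b[9]) / (cu_k[10] - cu_k[9])
  lo <- cu_val < cu_k[1]
  hi <- cu_val > cu_k[10]
  out[lo] <- b[1] + sl_lo * (cu_val[lo] - cu_k[1])
  out[hi] <- b[10] + sl_hi * (cu_val[hi] - cu_k[10])
  out
}

#' Equal-loudness contour of a fitted profile
#'
#' The level at each profile frequency producing a fixed loudness
#' category boundary: row extraction from the boundary matrix.
#'
#' @param profile A `loudness_profile`.
#' @param category_boundary Boundary index 1..10 (2 = "very soft" edge,
#'   5/6 bracket "medium", 9 = "very loud" edge).
#' @return Named numeric vector of levels (dB SPL) across frequency.
#' @export
elc <- function(profile, category_boundary) {
  stopifnot(category_boundary %in% 1:10)
  profile$boundaries[category_boundary, ]
}

#' @export
plot.loudness_profile <- function(x, boundaries = c(2, 5, 9), ...) {
  f <- PROFILE_FREQS / 1000
  graphics::matplot(f, t(x$boundaries[boundaries, , drop = FALSE]),
                    type = "b", log = "x", pch = 19, lty = 1,
                    xlab = "Frequency (kHz)", ylab = "Level (dB SPL)",
                    main = sprintf("Loudness profile (%s)", x$stim_type), ...)
  graphics::legend("topright", legend = paste0("boundary ", boundaries),
                   col = seq_along(boundaries), lty = 1, pch = 19, bty = "n")
  invisible(x)
}
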