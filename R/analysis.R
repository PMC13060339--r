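#' Loudness-growth slope of a fitted profile
#'
#' Least-squares slope of categorical loudness against boundary level at
#' one frequency, using boundaries 2-9 (the extreme boundaries are
#' excluded to avoid floor/ceiling distortion), in categorical units per
#' dB. Optionally restricts the regression to boundary levels below
#' `level_max` (e.g. 80 dB SPL).
#'
#' @param profile A `loudness_profile`.
#' @param freq One of the profile frequencies, Hz.
#' @param boundaries Boundary indices entering the regression.
#' @param level_max Optional upper limit (dB SPL) on boundary levels used.
#' @return Slope in cat/dB.
#' @export
loudness_slope <- function(profile, freq, boundaries = 2:9,
                           level_max = NULL) {
  b <- profile_column(profile, freq)[boundaries]
  cu_k <- boundaries - 0.5
  if (!is.null(level_max)) {
    keep <- b <= level_max
    b <- b[keep]
    cu_k <- cu_k[keep]
  }
  if (length(b) < 2) stop("undefined-slope: fewer than 2 usable boundaries",
                          call. = FALSE)
  if (stats::var(b) < 1e-12) stop("undefined-slope: degenerate boundary levels",
                                  call. = FALSE)
  as.numeric(stats::cov(cu_k, b) / stats::var(b))
}

#' Loudness reduction of a narrow-band stimulus relative to a tone
#'
#' The level difference between a narrow-band stimulus and the equally
#' loud tone at the same center frequency: the narrow-band profile is
#' read at (freq, level) to get its categorical loudness, the tone
#' profile is inverted at that loudness, and the reduction is
#' `level - equally_loud_tone_level`. Positive values mean the
#' narrow-band stimulus is softer than an equal-level tone.
#'
#' @param profile_tone Tone-condition `loudness_profile`.
#' @param profile_narrow Noise-condition `loudness_profile` of the same
#'   listener.
#' @param freq One of the profile frequencies, Hz.
#' @param level Stimulus level, dB SPL.
#' @return Reduction in dB.
#' @export
loudness_reduction <- function(profile_tone, profile_narrow, freq, level) {
  cu_n <- predict(profile_narrow, freq, level)
  level - profile_level(profile_tone, freq, cu_n, warn = FALSE)
}

#' Loudness summation of one-octave relative to quarter-octave noise
#'
#' The level difference between the quarter-octave stimulus equally loud
#' to the one-octave stimulus and the common stimulus level. Positive
#' values mean the one-octave noise is louder than equal-level
#' quarter-octave noise.
#'
#' @param profile_quarter Quarter-octave `loudness_profile`.
#' @param profile_octave One-octave `loudness_profile` of the same listener.
#' @param freq One of the profile frequencies, Hz.
#' @param level Stimulus level, dB SPL.
#' @return Summation in dB.
#' @export
loudness_summation <- function(profile_quarter, profile_octave, freq, level) {
  cu_o <- predict(profile_octave, freq, level)
  profile_level(profile_quarter, freq, cu_o, warn = FALSE) - level
}

#' Long-format category-boundary table for group statistics
#'
#' Stacks fitted profiles into the long format consumed by
#' [group_lmm()]: one row per (participant, stimulus bandwidth, boundary,
#' frequency) with the boundary level in dB SPL.
#'
#' @param profiles A list of `loudness_profile` objects (any mix of
#'   listeners and conditions).
#' @param freq Optional single frequency (Hz) to restrict the table to.
#' @return A data frame with columns `participant`, `group`, `bandwidth`,
#'   `category`, `freq`, `level`.
#' @export
boundary_table <- function(profiles, freq = NULL) {
  rows <- lapply(profiles, function(p) {
    b <- p$boundaries
    data.frame(participant = p$listener_id,
               group = p$group,
               bandwidth = p$stim_type,
               category = rep(paste0("b", 1:10), times = ncol(b)),
               freq = rep(PROFILE_FREQS, each = 10),
               level = as.numeric(b))
  })
  out <- do.call(rbind, rows)
  if (!is.null(freq)) out <- out[abs(out$freq - freq) < 1e-6, ]
  out$group <- factor(out$group, levels = c("NH", "HL"))
  out$bandwidth <- factor(out$bandwidth,
                          levels = c("tone", "quarter_octave", "one_octave"))
  out$category <- factor(out$category, levels = paste0("b", 1:10))
  rownames(out) <- NULL
  out
}

#' Mixed-effects model of category-boundary levels
#'
#' REML fit of `level ~ group * bandwidth * category + (1 | participant)`
#' with Type III F-tests using Satterthwaite degrees of freedom
#' (delegated to \pkg{lmerTest}). The bandwidth contrast of interest —
#' quarter-octave noise vs tone within each group, pooled across
#' category boundaries — is extracted with \pkg{emmeans}.
#'
#' @param table A long-format boundary table from [boundary_table()]
#'   (typically restricted to one frequency).
#' @return An object of class `cls_lmm`: the fitted model, the Type III
#'   ANOVA table, and the per-group quarter-vs-tone contrasts.
#' @export
group_lmm <- function(table) {
  n_per_group <- tapply(table$participant, table$group,
                        function(x) length(unique(x)))
  if (any(is.na(n_per_group)) || any(n_per_group < 2)) {
    stop("need at least 2 participants per group", call. = FALSE)
  }
  dropped <- c(group = nlevels(droplevels(table$group)) < 2,
               bandwidth = nlevels(droplevels(table$bandwidth)) < 2,
               category = nlevels(droplevels(table$category)) < 2)
  if (any(dropped)) {
    stop("rank-deficient design: no variation in term(s) ",
         paste(names(dropped)[dropped], collapse = ", "), call. = FALSE)
  }
  fit <- lmerTest::lmer(level ~ group * bandwidth * category +
                          (1 | participant),
                        data = table, REML = TRUE)
  a3 <- stats::anova(fit, type = "III")
  emm <- emmeans::emmeans(fit, ~ bandwidth | group)
  ctr <- emmeans::contrast(emm, method = list(
    quarter_vs_tone = c(-1, 1, 0)[seq_len(nlevels(droplevels(table$bandwidth)))]))
  ctr <- as.data.frame(ctr)
  structure(list(fit = fit, anova = a3, contrasts = ctr), class = "cls_lmm")
}

#' @export
print.cls_lmm <- function(x, ...) {
  cat("Mixed-effects model of category-boundary levels (REML)\n\n")
  cat("Type III F-tests (Satterthwaite df):\n")
  print(round(as.data.frame(x$anova), 3))
  cat("\nQuarter-octave vs tone contrast (dB, pooled across boundaries):\n")
  print(x$contrasts)
  invisible(x)
}

#' Quarter-octave-vs-tone contrast for one group
#'
#' @param lmm_fit A `cls_lmm` from [group_lmm()].
#' @param group `"NH"` or `"HL"`.
#' @return The contrast estimate in dB.
#' @export
mbld_contrast <- function(lmm_fit, group = "NH") {
  ctr <- lmm_fit$contrasts
  est <- ctr$estimate[ctr$group == group]
  if (length(est) != 1) stop("contrast for group not found", call. = FALSE)
  est
}

#' P-value of a Type III fixed-effect test
#'
#' @param lmm_fit A `cls_lmm`.
#' @param term Row name in the ANOVA table, e.g. `"group:bandwidth"`.
#' @return The p-value.
#' @export
lmm_term_p <- function(lmm_fit, term) {
  a <- as.data.frame(lmm_fit$anova)
  if (!term %in% rownames(a)) {
    stop("term not in ANOVA table: ", term, call. = FALSE)
  }
  a[term, "Pr(>F)"]
}

#' Independent-samples t-test on loudness-growth slopes
#'
#' Classic two-sample Student t-test (equal variances, df = n1 + n2 - 2),
#' as used to compare group slopes.
#'
#' @param slopes_nh,slopes_hl Numeric vectors of per-listener slopes.
#' @return A list with `t`, `df`, `p`.
#' @export
slope_ttest <- function(slopes_nh, slopes_hl) {
  tt <- stats::t.test(slopes_hl, slopes_nh, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Element-wise summary of a set of profiles
#'
#' Applies a summary function (median by default) across listeners'
#' boundary matrices, returning a synthetic profile-like object usable by
#' the contour and inversion helpers.
#'
#' @param profiles List of `loudness_profile` objects (same condition).
#' @param fun Summary function (e.g. `median`, `mean`).
#' @return A `loudness_profile` whose boundaries are the summary.
#' @export
profile_summary <- function(profiles, fun = stats::median) {
  arr <- simplify2array(lapply(profiles, coef))
  b <- apply(arr, c(1, 2), fun)
  p <- profiles[[1]]
  p$boundaries <- b
  p$listener_id <- sprintf("summary(%d)", length(profiles))
  p$diagnostics$summary_fun <- deparse(substitute(fun))
  p
}

#' Loudness loss: hearing-impaired minus normal-hearing contours
#'
#' Subtracts the normal-hearing equal-loudness contours from the
#' hearing-loss contours, per category boundary and frequency.
#'
#' @param median_hl_profile Summary profile of the HL group.
#' @param mean_nh_profile Summary profile of the NH group.
#' @return A 10 x 10 matrix of dB differences.
#' @export
loudness_loss <- function(median_hl_profile, mean_nh_profile) {
  coef(median_hl_profile) - coef(mean_nh_profile)
}

#' Hearing-aid gain restoring normal loudness
#'
#' For each input level, the gain (dB) that would raise a hearing-loss
#' listener's stimulus to the level producing the normal-hearing
#' loudness: `gain(f, L) = L_HL(cu_NH(L)) - L`. For recruiting surfaces
#' the gain shrinks with increasing level.
#'
#' @param nh_profile,hl_profile Profiles (or group summaries).
#' @param freq One of the profile frequencies, Hz.
#' @param levels Input levels, dB SPL.
#' @return Named vector of gains (dB) at `levels`.
#' @export
hearing_aid_gain <- function(nh_profile, hl_profile, freq,
                             levels = seq(20, 100, by = 10)) {
  cu_nh <- predict(nh_profile, freq, levels)
  g <- profile_level(hl_profile, freq, cu_nh, warn = FALSE) - levels
  stats::setNames(g, levels)
}
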