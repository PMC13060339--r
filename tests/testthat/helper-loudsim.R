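## Shared fixtures and memoised heavy computations for the test suite.

## Canonical NH / HL listeners with exactly the group-default parameters
## (no between-subject jitter) -- handy analytic references.
default_nh_listener <- function(params = cls_params()) {
  make_listener("NH", c(5, 5, 8), rep(params$slope_nh, 3),
                mbld_scale = 1, params = params, id = "NHref", seed = 1)
}

default_hl_listener <- function(params = cls_params()) {
  make_listener("HL", c(30, 32, 40), rep(params$slope_hl, 3),
                mbld_scale = 1, params = params, id = "HLref", seed = 2)
}

## Least-squares slope of boundary CU on level, the same statistic
## loudness_slope() computes, written independently as a closed-form
## oracle on a boundary-level vector.
ls_slope_oracle <- function(levels, boundaries = 2:9) {
  cu <- boundaries - 0.5
  lv <- levels[boundaries]
  sum((cu - mean(cu)) * (lv - mean(lv))) / sum((lv - mean(lv))^2)
}

## LS slope restricted to boundaries at or below a level ceiling.
ls_slope_oracle_below <- function(levels, lmax) {
  keep <- which(levels[2:9] <= lmax) + 1
  cu <- keep - 0.5
  lv <- levels[keep]
  sum((cu - mean(cu)) * (lv - mean(lv))) / sum((lv - mean(lv))^2)
}

## inverse of a listener's 1-kHz CU growth
twoseg_level_t <- function(listener, cu_val) {
  p <- listener$params
  loudsim:::twoseg_level(cu_val, listener$anchor_thresholds[2],
                         listener$anchor_slopes[2], p$knee_cu,
                         p$segment_ratio)
}

## A loudness_profile built directly from a listener's ground truth,
## bypassing the fitting pipeline (used as an analysis-level oracle).
truth_profile <- function(listener, bandwidth_oct = 0) {
  structure(list(
    boundaries = true_boundaries(listener, bandwidth_oct),
    bandwidth_oct = bandwidth_oct,
    stim_type = if (bandwidth_oct == 0) "tone" else
      if (bandwidth_oct == 0.25) "quarter_octave" else "one_octave",
    listener_id = listener$id, group = listener$group,
    estimates = NULL, config = qcls_config(), params = listener$params,
    diagnostics = list(logLik = NA, n_trials = 0, convergence = 0,
                       extrapolated_freqs = 8000)),
    class = "loudness_profile")
}

## Small hypothesis space + candidate lattice for exact/brute-force tests.
tiny_qcls_config <- function() {
  qcls_config(t_center_grid = c(0, 20, 40),
              dt_low_grid = 0, dt_high_grid = c(0, 10),
              slope_grid = c(0.08, 0.12),
              freqs = c(500, 1000, 2000, 4000, 6000),
              levels = seq(20, 80, by = 15))
}

## Memoised store for expensive shared computations (full-cohort pipeline,
## calibrated NEA model). Filled on first use, reused across test files.
.test_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

## Full default-cohort pipeline (32 NH + 68 HL, three conditions,
## 100-trial adaptive runs) under a fixed seed, mirroring
## scripts/acceptance.R: per-run tone fits for slopes, joint fits of each
## listener's three condition runs for the MBLD quantities.
acceptance_pipeline <- function() {
  memo("pipeline", {
    cohort <- make_cohort(32, 68, seed = 42)
    cfg <- qcls_config()
    groups <- vapply(cohort, `[[`, character(1), "group")
    conds <- c(tone = 0, quarter_octave = 0.25, one_octave = 1)
    trials <- lapply(names(conds), function(cd) {
      lapply(seq_along(cohort), function(i) {
        run_qcls(cohort[[i]], conds[[cd]], 100,
                 seed = derive_seed_t(42, 100 * i + match(cd, names(conds))),
                 config = cfg)
      })
    })
    names(trials) <- names(conds)
    tone_profiles <- lapply(trials$tone, fit_profile, config = cfg)
    joint <- lapply(seq_along(cohort), function(i) {
      fit_profiles_joint(lapply(trials, `[[`, i), cfg)
    })
    list(cohort = cohort, groups = groups, config = cfg,
         tone_profiles = tone_profiles, joint = joint)
  })
}

## the package-internal seed-derivation, re-exposed for test reproducibility
derive_seed_t <- function(seed, k) loudsim:::derive_seed(seed, k)

## Calibrated NEA model at the reduced acceptance scale.
acceptance_nea_model <- function() {
  memo("nea", nea_calibrate(nea_model(n_channels = 20, n1 = 20),
                            n_reps = 10, seed = 7))
}
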