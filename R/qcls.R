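#' Configuration of the adaptive categorical loudness-scaling procedure
#'
#' Defines the discrete hypothesis space and the candidate stimulus
#' lattice of the Bayesian adaptive procedure. Hypotheses parameterize a
#' correlated loudness surface: threshold levels at three anchor
#' frequencies (0.5, 1, 4 kHz) and a nominal growth slope shared across
#' anchors, with log-frequency interpolation in between. Candidate
#' stimuli live on a lattice of nine center frequencies (0.25-6 kHz;
#' 8 kHz is never sampled) by 2-dB level steps over 0-100 dB SPL.
#'
#' The hypothesis grid expresses cross-frequency correlation directly:
#' the 1-kHz anchor threshold takes values on a fine grid, while the
#' 0.5- and 4-kHz anchors are offsets from it (audiograms are smooth, so
#' only nearby combinations are entertained), and one nominal slope is
#' shared across anchors. The continuous profile fit
#' ([fit_profile()]) later frees the per-anchor slopes.
#'
#' @param t_center_grid Candidate 1-kHz anchor thresholds, dB SPL.
#' @param dt_low_grid Candidate offsets of the 0.5-kHz anchor from the
#'   1-kHz anchor, dB.
#' @param dt_high_grid Candidate offsets of the 4-kHz anchor, dB.
#' @param slope_grid Candidate nominal slopes, cat/dB.
#' @param freqs Candidate stimulus frequencies, Hz.
#' @param levels Candidate stimulus levels, dB SPL.
#' @param response_sd Response-noise SD assumed by the procedure, CU.
#' @param knee_cu,segment_ratio Growth-segment parameters (see
#'   [cls_params()]).
#' @param lik_floor Lower floor on category likelihoods, guarding the
#'   update against lapse responses outside the model.
#' @param prune_tol The information-gain computation runs over the
#'   smallest hypothesis set covering `1 - prune_tol` of the posterior
#'   mass (never applied to updates).
#' @return A list of class `qcls_config`.
#' @export
qcls_config <- function(t_center_grid = seq(-5, 65, by = 5),
                        dt_low_grid = c(-10, -5, 0, 5, 10),
                        dt_high_grid = c(-10, 0, 10, 20, 30),
                        slope_grid = seq(0.05, 0.17, by = 0.015),
                        freqs = SAMPLED_FREQS,
                        levels = seq(0, 100, by = 2),
                        response_sd = 0.8, knee_cu = 2.5, segment_ratio = 2,
                        lik_floor = 1e-6, prune_tol = 1e-9) {
  if (length(t_center_grid) < 1 || length(dt_low_grid) < 1 ||
      length(dt_high_grid) < 1 || length(slope_grid) < 1 ||
      length(freqs) < 1 || length(levels) < 1) {
    stop("invalid-config: empty hypothesis or candidate grid", call. = FALSE)
  }
  structure(list(t_center_grid = t_center_grid, dt_low_grid = dt_low_grid,
                 dt_high_grid = dt_high_grid, slope_grid = slope_grid,
                 freqs = freqs, levels = levels, response_sd = response_sd,
                 knee_cu = knee_cu, segment_ratio = segment_ratio,
                 lik_floor = lik_floor, prune_tol = prune_tol),
            class = "qcls_config")
}

## Interpolation weights of the three anchor frequencies at `freq`
## (linear in log2 frequency, straight-line extrapolation outside).
anchor_weights <- function(freq) {
  x <- log2(ANCHOR_FREQS)
  xf <- log2(freq)
  w <- numeric(3)
  if (xf <= x[2]) {
    a <- (xf - x[1]) / (x[2] - x[1])
    w[1] <- 1 - a
    w[2] <- a
  } else {
    a <- (xf - x[2]) / (x[3] - x[2])
    w[2] <- 1 - a
    w[3] <- a
  }
  w
}

## Hypothesis parameter matrix (G x 4: t1, t2, t3, s).
hypothesis_grid <- function(config) {
  g <- expand.grid(t2 = config$t_center_grid, d1 = config$dt_low_grid,
                   d3 = config$dt_high_grid, s = config$slope_grid,
                   KEEP.OUT.ATTRS = FALSE)
  m <- cbind(t1 = g$t2 + g$d1, t2 = g$t2, t3 = g$t2 + g$d3, s = g$s)
  m
}

## CU of every hypothesis at a single (freq, level).
hyp_cu <- function(grid, freq, level, config) {
  w <- anchor_weights(freq)
  t <- grid[, 1:3, drop = FALSE] %*% w
  twoseg_cu(level, t, grid[, 4], config$knee_cu, config$segment_ratio)
}

#' Initialize a uniform posterior over the hypothesis grid
#'
#' @param config A `qcls_config`.
#' @return An object of class `qcls_posterior` with fields `grid`
#'   (hypothesis parameters), `log_mass`, `trial_count`, `config`.
#' @export
init_posterior <- function(config = qcls_config()) {
  grid <- hypothesis_grid(config)
  structure(list(grid = grid,
                 log_mass = rep(-log(nrow(grid)), nrow(grid)),
                 trial_count = 0L, config = config),
            class = "qcls_posterior")
}

#' @export
print.qcls_posterior <- function(x, ...) {
  cat(sprintf("<qcls_posterior> %d hypotheses, %d trials, entropy %.2f nats\n",
              nrow(x$grid), x$trial_count, posterior_entropy(x)))
  invisible(x)
}

#' Posterior entropy (nats)
#'
#' @param post A `qcls_posterior`.
#' @return Shannon entropy of the posterior mass.
#' @export
posterior_entropy <- function(post) shannon_entropy(exp(post$log_mass))

#' Posterior-mode hypothesis
#'
#' @param post A `qcls_posterior`.
#' @return Named numeric vector (t1, t2, t3, s) of the maximum-mass hypothesis.
#' @export
posterior_mode <- function(post) {
  i <- which.max(post$log_mass)
  stats::setNames(post$grid[i, ], c("t1", "t2", "t3", "s"))
}

#' Likelihood of a categorical response under a hypothesis
#'
#' Probability of `category` under the discretized-Gaussian
#' multi-category psychometric function implied by the hypothesis CU
#' surface at (freq, level).
#'
#' @param hypothesis Numeric vector (t1, t2, t3, s) or a hypothesis
#'   matrix with those columns.
#' @param freq Frequency, Hz.
#' @param level Level, dB SPL.
#' @param category Integer 0..10.
#' @param config A `qcls_config`.
#' @param floor Apply the robustness floor `config$lik_floor`?
#' @return Likelihood value(s), one per hypothesis row.
#' @export
likelihood <- function(hypothesis, freq, level, category,
                       config = qcls_config(), floor = TRUE) {
  stopifnot(category %in% 0:10)
  if (is.null(dim(hypothesis))) hypothesis <- matrix(hypothesis, nrow = 1)
  cu_h <- hyp_cu(hypothesis, freq, level, config)
  sd <- config$response_sd
  lo <- if (category == 0) -Inf else category - 0.5
  hi <- if (category == 10) Inf else category + 0.5
  p <- stats::pnorm((hi - cu_h) / sd) - stats::pnorm((lo - cu_h) / sd)
  if (floor) p <- pmax(p, config$lik_floor)
  as.numeric(p)
}

#' Bayes update of the posterior with one trial
#'
#' @param post A `qcls_posterior`.
#' @param trial A list or one-row data frame with `freq`, `level`,
#'   `category`.
#' @return The updated `qcls_posterior`.
#' @export
update_posterior <- function(post, trial) {
  ## fast path: stimuli on the candidate lattice hit the precomputed table
  tab <- .loudsim_cache[[config_key(post$config)]]
  j <- if (!is.null(tab)) {
    which(tab$cand$freq == trial$freq & tab$cand$level == trial$level)
  } else integer(0)
  lik <- if (length(j) == 1) {
    pmax(tab$PtQ[11L * (j - 1L) + trial$category + 1L, ] / 1048576,
         post$config$lik_floor)
  } else {
    likelihood(post$grid, trial$freq, trial$level, trial$category,
               post$config, floor = TRUE)
  }
  lm <- post$log_mass + log(lik)
  m <- max(lm)
  if (!is.finite(m)) stop("numerical-underflow: posterior vanished", call. = FALSE)
  lm <- lm - (m + log(sum(exp(lm - m))))
  post$log_mass <- lm
  post$trial_count <- post$trial_count + 1L
  post
}

## ---- Precomputed likelihood tables for stimulus selection -------------

.loudsim_cache <- new.env(parent = emptyenv())

config_key <- function(config) {
  paste(c(config$t_center_grid, config$dt_low_grid, config$dt_high_grid,
          config$slope_grid, config$freqs,
          config$levels, config$response_sd, config$knee_cu,
          config$segment_ratio, config$lik_floor), collapse = ",")
}

## Candidate lattice plus the precomputed tables driving the
## information-gain search: Pt holds the 11 category probabilities of
## every (candidate, hypothesis) pair (hypotheses in columns), Ht the
## per-hypothesis response entropy at each candidate.
get_qcls_tables <- function(config) {
  key <- config_key(config)
  tab <- .loudsim_cache[[key]]
  if (!is.null(tab)) return(tab)
  grid <- hypothesis_grid(config)
  cand <- expand.grid(level = config$levels, freq = config$freqs,
                      KEEP.OUT.ATTRS = FALSE)[, c("freq", "level")]
  G <- nrow(grid)
  nc <- nrow(cand)
  PtQ <- matrix(0L, 11L * nc, G)
  Ht <- matrix(0, nc, G)
  for (j in seq_len(nc)) {
    cu_h <- hyp_cu(grid, cand$freq[j], cand$level[j], config)
    pj <- pmax(category_probs(cu_h, config$response_sd), config$lik_floor)
    PtQ[(11L * (j - 1L) + 1L):(11L * j), ] <-
      as.integer(round(t(pj) * 1048576))
    Ht[j, ] <- -rowSums(pj * log(pj))
  }
  tab <- list(grid = grid, cand = cand, PtQ = PtQ, Ht = Ht)
  .loudsim_cache[[key]] <- tab
  tab
}

#' Select the next stimulus by expected information gain
#'
#' Returns the candidate (frequency, level) maximizing the expected
#' reduction in posterior entropy (equivalently, the mutual information
#' between the next categorical response and the hypothesis). Ties are
#' broken by lowest level, then lowest frequency.
#'
#' @param post A `qcls_posterior`.
#' @param config A `qcls_config` (defaults to the posterior's).
#' @return A list with `freq`, `level` and the expected `gain` (nats).
#' @export
select_next_stimulus <- function(post, config = post$config) {
  tab <- get_qcls_tables(config)
  if (post$trial_count == 0L) {
    ## the first selection from the uniform prior is a pure function of
    ## the config; cache it alongside the tables
    if (!is.null(tab$first_sel)) return(tab$first_sel)
  }
  w <- exp(post$log_mass)
  ## smallest hypothesis set covering 1 - prune_tol of the mass
  o <- order(w, decreasing = TRUE)
  ncov <- max(32L, which(cumsum(w[o]) >= 1 - config$prune_tol)[1])
  keep <- o[seq_len(min(ncov, length(w)))]
  wk <- w[keep] / sum(w[keep])
  gain <- qcls_gain_kernel(tab$PtQ, tab$Ht, wk, keep, 11L)
  best <- which(gain >= max(gain) - 1e-12)
  ## tie-break: lowest level, then lowest frequency
  best <- best[order(tab$cand$level[best], tab$cand$freq[best])][1]
  sel <- list(freq = tab$cand$freq[best], level = tab$cand$level[best],
              gain = gain[best])
  if (post$trial_count == 0L) {
    tab$first_sel <- sel
    .loudsim_cache[[config_key(config)]] <- tab
  }
  sel
}

#' Run a simulated adaptive loudness-scaling track
#'
#' Alternates stimulus selection, simulated listener response, and Bayes
#' update for `n_trials` trials (100 by default, one run per stimulus
#' condition). Fully reproducible from `seed`.
#'
#' @param listener A `listener`.
#' @param bandwidth_oct Stimulus bandwidth of the run: 0 (tones), 0.25 or 1.
#' @param n_trials Number of trials.
#' @param seed Integer seed driving the listener's response stream.
#' @param config A `qcls_config`.
#' @param placement `"adaptive"` (information gain) or `"random"`
#'   (uniform over the candidate lattice; baseline for efficiency checks).
#' @return A data frame of class `qcls_trials` with columns `trial`,
#'   `freq`, `level`, `bandwidth_oct`, `category`; the final posterior is
#'   attached as attribute `"posterior"`, the listener id as
#'   `"listener_id"`.
#' @export
run_qcls <- function(listener, bandwidth_oct = 0, n_trials = 100, seed = 1,
                     config = qcls_config(), placement = c("adaptive", "random")) {
  stopifnot(n_trials >= 1)
  placement <- match.arg(placement)
  post <- init_posterior(config)
  rec <- data.frame(trial = seq_len(n_trials), freq = NA_real_,
                    level = NA_real_, bandwidth_oct = bandwidth_oct,
                    category = NA_integer_)
  for (i in seq_len(n_trials)) {
    if (placement == "adaptive") {
      sel <- select_next_stimulus(post, config)
    } else {
      sel <- with_seed(derive_seed(seed, 10000 + i), {
        list(freq = sample(config$freqs, 1),
             level = sample(config$levels, 1))
      })
    }
    cat_i <- respond(listener, sel$freq, sel$level, bandwidth_oct,
                     trial_seed = derive_seed(seed, i))
    rec$freq[i] <- sel$freq
    rec$level[i] <- sel$level
    rec$category[i] <- cat_i
    post <- update_posterior(post, list(freq = sel$freq, level = sel$level,
                                        category = cat_i))
  }
  attr(rec, "posterior") <- post
  attr(rec, "listener_id") <- listener$id
  attr(rec, "group") <- listener$group
  class(rec) <- c("qcls_trials", "data.frame")
  rec
}
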