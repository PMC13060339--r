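test_that("the prior is uniform and the posterior conserves mass", {
  cfg <- tiny_qcls_config()
  post <- init_posterior(cfg)
  w <- exp(post$log_mass)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(max(w) - min(w), 0)
  expect_equal(posterior_entropy(post), log(nrow(post$grid)), tolerance = 1e-9)
  ## mass conservation through a chain of updates
  set.seed(4)
  for (i in 1:30) {
    trial <- list(freq = sample(cfg$freqs, 1), level = sample(cfg$levels, 1),
                  category = sample(0:10, 1))
    post <- update_posterior(post, trial)
    expect_equal(sum(exp(post$log_mass)), 1, tolerance = 1e-9)
  }
  expect_equal(post$trial_count, 30L)
  expect_error(init_posterior(qcls_config(slope_grid = numeric(0))),
               "invalid-config")
})

test_that("category likelihoods are a proper probability model", {
  cfg <- qcls_config()
  h <- c(t1 = 5, t2 = 5, t3 = 10, s = 0.1)
  p_all <- vapply(0:10, function(k) {
    likelihood(h, 1000, 50, k, cfg, floor = FALSE)
  }, numeric(1))
  expect_equal(sum(p_all), 1, tolerance = 1e-9)
  expect_true(all(likelihood(loudsim:::hypothesis_grid(cfg), 1000, 50, 5, cfg) >=
                    cfg$lik_floor))
  ## vanishing response noise concentrates mass on the rounded CU
  cfg0 <- qcls_config(response_sd = 1e-5)
  cu_h <- cu(default_nh_listener(), 1000, 50)
  expect_gt(likelihood(h, 1000, 50, round(cu_h), cfg0, floor = FALSE), 0.999)
})

test_that("a Bayes update multiplies posterior odds by the likelihood ratio", {
  cfg <- qcls_config(t_center_grid = c(10, 30), dt_low_grid = 0,
                     dt_high_grid = 0, slope_grid = 0.2)
  post <- init_posterior(cfg)
  expect_equal(nrow(post$grid), 2)
  trial <- list(freq = 1000, level = 40, category = 3)
  lik <- likelihood(post$grid, 1000, 40, 3, cfg)
  post2 <- update_posterior(post, trial)
  odds_prior <- 1
  odds_post <- exp(post2$log_mass[1] - post2$log_mass[2])
  expect_equal(odds_post, odds_prior * lik[1] / lik[2], tolerance = 1e-9)
  ## an uninformative trial leaves the posterior unchanged: feed equal
  ## likelihoods by making both hypotheses saturate at category 10
  trial_sat <- list(freq = 1000, level = 100, category = 10)
  lik_sat <- likelihood(post$grid, 1000, 100, 10, cfg)
  expect_equal(lik_sat[1], lik_sat[2], tolerance = 1e-9)
  post3 <- update_posterior(post, trial_sat)
  expect_equal(post3$log_mass, post$log_mass, tolerance = 1e-9)
})

test_that("greedy selection matches the brute-force information oracle", {
  cfg <- qcls_config(t_center_grid = c(0, 15, 30), dt_low_grid = c(-5, 5),
                     dt_high_grid = c(0, 15), slope_grid = c(0.08, 0.14),
                     freqs = c(500, 1000, 2000, 4000, 6000),
                     levels = c(20, 35, 50, 65, 80))
  post <- init_posterior(cfg)
  l <- default_nh_listener()
  for (i in 1:6) {
    sel <- select_next_stimulus(post, cfg)
    ## independent brute force: expected posterior entropy per candidate
    w <- exp(post$log_mass)
    best <- NULL
    for (f in cfg$freqs) for (lv in cfg$levels) {
      pk <- vapply(0:10, function(k) {
        sum(w * likelihood(post$grid, f, lv, k, cfg))
      }, numeric(1))
      eh <- sum(vapply(0:10, function(k) {
        wk <- w * likelihood(post$grid, f, lv, k, cfg)
        pk[k + 1] * loudsim:::shannon_entropy(wk / sum(wk))
      }, numeric(1)))
      gain <- loudsim:::shannon_entropy(w) - eh
      if (is.null(best) || gain > best$gain + 1e-10) {
        best <- list(freq = f, level = lv, gain = gain)
      }
    }
    expect_equal(sel$freq, best$freq)
    expect_equal(sel$level, best$level)
    expect_equal(sel$gain, best$gain, tolerance = 1e-4)
    cat_i <- respond(l, sel$freq, sel$level, trial_seed = derive_seed_t(3, i))
    post <- update_posterior(post, list(freq = sel$freq, level = sel$level,
                                        category = cat_i))
  }
})

test_that("adaptive runs are reproducible and stay on the lattice", {
  cfg <- qcls_config()
  l <- default_nh_listener()
  tr1 <- run_qcls(l, 0, 40, seed = 5, config = cfg)
  tr2 <- run_qcls(l, 0, 40, seed = 5, config = cfg)
  expect_identical(tr1, tr2)
  expect_equal(nrow(tr1), 40)
  expect_true(all(tr1$level >= 0 & tr1$level <= 100))
  expect_true(all(tr1$freq %in% cfg$freqs))
  expect_true(all(tr1$category %in% 0:10))
})

test_that("posterior uncertainty shrinks as trials accumulate", {
  cfg <- qcls_config()
  co <- make_cohort(3, 3, seed = 8)
  for (l in co) {
    tr <- run_qcls(l, 0, 100, seed = derive_seed_t(11, l$seed), config = cfg)
    post10 <- init_posterior(cfg)
    for (i in 1:10) post10 <- update_posterior(post10, tr[i, ])
    post100 <- attr(tr, "posterior")
    expect_lt(posterior_entropy(post100), posterior_entropy(post10))
  }
})

test_that("a noiseless grid-member listener is identified exactly", {
  cfg <- qcls_config()
  g <- loudsim:::hypothesis_grid(cfg)
  truth <- g[2674, ]  # arbitrary interior hypothesis
  l <- make_listener(if (mean(truth[1:3]) > 16) "HL" else "NH",
                     truth[1:3], rep(truth[4], 3), mbld_scale = 1,
                     params = cls_params(), id = "grid-member", seed = 1)
  l$response_sd <- 0
  tr <- run_qcls(l, 0, 100, seed = 13, config = cfg)
  m <- posterior_mode(attr(tr, "posterior"))
  expect_equal(unname(m), unname(truth))
})

test_that("adaptive placement beats random placement on boundary error", {
  cfg <- qcls_config()
  co <- make_cohort(6, 14, seed = 4)
  rmse <- function(p, l) {
    sqrt(mean((p$boundaries[, 1:9] -
                 true_boundaries(l, 0, PROFILE_FREQS[1:9]))^2))
  }
  res <- t(vapply(seq_along(co), function(i) {
    trA <- run_qcls(co[[i]], 0, 100, seed = derive_seed_t(500, i),
                    config = cfg)
    trR <- run_qcls(co[[i]], 0, 100, seed = derive_seed_t(500, i),
                    config = cfg, placement = "random")
    c(rmse(fit_profile(trA, cfg), co[[i]]),
      rmse(fit_profile(trR, cfg), co[[i]]))
  }, numeric(2)))
  expect_lt(mean(res[, 1]), mean(res[, 2]))
})
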