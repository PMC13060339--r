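test_that("loudness slope is the least-squares CU-on-level regression", {
  l <- default_nh_listener()
  p <- truth_profile(l)
  ## boundaries spaced exactly 10 dB apart give slope 0.10 exactly
  p10 <- p
  p10$boundaries[] <- rep(seq(10, 100, by = 10), 10)
  expect_equal(loudness_slope(p10, 1000), 0.10)
  ## matches the independent closed-form oracle on real boundaries
  expect_equal(loudness_slope(p, 1000), ls_slope_oracle(p$boundaries[, "1000"]))
  ## level_max restriction drops high boundaries from the regression
  expect_equal(loudness_slope(p, 1000, level_max = 80),
               ls_slope_oracle_below(p$boundaries[, "1000"], 80))
  ## degenerate input errors
  pdeg <- p
  pdeg$boundaries[, 4] <- 50
  expect_error(loudness_slope(pdeg, 1000), "undefined-slope")
})

test_that("loudness reduction and summation recover the offset surface", {
  l <- default_nh_listener()
  pt <- truth_profile(l, 0)
  pq <- truth_profile(l, 0.25)
  po <- truth_profile(l, 1)
  ## identical profiles give identically zero reduction
  expect_equal(loudness_reduction(pt, pt, 1000, 60), 0)
  expect_equal(loudness_summation(pq, pq, 1000, 60), 0)
  ## the generating surface is recovered at the peak: 7 dB quarter-octave
  ## reduction, 3 dB quarter-vs-octave difference
  expect_equal(loudness_reduction(pt, pq, 1000, 60), 7, tolerance = 0.2)
  expect_equal(loudness_reduction(pt, po, 1000, 60), 4, tolerance = 0.2)
  expect_equal(loudness_summation(pq, po, 1000, 60), 3, tolerance = 0.2)
  ## algebraic identity between reduction and summation
  expect_equal(loudness_summation(pq, po, 1000, 60),
               loudness_reduction(pt, pq, 1000, 60) -
                 loudness_reduction(pt, po, 1000, 60),
               tolerance = 0.15)
  ## positive reduction = noise softer; HL reductions are smaller
  hl <- default_hl_listener()
  expect_lt(loudness_reduction(truth_profile(hl, 0), truth_profile(hl, 0.25),
                               1000, 60),
            loudness_reduction(pt, pq, 1000, 60))
})

test_that("slope t-test matches the closed-form two-sample computation", {
  ## equal groups -> t = 0, df = n1 + n2 - 2
  r0 <- slope_ttest(c(0.1, 0.11, 0.12), c(0.1, 0.11, 0.12))
  expect_equal(r0$t, 0)
  expect_equal(r0$df, 4)
  ## hand-computed toy: x = (1,2,3), y = (2,4,6)
  ## pooled s^2 = (2 + 8) / 4 = 2.5, t = (4-2)/sqrt(2.5*(2/3)) = 1.549
  r <- slope_ttest(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$t, 2 / sqrt(2.5 * (2 / 3)), tolerance = 1e-12)
  expect_equal(r$df, 4)
})

test_that("boundary tables are one row per cell and correctly labelled", {
  l1 <- default_nh_listener()
  l2 <- default_hl_listener()
  tab <- boundary_table(list(truth_profile(l1, 0), truth_profile(l1, 0.25),
                             truth_profile(l2, 0)))
  expect_equal(nrow(tab), 3 * 100)
  expect_setequal(levels(tab$bandwidth),
                  c("tone", "quarter_octave", "one_octave"))
  tab1k <- boundary_table(list(truth_profile(l1, 0)), freq = 1000)
  expect_equal(nrow(tab1k), 10)
  expect_equal(tab1k$level, unname(true_boundaries(l1, 0)[, "1000"]))
})

test_that("the mixed model recovers known structure", {
  ## zero-noise table with no group/bandwidth effects: all non-intercept
  ## fixed effects are zero
  participants <- sprintf("P%02d", 1:8)
  grid <- expand.grid(participant = participants,
                      bandwidth = c("tone", "quarter_octave"),
                      category = paste0("b", 1:10),
                      stringsAsFactors = FALSE)
  grid$group <- ifelse(grid$participant %in% participants[1:4], "NH", "HL")
  grid$freq <- 1000
  grid$level <- 20 + 7 * as.integer(sub("b", "", grid$category))
  grid$group <- factor(grid$group, levels = c("NH", "HL"))
  grid$bandwidth <- factor(grid$bandwidth,
                           levels = c("tone", "quarter_octave", "one_octave"))
  grid$category <- factor(grid$category, levels = paste0("b", 1:10))
  fit0 <- suppressWarnings(suppressMessages(group_lmm(grid)))
  fe <- lme4::fixef(fit0$fit)
  expect_lt(max(abs(fe[names(fe) != "(Intercept)" &
                        !grepl("^category", names(fe))])), 1e-8)
  expect_equal(mbld_contrast(fit0, "NH"), 0, tolerance = 1e-8)

  ## random-intercept variance recovered within 20% at a known value
  set.seed(9)
  n <- 100
  ids <- sprintf("P%03d", 1:n)
  b <- rnorm(n, 0, 5)
  tab <- do.call(rbind, lapply(1:n, function(i) {
    data.frame(participant = ids[i],
               group = ifelse(i <= 50, "NH", "HL"),
               bandwidth = rep(c("tone", "quarter_octave"), each = 10),
               category = rep(paste0("b", 1:10), 2),
               freq = 1000,
               level = 20 + 7 * rep(1:10, 2) + b[i] + rnorm(20, 0, 2))
  }))
  tab$group <- factor(tab$group, levels = c("NH", "HL"))
  tab$bandwidth <- factor(tab$bandwidth,
                          levels = c("tone", "quarter_octave", "one_octave"))
  tab$category <- factor(tab$category, levels = paste0("b", 1:10))
  fit <- suppressMessages(group_lmm(tab))
  vc <- as.data.frame(lme4::VarCorr(fit$fit))
  sd_hat <- vc$sdcor[vc$grp == "participant"]
  expect_gt(sd_hat, 5 * 0.8)
  expect_lt(sd_hat, 5 * 1.2)

  ## rank-deficient designs are rejected with an informative message
  expect_error(group_lmm(grid[grid$bandwidth == "tone", ]),
               "rank-deficient.*bandwidth")
})

test_that("loudness loss and hearing-aid gain behave as recruitment implies", {
  nh <- default_nh_listener()
  hl <- default_hl_listener()
  pn <- truth_profile(nh)
  ph <- truth_profile(hl)
  ## identical cohorts: zero loss and zero gain
  expect_true(all(abs(loudness_loss(pn, pn)) < 1e-12))
  expect_true(all(abs(hearing_aid_gain(pn, pn, 1000)) < 1e-9))
  ## loss is positive and approximately the audiogram shift at threshold
  loss <- loudness_loss(ph, pn)
  expect_true(all(loss > 0))
  expect_equal(loss["b1", "1000"],
               hl$audiogram[["1000"]] - nh$audiogram[["1000"]],
               tolerance = 1.5)
  ## recruiting surfaces need less gain at high levels
  g <- hearing_aid_gain(pn, ph, 1000, levels = seq(30, 90, by = 10))
  expect_true(all(diff(g) < 0))
  expect_true(all(g > 0))
})
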