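#' Write / read a cohort as JSON
#'
#' One record per listener: group, id, anchor thresholds and slopes,
#' audiogram, PTA, offset multiplier, response SD and seed. Round-trips
#' exactly.
#'
#' @param cohort A `cohort` from [make_cohort()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  recs <- lapply(cohort, function(l) {
    list(id = l$id, group = l$group,
         anchor_thresholds = l$anchor_thresholds,
         anchor_slopes = l$anchor_slopes,
         mbld_scale = l$mbld_scale, response_sd = l$response_sd,
         seed = l$seed)
  })
  params <- unclass(cohort[[1]]$params)
  jsonlite::write_json(list(params = params, listeners = recs), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(cls_params, x$params)
  recs <- x$listeners
  out <- lapply(seq_len(nrow(recs)), function(i) {
    make_listener(recs$group[i],
                  anchor_thresholds = recs$anchor_thresholds[[i]],
                  anchor_slopes = recs$anchor_slopes[[i]],
                  mbld_scale = recs$mbld_scale[i], params = params,
                  id = recs$id[i], seed = recs$seed[i])
  })
  structure(out, class = "cohort")
}

#' Write / read trial records as CSV
#'
#' Columns: `run_id`, `trial`, `freq_hz`, `level_db_spl`, `bandwidth_oct`,
#' `category`, `category_label`.
#'
#' @param trials A `qcls_trials` data frame (or a list of them).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  if (inherits(trials, "data.frame")) trials <- list(trials)
  rows <- lapply(trials, function(tr) {
    data.frame(run_id = attr(tr, "listener_id"),
               group = attr(tr, "group"),
               trial = tr$trial, freq_hz = tr$freq,
               level_db_spl = tr$level, bandwidth_oct = tr$bandwidth_oct,
               category = tr$category,
               category_label = category_label(tr$category))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  split_x <- split(x, x$run_id)
  out <- lapply(split_x, function(d) {
    tr <- data.frame(trial = d$trial, freq = d$freq_hz,
                     level = d$level_db_spl, bandwidth_oct = d$bandwidth_oct,
                     category = as.integer(d$category))
    attr(tr, "listener_id") <- d$run_id[1]
    attr(tr, "group") <- d$group[1]
    class(tr) <- c("qcls_trials", "data.frame")
    tr
  })
  out
}

#' Write a loudness profile as CSV
#'
#' Rows are boundary indices 1..10, columns the ten profile frequencies.
#'
#' @param profile A `loudness_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  b <- as.data.frame(profile$boundaries)
  b <- cbind(boundary = 1:10, b, stringsAsFactors = FALSE)
  utils::write.csv(b, path, row.names = FALSE)
  invisible(path)
}

#' Experiment configuration
#'
#' Bundles the cohort, procedure and output settings of a full simulated
#' experiment: three stimulus conditions (tone, quarter-octave,
#' one-octave noise) tested in randomized order per listener.
#'
#' @param n_nh,n_hl Group sizes.
#' @param n_trials Trials per adaptive run.
#' @param seed Master seed.
#' @param params A `cls_params`.
#' @param config A `qcls_config`.
#' @param out_dir Output directory for artifacts.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_nh = 32, n_hl = 68, n_trials = 100,
                              seed = 1, params = cls_params(),
                              config = qcls_config(), out_dir = "loudsim-out") {
  structure(list(n_nh = n_nh, n_hl = n_hl, n_trials = n_trials,
                 seed = seed, params = params, config = config,
                 conditions = c(tone = 0, quarter_octave = 0.25,
                                one_octave = 1),
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Run the full simulated experiment
#'
#' Generates the cohort, runs one adaptive track per listener and
#' condition (conditions in randomized order per listener), fits all
#' loudness profiles, and computes the group statistics (slopes,
#' loudness reduction and summation at 1 kHz / 60 dB SPL, and the
#' mixed-model bandwidth contrast). Artifacts (cohort JSON, trial CSVs,
#' profile CSVs, report JSON, manifest) are written to
#' `config$out_dir`; stages with existing artifacts are skipped unless
#' `overwrite = TRUE`, so an interrupted run resumes at the last
#' completed stage.
#'
#' @param config An `experiment_config`.
#' @param overwrite Recompute stages whose artifacts already exist?
#' @param progress Print stage progress?
#' @return A list with the cohort, profiles, boundary table, and the
#'   report (invisible).
#' @export
run_experiment <- function(config = experiment_config(), overwrite = FALSE,
                           progress = TRUE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (progress) message(sprintf(...))

  cohort_path <- file.path(config$out_dir, "cohort.json")
  if (!file.exists(cohort_path) || overwrite) {
    cohort <- make_cohort(config$n_nh, config$n_hl, config$params,
                          seed = config$seed)
    write_cohort(cohort, cohort_path)
    say("cohort: %d listeners -> %s", length(cohort), cohort_path)
  } else {
    cohort <- read_cohort(cohort_path)
    say("cohort: reusing %s", cohort_path)
  }

  profiles <- list()
  all_trials <- list()
  for (cd in names(config$conditions)) {
    bw <- config$conditions[[cd]]
    tpath <- file.path(config$out_dir, sprintf("trials_%s.csv", cd))
    if (file.exists(tpath) && !overwrite) {
      trials <- read_trials(tpath)
      trials <- trials[vapply(cohort, `[[`, character(1), "id")]
      say("%s: reusing %s", cd, tpath)
    } else {
      trials <- lapply(seq_along(cohort), function(i) {
        ## condition order randomized per listener via the seed stream
        ord <- with_seed(derive_seed(config$seed, 9000 + i),
                         sample(seq_along(config$conditions)))
        k <- ord[match(cd, names(config$conditions))]
        run_qcls(cohort[[i]], bw, config$n_trials,
                 seed = derive_seed(config$seed, 100 * i + k),
                 config = config$config)
      })
      names(trials) <- vapply(cohort, `[[`, character(1), "id")
      write_trials(trials, tpath)
      say("%s: %d runs -> %s", cd, length(trials), tpath)
    }
    all_trials[[cd]] <- trials
  }

  ## one joint fit per listener (shared anchors across conditions; the
  ## tone run anchors the thresholds/slopes, the noise runs contribute
  ## their bandwidth-offset amplitudes)
  for (cd in names(config$conditions)) {
    dir.create(file.path(config$out_dir, "profiles", cd),
               showWarnings = FALSE, recursive = TRUE)
  }
  joint <- lapply(seq_along(cohort), function(i) {
    fit_profiles_joint(lapply(all_trials, `[[`, i), config$config,
                       config$params)
  })
  profiles <- lapply(names(config$conditions), function(cd) {
    lapply(seq_along(cohort), function(i) {
      p <- joint[[i]][[cd]]
      write_profile(p, file.path(config$out_dir, "profiles", cd,
                                 paste0(p$listener_id, ".csv")))
      p
    })
  })
  names(profiles) <- names(config$conditions)

  tab <- boundary_table(unlist(profiles, recursive = FALSE), freq = 1000)
  lmm <- group_lmm(tab)
  groups <- vapply(cohort, `[[`, character(1), "group")
  slopes <- vapply(profiles$tone, loudness_slope, numeric(1), freq = 1000)
  reductions <- mapply(loudness_reduction, profiles$tone,
                       profiles$quarter_octave,
                       MoreArgs = list(freq = 1000, level = 60))
  summations <- mapply(loudness_summation, profiles$quarter_octave,
                       profiles$one_octave,
                       MoreArgs = list(freq = 1000, level = 60))
  tt <- slope_ttest(slopes[groups == "NH"], slopes[groups == "HL"])
  report <- list(
    n_nh = sum(groups == "NH"), n_hl = sum(groups == "HL"),
    slope_nh = mean(slopes[groups == "NH"]),
    slope_hl = mean(slopes[groups == "HL"]),
    slope_ttest = tt,
    reduction_nh_median = stats::median(reductions[groups == "NH"]),
    reduction_hl_median = stats::median(reductions[groups == "HL"]),
    summation_nh_median = stats::median(summations[groups == "NH"]),
    contrast_nh_quarter_vs_tone = mbld_contrast(lmm, "NH"),
    contrast_hl_quarter_vs_tone = mbld_contrast(lmm, "HL"),
    p_group_bandwidth = lmm_term_p(lmm, "group:bandwidth"),
    seed = config$seed)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(package = "loudsim",
                   version = as.character(utils::packageVersion("loudsim")),
                   seed = config$seed, n_trials = config$n_trials,
                   conditions = config$conditions)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("report -> %s", file.path(config$out_dir, "report.json"))
  invisible(list(cohort = cohort, trials = all_trials, profiles = profiles,
                 boundary_table = tab, lmm = lmm, report = report))
}
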