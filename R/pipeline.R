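#' @importFrom jsonlite toJSON write_json read_json
NULL

#' Packaged demo study configuration
#'
#' A fully synthetic, seeded end-to-end configuration: a noiseless-ish LC
#' phantom, one short night of staged EEG, and a 52-participant cohort
#' (33 younger / 19 older) with planted interaction and mediation
#' effects. Deterministic given its seed: two runs produce byte-identical
#' numeric outputs.
#'
#' @param out_dir output directory for [run_pipeline()].
#' @param seed global integer seed.
#' @return a config list understood by [validate_inputs()] /
#'   [run_pipeline()].
#' @export
demo_config <- function(out_dir = tempfile("lcsleep_demo_"), seed = 42L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    volume = list(generator = list(grid_shape = c(48L, 48L, 16L),
                                   lc_intensity = 120,
                                   background_intensity = 100,
                                   noise_sd = 0.5)),
    sleep = list(generator = list(
      hypnogram = list(time_in_bed = 120, sleep_onset_epoch = 10L,
                       arousal_rate = 8, artifact_fraction = 0.02),
      spectrum = list(noise_sd = 1)
    )),
    cohort = list(generator = list(n_young = 33L, n_old = 19L,
                                   slope_young = 0, slope_old = 0.8,
                                   a = 0.5, b = 0.3, noise_sd = 1)),
    analysis = list(family = "gaussian", fdr_q = 0.05, swe_stages = "N3",
                    sensitivity = list(alpha = 0.05, power = 0.8,
                                       sides = 1, n_covariates = 4))
  )
}

config_sources <- function(config) {
  vapply(c("volume", "sleep", "cohort"), function(k) {
    blk <- config[[k]]
    if (is.null(blk)) "absent"
    else if (!is.null(blk$generator) && is.null(blk$paths) && is.null(blk$path)) "generator"
    else if (is.null(blk$generator) && (!is.null(blk$paths) || !is.null(blk$path))) "path"
    else "invalid"
  }, character(1))
}

#' Validate a study configuration and its inputs
#'
#' Schema checks (exactly one source per input block, mandatory seed when
#' any generator is used, output directory present) plus input-file
#' checks for path-based blocks: volume/mask grid compatibility, EEG
#' length vs hypnogram span, cohort schema completeness. Problems are
#' split into hard `errors` and `warnings`.
#'
#' @param config a config list, or the path of a JSON config file.
#' @return list with character vectors `errors` and `warnings` and
#'   `ok = length(errors) == 0`.
#' @export
validate_inputs <- function(config) {
  if (is.character(config)) config <- read_json(config, simplifyVector = TRUE)
  errors <- character()
  warnings <- character()
  if (is.null(config$out_dir)) errors <- c(errors, "out_dir: missing")
  src <- config_sources(config)
  for (k in names(src)) {
    if (src[[k]] == "invalid") {
      errors <- c(errors, sprintf("%s: specify exactly one of generator or path(s)", k))
    }
  }
  if (any(src == "generator") && is.null(config$seed)) {
    errors <- c(errors, "seed: mandatory when any generator is used")
  }
  if (src[["volume"]] == "path") {
    p <- config$volume$paths
    for (f in c(p$volume, p$mask_left, p$mask_right)) {
      if (!file.exists(f)) errors <- c(errors, sprintf("volume: unreadable file %s", f))
    }
    if (all(file.exists(c(p$volume, p$mask_left, p$mask_right)))) {
      vol <- read_nifti(p$volume)
      for (side in c("mask_left", "mask_right")) {
        m <- read_nifti(p[[side]])
        if (!identical(dim(m$data), dim(vol$data))) {
          errors <- c(errors, sprintf("volume: %s grid (%s) != volume grid (%s)",
                                      side, paste(dim(m$data), collapse = "x"),
                                      paste(dim(vol$data), collapse = "x")))
        }
      }
    }
  }
  if (src[["sleep"]] == "path") {
    p <- config$sleep$paths
    for (f in c(p$eeg, p$hypnogram, p$annotations)) {
      if (!is.null(f) && !file.exists(f)) {
        errors <- c(errors, sprintf("sleep: unreadable file %s", f))
      }
    }
    if (file.exists(p$eeg %||% "") && file.exists(p$hypnogram %||% "")) {
      eeg <- read_eeg_csv(p$eeg)
      hyp <- read_hypnogram_csv(p$hypnogram)
      span <- length(hyp$stages) * hyp$epoch_length
      have <- length(eeg$signal) / eeg$fs
      if (have < span) {
        errors <- c(errors, sprintf("sleep: EEG covers %g s but the hypnogram spans %g s",
                                    have, span))
      } else if (have > span) {
        warnings <- c(warnings, sprintf("sleep: EEG (%g s) longer than the hypnogram span (%g s); tail ignored",
                                        have, span))
      }
    }
  }
  if (src[["cohort"]] == "path" && file.exists(config$cohort$path %||% "")) {
    tab <- read_cohort_csv(config$cohort$path)
    need <- c(PRIMARY_OUTCOMES, "lc_activity", "age_group", "sex", "bmi", "tst")
    miss <- setdiff(need, names(tab))
    if (length(miss)) {
      errors <- c(errors, sprintf("cohort: missing column(s) %s",
                                  paste(miss, collapse = ", ")))
    }
  }
  list(errors = errors, warnings = warnings, ok = length(errors) == 0L)
}

write_csv_stamped <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config: %s seed: %d", stamp$hash, stamp$seed), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes, in order: LC contrast extraction (phantom or NIfTI inputs),
#' sleep metric extraction (synthetic or CSV inputs), cohort assembly,
#' and the statistical stage (six primary moderated models + BH-FDR,
#' sensitivity analysis). All numeric outputs are written under
#' `out_dir`, stamped with the config hash and seed; a rerun with an
#' identical config reproduces them byte for byte. Stage randomness uses
#' seeds derived from the global seed by fixed small offsets.
#'
#' @param config a config list (see [demo_config()]) or a JSON file path.
#' @return (invisibly) list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_json(config, simplifyVector = TRUE)
  v <- validate_inputs(config)
  for (w in v$warnings) warn_fmt("%s", w)
  if (!v$ok) {
    stop_fmt("invalid configuration:\n  - %s", paste(v$errors, collapse = "\n  - "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 0L)
  stamp <- list(hash = fnv1a32(as.character(toJSON(config[setdiff(names(config), "out_dir")],
                                                   auto_unbox = TRUE, digits = NA))),
                seed = seed)
  src <- config_sources(config)
  paths <- list()
  results <- list(config_hash = stamp$hash, seed = seed)

  ## stage 1: LC contrast -----------------------------------------------
  if (src[["volume"]] == "generator") {
    spec <- do.call(lc_volume_spec, config$volume$generator)
    gen <- generate_lc_volume(spec, seed = seed + 1L)
    vol <- gen$volume; masks <- gen$masks; ref_spec <- gen$ref_spec
    results$volume_truth <- gen$truth
  } else {
    p <- config$volume$paths
    vol <- read_nifti(p$volume)
    masks <- list(left = read_nifti(p$mask_left)$data != 0,
                  right = read_nifti(p$mask_right)$data != 0)
    centers <- read.csv(p$ref_centers)
    ref_spec <- reference_region_spec(centers, p$ref_size %||% 15L)
  }
  sides <- lapply(c(left = "left", right = "right"), function(s) {
    lc_contrast(vol, skeletonize_lc(vol, masks[[s]], s), ref_spec)
  })
  bilat <- bilateral_contrast(sides$left, sides$right)
  per_slice <- do.call(rbind, lapply(sides, function(r) {
    cbind(side = r$side, r$table)
  }))
  paths$lc_contrast_csv <- write_csv_stamped(per_slice,
                                             file.path(config$out_dir, "lc_contrast.csv"),
                                             stamp)
  contrast_summary <- list(config = stamp$hash, seed = seed,
                           left = sides$left$side_contrast,
                           right = sides$right$side_contrast,
                           bilateral = bilat)
  paths$lc_contrast_json <- file.path(config$out_dir, "lc_contrast.json")
  write_json(contrast_summary, paths$lc_contrast_json, auto_unbox = TRUE,
             digits = NA)
  results$contrast <- contrast_summary

  ## stage 2: sleep metrics ---------------------------------------------
  if (src[["sleep"]] == "generator") {
    g <- config$sleep$generator
    hspec <- do.call(hypnogram_spec, g$hypnogram %||% list())
    hgen <- generate_hypnogram(hspec, seed = seed + 2L)
    sspec <- do.call(stage_spectrum_spec, g$spectrum %||% list())
    egen <- generate_sleep_eeg(hgen$hypnogram, sspec, hgen$annotations,
                               seed = seed + 3L)
    hyp <- hgen$hypnogram; ann <- hgen$annotations
    signal <- egen$signal; fs <- egen$fs
    results$sleep_truth <- list(hypnogram = hgen$truth, spectrum = egen$truth)
  } else {
    p <- config$sleep$paths
    eeg <- read_eeg_csv(p$eeg)
    signal <- eeg$signal; fs <- eeg$fs
    hyp <- read_hypnogram_csv(p$hypnogram)
    ann <- if (is.null(p$annotations)) annotation_set() else
      read_annotations_csv(p$annotations)
  }
  sm <- sleep_metrics(signal, fs, hyp, ann,
                      swe_stages = config$analysis$swe_stages %||% "N3")
  bins <- rbind(cbind(metric = "swe", sm$swe_bins),
                cbind(metric = "rem_theta", sm$theta_bins))
  paths$bins_csv <- write_csv_stamped(bins,
                                      file.path(config$out_dir, "spectral_bins.csv"),
                                      stamp)
  metrics_record <- c(list(config = stamp$hash, seed = seed),
                      sm[c("tst_min", "sol_min", "efficiency", "rem_pct",
                           "swe", "rem_theta_energy", "rem_latency_min",
                           "rem_arousal_count", "rem_episode_min")])
  paths$sleep_json <- file.path(config$out_dir, "sleep_metrics.json")
  write_json(metrics_record, paths$sleep_json, auto_unbox = TRUE, digits = NA)
  results$sleep_metrics <- sm

  ## stage 3: cohort assembly -------------------------------------------
  if (src[["cohort"]] == "generator") {
    args <- config$cohort$generator
    args$seed <- seed + 4L
    cspec <- do.call(cohort_spec, args)
    cgen <- generate_cohort(cspec)
    cohort <- cgen$table
    results$cohort_truth <- cgen$truth
  } else {
    cohort <- read_cohort_csv(config$cohort$path)
  }
  paths$cohort_csv <- write_csv_stamped(cohort,
                                        file.path(config$out_dir, "cohort.csv"),
                                        stamp)

  ## stage 4: statistics -------------------------------------------------
  an <- config$analysis %||% list()
  report <- run_primary_models(cohort,
                               q = an$fdr_q %||% 0.05,
                               family = an$family %||% "gaussian")
  model_rows <- do.call(rbind, lapply(names(report$models), function(out) {
    m <- report$models[[out]]
    cbind(outcome = out,
          rbind(cbind(m$tests[c("term", "estimate", "se", "p", "partial_R2")],
                      group = NA),
                data.frame(term = "simple_slope",
                           estimate = m$slopes$slope, se = m$slopes$se,
                           p = m$slopes$p, partial_R2 = NA,
                           group = m$slopes$group)))
  }))
  paths$models_csv <- write_csv_stamped(model_rows,
                                        file.path(config$out_dir, "models.csv"),
                                        stamp)
  sens_args <- an$sensitivity %||% list()
  sens <- sensitivity_min_effect(n = nrow(cohort),
                                 alpha = sens_args$alpha %||% 0.05,
                                 power = sens_args$power %||% 0.8,
                                 sides = sens_args$sides %||% 1,
                                 n_covariates = sens_args$n_covariates %||% 4)
  stat_record <- list(config = stamp$hash, seed = seed,
                      fdr = list(q = report$q, on = report$fdr_on,
                                 critical_p = report$fdr$critical_p),
                      summary = report$summary,
                      sensitivity = unclass(sens)[c("n", "alpha", "power",
                                                    "sides", "n_covariates",
                                                    "min_detectable_r",
                                                    "min_detectable_R2")])
  paths$stats_json <- file.path(config$out_dir, "statistics.json")
  write_json(stat_record, paths$stats_json, auto_unbox = TRUE, digits = NA)
  results$report <- report
  results$sensitivity <- sens

  ## manifest: every option in effect, no timestamps (determinism) -------
  manifest <- list(config_hash = stamp$hash, seed = seed,
                   sources = as.list(src),
                   options = list(family = an$family %||% "gaussian",
                                  fdr_q = an$fdr_q %||% 0.05,
                                  fdr_on = report$fdr_on,
                                  swe_stages = an$swe_stages %||% "N3",
                                  mediator_reference = "covariate-adjusted mediator mean",
                                  sleep_onset_rule = "first non-wake epoch"),
                   outputs = lapply(paths, basename))
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  results$paths <- paths
  invisible(results)
}
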