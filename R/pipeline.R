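#' Default pipeline configuration
#'
#' A plain list mirroring the YAML configuration accepted by the pipeline
#' entry points: screen geometry, detector settings, quality-control
#' threshold, model formulas and the simulation seed.
#'
#' @param out_dir Directory for all CSV outputs.
#' @param seed Simulation seed.
#' @export
pipeline_config <- function(out_dir = ".", seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    screen = list(width_px = 1366, height_px = 768, distance_cm = 60,
                  dispersion_radius_px = 23),
    process = list(radius_px = 23, min_run = 2, sample_rate_hz = 30),
    curate = list(qc_threshold_ms = 2000),
    model = list(
      alpha = 0.05,
      fixed = ". ~ morphotype + nationality + gender + age + morphotype:nationality + gender:nationality",
      responses = c("diff_fix", "diff_dwell_ms"),
      participant = "participant_id", var_group = "nationality",
      weights = "weight"))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the blocks of [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- pipeline_config()
  utils::modifyList(base, cfg)
}

.gz_write <- function(df, cfg, name) {
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  path <- file.path(cfg$out_dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

.gz_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
}

.gz_screen <- function(cfg) {
  s <- cfg$screen
  screen_geometry(s$width_px, s$height_px, s$distance_cm, s$dispersion_radius_px)
}

#' Pipeline stage: simulate a raw dataset
#'
#' Writes `participants.csv`, `trials.csv`, `samples.csv`, `stimuli.csv`
#' and `orders.csv` to the configured output directory.
#' @param config A [pipeline_config()].
#' @return The simulated study (invisibly).
#' @export
run_simulate <- function(config = pipeline_config()) {
  study <- simulate_study(screen = .gz_screen(config), seed = config$seed)
  .gz_write(study$participants, config, "participants.csv")
  .gz_write(study$trials, config, "trials.csv")
  .gz_write(study$samples, config, "samples.csv")
  .gz_write(study$stimuli, config, "stimuli.csv")
  .gz_write(study$orders, config, "orders.csv")
  .gz_log("simulate", "seed=", config$seed,
          " participants=", nrow(study$participants),
          " trials=", nrow(study$trials),
          " samples=", nrow(study$samples))
  invisible(study)
}

#' Pipeline stage: raw samples to fixations and trial metrics
#'
#' Binocular averaging, fixation detection and per-trial metrics; writes
#' `fixations.csv` and `trial_metrics.csv`.
#' @param config A [pipeline_config()].
#' @param study Optional in-memory study (as from [run_simulate()]);
#'   when `NULL` the stage reads the CSV files from `config$out_dir`.
#' @return List with `metrics` and `fixations` (invisibly).
#' @export
run_process <- function(config = pipeline_config(), study = NULL) {
  if (is.null(study)) {
    samples <- utils::read.csv(file.path(config$out_dir, "samples.csv"))
  } else samples <- study$samples
  aois <- make_aoi_set(.gz_screen(config))
  pr <- config$process
  res <- process_samples(samples, aois, radius_px = pr$radius_px,
                         min_run = pr$min_run,
                         sample_rate_hz = pr$sample_rate_hz)
  .gz_write(res$metrics, config, "trial_metrics.csv")
  if (!is.null(res$fixations)) .gz_write(res$fixations, config, "fixations.csv")
  .gz_log("process", "trials=", nrow(res$metrics),
          " fixations=", if (is.null(res$fixations)) 0 else nrow(res$fixations))
  invisible(res)
}

#' Pipeline stage: curation
#'
#' Removes the practise trials, applies the quality-control dwell cut,
#' averages mirror pairs and attaches the difference responses; writes
#' `observations.csv` and `exclusions.csv` and logs the curation summary.
#' @param config A [pipeline_config()].
#' @param metrics,study Optional in-memory inputs; read from CSV when
#'   `NULL`.
#' @return List with `observations`, `exclusions`, `summary` (invisibly).
#' @export
run_curate <- function(config = pipeline_config(), metrics = NULL, study = NULL) {
  if (is.null(metrics))
    metrics <- utils::read.csv(file.path(config$out_dir, "trial_metrics.csv"))
  if (is.null(study)) {
    trials <- utils::read.csv(file.path(config$out_dir, "trials.csv"))
    stimuli <- utils::read.csv(file.path(config$out_dir, "stimuli.csv"))
    participants <- utils::read.csv(file.path(config$out_dir, "participants.csv"))
  } else {
    trials <- study$trials; stimuli <- study$stimuli
    participants <- study$participants
  }
  trials$is_practise <- NULL   # authoritative flag lives on the stimulus
  meta <- merge(trials, stimuli, by = "stimulus_version_id", sort = FALSE)
  tm <- merge(metrics, meta, by = "trial_id", sort = FALSE)
  tm <- tm[!tm$is_practise, , drop = FALSE]
  qc <- qc_filter(tm, config$curate$qc_threshold_ms)
  smry <- curation_summary(nrow(tm), nrow(qc$excluded))
  obs <- mirror_pair_average(qc$kept, participants)
  obs <- compute_differences(obs)
  canon <- intersect(c("cobra", "viper", "other"), unique(obs$morphotype))
  if (length(canon)) obs$morphotype <- factor(obs$morphotype, levels = canon)
  .gz_write(obs, config, "observations.csv")
  .gz_write(qc$log, config, "exclusions.csv")
  nat_counts <- table(factor(obs$nationality))
  .gz_log("curate", "total=", smry$n_total, " excluded=", smry$n_excluded,
          " (", sprintf("%.2f%%", smry$excluded_pct), ")",
          " retained=", smry$n_retained,
          " observations=", nrow(obs), " [",
          paste(names(nat_counts), as.integer(nat_counts),
                sep = "=", collapse = ", "), "]")
  invisible(list(observations = obs, exclusions = qc$log, summary = smry))
}

#' Pipeline stage: model fitting and report tables
#'
#' For each configured response: backward reduction from the full
#' fixed-effect structure, the full-versus-reduced likelihood-ratio and
#' AIC comparison, morphotype marginal means, and (when nationality is
#' retained) morphotype-by-nationality means with nationality contrasts.
#' Writes `fit_summary_<response>.csv`, `emmeans_<response>.csv` and
#' `contrasts_<response>.csv`.
#' @param config A [pipeline_config()].
#' @param observations Optional in-memory observations.
#' @return Named list per response with `reduction`, `emm`, `contrasts`
#'   (invisibly).
#' @export
run_fit <- function(config = pipeline_config(), observations = NULL) {
  if (is.null(observations))
    observations <- utils::read.csv(file.path(config$out_dir, "observations.csv"))
  mc <- config$model
  out <- list()
  for (resp in mc$responses) {
    form <- stats::as.formula(sub("^\\.", resp, mc$fixed))
    red <- backward_reduce(form, observations, participant = mc$participant,
                           var_group = mc$var_group, weights = mc$weights,
                           alpha = mc$alpha)
    kept <- attr(red$final$terms, "term.labels")
    focal <- if (any(grepl("morphotype:nationality|nationality:morphotype", kept)))
      c("morphotype", "nationality") else intersect("morphotype", kept)
    emms <- if (length(focal)) emm(red$final, focal) else NULL
    ctr <- if (length(focal) > 1)
      contrast_emm(red$final, "nationality", by = "morphotype") else NULL
    tab <- summary(red$final)$coefficients
    .gz_write(data.frame(term = rownames(tab), tab, check.names = FALSE),
              config, paste0("fit_summary_", resp, ".csv"))
    if (!is.null(emms))
      .gz_write(as.data.frame(emms), config, paste0("emmeans_", resp, ".csv"))
    if (!is.null(ctr))
      .gz_write(as.data.frame(ctr), config, paste0("contrasts_", resp, ".csv"))
    .gz_log("fit", resp, ": final=", paste(deparse(red$formula_final), collapse = " "),
            " LRT stat=", sprintf("%.2f", red$lrt$stat),
            " df=", red$lrt$df, " p=", sprintf("%.3f", red$lrt$p),
            " AIC full=", sprintf("%.1f", red$aic_full),
            " reduced=", sprintf("%.1f", red$aic_reduced))
    out[[resp]] <- list(reduction = red, emm = emms, contrasts = ctr)
  }
  invisible(out)
}

#' Run the whole pipeline in memory
#'
#' simulate, process, curate and fit, passing intermediates in memory
#' (each stage still writes its CSV outputs).
#' @param config A [pipeline_config()].
#' @return List with all stage results.
#' @export
run_study <- function(config = pipeline_config()) {
  study <- run_simulate(config)
  proc <- run_process(config, study = study)
  cur <- run_curate(config, metrics = proc$metrics, study = study)
  fits <- run_fit(config, observations = cur$observations)
  invisible(list(study = study, processed = proc, curated = cur, fits = fits))
}
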