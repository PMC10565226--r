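#' Average the two eyes into a single (cyclopean) gaze stream
#'
#' Per sample: if both eyes are valid the midpoint is used; if exactly one
#' eye is valid that eye's coordinates are used (set `strict = TRUE` to
#' require both eyes); if neither is valid the sample is kept in the
#' timeline as an invalid sample.
#'
#' @param samples Data frame with columns `t_ms`, `lx`, `ly`, `rx`, `ry`,
#'   `valid_l`, `valid_r` (one trial, time-ordered).
#' @param strict Require both eyes valid for a sample to count as valid.
#' @return Data frame with columns `t_ms`, `x`, `y`, `valid`.
#' @export
average_binocular <- function(samples, strict = FALSE) {
  vl <- as.logical(samples$valid_l); vr <- as.logical(samples$valid_r)
  valid <- if (strict) vl & vr else vl | vr
  x <- ifelse(vl & vr, (samples$lx + samples$rx) / 2,
              ifelse(vl, samples$lx, samples$rx))
  y <- ifelse(vl & vr, (samples$ly + samples$ry) / 2,
              ifelse(vl, samples$ly, samples$ry))
  x[!valid] <- NA_real_; y[!valid] <- NA_real_
  data.frame(t_ms = samples$t_ms, x = x, y = y, valid = valid)
}

#' Detect fixations with the lead-sample dispersion rule
#'
#' A single forward scan over the valid samples of one trial. The first
#' valid sample is the current lead (reference) sample; each subsequent
#' valid sample whose position lies within `radius_px` (Euclidean) of the
#' lead joins the current group; the first sample farther away closes the
#' group and becomes the new lead. A gap of invalid samples also closes the
#' current group (a blink ends a fixation). Closed groups with at least
#' `min_run` members are fixations; smaller groups (stray leads) are not,
#' although their samples still count toward dwell time elsewhere.
#'
#' Duration is `(last - first member time) + one sample interval`, so a
#' fixation spanning all n samples of a trial at rate r lasts exactly n/r.
#'
#' @param stream Averaged stream from [average_binocular()].
#' @param radius_px Dispersion radius in pixels.
#' @param min_run Minimum number of consecutive samples in a fixation.
#' @param sample_rate_hz Nominal sampling rate, used for the trailing
#'   sample interval of the duration.
#' @param aois Optional [make_aoi_set()]; when given, each fixation is
#'   labelled with the AOI containing its centroid.
#' @return Data frame with one row per fixation: `lead_index`,
#'   `first_index`, `last_index`, `n_samples`, `start_ms`, `end_ms`,
#'   `duration_ms`, `cx`, `cy` and (if `aois` given) `aoi`. Indices refer
#'   to rows of `stream`.
#' @export
detect_fixations <- function(stream, radius_px = 23, min_run = 2,
                             sample_rate_hz = 30, aois = NULL) {
  dt <- 1000 / sample_rate_hz
  n <- nrow(stream)
  groups_first <- integer(0); groups_last <- integer(0); groups_lead <- integer(0)
  lead <- NA_integer_; first <- NA_integer_; last <- NA_integer_
  close_group <- function() {
    if (!is.na(first) && (last - first + 1L) >= min_run) {
      groups_first <<- c(groups_first, first)
      groups_last  <<- c(groups_last, last)
      groups_lead  <<- c(groups_lead, lead)
    }
    lead <<- NA_integer_; first <<- NA_integer_; last <<- NA_integer_
  }
  for (i in seq_len(n)) {
    if (!stream$valid[i]) { close_group(); next }
    if (is.na(lead)) {
      lead <- i; first <- i; last <- i
    } else {
      d2 <- (stream$x[i] - stream$x[lead])^2 + (stream$y[i] - stream$y[lead])^2
      if (d2 <= radius_px^2) {
        last <- i
      } else {
        close_group()
        lead <- i; first <- i; last <- i
      }
    }
  }
  close_group()
  if (length(groups_first) == 0L) {
    out <- data.frame(lead_index = integer(0), first_index = integer(0),
                      last_index = integer(0), n_samples = integer(0),
                      start_ms = numeric(0), end_ms = numeric(0),
                      duration_ms = numeric(0), cx = numeric(0), cy = numeric(0))
  } else {
    cx <- mapply(function(a, b) mean(stream$x[a:b]), groups_first, groups_last)
    cy <- mapply(function(a, b) mean(stream$y[a:b]), groups_first, groups_last)
    out <- data.frame(
      lead_index = groups_lead,
      first_index = groups_first,
      last_index = groups_last,
      n_samples = groups_last - groups_first + 1L,
      start_ms = stream$t_ms[groups_first],
      end_ms = stream$t_ms[groups_last] + dt,
      duration_ms = stream$t_ms[groups_last] - stream$t_ms[groups_first] + dt,
      cx = cx, cy = cy)
  }
  if (!is.null(aois)) out$aoi <- assign_point(aois, out$cx, out$cy)
  out
}

#' Per-trial, per-AOI gaze metrics
#'
#' Number of fixations per AOI counts fixations whose centroid falls in the
#' AOI. Dwell (fixation) time per AOI is sample-based: the number of valid
#' samples whose position lies in the AOI times the sample interval -- it
#' is deliberately not the sum of fixation durations, so that stray
#' sub-threshold gaze still counts toward the quality-control dwell cut.
#'
#' @param stream Averaged stream from [average_binocular()].
#' @param fixations Result of [detect_fixations()] on the same stream.
#' @param aois An [make_aoi_set()].
#' @param sample_rate_hz Sampling rate in Hz.
#' @return One-row data frame: `n_samples`, `n_valid`, per-AOI fixation
#'   counts `n_fix_left/right/central/none`, per-AOI dwell
#'   `dwell_left_ms/right/central/none` and `combined_lr_dwell_ms`.
#' @export
compute_trial_metrics <- function(stream, fixations, aois, sample_rate_hz = 30) {
  dt <- 1000 / sample_rate_hz
  labs <- c("left", "right", "central", "none")
  samp_aoi <- assign_point(aois, stream$x, stream$y)
  samp_aoi[!stream$valid] <- NA
  dwell <- vapply(labs, function(l) sum(samp_aoi == l, na.rm = TRUE) * dt, 0)
  fix_aoi <- if (nrow(fixations)) {
    if (is.null(fixations$aoi)) assign_point(aois, fixations$cx, fixations$cy)
    else fixations$aoi
  } else character(0)
  nfix <- vapply(labs, function(l) sum(fix_aoi == l), 0L)
  data.frame(n_samples = nrow(stream), n_valid = sum(stream$valid),
             n_fix_left = nfix[["left"]], n_fix_right = nfix[["right"]],
             n_fix_central = nfix[["central"]], n_fix_none = nfix[["none"]],
             dwell_left_ms = dwell[["left"]], dwell_right_ms = dwell[["right"]],
             dwell_central_ms = dwell[["central"]], dwell_none_ms = dwell[["none"]],
             combined_lr_dwell_ms = dwell[["left"]] + dwell[["right"]])
}

#' Horizontally mirror a raw sample table
#'
#' Reflects both eyes' x-coordinates about the vertical screen midline
#' (pixel mirror `x -> width - 1 - x`). Together with swapping the
#' `side_of_threat` labels of the stimuli this leaves every curated
#' observation unchanged (mirror equivariance of the whole chain).
#'
#' @param samples Raw sample table (see [simulate_study()]).
#' @param screen A [screen_geometry()].
#' @export
mirror_samples <- function(samples, screen = screen_geometry()) {
  samples$lx <- mirror_x(samples$lx, screen)
  samples$rx <- mirror_x(samples$rx, screen)
  samples
}

#' Process a full table of raw binocular samples into trial metrics
#'
#' Batch driver over trials: binocular averaging, fixation detection and
#' per-trial metrics for every `trial_id` in `samples`.
#'
#' @param samples Sample table (columns `trial_id`, `t_ms`, `lx`, `ly`,
#'   `rx`, `ry`, `valid_l`, `valid_r`).
#' @param aois An [make_aoi_set()].
#' @param radius_px,min_run,sample_rate_hz Detector settings.
#' @return List with `metrics` (one row per trial, `trial_id` first) and
#'   `fixations` (all fixations, with `trial_id` and `fixation_index`).
#' @export
process_samples <- function(samples, aois, radius_px = 23, min_run = 2,
                            sample_rate_hz = 30) {
  parts <- split(samples, factor(samples$trial_id, levels = unique(samples$trial_id)))
  fix_list <- vector("list", length(parts))
  met_list <- vector("list", length(parts))
  for (k in seq_along(parts)) {
    tr <- parts[[k]]
    st <- average_binocular(tr)
    fx <- detect_fixations(st, radius_px = radius_px, min_run = min_run,
                           sample_rate_hz = sample_rate_hz, aois = aois)
    mt <- compute_trial_metrics(st, fx, aois, sample_rate_hz = sample_rate_hz)
    if (nrow(fx)) {
      fx <- cbind(trial_id = tr$trial_id[1], fixation_index = seq_len(nrow(fx)), fx)
      fix_list[[k]] <- fx
    }
    met_list[[k]] <- cbind(trial_id = tr$trial_id[1], mt)
  }
  list(metrics = do.call(rbind, met_list),
       fixations = if (all(vapply(fix_list, is.null, TRUE))) NULL
                   else do.call(rbind, fix_list))
}
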