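#' Quality-control filter on combined lateral dwell time
#'
#' Trials where the gaze spent less than `min_combined_dwell_ms` on the two
#' lateral AOIs combined are excluded (tracking loss or distraction). The
#' boundary is strict: a trial at exactly the threshold is kept.
#'
#' @param trial_metrics Metrics table from [process_samples()], experimental
#'   trials only (practise removed).
#' @param min_combined_dwell_ms Exclusion threshold in milliseconds.
#' @return List with `kept`, `excluded` (row subsets) and `log` (data frame
#'   `trial_id`, `combined_lr_dwell_ms`, `reason`).
#' @export
qc_filter <- function(trial_metrics, min_combined_dwell_ms = 2000) {
  bad <- trial_metrics$combined_lr_dwell_ms < min_combined_dwell_ms
  log <- data.frame(trial_id = trial_metrics$trial_id[bad],
                    combined_lr_dwell_ms = trial_metrics$combined_lr_dwell_ms[bad],
                    reason = rep(sprintf("combined L+R dwell under %g ms",
                                         min_combined_dwell_ms), sum(bad)),
                    stringsAsFactors = FALSE)
  list(kept = trial_metrics[!bad, , drop = FALSE],
       excluded = trial_metrics[bad, , drop = FALSE],
       log = log)
}

#' Curation summary arithmetic
#'
#' @param n_total Experimental trials before QC.
#' @param n_excluded Trials removed by [qc_filter()].
#' @return List with `n_total`, `n_excluded`, `excluded_pct` (rounded to
#'   2 d.p. as reported), and `n_retained`.
#' @export
curation_summary <- function(n_total, n_excluded) {
  list(n_total = n_total, n_excluded = n_excluded,
       excluded_pct = round(100 * n_excluded / n_total, 2),
       n_retained = n_total - n_excluded)
}

#' Average mirror-pair trials into participant-by-species observations
#'
#' Each surviving trial contributes threat-side and relaxed-side metrics
#' read off according to which lateral AOI held the threatening posture.
#' When both versions of a mirror pair survived QC the four metrics are
#' averaged and the observation gets weight 2; when only one survived, its
#' metrics are used with weight 1; when neither survived the participant
#' contributes no observation for that species.
#'
#' @param kept_trials QC-surviving metrics joined with trial metadata;
#'   must carry `participant_id`, `species_id`, `side_of_threat`,
#'   `n_fix_left`, `n_fix_right`, `dwell_left_ms`, `dwell_right_ms`.
#' @param participants Participant table (`participant_id`, `nationality`,
#'   `gender`, `age`) merged onto the observations.
#' @return Data frame of observations: identifiers, demographics, `weight`
#'   (1 or 2), `fix_threat`, `fix_relax`, `dwell_threat_ms`,
#'   `dwell_relax_ms`. Fixation counts can be half-integers after
#'   averaging.
#' @export
mirror_pair_average <- function(kept_trials, participants = NULL) {
  need <- c("participant_id", "species_id", "side_of_threat",
            "n_fix_left", "n_fix_right", "dwell_left_ms", "dwell_right_ms")
  miss <- setdiff(need, names(kept_trials))
  if (length(miss)) stop("kept_trials missing columns: ", paste(miss, collapse = ", "))
  thr_right <- kept_trials$side_of_threat == "right"
  kept_trials$fix_threat <- ifelse(thr_right, kept_trials$n_fix_right,
                                   kept_trials$n_fix_left)
  kept_trials$fix_relax <- ifelse(thr_right, kept_trials$n_fix_left,
                                  kept_trials$n_fix_right)
  kept_trials$dwell_threat_ms <- ifelse(thr_right, kept_trials$dwell_right_ms,
                                        kept_trials$dwell_left_ms)
  kept_trials$dwell_relax_ms <- ifelse(thr_right, kept_trials$dwell_left_ms,
                                       kept_trials$dwell_right_ms)
  key <- interaction(kept_trials$participant_id, kept_trials$species_id, drop = TRUE)
  sizes <- table(key)
  if (any(sizes > 2))
    stop("more than two surviving trials for one participant x species ",
         "(duplicate data)")
  agg <- function(v) tapply(v, key, mean)
  first <- function(v) tapply(as.character(v), key, `[`, 1L)
  obs <- data.frame(
    participant_id = first(kept_trials$participant_id),
    species_id = first(kept_trials$species_id),
    weight = as.integer(sizes[levels(key)]),
    fix_threat = as.numeric(agg(kept_trials$fix_threat)),
    fix_relax = as.numeric(agg(kept_trials$fix_relax)),
    dwell_threat_ms = as.numeric(agg(kept_trials$dwell_threat_ms)),
    dwell_relax_ms = as.numeric(agg(kept_trials$dwell_relax_ms)),
    stringsAsFactors = FALSE)
  if (!is.null(kept_trials$morphotype))
    obs$morphotype <- first(kept_trials$morphotype)
  rownames(obs) <- NULL
  if (!is.null(participants))
    obs <- merge(obs, participants[, intersect(
      c("participant_id", "nationality", "gender", "age"), names(participants))],
      by = "participant_id", sort = FALSE)
  obs[order(obs$participant_id, obs$species_id), , drop = FALSE]
}

#' Attach threat-minus-relaxed difference responses
#'
#' Positive differences mean more attention to the threatening posture.
#'
#' @param observations Result of [mirror_pair_average()].
#' @return The observations with `diff_fix` and `diff_dwell_ms` appended.
#' @export
compute_differences <- function(observations) {
  observations$diff_fix <- observations$fix_threat - observations$fix_relax
  observations$diff_dwell_ms <-
    observations$dwell_threat_ms - observations$dwell_relax_ms
  observations
}

#' Mann-Whitney comparison of two age samples
#'
#' Two-sided Mann-Whitney U test using the tie-corrected normal
#' approximation for the Z statistic (no continuity correction). The sign
#' of Z follows the first group: negative Z means the first group tends to
#' have smaller values.
#'
#' @param a,b Numeric vectors (e.g. ages of the two samples).
#' @return List with `U` (statistic of the first group), `Z` and `p`.
#' @export
compare_ages <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
  sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, Z = 0, p = 1))
  Z <- (U - mu) / sqrt(sigma2)
  list(U = U, Z = Z, p = 2 * stats::pnorm(-abs(Z)))
}
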