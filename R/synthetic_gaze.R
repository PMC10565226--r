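#' Calibrate attentional-bias parameters from target marginal quantities
#'
#' The generator separates attentional bias into an orienting component
#' (which side the next fixation lands on; logistic in a per-morphotype
#' log-odds) and a maintenance component (a threat-side multiplier on
#' fixation duration, per morphotype and nationality). Given target
#' threat-minus-relaxed differences in fixation counts and dwell times and
#' the target per-trial totals, the two components follow in closed form
#' from the expectation algebra of the generative model: with lateral
#' fixation count n, total lateral dwell T, threat-side probability p and
#' duration multiplier kappa,
#' \deqn{E[\Delta fix] = n (2p - 1), \qquad
#'       E[\Delta dwell] = T \frac{p\kappa - (1-p)}{p\kappa + (1-p)}.}
#'
#' Two second-order detector interactions enter the algebra. First,
#' within-fixation jitter occasionally splits a long fixation at the
#' dispersion detector (one extra counted fixation per excursion), and
#' longer threat-side fixations split more often; with per-sample split
#' probability \eqn{q} the realized count difference gains
#' \eqn{q\,E[\Delta dwell]/\Delta t}. Second, the single-sample saccade
#' transit between two same-side fixations lies inside that (convex) AOI
#' and counts toward its dwell, adding \eqn{n(1-c)(2p-1)} transit samples
#' to the dwell difference (c = central-episode fraction).
#'
#' @param diff_fix Named vector of target fixation-count differences per
#'   morphotype (threat minus relaxed).
#' @param diff_dwell Matrix of target dwell differences (ms), morphotypes
#'   in rows, nationalities in columns.
#' @param mean_fix_per_trial,mean_dwell_per_trial Target per-trial lateral
#'   totals.
#' @param center_fraction Probability an episode targets the fixation
#'   cross (must match the generator setting).
#' @param split_prob Per-sample probability that jitter carries a sample
#'   beyond the dispersion radius from its fixation's lead
#'   (`exp(-radius^2 / (4 * jitter_sd^2))` for Gaussian jitter; 0.005 at
#'   the defaults).
#' @param sample_rate_hz Sampling rate.
#' @return List with `side_bias` (log-odds per morphotype) and
#'   `threat_dur_mult` (matrix, morphotype x nationality).
#' @export
calibrate_attention_params <- function(
    diff_fix = c(cobra = 1.85, viper = 0.46, other = 0.28),
    diff_dwell = cbind(somali = c(cobra = 584.7, viper = 15.4, other = 148.8),
                       czech = c(cobra = 475.3, viper = 300.2, other = 334.5)),
    mean_fix_per_trial = 18.07, mean_dwell_per_trial = 4368,
    center_fraction = 0.13, split_prob = 0.005, sample_rate_hz = 30) {
  dt <- 1000 / sample_rate_hz
  n <- mean_fix_per_trial
  # orienting component: remove the jitter-split surplus, then invert
  # E[diff_fix] = n (2p - 1)
  dwell_mean <- rowMeans(diff_dwell)
  core_fix <- (diff_fix - split_prob * dwell_mean / dt) / (1 - split_prob)
  p <- (1 + core_fix / n) / 2
  # maintenance component: remove the same-side transit surplus from both
  # the difference and the total, then invert the duration-share ratio
  tl <- 1 - center_fraction                 # lateral-to-lateral transit share
  num <- sweep(diff_dwell / (n * dt), 1, tl * (2 * p - 1), `-`)
  den <- mean_dwell_per_trial / (n * dt) - tl * (p^2 + (1 - p)^2)
  rho <- sweep(num, 1, den, `/`)
  kappa <- sweep((1 + rho) / (1 - rho), 1, (1 - p) / p, `*`)
  list(side_bias = stats::qlogis(p), threat_dur_mult = kappa)
}

#' Default attention parameters of the synthetic study
#'
#' The defaults emulate the study conditions: per-trial lateral totals of
#' about 18 fixations and 4.4 s dwell in a 5-s trial, a morphotype-graded
#' bias toward the threatening posture (strongest for cobras), a
#' nationality-specific maintenance component, participant-level bias
#' heterogeneity (what the model's random intercept recovers), a larger
#' dwell-noise scale for the Somali sample (what the nationality variance
#' stratum recovers), and a 7.34% per-trial dropout probability producing
#' the quality-control exclusions.
#'
#' @param calibration Result of [calibrate_attention_params()].
#' @return List of generator parameters; see field comments in the source.
#' @export
default_attention_params <- function(calibration = calibrate_attention_params()) {
  list(
    side_bias = calibration$side_bias,          # log-odds threat side, per morphotype
    threat_dur_mult = calibration$threat_dur_mult, # morphotype x nationality
    mean_fixation_duration_ms = 224,
    fixation_duration_sd_ms = 70,
    central_duration_ms = 133,
    within_fixation_jitter_sd_px = 5,           # must stay well under the radius
    eye_offset_sd_px = 1.5,                     # per-eye deviation from gaze point
    saccade_duration_samples = 1L,
    center_dwell_fraction = 0.13,               # prob. an episode targets the cross
    dropout_rate = 0.0734,                      # per-trial long invalid episode
    participant_bias_sd = 0.15,                 # sd of per-participant log-odds offset
    nationality_sd_scale = c(somali = 1.25, czech = 1), # duration-noise scale
    aoi_margin_px = 35)                         # fixation points keep this margin
}

#' Simulate the participant roster
#'
#' @param n_per_nationality Participants per nationality.
#' @param n_women Women per nationality (the rest are men).
#' @param age_mean,age_sd,age_range Named per-nationality age settings
#'   (years; sampled from a rounded truncated normal).
#' @param seed Integer seed.
#' @return Data frame: `participant_id`, `nationality`, `gender`, `age`,
#'   `assigned_order` (1..4, uniform at random).
#' @export
simulate_participants <- function(n_per_nationality = c(somali = 71, czech = 71),
                                  n_women = 25,
                                  age_mean = c(somali = 22.4, czech = 24.6),
                                  age_sd = c(somali = 3.5, czech = 4.5),
                                  age_range = list(somali = c(19, 39),
                                                   czech = c(18, 44)),
                                  seed = 1L) {
  if (any(n_per_nationality < 0) || n_women < 0)
    stop("participant counts must be non-negative")
  set.seed(seed)
  rows <- list()
  for (nat in names(n_per_nationality)) {
    n <- n_per_nationality[[nat]]
    nw <- min(n_women, n)
    rng <- age_range[[nat]]
    ages <- integer(0)
    while (length(ages) < n) {
      a <- round(stats::rnorm(n, age_mean[[nat]], age_sd[[nat]]))
      ages <- c(ages, a[a >= rng[1] & a <= rng[2]])
    }
    rows[[nat]] <- data.frame(
      participant_id = sprintf("%s%03d", substr(nat, 1, 3), seq_len(n)),
      nationality = nat,
      gender = c(rep("woman", nw), rep("man", n - nw)),
      age = ages[seq_len(n)],
      assigned_order = sample(1:4, n, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## random point inside a rectangle, keeping a margin from its edges
.gz_point_in <- function(rect, margin) {
  x0 <- rect[1] + margin; x1 <- rect[3] - margin
  y0 <- rect[2] + margin; y1 <- rect[4] - margin
  if (x1 <= x0) { x0 <- (rect[1] + rect[3]) / 2; x1 <- x0 }
  if (y1 <= y0) { y0 <- (rect[2] + rect[4]) / 2; y1 <- y0 }
  c(stats::runif(1, x0, x1), stats::runif(1, y0, y1))
}

#' Simulate the binocular gaze stream of one trial
#'
#' The stream alternates fixation episodes with single-sample saccade
#' transits. Each episode targets the fixation cross with probability
#' `center_dwell_fraction`, otherwise one of the lateral AOIs, choosing
#' the side holding the threatening posture with probability
#' `plogis(side_bias[morphotype] + participant_offset)`. Episode duration
#' is a truncated normal (minimum two samples), multiplied by the
#' threat-side maintenance factor on the threat side. Samples scatter
#' around the episode's fixation point with Gaussian jitter well inside
#' the dispersion radius; each eye adds small independent noise to the
#' common gaze point. With probability `dropout_rate` a long contiguous
#' block of samples is invalidated (tracking loss / distraction), sized so
#' the trial fails the 2000 ms quality-control dwell cut.
#'
#' @param stimulus One row of [build_stimulus_set()].
#' @param aois An [make_aoi_set()].
#' @param params See [default_attention_params()].
#' @param seed Optional seed; when `NULL` the current RNG state is used.
#' @param participant_offset Participant-specific log-odds offset.
#' @param nationality Nationality of the participant (selects the
#'   maintenance column and the duration-noise scale); `NULL` uses the
#'   first column and scale 1.
#' @param duration_s,sample_rate_hz Trial timing.
#' @return Data frame: `t_ms`, `lx`, `ly`, `rx`, `ry`, `valid_l`,
#'   `valid_r`.
#' @export
simulate_trial_gaze <- function(stimulus, aois, params = default_attention_params(),
                                seed = NULL, participant_offset = 0,
                                nationality = NULL,
                                duration_s = 5, sample_rate_hz = 30) {
  if (!is.null(seed)) set.seed(seed)
  dt <- 1000 / sample_rate_hz
  n <- round(duration_s * sample_rate_hz)
  morph <- as.character(stimulus$morphotype)
  bias <- if (morph %in% names(params$side_bias))
    params$side_bias[[morph]] else 0
  kap_col <- if (!is.null(nationality) &&
                 nationality %in% colnames(params$threat_dur_mult)) nationality
             else colnames(params$threat_dur_mult)[1]
  kappa <- if (morph %in% rownames(params$threat_dur_mult))
    params$threat_dur_mult[morph, kap_col] else 1
  sd_scale <- if (!is.null(nationality) &&
                  nationality %in% names(params$nationality_sd_scale))
    params$nationality_sd_scale[[nationality]] else 1
  threat_aoi <- as.character(stimulus$side_of_threat)
  relax_aoi <- if (threat_aoi == "left") "right" else "left"
  p_threat <- stats::plogis(bias + participant_offset)
  mu_samp <- params$mean_fixation_duration_ms / dt
  sd_samp <- params$fixation_duration_sd_ms * sd_scale / dt
  x <- numeric(n); y <- numeric(n)
  i <- 1L
  prev <- c(aois$screen$width_px / 2, aois$screen$height_px / 2)
  first <- TRUE
  while (i <= n) {
    if (stats::runif(1) < params$center_dwell_fraction) {
      target <- "central"
      pt <- c(aois$screen$width_px / 2, aois$screen$height_px / 2) +
        stats::rnorm(2, 0, 8)
      m <- max(2L, round(params$central_duration_ms / dt))
    } else {
      target <- if (stats::runif(1) < p_threat) threat_aoi else relax_aoi
      pt <- .gz_point_in(aois[[target]], params$aoi_margin_px)
      mult <- if (target == threat_aoi) kappa else 1
      m <- max(2L, round(stats::rnorm(1, mu_samp * mult, sd_samp)))
    }
    if (!first && params$saccade_duration_samples > 0) {
      for (s in seq_len(params$saccade_duration_samples)) {
        if (i > n) break
        frac <- s / (params$saccade_duration_samples + 1)
        x[i] <- prev[1] + frac * (pt[1] - prev[1])
        y[i] <- prev[2] + frac * (pt[2] - prev[2])
        i <- i + 1L
      }
    }
    m <- min(m, n - i + 1L)
    if (m > 0) {
      idx <- i:(i + m - 1L)
      x[idx] <- pt[1] + stats::rnorm(m, 0, params$within_fixation_jitter_sd_px)
      y[idx] <- pt[2] + stats::rnorm(m, 0, params$within_fixation_jitter_sd_px)
      i <- i + m
    }
    prev <- pt; first <- FALSE
  }
  valid <- rep(TRUE, n)
  if (stats::runif(1) < params$dropout_rate) {
    len <- round(stats::runif(1, 0.65, 0.95) * n)
    start <- sample.int(n - len + 1L, 1L)
    valid[start:(start + len - 1L)] <- FALSE
  }
  eo <- params$eye_offset_sd_px
  out <- data.frame(
    t_ms = (seq_len(n) - 1) * dt,
    lx = x + stats::rnorm(n, 0, eo), ly = y + stats::rnorm(n, 0, eo),
    rx = x + stats::rnorm(n, 0, eo), ry = y + stats::rnorm(n, 0, eo),
    valid_l = valid, valid_r = valid)
  out$lx[!valid] <- NA_real_; out$ly[!valid] <- NA_real_
  out$rx[!valid] <- NA_real_; out$ry[!valid] <- NA_real_
  out
}

#' Simulate a complete study
#'
#' One gaze stream per participant and slide (41 slides at the default
#' catalogue: 40 experimental plus the flagged practise slide shown
#' first), following each participant's assigned presentation order.
#' Deterministic for a given seed.
#'
#' @param participants From [simulate_participants()]; simulated here when
#'   `NULL`.
#' @param stimuli From [build_stimulus_set()].
#' @param params See [default_attention_params()].
#' @param screen A [screen_geometry()].
#' @param seed Integer seed for everything (roster, orders, streams).
#' @return List with `participants`, `stimuli`, `orders`, `trials`
#'   (trial_id, participant_id, stimulus_version_id, order_id, position,
#'   is_practise) and `samples` (all gaze samples, keyed by trial_id).
#' @export
simulate_study <- function(participants = NULL,
                           stimuli = build_stimulus_set(),
                           params = default_attention_params(),
                           screen = screen_geometry(), seed = 1L) {
  set.seed(seed)
  if (is.null(participants))
    participants <- simulate_participants(seed = seed + 1L)
  orders <- build_presentation_orders(stimuli, seed = seed + 2L)
  aois <- make_aoi_set(screen)
  set.seed(seed + 3L)
  offsets <- stats::setNames(
    stats::rnorm(nrow(participants), 0, params$participant_bias_sd),
    participants$participant_id)
  practise <- stimuli[stimuli$is_practise, , drop = FALSE]
  trial_rows <- list(); sample_rows <- list()
  for (pi in seq_len(nrow(participants))) {
    pid <- participants$participant_id[pi]
    nat <- participants$nationality[pi]
    ord <- orders[orders$order_id == participants$assigned_order[pi], ]
    seq_ids <- c(practise$stimulus_version_id, ord$stimulus_version_id[order(ord$position)])
    for (pos in seq_along(seq_ids)) {
      stim <- stimuli[stimuli$stimulus_version_id == seq_ids[pos], ]
      trial_id <- sprintf("%s_t%02d", pid, pos)
      st <- simulate_trial_gaze(stim, aois, params,
                                participant_offset = offsets[[pid]],
                                nationality = nat)
      trial_rows[[trial_id]] <- data.frame(
        trial_id = trial_id, participant_id = pid,
        stimulus_version_id = seq_ids[pos],
        order_id = participants$assigned_order[pi], position = pos,
        is_practise = stim$is_practise, stringsAsFactors = FALSE)
      st$trial_id <- trial_id
      sample_rows[[trial_id]] <- st
    }
  }
  trials <- do.call(rbind, trial_rows)
  samples <- do.call(rbind, sample_rows)
  rownames(trials) <- rownames(samples) <- NULL
  samples <- samples[, c("trial_id", "t_ms", "lx", "ly", "rx", "ry",
                         "valid_l", "valid_r")]
  list(participants = participants, stimuli = stimuli, orders = orders,
       trials = trials, samples = samples)
}
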