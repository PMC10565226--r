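# Shared fixtures and independent oracles used across the test files.

# literal re-scan of the lead-sample grouping rule, written independently
# of detect_fixations(): walk the timeline, keep a lead, collect runs
brute_force_fixations <- function(stream, radius_px = 23, min_run = 2,
                                  sample_rate_hz = 30) {
  dt <- 1000 / sample_rate_hz
  groups <- list()
  cur <- integer(0)   # indices of the current group; first element is lead
  for (i in seq_len(nrow(stream))) {
    if (!stream$valid[i]) {
      if (length(cur) >= min_run) groups[[length(groups) + 1L]] <- cur
      cur <- integer(0)
      next
    }
    if (!length(cur)) {
      cur <- i
    } else {
      lead <- cur[1]
      d <- sqrt((stream$x[i] - stream$x[lead])^2 +
                (stream$y[i] - stream$y[lead])^2)
      if (d <= radius_px) {
        cur <- c(cur, i)
      } else {
        if (length(cur) >= min_run) groups[[length(groups) + 1L]] <- cur
        cur <- i
      }
    }
  }
  if (length(cur) >= min_run) groups[[length(groups) + 1L]] <- cur
  data.frame(
    lead_index = vapply(groups, `[`, 0L, 1L),
    first_index = vapply(groups, min, 0L),
    last_index = vapply(groups, max, 0L),
    n_samples = lengths(groups),
    duration_ms = vapply(groups, function(g)
      stream$t_ms[max(g)] - stream$t_ms[min(g)] + dt, 0),
    cx = vapply(groups, function(g) mean(stream$x[g]), 0),
    cy = vapply(groups, function(g) mean(stream$y[g]), 0))
}

# random-walk monocular stream with occasional invalid gaps
random_walk_stream <- function(n = 60, step_sd = 15, p_invalid = 0.05,
                               sample_rate_hz = 30) {
  x <- cumsum(rnorm(n, 0, step_sd)) + 683
  y <- cumsum(rnorm(n, 0, step_sd)) + 384
  valid <- runif(n) > p_invalid
  x[!valid] <- NA_real_; y[!valid] <- NA_real_
  data.frame(t_ms = (seq_len(n) - 1) * 1000 / sample_rate_hz,
             x = x, y = y, valid = valid)
}

# dense multivariate-normal evaluation of the profiled (RE)ML
# log-likelihood: builds the full n x n covariance and evaluates the
# Gaussian likelihood directly, profiling beta (GLS) and sigma^2
dense_profile_loglik <- function(design, lambda, delta, method = "REML") {
  X <- design$X; y <- design$y
  n <- length(y); p <- ncol(X)
  d_full <- c(0, delta)[design$g]
  v <- exp(2 * d_full) / design$w
  Z <- outer(design$pid, levels(design$pid), `==`) * 1
  W <- diag(v) + lambda * tcrossprod(Z)
  Wi <- solve(W)
  XtWX <- t(X) %*% Wi %*% X
  beta <- solve(XtWX, t(X) %*% Wi %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Wi %*% r)
  ldW <- determinant(W, logarithm = TRUE)$modulus
  if (method == "ML") {
    s2 <- rss / n
    -0.5 * (n * log(2 * pi) + n * log(s2) + ldW + n)
  } else {
    s2 <- rss / (n - p)
    ldX <- determinant(XtWX, logarithm = TRUE)$modulus
    -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2) + ldW + ldX + (n - p))
  }
}

# small random mixed-model dataset for likelihood property tests
random_lmm_data <- function(n_participants = 6, n_per = 5,
                            two_strata = TRUE) {
  d <- expand.grid(participant_id = sprintf("p%02d", seq_len(n_participants)),
                   rep = seq_len(n_per), stringsAsFactors = FALSE)
  d$group <- factor(sample(c("a", "b", "c"), nrow(d), replace = TRUE))
  d$nationality <- if (two_strata)
    factor(ifelse(match(d$participant_id, unique(d$participant_id)) %%
                    2 == 0, "czech", "somali"))
  else factor("all")
  d$weight <- sample(1:2, nrow(d), replace = TRUE)
  b <- rnorm(n_participants, 0, 1.5)
  d$y <- 2 + 0.8 * (d$group == "b") +
    b[match(d$participant_id, unique(d$participant_id))] +
    rnorm(nrow(d), 0, 1)
  d
}

# a reduced experiment: scaled stimulus catalogue (2 cobra, 2 viper,
# 1 python, 1 colubrid) and a small roster, for fast end-to-end runs
scaled_catalogue <- function() {
  data.frame(
    species_id = c("cobra01", "cobra02", "viper01", "viper02",
                   "python01", "colubrid01"),
    morphotype = factor(c("cobra", "cobra", "viper", "viper",
                          "other", "other"),
                        levels = c("cobra", "viper", "other")),
    taxon = c("cobra", "cobra", "viper", "viper", "python", "colubrid"),
    stringsAsFactors = FALSE)
}

small_study <- function(n_per_nat = 6, seed = 1, params = default_attention_params()) {
  parts <- simulate_participants(
    n_per_nationality = c(somali = n_per_nat, czech = n_per_nat),
    n_women = max(1, n_per_nat %/% 2), seed = seed)
  simulate_study(participants = parts,
                 stimuli = build_stimulus_set(scaled_catalogue(),
                                              allow_scaled = TRUE),
                 params = params, seed = seed)
}

# run a study through processing and curation, returning observations
study_to_observations <- function(study, qc_ms = 2000) {
  aois <- make_aoi_set()
  proc <- process_samples(study$samples, aois)
  trials <- study$trials; trials$is_practise <- NULL
  meta <- merge(trials, study$stimuli, by = "stimulus_version_id", sort = FALSE)
  tm <- merge(proc$metrics, meta, by = "trial_id", sort = FALSE)
  tm <- tm[!tm$is_practise, , drop = FALSE]
  qc <- qc_filter(tm, qc_ms)
  obs <- mirror_pair_average(qc$kept, study$participants)
  compute_differences(obs)
}
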