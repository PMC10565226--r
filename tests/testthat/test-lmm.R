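test_that("profiled log-likelihood matches a dense multivariate-normal oracle", {
  set.seed(14)
  for (rep in 1:30) {
    d <- random_lmm_data(n_participants = sample(3:8, 1),
                         n_per = sample(3:6, 1),
                         two_strata = rep %% 2 == 0)
    des <- lmm_design(y ~ group, d, var_group =
                        if (nlevels(d$nationality) > 1) "nationality" else NULL,
                      weights = "weight")
    k <- length(des$g_levels) - 1
    lambda <- runif(1, 0, 3)
    delta <- if (k) runif(k, -0.7, 0.7) else numeric(0)
    for (method in c("ML", "REML")) {
      mine <- lmm_profile_loglik(des, lambda, delta, method)
      oracle <- dense_profile_loglik(des, lambda, delta, method)
      expect_equal(mine, as.numeric(oracle), tolerance = 1e-8)
    }
  }
})

test_that("with no random effect and unit weights the ML log-likelihood is OLS", {
  set.seed(2)
  d <- random_lmm_data(n_participants = 5, n_per = 6, two_strata = FALSE)
  d$weight <- 1
  des <- lmm_design(y ~ group, d, weights = "weight")
  ll <- lmm_profile_loglik(des, lambda = 0, delta = numeric(0), method = "ML")
  ols <- stats::lm(y ~ group, d)
  expect_equal(ll, as.numeric(stats::logLik(ols)), tolerance = 1e-8)
})

test_that("REML log-likelihood is invariant to shifting the response", {
  set.seed(8)
  d <- random_lmm_data()
  des1 <- lmm_design(y ~ group, d, var_group = "nationality", weights = "weight")
  d2 <- d; d2$y <- d2$y + 37.5
  des2 <- lmm_design(y ~ group, d2, var_group = "nationality", weights = "weight")
  expect_equal(lmm_profile_loglik(des1, 0.8, 0.3),
               lmm_profile_loglik(des2, 0.8, 0.3), tolerance = 1e-10)
})

test_that("REML variance components match one-way ANOVA closed forms", {
  # balanced one-factor (participant) design, homoscedastic, unweighted:
  # sigma2 = MSW, sigma_b2 = (MSB - MSW) / n_per
  set.seed(33)
  m <- 12; n_per <- 8
  d <- data.frame(participant_id = rep(sprintf("p%02d", 1:m), each = n_per))
  b <- rnorm(m, 0, 2)
  d$y <- 5 + b[match(d$participant_id, unique(d$participant_id))] +
    rnorm(nrow(d), 0, 1.3)
  fit <- gazelmm(y ~ 1, d)
  grand <- mean(d$y)
  gm <- tapply(d$y, d$participant_id, mean)
  msb <- n_per * sum((gm - grand)^2) / (m - 1)
  msw <- sum((d$y - gm[d$participant_id])^2) / (m * (n_per - 1))
  expect_equal(fit$sigma2, msw, tolerance = 1e-6)
  expect_equal(fit$sigma_b2, (msb - msw) / n_per, tolerance = 1e-6)
})

test_that("zero-noise data recover the generating fixed effects exactly", {
  d <- expand.grid(participant_id = sprintf("p%d", 1:6),
                   group = factor(c("a", "b", "c")), rep = 1:2)
  mu <- c(a = 1, b = 3, c = -2)
  b <- seq(-0.5, 0.5, length.out = 6)
  d$y <- mu[d$group] + b[match(d$participant_id, unique(d$participant_id))]
  fit <- gazelmm(y ~ group, d)
  expect_equal(unname(coef(fit)), c(1, 2, -3), tolerance = 1e-4)
})

test_that("the engine agrees with nlme on the study-like model", {
  skip_if_not_installed("nlme")
  set.seed(19)
  d <- random_lmm_data(n_participants = 14, n_per = 10)
  d$invw <- 1 / d$weight
  for (method in c("REML", "ML")) {
    fit <- gazelmm(y ~ group + nationality, d, var_group = "nationality",
                   weights = "weight", method = method)
    ref <- nlme::lme(y ~ group + nationality, random = ~1 | participant_id,
                     data = d,
                     weights = nlme::varComb(
                       nlme::varIdent(form = ~1 | nationality),
                       nlme::varFixed(~invw)),
                     method = method, control = nlme::lmeControl(opt = "optim"))
    expect_equal(fit$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
    expect_equal(unname(coef(fit)), unname(nlme::fixef(ref)), tolerance = 1e-4)
    # per-stratum residual variances (independent of the reference choice:
    # nlme's varIdent references the first stratum met in data order)
    vi <- ref$modelStruct$varStruct[[1]]
    sd_ratio <- stats::coef(vi, unconstrained = FALSE, allCoef = TRUE)
    ref_var <- ref$sigma^2 * sd_ratio^2
    mine_var <- stats::setNames(
      fit$sigma2 * exp(2 * c(0, fit$delta)), fit$design$g_levels)
    expect_equal(unname(mine_var[names(ref_var)]), unname(ref_var),
                 tolerance = 1e-3)
    expect_equal(unname(sqrt(diag(vcov(fit)))),
                 unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-3)
  }
})

test_that("heteroscedasticity parameter is recovered from simulated data", {
  set.seed(44)
  hits <- 0
  for (rep in 1:20) {
    m <- 40; n_per <- 10
    d <- expand.grid(participant_id = sprintf("p%02d", 1:m), rep = 1:n_per)
    d$nationality <- factor(ifelse(match(d$participant_id,
                                         unique(d$participant_id)) <= m / 2,
                                   "czech", "somali"))
    d$weight <- sample(1:2, nrow(d), TRUE)
    b <- rnorm(m, 0, 1)
    delta_true <- 0.5
    sd_i <- sqrt(exp(2 * delta_true * (d$nationality == "somali")) / d$weight)
    d$y <- 2 + b[match(d$participant_id, unique(d$participant_id))] +
      rnorm(nrow(d), 0, sd_i)
    fit <- gazelmm(y ~ 1, d, var_group = "nationality", weights = "weight")
    if (abs(fit$delta - delta_true) < 0.15) hits <- hits + 1
  }
  expect_gte(hits, 16)
})

test_that("fit object invariants hold", {
  set.seed(3)
  d <- random_lmm_data(n_participants = 8, n_per = 6)
  fit <- gazelmm(y ~ group + nationality, d, var_group = "nationality",
                 weights = "weight")
  V <- vcov(fit)
  expect_true(isSymmetric(V, tol = 1e-10))
  expect_true(all(eigen(V, only.values = TRUE)$values > -1e-10))
  expect_gte(fit$sigma_b2, 0)
  expect_gt(fit$sigma2, 0)
  expect_equal(fit$aic, -2 * fit$logLik + 2 * (fit$n_fixed + fit$n_varpar))
  expect_error(gazelmm(y ~ group + missingcol, d), "not found")
  d2 <- d; d2$y[3] <- NA
  expect_error(gazelmm(y ~ group, d2), "missing values in column 'y'")
})

test_that("residuals and BLUPs decompose the response sensibly", {
  set.seed(70)
  d <- random_lmm_data(n_participants = 10, n_per = 8)
  fit <- gazelmm(y ~ group, d, var_group = "nationality", weights = "weight")
  r_pop <- residuals(fit)
  r_cond <- residuals(fit, level = "participant")
  expect_equal(unname(r_pop - r_cond),
               unname(ranef(fit)[as.integer(fit$design$pid)]), tolerance = 1e-10)
  # BLUPs shrink participant means toward zero
  expect_lt(max(abs(ranef(fit))), max(abs(tapply(r_pop, d$participant_id, mean))) + 1e-9)
  # simulate returns the right shape and responds to the seed
  s1 <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(s1), c(nrow(d), 2L))
  expect_identical(simulate(fit, seed = 5), simulate(fit, seed = 5))
})
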