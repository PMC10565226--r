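test_that("likelihood-ratio arithmetic reproduces the reported comparisons", {
  # the statistics are reported to 2 d.p., so the p-values carry that
  # rounding: agreement to ~1e-3 is the attainable precision
  expect_equal(lrt_pvalue(7.00, 6), 0.321, tolerance = 0.002)
  expect_equal(lrt_pvalue(3.66, 3), 0.300, tolerance = 0.004)
  # monotone in the statistic
  stats_grid <- seq(0, 20, by = 0.5)
  expect_true(all(diff(lrt_pvalue(stats_grid, 6)) < 0))
})

test_that("lrt() validates nesting and degenerates correctly", {
  set.seed(9)
  d <- random_lmm_data(n_participants = 8, n_per = 6)
  full <- gazelmm(y ~ group + nationality, d, var_group = "nationality",
                  weights = "weight", method = "ML")
  red <- gazelmm(y ~ group, d, var_group = "nationality",
                 weights = "weight", method = "ML")
  lr <- lrt(full, red)
  expect_gte(lr$stat, 0)
  expect_equal(lr$df, 1)
  expect_equal(lr$p, stats::pchisq(lr$stat, 1, lower.tail = FALSE))
  # AIC identity for nested ML fits: AIC difference = LRT stat - 2 df
  expect_equal(red$aic - full$aic, lr$stat - 2 * lr$df, tolerance = 1e-6)
  expect_error(lrt(red, full), "not nested|more fixed parameters")
  remlfit <- gazelmm(y ~ group, d, method = "REML")
  expect_error(lrt(full, remlfit), "requires ML")
})

test_that("inner-outer df bookkeeping matches the two-level rule", {
  set.seed(12)
  m <- 10; n_per <- 6
  d <- expand.grid(participant_id = sprintf("p%02d", 1:m), rep = 1:n_per)
  d$morphotype <- factor(sample(c("cobra", "viper", "other"), nrow(d), TRUE))
  idx <- match(d$participant_id, unique(d$participant_id))
  d$nationality <- factor(ifelse(idx <= m / 2, "czech", "somali"))
  d$gender <- factor(ifelse(idx %% 2 == 0, "m", "w"))
  d$age <- (20 + idx)[idx] * 1.0
  d$y <- rnorm(nrow(d))
  fit <- gazelmm(y ~ morphotype + nationality + gender + age +
                   morphotype:nationality + nationality:gender, d)
  df <- fit$df
  expect_equal(unname(df$term_level[c("morphotype", "morphotype:nationality")]),
               c("within", "within"))
  expect_equal(unname(df$term_level[c("nationality", "gender", "age",
                                      "nationality:gender")]),
               rep("between", 4))
  # p_between: nationality + gender + age + nationality:gender = 4 columns
  expect_equal(df$p_between, 4)
  expect_equal(df$p_within, 4)          # morphotype (2) + interaction (2)
  expect_equal(df$between, m - 4)
  expect_equal(df$within, m * n_per - m - 4)
  # nlme convention subtracts the intercept at the between level
  fit2 <- gazelmm(y ~ morphotype + nationality, d, nlme_convention = TRUE)
  expect_equal(fit2$df$between, m - 1 - 1)
})

test_that("df arithmetic reproduces the study-scale printed values", {
  # 142 participants, 2737 curated observations: full model between terms
  # are tested on 138 df, the reduced dwell model's nationality on 141,
  # morphotype-level terms on 2591/2593
  m <- 142; N <- 2737
  expect_equal(m - 4, 138)      # nationality+gender+age+nat:gender retained
  expect_equal(m - 1, 141)      # nationality the only between term
  expect_equal(N - m - 4, 2591) # morphotype + morphotype:nationality
  expect_equal(N - m - 2, 2593) # morphotype only
})

test_that("marginal Wald F tests are consistent with coefficient tests", {
  set.seed(25)
  d <- random_lmm_data(n_participants = 12, n_per = 8)
  fit <- gazelmm(y ~ group + nationality, d, var_group = "nationality",
                 weights = "weight")
  tab <- anova(fit)
  expect_equal(tab$term, c("group", "nationality"))
  # single-df term: F equals t^2 from the coefficient table
  st <- summary(fit)$coefficients
  tnat <- st["nationalitysomali", "t value"]
  expect_equal(tab$`F value`[tab$term == "nationality"], tnat^2,
               tolerance = 1e-8)
  expect_true(all(tab$`p value` >= 0 & tab$`p value` <= 1))
})

test_that("marginal means equal GLS cell estimates in a saturated model", {
  set.seed(61)
  d <- random_lmm_data(n_participants = 10, n_per = 8, two_strata = FALSE)
  fit <- gazelmm(y ~ group, d)
  e <- emm(fit, "group")
  beta <- coef(fit)
  expect_equal(e$estimate[e$group == "a"], unname(beta[1]), tolerance = 1e-10)
  expect_equal(e$estimate[e$group == "b"], unname(beta[1] + beta["groupb"]),
               tolerance = 1e-10)
  expect_equal(e$ci_hi - e$estimate, e$estimate - e$ci_lo, tolerance = 1e-10)
  # CI uses the t quantile at the focal term's df
  expect_equal(e$ci_hi[1] - e$estimate[1],
               stats::qt(0.975, e$df[1]) * e$se[1], tolerance = 1e-10)
})

test_that("marginal means and SEs match the emmeans package on an nlme fit", {
  skip_if_not_installed("nlme")
  skip_if_not_installed("emmeans")
  set.seed(83)
  d <- random_lmm_data(n_participants = 12, n_per = 8, two_strata = TRUE)
  d$invw <- 1 / d$weight
  fit <- gazelmm(y ~ group * nationality, d, var_group = "nationality",
                 weights = "weight")
  ref <- nlme::lme(y ~ group * nationality, random = ~1 | participant_id,
                   data = d,
                   weights = nlme::varComb(nlme::varIdent(form = ~1 | nationality),
                                           nlme::varFixed(~invw)),
                   control = nlme::lmeControl(opt = "optim"))
  em_ref <- suppressMessages(
    as.data.frame(emmeans::emmeans(ref, c("group", "nationality"))))
  mine <- emm(fit, c("group", "nationality"))
  key_ref <- paste(em_ref$group, em_ref$nationality)
  key_mine <- paste(mine$group, mine$nationality)
  ord <- match(key_ref, key_mine)
  expect_equal(mine$estimate[ord], em_ref$emmean, tolerance = 1e-4)
  expect_equal(mine$se[ord], em_ref$SE, tolerance = 1e-3)
})

test_that("contrasts difference the marginal means with propagated SE", {
  set.seed(47)
  d <- random_lmm_data(n_participants = 12, n_per = 8)
  fit <- gazelmm(y ~ group * nationality, d, var_group = "nationality",
                 weights = "weight")
  e <- emm(fit, c("nationality", "group"))
  ct <- contrast_emm(fit, "nationality", by = "group")
  for (g in levels(factor(d$group))) {
    d1 <- e$estimate[e$nationality == "czech" & e$group == g]
    d2 <- e$estimate[e$nationality == "somali" & e$group == g]
    expect_equal(ct$estimate[ct$group == g], d1 - d2, tolerance = 1e-10)
  }
  # nationality is participant-constant: contrast df is the between df
  expect_true(all(ct$df == fit$df$between))
})

test_that("backward reduction respects marginality and the alpha gate", {
  set.seed(59)
  m <- 24; n_per <- 12
  d <- expand.grid(participant_id = sprintf("p%02d", 1:m), rep = 1:n_per)
  d$morphotype <- factor(sample(c("cobra", "viper", "other"), nrow(d), TRUE),
                         levels = c("cobra", "viper", "other"))
  idx <- match(d$participant_id, unique(d$participant_id))
  d$nationality <- factor(ifelse(idx <= m / 2, "czech", "somali"))
  d$gender <- factor(ifelse(idx %% 2 == 0, "m", "w"))
  d$age <- 20 + (idx %% 7)
  d$weight <- sample(1:2, nrow(d), TRUE)
  b <- rnorm(m, 0, 0.4)
  # strong morphotype effect only
  d$y <- 2 * (d$morphotype == "cobra") + b[idx] + rnorm(nrow(d), 0, 1)
  red <- backward_reduce(
    y ~ morphotype + nationality + gender + age +
      morphotype:nationality + nationality:gender,
    d, var_group = "nationality", weights = "weight")
  expect_equal(attr(red$final$terms, "term.labels"), "morphotype")
  # interactions always leave before their main effects
  tr <- red$trace
  drop_nat_int <- which(tr$term == "morphotype:nationality" &
                          tr$action == "dropped")
  drop_nat <- which(tr$term == "nationality" & tr$action == "dropped")
  expect_true(drop_nat_int < drop_nat)
  # alpha = 1 drops nothing
  red_all <- backward_reduce(y ~ morphotype + nationality, d,
                             var_group = "nationality", weights = "weight",
                             alpha = 1 + 1e-9)
  expect_setequal(attr(red_all$final$terms, "term.labels"),
                  c("morphotype", "nationality"))
  # reduction is invariant to the order terms are written in
  red2 <- backward_reduce(
    y ~ nationality:gender + age + gender + morphotype:nationality +
      nationality + morphotype,
    d, var_group = "nationality", weights = "weight")
  expect_equal(sort(attr(red2$final$terms, "term.labels")),
               sort(attr(red$final$terms, "term.labels")))
})
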