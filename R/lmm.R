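## ---- design construction ---------------------------------------------------

#' Build the design for the heteroscedastic participant-intercept model
#'
#' Assembles the fixed-effect model matrix, the participant grouping index,
#' the variance-stratum indicator and the fixed precision weights for the
#' model
#' \deqn{y_i = x_i'\beta + b_{p(i)} + \epsilon_i,\quad
#'       b_p \sim N(0, \sigma_b^2),\quad
#'       \epsilon_i \sim N(0, \sigma^2 e^{2\delta_{g(i)}} / w_i).}
#' The first level of the variance-stratum factor is the reference
#' (\eqn{\delta = 0}).
#'
#' @param formula Fixed-effects formula (response on the left).
#' @param data Data frame of observations.
#' @param participant Name of the grouping column (random intercept).
#' @param var_group Optional name of the factor defining residual variance
#'   strata (e.g. nationality), or `NULL` for a single stratum.
#' @param weights Optional name of the observation-weight column
#'   (residual variance proportional to 1/weight), or `NULL`.
#' @return A list of class `gazelmm_design` with elements `X`, `y`, `pid`
#'   (factor), `g` (integer stratum index, 1 = reference), `w`, `terms`,
#'   and bookkeeping fields.
#' @export
lmm_design <- function(formula, data, participant = "participant_id",
                       var_group = NULL, weights = NULL) {
  vars <- all.vars(formula)
  used <- unique(c(vars, participant, var_group, weights))
  miss_col <- setdiff(used, names(data))
  if (length(miss_col))
    stop("columns not found in data: ", paste(miss_col, collapse = ", "))
  for (v in used) {
    if (anyNA(data[[v]])) stop("missing values in column '", v, "'")
    if (is.character(data[[v]]) && v %in% vars)
      data[[v]] <- factor(data[[v]])
  }
  mf <- stats::model.frame(formula, data)
  trm <- attr(mf, "terms")
  X <- stats::model.matrix(trm, mf)
  y <- stats::model.response(mf)
  pid <- factor(data[[participant]])
  if (nlevels(pid) < 2) stop("need at least 2 participants")
  if (!is.null(var_group)) {
    gfac <- factor(data[[var_group]])
    if (any(table(gfac) < 2))
      stop("each variance stratum needs at least 2 observations")
  } else gfac <- factor(rep("all", nrow(data)))
  w <- if (!is.null(weights)) as.numeric(data[[weights]]) else rep(1, nrow(data))
  if (any(w <= 0)) stop("weights must be positive")
  structure(list(X = X, y = as.numeric(y), pid = pid,
                 g = as.integer(gfac), g_levels = levels(gfac),
                 w = w, terms = trm, formula = formula,
                 participant = participant, var_group = var_group,
                 weights_col = weights, data = data),
            class = "gazelmm_design")
}

## Profiled Gaussian (restricted) log-likelihood.
## W = Lambda + lambda * Z Z' block-diagonal over participants;
## Lambda = diag(exp(2 delta_g) / w). beta and sigma^2 are profiled out.
## Per-block Woodbury: no dense n x n matrix is ever formed.
.gz_profile <- function(des, lambda, delta, method = c("REML", "ML")) {
  method <- match.arg(method)
  X <- des$X; y <- des$y; pid <- des$pid
  n <- length(y); p <- ncol(X)
  d_full <- c(0, delta)[des$g]              # delta for each observation
  vinv <- des$w * exp(-2 * d_full)          # 1 / relative variance
  sp <- as.numeric(rowsum(vinv, pid))       # per-participant sum of 1/v
  cp <- lambda / (1 + lambda * sp)
  Xv <- X * vinv
  U <- rowsum(Xv, pid)                      # m x p: sum vinv * x per block
  uy <- as.numeric(rowsum(y * vinv, pid))
  XtWX <- crossprod(X, Xv) - crossprod(U, U * cp)
  XtWy <- crossprod(X, y * vinv) - crossprod(U, cp * uy)
  ytWy <- sum(vinv * y^2) - sum(cp * uy^2)
  R <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(R)) return(list(ll = -Inf))
  beta <- backsolve(R, backsolve(R, XtWy, transpose = TRUE))
  rss <- ytWy - sum(beta * XtWy)
  rss <- max(rss, 1e-300)
  logdetW <- -sum(log(vinv)) + sum(log1p(lambda * sp))
  if (method == "ML") {
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetW + n)
  } else {
    sigma2 <- rss / (n - p)
    logdetXtWX <- 2 * sum(log(diag(R)))
    ll <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(sigma2) +
                  logdetW + logdetXtWX + (n - p))
  }
  list(ll = as.numeric(ll), beta = drop(beta), sigma2 = sigma2,
       XtWX = XtWX, R = R, cp = cp, vinv = vinv, uy = uy, sp = sp)
}

#' Profiled log-likelihood of the heteroscedastic mixed model
#'
#' Evaluates the (restricted) log-likelihood at given variance parameters,
#' with the fixed effects and the residual scale profiled out. Computed
#' blockwise per participant via the Woodbury identity; no dense n-by-n
#' covariance is formed.
#'
#' @param design A [lmm_design()].
#' @param lambda Ratio \eqn{\sigma_b^2/\sigma^2} (non-negative).
#' @param delta Numeric vector of log standard-deviation ratios for the
#'   non-reference variance strata (length = number of strata - 1; may be
#'   length 0).
#' @param method `"REML"` or `"ML"`.
#' @return Scalar log-likelihood.
#' @export
lmm_profile_loglik <- function(design, lambda, delta = numeric(0),
                               method = c("REML", "ML")) {
  if (!is.finite(lambda) || lambda < 0 || any(!is.finite(delta)))
    stop("variance parameters must be finite and lambda >= 0")
  .gz_profile(design, lambda, delta, method)$ll
}

## ---- fitting ---------------------------------------------------------------

#' Fit a linear mixed model with participant intercept and heteroscedastic
#' residuals
#'
#' Fits, by profiled (restricted) maximum likelihood, the model
#' \deqn{y_i = x_i'\beta + b_{p(i)} + \epsilon_i}
#' with independent participant intercepts \eqn{b_p \sim N(0,\sigma_b^2)}
#' and independent residuals whose variance combines a stratum-specific
#' scale (e.g. per nationality) with fixed precision weights:
#' \eqn{\mathrm{Var}(\epsilon_i) = \sigma^2\, e^{2\delta_{g(i)}} / w_i},
#' \eqn{\delta = 0} in the reference stratum. The variance parameters
#' \eqn{(\log\lambda, \delta)} with \eqn{\lambda = \sigma_b^2/\sigma^2}
#' are optimised by a deterministic quasi-Newton search from a fixed
#' multi-start grid; \eqn{\beta} and \eqn{\sigma^2} are profiled out.
#'
#' @inheritParams lmm_design
#' @param method `"REML"` (default; used for coefficient reporting) or
#'   `"ML"` (used for nested-model likelihood-ratio comparison).
#' @param nlme_convention If `TRUE`, between-participant denominator
#'   degrees of freedom subtract one additional parameter for the
#'   intercept, as `anova.lme` does; the default counts only non-intercept
#'   parameters at each level.
#' @return An object of class `gazelmm`; see [summary.gazelmm()],
#'   [anova.gazelmm()], [emm()].
#' @export
gazelmm <- function(formula, data, participant = "participant_id",
                    var_group = NULL, weights = NULL,
                    method = c("REML", "ML"), nlme_convention = FALSE) {
  method <- match.arg(method)
  des <- lmm_design(formula, data, participant, var_group, weights)
  k <- length(des$g_levels) - 1L           # number of delta parameters
  obj <- function(par) {
    lam <- exp(par[1]); del <- if (k) par[-1] else numeric(0)
    -.gz_profile(des, lam, del, method)$ll
  }
  starts <- expand.grid(loglam = c(-2, 0, 2),
                        del1 = if (k) c(-0.5, 0, 0.5) else 0)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    par0 <- c(starts$loglam[s], if (k) c(starts$del1[s], rep(0, k - 1L)))
    fit <- tryCatch(
      stats::optim(par0, obj, method = "L-BFGS-B",
                   lower = c(-15, rep(-5, k)), upper = c(15, rep(5, k)),
                   control = list(factr = 1e3, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-10) best <- fit
  }
  if (is.null(best)) stop("mixed-model optimisation failed for all starts")
  lambda <- exp(best$par[1])
  boundary <- best$par[1] <= -15 + 1e-6
  if (boundary) lambda <- 0
  delta <- if (k) best$par[-1] else numeric(0)
  prof <- .gz_profile(des, lambda, delta, method)
  p <- ncol(des$X)
  n <- length(des$y)
  m <- nlevels(des$pid)
  vcov_beta <- prof$sigma2 * chol2inv(prof$R)
  dimnames(vcov_beta) <- list(colnames(des$X), colnames(des$X))
  beta <- stats::setNames(prof$beta, colnames(des$X))
  n_varpar <- 2L + k                        # sigma2, sigma_b2, deltas
  ll <- prof$ll
  fit <- structure(list(
    call = match.call(), formula = des$formula, terms = des$terms,
    design = des, method = method,
    coefficients = beta, vcov = vcov_beta,
    sigma2 = prof$sigma2, sigma_b2 = lambda * prof$sigma2,
    lambda = lambda, delta = stats::setNames(delta, des$g_levels[-1][seq_len(k)]),
    boundary = boundary,
    logLik = ll, aic = -2 * ll + 2 * (p + n_varpar),
    n_obs = n, n_participants = m, n_fixed = p, n_varpar = n_varpar,
    nlme_convention = nlme_convention,
    convergence = best$convergence), class = "gazelmm")
  fit$df <- denominator_df(fit)
  fit
}

## ---- denominator degrees of freedom ---------------------------------------

## a model-matrix column is "between" if constant within every participant
.gz_col_between <- function(des) {
  X <- des$X; pid <- des$pid
  rng <- rowsum(X, pid) / as.numeric(table(pid))
  expanded <- rng[as.integer(pid), , drop = FALSE]
  apply(abs(X - expanded) < 1e-9, 2, all)
}

#' Inner-outer denominator degrees of freedom
#'
#' Two-level assignment: fixed terms that are constant within participants
#' (demographics and their interactions) are tested against
#' between-participant degrees of freedom; terms varying within
#' participants (stimulus morphotype and its interactions) against
#' within-participant degrees of freedom. With m participants, N
#' observations, and \eqn{p_b}/\eqn{p_w} non-intercept parameters at the
#' between/within level, the defaults are \eqn{df_b = m - p_b} and
#' \eqn{df_w = N - m - p_w}; with `nlme_convention = TRUE` the between df
#' additionally subtract 1 for the intercept.
#'
#' @param fit A [gazelmm()] fit.
#' @return List with `between`, `within` (the two df values), `term_level`
#'   (named character vector "between"/"within" per term) and the
#'   parameter counts.
#' @export
denominator_df <- function(fit) {
  des <- fit$design
  between_col <- .gz_col_between(des)
  asg <- attr(des$X, "assign")
  labels <- attr(des$terms, "term.labels")
  term_level <- character(length(labels))
  for (j in seq_along(labels)) {
    cols <- which(asg == j)
    term_level[j] <- if (all(between_col[cols])) "between" else "within"
  }
  names(term_level) <- labels
  nonint <- asg != 0
  p_between <- sum(between_col & nonint)
  p_within <- sum(!between_col & nonint)
  m <- fit$n_participants; n <- fit$n_obs
  df_b <- m - p_between - if (isTRUE(fit$nlme_convention)) 1L else 0L
  df_w <- n - m - p_within
  if (df_w < 0) stop("within-participant degrees of freedom would be negative")
  list(between = df_b, within = df_w, term_level = term_level,
       p_between = p_between, p_within = p_within)
}

## ---- likelihood-ratio test and AIC ----------------------------------------

#' Likelihood-ratio test between nested ML fits
#'
#' @param full,reduced Two [gazelmm()] fits of nested fixed-effect
#'   structures on the same data, both fitted with `method = "ML"`.
#' @return List with `stat` (2 delta-log-likelihood, clipped at 0), `df`
#'   (difference in fixed-parameter count) and `p` (upper-tail chi-square).
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "gazelmm"), inherits(reduced, "gazelmm"))
  if (full$method != "ML" || reduced$method != "ML")
    stop("likelihood-ratio comparison requires ML fits")
  if (full$n_obs != reduced$n_obs)
    stop("fits are not on the same data (different n)")
  full_terms <- colnames(full$design$X)
  red_terms <- colnames(reduced$design$X)
  if (!all(red_terms %in% full_terms))
    stop("models are not nested (reduced has terms absent from full)")
  df <- full$n_fixed - reduced$n_fixed
  if (df <= 0) stop("full model must have more fixed parameters")
  stat <- max(0, 2 * (full$logLik - reduced$logLik))
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Chi-square p-value for a likelihood-ratio statistic
#'
#' Upper-tail chi-square probability, as used for full-versus-reduced
#' model comparison.
#' @param stat Likelihood-ratio statistic (2 delta-log-likelihood).
#' @param df Number of dropped parameters.
#' @export
lrt_pvalue <- function(stat, df) stats::pchisq(stat, df, lower.tail = FALSE)
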