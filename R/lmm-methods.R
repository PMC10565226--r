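#' @export
print.gazelmm <- function(x, ...) {
  cat("Linear mixed model (participant intercept, heteroscedastic residuals)\n")
  cat("  fixed:  ", paste(deparse(x$formula), collapse = " "), "\n")
  cat("  method: ", x$method, "   logLik:", format(x$logLik, digits = 7),
      "   AIC:", format(x$aic, digits = 7), "\n")
  cat("  n =", x$n_obs, "observations,", x$n_participants, "participants\n")
  cat("  sigma_b^2 =", format(x$sigma_b2, digits = 5),
      "  sigma^2 =", format(x$sigma2, digits = 5))
  if (length(x$delta))
    cat("  delta(", paste(names(x$delta), collapse = ","), ") =",
        paste(format(x$delta, digits = 4), collapse = ", "))
  cat("\n\nFixed effects:\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.gazelmm <- function(object, ...) object$coefficients

#' @export
vcov.gazelmm <- function(object, ...) object$vcov

#' @export
logLik.gazelmm <- function(object, ...) {
  structure(object$logLik,
            df = object$n_fixed + object$n_varpar,
            nobs = object$n_obs, class = "logLik")
}

#' Summary of a heteroscedastic mixed-model fit
#'
#' Coefficient table with standard errors, inner-outer denominator degrees
#' of freedom, t statistics and two-sided p-values, plus the variance
#' components.
#' @param object A [gazelmm()] fit.
#' @param ... Unused.
#' @export
summary.gazelmm <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  est <- object$coefficients
  asg <- attr(object$design$X, "assign")
  between_col <- .gz_col_between(object$design)
  dfs <- ifelse(between_col, object$df$between, object$df$within)
  dfs[asg == 0] <- object$df$within   # intercept tested against within df
  tval <- est / se
  tab <- cbind(Estimate = est, `Std.Error` = se, df = dfs,
               `t value` = tval,
               `p value` = 2 * stats::pt(-abs(tval), dfs))
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.gazelmm"
  out
}

#' @export
print.summary.gazelmm <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficient tests (inner-outer df):\n")
  stats::printCoefmat(x$coefficients, has.Pvalue = TRUE, P.values = TRUE)
  invisible(x)
}

#' Wald F tests per fixed term, or likelihood-ratio comparison of two fits
#'
#' With a single fit, computes marginal (drop-one) Wald F statistics for
#' every fixed term against its inner-outer denominator df. With two fits,
#' performs the likelihood-ratio test (requires ML fits) and reports AIC.
#'
#' @param object A [gazelmm()] fit.
#' @param ... Optionally a second nested fit.
#' @export
anova.gazelmm <- function(object, ...) {
  dots <- list(...)
  fits <- Filter(function(z) inherits(z, "gazelmm"), dots)
  if (length(fits)) {
    other <- fits[[1]]
    full <- if (object$n_fixed >= other$n_fixed) object else other
    red <- if (identical(full, object)) other else object
    lr <- lrt(full, red)
    out <- data.frame(model = c("full", "reduced"),
                      npar = c(full$n_fixed + full$n_varpar,
                               red$n_fixed + red$n_varpar),
                      AIC = c(full$aic, red$aic),
                      logLik = c(full$logLik, red$logLik),
                      LRT = c(NA, lr$stat), df = c(NA, lr$df),
                      `p value` = c(NA, lr$p), check.names = FALSE)
    return(out)
  }
  labels <- attr(object$terms, "term.labels")
  asg <- attr(object$design$X, "assign")
  V <- object$vcov; beta <- object$coefficients
  lev <- object$df$term_level
  res <- data.frame(term = labels,
                    numDF = rep(NA_integer_, length(labels)),
                    denDF = rep(NA_real_, length(labels)),
                    `F value` = rep(NA_real_, length(labels)),
                    `p value` = rep(NA_real_, length(labels)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_along(labels)) {
    cols <- which(asg == j)
    q <- length(cols)
    b <- beta[cols]
    Fstat <- drop(t(b) %*% solve(V[cols, cols, drop = FALSE], b)) / q
    ddf <- if (lev[labels[j]] == "between") object$df$between else object$df$within
    res$numDF[j] <- q; res$denDF[j] <- ddf
    res$`F value`[j] <- Fstat
    res$`p value`[j] <- stats::pf(Fstat, q, ddf, lower.tail = FALSE)
  }
  res
}

#' @export
fitted.gazelmm <- function(object, level = c("population", "participant"), ...) {
  level <- match.arg(level)
  xb <- drop(object$design$X %*% object$coefficients)
  if (level == "participant") xb <- xb + ranef(object)[as.integer(object$design$pid)]
  xb
}

#' @export
residuals.gazelmm <- function(object, level = c("population", "participant"),
                              type = c("response", "pearson"), ...) {
  level <- match.arg(level); type <- match.arg(type)
  r <- object$design$y - fitted(object, level = level)
  if (type == "pearson") {
    d_full <- c(0, object$delta)[object$design$g]
    v <- object$sigma2 * exp(2 * d_full) / object$design$w
    r <- r / sqrt(v)
  }
  r
}

#' Predicted participant intercepts (BLUPs)
#'
#' @param object A [gazelmm()] fit.
#' @param ... Unused.
#' @return Named numeric vector, one entry per participant.
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @export
ranef.gazelmm <- function(object, ...) {
  des <- object$design
  d_full <- c(0, object$delta)[des$g]
  vinv <- des$w * exp(-2 * d_full)
  r <- des$y - drop(des$X %*% object$coefficients)
  sp <- as.numeric(rowsum(vinv, des$pid))
  ur <- as.numeric(rowsum(r * vinv, des$pid))
  b <- object$lambda * ur / (1 + object$lambda * sp)
  stats::setNames(b, levels(des$pid))
}

#' @export
predict.gazelmm <- function(object, newdata = NULL,
                            level = c("population", "participant"), ...) {
  level <- match.arg(level)
  if (is.null(newdata)) return(fitted(object, level = level))
  used <- all.vars(stats::delete.response(object$terms))
  for (v in used)
    if (is.character(newdata[[v]])) newdata[[v]] <- factor(newdata[[v]])
  mf <- stats::model.frame(stats::delete.response(object$terms), newdata,
                           xlev = .gz_xlevels(object))
  X <- stats::model.matrix(stats::delete.response(object$terms), mf)
  out <- drop(X %*% object$coefficients)
  if (level == "participant") {
    b <- ranef(object)
    idx <- match(as.character(newdata[[object$design$participant]]), names(b))
    out <- out + ifelse(is.na(idx), 0, b[idx])
  }
  out
}

.gz_xlevels <- function(object) {
  dat <- object$design$data
  vars <- all.vars(stats::delete.response(object$terms))
  lv <- lapply(dat[vars], function(v)
    if (is.factor(v)) levels(v) else if (is.character(v)) levels(factor(v)) else NULL)
  Filter(Negate(is.null), lv)
}

#' Simulate responses from a fitted model
#'
#' Draws new response vectors from the estimated model: fixed effects plus
#' fresh participant intercepts and heteroscedastic residuals.
#' @param object A [gazelmm()] fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @export
simulate.gazelmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  des <- object$design
  xb <- drop(des$X %*% object$coefficients)
  d_full <- c(0, object$delta)[des$g]
  sd_eps <- sqrt(object$sigma2 * exp(2 * d_full) / des$w)
  m <- nlevels(des$pid)
  out <- replicate(nsim, {
    b <- stats::rnorm(m, 0, sqrt(object$sigma_b2))
    xb + b[as.integer(des$pid)] + stats::rnorm(length(xb), 0, sd_eps)
  })
  as.data.frame(out)
}
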