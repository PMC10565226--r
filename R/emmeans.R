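## Build the reference-grid weights (L matrix) for marginal means:
## focal factors at each of their level combinations, non-focal factors
## averaged with equal weight over their levels, covariates at their mean.
.gz_refgrid <- function(fit, specs) {
  trm <- stats::delete.response(fit$terms)
  vars <- all.vars(trm)
  dat <- fit$design$data
  fac <- vars[vapply(dat[vars], function(v) is.factor(v) || is.character(v), TRUE)]
  num <- setdiff(vars, fac)
  if (!all(specs %in% fac))
    stop("emm specs must name factors in the model: ",
         paste(setdiff(specs, fac), collapse = ", "))
  lv <- lapply(dat[fac], function(v) levels(factor(v)))
  grid <- expand.grid(lv, stringsAsFactors = TRUE)
  for (v in num) grid[[v]] <- mean(as.numeric(dat[[v]]))
  M <- stats::model.matrix(trm, stats::model.frame(trm, grid, xlev = lv))
  cell <- interaction(grid[specs], drop = FALSE, sep = ":")
  Lmat <- t(vapply(levels(cell),
                   function(cl) colMeans(M[cell == cl, , drop = FALSE]),
                   numeric(ncol(M))))
  cells <- unique(grid[specs])
  cells <- cells[match(levels(cell), do.call(paste, c(cells, sep = ":"))), ,
                 drop = FALSE]
  rownames(cells) <- NULL
  list(L = Lmat, cells = cells)
}

## df class of a set of focal factors: within if any focal factor appears
## in a within-level term, else between
.gz_focal_df <- function(fit, specs) {
  lev <- fit$df$term_level
  focal_level <- vapply(specs, function(s) {
    hit <- lev[names(lev) == s]
    if (!length(hit)) stop("factor '", s, "' is not a model term")
    hit
  }, character(1))
  if (any(focal_level == "within")) fit$df$within else fit$df$between
}

#' Estimated marginal means
#'
#' Model-based cell means for one or more focal factors, averaging with
#' equal weight over the levels of non-focal factors and holding
#' covariates at their sample mean. Each mean is tested against zero with
#' the inner-outer denominator degrees of freedom of the focal term.
#'
#' @param fit A [gazelmm()] fit (REML recommended for reporting).
#' @param specs Character vector of focal factor names, e.g.
#'   `"morphotype"` or `c("morphotype", "nationality")`.
#' @param level Confidence level for the interval.
#' @return A data frame of class `gazelmm_emm` with the focal levels,
#'   `estimate`, `se`, `df`, `ci_lo`, `ci_hi`, `t`, `p`.
#' @export
emm <- function(fit, specs, level = 0.95) {
  stopifnot(inherits(fit, "gazelmm"))
  rg <- .gz_refgrid(fit, specs)
  est <- drop(rg$L %*% fit$coefficients)
  se <- sqrt(diag(rg$L %*% fit$vcov %*% t(rg$L)))
  df <- .gz_focal_df(fit, specs)
  tcrit <- stats::qt(1 - (1 - level) / 2, df)
  out <- cbind(rg$cells,
               data.frame(estimate = est, se = se, df = df,
                          ci_lo = est - tcrit * se, ci_hi = est + tcrit * se,
                          t = est / se,
                          p = 2 * stats::pt(-abs(est / se), df)))
  rownames(out) <- NULL
  structure(out, class = c("gazelmm_emm", "data.frame"),
            specs = specs, conf_level = level)
}

#' Pairwise contrasts of marginal means across one factor
#'
#' Differences of estimated marginal means between levels of
#' `contrast_factor`, computed within each combination of the remaining
#' focal factors. The denominator degrees of freedom are those of the
#' contrasted factor (between-participant df for participant-constant
#' factors such as nationality).
#'
#' @param fit A [gazelmm()] fit.
#' @param contrast_factor Factor whose levels are differenced.
#' @param by Optional character vector of conditioning factors.
#' @param level Confidence level.
#' @return Data frame of class `gazelmm_emm` with one row per level pair
#'   (and `by` cell): `contrast`, `estimate`, `se`, `df`, CI, `t`, `p`.
#' @export
contrast_emm <- function(fit, contrast_factor, by = NULL, level = 0.95) {
  specs <- c(contrast_factor, by)
  rg <- .gz_refgrid(fit, specs)
  lev <- levels(factor(fit$design$data[[contrast_factor]]))
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  bycell <- if (length(by)) interaction(rg$cells[by], drop = TRUE, sep = ":")
            else factor(rep("all", nrow(rg$cells)))
  df <- .gz_focal_df(fit, contrast_factor)
  tcrit <- stats::qt(1 - (1 - level) / 2, df)
  rows <- list()
  for (bc in levels(bycell)) {
    sel <- which(bycell == bc)
    for (pr in pairs) {
      i <- sel[rg$cells[sel, contrast_factor] == pr[1]]
      j <- sel[rg$cells[sel, contrast_factor] == pr[2]]
      Ld <- rg$L[i, ] - rg$L[j, ]
      est <- sum(Ld * fit$coefficients)
      se <- sqrt(drop(t(Ld) %*% fit$vcov %*% Ld))
      row <- data.frame(contrast = paste(pr[1], "-", pr[2]),
                        estimate = est, se = se, df = df,
                        ci_lo = est - tcrit * se, ci_hi = est + tcrit * se,
                        t = est / se, p = 2 * stats::pt(-abs(est / se), df),
                        stringsAsFactors = FALSE)
      if (length(by)) row <- cbind(rg$cells[i, by, drop = FALSE], row)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("gazelmm_emm", "data.frame"),
            specs = specs, conf_level = level)
}

#' @export
print.gazelmm_emm <- function(x, digits = 4, ...) {
  cat("Estimated marginal means (",
      paste(attr(x, "specs"), collapse = " x "), "), ",
      round(100 * attr(x, "conf_level")), "% CI\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Plot marginal means with confidence intervals
#'
#' Base-graphics dot plot of the estimates with CI whiskers and a zero
#' reference line.
#' @param x A [emm()] result.
#' @param ... Passed to [plot()].
#' @export
plot.gazelmm_emm <- function(x, ...) {
  labcols <- setdiff(names(x), c("estimate", "se", "df", "ci_lo", "ci_hi",
                                 "t", "p"))
  labs <- do.call(paste, c(x[labcols], sep = " / "))
  n <- nrow(x)
  yl <- range(0, x$ci_lo, x$ci_hi)
  plot(seq_len(n), x$estimate, ylim = yl, xaxt = "n",
       xlab = "", ylab = "estimate", pch = 19, ...)
  graphics::axis(1, at = seq_len(n), labels = labs, las = 2, cex.axis = 0.8)
  graphics::segments(seq_len(n), x$ci_lo, seq_len(n), x$ci_hi)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}
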