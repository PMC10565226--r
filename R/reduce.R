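## marginality: term A is protected while any other retained term contains
## all of A's variables
.gz_eliminable <- function(trm) {
  fac <- attr(trm, "factors")
  labels <- attr(trm, "term.labels")
  if (!length(labels)) return(character(0))
  vars_of <- lapply(labels, function(l) rownames(fac)[fac[, l] > 0])
  ok <- vapply(seq_along(labels), function(j) {
    !any(vapply(seq_along(labels), function(k) {
      k != j && all(vars_of[[j]] %in% vars_of[[k]])
    }, TRUE))
  }, TRUE)
  labels[ok]
}

#' Backward reduction of fixed effects
#'
#' Starting from the full fixed-effect structure, repeatedly refits the
#' model (REML), computes marginal Wald F tests for every currently
#' eliminable term (interactions before their main effects; a main effect
#' is protected while it appears in a retained interaction), and drops the
#' term with the largest p-value at or above `alpha`, until every retained
#' term is significant or protected. The final reduced model and the full
#' model are then refitted with ML for the likelihood-ratio and AIC
#' comparison.
#'
#' @inheritParams gazelmm
#' @param alpha Retention threshold for the term F tests.
#' @return An object of class `gazelmm_reduction`: list with `final`
#'   (REML fit of the reduced model), `trace` (one row per examined step:
#'   term, F, numDF, denDF, p, action), `lrt` (full vs reduced, ML),
#'   `aic_full`, `aic_reduced`, and the two ML fits.
#' @export
backward_reduce <- function(formula, data, participant = "participant_id",
                            var_group = NULL, weights = NULL, alpha = 0.05,
                            nlme_convention = FALSE) {
  response <- deparse(formula[[2]])
  current <- formula
  trace <- list()
  step <- 0L
  repeat {
    fit <- gazelmm(current, data, participant, var_group, weights,
                   method = "REML", nlme_convention = nlme_convention)
    tab <- anova(fit)
    elig <- .gz_eliminable(fit$terms)
    cand <- tab[tab$term %in% elig & tab$`p value` >= alpha, , drop = FALSE]
    if (!nrow(cand) || !length(elig)) {
      for (i in seq_len(nrow(tab)))
        trace[[length(trace) + 1L]] <- data.frame(
          step = step, term = tab$term[i], numDF = tab$numDF[i],
          denDF = tab$denDF[i], F = tab$`F value`[i], p = tab$`p value`[i],
          action = "retained", stringsAsFactors = FALSE)
      break
    }
    worst <- cand$term[which.max(cand$`p value`)]
    i <- which(tab$term == worst)
    trace[[length(trace) + 1L]] <- data.frame(
      step = step, term = worst, numDF = tab$numDF[i], denDF = tab$denDF[i],
      F = tab$`F value`[i], p = tab$`p value`[i], action = "dropped",
      stringsAsFactors = FALSE)
    keep <- setdiff(attr(fit$terms, "term.labels"), worst)
    current <- if (length(keep)) stats::reformulate(keep, response)
               else stats::as.formula(paste(response, "~ 1"))
    step <- step + 1L
  }
  final <- gazelmm(current, data, participant, var_group, weights,
                   method = "REML", nlme_convention = nlme_convention)
  full_ml <- gazelmm(formula, data, participant, var_group, weights,
                     method = "ML", nlme_convention = nlme_convention)
  final_ml <- gazelmm(current, data, participant, var_group, weights,
                      method = "ML", nlme_convention = nlme_convention)
  lr <- if (full_ml$n_fixed > final_ml$n_fixed) lrt(full_ml, final_ml)
        else list(stat = 0, df = 0, p = 1)
  structure(list(final = final, formula_final = current,
                 trace = do.call(rbind, trace), lrt = lr,
                 aic_full = full_ml$aic, aic_reduced = final_ml$aic,
                 full_ml = full_ml, final_ml = final_ml, alpha = alpha),
            class = "gazelmm_reduction")
}

#' @export
print.gazelmm_reduction <- function(x, ...) {
  cat("Backward fixed-effect reduction (alpha =", x$alpha, ")\n")
  cat("final model:", paste(deparse(x$formula_final), collapse = " "), "\n\n")
  print(x$trace, row.names = FALSE)
  cat("\nLRT full vs reduced (ML): stat =", format(x$lrt$stat, digits = 4),
      " df =", x$lrt$df, " p =", format(x$lrt$p, digits = 4), "\n")
  cat("AIC: full", format(x$aic_full, digits = 7),
      " reduced", format(x$aic_reduced, digits = 7), "\n")
  invisible(x)
}
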