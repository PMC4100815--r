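# Mixed-model significance of discriminating parameters, Hochberg
# correction, and the cross-call-type comparison.

#' Hochberg step-up multiple-testing correction
#'
#' Order the m p-values ascending; reject hypotheses 1..k for the largest k
#' with `p(k) <= alpha / (m - k + 1)`. Adjusted p-values come from
#' `stats::p.adjust(method = "hochberg")`; the rejection set equals
#' `adjusted <= alpha`.
#'
#' @param pvalues Numeric p-values in `[0, 1]` (NAs carried through).
#' @param alpha Family-wise error level.
#' @return Data frame in input order: `p`, `p_adj`, `reject`.
#' @export
hochberg_adjust <- function(pvalues, alpha = 0.05) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop_validation("p-values must lie in [0, 1]")
  }
  adj <- rep(NA_real_, length(pvalues))
  adj[ok] <- stats::p.adjust(pvalues[ok], method = "hochberg")
  data.frame(p = pvalues, p_adj = adj,
             reject = !is.na(adj) & adj <= alpha)
}

#' Mixed-model significance of individual distinctiveness per parameter
#'
#' For each parameter (typically those whose DFA structure loadings exceed
#' 0.45 in absolute value), tests whether caller identity explains the
#' parameter after accounting for the non-independence of repeated call
#' segments: a linear mixed model with caller as fixed effect and sequence
#' id as random intercept, compared against the no-caller model by a
#' likelihood-ratio test (ML fits). Without repeated sequences (or on
#' non-convergence) a fixed-effects ANOVA F-test is used instead, with a
#' warning in the non-convergence case. P-values are Hochberg-corrected
#' across the tested set.
#'
#' @param table Feature table with caller and sequence columns.
#' @param parameters Parameters to test.
#' @param caller,sequence Column names.
#' @param alpha Family-wise error level for the Hochberg decisions.
#' @return Data frame: `parameter`, `p`, `p_adj`, `reject`, `method`.
#' @export
lmm_parameter_significance <- function(table, parameters,
                                       caller = "caller_id",
                                       sequence = "sequence_id",
                                       alpha = 0.05) {
  if (!length(parameters)) stop_validation("parameters must be nonempty")
  g <- factor(table[[caller]])
  if (nlevels(g) < 2L) stop_validation("need at least 2 callers")
  has_seq <- sequence %in% names(table) &&
    anyDuplicated(as.character(table[[sequence]])) > 0

  one_par <- function(p) {
    y <- table[[p]]
    ok <- !is.na(y)
    if (sum(ok) < nlevels(g) + 2L || stats::sd(y[ok]) == 0) {
      warning("degenerate fit for ", p, ": p set to missing")
      return(c(p = NA_real_, lmm = NA))
    }
    d <- data.frame(y = y[ok], caller = droplevels(g[ok]))
    if (has_seq) d$seqid <- factor(as.character(table[[sequence]])[ok])
    if (has_seq) {
      pv <- tryCatch({
        m1 <- suppressWarnings(suppressMessages(
          lme4::lmer(y ~ caller + (1 | seqid), data = d, REML = FALSE)))
        m0 <- suppressWarnings(suppressMessages(
          lme4::lmer(y ~ 1 + (1 | seqid), data = d, REML = FALSE)))
        a <- stats::anova(m1, m0)
        c(p = a[["Pr(>Chisq)"]][2L], lmm = TRUE)
      }, error = function(e) NULL)
      if (!is.null(pv)) return(pv)
      warning("mixed model failed for ", p, "; using fixed-effects ANOVA")
    }
    a <- stats::anova(stats::lm(y ~ caller, data = d))
    c(p = a[["Pr(>F)"]][1L], lmm = FALSE)
  }

  res <- vapply(parameters, one_par, numeric(2))
  hb <- hochberg_adjust(res["p", ], alpha = alpha)
  data.frame(parameter = parameters,
             p = hb$p, p_adj = hb$p_adj, reject = hb$reject,
             method = ifelse(is.na(res["lmm", ]), NA_character_,
                             ifelse(res["lmm", ] == 1, "lmm", "anova")),
             row.names = NULL)
}

#' Compare individual distinctiveness across call types
#'
#' Tests whether cross-validated correct-assignment proportions differ among
#' call types. Proportions are arcsine-square-root transformed
#' (`y = asin(sqrt(p))`); a linear mixed model with call type as fixed
#' factor and caller identity and the number of calls per cell as random
#' intercepts supplies the F-test of the call-type factor (Satterthwaite
#' denominator df). When the mixed model cannot be fit, a fixed-effects
#' ANOVA on call type is used with a warning; a constant response returns
#' F = 0, p = 1.
#'
#' @param accuracy Data frame with columns `caller_id`, `call_type`,
#'   `proportion` (correct-assignment proportion in `[0, 1]`) and `n_calls`.
#' @return List with `F`, `df1`, `df2`, `p`, `method`.
#' @export
compare_call_types <- function(accuracy) {
  req <- c("caller_id", "call_type", "proportion", "n_calls")
  missing_cols <- setdiff(req, names(accuracy))
  if (length(missing_cols)) {
    stop_validation("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (length(unique(accuracy$call_type)) < 2L) {
    stop_validation("need at least 2 call types")
  }
  if (any(accuracy$proportion < 0 | accuracy$proportion > 1)) {
    stop_validation("proportions must lie in [0, 1]")
  }
  d <- data.frame(y = asin(sqrt(accuracy$proportion)),
                  call_type = factor(accuracy$call_type),
                  caller = factor(accuracy$caller_id),
                  ncf = factor(accuracy$n_calls))
  k <- nlevels(d$call_type)
  if (stats::sd(d$y) == 0) {
    return(list(F = 0, df1 = k - 1L, df2 = nrow(d) - k, p = 1,
                method = "constant"))
  }
  res <- tryCatch({
    m <- suppressWarnings(suppressMessages(
      lmerTest::lmer(y ~ call_type + (1 | caller) + (1 | ncf), data = d)))
    a <- stats::anova(m)
    list(F = a["call_type", "F value"],
         df1 = a["call_type", "NumDF"],
         df2 = a["call_type", "DenDF"],
         p = a["call_type", "Pr(>F)"],
         method = "lmm")
  }, error = function(e) NULL)
  if (is.null(res)) {
    warning("mixed model failed; using fixed-effects ANOVA on call type")
    a <- stats::anova(stats::lm(y ~ call_type, data = d))
    res <- list(F = a[["F value"]][1L], df1 = a[["Df"]][1L],
                df2 = a[["Df"]][2L], p = a[["Pr(>F)"]][1L],
                method = "anova")
  }
  res
}
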