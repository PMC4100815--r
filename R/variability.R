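#' Coefficient of variation
#'
#' `100 * SD / MEAN`, with the sample standard deviation (n - 1 denominator).
#'
#' @param values Numeric vector with at least two values.
#' @return CV as a percentage; `NA` when the mean is zero (undefined).
#' @export
cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop_validation("cv needs at least 2 values")
  m <- mean(values)
  if (m == 0) return(NA_real_)
  100 * stats::sd(values) / m
}

#' Variability and identity-coding summary for one call type
#'
#' For each acoustic parameter: the inter-individual mean and SD over the
#' pooled calls of the type, the inter-individual CV
#' (`CV_inter = 100 * SD_inter / MEAN_inter`), the intra-individual CV
#' (unweighted mean of per-caller CVs), and the potential for identity
#' coding `PIC = CV_inter / CV_intra`. A PIC above 1 means between-caller
#' variation exceeds within-caller variation, i.e. the parameter could
#' support individual recognition. Per-parameter CVs are then averaged over
#' all parameters present, giving `CV_inter_mean`, `CV_intra_mean` and the
#' overall `PIC = CV_inter_mean / CV_intra_mean` of the call type.
#'
#' @param table Feature table: one row per call with a `caller_id` column
#'   and the parameter columns.
#' @param call_type Optional call type to subset on (requires a `call_type`
#'   column); `NULL` uses all rows.
#' @param parameters Parameter columns to summarise.
#' @return A list of class `variability_summary`: `per_parameter` data frame
#'   (`parameter`, `mean_inter`, `sd_inter`, `cv_inter`, `cv_intra`, `pic`),
#'   and `overall` one-row data frame (`call_type`, `cv_inter_mean`,
#'   `cv_intra_mean`, `overall_pic`, `n_calls`, `n_callers`).
#' @export
variability_summary <- function(table, call_type = NULL,
                                parameters = intersect(feature_names(), names(table))) {
  if (!is.null(call_type)) {
    table <- table[table$call_type == call_type, , drop = FALSE]
  }
  if (!length(parameters)) stop_validation("no parameter columns found")
  n_by_caller <- table(table$caller_id)
  small <- names(n_by_caller)[n_by_caller < 2L]
  if (length(small)) {
    warning("excluding caller(s) with < 2 calls: ", paste(small, collapse = ", "))
    table <- table[!table$caller_id %in% small, , drop = FALSE]
  }
  callers <- unique(table$caller_id)
  if (length(callers) < 2L) {
    stop_validation("need at least 2 callers with >= 2 calls each")
  }

  per_par <- lapply(parameters, function(p) {
    x <- table[[p]]
    ok <- !is.na(x)
    pooled <- x[ok]
    caller_cvs <- vapply(callers, function(cl) {
      xi <- x[ok & table$caller_id == cl]
      if (length(xi) < 2L) NA_real_ else cv(xi)
    }, numeric(1))
    cv_inter <- if (length(pooled) >= 2L) cv(pooled) else NA_real_
    cv_intra <- if (all(is.na(caller_cvs))) NA_real_ else mean(caller_cvs, na.rm = TRUE)
    data.frame(parameter = p,
               mean_inter = mean(pooled),
               sd_inter = stats::sd(pooled),
               cv_inter = cv_inter,
               cv_intra = cv_intra,
               pic = if (!is.na(cv_intra) && cv_intra > 0) cv_inter / cv_intra else NA_real_)
  })
  per_par <- do.call(rbind, per_par)

  cv_inter_mean <- mean(per_par$cv_inter, na.rm = TRUE)
  cv_intra_mean <- mean(per_par$cv_intra, na.rm = TRUE)
  overall <- data.frame(
    call_type = call_type %||% NA_character_,
    cv_inter_mean = cv_inter_mean,
    cv_intra_mean = cv_intra_mean,
    overall_pic = cv_inter_mean / cv_intra_mean,
    n_calls = nrow(table),
    n_callers = length(callers)
  )
  structure(list(per_parameter = per_par, overall = overall),
            class = "variability_summary")
}

#' @export
print.variability_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "Variability summary%s: %d calls, %d callers\n  CV_inter_mean %.1f%%  CV_intra_mean %.1f%%  overall PIC %.3f\n",
    if (is.na(o$call_type)) "" else paste0(" [", o$call_type, "]"),
    o$n_calls, o$n_callers, o$cv_inter_mean, o$cv_intra_mean, o$overall_pic))
  print(x$per_parameter, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Parameter-by-call-type matrix of a variability statistic
#'
#' Assembles per-call-type summaries into the parameter x call-type matrix
#' used for the Friedman comparisons across call types.
#'
#' @param summaries Named list of [variability_summary()] objects (names =
#'   call types).
#' @param what One of `"cv_intra"`, `"cv_inter"`, `"pic"`.
#' @return Numeric matrix, rows = parameters, columns = call types.
#' @export
cv_matrix <- function(summaries, what = c("cv_intra", "cv_inter", "pic")) {
  what <- match.arg(what)
  cols <- lapply(summaries, function(s) {
    stats::setNames(s$per_parameter[[what]], s$per_parameter$parameter)
  })
  pars <- Reduce(intersect, lapply(cols, names))
  do.call(cbind, lapply(cols, function(v) v[pars]))
}

#' Friedman rank test across call types
#'
#' Nonparametric comparison of a statistic (e.g. per-parameter CVs or PIC)
#' across call types, with acoustic parameters as blocks. Uses mid-ranks for
#' ties and the chi-squared approximation (`stats::friedman.test`).
#'
#' @param m Numeric matrix, blocks (rows) x treatments (columns), no
#'   missing cells, at least 2 x 2.
#' @return List with `chi2`, `df`, `p`.
#' @export
friedman_test <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop_validation("friedman_test: missing cells not allowed")
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop_validation("friedman_test needs at least 2 blocks and 2 treatments")
  }
  res <- stats::friedman.test(m)
  chi2 <- unname(res$statistic)
  p <- res$p.value
  if (!is.finite(chi2)) {
    # complete within-block ties: no rank variation at all
    chi2 <- 0
    p <- 1
  }
  list(chi2 = chi2, df = unname(res$parameter), p = p)
}
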