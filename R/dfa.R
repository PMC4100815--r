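# Discriminant-function analysis of caller identity.

# Within-group (W) and total (T) scatter matrices for the given columns.
scatter_matrices <- function(X, g) {
  Tc <- crossprod(scale(X, center = TRUE, scale = FALSE))
  W <- Reduce(`+`, lapply(split(seq_len(nrow(X)), g), function(i) {
    crossprod(scale(X[i, , drop = FALSE], center = TRUE, scale = FALSE))
  }))
  list(W = W, T = Tc)
}

# Wilks' Lambda det(W)/det(T) for a column subset; NA when W (or T) is
# numerically singular.
wilks_lambda <- function(W, T_, cols) {
  Ws <- W[cols, cols, drop = FALSE]
  Ts <- T_[cols, cols, drop = FALSE]
  dW <- det(Ws)
  dT <- det(Ts)
  if (!is.finite(dW) || !is.finite(dT) || dT <= 0 || dW <= 0) return(NA_real_)
  lam <- dW / dT
  if (lam > 1) lam <- 1
  lam
}

prep_dfa_table <- function(table, parameters, caller) {
  if (!caller %in% names(table)) stop_validation("missing column: ", caller)
  parameters <- intersect(parameters, names(table))
  if (!length(parameters)) stop_validation("no parameter columns present")
  # parameters undefined for the whole type are dropped; remaining missing
  # values are removed listwise
  all_na <- parameters[vapply(parameters, function(p) all(is.na(table[[p]])),
                              logical(1))]
  if (length(all_na)) {
    warning("dropping all-missing parameter(s): ", paste(all_na, collapse = ", "))
    parameters <- setdiff(parameters, all_na)
  }
  keep <- stats::complete.cases(table[parameters])
  if (!all(keep)) {
    warning("listwise deletion of ", sum(!keep), " incomplete row(s)")
    table <- table[keep, , drop = FALSE]
  }
  g <- factor(table[[caller]], levels = sort(unique(as.character(table[[caller]]))))
  if (nlevels(g) < 2L) stop_validation("need at least 2 callers")
  if (any(table(g) < 2L)) {
    stop_validation("every caller needs at least 2 complete calls")
  }
  const <- parameters[vapply(parameters, function(p) {
    stats::sd(table[[p]]) == 0
  }, logical(1))]
  if (length(const)) {
    warning("dropping constant parameter(s): ", paste(const, collapse = ", "))
    parameters <- setdiff(parameters, const)
  }
  if (!length(parameters)) stop_validation("no usable parameters")
  list(table = table, parameters = parameters, g = g,
       X = as.matrix(table[parameters]))
}

# Forward-stepwise selection minimizing Wilks' Lambda with F-to-enter /
# F-to-remove thresholds (SPSS-style partial F statistics).
stepwise_select <- function(X, g, f_in, f_out) {
  n <- nrow(X)
  ng <- nlevels(g)
  sm <- scatter_matrices(X, g)
  sel <- integer(0)
  lambda_sel <- 1
  repeat {
    changed <- FALSE
    cand <- setdiff(seq_len(ncol(X)), sel)
    if (length(cand)) {
      p <- length(sel)
      f_enter <- vapply(cand, function(j) {
        lam_new <- wilks_lambda(sm$W, sm$T, c(sel, j))
        if (is.na(lam_new) || lam_new <= 0) return(NA_real_)
        (lambda_sel / lam_new - 1) * (n - ng - p) / (ng - 1)
      }, numeric(1))
      if (any(!is.na(f_enter)) && max(f_enter, na.rm = TRUE) >= f_in) {
        j <- cand[which.max(f_enter)]
        sel <- c(sel, j)
        lambda_sel <- wilks_lambda(sm$W, sm$T, sel)
        changed <- TRUE
      }
    }
    if (length(sel) > 1L) {
      p <- length(sel)
      f_remove <- vapply(sel, function(j) {
        lam_without <- wilks_lambda(sm$W, sm$T, setdiff(sel, j))
        if (is.na(lam_without)) return(Inf)
        (lam_without / lambda_sel - 1) * (n - ng - p + 1) / (ng - 1)
      }, numeric(1))
      if (min(f_remove) < f_out) {
        j <- sel[which.min(f_remove)]
        sel <- setdiff(sel, j)
        lambda_sel <- wilks_lambda(sm$W, sm$T, sel)
        changed <- TRUE
      }
    }
    if (!changed || length(sel) >= min(n - ng - 1L, ncol(X))) break
  }
  list(sel = sel, lambda = lambda_sel, W = sm$W, T = sm$T)
}

#' Stepwise discriminant function analysis of caller identity
#'
#' Forward-stepwise parameter selection minimizing Wilks' Lambda (partial-F
#' entry/removal thresholds, SPSS defaults 3.84 / 2.71), canonical
#' discriminant functions on the selected parameters, structure loadings
#' (pooled within-group correlations between parameters and discriminant
#' scores), the chi-squared test of Wilks' Lambda, and classification of
#' calls to callers with equal priors: resubstitution and leave-one-out
#' (U-method) correct-classification rates per caller and overall.
#'
#' @param table Feature table: one row per call, a caller column plus
#'   parameter columns.
#' @param parameters Candidate parameter columns (default: the twenty
#'   acoustic parameters present in `table`).
#' @param caller Name of the caller-identity column.
#' @param f_in,f_out F-to-enter and F-to-remove thresholds.
#' @param call_type Optional label stored in the result.
#' @return An object of class `dfa_result`; see Details.
#' @details The result contains `selected_parameters` (in entry order),
#'   `n_functions`, `loadings`, `wilks_lambda`, `chi2`, `df`, `p`,
#'   `scores` (call x function discriminant scores), `resubstitution` and
#'   `leave_one_out` (each: `per_caller` data frame and `overall` percent),
#'   `chance` (= 100 / number of callers, equal priors), `callers`, `n` and
#'   `n_per_caller`.
#' @export
stepwise_dfa <- function(table, parameters = intersect(feature_names(), names(table)),
                         caller = "caller_id", f_in = 3.84, f_out = 2.71,
                         call_type = NULL) {
  prep <- prep_dfa_table(table, parameters, caller)
  X <- prep$X
  g <- prep$g
  n <- nrow(X)
  ng <- nlevels(g)

  st <- stepwise_select(X, g, f_in, f_out)
  if (!length(st$sel)) stop("no discriminating parameters")
  sel_names <- prep$parameters[st$sel]
  Xs <- X[, st$sel, drop = FALSE]

  Wsel <- st$W[st$sel, st$sel, drop = FALSE]
  Bsel <- st$T[st$sel, st$sel, drop = FALSE] - Wsel
  eig <- eigen(solve(Wsel, Bsel))
  ev <- Re(eig$values)
  n_fun <- min(ng - 1L, length(st$sel))
  V <- Re(eig$vectors[, seq_len(n_fun), drop = FALSE])
  # scale so discriminant scores have unit pooled within-group variance
  wvar <- diag(t(V) %*% Wsel %*% V) / (n - ng)
  V <- sweep(V, 2, sqrt(wvar), "/")
  scores <- scale(Xs, center = TRUE, scale = FALSE) %*% V
  colnames(scores) <- paste0("LD", seq_len(n_fun))

  # pooled within-group correlations (structure loadings)
  center_within <- function(M) {
    do.call(rbind, lapply(split(seq_len(nrow(M)), g), function(i) {
      scale(M[i, , drop = FALSE], center = TRUE, scale = FALSE)
    }))
  }
  Xw <- center_within(Xs)
  Sw <- center_within(scores)
  loadings <- stats::cor(Xw, Sw)
  rownames(loadings) <- sel_names

  lambda <- st$lambda
  p_sel <- length(st$sel)
  chi2 <- -(n - 1 - (p_sel + ng) / 2) * log(lambda)
  df <- p_sel * (ng - 1)

  cls <- MASS::lda(Xs, grouping = g, prior = rep(1 / ng, ng))
  pred <- stats::predict(cls)$class
  resub <- classification_rates(pred, g)
  loo <- loo_classification(prep$table, sel_names, caller = caller)

  structure(list(
    call_type = call_type,
    callers = levels(g),
    n = n,
    n_per_caller = as.integer(table(g)),
    selected_parameters = sel_names,
    n_functions = n_fun,
    eigenvalues = ev[seq_len(n_fun)],
    loadings = loadings,
    wilks_lambda = lambda,
    chi2 = chi2,
    df = df,
    p = stats::pchisq(chi2, df, lower.tail = FALSE),
    scores = scores,
    groups = g,
    resubstitution = resub,
    leave_one_out = loo,
    chance = 100 / ng
  ), class = "dfa_result")
}

classification_rates <- function(pred, g) {
  per <- vapply(levels(g), function(l) {
    100 * mean(pred[g == l] == l)
  }, numeric(1))
  list(per_caller = data.frame(caller = levels(g),
                               n = as.integer(table(g)),
                               pct = unname(per)),
       overall = 100 * mean(pred == g))
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("DFA%s: %d calls, %d callers (%s)\n",
              if (is.null(x$call_type)) "" else paste0(" [", x$call_type, "]"),
              x$n, length(x$callers), paste(x$callers, collapse = ", ")))
  cat(sprintf("  selected: %s\n", paste(x$selected_parameters, collapse = ", ")))
  cat(sprintf("  Wilks lambda %.3f, chi2 %.2f, df %d, p %.3g; %d function(s)\n",
              x$wilks_lambda, x$chi2, x$df, x$p, x$n_functions))
  cat(sprintf("  correct: %.1f%% (resubstitution), %.1f%% (leave-one-out), chance %.1f%%\n",
              x$resubstitution$overall, x$leave_one_out$overall, x$chance))
  invisible(x)
}

#' Leave-one-out (U-method) cross-validated classification
#'
#' Each call is assigned to a caller by a linear discriminant classifier
#' (equal priors) refit on all remaining calls, with the parameter set fixed
#' beforehand. Folds that would leave a caller with fewer than two calls are
#' skipped with a warning and excluded from the rates. Classification ties
#' resolve toward the lexicographically smallest caller.
#'
#' @param table Feature table with a caller column and the parameter columns.
#' @param parameters Parameter columns to classify on (fixed, no selection).
#' @param caller Name of the caller column.
#' @return List with `per_caller` (data frame: caller, n, n_classified,
#'   pct), `overall` percent correct, and `n_skipped` folds.
#' @export
loo_classification <- function(table, parameters, caller = "caller_id") {
  keep <- stats::complete.cases(table[parameters])
  table <- table[keep, , drop = FALSE]
  g <- factor(table[[caller]], levels = sort(unique(as.character(table[[caller]]))))
  if (nlevels(g) < 2L) stop_validation("need at least 2 callers")
  X <- as.matrix(table[parameters])
  n <- nrow(X)
  ng <- nlevels(g)
  counts <- table(g)
  pred <- factor(rep(NA_character_, n), levels = levels(g))
  skipped <- 0L
  for (i in seq_len(n)) {
    if (counts[g[i]] - 1L < 2L) {
      skipped <- skipped + 1L
      next
    }
    fit <- MASS::lda(X[-i, , drop = FALSE], grouping = g[-i],
                     prior = rep(1 / ng, ng))
    pred[i] <- stats::predict(fit, X[i, , drop = FALSE])$class
  }
  if (skipped) {
    warning(skipped, " fold(s) skipped (caller would drop below 2 calls)")
  }
  done <- !is.na(pred)
  per <- do.call(rbind, lapply(levels(g), function(l) {
    sel <- g == l & done
    data.frame(caller = l, n = sum(g == l), n_classified = sum(sel),
               pct = if (any(sel)) 100 * mean(pred[sel] == l) else NA_real_)
  }))
  list(per_caller = per,
       overall = 100 * mean(pred[done] == g[done]),
       n_skipped = skipped)
}
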