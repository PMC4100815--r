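# Permutation test for DFA classification rates (pDFA).

lda_fit_rate <- function(X, g, prior) {
  fit <- suppressWarnings(MASS::lda(X, grouping = g, prior = prior))
  100 * mean(stats::predict(fit)$class == g)
}

lda_cv_rate <- function(X, g, prior) {
  fit <- suppressWarnings(MASS::lda(X, grouping = g, prior = prior, CV = TRUE))
  cl <- fit$class
  ok <- !is.na(cl)
  100 * mean(cl[ok] == g[ok])
}

# Permute caller labels; when block ids are supplied (repeated call
# segments of one sequence), whole blocks keep their calls together and the
# block-to-caller assignment is shuffled instead.
permute_labels <- function(g, blocks = NULL) {
  if (is.null(blocks)) return(sample(g))
  ub <- unique(blocks)
  block_caller <- g[match(ub, blocks)]
  perm <- sample(block_caller)
  perm[match(blocks, ub)]
}

#' Permuted discriminant function analysis (pDFA)
#'
#' Attaches permutation p-values to observed DFA correct-classification
#' rates, for both the fitting (resubstitution) DFA (`P1`) and the
#' cross-validated, leave-one-out DFA (`P2`). For balanced designs the
#' caller labels of the full table are permuted. For unbalanced designs,
#' each of `n_selections` random balanced subsets (the minimum per-caller
#' count drawn from every caller) yields rates that are averaged into the
#' observed value, and each null iteration draws a fresh balanced subset
#' before permuting its labels. When sequences of repeated call segments
#' exist, labels are permuted at the sequence level so that non-independent
#' segments stay together. The p-value estimator is
#' `(count(null >= observed) + 1) / (n_permutations + 1)`.
#'
#' @param table Feature table with caller (and optionally sequence) columns.
#' @param parameters Parameter columns used by the classifier (fixed set —
#'   typically the stepwise-selected parameters).
#' @param caller Caller-identity column name.
#' @param sequence Sequence-id column name (ignored when absent or when no
#'   sequence repeats).
#' @param n_selections Balanced random subsets for unbalanced designs.
#' @param n_permutations Label permutations for the null distribution.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param cv Also compute the cross-validated rate and `P2` (default TRUE).
#' @return Object of class `pdfa_result`: observed rates, null rate
#'   distributions, `P1`, `P2`, `n_selections`, `n_permutations`,
#'   `balanced`, `seed`.
#' @export
pdfa <- function(table, parameters, caller = "caller_id",
                 sequence = "sequence_id", n_selections = 100,
                 n_permutations = 1000, seed = 1, cv = TRUE) {
  parameters <- intersect(parameters, names(table))
  if (!length(parameters)) stop_validation("no parameter columns present")
  keep <- stats::complete.cases(table[parameters])
  table <- table[keep, , drop = FALSE]
  g <- factor(table[[caller]], levels = sort(unique(as.character(table[[caller]]))))
  ng <- nlevels(g)
  if (ng < 2L) stop_validation("need at least 2 callers")
  counts <- table(g)
  n_min <- min(counts)
  if (n_min < 2L) stop_validation("minimum per-caller sample size is below 2")
  if (n_permutations < 100) warning("n_permutations < 100: p-values are coarse")
  X <- as.matrix(table[parameters])
  prior <- rep(1 / ng, ng)

  blocks <- NULL
  if (sequence %in% names(table)) {
    b <- as.character(table[[sequence]])
    if (anyDuplicated(b)) blocks <- b
  }
  balanced <- all(counts == n_min)

  rates <- function(Xs, gs) {
    c(fit = lda_fit_rate(Xs, gs, prior),
      cvr = if (cv) lda_cv_rate(Xs, gs, prior) else NA_real_)
  }
  draw_subset <- function() {
    unlist(lapply(levels(g), function(l) {
      i <- which(g == l)
      if (length(i) == n_min) i else sample(i, n_min)
    }), use.names = FALSE)
  }

  with_seed(seed, {
    if (balanced) {
      obs <- rates(X, g)
      null_mat <- vapply(seq_len(n_permutations), function(k) {
        gp <- factor(permute_labels(as.character(g), blocks), levels = levels(g))
        rates(X, gp)
      }, numeric(2))
    } else {
      obs_mat <- vapply(seq_len(n_selections), function(k) {
        i <- draw_subset()
        rates(X[i, , drop = FALSE], droplevels(g[i]))
      }, numeric(2))
      obs <- rowMeans(obs_mat)
      null_mat <- vapply(seq_len(n_permutations), function(k) {
        i <- draw_subset()
        gi <- as.character(g[i])
        bi <- if (is.null(blocks)) NULL else blocks[i]
        gp <- factor(permute_labels(gi, bi), levels = levels(g))
        rates(X[i, , drop = FALSE], gp)
      }, numeric(2))
    }
    p_of <- function(obs_r, null_r) (sum(null_r >= obs_r) + 1) / (n_permutations + 1)
    structure(list(
      observed_fit = unname(obs["fit"]),
      observed_cv = unname(obs["cvr"]),
      null_fit = unname(null_mat["fit", ]),
      null_cv = if (cv) unname(null_mat["cvr", ]) else NULL,
      P1 = p_of(obs["fit"], null_mat["fit", ]),
      P2 = if (cv) p_of(obs["cvr"], null_mat["cvr", ]) else NA_real_,
      n_selections = if (balanced) NA_integer_ else as.integer(n_selections),
      n_permutations = as.integer(n_permutations),
      balanced = balanced,
      n_per_caller = as.integer(counts),
      callers = levels(g),
      parameters = parameters,
      seed = seed
    ), class = "pdfa_result")
  })
}

#' @export
print.pdfa_result <- function(x, ...) {
  cat(sprintf("pDFA: %d callers, %s design, %d permutations%s (seed %d)\n",
              length(x$callers), if (x$balanced) "balanced" else "unbalanced",
              x$n_permutations,
              if (x$balanced) "" else sprintf(", %d balanced selections", x$n_selections),
              x$seed))
  cat(sprintf("  fitting DFA %.1f%%  P1 = %.4g\n", x$observed_fit, x$P1))
  if (!is.na(x$observed_cv)) {
    cat(sprintf("  cross-validated DFA %.1f%%  P2 = %.4g\n", x$observed_cv, x$P2))
  }
  invisible(x)
}
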