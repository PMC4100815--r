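test_that("stepwise selection finds the single informative parameter", {
  tab <- planted_table(n_per = 15, n_callers = 2, shift = 10,
                       informative = "duration")
  d <- stepwise_dfa(tab)
  expect_identical(d$selected_parameters, "duration")
  expect_equal(d$resubstitution$overall, 100)
  expect_equal(d$chance, 50)
  expect_equal(d$n_functions, 1)
  expect_equal(d$df, 1)
})

test_that("DFA preconditions are enforced", {
  tab <- planted_table(n_per = 10, n_callers = 1)
  expect_error(stepwise_dfa(tab), "at least 2 callers")
  # pure noise, no parameter passes entry
  set.seed(50)
  noise <- data.frame(caller_id = rep(c("A", "B"), each = 10),
                      duration = rnorm(20), pfmean = rnorm(20))
  expect_error(stepwise_dfa(noise), "no discriminating parameters")
})

test_that("Wilks lambda agrees with an independent eigen-decomposition", {
  tab <- synth_feature_table(signature_spec(
    calls_per_caller = c(20, 16, 12), effect_size = 2, seed = 8))
  d <- stepwise_dfa(tab)
  X <- as.matrix(tab[d$selected_parameters])
  g <- factor(tab$caller_id)
  Tm <- crossprod(scale(X, center = TRUE, scale = FALSE))
  W <- Reduce(`+`, lapply(split(seq_len(nrow(X)), g), function(i) {
    crossprod(scale(X[i, , drop = FALSE], center = TRUE, scale = FALSE))
  }))
  ev <- Re(eigen(solve(W) %*% (Tm - W))$values)
  lambda_oracle <- prod(1 / (1 + ev))
  expect_equal(d$wilks_lambda, lambda_oracle, tolerance = 1e-10)
  expect_gt(d$wilks_lambda, 0)
  expect_lte(d$wilks_lambda, 1)
  n <- nrow(X); p <- length(d$selected_parameters); ng <- nlevels(g)
  expect_equal(d$chi2, -(n - 1 - (p + ng) / 2) * log(lambda_oracle),
               tolerance = 1e-10)
})

test_that("leave-one-out matches an explicit refit-per-sample loop", {
  set.seed(60)
  tab <- data.frame(caller_id = rep(c("A", "B", "C", "D"), each = 5),
                    duration = rnorm(20) + rep(c(0, 1.5, 3, 4.5), each = 5),
                    pfmean = rnorm(20) + rep(c(0, 2, 0, 2), each = 5))
  res <- loo_classification(tab, c("duration", "pfmean"))
  X <- as.matrix(tab[c("duration", "pfmean")])
  oracle <- vapply(seq_len(20), function(i) {
    hand_ldc_predict(X[-i, ], tab$caller_id[-i], X[i, ])
  }, character(1))
  expect_equal(res$overall, 100 * mean(oracle == tab$caller_id))
  per_oracle <- vapply(sort(unique(tab$caller_id)), function(l) {
    100 * mean(oracle[tab$caller_id == l] == l)
  }, numeric(1))
  expect_equal(res$per_caller$pct, unname(per_oracle))
})

test_that("identically distributed callers classify at chance", {
  # leave-one-out predictions within one table are correlated, so a single
  # table varies well beyond the binomial interval; average over tables
  set.seed(70)
  accs <- vapply(1:15, function(s) {
    tab <- data.frame(caller_id = rep(c("A", "B", "C"), each = 50),
                      duration = rnorm(150), pfmean = rnorm(150))
    loo_classification(tab, c("duration", "pfmean"))$overall
  }, numeric(1))
  expect_lt(abs(mean(accs) - 100 / 3), 4)
})

test_that("folds that would empty a caller are skipped with a warning", {
  set.seed(71)
  tab <- data.frame(caller_id = c(rep("A", 6), "B", "B"),
                    duration = c(rnorm(6), 8, 9))
  expect_warning(res <- loo_classification(tab, "duration"), "skipped")
  expect_equal(res$n_skipped, 2)
  expect_equal(res$per_caller$n_classified[res$per_caller$caller == "B"], 0)
})

test_that("resubstitution is optimistic relative to leave-one-out on average", {
  set.seed(80)
  diffs <- vapply(1:100, function(i) {
    tab <- data.frame(caller_id = rep(c("A", "B", "C"), each = 8),
                      duration = rnorm(24) + rep(rnorm(3, sd = 0.8), each = 8),
                      pfmean = rnorm(24) + rep(rnorm(3, sd = 0.8), each = 8))
    g <- factor(tab$caller_id)
    fit <- MASS::lda(tab[c("duration", "pfmean")], grouping = g,
                     prior = rep(1 / 3, 3))
    resub <- 100 * mean(predict(fit)$class == g)
    loo <- loo_classification(tab, c("duration", "pfmean"))$overall
    resub - loo
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})

test_that("classification is invariant to affine rescaling of a parameter", {
  tab <- synth_feature_table(signature_spec(calls_per_caller = 18,
                                            effect_size = 2, seed = 12))
  d1 <- stepwise_dfa(tab)
  tab2 <- tab
  tab2$pfmean <- 1000 * tab2$pfmean + 5
  tab2$diffreq <- -2 * tab2$diffreq
  d2 <- stepwise_dfa(tab2)
  expect_identical(d2$selected_parameters, d1$selected_parameters)
  expect_equal(d2$wilks_lambda, d1$wilks_lambda, tolerance = 1e-8)
  expect_equal(d2$resubstitution$overall, d1$resubstitution$overall)
  expect_equal(d2$leave_one_out$overall, d1$leave_one_out$overall)
})

test_that("planted signature parameters are recovered by the stepwise search", {
  planted <- c("pfmean", "duration")
  hits <- vapply(1:50, function(i) {
    tab <- synth_feature_table(signature_spec(
      calls_per_caller = 20, effect_size = 3,
      signature_parameters = planted, seed = 1000 + i))
    d <- tryCatch(suppressWarnings(stepwise_dfa(tab)), error = function(e) NULL)
    !is.null(d) && all(planted %in% d$selected_parameters)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("structure loadings are pooled within-group correlations", {
  tab <- synth_feature_table(signature_spec(calls_per_caller = 25,
                                            effect_size = 2, seed = 3))
  d <- stepwise_dfa(tab)
  expect_equal(rownames(d$loadings), d$selected_parameters)
  expect_true(all(abs(d$loadings) <= 1 + 1e-12))
  expect_equal(ncol(d$loadings), d$n_functions)
})
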