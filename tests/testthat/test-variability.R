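test_that("cv matches hand computations", {
  expect_equal(cv(c(5, 5, 5)), 0)
  expect_equal(cv(c(1, 2, 3)), 50)
  expect_equal(cv(c(10, 20)), 47.14, tolerance = 1e-4)
  expect_error(cv(7), "at least 2")
  expect_true(is.na(cv(c(-1, 1))))
})

test_that("cv is scale invariant", {
  set.seed(2)
  x <- rlnorm(30)
  for (c_scale in c(0.01, 3, 1000)) {
    expect_equal(cv(c_scale * x), cv(x), tolerance = 1e-12)
  }
})

test_that("inter/intra CV and PIC follow their definitions", {
  tab <- data.frame(caller_id = rep(c("A", "B"), each = 3),
                    duration = c(1, 2, 3, 4, 5, 6))
  s <- variability_summary(tab, parameters = "duration")
  pp <- s$per_parameter
  expect_equal(pp$mean_inter, 3.5)
  expect_equal(pp$sd_inter, sd(1:6))
  expect_equal(pp$cv_inter, 53.45, tolerance = 1e-3)
  expect_equal(pp$cv_intra, 35)  # mean of 50% and 20%
  expect_equal(pp$pic, 1.527, tolerance = 1e-3)
  expect_equal(s$overall$overall_pic, pp$cv_inter / pp$cv_intra)

  # identical per-caller multisets: pooled variation below within-caller
  tab2 <- data.frame(caller_id = rep(c("A", "B"), each = 3),
                     duration = c(1, 2, 3, 1, 2, 3))
  s2 <- variability_summary(tab2, parameters = "duration")
  expect_equal(s2$per_parameter$pic, 0.894, tolerance = 1e-3)
})

test_that("small callers are excluded and too-few callers error", {
  tab <- data.frame(caller_id = c("A", "A", "A", "B"),
                    duration = c(1, 2, 3, 9))
  expect_warning(expect_error(variability_summary(tab, parameters = "duration"),
                              "at least 2 callers"),
                 "excluding")
})

test_that("relabelling a pooled sample drives PIC to 1", {
  set.seed(77)
  tab <- data.frame(caller_id = sample(rep(c("A", "B", "C"), each = 200)),
                    duration = rlnorm(600, meanlog = 2, sdlog = 0.4))
  s <- variability_summary(tab, parameters = "duration")
  expect_lt(abs(s$per_parameter$pic - 1), 0.1)
})

test_that("Friedman test matches closed-form rank arithmetic", {
  # identical values across treatments in every block
  r0 <- friedman_test(matrix(5, 4, 3))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)

  m <- matrix(c(1, 2, 3), 3, 3, byrow = TRUE)
  r <- friedman_test(m)
  expect_equal(r$chi2, 6)
  expect_equal(r$df, 2)

  # closed form 12/(nk(k+1)) * sum(Rj^2) - 3n(k+1) on tie-free matrices
  set.seed(10)
  for (i in 1:20) {
    m2 <- matrix(sample(100, 9), 3, 3)
    Rj <- colSums(t(apply(m2, 1, rank)))
    chi_closed <- 12 / (3 * 3 * 4) * sum(Rj^2) - 3 * 3 * 4
    expect_equal(friedman_test(m2)$chi2, chi_closed, tolerance = 1e-10)
  }

  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
  expect_error(friedman_test(matrix(1, 1, 3)), "at least 2")
})

test_that("Friedman is invariant to within-block monotone transforms", {
  set.seed(4)
  m <- matrix(runif(40, 1, 5), 8, 5)
  transforms <- list(function(x) exp(x), function(x) x^3,
                     function(x) log(x), function(x) 10 * x - 2)
  m2 <- t(vapply(seq_len(nrow(m)), function(i) {
    transforms[[1 + (i %% length(transforms))]](m[i, ])
  }, numeric(ncol(m))))
  expect_equal(friedman_test(m2)$chi2, friedman_test(m)$chi2, tolerance = 1e-10)
})

test_that("cv_matrix assembles per-type summaries by parameter", {
  tab <- synth_feature_table(signature_spec(
    call_types = c("hum", "scream"), calls_per_caller = 12, seed = 5))
  sums <- lapply(setNames(c("hum", "scream"), c("hum", "scream")), function(ct) {
    variability_summary(tab, call_type = ct)
  })
  m <- cv_matrix(sums, "pic")
  expect_equal(dim(m), c(20L, 2L))
  expect_equal(colnames(m), c("hum", "scream"))
  expect_equal(m["duration", "hum"],
               sums$hum$per_parameter$pic[sums$hum$per_parameter$parameter == "duration"])
})
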