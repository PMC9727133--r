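test_that("ROC curve handles perfect separation, no-information and tied data", {
  perfect <- build_roc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(any(perfect$sens == 1 & perfect$spec == 1))
  expect_equal(auc_trapezoid(perfect), 1)

  flat <- build_roc(rep(2, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(auc_trapezoid(flat), 0.5)
  expect_equal(nrow(flat), 2)  # only the trivial operating points

  mixed <- build_roc(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(auc_trapezoid(mixed), 0.75)
  expect_equal(auc_trapezoid(mixed), oracle_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)))

  expect_error(build_roc(c(1, 2), c(TRUE, TRUE)), "degenerate")
  expect_error(build_roc(c(1, NA), c(TRUE, FALSE)), "finite")
})

test_that("trapezoidal AUC and Youden optimum match brute force on 500 tied instances", {
  withr::with_seed(2024, {
    for (i in 1:500) {
      inst <- random_roc_instance()
      curve <- build_roc(inst$scores, inst$labels)
      expect_equal(auc_trapezoid(curve), oracle_auc(inst$scores, inst$labels),
                   tolerance = 1e-12)
      expect_equal(youden_optimal(curve)$youden,
                   oracle_youden(inst$scores, inst$labels),
                   tolerance = 1e-12)
      expect_true(all(diff(curve$sens) <= 1e-12))
      expect_true(all(diff(curve$spec) >= -1e-12))
    }
  })
})

test_that("negating scores maps AUC to its complement", {
  withr::with_seed(5, {
    for (i in 1:20) {
      inst <- random_roc_instance()
      a <- auc_trapezoid(build_roc(inst$scores, inst$labels))
      b <- auc_trapezoid(build_roc(-inst$scores, inst$labels))
      expect_equal(a + b, 1, tolerance = 1e-12)
    }
  })
})

test_that("Youden ties break towards sensitivity then the smaller cutoff", {
  opt <- youden_optimal(build_roc(c(1, 2, 3, 4), c(0, 1, 0, 1)))
  expect_equal(opt$youden, 0.5)
  expect_equal(opt$cutoff, 1)     # ties at c=1 and c=3; sens 1.0 wins
  expect_equal(opt$sens, 1)
  expect_equal(youden_optimal(build_roc(1:4, c(0, 0, 1, 1)))$youden, 1)
})

test_that("Hanley-McNeil interval matches the closed form and is symmetric at 0.5", {
  # exact AUC 0.75 sample with n = 50/50: neg at 1..50; half the pos above
  # all neg, half above 25 of them. Expected interval from Q1 = A/(2-A),
  # Q2 = 2A^2/(1+A) evaluated by hand.
  labels <- c(rep(FALSE, 50), rep(TRUE, 50))
  scores <- c(1:50, rep(100, 25), rep(25.5, 25))
  expect_equal(oracle_auc(scores, labels), 0.75)
  ci <- auc_ci(scores, labels, method = "hanley-mcneil")
  expect_equal(unname(ci), c(0.654, 0.846), tolerance = 1e-3)

  even <- auc_ci(c(1, 2, 1, 2), c(TRUE, FALSE, FALSE, TRUE),
                 method = "hanley-mcneil")
  expect_equal(unname(0.5 - even["low"]), unname(even["high"] - 0.5),
               tolerance = 1e-12)
})

test_that("DeLong and bootstrap intervals agree on a binormal sample", {
  sam <- generate_binormal(100, 100, mu1 = 1, seed = 31)
  d <- auc_ci(sam$score, sam$label, method = "delong")
  b <- auc_ci(sam$score, sam$label, method = "bootstrap", seed = 32)
  expect_lt(abs(diff(d) - diff(b)) / diff(d), 0.2)
  expect_error(auc_ci(sam$score, sam$label, method = "bootstrap"), "seed")
  expect_error(auc_ci(sam$score, sam$label, method = "nope"))
})

test_that("DeLong interval agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  sam <- generate_binormal(150, 120, mu1 = 0.8, seed = 77)
  ours <- evaluate_index(sam$score, sam$label, ci_method = "delong")
  ref <- pROC::roc(sam$label, sam$score, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(c(ours$ci_low, ours$ci_high), ref_ci[c(1, 3)],
               tolerance = 1e-6)
})

test_that("discrimination bands follow the closed-left AUC ranges", {
  expect_equal(discrimination_band(c(0.95, 0.9, 0.83, 0.8, 0.75, 0.7, 0.65,
                                     0.6, 0.58, 0.5)),
               c("excellent", "excellent", "good", "good", "fair", "fair",
                 "poor", "poor", "failed", "failed"))
  expect_warning(below <- discrimination_band(0.4), "chance")
  expect_equal(below, "failed")
  expect_error(discrimination_band(1.2), "auc")
})

test_that("evaluate_index keeps its fields mutually consistent", {
  sam <- generate_binormal(300, 300, mu1 = 1, seed = 12)
  fit <- evaluate_index(sam$score, sam$label)
  expect_equal(fit$youden, fit$sens + fit$spec - 1, tolerance = 1e-12)
  expect_true(fit$ci_low <= fit$auc && fit$auc <= fit$ci_high)
  expect_lt(abs(fit$auc - analytic_auc_binormal(0, 1)),
            3 * sqrt(fit$auc * (1 - fit$auc) / 300))
  td <- tidy(fit)
  expect_equal(nrow(td), 1)
  expect_equal(td$auc, fit$auc)
  expect_equal(glance(fit)$n_pos, 300)

  perfect <- evaluate_index(1:10, rep(c(FALSE, TRUE), each = 5))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$youden, 1)
  expect_equal(perfect$band, "excellent")
})

test_that("roc_table covers strata and flags single-class strata as not estimable", {
  fx <- fixture_cohort()
  ix <- compute_indices(fx)
  fl <- classify_atp3(fx)
  tab <- suppressWarnings(roc_table(ix, fl))  # tiny fixture, ABSI below chance
  expect_equal(nrow(tab), 21)
  expect_setequal(unique(tab$stratum), c("total", "male", "female"))
  expect_true(all(is.finite(tab$auc)))

  only_pos_f <- fl
  only_pos_f$msyn[only_pos_f$sex == "female"] <- TRUE
  tab2 <- roc_table(ix, only_pos_f, strata = "female")
  expect_true(all(tab2$note == "not estimable"))
  expect_true(all(is.na(tab2$auc)))
})

test_that("autoplot returns a ggplot for curves and summaries", {
  sam <- generate_binormal(40, 40, mu1 = 1, seed = 4)
  expect_s3_class(autoplot(build_roc(sam$score, sam$label)), "ggplot")
  expect_s3_class(autoplot(evaluate_index(sam$score, sam$label)), "ggplot")
})
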