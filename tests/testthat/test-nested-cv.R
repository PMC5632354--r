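test_that("fold plans partition subjects evenly with both classes in training", {
  labels <- rep(c("ADHD", "TD"), each = 22)
  plan <- make_fold_plan(labels, k = 10, seed = 1)
  all_idx <- sort(unlist(plan$folds))
  expect_equal(all_idx, 1:44)                       # disjoint union = cohort
  sizes <- lengths(plan$folds)
  expect_lte(max(sizes) - min(sizes), 1)
  for (f in seq_len(10)) {
    train <- unlist(plan$folds[-f])
    expect_setequal(unique(labels[train]), c("ADHD", "TD"))
  }
  # seeded determinism
  expect_identical(plan$folds, make_fold_plan(labels, k = 10, seed = 1)$folds)
})

test_that("fold metrics follow their confusion-table definitions", {
  expect_equal(fold_metrics(c("ADHD", "TD"), c("ADHD", "TD")),
               c(accuracy = 1, sensitivity = 1, specificity = 1))
  expect_equal(fold_metrics(rep("TD", 4), c("ADHD", "ADHD", "TD", "TD")),
               c(accuracy = 0.5, sensitivity = 0, specificity = 1))
  # a fold without positives leaves sensitivity undefined
  m <- fold_metrics(c("TD", "ADHD"), c("TD", "TD"))
  expect_true(is.na(m["sensitivity"]))
  expect_equal(unname(m["specificity"]), 0.5)

  # direct count oracle on a random confusion pattern
  set.seed(31)
  actual <- sample(c("ADHD", "TD"), 40, replace = TRUE, prob = c(0.4, 0.6))
  predicted <- sample(c("ADHD", "TD"), 40, replace = TRUE)
  tp <- sum(predicted == "ADHD" & actual == "ADHD")
  fn <- sum(predicted == "TD" & actual == "ADHD")
  tn <- sum(predicted == "TD" & actual == "TD")
  fp <- sum(predicted == "ADHD" & actual == "TD")
  m2 <- fold_metrics(predicted, actual)
  expect_equal(unname(m2), c((tp + tn) / 40, tp / (tp + fn), tn / (tn + fp)))
  # metrics identity: accuracy recombines from the class-conditional rates
  expect_equal(unname(m2["accuracy"]),
               (m2[["sensitivity"]] * sum(actual == "ADHD") +
                  m2[["specificity"]] * sum(actual == "TD")) / 40)
})

test_that("nested CV predicts every subject exactly once and is deterministic", {
  cfg <- cohort_config(n_per_group = 8, n_nps_features = 4,
                       nps_effect_sizes = c(2, 1, 0, 0), seed = 5)
  tab <- generate_feature_table(cfg, "NPS")
  plan <- make_fold_plan(tab$labels, k = 4, seed = 2)
  res <- nested_cv(tab, plan)

  expect_false(anyNA(res$predictions$predicted))
  expect_equal(sort(unlist(plan$folds)), seq_len(16))
  expect_equal(vapply(seq_len(16), function(i) {
    sum(vapply(plan$folds, function(f) i %in% f, TRUE))
  }, 0), rep(1, 16))                                 # one outer test each
  expect_equal(res$rounds[[1]]$evaluated_count, 2^4 - 1)
  expect_true(all(res$metrics >= 0 & res$metrics <= 1, na.rm = TRUE))

  res2 <- nested_cv(tab, plan)
  expect_identical(res$predictions, res2$predictions)
})

test_that("perturbing an outer-test fold leaves that round's selection unchanged", {
  cfg <- cohort_config(n_per_group = 8, n_nps_features = 4,
                       nps_effect_sizes = c(1.5, 0.5, 0, 0), seed = 6)
  tab <- generate_feature_table(cfg, "NPS")
  plan <- make_fold_plan(tab$labels, k = 4, seed = 9)
  res <- nested_cv(tab, plan)

  for (r in c(1, 3)) {
    tab2 <- tab
    idx <- plan$folds[[r]]
    tab2$x[idx, ] <- tab2$x[idx, ] + 100
    res2 <- nested_cv(tab2, plan)
    expect_identical(res2$rounds[[r]]$best_subset, res$rounds[[r]]$best_subset)
    expect_equal(res2$rounds[[r]]$best_inner_score,
                 res$rounds[[r]]$best_inner_score)
  }
})

test_that("occurrence-frequency importance counts round-optimal memberships", {
  cfg <- cohort_config(n_per_group = 10, n_nps_features = 3,
                       nps_effect_sizes = c(4, 0, 0), seed = 8)
  tab <- generate_feature_table(cfg, "NPS")
  plan <- make_fold_plan(tab$labels, k = 5, seed = 3)
  res <- nested_cv(tab, plan)
  imp <- importance(res)

  expect_setequal(imp$feature, colnames(tab$x))
  expect_true(all(imp$count >= 0 & imp$count <= plan$k))
  # bookkeeping: counts sum to the total size of the optimal subsets
  expect_equal(sum(imp$count),
               sum(lengths(lapply(res$rounds, `[[`, "best_subset"))))
  # the dominant feature wins every round; pure-noise features may never appear
  expect_equal(imp$count[imp$feature == "f1"], plan$k)
})

test_that("group-comparison statistics match their textbook formulas", {
  # 2x2 gender table of a 22 vs 22 cohort with one female control
  g <- chi2_2x2(rbind(c(0, 22), c(1, 21)))
  expect_equal(round(g$statistic, 3), 1.023)
  expect_equal(chi2_2x2(rbind(c(10, 10), c(10, 10)))$statistic, 0)

  # formula oracle n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  set.seed(14)
  for (i in 1:5) {
    tb <- matrix(rpois(4, 8) + 1, 2, 2)
    a <- tb[1, 1]; b <- tb[1, 2]; c_ <- tb[2, 1]; d <- tb[2, 2]
    n <- sum(tb)
    manual <- n * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    expect_equal(suppressWarnings(chi2_2x2(tb))$statistic, manual,
                 tolerance = 1e-12)
  }
  expect_error(chi2_2x2(rbind(c(0, 0), c(1, 2))), "marginal")

  # pooled-variance t equals the hand formula
  set.seed(15)
  x <- rnorm(12, 1); y <- rnorm(10)
  tt <- group_t_test(x, y)
  sp2 <- ((11 * var(x) + 9 * var(y)) / 20)
  manual_t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 12 + 1 / 10))
  expect_equal(tt$statistic, manual_t, tolerance = 1e-12)
  expect_equal(tt$df, 20)
})
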