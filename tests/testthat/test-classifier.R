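test_that("confusion metrics follow the standard definitions", {
  m <- confusion_metrics(3, 1, 3, 1)
  expect_equal(unlist(m), c(accuracy = 0.75, sensitivity = 0.75,
                            specificity = 0.75, ppv = 0.75, npv = 0.75))
  expect_equal(unlist(confusion_metrics(10, 0, 10, 0)), rep(1, 5),
               ignore_attr = TRUE)
  deg <- confusion_metrics(0, 0, 10, 0)
  expect_true(is.na(deg$sensitivity))
  expect_true(is.na(deg$ppv))
  expect_equal(deg$specificity, 1)
  expect_equal(deg$accuracy, 1)
  expect_error(confusion_metrics(-1, 0, 0, 1), "non-negative")
  expect_error(confusion_metrics(0, 0, 0, 0), "positive")
})

test_that("importance selection finds a separating feature among noise", {
  df <- toy_features(n_per = 25, sep = 3)
  cfg <- classifier_config(seed = 5, n_trees = 300,
                           candidate_features = c("signal", "noise1",
                                                  "noise2", "noise3"))
  sel <- select_features(df, df$label, cfg)
  expect_true("signal" %in% sel)
  expect_identical(sel, select_features(df, df$label, cfg))  # deterministic
  expect_error(select_features(df, rep("terminating", nrow(df)), cfg),
               "two classes")
})

test_that("identical feature copies still yield a non-empty selection", {
  df <- toy_features(n_per = 15, sep = 1.5)
  df$copy1 <- df$signal
  df$copy2 <- df$signal
  cfg <- classifier_config(seed = 2, n_trees = 200,
                           candidate_features = c("signal", "copy1", "copy2"))
  expect_gte(length(select_features(df, df$label, cfg)), 1)
})

test_that("perfectly separable features give perfect pooled metrics", {
  df <- toy_features(n_per = 20, sep = 30)
  cfg <- classifier_config(seed = 7, n_trees = 200, k_folds = 5,
                           candidate_features = c("signal", "noise1",
                                                  "noise2", "noise3"))
  ev <- cross_validate(df, cfg = cfg)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$auroc, 1)
  expect_equal(unname(ev$accuracy_ci95), c(1, 1))
})

test_that("cross-validation is reproducible and the CI brackets the accuracy", {
  ch <- generate_cohort(cohort_spec(seed = 77))
  ft <- suppressMessages(cohort_features(ch))
  cfg <- classifier_config(seed = 13, n_trees = 200)
  ev1 <- cross_validate(ft, cfg = cfg)
  ev2 <- cross_validate(ft, cfg = cfg)
  expect_identical(ev1$predictions$prob, ev2$predictions$prob)
  expect_identical(ev1$accuracy, ev2$accuracy)
  expect_identical(ev1$selected_features, ev2$selected_features)
  expect_lte(ev1$accuracy_ci95[["low"]], ev1$accuracy)
  expect_gte(ev1$accuracy_ci95[["high"]], ev1$accuracy)
  expect_true(all(ev1$predictions$fold %in% 1:10))
  # stratification: both classes in every fold
  tab <- table(ev1$predictions$fold, ev1$predictions$label)
  expect_true(all(tab > 0))
})

test_that("swapping the positive class swaps sensitivity/specificity and PPV/NPV", {
  df <- toy_features(n_per = 15, sep = 1.2)
  base <- classifier_config(seed = 11, n_trees = 301, k_folds = 5,
                            candidate_features = c("signal", "noise1", "noise2"))
  flip <- base; flip$positive_class <- "sustained"
  ev_t <- cross_validate(df, cfg = base)
  ev_s <- cross_validate(df, cfg = flip)
  expect_equal(ev_t$accuracy, ev_s$accuracy)
  expect_equal(ev_t$sensitivity, ev_s$specificity)
  expect_equal(ev_t$specificity, ev_s$sensitivity)
  expect_equal(ev_t$ppv, ev_s$npv)
  expect_equal(ev_t$npv, ev_s$ppv)
})

test_that("pooled metrics do not depend on prediction order", {
  withr::with_seed(9, {
    truth <- sample(c(TRUE, FALSE), 60, replace = TRUE)
    prob <- runif(60)
    metrics_of <- function(tr, pr) {
      confusion_metrics(sum(pr >= 0.5 & tr), sum(pr >= 0.5 & !tr),
                        sum(pr < 0.5 & !tr), sum(pr < 0.5 & tr))
    }
    perm <- sample(60)
    expect_identical(metrics_of(truth, prob), metrics_of(truth[perm], prob[perm]))
  })
})

test_that("per-fold selection does not leak labels into the evaluation", {
  accs <- aucs <- numeric(0)
  for (s in 1:12) {
    df <- withr::with_seed(6000 + s, {
      data.frame(label = rep(c("terminating", "sustained"), c(36, 33)),
                 n1 = rnorm(69), n2 = rnorm(69), n3 = rnorm(69),
                 n4 = rnorm(69), n5 = rnorm(69))
    })
    cfg <- classifier_config(seed = s, n_trees = 200,
                             candidate_features = paste0("n", 1:5))
    ev <- cross_validate(df, cfg = cfg)
    accs <- c(accs, ev$accuracy)
    aucs <- c(aucs, ev$auroc)
  }
  expect_lt(abs(mean(accs) - 0.5), 0.15)
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})

test_that("undersized classes are rejected with a pointer to smaller k", {
  df <- toy_features(n_per = 5)
  cfg <- classifier_config(k_folds = 10,
                           candidate_features = c("signal", "noise1"))
  expect_error(cross_validate(df, cfg = cfg), "smaller k")
})

test_that("patient-grouped folds never split a patient across train and test", {
  ch <- generate_cohort(cohort_spec(seed = 31))
  ft <- suppressMessages(cohort_features(ch))
  cfg <- classifier_config(seed = 3, n_trees = 150, k_folds = 5,
                           group_by_patient = TRUE)
  ev <- cross_validate(ft, cfg = cfg)
  folds <- tapply(ev$predictions$fold, ft$patient_id[match(
    ev$predictions$episode_id, ft$episode_id)], function(v) length(unique(v)))
  expect_true(all(folds == 1))
})
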