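test_that("metrics match their closed forms and the confusion oracle", {
  # counts tp=8 fp=1 tn=9 fn=2
  y_true <- c(rep(1, 8), rep(0, 1), rep(0, 9), rep(1, 2))
  y_pred <- c(rep(1, 8), rep(1, 1), rep(0, 9), rep(0, 2))
  set.seed(1)
  m <- compute_metrics(y_true, y_pred, y_pred + runif(20, -0.1, 0.1))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 8 / 9)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$f1, 2 * (8 / 9) * 0.8 / ((8 / 9) + 0.8))
  expect_equal(m$counts, list(tp = 8L, fp = 1L, tn = 9L, fn = 2L))

  # 1000 random cases against the enumeration oracle
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(4:30, 1)
    yt <- c(0, 1, rbinom(n - 2, 1, 0.5))
    yp <- rbinom(n, 1, 0.5)
    cc <- oracle_confusion(yt, yp)
    got <- suppressWarnings(compute_metrics(yt, yp, runif(n)))
    expect_equal(got$counts, cc)
    expect_equal(got$accuracy, (cc$tp + cc$tn) / n)
    expect_equal(got$precision, if (cc$tp + cc$fp == 0) 0 else cc$tp / (cc$tp + cc$fp))
    expect_equal(got$sensitivity, if (cc$tp + cc$fn == 0) 0 else cc$tp / (cc$tp + cc$fn))
  }

  expect_warning(compute_metrics(c(0, 1), c(0, 0), c(0.1, 0.2)), "precision")
  expect_error(compute_metrics(c(1, 1), c(1, 0), c(0.9, 0.1)), "single class")
  expect_error(compute_metrics(c(0, 1), c(0, 1, 1), c(0.1, 0.9, 0.9)), "length")
})

test_that("ROC and AUC match the pairwise-concordance statistic", {
  # hand-enumerated example: 3 concordant of 4 pairs
  expect_equal(auc_score(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.3)), 0.75)
  expect_equal(auc_score(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(auc_score(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9)), 0.0)

  roc <- roc_curve(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  # perfect scores trace (0,0) -> (0,1) -> (1,1)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))

  set.seed(101)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    yt <- c(0, 1, rbinom(n - 2, 1, 0.4))
    ys <- runif(n)                           # ties almost surely absent
    expect_equal(auc_score(yt, ys), oracle_auc(yt, ys), tolerance = 1e-12)
    ys_tied <- round(ys, 1)                  # heavy ties
    expect_equal(auc_score(yt, ys_tied), oracle_auc(yt, ys_tied), tolerance = 1e-12)
  }
  expect_error(roc_curve(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  yt <- c(0, 1, rbinom(48, 1, 0.35))
  ys <- runif(50)
  ref <- as.numeric(pROC::auc(pROC::roc(yt, ys, quiet = TRUE, direction = "<")))
  expect_equal(auc_score(yt, ys), ref, tolerance = 1e-12)
})

test_that("trial averaging is macro, not pooled", {
  # two trials whose pooled and averaged precisions differ
  t1 <- list(y = c(1, 1, 0, 0), p = c(1, 1, 1, 0))   # precision 2/3
  t2 <- list(y = c(1, 0, 0, 0), p = c(1, 0, 0, 0))   # precision 1
  prec <- function(tr) {
    cc <- oracle_confusion(tr$y, tr$p)
    cc$tp / (cc$tp + cc$fp)
  }
  macro <- mean(c(prec(t1), prec(t2)))
  pooled <- {
    cc <- oracle_confusion(c(t1$y, t2$y), c(t1$p, t2$p))
    cc$tp / (cc$tp + cc$fp)
  }
  expect_false(isTRUE(all.equal(macro, pooled)))

  d <- generate_separable(120, seed = 31)
  res <- run_experiment(d, experiment_spec("e", "all", n_trials = 3, seed = 40),
                        "proposed", default_config(n_folds = 5))
  expect_equal(unname(res$means["accuracy"]), mean(res$trials$accuracy))
  expect_equal(nrow(res$trials), 3)
})

test_that("experiments are reproducible and single-trial means collapse", {
  d <- tiny_dataset(n = 80, seed = 41)
  cfg <- default_config(n_folds = 4,
                        learners = list(learner_spec("logistic"),
                                        learner_spec("tree")))
  spec1 <- experiment_spec("one", "all", n_trials = 1, seed = 60)
  r1 <- run_experiment(d, spec1, "proposed", cfg)
  expect_equal(unname(r1$means["auc"]), r1$trials$auc[1])

  r2 <- run_experiment(d, spec1, "proposed", cfg)
  expect_identical(r1$trials, r2$trials)
})

test_that("feature-subset rules resolve against criticality metadata", {
  d <- generate_risk_data(generator_config(n = 300, seed = 9))
  expect_length(resolve_idx <- tierstack:::resolve_feature_subset(d, "primary_only"), 8)
  expect_true(all(d$meta$criticality[resolve_idx] == "primary"))
  t5 <- tierstack:::resolve_feature_subset(d, "top5_secondary")
  expect_length(t5, 5)
  expect_true(all(d$meta$criticality[t5] == "secondary"))
  both <- tierstack:::resolve_feature_subset(d, "primary_plus_top5_secondary")
  expect_length(both, 13)
  expect_error(tierstack:::resolve_feature_subset(d, "nope"), "unknown")
})

test_that("algorithm comparison tabulates every spec x algorithm cell", {
  d <- generate_separable(150, seed = 61)
  specs <- list(experiment_spec("a", "all", n_trials = 2, seed = 70),
                experiment_spec("b", "primary_only", n_trials = 2, seed = 70))
  cfg <- default_config(n_folds = 5,
                        learners = list(learner_spec("logistic"),
                                        learner_spec("tree")))
  cmp <- compare_algorithms(d, specs, cfg)
  expect_equal(nrow(cmp$table), 4)
  expect_equal(nrow(cmp$differences), 2)
  expect_setequal(unique(cmp$table$algo), c("proposed", "traditional_se"))

  dir <- withr::local_tempdir()
  paths <- write_comparison(cmp, dir)
  expect_true(all(file.exists(paths)))
  expect_equal(nrow(utils::read.csv(paths[1])), 4)
})
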