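test_that("stratified folds are disjoint, exhaustive, balanced and reproducible", {
  y <- rep(c(0, 1), each = 50)
  fp <- make_stratified_folds(y, 10, seed = 8)
  expect_equal(sort(unique(fp$assignments)), 1:10)
  expect_length(fp$assignments, 100)
  for (f in 1:10) {
    idx <- fp$assignments == f
    expect_equal(sum(y[idx] == 1), 5)
    expect_equal(sum(y[idx] == 0), 5)
  }
  expect_identical(make_stratified_folds(y, 10, seed = 8), fp)
  expect_false(identical(make_stratified_folds(y, 10, seed = 9)$assignments,
                         fp$assignments))

  # n = n_folds: singleton folds
  fp1 <- make_stratified_folds(c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1), 10, seed = 1)
  expect_equal(sort(tabulate(fp1$assignments, 10)), rep(1L, 10))

  # uneven classes: per-fold positive counts within +/-1 of each other
  y2 <- c(rep(0, 73), rep(1, 27))
  fp2 <- make_stratified_folds(y2, 10, seed = 3)
  pos_per_fold <- vapply(1:10, function(f) sum(y2[fp2$assignments == f] == 1),
                         integer(1))
  expect_lte(diff(range(pos_per_fold)), 1)

  expect_error(make_stratified_folds(c(0, 1), 10), "at least")
})

test_that("base tier fills every out-of-fold cell exactly once", {
  d <- tiny_dataset(n = 50, seed = 13)
  folds <- make_stratified_folds(d$y, 5, seed = 1)
  learners <- list(learner_spec("logistic"), learner_spec("tree"),
                   learner_spec("nbayes"))
  base <- fit_base_tier(d$X, d$y, learners, folds)
  expect_equal(dim(base$scores), c(50, 3))
  expect_false(anyNA(base$scores))
  expect_true(all(base$scores >= 0 & base$scores <= 1))
  expect_identical(base$labels, (base$scores >= 0.5) * 1)
  expect_length(base$fitted, 3)
  # fold test-set sizes partition n
  expect_equal(sum(tabulate(folds$assignments, 5)), 50)
})

test_that("a decision tree recovers a noise-free linear coding out of fold", {
  set.seed(2)
  X <- matrix(rbinom(80 * 4, 1, 0.5), 80, 4)
  y <- X[, 1]
  folds <- make_stratified_folds(y, 5, seed = 2)
  base <- fit_base_tier(X, y, list(learner_spec("tree"), learner_spec("logistic")),
                        folds)
  expect_equal(mean(base$labels[, 1] == y), 1.0)
})

test_that("combination schemes match their counting/arithmetic oracles", {
  expect_equal(combine_average(c(0.2, 0.4, 0.9)), 0.5)
  expect_equal(combine_average(0.73), 0.73)
  set.seed(6)
  v <- runif(5)
  expect_equal(combine_average(sample(v)), combine_average(v))
  expect_error(combine_average(numeric(0)), "empty")

  expect_equal(combine_majority(c(1, 1, 0)), 1)
  expect_equal(combine_majority(c(0, 0, 1, 1)), 1)  # tie resolves to PTB
  expect_error(combine_majority(numeric(0)), "empty")

  # exhaustive equivalence with the counting oracle for m = 2..5
  for (m in 2:5) {
    patterns <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    for (i in seq_len(nrow(patterns))) {
      expect_equal(combine_majority(patterns[i, ]),
                   oracle_majority(patterns[i, ]))
    }
  }
})

test_that("meta-features follow the scheme roster", {
  oof <- list(scores = rbind(c(0.9, 0.8, 0.2)),
              labels = rbind(c(1, 1, 0)))
  schemes <- list(combination_scheme("average"), combination_scheme("majority"))
  M <- build_meta_features(oof, schemes)
  expect_equal(dim(M), c(1, 2))
  expect_equal(unname(M[1, ]), c(mean(c(0.9, 0.8, 0.2)), 1))
  expect_equal(colnames(M), c("average", "majority"))

  # identical learners: averaging equals any single learner's column
  oof2 <- list(scores = matrix(rep(c(0.3, 0.7, 0.1), 3), 3, 3),
               labels = matrix(rep(c(0, 1, 0), 3), 3, 3))
  M2 <- build_meta_features(oof2, list(combination_scheme("average")))
  expect_equal(unname(M2[, 1]), c(0.3, 0.7, 0.1))

  # all registered schemes stay in [0, 1]
  set.seed(9)
  oof3 <- list(scores = matrix(runif(40), 10, 4))
  oof3$labels <- (oof3$scores >= 0.5) * 1
  all_schemes <- lapply(c("average", "majority", "max", "product"),
                        combination_scheme)
  M3 <- build_meta_features(oof3, all_schemes)
  expect_equal(ncol(M3), 4)
  expect_true(all(M3 >= 0 & M3 <= 1))

  # scheme symmetry: permuting learners leaves meta-features unchanged
  perm <- c(3, 1, 4, 2)
  oof3p <- list(scores = oof3$scores[, perm], labels = oof3$labels[, perm])
  expect_equal(build_meta_features(oof3p, all_schemes), M3)
})

test_that("the tiered model wires schemes and raw features into the meta-learner", {
  d <- tiny_dataset(n = 60, seed = 17)
  model <- fit_tiered_ensemble(d$X, d$y, n_folds = 5, seed = 3)
  expect_s3_class(model, "tiered_model")
  expect_length(model$schemes, 2)
  expect_length(model$selected_features, 3)   # level-1 width = s + 3

  pred <- predict(model, d$X)
  expect_equal(nrow(pred), 60)
  expect_true(all(pred$ptb_score >= 0 & pred$ptb_score <= 1))
  expect_identical(pred$ptb_label, as.integer(pred$ptb_score >= 0.5))
  # identical rows receive identical scores
  X2 <- d$X[c(1, 1, 2, 2), ]
  p2 <- predict(model, X2)
  expect_equal(p2$ptb_score[1], p2$ptb_score[2])
  expect_equal(p2$ptb_score[3], p2$ptb_score[4])
  expect_error(predict(model, d$X[, 1:2]), "columns")
})

test_that("the traditional baseline trains the meta-learner on raw OOF scores", {
  d <- tiny_dataset(n = 60, seed = 19)
  model <- fit_traditional_se(d$X, d$y, n_folds = 5, seed = 3)
  expect_equal(model$variant, "traditional")
  expect_length(model$selected_features, 0)
  pred <- predict(model, d$X)
  expect_true(all(pred$ptb_score >= 0 & pred$ptb_score <= 1))
  # same seed gives both algorithms the same fold plan
  expect_identical(make_stratified_folds(d$y, 5, 3),
                   make_stratified_folds(d$y, 5, 3))
})

test_that("degenerate configuration reduces to the single learner", {
  d <- tiny_dataset(n = 50, seed = 23)
  learners <- list(learner_spec("logistic"), learner_spec("logistic"))
  model <- fit_tiered_ensemble(d$X, d$y, learners,
                               schemes = list(combination_scheme("average")),
                               meta_learner = "passthrough", k_meta = 0,
                               n_folds = 5, seed = 4)
  single <- learner_spec("logistic")
  fit <- single$fit(d$X, d$y)
  expect_equal(predict(model, d$X)$ptb_score, single$score(fit, d$X),
               tolerance = 1e-12)

  # ... and the prediction equals the directly computed soft vote
  model2 <- fit_tiered_ensemble(d$X, d$y,
                                list(learner_spec("logistic"), learner_spec("tree")),
                                schemes = list(combination_scheme("average")),
                                meta_learner = "passthrough", k_meta = 0,
                                n_folds = 5, seed = 4)
  base_scores <- vapply(
    list(learner_spec("logistic"), learner_spec("tree")),
    function(lr) lr$score(lr$fit(d$X, d$y), d$X), numeric(50))
  expect_equal(predict(model2, d$X)$ptb_score, rowMeans(base_scores),
               tolerance = 1e-12)
})

test_that("models round-trip through serialization", {
  d <- tiny_dataset(n = 40, seed = 29)
  model <- fit_tiered_ensemble(d$X, d$y, n_folds = 4, seed = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  model2 <- load_model(path)
  expect_equal(predict(model2, d$X), predict(model, d$X))
})
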