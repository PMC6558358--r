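#' Average combination scheme
#'
#' @param scores per-learner PTB probabilities for one instance.
#' @return Their arithmetic mean.
#' @export
combine_average <- function(scores) {
  if (length(scores) == 0) stop("cannot combine an empty score vector")
  mean(scores)
}

#' Majority-vote combination scheme
#'
#' Returns the modal hard label; an exact tie resolves to 1 (PTB), because a
#' missed preterm birth is the costlier error.
#'
#' @param labels per-learner hard 0/1 labels for one instance.
#' @return 0 or 1.
#' @export
combine_majority <- function(labels) {
  if (length(labels) == 0) stop("cannot combine an empty label vector")
  stopifnot(all(labels %in% c(0, 1)))
  as.numeric(mean(labels) >= 0.5)
}

#' Construct a combination scheme
#'
#' A combination scheme is a fixed (non-trained) rule that merges the base
#' learners' predictions for one instance into a single number in
#' \code{[0, 1]}; each scheme contributes one meta-feature column.
#' Score-type schemes consume probabilities, label-type schemes consume hard
#' labels (scores thresholded at 0.5). Available identifiers:
#' \code{"average"}, \code{"majority"}, \code{"max"}, and \code{"product"}
#' (geometric mean of scores, i.e. the m-th root of their product, which
#' keeps the product rule on the \code{[0, 1]} scale).
#'
#' @param id scheme identifier.
#' @return A \code{combination_scheme} object with fields \code{id},
#'   \code{type} (\code{"score"} or \code{"label"}) and \code{combine}.
#' @export
combination_scheme <- function(id) {
  def <- switch(id,
    average = list(type = "score", combine = combine_average),
    majority = list(type = "label", combine = combine_majority),
    max = list(type = "score", combine = function(s) {
      if (length(s) == 0) stop("cannot combine an empty score vector")
      max(s)
    }),
    product = list(type = "score", combine = function(s) {
      if (length(s) == 0) stop("cannot combine an empty score vector")
      prod(s)^(1 / length(s))
    }),
    stop("unknown combination scheme: ", id)
  )
  structure(list(id = id, type = def$type, combine = def$combine),
            class = "combination_scheme")
}

#' The default combination-scheme roster
#'
#' Averaging and majority voting — with the default three appended raw
#' features the generalization tier sees five columns. The \code{"max"} and
#' \code{"product"} schemes remain available in the registry but are not
#' defaults: their meta-feature distributions are degenerate (the product
#' rule collapses to 0 whenever any learner outputs a hard 0, and the
#' maximum saturates near 1), which measurably hurts the stacked model.
#'
#' @return List of two [combination_scheme()]s.
#' @export
default_schemes <- function() {
  lapply(c("average", "majority"), combination_scheme)
}

#' Stratified fold assignment
#'
#' Partitions instances into \code{n_folds} disjoint, exhaustive folds with
#' per-class round-robin assignment after a seeded shuffle, so each fold's
#' positive count differs from perfect proportionality by at most one.
#'
#' @param y 0/1 labels.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return A \code{fold_plan}: list with \code{assignments} (fold index in
#'   \code{1..n_folds} per instance) and \code{n_folds}.
#' @export
make_stratified_folds <- function(y, n_folds = 10, seed = 1) {
  n <- length(y)
  if (n < n_folds) stop("need at least n_folds instances")
  assignments <- integer(n)
  withr::with_seed(seed, {
    offset <- 0L
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      # continue the round-robin across classes so fold sizes stay balanced
      assignments[idx] <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
      offset <- offset + length(idx)
    }
  })
  if (length(unique(assignments)) < n_folds) {
    stop("some folds are empty; reduce n_folds")
  }
  structure(list(assignments = assignments, n_folds = n_folds),
            class = "fold_plan")
}

#' Fit the base tier: cross-validated out-of-fold predictions
#'
#' Each learner is trained \code{n_folds} times, each time on all folds but
#' one, and scores the held-out fold; every (instance, learner) cell of the
#' out-of-fold matrix is therefore filled exactly once, by a model that
#' never saw that instance. Each learner is additionally refit on all rows
#' for deployment-time prediction.
#'
#' @param X preprocessed numeric matrix.
#' @param y 0/1 labels.
#' @param learners list of [learner_spec()]s (at least 2).
#' @param folds a [make_stratified_folds()] plan.
#' @return List with \code{scores} (n x m out-of-fold probability matrix),
#'   \code{labels} (scores thresholded at 0.5), and \code{fitted} (the
#'   refit learners).
#' @export
fit_base_tier <- function(X, y, learners, folds) {
  stopifnot(inherits(folds, "fold_plan"), length(learners) >= 2)
  X <- as.matrix(X)
  n <- nrow(X)
  m <- length(learners)
  scores <- matrix(NA_real_, n, m,
                   dimnames = list(NULL, vapply(learners, `[[`, "", "id")))
  for (f in seq_len(folds$n_folds)) {
    test_idx <- which(folds$assignments == f)
    train_idx <- setdiff(seq_len(n), test_idx)
    for (j in seq_len(m)) {
      lr <- learners[[j]]
      fit <- tryCatch(lr$fit(X[train_idx, , drop = FALSE], y[train_idx]),
                      error = function(e) {
                        stop("learner '", lr$id, "' failed to fit on fold ", f,
                             ": ", conditionMessage(e))
                      })
      scores[test_idx, j] <- lr$score(fit, X[test_idx, , drop = FALSE])
    }
  }
  stopifnot(!anyNA(scores), all(scores >= 0), all(scores <= 1))
  fitted <- lapply(learners, function(lr) lr$fit(X, y))
  list(scores = scores, labels = (scores >= 0.5) * 1, fitted = fitted)
}

#' Build the ensemble tier's meta-features
#'
#' Applies each combination scheme row-wise to the out-of-fold predictions:
#' score-type schemes see the probability matrix, label-type schemes the
#' hard-label matrix. Column j of the result is scheme j's meta-feature.
#'
#' @param oof list with \code{scores} and \code{labels} matrices (from
#'   [fit_base_tier()]).
#' @param schemes list of [combination_scheme()]s.
#' @return n x s meta-feature matrix with scheme ids as column names.
#' @export
build_meta_features <- function(oof, schemes) {
  stopifnot(length(schemes) >= 1)
  cols <- lapply(schemes, function(sc) {
    src <- if (sc$type == "label") oof$labels else oof$scores
    apply(src, 1, sc$combine)
  })
  M <- do.call(cbind, cols)
  colnames(M) <- vapply(schemes, `[[`, "", "id")
  if (any(M < 0) || any(M > 1)) {
    stop("combination scheme output outside [0, 1]")
  }
  M
}

#' Fit the three-tier stacked ensemble
#'
#' The base tier produces cross-validated out-of-fold predictions; the
#' ensemble tier condenses them through the combination schemes into one
#' meta-feature per scheme; the generalization tier trains the meta-learner
#' on those meta-features concatenated with the \code{k_meta} raw features
#' most correlated (in absolute value) with the label.
#'
#' @param X preprocessed numeric matrix (no missing values).
#' @param y 0/1 labels.
#' @param learners base-learner roster (default [default_learners()]).
#' @param schemes combination schemes (default [default_schemes()]).
#' @param meta_learner meta-learner id or [learner_spec()] (default
#'   logistic regression).
#' @param k_meta number of raw features appended to the meta-features
#'   (default 3).
#' @param n_folds folds for the base tier (default 10).
#' @param seed integer seed (fold assignment).
#' @return A fitted \code{tiered_model}.
#' @seealso [fit_traditional_se()] for the classical stacked-ensemble
#'   baseline, [predict.tiered_model()].
#' @export
fit_tiered_ensemble <- function(X, y, learners = default_learners(),
                                schemes = default_schemes(),
                                meta_learner = "logistic", k_meta = 3,
                                n_folds = 10, seed = 1) {
  X <- as.matrix(X)
  stopifnot(length(schemes) >= 1, k_meta >= 0, k_meta <= ncol(X))
  folds <- make_stratified_folds(y, n_folds, seed)
  base <- fit_base_tier(X, y, learners, folds)
  M <- build_meta_features(base, schemes)
  selected <- integer(0)
  if (k_meta > 0) {
    ranking <- rank_by_correlation(X, y)
    selected <- select_top_k(ranking, k_meta)
  }
  L1 <- cbind(M, X[, selected, drop = FALSE])
  meta <- make_meta_learner(meta_learner)
  meta_fit <- meta$fit(L1, y)
  structure(list(
    variant = "tiered",
    learner_specs = learners,
    base_fitted = base$fitted,
    schemes = schemes,
    selected_features = selected,
    feature_names = colnames(X),
    meta_spec = meta,
    meta_fitted = meta_fit,
    n_features = ncol(X),
    n_folds = n_folds,
    seed = seed,
    version = "1.0"
  ), class = "tiered_model")
}

#' Fit the traditional stacked-ensemble baseline
#'
#' Classical two-level stacked generalization: the meta-learner is trained
#' directly on the n x m matrix of out-of-fold base-learner scores, with no
#' combination schemes and no appended raw features. Given the same seed it
#' uses the same fold plan as [fit_tiered_ensemble()], enabling paired
#' comparison.
#'
#' @inheritParams fit_tiered_ensemble
#' @return A fitted \code{tiered_model} with \code{variant = "traditional"}.
#' @export
fit_traditional_se <- function(X, y, learners = default_learners(),
                               meta_learner = "logistic", n_folds = 10,
                               seed = 1) {
  X <- as.matrix(X)
  folds <- make_stratified_folds(y, n_folds, seed)
  base <- fit_base_tier(X, y, learners, folds)
  meta <- make_meta_learner(meta_learner)
  meta_fit <- meta$fit(base$scores, y)
  structure(list(
    variant = "traditional",
    learner_specs = learners,
    base_fitted = base$fitted,
    schemes = list(),
    selected_features = integer(0),
    feature_names = colnames(X),
    meta_spec = meta,
    meta_fitted = meta_fit,
    n_features = ncol(X),
    n_folds = n_folds,
    seed = seed,
    version = "1.0"
  ), class = "tiered_model")
}

#' Predict PTB scores and labels from a fitted model
#'
#' Every refit base learner scores the new rows; for the tiered variant the
#' combination schemes turn those scores into meta-features and the stored
#' top-correlated raw columns are appended; the meta-learner then produces
#' the PTB score. The hard label is \code{score >= 0.5}.
#'
#' @param object a fitted \code{tiered_model}.
#' @param newdata numeric matrix preprocessed like the training data (same
#'   columns).
#' @param ... unused.
#' @return A data frame with columns \code{ptb_score} and \code{ptb_label}.
#' @export
predict.tiered_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_features) {
    stop("newdata has ", ncol(X), " columns; model expects ", object$n_features)
  }
  m <- length(object$learner_specs)
  scores <- matrix(NA_real_, nrow(X), m)
  for (j in seq_len(m)) {
    scores[, j] <- object$learner_specs[[j]]$score(object$base_fitted[[j]], X)
  }
  oof_like <- list(scores = scores, labels = (scores >= 0.5) * 1)
  L1 <- if (object$variant == "traditional") {
    scores
  } else {
    cbind(build_meta_features(oof_like, object$schemes),
          X[, object$selected_features, drop = FALSE])
  }
  s <- clip01(object$meta_spec$score(object$meta_fitted, L1))
  data.frame(ptb_score = as.numeric(s), ptb_label = as.integer(s >= 0.5))
}

#' @export
print.tiered_model <- function(x, ...) {
  cat(sprintf("tiered_model (%s): %d base learners", x$variant,
              length(x$learner_specs)))
  if (x$variant == "tiered") {
    cat(sprintf(", %d schemes, %d raw features appended", length(x$schemes),
                length(x$selected_features)))
  }
  cat(sprintf("\n  meta-learner: %s; %d-fold base tier; seed %d\n",
              x$meta_spec$id, x$n_folds, x$seed))
  invisible(x)
}

#' Save / load a fitted model
#'
#' Serializes the fitted model (including its preprocessing parameters when
#' attached by the training front-end) to a single versioned file.
#'
#' @param model a \code{tiered_model}.
#' @param path file path.
#' @return \code{path} (save) or the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "tiered_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "tiered_model")) stop("not a tiered_model file: ", path)
  model
}
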