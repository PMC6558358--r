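#' Confusion counts for binary predictions
#'
#' @param y_true true 0/1 labels.
#' @param y_pred predicted 0/1 labels.
#' @return List with \code{tp}, \code{fp}, \code{tn}, \code{fn}.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  list(
    tp = sum(y_true == 1 & y_pred == 1),
    fp = sum(y_true == 0 & y_pred == 1),
    tn = sum(y_true == 0 & y_pred == 0),
    fn = sum(y_true == 1 & y_pred == 0)
  )
}

#' ROC curve
#'
#' Sweeps the decision threshold over the unique scores in descending order;
#' at each threshold an instance is called PTB when its score is at least the
#' threshold. Points are monotone non-decreasing in both coordinates and the
#' curve always starts at (0, 0) and ends at (1, 1). Tied scores move along
#' the curve together (one point per distinct score), which matches the
#' ties-count-half convention of the pairwise-concordance view of AUC.
#'
#' @param y_true 0/1 labels containing both classes.
#' @param y_score PTB scores.
#' @return Data frame with columns \code{fpr}, \code{tpr}.
#' @export
roc_curve <- function(y_true, y_score) {
  if (length(unique(y_true)) < 2) {
    stop("ROC requires both classes in y_true")
  }
  if (length(y_true) != length(y_score)) stop("length mismatch")
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  ord <- order(y_score, decreasing = TRUE)
  yt <- y_true[ord]
  ys <- y_score[ord]
  # advance over groups of tied scores
  last_of_group <- which(!duplicated(ys, fromLast = TRUE))
  tpr <- cumsum(yt == 1)[last_of_group] / n_pos
  fpr <- cumsum(yt == 0)[last_of_group] / n_neg
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Area under the ROC curve (trapezoidal rule)
#'
#' @param y_true 0/1 labels.
#' @param y_score PTB scores.
#' @return AUC in \code{[0, 1]}.
#' @export
auc_score <- function(y_true, y_score) {
  roc <- roc_curve(y_true, y_score)
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Compute the full metric set for one evaluation
#'
#' Accuracy, precision, sensitivity (PTB recall), F1 (harmonic mean of
#' precision and sensitivity), and trapezoidal AUC. Precision is defined as
#' 0 (with a warning) when nothing is predicted positive; sensitivity and F1
#' degrade to 0 analogously.
#'
#' @param y_true true 0/1 labels (both classes required for AUC).
#' @param y_pred predicted 0/1 labels.
#' @param y_score PTB scores used for the ROC; defaults to \code{y_pred}.
#' @return A \code{metrics_report}: list with \code{accuracy},
#'   \code{precision}, \code{sensitivity}, \code{f1}, \code{auc},
#'   \code{counts}, and \code{roc_points}.
#' @export
compute_metrics <- function(y_true, y_pred, y_score = y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) != length(y_score)) {
    stop("length mismatch")
  }
  cc <- confusion_counts(y_true, y_pred)
  n <- length(y_true)
  accuracy <- (cc$tp + cc$tn) / n
  if (cc$tp + cc$fp == 0) {
    warning("no positive predictions; precision defined as 0")
    precision <- 0
  } else {
    precision <- cc$tp / (cc$tp + cc$fp)
  }
  sensitivity <- if (cc$tp + cc$fn == 0) 0 else cc$tp / (cc$tp + cc$fn)
  f1 <- if (precision + sensitivity == 0) 0 else {
    2 * precision * sensitivity / (precision + sensitivity)
  }
  if (length(unique(y_true)) < 2) {
    stop("AUC undefined: y_true contains a single class")
  }
  roc <- roc_curve(y_true, y_score)
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  structure(list(accuracy = accuracy, precision = precision,
                 sensitivity = sensitivity, f1 = f1, auc = auc,
                 counts = cc, roc_points = roc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %.4f  sensitivity %.4f  f1 %.4f  auc %.4f\n",
              x$accuracy, x$precision, x$sensitivity, x$f1, x$auc))
  invisible(x)
}

#' Define an experiment over a feature subset
#'
#' An experiment names a feature-subset rule, a trial count and a base seed.
#' Subset rules: \code{"all"}, \code{"primary_only"}, \code{"secondary_only"},
#' \code{"top5_secondary"} (the five secondary features most correlated with
#' the label over the full dataset), \code{"primary_plus_top5_secondary"},
#' or a custom integer vector of feature indices.
#'
#' @param name experiment name.
#' @param feature_subset one of the rule strings above, or feature indices.
#' @param n_trials repeated trials (default 10).
#' @param seed base seed; trial t uses \code{seed + t}.
#' @return An \code{experiment_spec} object.
#' @export
experiment_spec <- function(name, feature_subset = "all", n_trials = 10, seed = 100) {
  structure(list(name = name, feature_subset = feature_subset,
                 n_trials = n_trials, seed = seed),
            class = "experiment_spec")
}

#' The default experiment roster
#'
#' Five feature-subset experiments probing the contribution of primary
#' (critical) versus secondary risk factors.
#'
#' @param n_trials trials per experiment (default 10).
#' @param seed base seed.
#' @return List of five [experiment_spec()]s.
#' @export
default_experiment_specs <- function(n_trials = 10, seed = 100) {
  list(
    experiment_spec("all_factors", "all", n_trials, seed),
    experiment_spec("primary_only", "primary_only", n_trials, seed),
    experiment_spec("all_secondary", "secondary_only", n_trials, seed),
    experiment_spec("top5_secondary", "top5_secondary", n_trials, seed),
    experiment_spec("primary_plus_top5_secondary", "primary_plus_top5_secondary",
                    n_trials, seed)
  )
}

resolve_feature_subset <- function(data, rule) {
  if (is.numeric(rule)) {
    idx <- as.integer(rule)
  } else {
    primary <- which(data$meta$criticality == "primary")
    secondary <- which(data$meta$criticality == "secondary")
    top5_sec <- function() {
      if (length(secondary) == 0) return(integer(0))
      imputed <- impute_missing(data, fit_imputer(data))
      rk <- rank_by_correlation(imputed$X[, secondary, drop = FALSE], imputed$y)
      secondary[select_top_k(rk, min(5, length(secondary)))]
    }
    idx <- switch(rule,
      all = seq_len(ncol(data$X)),
      primary_only = primary,
      secondary_only = secondary,
      top5_secondary = top5_sec(),
      primary_plus_top5_secondary = sort(c(primary, top5_sec())),
      stop("unknown feature subset rule: ", rule)
    )
  }
  if (length(idx) == 0) stop("feature subset is empty")
  if (any(idx < 1 | idx > ncol(data$X))) stop("feature subset index out of range")
  idx
}

# Stratified train/test split preserving the mix of the four cases
# (any-primary-risk-factor x outcome); strata with fewer than 2 members go
# entirely to the training set.
split_four_case <- function(data, test_frac = 0.2, seed = 1) {
  primary <- which(data$meta$criticality == "primary")
  has_risk <- if (length(primary) > 0) {
    as.integer(rowSums(data$X[, primary, drop = FALSE] >= 0.5, na.rm = TRUE) > 0)
  } else {
    rep(0L, nrow(data$X))
  }
  stratum <- paste(has_risk, data$y, sep = "/")
  test_idx <- withr::with_seed(seed, {
    unlist(lapply(unique(stratum), function(s) {
      idx <- which(stratum == s)
      if (length(idx) < 2) return(integer(0))
      n_test <- max(1, round(test_frac * length(idx)))
      n_test <- min(n_test, length(idx) - 1)
      sample(idx, n_test)
    }))
  })
  list(train = setdiff(seq_len(nrow(data$X)), test_idx), test = sort(test_idx))
}

fit_algo <- function(algo, X, y, config, seed) {
  learners <- config$learners
  if (is.null(learners)) learners <- default_learners()
  meta <- if (is.null(config$meta_learner)) "logistic" else config$meta_learner
  n_folds <- if (is.null(config$n_folds)) 10 else config$n_folds
  if (algo == "proposed") {
    schemes <- config$schemes
    if (is.null(schemes)) schemes <- default_schemes()
    k_meta <- if (is.null(config$select$k_meta)) 3 else config$select$k_meta
    fit_tiered_ensemble(X, y, learners, schemes, meta,
                        k_meta = min(k_meta, ncol(X)), n_folds = n_folds,
                        seed = seed)
  } else if (algo == "traditional_se") {
    fit_traditional_se(X, y, learners, meta, n_folds = n_folds, seed = seed)
  } else {
    stop("unknown algorithm: ", algo)
  }
}

#' Run a repeated-trial experiment
#'
#' For each trial t (seed = base seed + t): stratified 80/20 train/test
#' split preserving the four-case mix (risk factors x outcome);
#' preprocessing fitted on the training partition only; model fitted on the
#' preprocessed training data; metrics computed on the held-out test set.
#' Metrics are averaged across trials (macro averaging: the mean of
#' per-trial metrics).
#'
#' @param data a [risk_dataset()].
#' @param spec an [experiment_spec()].
#' @param algo \code{"proposed"} (three-tier ensemble) or
#'   \code{"traditional_se"} (classical stacking baseline).
#' @param config pipeline configuration (see [default_config()]).
#' @return List with \code{spec}, \code{algo}, \code{trials} (per-trial
#'   metric data frame), \code{means} (named vector of macro-averaged
#'   metrics), and \code{roc} (per-trial ROC point sets).
#' @export
run_experiment <- function(data, spec, algo = "proposed",
                           config = default_config()) {
  stopifnot(inherits(data, "risk_dataset"), inherits(spec, "experiment_spec"))
  subset_idx <- resolve_feature_subset(data, spec$feature_subset)
  sub <- risk_dataset(data$X[, subset_idx, drop = FALSE], data$y,
                      data$meta[subset_idx, , drop = FALSE])
  if (identical(config$smote$scope, "full") && isTRUE(config$smote$enabled)) {
    # whole-dataset balancing before the split; training-stage SMOTE is then
    # redundant and switched off
    sub <- impute_missing(sub, fit_imputer(sub))
    bal <- smote_balance(sub$X, sub$y, k = config$smote$k, seed = spec$seed,
                         round_binary = isTRUE(config$smote$round_binary),
                         binary_cols = which(sub$meta$dtype == "binary"))
    sub <- risk_dataset(bal$X, bal$y, sub$meta)
    config$smote$enabled <- FALSE
  }
  trials <- vector("list", spec$n_trials)
  rocs <- vector("list", spec$n_trials)
  for (t in seq_len(spec$n_trials)) {
    seed_t <- spec$seed + t
    sp <- split_four_case(sub, test_frac = 0.2, seed = seed_t)
    train <- risk_dataset(sub$X[sp$train, , drop = FALSE], sub$y[sp$train], sub$meta)
    test <- risk_dataset(sub$X[sp$test, , drop = FALSE], sub$y[sp$test], sub$meta)
    pre <- preprocess_fit(train, config, seed = seed_t)
    model <- fit_algo(algo, pre$train$X, pre$train$y, config, seed_t)
    X_test <- preprocess_apply(pre$params, test)
    pred <- predict(model, X_test)
    rep_t <- compute_metrics(test$y, pred$ptb_label, pred$ptb_score)
    trials[[t]] <- data.frame(trial = t, accuracy = rep_t$accuracy,
                              precision = rep_t$precision,
                              sensitivity = rep_t$sensitivity,
                              f1 = rep_t$f1, auc = rep_t$auc)
    rocs[[t]] <- rep_t$roc_points
  }
  trials <- do.call(rbind, trials)
  means <- colMeans(trials[, c("accuracy", "precision", "sensitivity", "f1", "auc")])
  list(spec = spec, algo = algo, trials = trials, means = means, roc = rocs)
}

#' Compare the proposed algorithm with the traditional stacked ensemble
#'
#' Runs every experiment spec with both algorithms under identical seeds
#' (hence identical splits and fold plans — a paired comparison) and
#' tabulates mean metrics and their differences (proposed minus
#' traditional).
#'
#' @param data a [risk_dataset()].
#' @param specs list of [experiment_spec()]s.
#' @param config pipeline configuration.
#' @return List with \code{table} (one row per spec x algorithm),
#'   \code{differences} (per-spec proposed-minus-SE metric deltas), and
#'   \code{runs} (the full [run_experiment()] results).
#' @export
compare_algorithms <- function(data, specs, config = default_config()) {
  stopifnot(length(specs) >= 1)
  runs <- list()
  rows <- list()
  diffs <- list()
  metric_names <- c("accuracy", "precision", "sensitivity", "f1", "auc")
  for (spec in specs) {
    res_p <- run_experiment(data, spec, "proposed", config)
    res_t <- run_experiment(data, spec, "traditional_se", config)
    runs[[spec$name]] <- list(proposed = res_p, traditional_se = res_t)
    rows[[length(rows) + 1]] <- data.frame(experiment = spec$name,
                                           algo = "proposed",
                                           t(res_p$means))
    rows[[length(rows) + 1]] <- data.frame(experiment = spec$name,
                                           algo = "traditional_se",
                                           t(res_t$means))
    diffs[[length(diffs) + 1]] <- data.frame(
      experiment = spec$name,
      t(res_p$means[metric_names] - res_t$means[metric_names]))
  }
  list(table = do.call(rbind, rows), differences = do.call(rbind, diffs),
       runs = runs)
}

#' Write comparison outputs
#'
#' Emits the comparison table as CSV, a JSON summary (means and
#' differences), and optionally a PNG grid of ROC curves (one column per
#' experiment; traditional stacking on the first row, the proposed
#' algorithm on the second).
#'
#' @param cmp a [compare_algorithms()] result.
#' @param out_dir output directory (created if absent).
#' @param roc_png also write \code{roc_grid.png}.
#' @return Invisibly, the paths written.
#' @export
write_comparison <- function(cmp, out_dir, roc_png = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(out_dir, "comparison.csv")
  utils::write.csv(cmp$table, csv_path, row.names = FALSE)
  json_path <- file.path(out_dir, "comparison.json")
  jsonlite::write_json(list(table = cmp$table, differences = cmp$differences),
                       json_path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  paths <- c(csv_path, json_path)
  if (roc_png) {
    png_path <- file.path(out_dir, "roc_grid.png")
    grDevices::png(png_path, width = 320 * length(cmp$runs), height = 640)
    graphics::par(mfrow = c(2, length(cmp$runs)), mar = c(4, 4, 2, 1))
    for (algo in c("traditional_se", "proposed")) {
      for (nm in names(cmp$runs)) {
        rocs <- cmp$runs[[nm]][[algo]]$roc
        graphics::plot(0:1, 0:1, type = "l", lty = 3, col = "grey40",
                       xlab = "FPR", ylab = "TPR",
                       main = paste(nm, algo, sep = " / "))
        for (rc in rocs) graphics::lines(rc$fpr, rc$tpr, col = "#00000055")
      }
    }
    grDevices::dev.off()
    paths <- c(paths, png_path)
  }
  invisible(paths)
}
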