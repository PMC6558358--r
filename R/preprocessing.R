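#' Fit criticality-aware imputation values
#'
#' Missing values in critical (primary) features are replaced by that
#' feature's mean over the observed training values; missing values in
#' non-critical (secondary) features are replaced by the feature's declared
#' default value. Imputation values are a function of the training partition
#' only and are reused unchanged on held-out data.
#'
#' @param data training [risk_dataset()].
#' @return Named numeric vector of per-feature imputation values.
#' @export
fit_imputer <- function(data) {
  stopifnot(inherits(data, "risk_dataset"))
  vals <- numeric(ncol(data$X))
  names(vals) <- data$meta$name
  for (j in seq_len(ncol(data$X))) {
    if (data$meta$criticality[j] == "primary") {
      obs <- data$X[, j][!is.na(data$X[, j])]
      if (length(obs) == 0) {
        stop("cannot fit imputer: critical feature '", data$meta$name[j],
             "' has no observed training values")
      }
      vals[j] <- mean(obs)
    } else {
      vals[j] <- data$meta$default_value[j]
    }
  }
  vals
}

#' Impute missing values
#'
#' @param data a [risk_dataset()] possibly containing missing cells.
#' @param values per-feature imputation values from [fit_imputer()].
#' @return The dataset with no missing cells.
#' @export
impute_missing <- function(data, values) {
  stopifnot(inherits(data, "risk_dataset"))
  if (length(values) != ncol(data$X)) {
    stop("imputation values length must match feature count")
  }
  X <- data$X
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- values[j]
  }
  risk_dataset(X, data$y, data$meta)
}

#' Default minimum-frequency threshold for the outlier screen
#'
#' @param n number of instances.
#' @return \code{max(2, ceiling(0.001 * n))}.
#' @export
outlier_min_count <- function(n) max(2L, as.integer(ceiling(0.001 * n)))

#' Flag outliers by rare concatenated binary codes
#'
#' The five most label-correlated binary features are concatenated into a
#' 5-bit code per instance; instances whose (code, label) pair occurs fewer
#' than \code{min_count} times in the dataset sit far from the central mass
#' of the code/label scatter and are flagged as outliers. The caller removes
#' flagged instances before training. Values of binary features that have
#' been mean-imputed may be fractional; they are rounded at 0.5 when forming
#' the code.
#'
#' @param data a [risk_dataset()] with no missing cells.
#' @param top5 indices of the (typically five) binary screening features.
#' @param min_count minimum pair frequency; pairs rarer than this are flagged.
#' @return Integer vector of flagged instance indices (possibly empty).
#' @export
flag_outliers <- function(data, top5, min_count = outlier_min_count(nrow(data$X))) {
  stopifnot(inherits(data, "risk_dataset"), min_count >= 1)
  if (length(top5) == 0) return(integer(0))
  if (!all(data$meta$dtype[top5] == "binary")) {
    stop("outlier screening features must be binary")
  }
  codes <- apply(data$X[, top5, drop = FALSE], 1,
                 function(r) paste(as.integer(r >= 0.5), collapse = ""))
  key <- paste(codes, data$y, sep = "/")
  counts <- table(key)
  which(as.vector(counts[key]) < min_count)
}

#' Fit column means for mean-cancellation
#'
#' @param X numeric training matrix.
#' @return Numeric vector of column means.
#' @export
fit_mean_cancel <- function(X) colMeans(as.matrix(X))

#' Mean-cancellation normalization
#'
#' Centers every column by subtracting its stored training mean; the same
#' shift is applied to training and held-out data.
#'
#' @param X numeric matrix.
#' @param means column means fitted on training rows ([fit_mean_cancel()]).
#' @return The centered matrix.
#' @export
mean_cancel <- function(X, means) {
  X <- as.matrix(X)
  if (ncol(X) != length(means)) {
    stop("column count does not match fitted means")
  }
  sweep(X, 2, means, "-")
}

#' SMOTE minority oversampling
#'
#' Balances a binary-labelled matrix by synthesizing minority-class samples
#' until the minority count equals the majority count. Each synthetic sample
#' is \code{x + u * (x_nn - x)} for a minority instance \code{x}, one of its
#' \code{k} nearest minority neighbors \code{x_nn} under Euclidean distance,
#' and \code{u ~ Uniform(0, 1)}. Original rows are preserved unchanged;
#' synthetic rows are appended. Synthetic values of binary features are kept
#' continuous by default (\code{round_binary = TRUE} rounds them back to
#' 0/1).
#'
#' @param X numeric matrix with no missing values.
#' @param y 0/1 labels.
#' @param k neighbor count (default 5; capped at minority size minus one).
#' @param seed integer seed; output is reproducible given the seed.
#' @param round_binary round synthetic values of the columns in
#'   \code{binary_cols} to 0/1.
#' @param binary_cols column indices treated as binary when
#'   \code{round_binary} is \code{TRUE} (default: all columns).
#' @return List with the augmented \code{X} and \code{y}; the first
#'   \code{nrow(X)} rows are the originals.
#' @export
smote_balance <- function(X, y, k = 5, seed = 1, round_binary = FALSE,
                          binary_cols = seq_len(ncol(X))) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(k >= 1, nrow(X) == length(y))
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0)) stop("SMOTE requires both classes to be present")
  minority <- if (tab["1"] <= tab["0"]) 1L else 0L
  n_min <- as.integer(min(tab))
  n_maj <- as.integer(max(tab))
  if (n_min < 2) stop("SMOTE requires at least 2 minority instances")
  n_syn <- n_maj - n_min
  if (n_syn == 0) return(list(X = X, y = y))

  min_idx <- which(y == minority)
  Xm <- X[min_idx, , drop = FALSE]
  k_eff <- min(k, n_min - 1)
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  # k nearest minority neighbors of each minority row (ties by row order)
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_eff)]))
  if (k_eff == 1) nn <- matrix(nn, ncol = 1)

  syn <- withr::with_seed(seed, {
    base <- rep_len(seq_len(n_min), n_syn)
    pick <- sample.int(k_eff, n_syn, replace = TRUE)
    u <- stats::runif(n_syn)
    Xa <- Xm[base, , drop = FALSE]
    Xb <- Xm[nn[cbind(base, pick)], , drop = FALSE]
    Xa + u * (Xb - Xa)
  })
  if (round_binary && length(binary_cols) > 0) {
    syn[, binary_cols] <- round(syn[, binary_cols])
  }
  list(X = rbind(X, syn), y = c(y, rep(minority, n_syn)))
}

#' Fit the full preprocessing pipeline on a training partition
#'
#' Applies the fixed pipeline order: impute missing values, remove
#' rare-code outliers, balance with SMOTE, then mean-cancel. All fitted
#' statistics (imputation values, column means, screening feature indices)
#' come from the training rows only, so transforming held-out data can never
#' alter them.
#'
#' @param data training [risk_dataset()].
#' @param config pipeline configuration (see [default_config()]).
#' @param seed integer seed controlling SMOTE.
#' @return List with \code{train} (the preprocessed training dataset: matrix
#'   \code{X}, labels \code{y}) and \code{params} (everything needed by
#'   [preprocess_apply()]).
#' @export
preprocess_fit <- function(data, config = default_config(), seed = 1) {
  stopifnot(inherits(data, "risk_dataset"))
  imput <- fit_imputer(data)
  data <- impute_missing(data, imput)

  outlier_removed <- integer(0)
  if (isTRUE(config$outlier$enabled)) {
    binary_feats <- which(data$meta$dtype == "binary")
    screen <- integer(0)
    if (length(binary_feats) > 0) {
      rk <- rank_by_correlation(data$X[, binary_feats, drop = FALSE], data$y)
      k_out <- min(config$select$k_outlier, length(binary_feats))
      screen <- binary_feats[select_top_k(rk, k_out)]
    }
    min_count <- config$outlier$min_count
    if (is.null(min_count)) min_count <- outlier_min_count(nrow(data$X))
    outlier_removed <- flag_outliers(data, screen, min_count)
    if (length(outlier_removed) > 0) {
      keep <- setdiff(seq_len(nrow(data$X)), outlier_removed)
      data <- risk_dataset(data$X[keep, , drop = FALSE], data$y[keep], data$meta)
    }
  }

  X <- data$X
  y <- data$y
  if (isTRUE(config$smote$enabled) && length(unique(y)) == 2 &&
      min(table(y)) >= 2) {
    bal <- smote_balance(X, y, k = config$smote$k, seed = seed,
                         round_binary = isTRUE(config$smote$round_binary),
                         binary_cols = which(data$meta$dtype == "binary"))
    X <- bal$X
    y <- bal$y
  }

  means <- fit_mean_cancel(X)
  X <- mean_cancel(X, means)

  params <- structure(list(
    imputation_values = imput,
    column_means = means,
    meta = data$meta,
    n_outliers_removed = length(outlier_removed)
  ), class = "preproc_params")
  list(train = list(X = X, y = y), params = params)
}

#' Apply fitted preprocessing to new data
#'
#' Held-out data get the training-fitted imputation and mean-cancellation;
#' outlier removal and SMOTE apply to training data only.
#'
#' @param params fitted parameters from [preprocess_fit()].
#' @param data a [risk_dataset()] (or bare matrix) with the training columns.
#' @return The transformed numeric matrix.
#' @export
preprocess_apply <- function(params, data) {
  stopifnot(inherits(params, "preproc_params"))
  if (inherits(data, "risk_dataset")) {
    data <- impute_missing(data, params$imputation_values)
    X <- data$X
  } else {
    X <- as.matrix(data)
    for (j in seq_len(ncol(X))) {
      miss <- is.na(X[, j])
      if (any(miss)) X[miss, j] <- params$imputation_values[j]
    }
  }
  mean_cancel(X, params$column_means)
}
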