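# Base-learner registry. Every learner exposes fit(X, y) -> fitted object
# and score(fitted, X) -> PTB probability in [0, 1]. Learners are diverse and
# individually only moderately strong, which is what makes stacking them
# worthwhile.

#' Construct a base-learner specification
#'
#' Available identifiers:
#' \describe{
#'   \item{logistic}{logistic regression (binomial GLM).}
#'   \item{tree}{CART decision tree via \pkg{rpart}.}
#'   \item{nbayes}{Gaussian naive Bayes via \pkg{e1071}, with a small
#'     variance floor so zero-variance columns cannot produce degenerate
#'     densities.}
#'   \item{knn}{k-nearest-neighbors (default \code{k = 5}); the score is the
#'     neighbor vote fraction for PTB.}
#'   \item{svm_linear}{linear-kernel support vector machine; decision values
#'     are mapped to probabilities by a logistic (Platt-type) calibration
#'     fitted on the training decision values.}
#' }
#'
#' @param id learner identifier.
#' @param ... hyperparameters (e.g. \code{k} for \code{knn}, \code{cost} for
#'   \code{svm_linear}).
#' @return A \code{learner_spec} object.
#' @export
learner_spec <- function(id, ...) {
  hyper <- list(...)
  builder <- switch(id,
    logistic = learner_logistic,
    tree = learner_tree,
    nbayes = learner_nbayes,
    knn = learner_knn,
    svm_linear = learner_svm_linear,
    stop("unknown learner id: ", id)
  )
  structure(c(builder(hyper), list(id = id, hyper = hyper)),
            class = "learner_spec")
}

#' The default base-learner roster
#'
#' Five diverse, moderately performing learners: logistic regression,
#' decision tree, Gaussian naive Bayes, 5-nearest-neighbors, and a linear
#' SVM. The roster is configuration-driven; any list of [learner_spec()]
#' objects may be substituted.
#'
#' @return List of five \code{learner_spec}s.
#' @export
default_learners <- function() {
  list(
    learner_spec("logistic"),
    learner_spec("tree"),
    learner_spec("nbayes"),
    learner_spec("knn", k = 5),
    learner_spec("svm_linear")
  )
}

clip01 <- function(p) pmin(1, pmax(0, p))

learner_logistic <- function(hyper) {
  list(
    fit = function(X, y) {
      df <- as.data.frame(X)
      names(df) <- paste0("x", seq_len(ncol(X)))
      df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    score = function(fitted, X) {
      df <- as.data.frame(X)
      names(df) <- paste0("x", seq_len(ncol(X)))
      clip01(unname(stats::predict(fitted, newdata = df, type = "response")))
    }
  )
}

learner_tree <- function(hyper) {
  list(
    fit = function(X, y) {
      df <- as.data.frame(X)
      names(df) <- paste0("x", seq_len(ncol(X)))
      df$.y <- factor(y, levels = c(0, 1))
      rpart::rpart(.y ~ ., data = df, method = "class")
    },
    score = function(fitted, X) {
      df <- as.data.frame(X)
      names(df) <- paste0("x", seq_len(ncol(X)))
      p <- stats::predict(fitted, newdata = df, type = "prob")
      if ("1" %in% colnames(p)) unname(p[, "1"]) else rep(0, nrow(df))
    }
  )
}

learner_nbayes <- function(hyper) {
  list(
    fit = function(X, y) {
      df <- as.data.frame(X)
      names(df) <- paste0("x", seq_len(ncol(X)))
      m <- e1071::naiveBayes(df, factor(y, levels = c(0, 1)))
      # floor per-class standard deviations: zero-variance columns otherwise
      # yield degenerate Gaussian densities
      m$tables <- lapply(m$tables, function(tb) {
        tb[, 2] <- pmax(tb[, 2], 1e-6)
        tb
      })
      m
    },
    score = function(fitted, X) {
      df <- as.data.frame(X)
      names(df) <- paste0("x", seq_len(ncol(X)))
      p <- stats::predict(fitted, df, type = "raw")
      clip01(unname(p[, "1"]))
    }
  )
}

learner_knn <- function(hyper) {
  k <- if (is.null(hyper$k)) 5 else hyper$k
  # Vote-fraction kNN computed in-package: binary risk-factor rows are
  # heavily duplicated, so distance ties are the norm; ties are broken
  # deterministically by training-row order.
  list(
    fit = function(X, y) list(X = as.matrix(X), y = as.integer(y), k = k),
    score = function(fitted, X) {
      X <- as.matrix(X)
      k_eff <- min(fitted$k, nrow(fitted$X))
      r_train <- rowSums(fitted$X^2)
      out <- numeric(nrow(X))
      for (start in seq(1, nrow(X), by = 512)) {
        idx <- start:min(start + 511, nrow(X))
        blk <- X[idx, , drop = FALSE]
        d2 <- outer(rowSums(blk^2), r_train, "+") - 2 * tcrossprod(blk, fitted$X)
        out[idx] <- apply(d2, 1, function(dr) {
          mean(fitted$y[order(dr)[seq_len(k_eff)]] == 1L)
        })
      }
      out
    }
  )
}

learner_svm_linear <- function(hyper) {
  cost <- if (is.null(hyper$cost)) 1 else hyper$cost
  list(
    fit = function(X, y) {
      yf <- factor(y, levels = c(0, 1))
      m <- e1071::svm(as.matrix(X), yf, kernel = "linear", cost = cost,
                      scale = FALSE)
      dvm <- attr(stats::predict(m, as.matrix(X), decision.values = TRUE),
                  "decision.values")
      # decision-value sign convention depends on which class e1071 saw
      # first; orient so larger values mean PTB
      flip <- identical(colnames(dvm), "0/1")
      dv <- as.numeric(dvm)
      if (flip) dv <- -dv
      calib <- suppressWarnings(
        stats::glm(y ~ dv, family = stats::binomial(),
                   data = data.frame(y = as.integer(y == 1), dv = dv))
      )
      list(svm = m, calib = calib, flip = isTRUE(flip))
    },
    score = function(fitted, X) {
      dv <- as.numeric(attr(stats::predict(fitted$svm, as.matrix(X),
                                           decision.values = TRUE),
                            "decision.values"))
      if (fitted$flip) dv <- -dv
      clip01(unname(stats::predict(fitted$calib, newdata = data.frame(dv = dv),
                                   type = "response")))
    }
  )
}

# Meta-learner registry: the generalization-tier model trained on the
# level-1 input. "passthrough" averages the level-1 columns, which with a
# single column is the identity; it exists for degenerate configurations
# and equivalence checks.
make_meta_learner <- function(id, hyper = list()) {
  if (inherits(id, "learner_spec")) return(id)
  if (id == "passthrough") {
    return(structure(list(
      fit = function(X, y) list(),
      score = function(fitted, X) rowMeans(as.matrix(X)),
      id = "passthrough", hyper = list()
    ), class = "learner_spec"))
  }
  do.call(learner_spec, c(list(id = id), hyper))
}
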