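#' Rank features by absolute correlation with the class label
#'
#' Scores every feature by the absolute Pearson product-moment correlation
#' between its column and the 0/1 label vector. For a binary feature against
#' a binary label this is the phi coefficient, so one code path covers binary
#' and numeric features alike. Constant columns have undefined correlation
#' and score 0. Ties are broken by ascending feature index so the ranking is
#' deterministic.
#'
#' @param X numeric matrix with no missing values.
#' @param y 0/1 labels containing both classes.
#' @return A \code{feature_ranking}: data frame with columns \code{feature}
#'   (column index), \code{name}, \code{score}, sorted by non-increasing
#'   score.
#' @export
rank_by_correlation <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    stop("correlation ranking requires both classes in y")
  }
  scores <- vapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    if (stats::sd(v) == 0) return(0)
    abs(stats::cor(v, y))
  }, numeric(1))
  ord <- order(-scores, seq_along(scores))
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("f", seq_len(ncol(X)))
  structure(
    data.frame(feature = ord, name = nm[ord], score = scores[ord],
               stringsAsFactors = FALSE),
    class = c("feature_ranking", "data.frame")
  )
}

#' Select the top-k ranked features
#'
#' @param ranking a [rank_by_correlation()] result.
#' @param k number of features to keep.
#' @return Integer vector of the first \code{k} feature indices, in rank
#'   order.
#' @export
select_top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (k > nrow(ranking)) {
    stop("k (", k, ") exceeds the number of ranked features (", nrow(ranking), ")")
  }
  if (k <= 0) return(integer(0))
  ranking$feature[seq_len(k)]
}
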