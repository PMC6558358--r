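#' Default pipeline configuration
#'
#' One nested list drives preprocessing, the tier rosters, and the
#' evaluation protocol. Keys:
#' \describe{
#'   \item{smote}{\code{enabled}, neighbor count \code{k} (default 5),
#'     \code{scope} (\code{"train"}: balance the training partition only,
#'     the default; \code{"full"}: balance the whole dataset before
#'     splitting), \code{round_binary} (round synthetic binary values).}
#'   \item{outlier}{\code{enabled}; \code{min_count} (\code{NULL} means
#'     \code{max(2, ceiling(0.001 n))}).}
#'   \item{select}{\code{k_meta} raw features appended at the
#'     generalization tier (default 3); \code{k_outlier} screening features
#'     (default 5).}
#'   \item{n_folds}{base-tier folds (default 10).}
#'   \item{learners, schemes, meta_learner}{rosters; \code{NULL} means the
#'     package defaults.}
#' }
#'
#' @param ... replacements for top-level keys.
#' @return The configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    smote = list(enabled = TRUE, k = 5, scope = "train", round_binary = FALSE),
    outlier = list(enabled = TRUE, min_count = NULL),
    select = list(k_meta = 3, k_outlier = 5),
    n_folds = 10,
    learners = NULL,
    schemes = NULL,
    meta_learner = "logistic"
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  cfg
}
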