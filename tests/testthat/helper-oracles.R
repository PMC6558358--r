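# Independent oracles used to check the implementation against first
# principles. These deliberately share no code with the package internals.

# confusion matrix by explicit enumeration
oracle_confusion <- function(y_true, y_pred) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(y_true)) {
    if (y_true[i] == 1 && y_pred[i] == 1) tp <- tp + 1L
    else if (y_true[i] == 0 && y_pred[i] == 1) fp <- fp + 1L
    else if (y_true[i] == 0 && y_pred[i] == 0) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# AUC as the Mann-Whitney pairwise concordance statistic (ties count half)
oracle_auc <- function(y_true, y_score) {
  pos <- y_score[y_true == 1]
  neg <- y_score[y_true == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# modal label by direct counting, ties to 1
oracle_majority <- function(labels) {
  ones <- sum(labels == 1)
  zeros <- sum(labels == 0)
  if (ones > zeros) 1 else if (zeros > ones) 0 else 1
}

# Pearson correlation from the raw definition (no stats::cor)
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  if (den == 0) return(NA_real_)
  num / den
}

# small helper dataset with mixed criticality for data-model tests
tiny_meta <- function() {
  feature_meta(
    name = c("p1", "p2", "s1", "s2"),
    criticality = c("primary", "primary", "secondary", "secondary"),
    dtype = "binary",
    default_value = 0
  )
}

tiny_dataset <- function(n = 40, seed = 7) {
  withr::with_seed(seed, {
    X <- matrix(rbinom(n * 4, 1, 0.4), n, 4)
    y <- as.integer(runif(n) < plogis(-1 + 2 * X[, 1] + X[, 2]))
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    risk_dataset(X, y, tiny_meta())
  })
}
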