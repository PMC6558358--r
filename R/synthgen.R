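#' Configuration for the synthetic risk-factor generator
#'
#' Emulates the structure of a masked obstetric risk-factor registry:
#' independent binary risk factors split into primary (critical, strong) and
#' secondary (weaker) groups, a logistic latent model for the preterm-birth
#' probability, label noise, sporadic missing cells, and class imbalance
#' skewed toward term birth so PTB is the minority class.
#'
#' Defaults: 2600 patients, 8 primary and 12 secondary factors, primary
#' log-odds effects descending 1.5 to 0.4, secondary 0.3 to 0.05 (every
#' primary effect exceeds every secondary effect), intercept -3.5 (PTB
#' prevalence around 0.29 by Monte-Carlo, so PTB is clearly the minority),
#' factor prevalences evenly spaced 0.30 down to 0.05, 2% label flips, 1%
#' missing cells.
#'
#' @param n instances.
#' @param n_primary,n_secondary factor counts per criticality group.
#' @param primary_weights,secondary_weights log-odds effect sizes.
#' @param intercept log-odds baseline; negative values keep PTB the
#'   minority.
#' @param factor_prevalences per-factor Bernoulli rates (recycled).
#' @param label_noise probability of flipping a generated label.
#' @param missing_rate per-cell missingness probability (labels never go
#'   missing).
#' @param seed integer seed.
#' @return A validated \code{generator_config} list.
#' @export
generator_config <- function(n = 2600, n_primary = 8, n_secondary = 12,
                             primary_weights = seq(1.5, 0.4, length.out = n_primary),
                             secondary_weights = seq(0.3, 0.05, length.out = n_secondary),
                             intercept = -3.5,
                             factor_prevalences = seq(0.30, 0.05,
                                                      length.out = n_primary + n_secondary),
                             label_noise = 0.02, missing_rate = 0.01,
                             seed = 1) {
  cfg <- list(n = as.integer(n), n_primary = as.integer(n_primary),
              n_secondary = as.integer(n_secondary),
              primary_weights = as.numeric(primary_weights),
              secondary_weights = as.numeric(secondary_weights),
              intercept = as.numeric(intercept),
              factor_prevalences = rep_len(as.numeric(factor_prevalences),
                                           n_primary + n_secondary),
              label_noise = as.numeric(label_noise),
              missing_rate = as.numeric(missing_rate),
              seed = as.integer(seed))
  if (cfg$n_primary < 1 || cfg$n_secondary < 1) {
    stop("need at least one primary and one secondary factor")
  }
  if (length(cfg$primary_weights) != cfg$n_primary ||
      length(cfg$secondary_weights) != cfg$n_secondary) {
    stop("weight vector lengths must match factor counts")
  }
  rates <- c(cfg$factor_prevalences, cfg$label_noise, cfg$missing_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (min(cfg$primary_weights) <= max(cfg$secondary_weights)) {
    stop("every primary weight must exceed every secondary weight")
  }
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic risk-factor dataset
#'
#' Features are drawn as independent Bernoulli variables; the latent PTB
#' probability is \code{plogis(intercept + sum(w_j x_j))}; labels are
#' Bernoulli draws from it, then flipped with probability
#' \code{label_noise}; missing cells are injected at \code{missing_rate}
#' (never in the label). The generator guarantees that all four clinical
#' cases occur — (risk factors, PTB), (no risk factors, PTB), (risk
#' factors, TB), (no risk factors, TB), where "risk factors" means at least
#' one active primary factor — by redrawing the labels up to 100 times and
#' erroring if the mix is unattainable.
#'
#' @param config a [generator_config()].
#' @return A [risk_dataset()] with criticality metadata and
#'   \code{default_value = 0} for every factor.
#' @export
generate_risk_data <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  p <- config$n_primary + config$n_secondary
  meta <- feature_meta(
    name = c(sprintf("primary_%02d", seq_len(config$n_primary)),
             sprintf("secondary_%02d", seq_len(config$n_secondary))),
    criticality = rep(c("primary", "secondary"),
                      c(config$n_primary, config$n_secondary)),
    dtype = "binary", default_value = 0
  )
  weights <- c(config$primary_weights, config$secondary_weights)
  withr::with_seed(config$seed, {
    X <- matrix(stats::rbinom(config$n * p, 1,
                              rep(config$factor_prevalences, each = config$n)),
                config$n, p)
    prob <- stats::plogis(config$intercept + as.vector(X %*% weights))
    has_risk <- rowSums(X[, seq_len(config$n_primary), drop = FALSE]) > 0
    y <- NULL
    for (attempt in seq_len(100)) {
      cand <- stats::rbinom(config$n, 1, prob)
      flip <- stats::rbinom(config$n, 1, config$label_noise) == 1
      cand[flip] <- 1L - cand[flip]
      if (all(c("0/0", "0/1", "1/0", "1/1") %in%
              unique(paste(as.integer(has_risk), cand, sep = "/")))) {
        y <- cand
        break
      }
    }
    if (is.null(y)) {
      stop("could not obtain all four (risk, outcome) cases in 100 attempts; ",
           "check intercept/weights/noise")
    }
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(config$n * p) < config$missing_rate,
                     config$n, p)
      X[miss] <- NA_real_
    }
    risk_dataset(X, y, meta)
  })
}

#' Generate a noise-free, perfectly separable dataset
#'
#' The label is the logical OR of the first two primary factors; there is no
#' label noise and no missingness, so any reasonable classifier can reach
#' perfect held-out accuracy. Intended as an exactness fixture.
#'
#' @param n instances (at least 20).
#' @param seed integer seed.
#' @return A [risk_dataset()] with 4 primary and 4 secondary binary factors.
#' @export
generate_separable <- function(n, seed = 1) {
  stopifnot(n >= 20)
  n_feat <- 8
  meta <- feature_meta(
    name = c(sprintf("primary_%02d", 1:4), sprintf("secondary_%02d", 1:4)),
    criticality = rep(c("primary", "secondary"), each = 4),
    dtype = "binary", default_value = 0
  )
  withr::with_seed(seed, {
    X <- matrix(stats::rbinom(n * n_feat, 1, 0.3), n, n_feat)
    y <- as.integer(X[, 1] == 1 | X[, 2] == 1)
    risk_dataset(X, y, meta)
  })
}
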