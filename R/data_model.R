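#' Construct feature metadata
#'
#' Feature metadata records, for every column of a risk-factor table, its
#' name, its criticality (\code{"primary"} features are the clinically
#' critical risk factors, \code{"secondary"} the less critical ones), its
#' type, and the default value used to impute missing entries of
#' non-critical features.
#'
#' @param name character vector of unique feature names.
#' @param criticality character vector, each \code{"primary"} or
#'   \code{"secondary"}.
#' @param dtype character vector, each \code{"binary"} or \code{"numeric"}.
#' @param default_value numeric vector of imputation defaults; must be 0 or 1
#'   for binary features.
#' @return A \code{data.frame} with one row per feature and columns
#'   \code{name}, \code{criticality}, \code{dtype}, \code{default_value}.
#' @export
feature_meta <- function(name, criticality, dtype = "binary", default_value = 0) {
  n <- length(name)
  meta <- data.frame(
    name = as.character(name),
    criticality = rep_len(as.character(criticality), n),
    dtype = rep_len(as.character(dtype), n),
    default_value = rep_len(as.numeric(default_value), n),
    stringsAsFactors = FALSE
  )
  validate_feature_meta(meta)
  meta
}

validate_feature_meta <- function(meta) {
  stopifnot(is.data.frame(meta))
  required <- c("name", "criticality", "dtype", "default_value")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    stop("feature metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$name)) {
    stop("feature names must be unique; duplicated: ",
         paste(unique(meta$name[duplicated(meta$name)]), collapse = ", "))
  }
  if (!all(meta$criticality %in% c("primary", "secondary"))) {
    stop("criticality must be 'primary' or 'secondary'")
  }
  if (!all(meta$dtype %in% c("binary", "numeric"))) {
    stop("dtype must be 'binary' or 'numeric'")
  }
  bad <- meta$dtype == "binary" & !(meta$default_value %in% c(0, 1))
  if (any(bad)) {
    stop("default_value must be 0 or 1 for binary features: ",
         paste(meta$name[bad], collapse = ", "))
  }
  invisible(meta)
}

#' Construct a risk-factor dataset
#'
#' The central container for this package: a numeric feature matrix (rows are
#' patients), a binary outcome vector with 1 = preterm birth (PTB, the
#' positive and typically minority class) and 0 = term birth (TB), and
#' per-feature metadata. Missing feature values may be present (as \code{NA})
#' before preprocessing; labels are never missing.
#'
#' @param X numeric matrix, one row per instance.
#' @param y outcome vector of 0/1 (or \code{"TB"}/\code{"PTB"} strings, which
#'   are mapped to 0/1).
#' @param meta feature metadata (see [feature_meta()]); one row per column
#'   of \code{X}.
#' @return An object of class \code{risk_dataset}: a list with elements
#'   \code{X}, \code{y}, \code{meta}.
#' @export
risk_dataset <- function(X, y, meta) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- encode_labels(y)
  validate_feature_meta(meta)
  if (nrow(X) != length(y)) {
    stop("nrow(X) must equal length(y)")
  }
  if (ncol(X) != nrow(meta)) {
    stop("ncol(X) must equal nrow(meta)")
  }
  if (anyNA(y)) stop("labels must not be missing")
  colnames(X) <- meta$name
  structure(list(X = X, y = y, meta = meta), class = "risk_dataset")
}

# Map outcome codings to the fixed internal convention PTB = 1, TB = 0.
encode_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    out <- ifelse(y %in% c("PTB", "1"), 1L,
                  ifelse(y %in% c("TB", "NB", "0"), 0L, NA_integer_))
    if (anyNA(out) && !anyNA(y)) {
      bad <- unique(y[is.na(out)])
      stop("outcome values outside {TB, PTB, 0, 1}: ", paste(bad, collapse = ", "))
    }
    return(out)
  }
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L), na.rm = TRUE)) {
    stop("outcome values outside {TB, PTB, 0, 1}")
  }
  y
}

#' @export
print.risk_dataset <- function(x, ...) {
  cat(sprintf("risk_dataset: %d instances x %d features\n", nrow(x$X), ncol(x$X)))
  cat(sprintf("  PTB (positive): %d   TB: %d   missing cells: %d\n",
              sum(x$y == 1), sum(x$y == 0), sum(is.na(x$X))))
  cat(sprintf("  primary features: %d   secondary features: %d\n",
              sum(x$meta$criticality == "primary"),
              sum(x$meta$criticality == "secondary")))
  invisible(x)
}

#' Read a dataset schema
#'
#' The schema file (YAML or JSON) declares the outcome column name and the
#' per-feature metadata; feature criticality is declared here, never inferred
#' from the data.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} schema file.
#' @return A list with elements \code{outcome} (column name) and \code{meta}
#'   (a feature-metadata data frame).
#' @examples
#' \dontrun{
#' schema <- read_schema("schema.yaml")
#' data <- read_dataset("data.csv", schema)
#' }
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$outcome) || is.null(raw$features)) {
    stop("schema must declare 'outcome' and 'features'")
  }
  feats <- raw$features
  meta <- feature_meta(
    name = vapply(feats, function(f) f$name, character(1)),
    criticality = vapply(feats, function(f) f$criticality, character(1)),
    dtype = vapply(feats, function(f) if (is.null(f$dtype)) "binary" else f$dtype, character(1)),
    default_value = vapply(feats, function(f) {
      if (is.null(f$default_value)) 0 else as.numeric(f$default_value)
    }, numeric(1))
  )
  list(outcome = raw$outcome, meta = meta)
}

#' Write a dataset schema
#'
#' @param meta feature metadata data frame.
#' @param outcome outcome column name.
#' @param path output path (written as YAML).
#' @return \code{path}, invisibly.
#' @export
write_schema <- function(meta, outcome, path) {
  validate_feature_meta(meta)
  features <- lapply(seq_len(nrow(meta)), function(i) {
    list(name = meta$name[i],
         criticality = meta$criticality[i],
         dtype = meta$dtype[i],
         default_value = meta$default_value[i])
  })
  yaml::write_yaml(list(outcome = outcome, features = features), path)
  invisible(path)
}

#' Read a risk-factor dataset from CSV
#'
#' Reads an RFC-4180 CSV with a header row. All schema features and the
#' outcome column must be present; unexpected columns are an error. Empty
#' cells and the string \code{"NA"} are flagged as missing (never silently
#' zeroed); rows are never dropped. Outcome values must be \code{TB},
#' \code{PTB}, \code{0} or \code{1}.
#'
#' @param path CSV file path.
#' @param schema a schema as returned by [read_schema()], or a path to a
#'   schema file.
#' @param require_outcome when \code{FALSE}, a CSV without the outcome
#'   column is accepted (labels set to 0) — useful for prediction-time
#'   input.
#' @return A [risk_dataset()].
#' @export
read_dataset <- function(path, schema, require_outcome = TRUE) {
  if (is.character(schema)) schema <- read_schema(schema)
  if (!file.exists(path)) stop("dataset file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = c("", "NA"))
  expected <- c(schema$meta$name, schema$outcome)
  unknown <- setdiff(names(df), expected)
  if (length(unknown) > 0) {
    stop("schema error: unknown column(s) in CSV: ", paste(unknown, collapse = ", "))
  }
  absent <- setdiff(schema$meta$name, names(df))
  if (length(absent) > 0) {
    stop("schema error: column(s) missing from CSV: ", paste(absent, collapse = ", "))
  }
  if (!schema$outcome %in% names(df)) {
    if (require_outcome) {
      stop("schema error: outcome column '", schema$outcome, "' missing from CSV")
    }
    y <- rep(0L, nrow(df))
  } else {
    y_raw <- df[[schema$outcome]]
    if (anyNA(y_raw)) stop("parse error: missing outcome value")
    y <- encode_labels(y_raw)
  }
  X <- matrix(NA_real_, nrow = nrow(df), ncol = nrow(schema$meta),
              dimnames = list(NULL, schema$meta$name))
  for (nm in schema$meta$name) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (any(is.na(v) & !is.na(df[[nm]]))) {
      stop("parse error: non-numeric value in feature column '", nm, "'")
    }
    X[, nm] <- v
  }
  risk_dataset(X, y, schema$meta)
}

#' Write a risk-factor dataset to CSV
#'
#' Labels are written as \code{PTB}/\code{TB}; missing feature cells are
#' written as empty fields. A complete dataset round-trips bit-exactly
#' through [read_dataset()].
#'
#' @param data a [risk_dataset()].
#' @param path output CSV path.
#' @param outcome name for the outcome column (default \code{"birth"}).
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(data, path, outcome = "birth") {
  stopifnot(inherits(data, "risk_dataset"))
  df <- as.data.frame(data$X)
  df[[outcome]] <- ifelse(data$y == 1, "PTB", "TB")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write per-patient predictions to CSV
#'
#' @param path output path.
#' @param ids instance identifiers.
#' @param scores PTB probabilities in \code{[0, 1]}.
#' @param labels hard 0/1 labels.
#' @return \code{path}, invisibly.
#' @export
write_predictions <- function(path, ids, scores, labels) {
  if (length(ids) != length(scores) || length(scores) != length(labels)) {
    stop("ids, scores and labels must have equal lengths")
  }
  df <- data.frame(id = ids, ptb_score = as.numeric(scores),
                   ptb_label = as.integer(labels))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read predictions written by [write_predictions()]
#'
#' @param path CSV path with columns \code{id}, \code{ptb_score},
#'   \code{ptb_label}.
#' @return A data frame with those three columns.
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  required <- c("id", "ptb_score", "ptb_label")
  if (!all(required %in% names(df))) {
    stop("predictions file must have columns id, ptb_score, ptb_label")
  }
  df
}
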