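## Feature tables, prediction tables, and their delimited-text forms.

#' Construct a feature table
#'
#' The universal classifier input: an n x d numeric matrix with sample ids
#' and optional class labels. The class set is the sorted unique labels; this
#' ordering is used everywhere downstream (state matrices, score rows,
#' reports).
#'
#' @param X Numeric matrix (n samples x d features).
#' @param sample_ids Character vector of length n (default "s1".."sn").
#' @param labels Optional character vector of class labels, length n.
#' @return A `feature_table`: list with `X`, `sample_ids`, `labels`, `classes`.
#' @export
feature_table <- function(X, sample_ids = NULL, labels = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 1L || ncol(X) < 1L)
    rawalk_stop("feature table needs at least 1 sample and 1 feature")
  if (anyNA(X) || !all(is.finite(X)))
    rawalk_stop("feature table contains missing or non-finite values")
  sample_ids <- as.character(sample_ids %||% paste0("s", seq_len(nrow(X))))
  if (length(sample_ids) != nrow(X))
    rawalk_stop("sample_ids length does not match row count")
  if (anyDuplicated(sample_ids)) {
    warning("duplicate sample ids; suffixing to make unique", call. = FALSE)
    sample_ids <- make.unique(sample_ids, sep = "_dup")
  }
  rownames(X) <- sample_ids
  classes <- NULL
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(X))
      rawalk_stop("labels length does not match row count")
    classes <- sort(unique(labels))
  }
  structure(list(X = X, sample_ids = sample_ids, labels = labels,
                 classes = classes),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$X), " samples x ", ncol(x$X), " features",
      sep = "")
  if (!is.null(x$labels))
    cat("; ", length(x$classes), " classes (",
        paste(x$classes, collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$X)

#' Read a delimited feature table
#'
#' Accepts the common "id, features..., label" layout (e.g. the UCI yeast
#' file: name, 8 numeric attributes, localization class). The first column is
#' the sample id; when `labeled` the last column is the class label,
#' otherwise every non-id column is a feature.
#'
#' @param path Path to a delimited text file.
#' @param labeled Logical; treat the last column as a class label
#'   (default `TRUE`).
#' @param delimiter Field delimiter; the default `""` splits on any
#'   whitespace (accepting the UCI layout verbatim), use `","` for CSV.
#' @param header Logical; whether the file has a header row (default `FALSE`).
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, labeled = TRUE, delimiter = "",
                               header = FALSE) {
  if (!file.exists(path)) rawalk_stop("feature table not found: ", path)
  df <- utils::read.table(path, sep = delimiter, header = header,
                          stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = "character")
  if (nrow(df) == 0L) rawalk_stop("empty feature table: ", path)
  if (ncol(df) < (2L + as.integer(labeled)))
    rawalk_stop("feature table '", path, "' has too few columns")
  ids <- df[[1L]]
  labels <- NULL
  feat_cols <- 2L:ncol(df)
  if (labeled) {
    labels <- df[[ncol(df)]]
    feat_cols <- feat_cols[-length(feat_cols)]
  }
  X <- matrix(NA_real_, nrow(df), length(feat_cols))
  for (j in seq_along(feat_cols)) {
    vals <- suppressWarnings(as.numeric(df[[feat_cols[j]]]))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1L]
      rawalk_stop("non-numeric feature value '", df[[feat_cols[j]]][bad],
                  "' at row ", bad, ", column ", feat_cols[j], " of ", path)
    }
    X[, j] <- vals
  }
  colnames(X) <- paste0("f", seq_along(feat_cols))
  feature_table(X, sample_ids = ids, labels = labels)
}

#' Write a feature table as delimited text
#'
#' Writes "id, features..., label" rows, the layout [read_feature_table()]
#' reads back.
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, delimiter = "\t") {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(id = table$sample_ids,
                   format(table$X, trim = TRUE, digits = 15),
                   stringsAsFactors = FALSE)
  if (!is.null(table$labels)) df$label <- table$labels
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a prediction table
#'
#' One row per test sample: the predicted class plus the per-class walk
#' arrival scores (columns in class-set order, matching the score matrix).
#'
#' @param sample_ids Character vector of test sample ids.
#' @param predicted Character vector of predicted classes.
#' @param scores m x q score matrix (classes x samples), rows named by class.
#' @return A `prediction_table` object.
#' @export
prediction_table <- function(sample_ids, predicted, scores) {
  scores <- as.matrix(scores)
  q <- length(sample_ids)
  if (q == 0L) rawalk_stop("empty prediction table")
  if (length(predicted) != q || ncol(scores) != q)
    rawalk_stop("prediction table parts disagree on sample count")
  structure(list(sample_ids = as.character(sample_ids),
                 predicted = as.character(predicted), scores = scores),
            class = "prediction_table")
}

#' Write predictions as tab-separated text
#'
#' Output columns: `id`, `predicted`, then one `score_<class>` column per
#' class in class-set order, each formatted to six decimals.
#'
#' @param table A [prediction_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(table, path) {
  stopifnot(inherits(table, "prediction_table"))
  if (length(table$sample_ids) == 0L) rawalk_stop("empty prediction table")
  classes <- rownames(table$scores) %||% paste0("c", seq_len(nrow(table$scores)))
  sc <- t(table$scores)
  sc_chr <- matrix(sprintf("%.6f", sc), nrow = nrow(sc), ncol = ncol(sc))
  df <- data.frame(id = table$sample_ids, predicted = table$predicted,
                   sc_chr, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("id", "predicted", paste0("score_", classes))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a predictions file
#'
#' @param path Path written by [write_predictions()].
#' @return A [prediction_table()].
#' @export
read_predictions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  score_cols <- grep("^score_", names(df))
  scores <- t(as.matrix(df[, score_cols, drop = FALSE]))
  rownames(scores) <- sub("^score_", "", names(df)[score_cols])
  prediction_table(df$id, df$predicted, scores)
}
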