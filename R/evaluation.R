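## Evaluation harness: stratified k-fold CV, per-class metrics, one-vs-rest
## ROC/AUC, laziness/steps sweeps and the gamma grid search.

#' The canonical gamma search grid
#'
#' The 12 odd powers of two from 2^-11 to 2^11, the standard search space
#' for the RBF width gamma = 1/(2 sigma^2).
#'
#' @return Numeric vector of length 12.
#' @export
gamma_grid <- function() 2^seq(-11, 11, by = 2)

#' Stratified k-fold partition
#'
#' Shuffles each class with the seeded generator and deals its members
#' round-robin into k folds, so every fold's class proportions match the
#' global proportions within rounding. Classes with fewer members than k
#' appear in only some folds (warned).
#'
#' @param labels Character vector of class labels.
#' @param k Number of folds, 2 <= k <= n.
#' @param seed Integer seed.
#' @return List of k disjoint integer index vectors covering 1..n.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L) rawalk_stop("k must be at least 2")
  if (k > n) rawalk_stop("k = ", k, " exceeds the sample count ", n)
  folds <- vector("list", k)
  with_seed(seed, {
    offset <- 0L
    for (cl in sort(unique(labels))) {
      members <- which(labels == cl)
      if (length(members) < k)
        warning("class '", cl, "' has fewer members (", length(members),
                ") than folds (", k, ")", call. = FALSE)
      perm <- if (length(members) > 1L) sample(members) else members
      for (i in seq_along(perm)) {
        f <- ((i - 1L + offset) %% k) + 1L
        folds[[f]] <- c(folds[[f]], perm[[i]])
      }
      offset <- (offset + length(perm)) %% k
    }
  })
  lapply(folds, sort)
}

#' Confusion matrix
#'
#' counts\[a, b\] = number of samples with true class a predicted as b.
#'
#' @param true_labels,predicted_labels Equal-length character vectors.
#' @param class_order Ordered class names covering both vectors.
#' @return m x m integer matrix with `class_order` dimnames.
#' @export
confusion <- function(true_labels, predicted_labels,
                      class_order = sort(unique(c(true_labels,
                                                  predicted_labels)))) {
  if (length(true_labels) == 0L) rawalk_stop("empty label vectors")
  if (length(true_labels) != length(predicted_labels))
    rawalk_stop("label vectors differ in length")
  if (!all(c(true_labels, predicted_labels) %in% class_order))
    rawalk_stop("labels outside class_order")
  tab <- table(factor(true_labels, levels = class_order),
               factor(predicted_labels, levels = class_order))
  m <- matrix(as.integer(tab), nrow = length(class_order),
              dimnames = list(true = class_order, predicted = class_order))
  m
}

#' Per-class metrics from a confusion matrix
#'
#' Sensitivity (recall) TP/(TP+FN), precision TP/(TP+FP), specificity
#' TN/(TN+FP) per class, plus total accuracy = trace/total. Precision for a
#' class never predicted is undefined and stored as `NA` (rendered "-" in
#' reports).
#'
#' @param cm Confusion matrix from [confusion()].
#' @param fold_accuracies Optional per-fold accuracies whose standard
#'   deviation is reported alongside the total accuracy.
#' @return A `class_metrics` object: data frame `per_class` plus
#'   `total_accuracy` and `accuracy_sd`.
#' @export
class_metrics <- function(cm, fold_accuracies = NULL) {
  if (length(cm) == 0L || sum(cm) == 0L) rawalk_stop("empty confusion matrix")
  classes <- rownames(cm)
  total <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  per_class <- data.frame(class = classes, support = rowSums(cm),
                          sensitivity = sens, precision = prec,
                          specificity = spec, row.names = NULL,
                          stringsAsFactors = FALSE)
  structure(list(per_class = per_class,
                 total_accuracy = sum(tp) / total,
                 accuracy_sd = if (!is.null(fold_accuracies))
                   stats::sd(fold_accuracies) else NA_real_,
                 fold_accuracies = fold_accuracies,
                 confusion = cm),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, digits = 4, ...) {
  df <- x$per_class
  fmt <- function(v) ifelse(is.na(v), "-", formatC(v, digits = digits,
                                                   format = "f"))
  out <- data.frame(class = df$class, support = df$support,
                    sensitivity = fmt(df$sensitivity),
                    precision = fmt(df$precision),
                    specificity = fmt(df$specificity))
  print(out, row.names = FALSE)
  cat(sprintf("Total accuracy: %.4f", x$total_accuracy))
  if (!is.na(x$accuracy_sd))
    cat(sprintf(" +/- %.4f (SD across folds)", x$accuracy_sd))
  cat("\n")
  invisible(x)
}

#' Write a metrics report as TSV
#'
#' @param metrics A [class_metrics()] object.
#' @param path Output path. Undefined rates are written as "-".
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  df <- metrics$per_class
  for (col in c("sensitivity", "precision", "specificity"))
    df[[col]] <- ifelse(is.na(df[[col]]), "-", sprintf("%.6f", df[[col]]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("# total_accuracy\t%.6f\n# accuracy_sd\t%s\n",
              metrics$total_accuracy,
              ifelse(is.na(metrics$accuracy_sd), "-",
                     sprintf("%.6f", metrics$accuracy_sd))),
      file = path, append = TRUE)
  invisible(path)
}

#' One-vs-rest ROC curves and AUC per class
#'
#' For each class j, the score row f_j. is thresholded at every distinct
#' value (ties grouped) to sweep the true-positive rate against the
#' false-positive rate of "class j vs the rest"; AUC by the trapezoid rule.
#' A class absent from the true labels gets `NA` AUC.
#'
#' @param scores m x q score matrix (rows = classes).
#' @param true_labels Length-q character vector.
#' @param class_order Class names matching the score rows.
#' @return A `roc_result`: per class a list with `fpr`, `tpr`, `thresholds`,
#'   `auc`.
#' @export
roc_one_vs_rest <- function(scores, true_labels,
                            class_order = rownames(scores)) {
  scores <- as.matrix(scores)
  if (ncol(scores) != length(true_labels))
    rawalk_stop("score columns do not align with labels")
  res <- lapply(seq_along(class_order), function(j) {
    pos <- true_labels == class_order[[j]]
    s <- scores[j, ]
    if (!any(pos) || all(pos))
      return(list(fpr = NA_real_, tpr = NA_real_, thresholds = NA_real_,
                  auc = NA_real_))
    thr <- sort(unique(s), decreasing = TRUE)
    tpr <- c(0, vapply(thr, function(th) mean(s[pos] >= th), numeric(1)))
    fpr <- c(0, vapply(thr, function(th) mean(s[!pos] >= th), numeric(1)))
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
    list(fpr = fpr, tpr = tpr, thresholds = c(Inf, thr), auc = auc)
  })
  names(res) <- class_order
  structure(res, class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  aucs <- vapply(x, `[[`, numeric(1), "auc")
  cat("<roc_result> one-vs-rest AUC per class:\n")
  for (cl in names(aucs))
    cat(sprintf("  %s: %s\n", cl,
                ifelse(is.na(aucs[[cl]]), "-", sprintf("%.4f", aucs[[cl]]))))
  invisible(x)
}

#' Stratified k-fold cross-validation of the walk classifier
#'
#' Fits on k-1 folds, scores the held-out fold, and pools predictions and
#' scores over all folds. Total accuracy is reported over the pooled
#' held-out predictions with the standard deviation of the per-fold
#' accuracies; ROC/AUC are computed from the pooled score matrix.
#'
#' @param table A labeled [feature_table()].
#' @param k Number of folds (default 10).
#' @param gamma,alpha,t,lambda_reg Model hyperparameters.
#' @param seed Seed controlling the fold partition and the per-fit split
#'   (fits use `seed + fold`).
#' @param splits Splits averaged per fit (see [rawalk_fit()]).
#' @return List with `metrics` ([class_metrics()]), `roc`
#'   ([roc_one_vs_rest()]), `confusion`, `predicted`, `scores`, `folds`.
#' @export
cross_validate <- function(table, k = 10L, gamma = 1, alpha = 0.75, t = 5L,
                           lambda_reg = 1e-4, seed = 1L, splits = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) rawalk_stop("cross-validation needs labels")
  n <- nrow(table$X)
  folds <- stratified_kfold(table$labels, k = k, seed = seed)
  class_order <- table$classes
  predicted <- character(n)
  scores <- matrix(NA_real_, length(class_order), n,
                   dimnames = list(class_order, table$sample_ids))
  fold_acc <- numeric(length(folds))
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    if (length(test_idx) == 0L) next
    train_idx <- setdiff(seq_len(n), test_idx)
    train_tab <- feature_table(table$X[train_idx, , drop = FALSE],
                               sample_ids = table$sample_ids[train_idx],
                               labels = table$labels[train_idx])
    model <- rawalk_fit(train_tab, gamma = gamma, alpha = alpha, t = t,
                        lambda_reg = lambda_reg, seed = seed + f,
                        splits = splits)
    sc <- predict_scores(model, table$X[test_idx, , drop = FALSE])
    ## fold models may see fewer classes than the full table
    scores[model$class_order, test_idx] <- sc
    scores[setdiff(class_order, model$class_order), test_idx] <- 0
    predicted[test_idx] <- predict_labels(sc, model$class_order)
    fold_acc[f] <- mean(predicted[test_idx] == table$labels[test_idx])
  }
  cm <- confusion(table$labels, predicted, class_order)
  metrics <- class_metrics(cm, fold_accuracies = fold_acc)
  roc <- roc_one_vs_rest(scores, table$labels, class_order)
  list(metrics = metrics, roc = roc, confusion = cm, predicted = predicted,
       scores = scores, folds = folds)
}

#' Accuracy sweep over laziness and walk length
#'
#' Cross-validated total accuracy for every (alpha, t) combination with
#' t = 1..t_max, the grid behind the accuracy-vs-steps curves.
#'
#' @param table A labeled [feature_table()].
#' @param alphas Laziness values (default the canonical five:
#'   0.05, 0.25, 0.5, 0.75, 0.95).
#' @param t_max Maximum number of walk steps (default 30).
#' @param k,gamma,lambda_reg,seed As in [cross_validate()].
#' @return Data frame with columns `alpha`, `t`, `accuracy`.
#' @export
parameter_sweep <- function(table, alphas = c(0.05, 0.25, 0.5, 0.75, 0.95),
                            t_max = 30L, k = 10L, gamma = 1,
                            lambda_reg = 1e-4, seed = 1L) {
  grid <- expand.grid(alpha = alphas, t = seq_len(t_max),
                      KEEP.OUT.ATTRS = FALSE)
  grid$accuracy <- mapply(function(a, tt) {
    cross_validate(table, k = k, gamma = gamma, alpha = a, t = tt,
                   lambda_reg = lambda_reg,
                   seed = seed)$metrics$total_accuracy
  }, grid$alpha, grid$t)
  grid[order(grid$alpha, grid$t), , drop = FALSE]
}

#' Grid search for the RBF width gamma
#'
#' Evaluates every gamma in [gamma_grid()] by k-fold cross-validation and
#' returns the one with the highest total accuracy (ties broken toward the
#' smaller gamma).
#'
#' @param table A labeled [feature_table()].
#' @param k,alpha,t,lambda_reg,seed As in [cross_validate()].
#' @param grid Candidate gammas (default [gamma_grid()]).
#' @return List with `best_gamma`, `best_accuracy`, and `results`
#'   (data frame gamma x accuracy).
#' @export
gamma_grid_search <- function(table, k = 10L, alpha = 0.75, t = 5L,
                              lambda_reg = 1e-4, seed = 1L,
                              grid = gamma_grid()) {
  grid <- sort(grid)
  acc <- vapply(grid, function(g) {
    cross_validate(table, k = k, gamma = g, alpha = alpha, t = t,
                   lambda_reg = lambda_reg,
                   seed = seed)$metrics$total_accuracy
  }, numeric(1))
  best <- which.max(acc)  # first max = smallest gamma on ties
  list(best_gamma = grid[[best]], best_accuracy = acc[[best]],
       results = data.frame(gamma = grid, accuracy = acc))
}
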