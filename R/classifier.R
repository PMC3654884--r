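## The RaWa classifier: state matrices, complementary-split training with
## loss-derived subset weights, and the regularized kernel prediction rule
## F(x) = Ytilde Q^t (K + lambda I)^+ k(X, x).

#' One-hot state matrix
#'
#' Encodes class labels as an m x n 0/1 matrix Y: column i is the one-hot
#' state of sample i, with y_ji = 1 iff sample i belongs to the j-th class
#' of `class_order`.
#'
#' @param labels Character vector of class labels.
#' @param class_order Ordered class names; every label must occur in it.
#' @return m x n 0/1 matrix with rownames `class_order`.
#' @export
one_hot_states <- function(labels, class_order) {
  if (length(labels) == 0L) rawalk_stop("empty label list")
  j <- match(labels, class_order)
  if (anyNA(j))
    rawalk_stop("label '", labels[which(is.na(j))[1L]],
                "' not in class_order")
  Y <- matrix(0, length(class_order), length(labels),
              dimnames = list(class_order, NULL))
  Y[cbind(j, seq_along(labels))] <- 1
  Y
}

#' Stratified half split of the training indices
#'
#' Partitions the samples into two complementary subsets S and T of similar
#' size, each holding about half of every class: per class, members are
#' shuffled with the seeded generator and dealt alternately. The starting
#' side alternates across odd-count classes so the subset sizes differ by at
#' most the number of such classes.
#'
#' @param labels Character vector of class labels.
#' @param seed Integer seed; same seed, same split.
#' @return List with integer index vectors `S` and `T` (disjoint, covering
#'   all samples).
#' @export
stratified_half_split <- function(labels, seed = 1L) {
  n <- length(labels)
  if (n < 2L) rawalk_stop("need at least 2 samples to split")
  S <- integer(0); T <- integer(0)
  with_seed(seed, {
    start_S <- TRUE
    for (cl in sort(unique(labels))) {
      members <- which(labels == cl)
      perm <- if (length(members) > 1L) sample(members) else members
      side1 <- perm[seq_along(perm) %% 2L == 1L]
      side2 <- perm[seq_along(perm) %% 2L == 0L]
      if (start_S) { S <- c(S, side1); T <- c(T, side2) }
      else         { T <- c(T, side1); S <- c(S, side2) }
      if (length(members) %% 2L == 1L) start_S <- !start_S
    }
  })
  list(S = sort(S), T = sort(T))
}

#' Cross-prediction losses of a complementary split
#'
#' Each half predicts the other with the walk classifier restricted to its
#' own similarity graph: F_S(T) = Y_S Q_S^t (W_S + lambda I)^+ w(S, T), and
#' the loss is the squared Frobenius distance to the other half's states,
#' eps_S = ||F_S(T) - Y_T||_F^2 (symmetrically for eps_T). Lower loss means
#' a more informative half.
#'
#' @param X n x d feature matrix.
#' @param Y m x n state matrix (see [one_hot_states()]).
#' @param S,T Disjoint integer index vectors covering 1..n.
#' @param gamma,alpha,t,lambda_reg Model hyperparameters (shared with the
#'   final model).
#' @return List with `eps_S` and `eps_T`, both non-negative.
#' @export
cross_prediction_loss <- function(X, Y, S, T, gamma = 1, alpha = 0.75,
                                  t = 5L, lambda_reg = 1e-4) {
  if (length(S) == 0L || length(T) == 0L)
    rawalk_stop("both subsets must be non-empty")
  loss_from <- function(A, B) {
    W_A <- rbf_kernel(X[A, , drop = FALSE], gamma = gamma)
    Q_A <- lazy_operator(transition_from_weights(W_A), alpha)
    Fhat <- Y[, A, drop = FALSE] %*% walk_power(Q_A, t) %*%
      regularized_pinv(W_A, lambda_reg)
    FAB <- Fhat %*% rbf_kernel(X[A, , drop = FALSE], X[B, , drop = FALSE],
                               gamma = gamma)
    sum((FAB - Y[, B, drop = FALSE])^2)
  }
  list(eps_S = loss_from(S, T), eps_T = loss_from(T, S))
}

#' Subset weights from cross-prediction losses
#'
#' alpha_S = eps_T / (eps_S + eps_T), alpha_T = eps_S / (eps_S + eps_T):
#' the half with the smaller loss gets the larger weight, and the weights
#' sum to 1. Both losses zero is taken as no evidence either way, (0.5, 0.5).
#'
#' @param eps_S,eps_T Non-negative losses.
#' @return List with `alpha_S` and `alpha_T`.
#' @export
split_weights <- function(eps_S, eps_T) {
  if (eps_S < 0 || eps_T < 0) rawalk_stop("losses must be non-negative")
  tot <- eps_S + eps_T
  if (tot == 0) return(list(alpha_S = 0.5, alpha_T = 0.5))
  list(alpha_S = eps_T / tot, alpha_T = eps_S / tot)
}

#' Total loss of a complementary split
#'
#' eps = eps_S * eps_T / (eps_S + eps_T), a harmonic-style combination never
#' exceeding the smaller of the two losses; 0 when either loss is 0.
#'
#' @param eps_S,eps_T Non-negative losses.
#' @return Non-negative scalar.
#' @export
total_loss <- function(eps_S, eps_T) {
  if (eps_S < 0 || eps_T < 0) rawalk_stop("losses must be non-negative")
  if (eps_S + eps_T == 0) return(0)
  eps_S * eps_T / (eps_S + eps_T)
}

#' Fit the random-walk classifier
#'
#' Training proceeds in three stages. (1) A stratified half split gives
#' complementary subsets S and T; their cross-prediction losses weight each
#' subset's contribution, scaling column i of the state matrix by alpha_S if
#' i is in S and alpha_T otherwise (Ytilde). (2) The RBF kernel K doubles as
#' the complete-graph weight matrix; its row-normalization, made lazy with
#' laziness `alpha`, is raised to the t-th power. (3) The prediction
#' projection Ytilde Q^t (K + lambda I)^+ is precomputed, so scoring a test
#' point x reduces to a matrix product with its similarity column k(X, x).
#'
#' @param table A labeled [feature_table()].
#' @param gamma RBF kernel width (default 1).
#' @param alpha Walk laziness in \[0, 1\] (default 0.75).
#' @param t Number of walk steps (default 5).
#' @param lambda_reg Kernel ridge regularization (default 1e-4).
#' @param seed Seed for the stratified half split (default 1).
#' @param splits Number of random splits whose subset weights are averaged
#'   (default 1; the loss-derived weighting is the cheap alternative to
#'   minimizing total loss over many partitions).
#' @return A `rawalk_model` object.
#' @export
rawalk_fit <- function(table, gamma = 1, alpha = 0.75, t = 5L,
                       lambda_reg = 1e-4, seed = 1L, splits = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) rawalk_stop("training table must be labeled")
  n <- nrow(table$X)
  if (n < 2L) rawalk_stop("need at least 2 training samples")
  if (alpha < 0 || alpha > 1) rawalk_stop("alpha must lie in [0, 1]")
  class_order <- table$classes
  if (length(class_order) == 1L)
    warning("single-class training set; every prediction will be that class",
            call. = FALSE)
  Y <- one_hot_states(table$labels, class_order)

  ## complementary-split weighting (averaged over `splits` seeded splits)
  w_S <- w_T <- eps_S <- eps_T <- 0
  split1 <- NULL
  for (r in seq_len(splits)) {
    sp <- stratified_half_split(table$labels, seed = seed + (r - 1L))
    if (r == 1L) split1 <- sp
    if (length(sp$S) == 0L || length(sp$T) == 0L) {
      w_S <- w_S + 0.5; w_T <- w_T + 0.5
      next
    }
    eps <- cross_prediction_loss(table$X, Y, sp$S, sp$T, gamma = gamma,
                                 alpha = alpha, t = t,
                                 lambda_reg = lambda_reg)
    wts <- split_weights(eps$eps_S, eps$eps_T)
    w_S <- w_S + wts$alpha_S; w_T <- w_T + wts$alpha_T
    eps_S <- eps_S + eps$eps_S; eps_T <- eps_T + eps$eps_T
  }
  w_S <- w_S / splits; w_T <- w_T / splits
  eps_S <- eps_S / splits; eps_T <- eps_T / splits

  ## weighted state matrix: column scaling by subset membership
  col_w <- rep(w_T, n)
  col_w[split1$S] <- w_S
  Y_tilde <- Y * rep(col_w, each = nrow(Y))

  K <- rbf_kernel(table$X, gamma = gamma)
  Q <- lazy_operator(transition_from_weights(K), alpha)
  projection <- Y_tilde %*% walk_power(Q, t) %*%
    regularized_pinv(K, lambda_reg)

  structure(list(X_train = table$X, class_order = class_order,
                 Y_tilde = Y_tilde, gamma = gamma, alpha = alpha,
                 t = as.integer(t), lambda_reg = lambda_reg,
                 projection = projection, seed = as.integer(seed),
                 split = list(S = split1$S, T = split1$T,
                              eps_S = eps_S, eps_T = eps_T,
                              alpha_S = w_S, alpha_T = w_T,
                              total_loss = total_loss(eps_S, eps_T))),
            class = "rawalk_model")
}

#' @export
print.rawalk_model <- function(x, ...) {
  cat("<rawalk_model> ", nrow(x$X_train), " training samples, ",
      length(x$class_order), " classes\n", sep = "")
  cat(sprintf("  gamma = %g, alpha = %g, t = %d, lambda = %g\n",
              x$gamma, x$alpha, x$t, x$lambda_reg))
  cat(sprintf("  split losses: eps_S = %.4g, eps_T = %.4g (total %.4g); ",
              x$split$eps_S, x$split$eps_T, x$split$total_loss))
  cat(sprintf("weights: alpha_S = %.3f, alpha_T = %.3f\n",
              x$split$alpha_S, x$split$alpha_T))
  invisible(x)
}

#' Walk-arrival scores for test points
#'
#' Scores = projection %*% k(X_train, X_test): entry (j, i) is the total
#' arrival score of test point i on class j under the t-step lazy walk. The
#' column argmax defines the predicted class.
#'
#' @param model A fitted [rawalk_fit()] model.
#' @param X_test q x d numeric matrix (or [feature_table()]).
#' @return m x q score matrix, rows named by class.
#' @export
predict_scores <- function(model, X_test) {
  stopifnot(inherits(model, "rawalk_model"))
  if (inherits(X_test, "feature_table")) X_test <- X_test$X
  X_test <- as.matrix(X_test)
  if (ncol(X_test) != ncol(model$X_train))
    rawalk_stop("test dimensionality ", ncol(X_test),
                " does not match training dimensionality ",
                ncol(model$X_train))
  scores <- model$projection %*%
    rbf_kernel(model$X_train, X_test, gamma = model$gamma)
  rownames(scores) <- model$class_order
  scores
}

#' Labels from a score matrix
#'
#' Per test point (column), the class with the maximal arrival score; exact
#' ties go to the lowest class index in `class_order`, which is what
#' `which.max` yields.
#'
#' @param scores m x q score matrix.
#' @param class_order Class names matching the score rows.
#' @return Character vector of q predicted classes.
#' @export
predict_labels <- function(scores, class_order = rownames(scores)) {
  scores <- as.matrix(scores)
  if (ncol(scores) == 0L || nrow(scores) == 0L)
    rawalk_stop("empty score matrix")
  if (anyNA(scores)) rawalk_stop("score matrix contains NaN/NA")
  if (length(class_order) != nrow(scores))
    rawalk_stop("class_order length does not match score rows")
  class_order[apply(scores, 2, which.max)]
}

#' @export
predict.rawalk_model <- function(object, newdata, type = c("class", "scores"),
                                 ...) {
  type <- match.arg(type)
  scores <- predict_scores(object, newdata)
  if (type == "scores") scores else predict_labels(scores, object$class_order)
}

#' Save a fitted model as JSON
#'
#' Serializes the training features, weighted state matrix, hyperparameters,
#' class order and the precomputed projection (re-derivable; stored so
#' prediction needs no refit).
#'
#' @param model A `rawalk_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "rawalk_model"))
  obj <- list(package = "rawalk",
              version = as.character(utils::packageVersion("rawalk")),
              class_order = model$class_order,
              gamma = model$gamma, alpha = model$alpha, t = model$t,
              lambda_reg = model$lambda_reg, seed = model$seed,
              split = model$split,
              X_train = model$X_train, Y_tilde = model$Y_tilde,
              projection = model$projection)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Path to the JSON model file.
#' @return A `rawalk_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$package, "rawalk"))
    rawalk_stop("'", path, "' is not a rawalk model file")
  m <- structure(list(X_train = as.matrix(obj$X_train),
                      class_order = obj$class_order,
                      Y_tilde = as.matrix(obj$Y_tilde),
                      gamma = obj$gamma, alpha = obj$alpha,
                      t = as.integer(obj$t), lambda_reg = obj$lambda_reg,
                      projection = as.matrix(obj$projection),
                      seed = as.integer(obj$seed),
                      split = obj$split),
                 class = "rawalk_model")
  rownames(m$projection) <- m$class_order
  rownames(m$Y_tilde) <- m$class_order
  m
}
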