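## Similarity graph and walk operators: RBF weights, degree normalization,
## lazy transition operator, t-step powers, regularized pseudo-inverse.

#' RBF (Gaussian) kernel between two point sets
#'
#' Entry (i, j) is exp(-gamma * ||a_i - b_j||^2). With `A = B` this is the
#' complete-graph weight matrix W of the similarity graph (diagonal 1); with
#' `B` a set of test points it is the similarity column block k(X, x).
#'
#' @param A p x d numeric matrix.
#' @param B q x d numeric matrix (default `A`).
#' @param gamma Positive kernel width, gamma = 1 / (2 sigma^2). Default 1.
#' @return p x q matrix with entries in (0, 1].
#' @export
rbf_kernel <- function(A, B = A, gamma = 1) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B))
    rawalk_stop("dimension mismatch: ", ncol(A), " vs ", ncol(B), " features")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    rawalk_stop("gamma must be a positive scalar")
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0  # clip tiny negative round-off
  exp(-gamma * d2)
}

#' Row-normalize a weight matrix into a transition matrix
#'
#' P = D^-1 W with D = diag(W 1_n): each row of the edge-weight matrix is
#' divided by its degree, giving the one-step transition probabilities of a
#' random walk on the complete similarity graph.
#'
#' @param W n x n non-negative weight matrix with strictly positive row sums.
#' @return n x n row-stochastic matrix.
#' @export
transition_from_weights <- function(W) {
  W <- as.matrix(W)
  deg <- rowSums(W)
  if (any(deg <= 0))
    rawalk_stop("zero row sum at row ", which(deg <= 0)[1L],
                "; weight matrix is degenerate")
  W / deg
}

#' Lazy walk operator
#'
#' Q = alpha * I + (1 - alpha) * P: the walker stays in place with
#' probability alpha and otherwise steps by P. alpha = 0 gives P back;
#' alpha = 1 gives the identity (both endpoints accepted as degenerate
#' cases).
#'
#' @param P n x n row-stochastic matrix.
#' @param alpha Laziness in \[0, 1\].
#' @return n x n row-stochastic matrix.
#' @export
lazy_operator <- function(P, alpha) {
  P <- as.matrix(P)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    rawalk_stop("alpha must lie in [0, 1], got ", alpha)
  alpha * diag(nrow(P)) + (1 - alpha) * P
}

#' t-step walk operator
#'
#' Q^t by exponentiation through repeated squaring; t = 0 gives the
#' identity. Row-stochasticity is preserved exactly up to round-off.
#'
#' @param Q n x n row-stochastic matrix.
#' @param t Non-negative integer number of steps.
#' @return n x n matrix Q^t.
#' @export
walk_power <- function(Q, t) {
  Q <- as.matrix(Q)
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t != round(t))
    rawalk_stop("t must be a non-negative integer, got ", t)
  t <- as.integer(t)
  out <- diag(nrow(Q))
  base <- Q
  while (t > 0L) {
    if (t %% 2L == 1L) out <- out %*% base
    t <- t %/% 2L
    if (t > 0L) base <- base %*% base
  }
  out
}

#' Regularized Moore-Penrose pseudo-inverse of a symmetric matrix
#'
#' Computes (K + lambda I)^+ through a symmetric eigendecomposition,
#' zeroing eigenvalues below `n * eps * max(|eigenvalue|)` (the standard
#' Moore-Penrose cutoff). With lambda > 0 the matrix is typically
#' well-conditioned and this is the exact inverse; lambda = 0 falls back to
#' the plain pseudo-inverse, defined even for singular K.
#'
#' @param K n x n symmetric numeric matrix.
#' @param lambda_reg Non-negative ridge added to the diagonal (default 0).
#' @return n x n matrix.
#' @export
regularized_pinv <- function(K, lambda_reg = 0) {
  K <- as.matrix(K)
  if (anyNA(K)) rawalk_stop("matrix contains NA entries")
  if (nrow(K) != ncol(K)) rawalk_stop("matrix must be square")
  if (lambda_reg < 0) rawalk_stop("lambda_reg must be non-negative")
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
    rawalk_stop("matrix is not symmetric")
  M <- (K + t(K)) / 2 + diag(lambda_reg, nrow(K))
  e <- eigen(M, symmetric = TRUE)
  tol <- nrow(M) * .Machine$double.eps * max(abs(e$values), 0)
  inv <- ifelse(abs(e$values) > tol, 1 / e$values, 0)
  e$vectors %*% (inv * t(e$vectors))
}
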