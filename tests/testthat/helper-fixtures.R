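# Shared fixture builders; everything generated in code at test time.

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A tiny labeled table with two visibly separated 2-d classes.
tiny_table <- function(n_per_class = 4, sep = 4, seed = 11) {
  gaussian_mixture_dataset(rep(n_per_class, 2), d = 2, separation = sep,
                           seed = seed)
}

# Random row-stochastic matrix from RBF weights over random points.
random_transition <- function(n, d = 3, gamma = 0.5) {
  X <- matrix(rnorm(n * d), n, d)
  transition_from_weights(rbf_kernel(X, gamma = gamma))
}

# Exhaustive path-enumeration oracle for (Q^t)[i, j]: sum over all length-t
# node paths i -> ... -> j of the product of single-step probabilities.
enumerate_walk_prob <- function(Q, t, i, j) {
  n <- nrow(Q)
  if (t == 0) return(as.numeric(i == j))
  paths <- expand.grid(rep(list(seq_len(n)), t - 1))
  total <- 0
  if (t == 1) return(Q[i, j])
  for (r in seq_len(nrow(paths))) {
    nodes <- c(i, as.integer(paths[r, ]), j)
    total <- total + prod(Q[cbind(nodes[-length(nodes)], nodes[-1])])
  }
  total
}

# Independent literal transcription of the prediction rule
# F(x) = Ytilde Q^t (K + lambda I)^+ k(X, x), using MASS::ginv as the
# pseudo-inverse routine and naive repeated multiplication for the power.
oracle_predict_scores <- function(X, labels, X_test, gamma, alpha, t,
                                  lambda_reg, split, weights) {
  class_order <- sort(unique(labels))
  Y <- matrix(0, length(class_order), length(labels))
  for (i in seq_along(labels)) Y[match(labels[i], class_order), i] <- 1
  colw <- rep(weights$alpha_T, length(labels))
  colw[split$S] <- weights$alpha_S
  Ytilde <- sweep(Y, 2, colw, `*`)
  K <- exp(-gamma * as.matrix(dist(X))^2)
  P <- sweep(K, 1, rowSums(K), `/`)
  Q <- alpha * diag(nrow(K)) + (1 - alpha) * P
  Qt <- diag(nrow(K))
  for (s in seq_len(t)) Qt <- Qt %*% Q
  kx <- exp(-gamma * outer(rowSums(X^2), rowSums(X_test^2), `+`) +
              2 * gamma * tcrossprod(X, X_test))
  Ytilde %*% Qt %*% MASS::ginv(K + lambda_reg * diag(nrow(K))) %*% kx
}
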