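# The walk classifier: state matrices, complementary-split training,
# prediction rule.

test_that("one_hot_states builds column one-hot state matrices", {
  Y <- one_hot_states(c("c1", "c1", "c2"), c("c1", "c2"))
  expect_equal(unname(Y), rbind(c(1, 1, 0), c(0, 0, 1)))
  expect_equal(unname(colSums(Y)), rep(1, 3))
  Y1 <- one_hot_states("c2", c("c1", "c2"))
  expect_equal(dim(Y1), c(2L, 1L))
  expect_error(one_hot_states(c("c1", "c9"), c("c1", "c2")), "c9")
})

test_that("stratified_half_split is balanced, disjoint and seeded", {
  labels <- c("a", "a", "b", "b")
  sp <- stratified_half_split(labels, seed = 3)
  expect_setequal(c(sp$S, sp$T), 1:4)
  expect_length(intersect(sp$S, sp$T), 0)
  # forced by stratification: one member of each class per side
  expect_setequal(labels[sp$S], c("a", "b"))
  expect_setequal(labels[sp$T], c("a", "b"))

  # singleton class lands on exactly one side
  labels2 <- c("a", "a", "a", "b")
  sp2 <- stratified_half_split(labels2, seed = 1)
  expect_setequal(c(sp2$S, sp2$T), 1:4)
  expect_equal(sum(4 %in% sp2$S, 4 %in% sp2$T), 1)

  # determinism and seed sensitivity
  labels3 <- rep(c("a", "b", "c"), each = 10)
  s1 <- stratified_half_split(labels3, seed = 7)
  s2 <- stratified_half_split(labels3, seed = 7)
  expect_identical(s1, s2)
  s3 <- stratified_half_split(labels3, seed = 8)
  expect_false(identical(s1, s3))
  # sizes within one of each other for even classes
  expect_lte(abs(length(s1$S) - length(s1$T)), 1)

  expect_error(stratified_half_split(character(0)), "at least 2")
})

test_that("split size imbalance is bounded by the odd-count classes", {
  set.seed(99)
  for (rep in 1:20) {
    counts <- sample(1:9, sample(2:5, 1), replace = TRUE)
    labels <- rep(paste0("c", seq_along(counts)), counts)
    sp <- stratified_half_split(labels, seed = rep)
    expect_setequal(c(sp$S, sp$T), seq_along(labels))
    expect_lte(abs(length(sp$S) - length(sp$T)), sum(counts %% 2 == 1))
  }
})

test_that("split_weights and total_loss follow their formulas", {
  expect_equal(split_weights(1, 1), list(alpha_S = 0.5, alpha_T = 0.5))
  expect_equal(split_weights(1, 3), list(alpha_S = 0.75, alpha_T = 0.25))
  expect_equal(split_weights(0, 0), list(alpha_S = 0.5, alpha_T = 0.5))
  expect_error(split_weights(-1, 1), "non-negative")

  expect_equal(total_loss(1, 1), 0.5)
  expect_equal(total_loss(0, 5), 0)
  expect_equal(total_loss(2, 3), 1.2)
  expect_equal(total_loss(0, 0), 0)
  expect_error(total_loss(-1, 2), "non-negative")

  # laws: weights sum to 1, smaller loss gets the larger weight,
  # total loss never exceeds the smaller loss
  set.seed(6)
  for (rep in 1:50) {
    e <- runif(2, 0, 10)
    w <- split_weights(e[1], e[2])
    expect_equal(w$alpha_S + w$alpha_T, 1, tolerance = 1e-12)
    if (e[1] < e[2]) expect_gt(w$alpha_S, w$alpha_T)
    if (e[2] < e[1]) expect_gt(w$alpha_T, w$alpha_S)
    expect_lte(total_loss(e[1], e[2]), min(e) + 1e-12)
  }
})

test_that("cross-prediction losses match a direct transcription and are
           symmetric in the roles of the halves", {
  tab <- tiny_table(n_per_class = 5, sep = 3, seed = 2)
  Y <- one_hot_states(tab$labels, tab$classes)
  sp <- stratified_half_split(tab$labels, seed = 2)
  eps <- cross_prediction_loss(tab$X, Y, sp$S, sp$T, gamma = 0.5,
                               alpha = 0.75, t = 3, lambda_reg = 1e-4)
  expect_gte(eps$eps_S, 0)
  expect_gte(eps$eps_T, 0)

  # swapping the subsets swaps the losses
  eps_swapped <- cross_prediction_loss(tab$X, Y, sp$T, sp$S, gamma = 0.5,
                                       alpha = 0.75, t = 3,
                                       lambda_reg = 1e-4)
  expect_equal(eps_swapped$eps_S, eps$eps_T)
  expect_equal(eps_swapped$eps_T, eps$eps_S)

  # direct dense-algebra transcription of the defining equation
  direct_loss <- function(A, B) {
    XA <- tab$X[A, , drop = FALSE]; XB <- tab$X[B, , drop = FALSE]
    W <- exp(-0.5 * as.matrix(dist(XA))^2)
    Q <- 0.75 * diag(nrow(W)) + 0.25 * sweep(W, 1, rowSums(W), `/`)
    FAB <- Y[, A] %*% (Q %*% Q %*% Q) %*%
      MASS::ginv(W + 1e-4 * diag(nrow(W))) %*%
      exp(-0.5 * (outer(rowSums(XA^2), rowSums(XB^2), `+`) -
                    2 * tcrossprod(XA, XB)))
    sum((FAB - Y[, B])^2)
  }
  expect_equal(eps$eps_S, direct_loss(sp$S, sp$T), tolerance = 1e-8)
  expect_equal(eps$eps_T, direct_loss(sp$T, sp$S), tolerance = 1e-8)

  expect_error(cross_prediction_loss(tab$X, Y, integer(0), sp$T),
               "non-empty")
})

test_that("duplicated points with a sharp kernel give near-minimal loss", {
  # T's points sit inside S as exact duplicates with matching labels; with a
  # large gamma the prediction concentrates on the duplicated columns
  X_T <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
  X_S <- rbind(X_T, matrix(c(0.01, 0, 5.01, 5), 2, 2, byrow = TRUE))
  X <- rbind(X_S, X_T)
  labels <- c("a", "b", "a", "b", "a", "b")
  Y <- one_hot_states(labels, c("a", "b"))
  eps <- cross_prediction_loss(X, Y, S = 1:4, T = 5:6, gamma = 50,
                               alpha = 0.5, t = 1, lambda_reg = 1e-6)
  # F_S(T) should essentially reproduce Y_T
  expect_lt(eps$eps_S, 0.05)
})

test_that("fitting produces a consistent, deterministic model", {
  tab <- tiny_table(n_per_class = 6, sep = 4, seed = 5)
  m <- rawalk_fit(tab, gamma = 0.5, alpha = 0.75, t = 5, seed = 9)
  expect_s3_class(m, "rawalk_model")
  expect_equal(dim(m$projection), c(2L, 12L))
  expect_equal(m$split$alpha_S + m$split$alpha_T, 1, tolerance = 1e-12)
  # Ytilde columns are scaled one-hot columns
  expect_equal(unname(colSums(m$Y_tilde)[m$split$S]),
               rep(m$split$alpha_S, length(m$split$S)))

  m2 <- rawalk_fit(tab, gamma = 0.5, alpha = 0.75, t = 5, seed = 9)
  expect_identical(m$projection, m2$projection)

  # alpha = 1 collapses the walk: projection is t-independent
  m_a <- rawalk_fit(tab, gamma = 0.5, alpha = 1, t = 2, seed = 9)
  m_b <- rawalk_fit(tab, gamma = 0.5, alpha = 1, t = 17, seed = 9)
  expect_equal(m_a$projection, m_b$projection, tolerance = 1e-10)

  expect_error(rawalk_fit(feature_table(matrix(1, 1, 1), labels = "a")),
               "at least 2")
  expect_warning(rawalk_fit(feature_table(matrix(rnorm(6), 3, 2),
                                          labels = rep("a", 3)),
                            seed = 1), "single-class")
})

test_that("predict_scores matches the independent transcription oracle", {
  set.seed(77)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    tab <- gaussian_mixture_dataset(c(ceiling(n / 2), floor(n / 2)), d = 3,
                                    separation = 2, seed = 100 + rep)
    gamma <- runif(1, 0.2, 1.5); alpha <- runif(1, 0.1, 0.9)
    t <- sample(0:4, 1)
    m <- rawalk_fit(tab, gamma = gamma, alpha = alpha, t = t,
                    lambda_reg = 1e-4, seed = rep)
    X_test <- matrix(rnorm(6), 2, 3)
    scores <- predict_scores(m, X_test)
    oracle <- oracle_predict_scores(
      tab$X, tab$labels, X_test, gamma, alpha, t, 1e-4,
      split = m$split, weights = list(alpha_S = m$split$alpha_S,
                                      alpha_T = m$split$alpha_T))
    expect_equal(unname(scores), unname(oracle), tolerance = 1e-10)
  }
})

test_that("a test point colliding with a training point recovers its
           projection column", {
  tab <- tiny_table(n_per_class = 4, sep = 6, seed = 3)
  m <- rawalk_fit(tab, gamma = 200, alpha = 0.75, t = 2, seed = 1)
  scores <- predict_scores(m, tab$X[3, , drop = FALSE])
  # with a very sharp kernel k(X, x) ~ e_3
  expect_equal(unname(scores[, 1]), unname(m$projection[, 3]),
               tolerance = 1e-4)
})

test_that("predict_labels takes the column argmax with a deterministic
           tie-break", {
  sc <- matrix(c(0.2, 0.8), 2, dimnames = list(c("c1", "c2"), NULL))
  expect_equal(predict_labels(sc), "c2")
  tie <- matrix(c(0.5, 0.5), 2, dimnames = list(c("c1", "c2"), NULL))
  expect_equal(predict_labels(tie), "c1")
  expect_error(predict_labels(matrix(c(NA, 1), 2),
                              class_order = c("c1", "c2")), "NaN|NA")
  expect_error(predict_labels(matrix(numeric(0), 2, 0),
                              class_order = c("c1", "c2")), "empty")

  # argmax is invariant to positive rescaling of the state weights
  tab <- tiny_table(n_per_class = 5, sep = 2, seed = 4)
  m <- rawalk_fit(tab, gamma = 0.3, t = 3, seed = 2)
  X_test <- matrix(rnorm(10), 5, 2)
  base <- predict_labels(predict_scores(m, X_test), m$class_order)
  m_scaled <- m
  m_scaled$projection <- 7.3 * m$projection
  expect_equal(predict_labels(predict_scores(m_scaled, X_test),
                              m$class_order), base)
})

test_that("equal split losses reduce to the unweighted half-scaled model", {
  # duplicated points per class make any stratified half split symmetric,
  # forcing eps_S == eps_T and hence weights (0.5, 0.5)
  X <- rbind(matrix(rep(c(0, 0), 4), 4, 2, byrow = TRUE),
             matrix(rep(c(5, 5), 4), 4, 2, byrow = TRUE))
  tab <- feature_table(X, labels = rep(c("a", "b"), each = 4))
  m <- rawalk_fit(tab, gamma = 0.4, alpha = 0.75, t = 3, seed = 2)
  expect_equal(m$split$eps_S, m$split$eps_T, tolerance = 1e-10)
  expect_equal(m$split$alpha_S, 0.5, tolerance = 1e-10)

  Y <- one_hot_states(tab$labels, tab$classes)
  K <- rbf_kernel(tab$X, gamma = 0.4)
  Q <- lazy_operator(transition_from_weights(K), 0.75)
  proj_eq <- (0.5 * Y) %*% walk_power(Q, 3) %*% regularized_pinv(K, 1e-4)
  expect_equal(unname(m$projection), unname(proj_eq), tolerance = 1e-10)

  set.seed(41)
  X_test <- matrix(rnorm(8, 2.5), 4, 2)
  expect_equal(predict_labels(predict_scores(m, X_test), tab$classes),
               predict_labels(proj_eq %*% rbf_kernel(tab$X, X_test,
                                                     gamma = 0.4),
                              tab$classes))
})

test_that("models round-trip through JSON serialization", {
  tab <- tiny_table(n_per_class = 4, sep = 4, seed = 8)
  m <- rawalk_fit(tab, gamma = 0.6, alpha = 0.5, t = 4, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$projection, m$projection, tolerance = 1e-14)
  expect_equal(m2$class_order, m$class_order)
  expect_equal(m2$gamma, m$gamma)
  X_test <- matrix(rnorm(6), 3, 2)
  expect_equal(predict_scores(m2, X_test), predict_scores(m, X_test),
               tolerance = 1e-12)
})
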