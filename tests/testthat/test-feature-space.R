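test_that("Z-scoring uses the sample sd and handles degenerate columns", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(-1, 0, 1))
  sc <- zscore_fit(X)
  Xs <- zscore_apply(X, sc)
  expect_equal(Xs[, "a"], c(-1, 0, 1), ignore_attr = TRUE)  # sample sd = 1
  expect_equal(Xs[, "b"], c(0, 0, 0), ignore_attr = TRUE)   # zero variance -> 0
  expect_equal(zscore_apply(Xs, zscore_fit(Xs)), Xs, tolerance = 1e-12)
  expect_error(zscore_fit(X[1, , drop = FALSE]), "2 samples")
})

test_that("t-selection ranks by pooled-variance |t| with a ceiling count", {
  X <- cbind(f1 = c(0, 1, 2, 3), f2 = c(1, 0, 0, 1))
  labels <- c("A", "A", "B", "B")
  expect_equal(t_select(X, labels, 0.5), 1L)  # |t| = 2/sqrt(0.5) beats 0
  # explicit pooled t for f1: mean diff -2, sp2 = 0.5, se = sqrt(0.5)
  expect_equal(abs(-2 / sqrt(0.5)), 2.828427, tolerance = 1e-6)
  Xbig <- matrix(rnorm(4 * 250), 4)
  expect_length(t_select(Xbig, labels, 0.01), 3L)  # ceiling(2.5)
  expect_error(t_select(X, c("A", "B", "B", "B")), "2 samples")
  expect_error(t_select(X, c("A", "B", "C", "A")), "2 classes")
})

test_that("zero-t features are never selected ahead of informative ones", {
  X <- cbind(same = c(1, 2, 1, 2), diff = c(0, 0, 5, 5))
  expect_equal(t_select(X, c("A", "A", "B", "B"), 0.5), 2L)
})

test_that("Q-mode PCA preserves variance and applies the threshold rule", {
  set.seed(15)
  X <- matrix(rnorm(6 * 40), 6, 40)
  fit <- qmode_pca(X, beta = 0.95)
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(sum(fit$scores^2), sum(Xc^2), tolerance = 1e-10)
  # cross-check ratios and scores against prcomp
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  expect_equal(fit$var_ratio[1:5], (pr$sdev^2 / sum(pr$sdev^2))[1:5],
               tolerance = 1e-10)
  expect_equal(abs(fit$scores[, 1:5]), abs(pr$x[, 1:5]), tolerance = 1e-8,
               ignore_attr = TRUE)
  # one direction of variation -> k = 1, first ratio 1
  one <- outer(c(1, 2, 3, 4), rnorm(20))
  f1 <- qmode_pca(one, beta = 0.5)
  expect_equal(f1$k, 1L)
  expect_equal(f1$var_ratio[1], 1, tolerance = 1e-12)
  expect_error(qmode_pca(X, beta = 1.5), "beta")
})

test_that("variance-threshold truncation counts leading components", {
  # construct scores with variance ratios (0.6, 0.3, 0.1)
  U <- qr.Q(qr(matrix(rnorm(16), 4)))
  D <- diag(sqrt(c(0.6, 0.3, 0.1, 0)))
  X <- U %*% D %*% t(qr.Q(qr(matrix(rnorm(16), 4))))
  X <- sweep(X, 2, colMeans(X))  # keep it centered
  fit <- qmode_pca(X, beta = 0.9)
  # centering may slightly redistribute; ratios should be close
  expect_equal(fit$k, which(cumsum(fit$var_ratio) >= 0.9)[1])
})

test_that("PCA projection reproduces training scores and zeroes the mean row", {
  set.seed(16)
  X <- matrix(rnorm(8 * 30), 8, 30)
  fit <- qmode_pca(X, beta = 1)
  proj <- pca_project(X, fit, k = 8)
  expect_equal(proj, fit$scores, tolerance = 1e-10, ignore_attr = TRUE)
  mu_row <- matrix(fit$mu, 1)
  expect_equal(as.vector(pca_project(mu_row, fit)), rep(0, fit$k),
               tolerance = 1e-10)
  expect_equal(dim(pca_project(matrix(rnorm(5 * 30), 5), fit, k = 3)), c(5L, 3L))
  expect_error(pca_project(matrix(0, 2, 7), fit), "column count")
})

test_that("Fisher LDA recovers a separating axis and is permutation invariant", {
  set.seed(17)
  V <- rbind(cbind(rnorm(20, -3, 0.5), rnorm(20, 0, 2)),
             cbind(rnorm(20, 3, 0.5), rnorm(20, 0, 2)))
  labels <- rep(c("a", "b"), each = 20)
  fit <- lda_fit(V, labels)
  dir <- fit$A[, 1] / sqrt(sum(fit$A[, 1]^2))
  expect_gt(abs(dir[1]), 0.99)  # discriminant along the separated axis
  perm <- sample(40)
  expect_equal(lda_fit(V[perm, ], labels[perm])$A, fit$A, tolerance = 1e-8)
  expect_error(lda_fit(V, c("a", rep("b", 39))), "fewer than 2")
})

test_that("LDA direction agrees with MASS::lda up to scale", {
  set.seed(18)
  V <- rbind(matrix(rnorm(60, 0), ncol = 3), matrix(rnorm(60, 1.5), ncol = 3))
  labels <- rep(c("a", "b"), each = 20)
  A <- lda_fit(V, labels)$A[, 1]
  B <- MASS::lda(V, grouping = labels)$scaling[, 1]
  cosang <- abs(sum(A * B)) / sqrt(sum(A^2) * sum(B^2))
  expect_gt(cosang, 1 - 1e-6)
})

test_that("collinear class means give one dominant discriminant", {
  set.seed(19)
  mus <- rbind(c(-4, 0), c(0, 0), c(4, 0))  # means on a line
  V <- do.call(rbind, lapply(1:3, function(i) {
    cbind(rnorm(60, mus[i, 1], 0.4), rnorm(60, mus[i, 2], 0.4))
  }))
  labels <- rep(c("a", "b", "c"), each = 60)
  fit <- lda_fit(V, labels)
  d1 <- fit$A[, 1] / sqrt(sum(fit$A[, 1]^2))
  expect_gt(abs(d1[1]), 0.99)
  expect_lt(fit$eig[2] / fit$eig[1], 0.05)  # second explains ~ no separation
})

test_that("LDA projection respects dimensions and identity weights", {
  sc <- matrix(rnorm(40), 10, 4)
  expect_equal(lda_project(sc, diag(4)), sc, ignore_attr = TRUE)
  expect_equal(dim(lda_project(sc, matrix(rnorm(8), 4, 2))), c(10L, 2L))
  expect_error(lda_project(sc, matrix(0, 3, 2)), "mismatch")
})

test_that("the fitted pipeline is deterministic and projects train/test coherently", {
  set.seed(20)
  X <- matrix(rnorm(30 * 200), 30, 200)
  shift <- rep(c(0, 1.2), each = 15)
  X[, 1:20] <- X[, 1:20] + shift
  labels <- rep(c("a", "b"), each = 15)
  f1 <- feature_space_fit(X, labels, select_fraction = 0.1, beta = 0.95)
  f2 <- feature_space_fit(X, labels, select_fraction = 0.1, beta = 0.95)
  expect_identical(serialize(f1, NULL), serialize(f2, NULL))
  # held-out samples from the same classes land near their training class means
  Xnew <- matrix(rnorm(20 * 200), 20, 200)
  Xnew[, 1:20] <- Xnew[, 1:20] + rep(c(0, 1.2), each = 10)
  Ztr <- predict(f1, X)
  Zte <- predict(f1, Xnew)
  m_tr <- tapply(Ztr[, 1], labels, mean)
  m_te <- tapply(Zte[, 1], rep(c("a", "b"), each = 10), mean)
  spread <- sd(Ztr[, 1])
  expect_lt(abs(m_tr["a"] - m_te["a"]), 1.5 * spread)
  expect_lt(abs(m_tr["b"] - m_te["b"]), 1.5 * spread)
  # projecting the training data reproduces the stored PCA scores
  Xs <- zscore_apply(X, f1$scaler)[, f1$selected]
  expect_equal(pca_project(Xs, f1$pca, k = f1$pca$k),
               f1$pca$scores[, seq_len(f1$pca$k)], tolerance = 1e-10,
               ignore_attr = TRUE)
})
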