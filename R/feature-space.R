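# High-dimensional feature pipeline: Z-score scaling, pooled-t feature
# selection, Q-mode PCA (p >> n), Fisher LDA, and the projection algebra
# that maps held-out samples through the fitted training-space model.

as_feature_matrix <- function(X, what = "X") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) stop_arg(what, " must be a numeric matrix or data frame")
  if (anyNA(X)) stop_arg(what, " contains missing values")
  X
}

#' Fit a Z-score scaler
#'
#' Per-feature mean and sample (n-1) standard deviation. Features with zero
#' variance keep a unit scale and map to 0 after centering, preserving
#' column alignment.
#'
#' @param X numeric matrix or data frame, samples in rows (n >= 2).
#' @return a `zscaler` list with `center` and `scale`.
#' @export
zscore_fit <- function(X) {
  X <- as_feature_matrix(X)
  if (nrow(X) < 2) stop_arg("Z-scoring needs at least 2 samples")
  ctr <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0] <- 1
  structure(list(center = ctr, scale = s), class = "zscaler")
}

#' Apply a fitted Z-score scaler
#' @param X matrix with the same columns the scaler was fit on.
#' @param scaler a `zscaler`.
#' @return scaled matrix.
#' @export
zscore_apply <- function(X, scaler) {
  X <- as_feature_matrix(X)
  if (ncol(X) != length(scaler$center)) stop_arg("column count does not match the scaler")
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, `/`)
}

#' Two-sample t-statistic feature selection
#'
#' Computes the pooled-variance two-sample t statistic for every feature
#' and returns the indices of the `ceiling(fraction * p)` features with the
#' largest `|t|`, sorted ascending. Features with zero variance in both
#' classes receive `t = 0`.
#'
#' @param X numeric matrix, samples in rows.
#' @param labels two-class label vector; each class needs >= 2 samples.
#' @param fraction fraction of features to keep (default 0.01).
#' @return integer vector of selected column indices (ascending).
#' @export
t_select <- function(X, labels, fraction = 0.01) {
  X <- as_feature_matrix(X)
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2) stop_arg("t_select requires exactly 2 classes")
  n1 <- sum(labels == cls[1]); n2 <- sum(labels == cls[2])
  if (min(n1, n2) < 2) stop_arg("each class needs >= 2 samples")
  X1 <- X[labels == cls[1], , drop = FALSE]
  X2 <- X[labels == cls[2], , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- apply(X1, 2, var); v2 <- apply(X2, 2, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  # zero pooled variance: |t| is 0 when the means agree, infinite otherwise
  t <- ifelse(se == 0, ifelse(m1 == m2, 0, sign(m1 - m2) * Inf), (m1 - m2) / se)
  keep <- ceiling(fraction * ncol(X))
  sort(order(-abs(t))[seq_len(keep)])
}

#' Q-mode principal component analysis
#'
#' PCA for matrices with many more features than samples, via singular
#' value decomposition of the column-centered data. Scores are `n x n`
#' (`V = X_centered W`), loadings `W` are `p x n`. Component signs are
#' fixed so the largest-magnitude loading of each component is positive.
#'
#' @param X numeric matrix or data frame, samples in rows (n >= 2).
#' @param beta cumulative variance threshold in (0, 1]; the retained count
#'   `k` is the smallest number of leading components whose cumulative
#'   variance ratio reaches `beta`.
#' @param k optional fixed component count overriding the threshold.
#' @return a `qmode_pca` list with `mu`, `loadings`, `scores`,
#'   `var_ratio`, `k`, `beta`.
#' @export
qmode_pca <- function(X, beta = 0.95, k = NULL) {
  X <- as_feature_matrix(X)
  if (nrow(X) < 2) stop_arg("PCA needs at least 2 samples")
  if (beta <= 0 || beta > 1) stop_arg("beta must be in (0, 1]")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = nrow(X), nv = min(dim(Xc)))
  n <- nrow(X)
  d <- numeric(n)
  d[seq_along(sv$d)] <- sv$d
  W <- matrix(0, ncol(X), n)
  W[, seq_len(ncol(sv$v))] <- sv$v
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(n)) {
    i <- which.max(abs(W[, j]))
    if (length(i) && W[i, j] < 0) {
      W[, j] <- -W[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(d, n, n)
  tot <- sum(d^2)
  var_ratio <- if (tot > 0) d^2 / tot else rep(0, n)
  kk <- if (!is.null(k)) {
    if (k < 1 || k > n) stop_arg("k must be in [1, n]")
    as.integer(k)
  } else which(cumsum(var_ratio) >= beta - 1e-12)[1]
  structure(list(mu = mu, loadings = W, scores = scores,
                 var_ratio = var_ratio, k = kk, beta = beta),
            class = "qmode_pca")
}

#' Project new samples into a fitted principal component space
#'
#' Rows are centered by the training means and multiplied by the first `k`
#' loadings: `V_new = (X_new - mu) W[, 1:k]`.
#'
#' @param X_new matrix with the training feature columns.
#' @param pca a `qmode_pca` fit.
#' @param k number of components (defaults to the fit's retained `k`).
#' @return score matrix `n_new x k`.
#' @export
pca_project <- function(X_new, pca, k = pca$k) {
  X_new <- as_feature_matrix(X_new, "X_new")
  if (ncol(X_new) != length(pca$mu)) stop_arg("column count does not match the PCA fit")
  sweep(X_new, 2, pca$mu) %*% pca$loadings[, seq_len(k), drop = FALSE]
}

#' Fisher linear discriminant analysis
#'
#' Maximizes the ratio of between-class to within-class scatter, yielding
#' `s - 1` discriminant directions for `s` classes. A ridge
#' `eps = 1e-8 tr(Sw)/k` stabilizes a singular within-class scatter (the
#' usual case when `k` exceeds the within-class degrees of freedom). Column
#' signs are fixed so each discriminant's largest-magnitude weight is
#' positive.
#'
#' @param V numeric score matrix, samples in rows (k columns).
#' @param labels class labels; every class needs >= 2 samples.
#' @return a `fisher_lda` list with weights `A` (`k x (s-1)`), class
#'   `levels`, discriminant eigenvalues `eig`.
#' @export
lda_fit <- function(V, labels) {
  V <- as_feature_matrix(V, "V")
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  s <- length(lev)
  if (s < 2) stop_arg("LDA needs >= 2 classes")
  counts <- table(factor(labels, lev))
  if (any(counts < 2))
    stop_arg("class '", names(counts)[counts < 2][1], "' has fewer than 2 samples")
  k <- ncol(V)
  if (k < s - 1) stop_arg("need at least s-1 = ", s - 1, " dimensions, got ", k)
  mu <- colMeans(V)
  Sw <- matrix(0, k, k)
  Sb <- matrix(0, k, k)
  for (cl in lev) {
    Vc <- V[labels == cl, , drop = FALSE]
    mc <- colMeans(Vc)
    Sw <- Sw + crossprod(sweep(Vc, 2, mc))
    Sb <- Sb + nrow(Vc) * tcrossprod(mc - mu)
  }
  R <- tryCatch(chol(Sw), error = function(e) NULL)
  if (is.null(R) || min(diag(R)) < sqrt(.Machine$double.eps * sum(diag(Sw)))) {
    Sw <- Sw + diag(1e-8 * sum(diag(Sw)) / k, k)
    R <- chol(Sw)
  }
  Ri <- backsolve(R, diag(k))
  M <- crossprod(Ri, Sb %*% Ri)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  A <- Ri %*% e$vectors[, seq_len(s - 1), drop = FALSE]
  for (j in seq_len(ncol(A))) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) A[, j] <- -A[, j]
  }
  colnames(A) <- paste0("LD", seq_len(ncol(A)))
  structure(list(A = A, levels = lev, eig = e$values[seq_len(s - 1)]),
            class = "fisher_lda")
}

#' Project scores onto fitted discriminant directions
#' @param V score matrix with `k` columns.
#' @param lda a `fisher_lda` fit (or a weight matrix `A`).
#' @return discriminant coordinates, `n x (s-1)`.
#' @export
lda_project <- function(V, lda) {
  A <- if (inherits(lda, "fisher_lda")) lda$A else lda
  V <- as_feature_matrix(V, "V")
  if (ncol(V) != nrow(A)) stop_arg("dimension mismatch: scores have ", ncol(V),
                                   " columns, weights expect ", nrow(A))
  V %*% A
}

#' Fit the full feature-space pipeline
#'
#' Chains Z-score scaling, optional two-class pooled-t feature selection,
#' Q-mode PCA truncation (variance threshold `beta` or fixed `k`), and
#' Fisher LDA. The fitted model maps raw feature vectors of held-out
#' samples into the training discriminant space via
#' [predict.feature_space()].
#'
#' @param X numeric feature matrix or data frame, samples in rows.
#' @param labels class labels.
#' @param select_fraction if non-NULL, keep this fraction of features by
#'   largest `|t|` (two-class problems only).
#' @param beta cumulative variance threshold for PCA truncation.
#' @param k fixed PCA component count (overrides `beta`).
#' @return a `feature_space` model.
#' @export
feature_space_fit <- function(X, labels, select_fraction = NULL,
                              beta = 0.95, k = NULL) {
  X <- as_feature_matrix(X)
  scaler <- zscore_fit(X)
  Xs <- zscore_apply(X, scaler)
  sel <- if (!is.null(select_fraction)) t_select(Xs, labels, select_fraction)
         else seq_len(ncol(X))
  pca <- qmode_pca(Xs[, sel, drop = FALSE], beta = beta, k = k)
  kk <- max(pca$k, length(unique(labels)) - 1)  # LDA needs >= s-1 dims
  lda <- lda_fit(pca$scores[, seq_len(kk), drop = FALSE], labels)
  structure(list(scaler = scaler, selected = sel, pca = pca, k = kk,
                 lda = lda, labels = as.character(labels)),
            class = "feature_space")
}

#' Map samples through a fitted feature-space model
#'
#' @param object a `feature_space` model.
#' @param newdata raw feature matrix with the training columns.
#' @param ... unused.
#' @return discriminant-coordinate matrix, `n x (s-1)`.
#' @export
predict.feature_space <- function(object, newdata, ...) {
  Xs <- zscore_apply(newdata, object$scaler)
  V <- pca_project(Xs[, object$selected, drop = FALSE], object$pca, k = object$k)
  lda_project(V, object$lda)
}

#' @export
print.feature_space <- function(x, ...) {
  cat("feature_space model:", length(x$scaler$center), "features ->",
      length(x$selected), "selected ->", x$k, "PCs ->",
      ncol(x$lda$A), "discriminants\n")
  invisible(x)
}

#' @exportS3Method
glance.feature_space <- function(x, ...) {
  tibble(n_features = length(x$scaler$center),
         n_selected = length(x$selected),
         k = x$k,
         variance_explained = sum(x$pca$var_ratio[seq_len(x$pca$k)]),
         n_discriminants = ncol(x$lda$A))
}

#' @exportS3Method
tidy.qmode_pca <- function(x, ...) {
  tibble(component = seq_along(x$var_ratio),
         var_ratio = x$var_ratio,
         cum_var = cumsum(x$var_ratio),
         retained = seq_along(x$var_ratio) <= x$k)
}
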