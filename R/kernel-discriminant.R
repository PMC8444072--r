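# Gaussian kernel density discriminant classifier: a per-class product
# Gaussian KDE with diagonal bandwidths, compared across classes in a
# posterior (or maximum likelihood) framework. This is the kernel model a
# classification tree applies within a node, used here as a single-node
# classifier; its posterior for the designated positive class is the
# predicted probability of malignancy P(mal) in the mass study.

#' Fit a Gaussian kernel discriminant model
#'
#' Per class, stores the training points and per-dimension bandwidths
#' `h_j = sd_j * n_c^(-1/(d+4))` (Scott's rule) or a fixed value. Priors
#' default to the empirical class proportions; a uniform prior reproduces
#' a pure maximum-likelihood rule.
#'
#' @param Z numeric matrix of training points (n x d), or data frame.
#' @param labels class labels (>= 1 point per class).
#' @param bandwidth `"scott"` or a fixed positive number.
#' @param priors `"empirical"`, `"uniform"`, or a named numeric vector
#'   summing to 1.
#' @return a `kernel_discriminant` model.
#' @export
kd_fit <- function(Z, labels, bandwidth = "scott", priors = "empirical") {
  Z <- as_feature_matrix(Z, "Z")
  labels <- as.character(labels)
  stopifnot(nrow(Z) == length(labels))
  lev <- sort(unique(labels))
  d <- ncol(Z)
  # global fallback bandwidth: pooled sd per dimension, Scott factor
  gh <- apply(Z, 2, sd) * nrow(Z)^(-1 / (d + 4))
  gh[!is.finite(gh) | gh <= 0] <- 1
  classes <- lapply(lev, function(cl) {
    P <- Z[labels == cl, , drop = FALSE]
    if (identical(bandwidth, "scott")) {
      h <- apply(P, 2, sd) * nrow(P)^(-1 / (d + 4))
      bad <- !is.finite(h) | h <= 0
      if (any(bad)) {
        warning("class '", cl, "': zero spread in ", sum(bad),
                " dimension(s); falling back to the global bandwidth")
        h[bad] <- gh[bad]
      }
    } else {
      if (!is.numeric(bandwidth) || bandwidth <= 0)
        stop_arg("bandwidth must be \"scott\" or a positive number")
      h <- rep(bandwidth, d)
    }
    list(points = P, h = h, n = nrow(P))
  })
  names(classes) <- lev
  pr <- if (identical(priors, "empirical")) {
    as.numeric(table(factor(labels, lev))) / length(labels)
  } else if (identical(priors, "uniform")) {
    rep(1 / length(lev), length(lev))
  } else {
    if (!all(lev %in% names(priors))) stop_arg("priors must name every class")
    p <- as.numeric(priors[lev])
    if (abs(sum(p) - 1) > 1e-8) stop_arg("priors must sum to 1")
    p
  }
  names(pr) <- lev
  structure(list(classes = classes, levels = lev, priors = pr, d = d),
            class = "kernel_discriminant")
}

# log KDE of class cl evaluated at rows of Znew (product Gaussian kernels)
kd_log_density <- function(cls, Znew) {
  n <- nrow(Znew)
  out <- numeric(n)
  P <- cls$points
  h <- cls$h
  for (i in seq_len(n)) {
    lk <- rep(-log(cls$n), cls$n)
    for (j in seq_along(h)) {
      lk <- lk + dnorm((Znew[i, j] - P[, j]) / h[j], log = TRUE) - log(h[j])
    }
    out[i] <- logsumexp(lk)
  }
  out
}

#' Predict classes and posterior probabilities
#'
#' Posterior `p_c ∝ prior_c * KDE_c(z)` normalized across classes; the
#' predicted label is the argmax, ties broken by label order. Queries where
#' every class density underflows to zero are classified by the nearest
#' class centroid and flagged.
#'
#' @param object a `kernel_discriminant` model.
#' @param newdata numeric matrix with `d` columns.
#' @param ... unused.
#' @return a tibble with `.pred` (label), one posterior column per class
#'   (`.prob_<class>`), and `.degenerate` (logical fallback flag).
#' @export
predict.kernel_discriminant <- function(object, newdata, ...) {
  Z <- as_feature_matrix(newdata, "newdata")
  if (ncol(Z) != object$d) stop_arg("newdata must have ", object$d, " columns")
  lev <- object$levels
  L <- vapply(lev, function(cl) kd_log_density(object$classes[[cl]], Z),
              numeric(nrow(Z)))
  L <- matrix(L, nrow = nrow(Z))
  L <- sweep(L, 2, log(object$priors), `+`)
  post <- matrix(0, nrow(Z), length(lev))
  degen <- rep(FALSE, nrow(Z))
  pred <- character(nrow(Z))
  for (i in seq_len(nrow(Z))) {
    li <- L[i, ]
    if (all(!is.finite(li))) {
      degen[i] <- TRUE
      cen <- vapply(lev, function(cl) {
        sqrt(sum((colMeans(object$classes[[cl]]$points) - Z[i, ])^2))
      }, numeric(1))
      j <- which.min(cen)
      post[i, j] <- 1
      pred[i] <- lev[j]
    } else {
      pi <- exp(li - logsumexp(li))
      post[i, ] <- pi / sum(pi)
      pred[i] <- lev[which.max(post[i, ])]
    }
  }
  out <- tibble(.pred = pred, .degenerate = degen)
  for (j in seq_along(lev)) out[[paste0(".prob_", lev[j])]] <- post[, j]
  out
}

#' Posterior probability of a designated positive class
#'
#' @param object a `kernel_discriminant` model.
#' @param newdata query matrix.
#' @param positive the positive class label (e.g. "malignant").
#' @return numeric vector of posteriors, one per query row.
#' @export
kd_positive_prob <- function(object, newdata, positive) {
  if (!positive %in% object$levels) stop_arg("unknown positive class: ", positive)
  predict(object, newdata)[[paste0(".prob_", positive)]]
}

#' @export
print.kernel_discriminant <- function(x, ...) {
  cat("Gaussian kernel discriminant:", length(x$levels), "classes, d =", x$d, "\n")
  cat("priors:", paste(sprintf("%s=%.3f", x$levels, x$priors), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method
glance.kernel_discriminant <- function(x, ...) {
  tibble(n_classes = length(x$levels), d = x$d,
         n_train = sum(vapply(x$classes, `[[`, numeric(1), "n")))
}
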