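# Bayesian estimator of classification accuracy: a single accuracy pi is
# assumed shared across classes, the per-class correct counts are binomial,
# and a uniform prior on pi yields a Beta(correct + 1, total - correct + 1)
# posterior. The posterior mean is (correct + 1) / (total + 2) and the
# credible interval is formed from beta quantiles.

#' Beta posterior for classification accuracy
#'
#' @param correct number of correctly classified samples (sum of the
#'   confusion-matrix diagonal).
#' @param total total number of samples.
#' @param level credible level in (0, 1), default 0.95.
#' @return a `posterior_accuracy` object: shape parameters, posterior
#'   mean, and the equal-tailed credible interval.
#' @export
posterior_accuracy <- function(correct, total, level = 0.95) {
  if (correct < 0 || correct > total) stop_arg("need 0 <= correct <= total")
  if (level <= 0 || level >= 1) stop_arg("level must be in (0, 1)")
  a <- correct + 1
  b <- total - correct + 1
  lo <- qbeta((1 - level) / 2, a, b)
  hi <- qbeta(1 - (1 - level) / 2, a, b)
  structure(list(correct = correct, total = total,
                 shape_a = a, shape_b = b,
                 mean = a / (a + b), level = level,
                 lower = lo, upper = hi),
            class = "posterior_accuracy")
}

#' Correct/total counts from a confusion matrix
#'
#' @param m square matrix of non-negative counts, true classes in rows.
#' @return named numeric vector `c(correct, total)` (trace and grand sum).
#' @export
accuracy_from_confusion <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop_arg("confusion matrix must be square")
  if (any(m < 0)) stop_arg("confusion matrix entries must be non-negative")
  c(correct = sum(diag(m)), total = sum(m))
}

#' Format a posterior accuracy as percentages
#'
#' One-decimal percentages, e.g. `"94.7% [88.8%, 98.5%]"`.
#'
#' @param x a `posterior_accuracy`.
#' @param ... unused.
#' @return a character scalar.
#' @export
format.posterior_accuracy <- function(x, ...) {
  sprintf("%.1f%% [%.1f%%, %.1f%%]", 100 * x$mean, 100 * x$lower, 100 * x$upper)
}

#' @export
print.posterior_accuracy <- function(x, ...) {
  cat(sprintf("Posterior accuracy (Beta(%d, %d), %d/%d correct): %s at %.0f%% credibility\n",
              x$shape_a, x$shape_b, x$correct, x$total, format(x), 100 * x$level))
  invisible(x)
}

#' @exportS3Method
tidy.posterior_accuracy <- function(x, ...) {
  tibble(correct = x$correct, total = x$total,
         shape_a = x$shape_a, shape_b = x$shape_b,
         mean = x$mean, lower = x$lower, upper = x$upper, level = x$level)
}
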