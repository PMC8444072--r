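# Reconstruction-error curves over moment orders and order-selection rules.

#' Mean squared error between two images
#'
#' Mean over all pixels of the squared difference (the sum of squares is
#' divided by the full pixel count N*M).
#'
#' @param a,b image matrices of identical dimensions.
#' @return non-negative scalar.
#' @export
img_mse <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop_arg("images must have identical dimensions")
  mean((unclass(a) - unclass(b))^2)
}

#' Reconstruction-MSE curve over moment orders
#'
#' For each requested order, computes the moments of `img`, reconstructs,
#' and records the mean squared error against the original. Krawtchouk
#' curves are non-increasing in the order (nested orthogonal projections);
#' generalized pseudo-Zernike curves trend downward but carry quadrature
#' error.
#'
#' @param img image matrix (square for `family = "gpzm"`).
#' @param family `"km"` or `"gpzm"`.
#' @param orders strictly increasing vector of orders (KM: `>= 1` and
#'   `<= min(dim(img))`; GPZM: `>= 0`).
#' @param p Krawtchouk weight parameter.
#' @param alpha GPZM side parameter.
#' @param image_id identifier recorded in the output (default "img").
#' @return an `mse_curve` tibble with columns `image_id`, `family`,
#'   `order`, `mse`.
#' @export
mse_curve <- function(img, family = c("km", "gpzm"), orders, p = 0.5,
                      alpha = 0, image_id = "img") {
  family <- match.arg(family)
  check_image(img)
  if (is.unsorted(orders, strictly = TRUE)) stop_arg("orders must be strictly increasing")
  if (family == "km") {
    if (min(orders) < 1 || max(orders) > min(dim(img)))
      stop_arg("KM orders must lie in [1, min(dim(img))]")
    # share the largest basis: order-l moments are the leading l x l block
    lmax <- max(orders)
    br <- krawtchouk_basis(lmax, nrow(img), p)
    bc <- if (ncol(img) == nrow(img)) br else krawtchouk_basis(lmax, ncol(img), p)
    Q <- unclass(br) %*% unclass(img) %*% t(unclass(bc))
    mse <- vapply(orders, function(l) {
      A <- t(unclass(br)[1:l, , drop = FALSE]) %*% Q[1:l, 1:l, drop = FALSE] %*%
        unclass(bc)[1:l, , drop = FALSE]
      mean((A - unclass(img))^2)
    }, numeric(1))
  } else {
    if (min(orders) < 0) stop_arg("GPZM orders must be >= 0")
    Z <- gpzm_moments(img, max(orders), alpha)
    mse <- vapply(orders, function(nm) {
      Zt <- Z
      Zt$n_max <- nm
      Zt$values <- Z$values[1:(nm + 1), (Z$n_max + 1 - nm):(Z$n_max + 1 + nm), drop = FALSE]
      mean((gpzm_reconstruct(Zt, Z$S) - unclass(img))^2)
    }, numeric(1))
  }
  structure(tibble(image_id = image_id, family = family, order = as.integer(orders),
                   mse = mse),
            class = c("mse_curve", class(tibble())))
}

#' Select a moment order from reconstruction-MSE curves
#'
#' Two rules: `"argmin_mean_mse"` picks the order minimizing the
#' across-image mean MSE; `"mean_of_argmins"` takes each image's
#' MSE-minimizing order and returns their mean rounded half away from
#' zero. Ties in a minimum go to the smallest order.
#'
#' @param curves one `mse_curve` tibble or a list of them (rows are pooled;
#'   images are distinguished by `image_id`).
#' @param rule selection rule.
#' @return integer order.
#' @export
select_order <- function(curves, rule = c("argmin_mean_mse", "mean_of_argmins")) {
  rule <- match.arg(rule)
  if (inherits(curves, "data.frame")) curves <- list(curves)
  if (length(curves) == 0) stop_arg("select_order needs at least one curve")
  d <- dplyr::bind_rows(curves)
  if (nrow(d) == 0) stop_arg("select_order needs at least one curve")
  if (rule == "argmin_mean_mse") {
    m <- d |>
      dplyr::group_by(.data$order) |>
      dplyr::summarise(mse = mean(.data$mse), .groups = "drop") |>
      dplyr::arrange(.data$order)
    as.integer(m$order[which.min(m$mse)])  # which.min takes the first = smallest order
  } else {
    am <- d |>
      dplyr::group_by(.data$image_id) |>
      dplyr::summarise(best = .data$order[which.min(.data$mse)], .groups = "drop")
    x <- mean(am$best)
    as.integer(sign(x) * floor(abs(x) + 0.5))  # round half away from zero
  }
}
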