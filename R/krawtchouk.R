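# Weighted Krawtchouk polynomial bases, Krawtchouk moments of rectangular
# images, exact reconstruction, and pose-normalized invariant features.
#
# The weighted Krawtchouk polynomial of order n on x = 0..N-1 is
#   kbar_n(x) = k_n(x; p, N-1) * sqrt(omega(x) / rho(n)),
# with k_n the hypergeometric Krawtchouk polynomial 2F1(-n, -x; -N+1; 1/p),
# omega the Binomial(N-1, p) mass function and rho(n) the squared norm
#   rho(n) = ((1-p)/p)^n * n! * (N-1-n)! / (N-1)!.
# Rows of the basis matrix are orthonormal: K K^T = I.

# Forward three-term recurrence in n, all rows, all columns. Numerically
# safe only in the region n <= min(x, N-1-x); callers patch the rest via
# the exact symmetries below.
kraw_recurrence_rows <- function(l, N, p) {
  x <- 0:(N - 1)
  Np <- N - 1
  K <- matrix(0, l, N)
  lw <- lchoose(Np, x) + x * log(p) + (Np - x) * log1p(-p)
  K[1, ] <- exp(lw / 2)
  if (l >= 2) K[2, ] <- (1 - x / (p * Np)) * K[1, ] / sqrt(((1 - p) / p) / Np)
  if (l >= 3) {
    for (n in 1:(l - 2)) {
      A <- p * (Np - n)
      B <- n * (1 - p)
      c1 <- sqrt(A / ((1 - p) * (n + 1)))
      c2 <- sqrt((p * (Np - n + 1) / ((1 - p) * n)) * (A / ((1 - p) * (n + 1))))
      K[n + 2, ] <- ((A + B - x) * c1 * K[n + 1, ] - B * c2 * K[n, ]) / A
    }
  }
  K
}

# p = 0.5 stable construction. Uses two exact identities:
#   kbar_n(x) = kbar_x(n)            (omega(n) * rho(n) is constant in n)
#   kbar_n(N-1-x) = (-1)^n kbar_n(x) (binomial symmetry at p = 1/2)
# so only rows n <= floor((N-1)/2) are taken from the recurrence.
kraw_basis_half <- function(l, N) {
  Np <- N - 1
  mid <- Np %/% 2
  base <- kraw_recurrence_rows(min(l, mid + 1), N, 0.5)
  if (l <= mid + 1) return(base[seq_len(l), , drop = FALSE])
  K <- matrix(0, l, N)
  K[seq_len(mid + 1), ] <- base
  x <- 0:Np
  xr <- pmin(x, Np - x)
  for (n in (mid + 1):(l - 1)) {
    sgn <- ifelse(x > mid, (-1)^n, 1)
    K[n + 1, ] <- sgn * base[cbind(xr + 1, n + 1)]
  }
  K
}

#' Weighted Krawtchouk polynomial basis
#'
#' Returns the `l` x `N` matrix whose row `n + 1` holds the weighted
#' Krawtchouk polynomial of order `n` evaluated at `x = 0, ..., N - 1`.
#' Rows are orthonormal. Evaluation uses the three-term recurrence in the
#' order, completed by the exact transpose/reflection symmetries of the
#' weighted polynomials, which keeps full-order bases orthonormal to
#' ~1e-13 even for `N` in the hundreds (at the default `p = 0.5`).
#'
#' @param l number of polynomials (orders 0..l-1); must satisfy `l <= N`.
#' @param N number of sample points.
#' @param p binomial weight parameter in (0, 1); default 0.5 centers the
#'   basis support on the image.
#' @return a `krawtchouk_basis` matrix with attributes `order`, `N`, `p`.
#' @export
krawtchouk_basis <- function(l, N, p = 0.5) {
  if (l < 1 || l > N)
    stop_arg("order l must satisfy 1 <= l <= N (only N orthogonal polynomials exist on N points)")
  if (p <= 0 || p >= 1) stop_arg("p must be in (0, 1)")
  if (p == 0.5) {
    K <- kraw_basis_half(l, N)
  } else {
    if (N > 128)
      warning("Krawtchouk basis with p != 0.5 is numerically validated only for N <= 128")
    q <- min(p, 1 - p)
    K <- kraw_recurrence_rows(l, N, q)
    # entries with n > x from the stable transpose region
    if (l >= 2) for (n in 1:(l - 1)) {
      xs <- 0:(n - 1)
      K[n + 1, xs + 1] <- K[xs + 1, n + 1]
    }
    if (p > 0.5) { # reflection identity kbar_n(x; p) = (-1)^n kbar_n(N-1-x; 1-p)
      K <- K[, N:1, drop = FALSE] * (-1)^(0:(l - 1))
    }
  }
  structure(K, order = l, N = N, p = p, class = c("krawtchouk_basis", "matrix", "array"))
}

check_basis <- function(b, len, what) {
  if (!inherits(b, "krawtchouk_basis")) stop_arg(what, " must be a krawtchouk_basis")
  if (!is.null(len) && attr(b, "N") != len)
    stop_arg(what, " has length ", attr(b, "N"), " but the image axis has ", len, " points")
  invisible(b)
}

#' Krawtchouk moments of an image
#'
#' Computes the l x l moment matrix `Q = K1 A K2^T` where `A` is the image,
#' `K1` the basis on the row axis and `K2` the basis on the column axis:
#' `Q[n, m] = sum_x sum_y kbar_n(x) kbar_m(y) f(x, y)` with `x` indexing
#' rows and `y` columns.
#'
#' @param img image matrix (N rows x M columns).
#' @param basis_row `krawtchouk_basis` of length N for the row axis.
#' @param basis_col `krawtchouk_basis` of length M for the column axis
#'   (defaults to `basis_row` for square images).
#' @return a `krawtchouk_moments` matrix (l x l) with attributes
#'   `dims`, `order`, `p`.
#' @export
km_moments <- function(img, basis_row, basis_col = basis_row) {
  check_image(img)
  check_basis(basis_row, nrow(img), "basis_row")
  check_basis(basis_col, ncol(img), "basis_col")
  if (attr(basis_row, "order") != attr(basis_col, "order"))
    stop_arg("row and column bases must share the same order")
  Q <- unclass(basis_row) %*% unclass(img) %*% t(unclass(basis_col))
  structure(Q, dims = dim(img), order = attr(basis_row, "order"),
            p = c(attr(basis_row, "p"), attr(basis_col, "p")),
            class = c("krawtchouk_moments", "matrix", "array"))
}

#' Reconstruct an image from Krawtchouk moments
#'
#' Inverse transform `A = K1^T Q K2`. Exact (to rounding) when the moment
#' order equals both image dimensions; a truncated-order `Q` gives the
#' orthogonal projection onto the span of the retained polynomials.
#'
#' @param Q `krawtchouk_moments` matrix.
#' @param basis_row,basis_col the bases used to compute `Q`.
#' @return the reconstructed image matrix (values clipped to `[0, 1]` only
#'   on request via `clip`).
#' @param clip clip the output into `[0, 1]` (default FALSE: the raw
#'   projection is returned, which may slightly overshoot).
#' @export
km_reconstruct <- function(Q, basis_row, basis_col = basis_row, clip = FALSE) {
  if (!inherits(Q, "krawtchouk_moments")) stop_arg("Q must be a krawtchouk_moments object")
  dims <- attr(Q, "dims")
  check_basis(basis_row, dims[1], "basis_row")
  check_basis(basis_col, dims[2], "basis_col")
  if (attr(basis_row, "order") != nrow(Q) || attr(basis_col, "order") != ncol(Q))
    stop_arg("basis order does not match the moment matrix")
  A <- t(unclass(basis_row)) %*% unclass(Q) %*% unclass(basis_col)
  if (clip) A <- pmin(pmax(A, 0), 1)
  A
}

#' @exportS3Method
tidy.krawtchouk_moments <- function(x, ...) {
  l <- attr(x, "order")
  tibble(n = rep(0:(l - 1), each = l), m = rep(0:(l - 1), l),
         value = as.vector(t(unclass(x))))
}

# Bilinear sampling of img at fractional (row, col) coordinates; zero
# outside the support.
bilinear_sample <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- numeric(length(ri))
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  val(r0, c0) * (1 - fr) * (1 - fc) + val(r0 + 1, c0) * fr * (1 - fc) +
    val(r0, c0 + 1) * (1 - fr) * fc + val(r0 + 1, c0 + 1) * fr * fc
}

#' Pose-normalize an image
#'
#' Canonicalizes translation, rotation and scale of the imaged shape:
#' the intensity centroid is moved to the frame center, the principal axis
#' of the intensity distribution (second central moments) is rotated to
#' horizontal, and the image is scaled isotropically so that its total
#' intensity mass equals `mass_fraction` of the frame area. The remaining
#' 180-degree ambiguity of the principal axis is resolved by requiring the
#' third central moment along the horizontal axis to be non-negative.
#'
#' @param img image matrix with positive total mass.
#' @param frame output dimensions `c(rows, cols)`; defaults to `dim(img)`.
#' @param mass_fraction target total mass as a fraction of frame area
#'   (default 0.25).
#' @return the pose-normalized image on the `frame` grid.
#' @export
pose_normalize <- function(img, frame = dim(img), mass_fraction = 0.25) {
  check_image(img)
  m00 <- sum(img)
  if (m00 <= 0) stop_arg("pose_normalize: image has zero total mass")
  nr <- nrow(img); nc <- ncol(img)
  rows <- row(img); cols <- col(img)
  rc <- sum(rows * img) / m00
  cc <- sum(cols * img) / m00
  mu20 <- sum((cols - cc)^2 * img) / m00   # horizontal spread
  mu02 <- sum((rows - rc)^2 * img) / m00
  mu11 <- sum((cols - cc) * (rows - rc) * img) / m00
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  scl <- sqrt(mass_fraction * prod(frame) / m00)
  render <- function(extra_rot) {
    th <- theta + extra_rot
    ct <- cos(th); st <- sin(th)
    ti <- matrix(seq_len(frame[1]), frame[1], frame[2])
    tj <- matrix(seq_len(frame[2]), frame[1], frame[2], byrow = TRUE)
    du <- (tj - (frame[2] + 1) / 2) / scl
    dv <- (ti - (frame[1] + 1) / 2) / scl
    su <- cc + ct * du - st * dv
    sv <- rc + st * du + ct * dv
    out <- matrix(bilinear_sample(unclass(img), as.vector(sv), as.vector(su)),
                  frame[1], frame[2])
    # mass is preserved up to resampling error; renormalize exactly
    out * (mass_fraction * prod(frame) / max(sum(out), .Machine$double.eps))
  }
  g <- render(0)
  mu30 <- sum((col(g) - (frame[2] + 1) / 2)^3 * g)
  if (mu30 < 0) g <- render(pi)
  new_image(pmin(pmax(g, 0), 1))
}

#' Krawtchouk moment invariant features
#'
#' Pose-normalizes the image (translation / rotation / scale) and computes
#' its Krawtchouk moments at the given order; the flattened moment matrix
#' (row-major) is returned as an `order^2`-long feature vector. Features of
#' translated, rotated or rescaled copies of the same shape agree up to
#' resampling error.
#'
#' @param img image matrix with positive total mass.
#' @param order moment order `l` (features have length `l^2`).
#' @param p Krawtchouk weight parameter (default 0.5).
#' @param frame reference frame dimensions `c(rows, cols)` used for the
#'   normalized image; defaults to `dim(img)`.
#' @param mass_fraction scale target passed to [pose_normalize()].
#' @return numeric vector of length `order^2`, named `f_0 ... f_{l^2-1}`.
#' @export
km_invariant_features <- function(img, order, p = 0.5, frame = dim(img),
                                  mass_fraction = 0.25) {
  g <- pose_normalize(img, frame = frame, mass_fraction = mass_fraction)
  br <- krawtchouk_basis(order, nrow(g), p)
  bc <- if (ncol(g) == nrow(g)) br else krawtchouk_basis(order, ncol(g), p)
  Q <- km_moments(g, br, bc)
  f <- as.vector(t(unclass(Q)))  # row-major
  names(f) <- paste0("f_", seq_along(f) - 1)
  f
}

#' Krawtchouk moment features for images extracted as tibble rows
#'
#' Convenience wrapper mapping a list of images to a feature matrix of
#' flattened Krawtchouk moments (no pose normalization; intended for
#' pre-registered regions of interest).
#'
#' @param imgs list of image matrices with identical dimensions.
#' @param order moment order.
#' @param p weight parameter.
#' @return numeric matrix, one row per image, `order^2` columns.
#' @export
km_feature_matrix <- function(imgs, order, p = 0.5) {
  stopifnot(length(imgs) >= 1)
  d <- dim(imgs[[1]])
  br <- krawtchouk_basis(order, d[1], p)
  bc <- if (d[2] == d[1]) br else krawtchouk_basis(order, d[2], p)
  out <- t(vapply(imgs, function(im) {
    as.vector(t(unclass(km_moments(im, br, bc))))
  }, numeric(order^2)))
  colnames(out) <- paste0("km_", seq_len(order^2) - 1)
  out
}
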