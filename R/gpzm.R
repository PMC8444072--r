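# Generalized pseudo-Zernike moments over the unit disk.
#
# The radial polynomial of order n and repetition m (|m| <= n) with side
# parameter alpha > -1 is
#   R^a_nm(r) = (n+|m|+1)! / (a+1)_{n+|m|+1} *
#               sum_j (-1)^j (a+1)_{2n+1-j} / (j! (n-|m|-j)! (n+|m|+1-j)!) r^{n-j}
# and reduces to the classic pseudo-Zernike R_nm at alpha = 0. The weighted
# radial polynomial multiplies in sqrt of the normalization constant
#   (2n+a+2) (a+1+n-|m|)_{2|m|+1} / (2 pi (n-|m|+1)_{2|m|+1})
# and the weight (1-r)^{a/2}, making V_nm = Rbar e^{i m theta} orthonormal
# on the disk. Coefficients are evaluated in log-space with sign tracking;
# the alternating sum still cancels in double precision at high order, so a
# practical order cap is documented (see the methods vignette).

GPZM_ORDER_SOFT_CAP <- 25

# log Pochhammer (a)_k for a > 0
lpoch <- function(a, k) lgamma(a + k) - lgamma(a)

#' Generalized pseudo-Zernike radial polynomial
#'
#' @param n order (>= 0).
#' @param m repetition, `|m| <= n`.
#' @param alpha side parameter, `> -1`; `alpha = 0` gives the classic
#'   pseudo-Zernike radial polynomial.
#' @param r radii in `[0, 1]` (vectorized).
#' @return numeric vector `R^alpha_nm(r)`.
#' @export
gpzm_radial <- function(n, m, alpha, r) {
  m <- abs(m)
  if (m > n) stop_arg("|m| must be <= n")
  if (alpha <= -1) stop_arg("alpha must be > -1")
  # leading coefficient in log space; successors by exact term ratios, so
  # the lgamma rounding is a common factor that cancellation cannot amplify
  j <- 0:(n - m)
  coef <- numeric(n - m + 1)
  coef[1] <- exp(lgamma(n + m + 2) - lpoch(alpha + 1, n + m + 1) +
                   lpoch(alpha + 1, 2 * n + 1) -
                   lgamma(n - m + 1) - lgamma(n + m + 2))
  if (n - m >= 1) for (jj in 0:(n - m - 1)) {
    coef[jj + 2] <- -coef[jj + 1] * (n - m - jj) * (n + m + 1 - jj) /
      ((alpha + 2 * n + 1 - jj) * (jj + 1))
  }
  drop(outer(r, n - j, `^`) %*% coef)
}

#' Weighted generalized pseudo-Zernike radial polynomial
#'
#' `Rbar^alpha_nm(r)`, including the orthonormalization constant and the
#' `(1 - r)^(alpha/2)` weight, so that `Rbar e^(i m theta)` is orthonormal
#' over the unit disk.
#'
#' @inheritParams gpzm_radial
#' @return numeric vector `Rbar^alpha_nm(r)`.
#' @export
gpzm_weighted_radial <- function(n, m, alpha, r) {
  m <- abs(m)
  if (alpha < 0 && any(r >= 1)) stop_arg("r must be < 1 when alpha < 0")
  lnorm <- log(2 * n + alpha + 2) + lpoch(alpha + 1 + n - m, 2 * m + 1) -
    log(2 * pi) - lpoch(n - m + 1, 2 * m + 1)
  gpzm_radial(n, m, alpha, r) * exp(lnorm / 2) * (1 - r)^(alpha / 2)
}

#' Index set of generalized pseudo-Zernike moments
#'
#' @param n_max maximum order.
#' @param nonneg if TRUE, only repetitions `m >= 0` (the index set of the
#'   magnitude features, of size `(n_max+1)(n_max+2)/2`); otherwise all
#'   `(n_max+1)^2` pairs.
#' @return tibble with columns `n`, `m` in lexicographic order.
#' @export
gpzm_index <- function(n_max, nonneg = FALSE) {
  stopifnot(n_max >= 0)
  idx <- do.call(rbind, lapply(0:n_max, function(n) {
    m <- if (nonneg) 0:n else -n:n
    cbind(n = rep(n, length(m)), m = m)
  }))
  as_tibble(as.data.frame(idx))
}

# Pixel-center disk grid for an S x S image: coordinates, polar form, pixel
# area in disk units, and the in-disk mask. Rows index y top-to-bottom.
gpzm_grid <- function(S, oversample = 1) {
  n <- S * oversample
  u <- (2 * (0:(n - 1)) + 1) / n - 1          # in (-1, 1)
  x <- matrix(u, n, n, byrow = TRUE)
  y <- matrix(rev(u), n, n)
  r <- sqrt(x^2 + y^2)
  inside <- r <= 1
  list(r = r[inside], theta = atan2(y, x)[inside], inside = inside,
       dA = (2 / n)^2, n = n, oversample = oversample)
}

#' Generalized pseudo-Zernike moments of a square image
#'
#' The image is mapped onto the unit disk inscribed in the square frame
#' (pixels outside the disk are ignored) and the moment integrals are
#' approximated by a midpoint Riemann sum over pixel centers,
#' `Z_nm ~ sum conj(Vbar_nm(r, theta)) f dA`. For real images the set
#' satisfies `Z[n, -m] = Conj(Z[n, m])` exactly by construction.
#'
#' @param img square image matrix.
#' @param n_max maximum order.
#' @param alpha side parameter (> -1), default 0.
#' @param oversample integer subpixel refinement factor of the quadrature
#'   grid (default 1; 2 quadruples the number of quadrature nodes).
#' @return a `gpzm_set` object.
#' @export
gpzm_moments <- function(img, n_max, alpha = 0, oversample = 1) {
  check_image(img)
  if (nrow(img) != ncol(img)) stop_arg("gpzm_moments requires a square image")
  if (n_max > GPZM_ORDER_SOFT_CAP)
    warning("GPZM orders above ", GPZM_ORDER_SOFT_CAP,
            " lose precision to cancellation in double arithmetic")
  S <- nrow(img)
  g <- gpzm_grid(S, oversample)
  f <- if (oversample > 1) {
    idx <- rep(seq_len(S), each = oversample)
    unclass(img)[idx, idx][g$inside]
  } else unclass(img)[g$inside]
  vals <- matrix(complex(real = NA), n_max + 1, 2 * n_max + 1)
  for (n in 0:n_max) {
    for (m in 0:n) {
      rad <- gpzm_weighted_radial(n, m, alpha, g$r)
      z <- sum(rad * exp(complex(imaginary = -m * g$theta)) * f) * g$dA
      vals[n + 1, n_max + 1 + m] <- z
      vals[n + 1, n_max + 1 - m] <- Conj(z)
    }
  }
  structure(list(values = vals, n_max = n_max, alpha = alpha, S = S),
            class = "gpzm_set")
}

#' Extract one moment from a gpzm_set
#' @param Z a `gpzm_set`.
#' @param n,m order and repetition.
#' @return complex scalar `Z_nm`.
#' @export
gpzm_get <- function(Z, n, m) {
  stopifnot(inherits(Z, "gpzm_set"), n >= 0, n <= Z$n_max, abs(m) <= n)
  Z$values[n + 1, Z$n_max + 1 + m]
}

#' @export
print.gpzm_set <- function(x, ...) {
  cat("Generalized pseudo-Zernike moment set: n_max =", x$n_max,
      " alpha =", x$alpha, " grid =", x$S, "x", x$S, "\n")
  invisible(x)
}

#' @exportS3Method
tidy.gpzm_set <- function(x, ...) {
  idx <- gpzm_index(x$n_max)
  z <- x$values[cbind(idx$n + 1, x$n_max + 1 + idx$m)]
  tibble(n = idx$n, m = idx$m, re = Re(z), im = Im(z), modulus = Mod(z))
}

#' Reconstruct an image from generalized pseudo-Zernike moments
#'
#' Inverse transform `f(r, theta) ~ sum_nm Z_nm Vbar_nm(r, theta)`, rendered
#' on an `S x S` grid; pixels outside the inscribed disk are 0. The
#' imaginary residue (zero up to rounding for real sources) is discarded
#' after a magnitude check.
#'
#' @param Z a `gpzm_set`.
#' @param S output grid side length (defaults to the grid the moments were
#'   computed on).
#' @return reconstructed image matrix.
#' @export
gpzm_reconstruct <- function(Z, S = Z$S) {
  stopifnot(inherits(Z, "gpzm_set"))
  g <- gpzm_grid(S)
  acc <- complex(real = numeric(length(g$r)))
  for (n in 0:Z$n_max) {
    for (m in 0:n) {
      z <- gpzm_get(Z, n, m)
      rad <- gpzm_weighted_radial(n, m, Z$alpha, g$r)
      v <- z * rad * exp(complex(imaginary = m * g$theta))
      acc <- acc + if (m == 0) v else v + Conj(v)
    }
  }
  if (max(abs(Im(acc))) > 1e-6 * max(1, max(abs(Re(acc)))))
    warning("non-negligible imaginary residue in GPZM reconstruction")
  out <- matrix(0, S, S)
  out[g$inside] <- Re(acc)
  out
}

#' Rotation-robust generalized pseudo-Zernike features
#'
#' Magnitudes `|Z_nm|` for `m >= 0`, flattened in `(n, m)` lexicographic
#' order; the feature vector has length `(n_max+1)(n_max+2)/2`. Magnitudes
#' are invariant to image rotation up to quadrature error.
#'
#' @inheritParams gpzm_moments
#' @return named numeric feature vector.
#' @export
gpzm_features <- function(img, n_max, alpha = 0, oversample = 1) {
  Z <- gpzm_moments(img, n_max, alpha, oversample)
  idx <- gpzm_index(n_max, nonneg = TRUE)
  f <- Mod(Z$values[cbind(idx$n + 1, Z$n_max + 1 + idx$m)])
  names(f) <- paste0("gpzm_", idx$n, "_", idx$m)
  f
}

# Precomputed conjugated basis over the disk pixels of an S x S grid,
# as a (#pixels x #moments) complex matrix for the m >= 0 half. Reused
# across images of identical geometry in batch feature extraction.
gpzm_basis_cache <- function(S, n_max, alpha = 0) {
  g <- gpzm_grid(S)
  idx <- gpzm_index(n_max, nonneg = TRUE)
  B <- matrix(complex(real = 0), length(g$r), nrow(idx))
  for (k in seq_len(nrow(idx))) {
    rad <- gpzm_weighted_radial(idx$n[k], idx$m[k], alpha, g$r)
    B[, k] <- rad * exp(complex(imaginary = -idx$m[k] * g$theta))
  }
  list(B = B, idx = idx, inside = g$inside, dA = g$dA, S = S,
       n_max = n_max, alpha = alpha)
}

#' Batch GPZM magnitude features with a shared basis
#'
#' @param imgs list of square images with identical side length.
#' @param n_max maximum order.
#' @param alpha side parameter.
#' @return numeric matrix, one row per image.
#' @export
gpzm_feature_matrix <- function(imgs, n_max, alpha = 0) {
  stopifnot(length(imgs) >= 1)
  S <- nrow(imgs[[1]])
  cache <- gpzm_basis_cache(S, n_max, alpha)
  out <- t(vapply(imgs, function(im) {
    check_image(im)
    if (nrow(im) != S || ncol(im) != S) stop_arg("all images must be ", S, " x ", S)
    Mod(crossprod(cache$B, unclass(im)[cache$inside])[, 1] * cache$dA)
  }, numeric(nrow(cache$idx))))
  colnames(out) <- paste0("gpzm_", cache$idx$n, "_", cache$idx$m)
  out
}
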