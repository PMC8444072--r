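# Shared fixtures and independent oracles, built in code.

img_of <- function(m, binary = FALSE) orthomoments:::new_image(m, binary = binary)

# smooth Gaussian blob, values in [0, 1]
gaussian_blob <- function(nr, nc = nr, cy = (nr + 1) / 2, cx = (nc + 1) / 2,
                          sigma = min(nr, nc) / 6) {
  y <- matrix(seq_len(nr), nr, nc)
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  img_of(exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2)))
}

# filled binary ellipse with optional rotation (angle in radians)
ellipse_image <- function(nr, nc, cy, cx, a, b, angle = 0) {
  y <- matrix(seq_len(nr), nr, nc) - cy
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  xr <- cos(angle) * x + sin(angle) * y
  yr <- -sin(angle) * x + cos(angle) * y
  img_of(((xr / a)^2 + (yr / b)^2 <= 1) * 1, binary = TRUE)
}

rotate90 <- function(img) {
  out <- t(unclass(img))[ncol(img):1, , drop = FALSE]
  orthomoments:::new_image(out, binary = orthomoments::is_binary_image(img))
}

rotate180 <- function(img) {
  out <- unclass(img)[nrow(img):1, ncol(img):1, drop = FALSE]
  orthomoments:::new_image(out, binary = orthomoments::is_binary_image(img))
}

# Independent weighted-Krawtchouk oracle: direct hypergeometric summation
# kbar_n(x) = 2F1(-n, -x; -(N-1); 1/p) * sqrt(omega(x) / rho(n)), evaluated
# term by term. Safe for small N only (the sum cancels at large N).
kraw_direct <- function(n, x, N, p = 0.5) {
  Np <- N - 1
  smax <- min(n, x)
  terms <- numeric(smax + 1)
  terms[1] <- 1
  if (smax >= 1) for (s in 0:(smax - 1)) {
    # exact term ratio of the hypergeometric series (small-integer products)
    terms[s + 2] <- -terms[s + 1] * (n - s) * (x - s) / ((Np - s) * p * (s + 1))
  }
  hyp <- sum(terms)
  w <- exp(lchoose(Np, x) + x * log(p) + (Np - x) * log1p(-p))
  rho <- ((1 - p) / p)^n * exp(lgamma(n + 1) + lgamma(Np - n + 1) - lgamma(Np + 1))
  hyp * sqrt(w / rho)
}

# Independent generalized pseudo-Zernike radial oracle: exact-rational-style
# brute force with plain factorials (safe for small n).
gpzm_radial_brute <- function(n, m, alpha, r) {
  m <- abs(m)
  poch <- function(a, k) if (k == 0) 1 else prod(a + 0:(k - 1))
  pre <- factorial(n + m + 1) / poch(alpha + 1, n + m + 1)
  out <- 0
  for (j in 0:(n - m)) {
    out <- out + (-1)^j * poch(alpha + 1, 2 * n + 1 - j) /
      (factorial(j) * factorial(n - m - j) * factorial(n + m + 1 - j)) * r^(n - j)
  }
  pre * out
}

# bisection quantile oracle on the regularized incomplete beta function
beta_quantile_bisect <- function(q, a, b, tol = 1e-12) {
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pbeta(mid, a, b) < q) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

rel_dist <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum((a + b)^2) / 4 + 1e-300)
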