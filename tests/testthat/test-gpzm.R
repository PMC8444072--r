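test_that("radial polynomial closed forms hold", {
  r <- c(0.1, 0.35, 0.5, 0.9)
  for (a in c(-0.5, 0, 1.5)) expect_equal(gpzm_radial(0, 0, a, r), rep(1, 4))
  for (n in 1:4) expect_equal(gpzm_radial(n, n, 0, r), r^n, tolerance = 1e-12)
  # classic pseudo-Zernike R_10(r) = 3r - 2 (two-term alternating sum)
  expect_equal(gpzm_radial(1, 0, 0, r), 3 * r - 2, tolerance = 1e-12)
  expect_error(gpzm_radial(2, 3, 0, r), "<= n")
})

test_that("log-gamma evaluation matches brute-force sums up to n = 5", {
  r <- seq(0.1, 0.9, by = 0.1)
  for (a in c(0, 0.7, 2)) {
    for (n in 0:5) for (m in 0:n) {
      got <- gpzm_radial(n, m, a, r)
      want <- gpzm_radial_brute(n, m, a, r)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("log-gamma evaluation matches exact rational arithmetic up to n = 8", {
  # reference values computed once with exact rational arithmetic
  # (symbolic factorials/Pochhammers, rational alpha and r), 20 digits
  exact_radial <- tibble::tribble(
    ~alpha, ~n, ~m, ~r, ~value,
    0.0, 5L, 0L, 0.1, 0.03862,
    0.0, 5L, 0L, 0.5, -0.3125,
    0.0, 5L, 0L, 0.9, -0.43962,
    0.0, 6L, 1L, 0.1, -1.396313,
    0.0, 6L, 1L, 0.5, -0.390625,
    0.0, 6L, 1L, 0.9, -0.373833,
    0.0, 7L, 2L, 0.1, -0.8830097,
    0.0, 7L, 2L, 0.5, -0.0078125,
    0.0, 7L, 2L, 0.9, -0.2345193,
    0.0, 8L, 0L, 0.1, -1.0225529,
    0.0, 8L, 0L, 0.5, 0.2734375,
    0.0, 8L, 0L, 0.9, 0.0951111,
    0.0, 8L, 3L, 0.1, -0.32079212,
    0.0, 8L, 3L, 0.5, 0.328125,
    0.0, 8L, 3L, 0.9, -0.07427052,
    0.0, 8L, 8L, 0.1, 1e-8,
    0.0, 8L, 8L, 0.5, 0.00390625,
    0.0, 8L, 8L, 0.9, 0.43046721,
    0.7, 5L, 0L, 0.1, 0.3084642672975,
    0.7, 5L, 0L, 0.5, -0.1159084453125,
    0.7, 5L, 0L, 0.9, -0.5538667299225,
    0.7, 6L, 1L, 0.1, -1.19907309084525,
    0.7, 6L, 1L, 0.5, -0.46820695703125,
    0.7, 6L, 1L, 0.9, -0.73294258650525,
    0.7, 7L, 2L, 0.1, -0.813940820642025,
    0.7, 7L, 2L, 0.5, -0.208589220703125,
    0.7, 7L, 2L, 0.9, -0.692396418672225,
    0.7, 8L, 0L, 0.1, -0.89754339243859140516,
    0.7, 8L, 0L, 0.5, 0.44255405800579833984,
    0.7, 8L, 0L, 0.9, -0.41302100502584805516,
    0.7, 8L, 3L, 0.1, -0.3031611855999525,
    0.7, 8L, 3L, 0.5, 0.1676890810546875,
    0.7, 8L, 3L, 0.9, -0.5344703997207525,
    0.7, 8L, 8L, 0.1, 1e-8,
    0.7, 8L, 8L, 0.5, 0.00390625,
    0.7, 8L, 8L, 0.9, 0.43046721,
    2.0, 5L, 0L, 0.1, 0.69087,
    2.0, 5L, 0L, 0.5, 0.46875,
    2.0, 5L, 0L, 0.9, 2.11863,
    2.0, 6L, 1L, 0.1, -0.872277,
    2.0, 6L, 1L, 0.5, -0.328125,
    2.0, 6L, 1L, 0.9, 0.238203,
    2.0, 7L, 2L, 0.1, -0.6948312,
    2.0, 7L, 2L, 0.5, -0.4375,
    2.0, 7L, 2L, 0.9, -0.8042328,
    2.0, 8L, 0L, 0.1, -0.59646978,
    2.0, 8L, 0L, 0.5, 0.4921875,
    2.0, 8L, 0L, 0.9, -2.97874818,
    2.0, 8L, 3L, 0.1, -0.27217572,
    2.0, 8L, 3L, 0.5, -0.140625,
    2.0, 8L, 3L, 0.9, -1.27887012,
    2.0, 8L, 8L, 0.1, 1e-8,
    2.0, 8L, 8L, 0.5, 0.00390625,
    2.0, 8L, 8L, 0.9, 0.43046721
  )
  for (i in seq_len(nrow(exact_radial))) {
    got <- gpzm_radial(exact_radial$n[i], exact_radial$m[i],
                       exact_radial$alpha[i], exact_radial$r[i])
    expect_equal(got, exact_radial$value[i], tolerance = 1e-10)
  }
})

test_that("weighted radial normalization gives the constant basis function", {
  expect_equal(gpzm_weighted_radial(0, 0, 0, c(0.2, 0.8)),
               rep(sqrt(1 / pi), 2), tolerance = 1e-12)
  # alpha weight (1-r)^(a/2) < 1 separates alpha = 0 from alpha = 2
  expect_false(isTRUE(all.equal(gpzm_weighted_radial(1, 1, 0, 0.5),
                                gpzm_weighted_radial(1, 1, 2, 0.5))))
})

test_that("weighted basis is orthonormal under fine radial quadrature", {
  rr <- seq(1e-7, 1 - 1e-7, length.out = 60000)
  dr <- rr[2] - rr[1]
  for (a in c(0, 1.3)) {
    for (m in 0:2) for (n in m:4) for (k in m:4) {
      v <- 2 * pi * sum(gpzm_weighted_radial(n, m, a, rr) *
                          gpzm_weighted_radial(k, m, a, rr) * rr) * dr
      expect_equal(v, as.numeric(n == k), tolerance = 1e-4)
    }
  }
})

test_that("constant image concentrates on Z00 = sqrt(pi)", {
  Z <- gpzm_moments(img_of(matrix(1, 150, 150)), 4)
  z00 <- Re(gpzm_get(Z, 0, 0))
  expect_lt(abs(z00 - sqrt(pi)) / sqrt(pi), 0.01)
  td <- tidy(Z)
  others <- td$modulus[!(td$n == 0 & td$m == 0)]
  expect_lt(max(others), 0.01 * z00)
})

test_that("moment sets of real images have exact conjugate symmetry", {
  set.seed(11)
  Z <- gpzm_moments(img_of(matrix(runif(48^2), 48, 48)), 6)
  for (n in 0:6) for (m in 0:n) {
    expect_identical(gpzm_get(Z, n, -m), Conj(gpzm_get(Z, n, m)))
  }
  expect_error(gpzm_moments(img_of(matrix(0.5, 4, 6)), 2), "square")
})

test_that("reconstruction inverts the transform on simple inputs", {
  # single moment Z00 = sqrt(pi) renders the constant 1 on the disk
  Z <- gpzm_moments(img_of(matrix(1, 120, 120)), 0)
  rec <- gpzm_reconstruct(Z)
  g <- orthomoments:::gpzm_grid(120)
  expect_equal(mean(rec[g$inside]), 1, tolerance = 0.01)
  expect_equal(rec[1, 1], 0)  # outside the disk
  # all-zero set reconstructs to zero
  Z0 <- gpzm_moments(img_of(matrix(0, 40, 40)), 3)
  expect_equal(max(abs(gpzm_reconstruct(Z0))), 0)
})

test_that("reconstruction error decreases with order on a smooth blob", {
  blob <- gaussian_blob(80, sigma = 12)
  mse_at <- function(nm) {
    img_mse(gpzm_reconstruct(gpzm_moments(blob, nm)), blob)
  }
  expect_lt(mse_at(12), mse_at(3))
})

test_that("feature vectors have the triangular length and vanish on zero images", {
  expect_equal(nrow(gpzm_index(126, nonneg = TRUE)), 8128)
  expect_equal(nrow(gpzm_index(10, nonneg = TRUE)), 66)
  expect_equal(nrow(gpzm_index(5)), 36)
  f <- gpzm_features(img_of(matrix(0, 32, 32)), 4)
  expect_length(f, 15)
  expect_equal(max(abs(f)), 0)
})

test_that("feature magnitudes are rotation invariant on smooth blobs", {
  blob <- gaussian_blob(100, cy = 38, cx = 61, sigma = 13)
  f1 <- gpzm_features(blob, 10)
  f2 <- gpzm_features(rotate90(blob), 10)
  expect_lt(rel_dist(f1, f2), 0.05)
})
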