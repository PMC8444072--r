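# Synthetic wing-venation images: multi-class binary images built from a
# fixed 19-landmark venation template inside an elliptical wing outline.
# Each class displaces the template control points by a class-specific
# offset of magnitude delta; each specimen adds Gaussian jitter. The
# landmark coordinates are returned alongside the rasterized image, giving
# a paired landmark-morphometry arm for the same specimens.

# Fixed venation template: 19 control points in normalized (u, v)
# coordinates (u along the width, v along the height), and the 6 polylines
# (vein paths) threading them. Arbitrary but frozen.
WING_TEMPLATE <- matrix(c(
  0.05, 0.50,
  0.20, 0.35,  0.40, 0.28,  0.62, 0.25,  0.85, 0.30,
  0.20, 0.50,  0.45, 0.48,  0.70, 0.45,  0.92, 0.48,
  0.20, 0.65,  0.42, 0.68,  0.65, 0.70,  0.85, 0.66,
  0.40, 0.38,  0.60, 0.35,
  0.45, 0.58,  0.62, 0.57,
  0.30, 0.75,  0.55, 0.80
), ncol = 2, byrow = TRUE)

WING_VEINS <- list(
  c(1, 2, 3, 4, 5),
  c(1, 6, 7, 8, 9),
  c(1, 10, 11, 12, 13),
  c(3, 14, 15, 8),
  c(7, 16, 17, 12),
  c(10, 18, 19, 13)
)

#' Specification for the synthetic wing generator
#'
#' @param n_classes number of species classes `s` (>= 2).
#' @param n_per_class specimens per class; a scalar or a length-`s` vector.
#'   The default, 5 per class with the last class at 4, yields 74 specimens
#'   for 15 classes.
#' @param width,height image dimensions in pixels (default 724 x 254).
#' @param delta between-class effect size: pixel displacement magnitude of
#'   the vein control points (default 8).
#' @param sigma_w within-class jitter sd of the control points in pixels
#'   (default 1.5).
#' @param thickness vein stroke thickness in pixels.
#' @param speckle_rate probability a background pixel is flipped on
#'   (scanning artefact stand-in).
#' @param seed integer seed; the generator is a pure function of the spec.
#' @return a `wing_spec` list.
#' @export
wing_spec <- function(n_classes = 15,
                      n_per_class = c(rep(5, n_classes - 1), 4),
                      width = 724, height = 254,
                      delta = 8, sigma_w = 1.5,
                      thickness = 3, speckle_rate = 2e-4, seed = 1) {
  if (n_classes < 2) stop_arg("need at least 2 classes")
  if (length(n_per_class) == 1) n_per_class <- rep(n_per_class, n_classes)
  if (length(n_per_class) != n_classes) stop_arg("n_per_class must have length n_classes")
  if (delta < 0) stop_arg("delta must be >= 0")
  if (sigma_w <= 0) stop_arg("sigma_w must be > 0")
  if (width < 60 || height < 30) stop_arg("frame too small to contain the vein skeleton")
  structure(list(n_classes = n_classes, n_per_class = n_per_class,
                 width = width, height = height, delta = delta,
                 sigma_w = sigma_w, thickness = thickness,
                 speckle_rate = speckle_rate, seed = seed),
            class = "wing_spec")
}

# stamp a thick line segment (pixel coordinates, x = column, y = row)
draw_segment <- function(img, x0, y0, x1, y1, thickness) {
  h <- thickness / 2
  rlo <- max(1L, floor(min(y0, y1) - h)); rhi <- min(nrow(img), ceiling(max(y0, y1) + h))
  clo <- max(1L, floor(min(x0, x1) - h)); chi <- min(ncol(img), ceiling(max(x0, x1) + h))
  if (rlo > rhi || clo > chi) return(img)
  rr <- rlo:rhi; cc <- clo:chi
  py <- matrix(rr, length(rr), length(cc))
  px <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx^2 + dy^2
  t <- if (len2 == 0) matrix(0, length(rr), length(cc)) else
    pmin(pmax(((px - x0) * dx + (py - y0) * dy) / len2, 0), 1)
  d2 <- (px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2
  img[rlo:rhi, clo:chi][d2 <= h^2] <- 1
  img
}

draw_polyline <- function(img, xy, thickness) {
  for (i in seq_len(nrow(xy) - 1)) {
    img <- draw_segment(img, xy[i, 1], xy[i, 2], xy[i + 1, 1], xy[i + 1, 2], thickness)
  }
  img
}

# elliptical wing outline as a polyline ring
wing_outline <- function(width, height) {
  t <- seq(0, 2 * pi, length.out = 181)
  cbind(width / 2 + 0.47 * width * cos(t), height / 2 + 0.42 * height * sin(t))
}

#' Generate synthetic wing images with paired landmarks
#'
#' Deterministic given the spec (seed included): per-class control-point
#' displacements are drawn from a class-keyed substream, per-specimen
#' jitter from a specimen-keyed substream.
#'
#' @param spec a [wing_spec()].
#' @return a tibble with columns `id`, `label` (character `sp01`, ...),
#'   `image` (list of binary matrices, height x width) and `landmarks`
#'   (list of 19 x 2 matrices of (x, y) pixel coordinates).
#' @export
gen_wings <- function(spec) {
  stopifnot(inherits(spec, "wing_spec"))
  W <- spec$width; H <- spec$height
  base <- cbind(WING_TEMPLATE[, 1] * (W - 1) + 1, WING_TEMPLATE[, 2] * (H - 1) + 1)
  # class-specific displacement directions (unit vectors per landmark)
  class_off <- lapply(seq_len(spec$n_classes), function(cl) {
    with_seed(substream_seed(spec$seed, cl), {
      ang <- runif(nrow(base), 0, 2 * pi)
      spec$delta * cbind(cos(ang), sin(ang))
    })
  })
  outline <- wing_outline(W, H)
  rows <- list()
  idx <- 0
  for (cl in seq_len(spec$n_classes)) {
    for (i in seq_len(spec$n_per_class[cl])) {
      idx <- idx + 1
      lm <- with_seed(substream_seed(spec$seed, 1000 + idx), {
        pts <- base + class_off[[cl]] +
          matrix(rnorm(2 * nrow(base), 0, spec$sigma_w), ncol = 2)
        pts[, 1] <- pmin(pmax(pts[, 1], 2), W - 1)
        pts[, 2] <- pmin(pmax(pts[, 2], 2), H - 1)
        pts
      })
      img <- matrix(0, H, W)
      img <- draw_polyline(img, outline, spec$thickness)
      for (v in WING_VEINS) img <- draw_polyline(img, lm[v, , drop = FALSE], spec$thickness)
      if (spec$speckle_rate > 0) {
        img <- with_seed(substream_seed(spec$seed, 2000000 + idx), {
          flip <- runif(length(img)) < spec$speckle_rate
          img[flip] <- 1
          img
        })
      }
      rows[[idx]] <- list(id = sprintf("wing_%03d", idx),
                          label = sprintf("sp%02d", cl),
                          image = list(new_image(img, binary = TRUE)),
                          landmarks = list(lm))
    }
  }
  dplyr::bind_rows(rows)
}

#' Landmark alignment features (light Procrustes analogue)
#'
#' Each landmark configuration is centered, scaled to unit centroid size,
#' and rotated onto a reference configuration by the least-squares
#' (Kabsch) rotation; the aligned coordinates are flattened to `2L`
#' features. Configurations differing only by translation, rotation and
#' scale map to identical features. This is a deliberately light stand-in
#' for a full Generalized Procrustes Analysis (no iterative mean shape).
#'
#' @param landmarks list of `L x 2` coordinate matrices (equal `L`).
#' @param reference optional reference configuration; defaults to the
#'   first, itself centered and scaled.
#' @return numeric matrix, one row per configuration, `2L` columns
#'   (`x1..xL, y1..yL` of the aligned coordinates).
#' @export
landmark_features <- function(landmarks, reference = NULL) {
  stopifnot(length(landmarks) >= 1)
  L <- nrow(landmarks[[1]])
  norm_cfg <- function(P) {
    if (nrow(P) != L) stop_arg("all configurations need the same landmark count")
    P <- sweep(P, 2, colMeans(P))
    cs <- sqrt(sum(P^2))
    if (cs < 1e-12) stop_arg("degenerate landmark configuration (all points coincide)")
    P / cs
  }
  ref <- norm_cfg(reference %||% landmarks[[1]])
  out <- t(vapply(landmarks, function(P) {
    P <- norm_cfg(P)
    s <- svd(crossprod(P, ref))
    R <- s$u %*% diag(c(1, det(s$u %*% t(s$v)))) %*% t(s$v)  # proper rotation
    as.vector(P %*% R)
  }, numeric(2 * L)))
  colnames(out) <- c(paste0("x", seq_len(L)), paste0("y", seq_len(L)))
  out
}
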