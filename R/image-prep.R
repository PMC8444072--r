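# Image preprocessing: PNG I/O, normalization, resizing, histogram
# equalization, binarization and centered crop/pad.
#
# Images are plain numeric matrices with values in [0, 1]; rows index the
# vertical axis and columns the horizontal axis. Binary images carry the
# attribute "binary" = TRUE and take values in {0, 1}.

new_image <- function(m, binary = FALSE) {
  stopifnot(is.matrix(m), is.numeric(m))
  attr(m, "binary") <- isTRUE(binary)
  m
}

#' Is an image binary?
#' @param img image matrix.
#' @return logical flag.
#' @export
is_binary_image <- function(img) isTRUE(attr(img, "binary"))

check_image <- function(img, what = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop_arg(what, " must be a numeric matrix")
  if (anyNA(img) || any(!is.finite(img)))
    stop_arg(what, " contains non-finite values")
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9)
    stop_arg(what, " has values outside [0, 1]")
  invisible(img)
}

#' Read a grayscale image from a PNG file
#'
#' RGB images are converted to grayscale by the unweighted channel mean;
#' an alpha channel, if present, is dropped. Pixel values are returned on
#' the [0, 1] scale (8-bit value v maps to v/255).
#'
#' @param path path to a PNG file.
#' @return an image matrix with values in [0, 1].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path, call. = FALSE)
  a <- tryCatch(png::readPNG(path),
                error = function(e) stop("cannot decode PNG file: ", path, call. = FALSE))
  if (length(dim(a)) == 3L) {
    nch <- min(dim(a)[3L], 3L)  # ignore alpha
    a <- apply(a[, , seq_len(nch), drop = FALSE], c(1, 2), mean)
  }
  new_image(pmin(pmax(a, 0), 1))
}

#' Write an image to a PNG file
#' @param img image matrix in [0, 1].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  check_image(img)
  png::writePNG(pmin(pmax(unclass(img), 0), 1), path)
  invisible(path)
}

#' Min-max normalize an image to span [0, 1]
#'
#' A constant image is returned unchanged.
#'
#' @param img image matrix.
#' @return normalized image.
#' @export
normalize_minmax <- function(img) {
  check_image(img)
  rng <- range(img)
  if (diff(rng) == 0) return(img)
  new_image((img - rng[1]) / diff(rng))
}

#' Resize an image
#'
#' Bilinear interpolation for grayscale images, nearest-neighbour for binary
#' images (so {0, 1} values are preserved).
#'
#' @param img image matrix.
#' @param height,width target dimensions (>= 1).
#' @return resized image with dimensions `height` x `width`.
#' @export
resize_image <- function(img, height, width) {
  check_image(img)
  if (height < 1 || width < 1) stop_arg("target dimensions must be >= 1")
  if (height == nrow(img) && width == ncol(img)) return(img)
  filt <- if (is_binary_image(img)) "none" else "bilinear"
  out <- EBImage::resize(unclass(img), w = height, h = width, filter = filt)
  new_image(pmin(pmax(out, 0), 1), binary = is_binary_image(img))
}

#' Histogram equalization
#'
#' Monotone intensity remapping by the empirical CDF computed on `n_bins`
#' equal-width bins over [0, 1]. Each pixel maps to the cumulative mass of
#' its bin, so output values lie in (0, 1]. A constant image is returned
#' unchanged.
#'
#' @param img grayscale (non-binary) image.
#' @param n_bins number of histogram bins (default 256).
#' @return equalized image.
#' @export
hist_equalize <- function(img, n_bins = 256) {
  check_image(img)
  if (is_binary_image(img)) stop_arg("hist_equalize expects a grayscale image")
  if (diff(range(img)) == 0) return(img)
  bin <- pmin(floor(img * n_bins), n_bins - 1L)  # bin index 0..n_bins-1
  counts <- tabulate(bin + 1L, nbins = n_bins)
  cdf <- cumsum(counts) / length(img)
  new_image(matrix(cdf[bin + 1L], nrow(img), ncol(img)))
}

#' Threshold an image to binary
#' @param img image matrix.
#' @param threshold scalar in (0, 1); pixels strictly above it become 1.
#' @return binary image.
#' @export
binarize <- function(img, threshold = 0.5) {
  check_image(img)
  if (threshold <= 0 || threshold >= 1) stop_arg("threshold must be in (0, 1)")
  new_image((unclass(img) > threshold) * 1, binary = TRUE)
}

#' Centered crop or zero-pad to target dimensions
#'
#' Larger inputs are center-cropped, smaller ones zero-padded; the two can
#' mix across axes. Offsets are split evenly, extra pixel toward the end.
#'
#' @param img image matrix.
#' @param height,width target dimensions.
#' @return image with dimensions `height` x `width`.
#' @export
crop_pad <- function(img, height, width) {
  check_image(img)
  out <- matrix(0, height, width)
  copy_axis <- function(src_n, dst_n) {
    n <- min(src_n, dst_n)
    s0 <- (src_n - n) %/% 2
    d0 <- (dst_n - n) %/% 2
    list(src = s0 + seq_len(n), dst = d0 + seq_len(n))
  }
  r <- copy_axis(nrow(img), height)
  c <- copy_axis(ncol(img), width)
  out[r$dst, c$dst] <- img[r$src, c$src]
  new_image(out, binary = is_binary_image(img))
}

#' Read an image manifest
#'
#' A manifest is a CSV with at least columns `path` and `label`, optionally
#' the expert-feature columns `assessment`, `shape`, `margin`, `density`,
#' `subtlety`.
#'
#' @param path CSV path.
#' @return a tibble, one row per image.
#' @export
read_manifest <- function(path) {
  m <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("path", "label") %in% names(m)))
    stop_arg("manifest must have columns 'path' and 'label'")
  if (anyDuplicated(m$path)) stop_arg("manifest paths must be unique")
  if (length(unique(m$label)) < 2) stop_arg("manifest needs >= 2 classes")
  m
}

#' Write an image manifest
#' @param manifest a data frame with columns `path`, `label`, ....
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
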