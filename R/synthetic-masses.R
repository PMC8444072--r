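# Synthetic mammographic mass-like regions of interest: two classes of
# grayscale blobs in correlated-noise backgrounds, plus five correlated
# categorical expert features sampled from class-conditional tables
# (mirroring BI-RADS assessment, mass shape, mass margin, breast density
# and subtlety). Benign masses are anisotropic blobs with a sharp
# sigmoidal margin; malignant masses sit on the same elliptical base but
# add a radial spiculation pattern r(theta) = r0 (1 + a |sin(k theta / 2)|^gamma)
# and a blurred margin. With zero spiculation and equal margin blur the
# two class generators coincide (the null configuration).

default_expert_tables <- function() {
  list(
    assessment = list(levels = c("0", "1", "2", "3", "4", "5", "6"),
                      benign    = c(0.02, 0.03, 0.30, 0.40, 0.20, 0.04, 0.01),
                      malignant = c(0.01, 0.01, 0.03, 0.10, 0.40, 0.35, 0.10)),
    shape = list(levels = c("oval", "round", "lobulated", "irregular"),
                 benign    = c(0.40, 0.30, 0.20, 0.10),
                 malignant = c(0.10, 0.10, 0.25, 0.55)),
    margin = list(levels = c("circumscribed", "obscured", "ill_defined", "spiculated"),
                  benign    = c(0.50, 0.25, 0.18, 0.07),
                  malignant = c(0.08, 0.15, 0.37, 0.40)),
    density = list(levels = c("1", "2", "3", "4"),
                   benign    = c(0.10, 0.40, 0.35, 0.15),
                   malignant = c(0.09, 0.39, 0.36, 0.16)),
    subtlety = list(levels = c("1", "2", "3", "4", "5"),
                    benign    = c(0.10, 0.20, 0.30, 0.25, 0.15),
                    malignant = c(0.06, 0.15, 0.28, 0.28, 0.23))
  )
}

check_tables <- function(tables) {
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    for (cl in c("benign", "malignant")) {
      p <- tb[[cl]]
      if (length(p) != length(tb$levels) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
        stop_arg("expert table '", nm, "' (", cl, ") is not a probability vector over its levels")
    }
  }
  invisible(tables)
}

#' Specification for the synthetic mass generator
#'
#' Class prevalence defaults to 48 benign / 52 malignant per 100 samples.
#'
#' @param n_benign,n_malignant class sample counts.
#' @param size square image side length in pixels (default 300).
#' @param spiculation_amp spiculation amplitude `a` of the malignant
#'   boundary (0 disables; default 0.35).
#' @param n_spikes spike count parameter `k` (default 11).
#' @param spike_sharpness exponent `gamma` of the spiculation profile.
#' @param margin_blur_benign,margin_blur_malignant sigmoidal margin widths
#'   (fraction of the mass radius).
#' @param anisotropy eccentricity of the elliptical mass base (0 = circle).
#' @param noise_amp amplitude of the correlated background noise.
#' @param noise_scale correlation length of the background, in pixels.
#' @param contrast mass-to-background intensity contrast.
#' @param expert_tables class-conditional categorical tables for the five
#'   expert features (see `default_expert_tables`); each entry must be a
#'   probability vector over its levels.
#' @param seed integer seed.
#' @return a `mass_spec` list.
#' @export
mass_spec <- function(n_benign = 48, n_malignant = 52, size = 300,
                      spiculation_amp = 0.35, n_spikes = 11,
                      spike_sharpness = 0.8,
                      margin_blur_benign = 0.04, margin_blur_malignant = 0.12,
                      anisotropy = 0.25, noise_amp = 0.12, noise_scale = 24,
                      contrast = 0.7,
                      expert_tables = default_expert_tables(), seed = 1) {
  check_tables(expert_tables)
  if (size < 32) stop_arg("size must be >= 32")
  structure(list(n_benign = n_benign, n_malignant = n_malignant, size = size,
                 spiculation_amp = spiculation_amp, n_spikes = n_spikes,
                 spike_sharpness = spike_sharpness,
                 margin_blur_benign = margin_blur_benign,
                 margin_blur_malignant = margin_blur_malignant,
                 anisotropy = anisotropy, noise_amp = noise_amp,
                 noise_scale = noise_scale, contrast = contrast,
                 expert_tables = expert_tables, seed = seed),
            class = "mass_spec")
}

# smooth correlated noise field: coarse white noise, bilinearly upsampled
correlated_noise <- function(size, scale) {
  n <- max(2L, ceiling(size / scale))
  coarse <- matrix(rnorm(n * n), n, n)
  EBImage::resize(coarse, w = size, h = size, filter = "bilinear")
}

render_mass <- function(spec, malignant) {
  S <- spec$size
  half <- S / 2
  cx <- half + runif(1, -0.08, 0.08) * S
  cy <- half + runif(1, -0.08, 0.08) * S
  r0 <- runif(1, 0.24, 0.34) * half
  ecc <- 1 + spec$anisotropy * runif(1, 0.2, 1)
  phi <- runif(1, 0, pi)
  phase <- runif(1, 0, 2 * pi)
  x <- matrix(seq_len(S), S, S, byrow = TRUE) - cx
  y <- matrix(seq_len(S), S, S) - cy
  xr <- cos(phi) * x + sin(phi) * y
  yr <- -sin(phi) * x + cos(phi) * y
  rr <- sqrt((xr / ecc)^2 + (yr * ecc)^2)          # elliptical radius
  theta <- atan2(yr, xr)
  bound <- if (malignant && spec$spiculation_amp > 0) {
    r0 * (1 + spec$spiculation_amp *
            abs(sin(spec$n_spikes * theta / 2 + phase))^spec$spike_sharpness)
  } else r0
  w <- if (malignant) spec$margin_blur_malignant else spec$margin_blur_benign
  mass <- stats::plogis((1 - rr / bound) / w)
  bg <- 0.15 + spec$noise_amp * correlated_noise(S, spec$noise_scale) +
    0.02 * rnorm(S * S)
  pmin(pmax(bg + spec$contrast * mass, 0), 1)
}

sample_expert <- function(tables, cl) {
  vapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    sample(tb$levels, 1, prob = tb[[cl]])
  }, character(1))
}

#' Generate synthetic mass images with expert features
#'
#' Deterministic given the spec. Expert features are drawn from the
#' class-conditional tables and are conditionally independent of the image
#' given the class (by construction).
#'
#' @param spec a [mass_spec()].
#' @return a tibble with `id`, `label` ("benign"/"malignant"), `image`
#'   (list of `size x size` matrices) and the five expert-feature columns
#'   `assessment`, `shape`, `margin`, `density`, `subtlety`.
#' @export
gen_masses <- function(spec) {
  stopifnot(inherits(spec, "mass_spec"))
  labels <- c(rep("benign", spec$n_benign), rep("malignant", spec$n_malignant))
  rows <- lapply(seq_along(labels), function(i) {
    cl <- labels[i]
    with_seed(substream_seed(spec$seed, 5000 + i), {
      img <- render_mass(spec, malignant = cl == "malignant")
      ef <- sample_expert(spec$expert_tables, cl)
      c(list(id = sprintf("mass_%03d", i), label = cl,
             image = list(new_image(img))),
        as.list(ef))
    })
  })
  dplyr::bind_rows(rows)
}

#' Mutual information between class and an expert feature table
#'
#' Exact mutual information (in nats) computed from a class-conditional
#' table and the class priors; used to verify which expert features the
#' generator makes informative.
#'
#' @param table one entry of the expert tables (list with `levels`,
#'   `benign`, `malignant`).
#' @param prior_benign prior probability of the benign class.
#' @return mutual information in nats.
#' @export
expert_feature_mi <- function(table, prior_benign = 0.48) {
  pb <- prior_benign; pm <- 1 - prior_benign
  joint <- rbind(pb * table$benign, pm * table$malignant)
  marg <- colSums(joint)
  mi <- 0
  for (i in 1:2) for (j in seq_along(marg)) {
    if (joint[i, j] > 0) {
      mi <- mi + joint[i, j] * log(joint[i, j] / (c(pb, pm)[i] * marg[j]))
    }
  }
  mi
}
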