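---
title: "Orthogonal image moments and kernel discriminant classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthogonal image moments and kernel discriminant classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthomoments)
```

# The analysis

`orthomoments` implements an image-classification pipeline for biological
images built around two families of orthogonal image moments:

* **Krawtchouk moments (KM)** — discrete orthogonal moments on the pixel
  lattice, built from binomial-weighted Krawtchouk polynomials. At full
  order they reconstruct the image exactly, and they are well suited to
  rectangular images such as insect wings.
* **Generalized pseudo-Zernike moments (GPZM)** — complex moments over the
  unit disk with radial polynomials $R^\alpha_{nm}$ and a tunable weight
  exponent $\alpha > -1$; their magnitudes $|Z_{nm}|$ are rotation
  invariant, which suits roughly registered square regions of interest
  such as mammographic masses.

Moment features feed a classical high-dimensional pipeline — Z-score
scaling, two-sample $t$ feature selection, Q-mode PCA, Fisher LDA — and a
Gaussian kernel density discriminant that yields class posterior
probabilities, including the predicted probability of malignancy
$P(\mathrm{mal})$ used as a fusion feature alongside categorical expert
features. Classifier accuracy is summarized by a Beta posterior under a
uniform prior.

Two synthetic generators provide data with the statistical structure the
analysis assumes: multi-class binary wing-venation images with paired
landmarks, and two-class grayscale mass-like regions of interest with five
correlated categorical expert features.

# Krawtchouk moments

The weighted Krawtchouk polynomial of order $n$ on $x = 0, \dots, N-1$ is

$$\bar k_n(x) = k_n(x;p,N-1)\sqrt{\omega(x;p,N-1) / \rho(n;p,N-1)},$$

where $k_n$ is the hypergeometric form ${}_2F_1(-n,-x;-N+1;1/p)$,
$\omega$ is the Binomial$(N-1,p)$ mass function, and
$\rho(n) = \left(\tfrac{1-p}{p}\right)^n \tfrac{n!\,(N-1-n)!}{(N-1)!}$ is
the squared norm (the product $\omega(n)\rho(n) = (1-p)^{N-1}$ is constant
in $n$, which pins down $\rho$ unambiguously). Rows of the basis matrix are
orthonormal, so the moments of an $N \times M$ image $A$ are
$Q = K_1 A K_2^\top$ and the inverse transform is $A = K_1^\top Q K_2$,
exact at full order.

**Numerical stability.** The three-term recurrence in the order $n$ is
accurate for $n \lesssim N/2$ but explodes near full order once $N$ reaches
the hundreds. Two exact identities rescue it: $\bar k_n(x) = \bar k_x(n)$
for every $p$ (a consequence of the constant $\omega\rho$ product), and
$\bar k_n(N-1-x) = (-1)^n \bar k_n(x)$ at $p = 1/2$. At the default
$p = 0.5$ the basis therefore computes only rows $n \le (N-1)/2$ by
recurrence and fills the remaining rows by symmetry; full-order bases stay
orthonormal to about $10^{-13}$ even at $N = 724$. For $p \ne 0.5$ the
reflection identity maps $p > 1/2$ onto $1-p$ and a transpose patch covers
$n > x$; this path is validated for $N \le 128$ and warns beyond.

**Parameter $p$.** $p$ shifts the region of the image the low-order
polynomials emphasize; $p = 0.5$ centers the basis support on the frame and
is the package default for both axes.

**Moment invariants.** Translation/rotation/scale-robust features are
produced by explicit pose normalization rather than by the
geometric-moment substitution algebra: the intensity centroid is moved to
the frame center, the principal axis of the second-moment ellipse is
rotated to horizontal, and the image is rescaled isotropically so its
total mass equals a fixed fraction (default 0.25) of the frame area. The
180° ambiguity of the principal axis is resolved by requiring the third
central moment along the horizontal axis to be non-negative. Both routes
satisfy the same contract — features of a transformed copy of a shape
agree up to resampling error — and the pose-normalization route makes the
canonical frame explicit and testable. Reflections are not canonicalized;
mirrored shapes are distinct. The invariants of an image at order $l$ are
the $l^2$ entries of $Q$ of the normalized image, flattened row-major
(order 200 gives 40,000 features).

# Generalized pseudo-Zernike moments

The radial polynomial is

$$R^\alpha_{nm}(r) = \frac{(n+|m|+1)!}{(\alpha+1)_{n+|m|+1}}
\sum_{j=0}^{n-|m|} (-1)^j
\frac{(\alpha+1)_{2n+1-j}}{j!\,(n-|m|-j)!\,(n+|m|+1-j)!}\, r^{n-j},$$

reducing to the classic pseudo-Zernike polynomial at $\alpha = 0$ (e.g.
$R_{10}(r) = 3r - 2$). The weighted form multiplies in the normalization
constant and the weight $(1-r)^{\alpha/2}$, making
$\bar V_{nm} = \bar R_{nm} e^{im\theta}$ orthonormal over the disk.

**Evaluation.** The leading coefficient is computed in log-gamma space and
the remaining coefficients follow by exact small-rational term ratios, so
the single log-gamma rounding is a common factor that cancellation cannot
amplify. Even so, the alternating sum loses digits at high order: the
largest coefficient grows roughly like $4^n$, so double precision is
exhausted somewhere beyond $n \approx 20{-}25$. The package warns above
order 25 and the mass study uses order 12 by default; this is a deliberate
trade-off — no recurrence for the *generalized* ($\alpha \ne 0$) radial
polynomials is established enough to adopt, and the classification studies
never need extreme orders. The triangular feature-length bookkeeping (for
example 8,128 magnitude features at order 126) is independent of
polynomial evaluation.

**Disk mapping and quadrature.** Square images are mapped onto the
inscribed circle, origin at the image center, $\theta$ counter-clockwise
from $+x$; pixels outside the disk are ignored. Integrals use a midpoint
Riemann sum over pixel centers with an optional integer oversampling
factor. For a constant image on a 300-pixel grid this reproduces
$\bar Z_{00} = \sqrt{\pi}$ to well under 1%.

**Features.** Whether to use real/imaginary parts or moduli is an open
choice; the package uses the moduli $|Z_{nm}|$ for $m \ge 0$ because they
are rotation invariant, which matches how the features are used (regions
of interest have arbitrary orientation). Conjugate symmetry
$Z_{n,-m} = \overline{Z_{nm}}$ makes the $m < 0$ half redundant for real
images.

# Order selection

Reconstruction-MSE curves (`mse_curve`) record, per image and order, the
mean squared error between the reconstruction and the original, dividing
by the full pixel count. Two selection rules are provided, matching the
two ways a per-image family of curves can be reduced: `argmin_mean_mse`
minimizes the across-image mean curve (ties to the smallest order), and
`mean_of_argmins` averages per-image argmin orders, rounding half away
from zero. KM curves are provably non-increasing (nested orthogonal
projections); GPZM curves carry quadrature error and need not be, though
they trend downward on smooth images.

# The feature-space pipeline

* **Z-scoring** uses the sample ($n-1$) standard deviation; zero-variance
  features keep unit scale and map to 0, preserving column alignment.
* **$t$ selection** uses the pooled-variance two-sample statistic (the
  plain "t-statistic" default; Welch would change little here because the
  class sizes are balanced) and keeps the $\lceil \text{fraction} \cdot p
  \rceil$ largest $|t|$. Features with zero pooled variance but unequal
  means are ranked first (infinite $|t|$); equal means give $t = 0$.
* **Q-mode PCA** factors the centered $n \times p$ matrix ($p \gg n$) by
  SVD; scores are $n \times n$, loadings $p \times n$. Truncation is
  either the smallest $k$ whose cumulative variance ratio reaches $\beta$
  (default 0.95) or a fixed $k$ (the wing study fixes $k = 60$). Component
  signs are fixed by making the largest-magnitude loading positive.
* **Fisher LDA** maximizes between/within scatter, giving $s-1$
  discriminants. When the within-class scatter is singular — the normal
  situation when $k$ exceeds the within-class degrees of freedom — a ridge
  $10^{-8}\,\mathrm{tr}(S_w)/k$ is added. Test samples are mapped as
  $V_{\text{test}} A$ with $A$ of size $k \times (s-1)$; this is the
  dimensionally consistent reading of the projection algebra (an $A^\top$
  in that position cannot produce $n_\text{test} \times (s-1)$).

# Kernel discriminant

Each class gets a product-Gaussian kernel density with per-dimension
Scott bandwidths $h_j = \hat\sigma_j n_c^{-1/(d+4)}$ (or a fixed value),
evaluated in log space. Posteriors are
$\pi_c \propto \text{prior}_c \cdot \hat f_c(z)$; empirical class priors
are the default because they calibrate $P(\mathrm{mal})$, and a uniform
prior flag reproduces a pure maximum-likelihood rule — both are exposed
because tree-node kernel classifiers are described either way. This is a
single-node stand-in for the kernel model a classification tree applies
within a node; tree growing, pruning, and variable-importance scoring are
out of scope. Queries where all class densities underflow are classified
by the nearest class centroid and flagged.

# Bayesian accuracy

Assuming one accuracy $\pi$ shared across classes, the diagonal counts of
the confusion matrix are binomial and a uniform prior yields a
$\mathrm{Beta}(\Sigma X_i + 1,\; N - \Sigma X_i + 1)$ posterior with mean
$(\Sigma X_i + 1)/(N + 2)$; credible intervals are equal-tailed beta
quantiles. The exact coverage of the 95% interval at $\pi = 0.8$,
$N = 74$ is computed in the test suite by summing the binomial law and
falls between 94% and 96%.

# Synthetic data

**Wings.** A fixed 19-landmark venation template (six polylines inside an
elliptical outline) is displaced per class by a random direction of fixed
magnitude $\delta$ and per specimen by Gaussian jitter $\sigma_w$, then
rasterized at a fixed stroke width with a small speckle rate. Defaults
mirror the 15-class, 74-specimen cohort design (five per class, four in
the last) at 724 × 254 pixels, with $\delta = 8$ px against
$\sigma_w = 1.5$ px — a between/within ratio at which wing venation
differences are morphologically obvious, the regime in which the original
taxonomic problem sits. $\delta = 0$ is the null configuration. Landmarks
are returned exactly as drawn, so the landmark arm sees noiseless
digitization — a deliberate favourable treatment of the comparison arm.

**Masses.** Both classes are anisotropic elliptical blobs in a
correlated-noise background (coarse white noise, bilinearly upsampled);
malignant masses add a radial spiculation profile
$r(\theta) = r_0 (1 + a\,|\sin(k\theta/2)|^\gamma)$ and a wider sigmoidal
margin. With $a = 0$ and equal margin widths the class generators
coincide exactly — the null configuration used in testing. Class
prevalence defaults to 48/52 per 100, mirroring the benign fraction of
the motivating cohort. The five expert features are drawn from
class-conditional tables chosen so that, by exact mutual information,
`assessment` is the most class-informative feature and `density` carries
essentially none; they are conditionally independent of the image given
the class, which makes the fusion models well-posed.

What the generators do **not** emulate: photorealistic texture, scanner
and film artefacts, annotation errors, within-class taxonomic structure,
or any clinical semantics of the BI-RADS vocabulary. Passing the recovery
tests therefore demonstrates that the pipeline recovers class structure of
the assumed form — not performance on real mammograms or wing slides.

# Evaluation pipeline

The wing study reports the training-set confusion matrix with its
posterior accuracy (matching how a small 74-sample, 15-class problem is
reported) plus a stratified cross-validated confusion matrix fitted
fold-wise; the null-effect check uses the cross-validated estimate, since
training accuracy of an overparameterized pipeline is high even on null
features. The mass study runs stratified 70/30 splits over 10 instances
(stratification stabilizes the small test sets; a `train_fraction`
argument and the seed control the plan), reporting each metric as mean ±
sd/√10. $P(\mathrm{mal})$ for training rows of the fusion models is
produced by 5-fold out-of-fold refits within the training set — in-sample
densities would leak — and categorical expert features are one-hot
encoded for the kernel discriminant. KM and GPZM feature blocks are
selected per block at the same fraction and concatenated before PCA.

Scaler, selection, PCA, LDA and bandwidths are fit on training rows only;
a regression test asserts that corrupting everything outside the training
rows leaves the fitted model bit-identical.

**Problem sizes.** The package's own study configurations are: wings at
full 724 × 254 scale with order-200 invariants and $k = 60$; masses
generated at 300 × 300, resized to a 128-pixel working frame with KM
order 64 and GPZM order 12. These sizes were chosen so a complete study
runs in well under a minute on one core while keeping the moment orders in
their numerically comfortable range.

# Known limitations

* GPZM evaluation is practically limited to order ≈ 20–25 in double
  precision (documented warning); very high orders would need a dedicated
  recurrence or extended precision.
* Krawtchouk bases with $p \ne 0.5$ are validated only to $N = 128$.
* Pose normalization canonicalizes similarity transforms but not
  reflections, and its resampling error bounds the invariance of the KM
  features (≈ a few percent relative distance for moderate orders).
* The kernel discriminant treats one-hot columns as continuous
  coordinates; a tree program handling categoricals natively may differ.
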