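# Seeded generator of B-mode-like ultrasound phantoms: a hypoechoic lesion
# (smooth ellipse for benign-like, radially perturbed for malignant-like)
# on a speckled background, plus the exact ground-truth mask.

#' Specification of one synthetic ultrasound phantom
#'
#' The phantom emulates the salient B-mode properties the segmentation task
#' depends on: a darker (hypoechoic) lesion, low lesion/background contrast,
#' multiplicative multi-look speckle, and mild system blur.
#'
#' @param side image side in pixels.
#' @param lesion_kind `"benign_like"` (smooth elliptical boundary) or
#'   `"malignant_like"` (irregular, spiculated boundary).
#' @param center lesion centre as (row, col) fractions of the side.
#' @param axes ellipse semi-axes (a, b) as fractions of the side.
#' @param rotation ellipse rotation, degrees.
#' @param boundary_irregularity amplitude of the low-frequency radial
#'   perturbation (0 = exact ellipse; malignant-like phantoms use ~0.15-0.35).
#' @param lesion_intensity,background_intensity mean echogenicities in
#'   `[0, 1]`; the lesion must be darker.
#' @param speckle_looks number of looks of the multiplicative speckle
#'   (fewer looks = noisier); `Inf` disables speckle.
#' @param blur_sigma Gaussian blur in pixels applied after speckle.
#' @param seed RNG seed; the phantom is a pure function of its spec.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(side = 64L,
                         lesion_kind = c("benign_like", "malignant_like"),
                         center = c(0.5, 0.5), axes = c(0.2, 0.15),
                         rotation = 0, boundary_irregularity = NULL,
                         lesion_intensity = 0.3, background_intensity = 0.55,
                         speckle_looks = 2L, blur_sigma = 1,
                         seed = 1L) {
  lesion_kind <- match.arg(lesion_kind)
  if (is.null(boundary_irregularity))
    boundary_irregularity <- if (lesion_kind == "malignant_like") 0.25 else 0
  if (any(axes <= 0)) stop("degenerate ellipse: axes must be > 0", call. = FALSE)
  if (lesion_intensity >= background_intensity)
    stop("lesion must be hypoechoic: lesion_intensity < background_intensity",
         call. = FALSE)
  if (lesion_intensity < 0 || background_intensity > 1)
    stop("intensities must lie in [0, 1]", call. = FALSE)
  if (boundary_irregularity < 0)
    stop("boundary_irregularity must be >= 0", call. = FALSE)
  structure(list(side = as.integer(side), lesion_kind = lesion_kind,
                 center = center, axes = axes, rotation = rotation,
                 boundary_irregularity = boundary_irregularity,
                 lesion_intensity = lesion_intensity,
                 background_intensity = background_intensity,
                 speckle_looks = speckle_looks, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Separable Gaussian blur with edge replication.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) pmin(pmax(seq(1 - rad, n + rad), 1), n)
  blur1 <- function(m) {       # along rows
    mp <- m[pad_idx(nrow(m)), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k))
      out <- out + k[i] * mp[seq_len(nrow(m)) + i - 1L, , drop = FALSE]
    out
  }
  t(blur1(t(blur1(img))))
}

# Lesion support: rotated ellipse with angularly modulated radius.
lesion_support <- function(spec, harmonics) {
  s <- spec$side
  rr <- matrix(seq_len(s), s, s)
  cc <- matrix(seq_len(s), s, s, byrow = TRUE)
  cy <- spec$center[1] * s
  cx <- spec$center[2] * s
  th <- spec$rotation * pi / 180
  dy <- rr - cy
  dx <- cc - cx
  u <- (cos(th) * dx + sin(th) * dy) / (spec$axes[2] * s)
  v <- (-sin(th) * dx + cos(th) * dy) / (spec$axes[1] * s)
  r <- sqrt(u^2 + v^2)
  if (spec$boundary_irregularity > 0) {
    ang <- atan2(v, u)
    mod <- matrix(0, s, s)
    for (k in seq_len(nrow(harmonics)))
      mod <- mod + harmonics[k, "a"] * cos(harmonics[k, "k"] * ang) +
        harmonics[k, "b"] * sin(harmonics[k, "k"] * ang)
    boundary <- 1 + spec$boundary_irregularity * mod
    boundary[boundary < 0.2] <- 0.2
  } else {
    boundary <- 1
  }
  (r <= boundary) * 1
}

#' Generate one phantom image with its ground-truth mask
#'
#' Pipeline: (1) piecewise-constant echogenicity map (background mean
#' outside, lesion mean inside the perturbed ellipse); (2) multiplicative
#' speckle — each pixel multiplied by the mean of `speckle_looks` squared
#' standard-normal draws (mean-one, gamma-like multi-look model); (3)
#' Gaussian blur; (4) clip to `[0, 1]`. The mask is the exact pre-noise
#' lesion support. Deterministic given the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (matrix in `[0, 1]`), `mask` (binary matrix)
#'   and `provenance` (the spec).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, function() {
    kmax <- 5L
    harmonics <- cbind(k = 2:kmax,
                       a = rnorm(kmax - 1L, sd = 1 / sqrt(kmax - 1)),
                       b = rnorm(kmax - 1L, sd = 1 / sqrt(kmax - 1)))
    mask <- lesion_support(spec, harmonics)
    img <- spec$background_intensity +
      (spec$lesion_intensity - spec$background_intensity) * mask
    if (is.finite(spec$speckle_looks)) {
      L <- spec$speckle_looks
      n <- length(img)
      speckle <- rowMeans(matrix(rnorm(n * L)^2, n, L))
      img <- img * matrix(speckle, spec$side, spec$side)
    }
    img <- gaussian_blur(img, spec$blur_sigma)
    img[img < 0] <- 0
    img[img > 1] <- 1
    list(image = img, mask = mask, provenance = spec)
  })
}

#' Generate a seeded dataset of phantoms
#'
#' Draws `n` phantom specs with randomised lesion geometry, contrast and
#' speckle severity within the package's stated ranges (contrast gap
#' 0.15-0.3, 1-4 looks), a `mix` fraction of them benign-like, and renders
#' them. Fully reproducible from `seed`.
#'
#' @param n number of phantoms (>= 1).
#' @param side image side in pixels.
#' @param mix fraction of benign-like lesions, default 0.5.
#' @param seed dataset seed.
#' @return list of samples (`image`, `mask`, `provenance`); attribute
#'   `"manifest"` is a data.frame of every spec parameter.
#' @export
generate_dataset <- function(n, side = 64L, mix = 0.5, seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  with_seed(seed, function() {
    n_benign <- round(n * mix)
    kinds <- sample(c(rep("benign_like", n_benign),
                      rep("malignant_like", n - n_benign)))
    samples <- vector("list", n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      bg <- runif(1, 0.45, 0.65)
      gap <- runif(1, 0.15, 0.3)
      spec <- phantom_spec(
        side = side, lesion_kind = kinds[i],
        center = c(runif(1, 0.35, 0.65), runif(1, 0.35, 0.65)),
        axes = c(runif(1, 0.12, 0.28), runif(1, 0.1, 0.22)),
        rotation = runif(1, 0, 180),
        boundary_irregularity = if (kinds[i] == "malignant_like")
          runif(1, 0.15, 0.35) else 0,
        lesion_intensity = bg - gap, background_intensity = bg,
        speckle_looks = sample(1:4, 1), blur_sigma = runif(1, 0.8, 1.4),
        seed = sample.int(.Machine$integer.max, 1))
      samples[[i]] <- generate_phantom(spec)
      rows[[i]] <- data.frame(
        id = i, lesion_kind = spec$lesion_kind, center_row = spec$center[1],
        center_col = spec$center[2], axis_a = spec$axes[1],
        axis_b = spec$axes[2], rotation = spec$rotation,
        boundary_irregularity = spec$boundary_irregularity,
        lesion_intensity = spec$lesion_intensity,
        background_intensity = spec$background_intensity,
        speckle_looks = spec$speckle_looks, blur_sigma = spec$blur_sigma,
        seed = spec$seed)
    }
    structure(samples, manifest = do.call(rbind, rows))
  })
}

#' Split a dataset into disjoint train/validation/test subsets
#'
#' @param samples a sample list (e.g. from [generate_dataset()]).
#' @param fractions length-3 non-negative weights for train/val/test.
#' @param seed shuffle seed.
#' @return list with `train`, `val`, `test` sample lists; attribute
#'   `"indices"` records the assignment.
#' @export
split_dataset <- function(samples, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  stopifnot(length(fractions) == 3, all(fractions >= 0), sum(fractions) > 0)
  n <- length(samples)
  with_seed(seed, function() {
    idx <- sample.int(n)
    f <- fractions / sum(fractions)
    n_train <- floor(n * f[1])
    n_val <- floor(n * f[2])
    tr <- idx[seq_len(n_train)]
    va <- idx[n_train + seq_len(n_val)]
    te <- idx[setdiff(seq_len(n), seq_len(n_train + n_val))]
    structure(list(train = samples[tr], val = samples[va], test = samples[te]),
              indices = list(train = tr, val = va, test = te))
  })
}
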