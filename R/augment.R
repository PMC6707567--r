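# Paired image+mask affine augmentation: the same geometric map is applied
# to both; images are interpolated bilinearly, masks re-binarised.

AUG_KINDS <- c("vertical_shift", "horizontal_shift", "shear", "horizontal_flip")

#' Specification of one paired affine transform
#'
#' @param kind one of `"vertical_shift"`, `"horizontal_shift"` (magnitude =
#'   signed fraction of the image side, |magnitude| <= 0.2), `"shear"`
#'   (magnitude = signed angle in degrees, |angle| <= 20) or
#'   `"horizontal_flip"` (no magnitude; an exact left-right mirror).
#' @param magnitude transform magnitude; ignored for flips.
#' @param fill intensity for border pixels exposed by the transform
#'   (default 0, echo-free black).
#' @return object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(kind, magnitude = 0, fill = 0) {
  kind <- match.arg(kind, AUG_KINDS)
  if (kind %in% c("vertical_shift", "horizontal_shift") &&
      abs(magnitude) > 0.2)
    stop("shift fraction must satisfy |magnitude| <= 0.2, got ", magnitude,
         call. = FALSE)
  if (kind == "shear" && abs(magnitude) > 20)
    stop("shear angle must satisfy |magnitude| <= 20 degrees, got ",
         magnitude, call. = FALSE)
  structure(list(kind = kind, magnitude = magnitude, fill = fill),
            class = "augmentation_spec")
}

# Bilinear sample of matrix `img` at fractional (row, col) positions;
# out-of-frame positions take `fill`.
bilinear_sample <- function(img, rr, cc, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  px <- function(r, c) {
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    v <- numeric(length(r)) + fill
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  v <- px(r0, c0) * (1 - fr) * (1 - fc) + px(r0 + 1, c0) * fr * (1 - fc) +
    px(r0, c0 + 1) * (1 - fr) * fc + px(r0 + 1, c0 + 1) * fr * fc
  matrix(v, nrow(rr), ncol(rr))
}

nearest_sample <- function(img, rr, cc, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  r <- round(rr); c <- round(cc)
  ok <- r >= 1 & r <= H & c >= 1 & c <= W
  v <- numeric(length(r)) + fill
  v[ok] <- img[cbind(r[ok], c[ok])]
  matrix(v, nrow(rr), ncol(rr))
}

# Source coordinates (inverse map) for each transform, about the image centre.
aug_source_coords <- function(spec, H, W) {
  grid_r <- matrix(seq_len(H), H, W)
  grid_c <- matrix(seq_len(W), H, W, byrow = TRUE)
  switch(spec$kind,
    vertical_shift = list(r = grid_r - spec$magnitude * H, c = grid_c),
    horizontal_shift = list(r = grid_r, c = grid_c - spec$magnitude * W),
    shear = {
      cy <- (H + 1) / 2
      cx <- (W + 1) / 2
      list(r = grid_r, c = grid_c - tan(spec$magnitude * pi / 180) *
             (grid_r - cy))
    },
    horizontal_flip = list(r = grid_r, c = W + 1 - grid_c))
}

#' Apply one paired transform to an image/mask sample
#'
#' The identical geometric map is applied to image and mask; the image is
#' resampled bilinearly, the mask by nearest neighbour so it stays strictly
#' binary. Flips are exact column mirrors (pixel-exact involution). Output
#' shape is preserved; exposed borders take the spec's fill value.
#'
#' @param sample list with `image` (matrix, `[0, 1]`) and `mask`
#'   (binary matrix of the same shape).
#' @param spec an [augmentation_spec()].
#' @return transformed sample (same structure).
#' @export
apply_paired <- function(sample, spec) {
  img <- sample$image
  msk <- sample$mask
  if (!identical(dim(img), dim(msk)))
    stop("image and mask shapes differ", call. = FALSE)
  if (spec$kind == "horizontal_flip") {
    out_i <- img[, ncol(img):1, drop = FALSE]
    out_m <- msk[, ncol(msk):1, drop = FALSE]
  } else {
    src <- aug_source_coords(spec, nrow(img), ncol(img))
    out_i <- bilinear_sample(img, src$r, src$c, spec$fill)
    out_m <- nearest_sample(msk, src$r, src$c, 0)
  }
  out <- sample
  out$image <- out_i
  out$mask <- out_m
  out$augmented <- spec$kind
  out
}

#' Expand a training set by the four paired affine transforms
#'
#' Per original sample, one transformed copy per transform kind (vertical
#' shift, horizontal shift, shear, left-right flip) with magnitudes drawn
#' uniformly from the default ranges (shifts in ±10% of the side, shear in
#' ±10°) under the given seed; the originals are kept, so `m` inputs yield
#' `5 m` samples.
#'
#' @param samples non-empty list of image/mask samples.
#' @param seed RNG seed for the magnitudes.
#' @param shift_max,shear_max half-ranges for the uniform magnitude draws.
#' @return list of `5 * length(samples)` samples (originals first);
#'   attribute `"manifest"` is a data.frame (original, transform,
#'   magnitude).
#' @export
expand_training_set <- function(samples, seed = 1L, shift_max = 0.1,
                                shear_max = 10) {
  if (length(samples) == 0) stop("empty training set", call. = FALSE)
  with_seed(seed, function() {
    m <- length(samples)
    out <- vector("list", 5L * m)
    out[seq_len(m)] <- samples
    origin <- integer(4L * m)
    kinds <- character(4L * m)
    mags <- numeric(4L * m)
    j <- 0L
    for (i in seq_len(m)) {
      for (kind in AUG_KINDS) {
        mag <- switch(kind,
                      vertical_shift = runif(1, -shift_max, shift_max),
                      horizontal_shift = runif(1, -shift_max, shift_max),
                      shear = runif(1, -shear_max, shear_max),
                      horizontal_flip = 0)
        j <- j + 1L
        out[[m + j]] <- apply_paired(samples[[i]], augmentation_spec(kind, mag))
        origin[j] <- i
        kinds[j] <- kind
        mags[j] <- mag
      }
    }
    manifest <- rbind(
      data.frame(original = seq_len(m), transform = "none", magnitude = 0),
      data.frame(original = origin, transform = kinds, magnitude = mags))
    structure(out, manifest = manifest)
  })
}
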