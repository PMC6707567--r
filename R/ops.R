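# Low-level tensor primitives. Batched feature maps are 4-d arrays in
# (row, col, channel, sample) order; single maps are 3-d (row, col, channel).

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature map must be an array", call. = FALSE)
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("feature map must be 2-d, 3-d or 4-d", call. = FALSE)
  x
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

#' Strided/dilated 2-d convolution with same-style zero padding
#'
#' Cross-correlates `x` with kernel bank `w`, sampling the input at offsets
#' spaced by `dilation` (atrous convolution) and moving the window by
#' `stride`. Zero padding keeps the output side at `ceiling(side / stride)`,
#' so `stride = 1` preserves spatial size for any dilation rate.
#'
#' @param x array `(H, W, Cin)` or `(H, W, Cin, N)`.
#' @param w kernel array `(K, K, Cin, Cout)`.
#' @param bias length-`Cout` numeric, or `NULL` for no bias.
#' @param stride window step, 1 or 2 in this architecture.
#' @param dilation dilation rate `r >= 1`.
#' @return array `(Ho, Wo, Cout, N)` (4-d, even for 3-d input).
#' @export
conv2d <- function(x, w, bias = NULL, stride = 1L, dilation = 1L) {
  if (dilation < 1L) stop("dilation rate must be >= 1", call. = FALSE)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  x <- as_batch(x)
  if (is.null(bias)) bias <- numeric(0)
  .conv2d_fwd(x, w, as.numeric(bias), as.integer(stride), as.integer(dilation))
}

conv2d_grad <- function(x, w, dy, stride = 1L, dilation = 1L, need_dx = TRUE) {
  .conv2d_bwd(x, w, dy, as.integer(stride), as.integer(dilation), need_dx)
}

relu <- function(x) .relu(x)

relu_grad <- function(y, dy) .relu_grad(y, dy)

sigmoid <- function(x) .sigmoid(x)

sigmoid_grad <- function(y, dy) dy * y * (1 - y)

# Batch normalisation over (row, col, sample) per channel.
# Returns y plus the cache needed for the backward pass.
bn_forward <- function(x, gamma, beta, running_mean = NULL, running_var = NULL,
                       training = TRUE, eps = 1e-5) {
  if (training || is.null(running_mean)) {
    st <- .bn_stats(x)
    mu <- st$mu
    v <- pmax(st$msq - st$mu^2, 0)
  } else {
    mu <- running_mean
    v <- running_var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- .chan_affine(x, ivar, -mu * ivar)
  y <- .chan_affine(xhat, gamma, beta)
  list(y = y, xhat = xhat, ivar = ivar, mu = mu, var = v, dims = dim(x))
}

bn_backward <- function(cache, gamma, dy) {
  d <- cache$dims
  M <- prod(d[c(1, 2, 4)])
  dots <- .chan_dots(dy, cache$xhat)
  dgamma <- dots$sum_ab
  dbeta <- dots$sum_a
  gi <- gamma * cache$ivar
  dx <- .chan_affine(dy, gi, -gi * dbeta / M) -
    .chan_affine(cache$xhat, gi * dgamma / M, numeric(length(gamma)))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Inference-mode batch norm on fixed statistics (an affine map per channel).
bn_apply <- function(x, gamma, beta, mean, var, eps = 1e-5) {
  scale <- gamma / sqrt(var + eps)
  .chan_affine(x, scale, beta - mean * scale)
}

#' Nearest-neighbour spatial upsampling by an integer factor
#'
#' Each pixel is replicated into a `factor x factor` block; channels and
#' samples are untouched. This is the resize used after the dilated bridge
#' and at every decoder stage.
#'
#' @param x array `(H, W, C)` or `(H, W, C, N)`.
#' @param factor integer magnification, default 2.
#' @return array with spatial sides multiplied by `factor`.
#' @export
upsample_nearest <- function(x, factor = 2L) {
  x <- as_batch(x)
  d <- dim(x)
  x[rep(seq_len(d[1]), each = factor), rep(seq_len(d[2]), each = factor), , ,
    drop = FALSE]
}

upsample_nearest_grad <- function(dy, factor = 2L) {
  d <- dim(dy)
  H <- d[1] %/% factor
  W <- d[2] %/% factor
  dx <- array(0, dim = c(H, W, d[3], d[4]))
  for (a in seq_len(factor)) {
    for (b in seq_len(factor)) {
      dx <- dx + dy[seq(a, d[1], by = factor), seq(b, d[2], by = factor), , ,
                    drop = FALSE]
    }
  }
  dx
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (any(da[c(1, 2, 4)] != db[c(1, 2, 4)]))
    stop("concat: spatial/batch dims differ: ", paste(da, collapse = "x"),
         " vs ", paste(db, collapse = "x"), call. = FALSE)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# He-normal initialisation for a conv kernel bank (fan-in = K*K*Cin).
he_init <- function(shape) {
  fan_in <- prod(shape[-length(shape)])
  array(rnorm(prod(shape), sd = sqrt(2 / fan_in)), dim = shape)
}

# Evaluate fn() under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}
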