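# The three computational building blocks — residual unit, dilated
# convolution, attention gate — as pure shape-contracted operations on
# (row, col, channel) feature maps. Inference semantics: batch-norm layers
# use the statistics supplied in `weights`, never batch statistics.

#' Specification of one residual unit
#'
#' A residual unit computes `y = relu(F(x) + shortcut(x))` where `F` is the
#' sequence conv(3x3, stride S) - BN - ReLU - conv(3x3) - BN, and the
#' shortcut is the identity when shapes agree or a strided 1x1 projection
#' when the channel count or resolution changes.
#'
#' @param filters_n output channel count (the schedule value `n`).
#' @param stride_s spatial stride of the first convolution, 1 or 2. Encoder
#'   units 2-6 use 2; the first encoder unit and all decoder units use 1.
#' @param kernel_size odd kernel side, default 3.
#' @param role `"encoder"` or `"decoder"`; decoder units must have stride 1.
#' @return object of class `residual_unit_spec`.
#' @export
residual_unit_spec <- function(filters_n, stride_s = 1L, kernel_size = 3L,
                               role = c("encoder", "decoder")) {
  role <- match.arg(role)
  stopifnot(filters_n >= 1, kernel_size %% 2 == 1)
  if (!stride_s %in% c(1L, 2L))
    stop("stride_s must be 1 or 2", call. = FALSE)
  if (role == "decoder" && stride_s != 1L)
    stop("decoder residual units must have stride 1", call. = FALSE)
  structure(list(filters_n = as.integer(filters_n),
                 stride_s = as.integer(stride_s),
                 kernel_size = as.integer(kernel_size), role = role),
            class = "residual_unit_spec")
}

#' Specification of one dilated convolution branch
#'
#' @param kernel_size_k odd kernel side (3 in the bridge).
#' @param dilation_r dilation rate `r >= 1`.
#' @param filters output channel count.
#' @return object of class `dilated_conv_spec`.
#' @export
dilated_conv_spec <- function(kernel_size_k = 3L, dilation_r = 1L, filters = 1L) {
  if (dilation_r < 1) stop("dilation rate must be >= 1", call. = FALSE)
  stopifnot(kernel_size_k %% 2 == 1, filters >= 1)
  structure(list(kernel_size_k = as.integer(kernel_size_k),
                 dilation_r = as.integer(dilation_r),
                 filters = as.integer(filters)),
            class = "dilated_conv_spec")
}

#' Specification of one attention gate
#'
#' All four kernel banks (W_h, W_g, W_int, W_k) are 1x1 convolutions. The
#' two input projections share a single bias vector.
#'
#' @param intermediate_channels width of the joint hidden representation.
#' @return object of class `attention_gate_spec`.
#' @export
attention_gate_spec <- function(intermediate_channels) {
  stopifnot(intermediate_channels >= 1)
  structure(list(intermediate_channels = as.integer(intermediate_channels)),
            class = "attention_gate_spec")
}

#' Receptive-field side length of a dilated kernel
#'
#' The architecture's receptive-field accounting for a `K x K` kernel at
#' dilation rate `r`: side = `(K + 1) * (r - 1) + K`; the receptive-field
#' area `N` is its square. At `K = 3` the bridge rates 1, 2, 4, 8, 16, 32
#' give sides 3, 7, 15, 31, 63, 127. (Note this bookkeeping is deliberately
#' larger than the dilated-kernel span `K + (K - 1)(r - 1)`; see the methods
#' vignette.)
#'
#' @param kernel_size_k kernel side, positive integer.
#' @param dilation_r dilation rate, positive integer.
#' @return integer side length in pixels.
#' @export
receptive_field_side <- function(kernel_size_k, dilation_r) {
  stopifnot(kernel_size_k >= 1, dilation_r >= 1)
  as.integer((kernel_size_k + 1L) * (dilation_r - 1L) + kernel_size_k)
}

#' Random inference weights for a residual unit
#'
#' He-normal conv kernels, unit-gain batch-norm parameters with zero running
#' mean and unit running variance. Draws from the current RNG state.
#'
#' @param spec a [residual_unit_spec()].
#' @param in_channels channel count of the unit input.
#' @return weight list with elements `conv1`, `bn1`, `conv2`, `bn2` and,
#'   when the shortcut needs a projection, `shortcut` (1x1 kernel bank).
#' @export
residual_unit_weights <- function(spec, in_channels) {
  k <- spec$kernel_size
  n <- spec$filters_n
  bn <- function(c) list(gamma = rep(1, c), beta = rep(0, c),
                         mean = rep(0, c), var = rep(1, c))
  w <- list(conv1 = he_init(c(k, k, in_channels, n)), bn1 = bn(n),
            conv2 = he_init(c(k, k, n, n)), bn2 = bn(n))
  if (in_channels != n || spec$stride_s != 1L)
    w$shortcut <- he_init(c(1, 1, in_channels, n))
  w
}

#' Apply one residual unit
#'
#' Main branch conv-BN-ReLU-conv-BN with the spec stride on the first
#' convolution, added to the (possibly 1x1-projected) shortcut, then ReLU.
#' Output side is `ceiling(input side / stride_s)`; output channels equal
#' `filters_n`.
#'
#' @param input feature map `(H, W, C)` (a batch axis is also accepted).
#' @param spec a [residual_unit_spec()].
#' @param weights list as produced by [residual_unit_weights()].
#' @return feature map `(Ho, Wo, filters_n)` (batch axis preserved).
#' @export
residual_unit <- function(input, spec, weights) {
  x <- as_batch(check_finite(input))
  w <- weights
  f <- conv2d(x, w$conv1, NULL, stride = spec$stride_s)
  f <- bn_apply(f, w$bn1$gamma, w$bn1$beta, w$bn1$mean, w$bn1$var)
  f <- relu(f)
  f <- conv2d(f, w$conv2, NULL, stride = 1L)
  f <- bn_apply(f, w$bn2$gamma, w$bn2$beta, w$bn2$mean, w$bn2$var)
  s <- if (is.null(w$shortcut)) x else conv2d(x, w$shortcut, NULL, spec$stride_s)
  if (!all(dim(f) == dim(s)))
    stop("residual unit branch shapes differ: main ",
         paste(dim(f), collapse = "x"), " vs shortcut ",
         paste(dim(s), collapse = "x"), call. = FALSE)
  y <- relu(f + s)
  if (length(dim(input)) == 3L) dim(y) <- dim(y)[1:3]
  y
}

#' Apply one dilated convolution branch
#'
#' ReLU of the dilated (atrous) cross-correlation plus a per-filter bias.
#' Stride is 1 and padding preserves the spatial size for every dilation
#' rate, so a 4x4 map stays 4x4 even at `r = 32`.
#'
#' @param input feature map `(H, W, C)`.
#' @param spec a [dilated_conv_spec()].
#' @param weights list with `kernel` `(K, K, C, filters)` and `bias`
#'   (length `filters`).
#' @return feature map `(H, W, filters)`.
#' @export
dilated_conv <- function(input, spec, weights) {
  x <- as_batch(check_finite(input))
  y <- relu(conv2d(x, weights$kernel, weights$bias, stride = 1L,
                   dilation = spec$dilation_r))
  if (length(dim(input)) == 3L) dim(y) <- dim(y)[1:3]
  y
}

#' Apply the six-branch dilated bridge
#'
#' The bottleneck map is passed through six parallel dilated convolutions
#' (rates 1, 2, 4, 8, 16, 32, equal filter counts); the branch outputs are
#' summed element-wise and upsampled by a factor of 2 before entering the
#' decoder.
#'
#' @param input feature map `(H, W, C)`.
#' @param specs list of six [dilated_conv_spec()]s with rates 1,2,4,8,16,32.
#' @param weights list of six branch weight lists (`kernel`, `bias`).
#' @return feature map `(2H, 2W, filters)`.
#' @export
dilated_bridge <- function(input, specs, weights) {
  rates <- vapply(specs, function(s) s$dilation_r, integer(1))
  if (!identical(rates, c(1L, 2L, 4L, 8L, 16L, 32L)))
    stop("bridge requires dilation rates 1, 2, 4, 8, 16, 32", call. = FALSE)
  nf <- vapply(specs, function(s) s$filters, integer(1))
  ks <- vapply(specs, function(s) s$kernel_size_k, integer(1))
  if (length(unique(nf)) != 1L || any(ks != 3L))
    stop("bridge branches must share filter count and use 3x3 kernels",
         call. = FALSE)
  acc <- NULL
  for (i in seq_along(specs)) {
    out <- dilated_conv(input, specs[[i]], weights[[i]])
    if (is.null(acc)) acc <- out
    else if (!all(dim(out) == dim(acc)))
      stop("bridge branch ", i, " output ", paste(dim(out), collapse = "x"),
           " disagrees with ", paste(dim(acc), collapse = "x"), call. = FALSE)
    else acc <- acc + out
  }
  y <- upsample_nearest(acc, 2L)
  if (length(dim(input)) == 3L) dim(y) <- dim(y)[1:3]
  y
}

#' Random weights for an attention gate
#'
#' @param spec an [attention_gate_spec()].
#' @param h_channels channels of the encoder-side input `h`.
#' @param g_channels channels of the decoder-side gating signal `g`.
#' @return list of the four 1x1 kernel banks and three bias vectors.
#' @export
attention_gate_weights <- function(spec, h_channels, g_channels) {
  ic <- spec$intermediate_channels
  list(W_h = he_init(c(1, 1, h_channels, ic)),
       W_g = he_init(c(1, 1, g_channels, ic)),
       b_hg = rep(0, ic),
       W_int = he_init(c(1, 1, ic, ic)),
       b_int = rep(0, ic),
       W_k = he_init(c(1, 1, ic, 1)),
       b_k = 0)
}

#' Apply one attention gate
#'
#' Computes the per-pixel attention coefficient
#' `alpha = sigmoid(W_k * (W_int * relu(W_h*h + W_g*g + b_hg) + b_int) + b_k)`
#' (all 1x1 convolutions, one shared bias on the joint projection) and
#' returns `alpha * h`, broadcasting the single-channel `alpha` over the
#' channels of `h`. `h` and `g` must share spatial size: the gate performs
#' no interpolation.
#'
#' @param h encoder-side feature map `(H, W, Ch)`.
#' @param g decoder-side gating map `(H, W, Cg)`, same `H`, `W`.
#' @param spec an [attention_gate_spec()].
#' @param weights list as from [attention_gate_weights()].
#' @return gated feature map with the shape of `h`; attribute `"alpha"`
#'   carries the `(H, W, 1)` coefficient map.
#' @export
attention_gate <- function(h, g, spec, weights) {
  hb <- as_batch(check_finite(h, "h"))
  gb <- as_batch(check_finite(g, "g"))
  if (any(dim(hb)[c(1, 2)] != dim(gb)[c(1, 2)]))
    stop("attention gate requires equal spatial sizes: h is ",
         paste(dim(hb)[1:2], collapse = "x"), ", g is ",
         paste(dim(gb)[1:2], collapse = "x"), call. = FALSE)
  w <- weights
  t1 <- relu(conv2d(hb, w$W_h, w$b_hg) + conv2d(gb, w$W_g, NULL))
  u <- conv2d(t1, w$W_int, w$b_int)
  alpha <- sigmoid(conv2d(u, w$W_k, w$b_k))
  d <- dim(hb)
  y <- hb * alpha[, , rep(1L, d[3]), , drop = FALSE]
  if (length(dim(h)) == 3L) {
    dim(y) <- dim(y)[1:3]
    dim(alpha) <- dim(alpha)[1:3]
  }
  attr(y, "alpha") <- alpha
  y
}
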