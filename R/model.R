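# Model factory: assembles RDAU-NET and its ablation variants from a
# configuration, deterministically given the seed.

ENCODER_FILTERS <- c(32L, 64L, 128L, 256L, 512L, 512L)  # layer 1 is a choice
DECODER_FILTERS <- c(512L, 256L, 128L, 64L, 32L)        # stages 5 .. 1

#' Architectural configuration of a segmentation network
#'
#' The canonical channel schedules are encoder 64, 128, 256, 512, 512 for
#' units 2-6 (unit 1, unstated in the source architecture, defaults to 32)
#' and decoder 512, 256, 128, 64, 32 for stages 5-1. `width` scales every
#' channel count (floor, minimum 1) for desk-scale experiments. The three
#' flags name the ablation family: all on = RDAU; `use_dilated_bridge`
#' off = RAU; `use_residual` off = DAU; `use_attention_gates` off = RDU.
#'
#' @param input_side input resolution, one of 64, 96, 128, 256 (any side
#'   divisible by 32 is accepted: the encoder halves it five times).
#' @param input_channels image channels, 1 for grayscale.
#' @param variant convenience name: `"rdau"`, `"rau"`, `"dau"` or `"rdu"`;
#'   sets the three flags.
#' @param use_residual,use_dilated_bridge,use_attention_gates explicit flag
#'   overrides.
#' @param encoder_filters,decoder_filters channel schedules; defaults are
#'   the canonical ones.
#' @param width multiplier applied to both schedules (and the attention
#'   gates' widths), default 1.
#' @param seed integer controlling weight initialisation.
#' @return object of class `model_config`.
#' @export
model_config <- function(input_side = 128L, input_channels = 1L,
                         variant = c("rdau", "rau", "dau", "rdu"),
                         use_residual = NULL, use_dilated_bridge = NULL,
                         use_attention_gates = NULL,
                         encoder_filters = ENCODER_FILTERS,
                         decoder_filters = DECODER_FILTERS,
                         width = 1, seed = 42L) {
  variant <- match.arg(variant)
  flags <- switch(variant,
                  rdau = c(TRUE, TRUE, TRUE),
                  rau = c(TRUE, FALSE, TRUE),
                  dau = c(FALSE, TRUE, TRUE),
                  rdu = c(TRUE, TRUE, FALSE))
  use_residual <- use_residual %||% flags[1]
  use_dilated_bridge <- use_dilated_bridge %||% flags[2]
  use_attention_gates <- use_attention_gates %||% flags[3]
  if (input_side %% 32L != 0L)
    stop("input_side must be divisible by 32 (five spatial halvings); got ",
         input_side, call. = FALSE)
  stopifnot(length(encoder_filters) == 6L, length(decoder_filters) == 5L)
  scale_f <- function(f) pmax(1L, as.integer(floor(f * width)))
  cfg <- list(input_side = as.integer(input_side),
              input_channels = as.integer(input_channels),
              use_residual = use_residual,
              use_dilated_bridge = use_dilated_bridge,
              use_attention_gates = use_attention_gates,
              encoder_filters = scale_f(encoder_filters),
              decoder_filters = scale_f(decoder_filters),
              width = width, seed = as.integer(seed))
  cfg$variant <- variant_name(cfg)
  structure(cfg, class = "model_config")
}

variant_name <- function(cfg) {
  key <- paste0(as.integer(c(cfg$use_residual, cfg$use_dilated_bridge,
                             cfg$use_attention_gates)), collapse = "")
  switch(key, "111" = "rdau", "101" = "rau", "011" = "dau", "110" = "rdu",
         paste0("custom-", key))
}

#' Build an executable segmentation network from a configuration
#'
#' Wiring: six encoder residual units (stride 1 then five stride-2 units,
#' halving the side to `input_side / 32`); the dilated bridge (or a plain
#' 3x3 conv block) with a x2 upsample; five decoder stages, each gating the
#' matching encoder output through an attention gate (or passing it raw),
#' concatenating it with the upsampled decoder signal and applying a
#' stride-1 residual unit; and a 1x1 convolution + sigmoid head producing a
#' per-pixel lesion probability. Weight initialisation is He-normal,
#' seeded, so two builds from one config are identical.
#'
#' @param config a [model_config()].
#' @return object of class `rdau_model`: use with [forward()],
#'   [train_model()], [evaluate_model()]; `describe()`/`print()` show the
#'   layer table.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  with_seed(config$seed, function() build_model_impl(config))
}

build_model_impl <- function(cfg) {
  ef <- cfg$encoder_filters
  df <- cfg$decoder_filters
  root <- new_layer("rdau_net")
  strides <- c(1L, 2L, 2L, 2L, 2L, 2L)
  cin <- cfg$input_channels
  for (i in 1:6) {
    root$children[[paste0("enc", i)]] <-
      layer_res_unit(cin, ef[i], stride = strides[i],
                     residual = cfg$use_residual)
    cin <- ef[i]
  }
  root$children$bridge <- layer_bridge(ef[6], ef[6],
                                       dilated = cfg$use_dilated_bridge)
  g_ch <- ef[6]                       # channels of the decoder-side signal
  for (s in 5:1) {
    h_ch <- ef[s]                     # encoder skip at this resolution
    if (cfg$use_attention_gates)
      root$children[[paste0("ag", s)]] <-
        layer_attention_gate(h_ch, g_ch, ic = h_ch)
    root$children[[paste0("dec", s)]] <-
      layer_res_unit(h_ch + g_ch, df[6 - s], stride = 1L,
                     residual = cfg$use_residual)
    g_ch <- df[6 - s]
  }
  head <- layer_conv(1L, df[5], 1L, bias = TRUE)
  # near-neutral start: tiny (not zero) kernel keeps sigmoid(logit) ~ 0.5 so
  # the Dice gradient is alive, while W != 0 lets gradient reach the decoder
  head$par$w[] <- head$par$w * 1e-3
  head$par$b[] <- 0
  root$children$head <- head
  model <- structure(list(config = cfg, net = root), class = "rdau_model")
  model
}

#' Run a forward pass
#'
#' @param model an [build_model()] result.
#' @param x input images: matrix `(side, side)`, array `(side, side, 1)` or
#'   batch `(side, side, 1, N)`, values in `[0, 1]`.
#' @param training use batch statistics and cache activations for a
#'   subsequent backward pass (internal; forward-only callers leave FALSE).
#' @return per-pixel lesion probability maps `(side, side, 1, N)`.
#' @export
forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  x <- as_batch(x)
  d <- dim(x)
  if (d[1] != cfg$input_side || d[2] != cfg$input_side ||
      d[3] != cfg$input_channels)
    stop("input shape ", paste(d[1:3], collapse = "x"), " does not match the ",
         "configured ", cfg$input_side, "x", cfg$input_side, "x",
         cfg$input_channels, call. = FALSE)
  ch <- model$net$children
  skips <- vector("list", 6)
  for (i in 1:6) {
    x <- ch[[paste0("enc", i)]]$fwd(x, training)
    skips[[i]] <- x
  }
  g <- ch$bridge$fwd(x, training)
  model$net$skips <- if (training) skips
  for (s in 5:1) {
    h <- skips[[s]]
    hg <- if (cfg$use_attention_gates) ch[[paste0("ag", s)]]$fwd(h, g, training)
          else h
    z <- concat_channels(g, hg)
    if (training) model$net[[paste0("gch", s)]] <- dim(g)[3]
    g <- ch[[paste0("dec", s)]]$fwd(z, training)
    if (s > 1L) g <- upsample_nearest(g, 2L)
  }
  sigmoid(ch$head$fwd(g, training))
}

# Backward pass for training: dy is the gradient w.r.t. the sigmoid output.
backward <- function(model, y_prob, dy) {
  cfg <- model$config
  ch <- model$net$children
  dz <- sigmoid_grad(y_prob, dy)
  dg <- ch$head$bwd(dz)
  dskip <- vector("list", 6)
  for (s in 1:5) {
    if (s > 1L) dg <- upsample_nearest_grad(dg, 2L)
    dzc <- ch[[paste0("dec", s)]]$bwd(dg)
    gch <- model$net[[paste0("gch", s)]]
    dgpart <- dzc[, , seq_len(gch), , drop = FALSE]
    dhg <- dzc[, , -seq_len(gch), , drop = FALSE]
    if (cfg$use_attention_gates) {
      gr <- ch[[paste0("ag", s)]]$bwd(dhg)
      dskip[[s]] <- gr$dh
      dg <- dgpart + gr$dg
    } else {
      dskip[[s]] <- dhg
      dg <- dgpart
    }
  }
  dx <- ch$bridge$bwd(dg)
  for (i in 6:1) {
    if (i < 6L) dx <- dx + dskip[[i]]
    dx <- ch[[paste0("enc", i)]]$bwd(dx)
  }
  model$net$skips <- NULL
  invisible(dx)
}

#' Layer-by-layer description of a built network
#'
#' @param model an `rdau_model`.
#' @return data.frame with block kind, output shape and parameter count per
#'   block; consecutive shapes chain from the input to the
#'   `side x side x 1` head.
#' @export
describe <- function(model) {
  cfg <- model$config
  side <- cfg$input_side
  rows <- list()
  add <- function(name, kind, side, chans, layer) {
    rows[[length(rows) + 1]] <<- data.frame(
      block = name, kind = kind,
      output_shape = sprintf("%dx%dx%d", side, side, chans),
      params = if (is.null(layer)) 0 else n_params(layer))
  }
  add("input", "input", side, cfg$input_channels, NULL)
  ch <- model$net$children
  strides <- c(1L, 2L, 2L, 2L, 2L, 2L)
  for (i in 1:6) {
    side <- ceiling(side / strides[i])
    add(paste0("enc", i), ch[[paste0("enc", i)]]$kind, side,
        cfg$encoder_filters[i], ch[[paste0("enc", i)]])
  }
  side <- side * 2L
  add("bridge", ch$bridge$kind, side, cfg$encoder_filters[6], ch$bridge)
  for (s in 5:1) {
    if (cfg$use_attention_gates)
      add(paste0("ag", s), "attention_gate", side, cfg$encoder_filters[s],
          ch[[paste0("ag", s)]])
    add(paste0("dec", s), ch[[paste0("dec", s)]]$kind, side,
        cfg$decoder_filters[6 - s], ch[[paste0("dec", s)]])
    if (s > 1L) side <- side * 2L
  }
  add("head", "conv1x1+sigmoid", side, 1L, ch$head)
  do.call(rbind, rows)
}

#' @export
print.rdau_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<rdau_model> variant=%s input=%dx%dx%d params=%s seed=%d\n",
              cfg$variant, cfg$input_side, cfg$input_side,
              cfg$input_channels, format(n_params(x$net), big.mark = ","),
              cfg$seed))
  print(describe(x), row.names = FALSE)
  invisible(x)
}

#' Total trainable parameter count
#' @param model an `rdau_model`.
#' @return numeric scalar.
#' @export
count_params <- function(model) n_params(model$net)

# Sum of parameters sitting in attention gates (used by the ablation check:
# RDAU minus RDU equals exactly this).
ag_param_count <- function(model) {
  ags <- Filter(function(l) l$kind == "attention_gate",
                model$net$children)
  sum(vapply(ags, n_params, numeric(1)))
}

# Flat get/set of all parameters, for checkpointing.
get_params <- function(model) lapply(collect_layers(model$net), function(l) l$par)

set_params <- function(model, params) {
  layers <- collect_layers(model$net)
  stopifnot(length(layers) == length(params))
  for (i in seq_along(layers)) layers[[i]]$par <- params[[i]]
  invisible(model)
}

get_bn_state <- function(model) {
  lapply(collect_layers(model$net), function(l)
    if (l$kind == "bn") list(mean = l$running_mean, var = l$running_var))
}

set_bn_state <- function(model, state) {
  layers <- collect_layers(model$net)
  for (i in seq_along(layers))
    if (!is.null(state[[i]])) {
      layers[[i]]$running_mean <- state[[i]]$mean
      layers[[i]]$running_var <- state[[i]]$var
    }
  invisible(model)
}
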