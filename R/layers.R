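# Trainable layer engine. Each layer is an environment exposing
#   fwd(x, training), bwd(dy), par (named list of arrays), grd (gradients).
# Composites additionally hold $children; parameters are traversed via
# collect_layers(). Gradients accumulate until zero_grads().

new_layer <- function(kind) {
  self <- new.env(parent = emptyenv())
  self$kind <- kind
  self$par <- list()
  self$grd <- list()
  self$children <- list()
  self
}

collect_layers <- function(layer) {
  out <- list()
  if (length(layer$par)) out <- list(layer)
  for (ch in layer$children) out <- c(out, collect_layers(ch))
  out
}

zero_grads <- function(layer) {
  for (l in collect_layers(layer))
    l$grd <- lapply(l$par, function(p) array(0, dim = dim(p) %||% length(p)))
  invisible(layer)
}

n_params <- function(layer) {
  sum(vapply(collect_layers(layer),
             function(l) sum(vapply(l$par, length, numeric(1))), numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

layer_conv <- function(k, cin, cout, stride = 1L, dilation = 1L, bias = TRUE) {
  self <- new_layer("conv")
  self$stride <- stride
  self$dilation <- dilation
  self$par <- list(w = he_init(c(k, k, cin, cout)))
  if (bias) self$par$b <- rep(0, cout)
  self$fwd <- function(x, training = FALSE) {
    self$x <- x
    conv2d(x, self$par$w, self$par$b, self$stride, self$dilation)
  }
  self$bwd <- function(dy, need_dx = TRUE) {
    g <- conv2d_grad(self$x, self$par$w, dy, self$stride, self$dilation, need_dx)
    self$grd$w <- self$grd$w + g$dw
    if (!is.null(self$par$b)) self$grd$b <- self$grd$b + g$db
    self$x <- NULL
    if (need_dx) g$dx else NULL
  }
  self
}

layer_bn <- function(c, momentum = 0.9, eps = 1e-5) {
  self <- new_layer("bn")
  self$par <- list(gamma = rep(1, c), beta = rep(0, c))
  self$running_mean <- rep(0, c)
  self$running_var <- rep(1, c)
  self$momentum <- momentum
  self$eps <- eps
  self$t <- 0
  self$fwd <- function(x, training = FALSE) {
    out <- bn_forward(x, self$par$gamma, self$par$beta,
                      self$running_mean, self$running_var,
                      training = training, eps = self$eps)
    if (training) {
      # cumulative average over the first steps, EMA once warmed up, so
      # evaluation-mode statistics are sane even after very few batches
      self$t <- self$t + 1
      m <- min(self$momentum, 1 - 1 / self$t)
      self$running_mean <- m * self$running_mean + (1 - m) * out$mu
      self$running_var <- m * self$running_var + (1 - m) * out$var
      self$cache <- out
    }
    out$y
  }
  self$bwd <- function(dy) {
    g <- bn_backward(self$cache, self$par$gamma, dy)
    self$grd$gamma <- self$grd$gamma + g$dgamma
    self$grd$beta <- self$grd$beta + g$dbeta
    self$cache <- NULL
    g$dx
  }
  self
}

layer_relu <- function() {
  self <- new_layer("relu")
  self$fwd <- function(x, training = FALSE) {
    y <- relu(x)
    if (training) self$y <- y
    y
  }
  self$bwd <- function(dy) {
    dx <- relu_grad(self$y, dy)
    self$y <- NULL
    dx
  }
  self
}

# Residual unit (or, with residual = FALSE, a plain conv-BN-ReLU x2 stack of
# the same geometry — the ablation without shortcuts).
layer_res_unit <- function(cin, n, stride = 1L, k = 3L, residual = TRUE) {
  self <- new_layer(if (residual) "res_unit" else "conv_block")
  self$residual <- residual
  conv1 <- layer_conv(k, cin, n, stride = stride, bias = FALSE)
  bn1 <- layer_bn(n)
  conv2 <- layer_conv(k, n, n, bias = FALSE)
  bn2 <- layer_bn(n)
  self$children <- list(conv1 = conv1, bn1 = bn1, conv2 = conv2, bn2 = bn2)
  self$project <- residual && (cin != n || stride != 1L)
  if (self$project) {
    sc <- layer_conv(1L, cin, n, stride = stride, bias = FALSE)
    self$children$shortcut <- sc
  }
  self$fwd <- function(x, training = FALSE) {
    ch <- self$children
    f <- ch$conv1$fwd(x, training)
    f <- ch$bn1$fwd(f, training)
    self$a1 <- if (training) relu(f) else relu(f)
    f <- ch$conv2$fwd(self$a1, training)
    f <- ch$bn2$fwd(f, training)
    if (!self$residual) {
      y <- relu(f)
      if (training) self$y <- y
      if (!training) self$a1 <- NULL
      return(y)
    }
    s <- if (self$project) ch$shortcut$fwd(x, training) else x
    y <- relu(f + s)
    if (training) self$y <- y else self$a1 <- NULL
    y
  }
  self$bwd <- function(dy) {
    ch <- self$children
    dz <- relu_grad(self$y, dy)
    self$y <- NULL
    df <- ch$bn2$bwd(dz)
    df <- ch$conv2$bwd(df)
    df <- relu_grad(self$a1, df)
    self$a1 <- NULL
    df <- ch$bn1$bwd(df)
    dx <- ch$conv1$bwd(df)
    if (!self$residual) return(dx)
    dx + if (self$project) ch$shortcut$bwd(dz) else dz
  }
  self
}

# Bridge: six parallel dilated conv branches (rates 1..32, each ReLU), the
# branch outputs summed, then nearest x2 upsample. With dilated = FALSE it
# degrades to a single plain 3x3 conv-BN-ReLU block plus the same upsample.
layer_bridge <- function(cin, filters, dilated = TRUE,
                         rates = c(1L, 2L, 4L, 8L, 16L, 32L)) {
  self <- new_layer(if (dilated) "dilated_bridge" else "conv_bridge")
  self$dilated <- dilated
  if (dilated) {
    for (i in seq_along(rates))
      self$children[[paste0("branch", i)]] <-
        layer_conv(3L, cin, filters, dilation = rates[i])
    self$rates <- rates
    self$fwd <- function(x, training = FALSE) {
      acts <- vector("list", length(self$children))
      acc <- NULL
      for (i in seq_along(self$children)) {
        z <- relu(self$children[[i]]$fwd(x, training))
        acts[[i]] <- if (training) z
        acc <- if (is.null(acc)) z else acc + z
      }
      if (training) self$acts <- acts
      upsample_nearest(acc, 2L)
    }
    self$bwd <- function(dy) {
      dsum <- upsample_nearest_grad(dy, 2L)
      dx <- NULL
      for (i in seq_along(self$children)) {
        dz <- relu_grad(self$acts[[i]], dsum)
        d <- self$children[[i]]$bwd(dz)
        dx <- if (is.null(dx)) d else dx + d
      }
      self$acts <- NULL
      dx
    }
  } else {
    self$children <- list(conv = layer_conv(3L, cin, filters, bias = FALSE),
                          bn = layer_bn(filters), act = layer_relu())
    self$fwd <- function(x, training = FALSE) {
      ch <- self$children
      upsample_nearest(ch$act$fwd(ch$bn$fwd(ch$conv$fwd(x, training),
                                            training), training), 2L)
    }
    self$bwd <- function(dy) {
      ch <- self$children
      ch$conv$bwd(ch$bn$bwd(ch$act$bwd(upsample_nearest_grad(dy, 2L))))
    }
  }
  self
}

# Attention gate: alpha = sigmoid(Wk(Wint(relu(Wh h + Wg g + b)) + bint) + bk),
# output = alpha (*) h broadcast over h's channels.
layer_attention_gate <- function(ch_h, ch_g, ic = ch_h) {
  self <- new_layer("attention_gate")
  self$children <- list(
    Wh = layer_conv(1L, ch_h, ic, bias = TRUE),   # carries the shared b_hg
    Wg = layer_conv(1L, ch_g, ic, bias = FALSE),
    Wint = layer_conv(1L, ic, ic, bias = TRUE),
    Wk = layer_conv(1L, ic, 1L, bias = TRUE))
  self$fwd <- function(h, g, training = FALSE) {
    ch <- self$children
    t1 <- relu(ch$Wh$fwd(h, training) + ch$Wg$fwd(g, training))
    u <- ch$Wint$fwd(t1, training)
    alpha <- sigmoid(ch$Wk$fwd(u, training))
    if (training) {
      self$t1 <- t1
      self$alpha <- alpha
      self$h <- h
    }
    d <- dim(h)
    h * alpha[, , rep(1L, d[3]), , drop = FALSE]
  }
  self$bwd <- function(dy) {
    ch <- self$children
    d <- dim(self$h)
    alpha_b <- self$alpha[, , rep(1L, d[3]), , drop = FALSE]
    dh_direct <- dy * alpha_b
    dyh <- matrix(aperm(dy * self$h, c(1, 2, 4, 3)), ncol = d[3])
    dalpha <- array(aperm(array(rowSums(dyh), dim = c(d[1], d[2], d[4], 1L)),
                          c(1, 2, 4, 3)),
                    dim = dim(self$alpha))
    dpre <- sigmoid_grad(self$alpha, dalpha)
    du <- ch$Wk$bwd(dpre)
    dt1 <- ch$Wint$bwd(du)
    dt1 <- relu_grad(self$t1, dt1)
    dh <- dh_direct + ch$Wh$bwd(dt1)
    dg <- ch$Wg$bwd(dt1)
    self$t1 <- NULL; self$alpha <- NULL; self$h <- NULL
    list(dh = dh, dg = dg)
  }
  self
}
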