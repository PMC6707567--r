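# Finite-difference validation of the training engine's backward passes.
# These are what guarantee the optimiser sees correct gradients.

fd_check <- function(fwd_loss, get, set, analytic, eps = 1e-5, tol = 1e-5,
                     n_probe = 6) {
  v <- get()
  idx <- sample(length(v), min(n_probe, length(v)))
  for (k in idx) {
    vp <- v; vp[k] <- vp[k] + eps; set(vp)
    lp <- fwd_loss()
    vm <- v; vm[k] <- vm[k] - eps; set(vm)
    lm <- fwd_loss()
    set(v)
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - analytic[k]), tol * max(1, abs(num)))
  }
}

# Scalar loss = sum(y * R) for a fixed random R, so dL/dy = R.
layer_loss <- function(layer, x, R = NULL, ...) {
  y <- layer$fwd(x, training = TRUE)
  if (is.null(R)) R <- array(rnorm(length(y)), dim = dim(y))
  list(loss = sum(y * R), R = R)
}

test_that("conv layer gradients (weights, bias, input) pass finite differences", {
  set.seed(10)
  for (case in list(list(k = 3L, s = 1L, d = 1L), list(k = 3L, s = 2L, d = 1L),
                    list(k = 3L, s = 1L, d = 2L), list(k = 1L, s = 1L, d = 1L))) {
    l <- layer_conv(case$k, 2L, 3L, stride = case$s, dilation = case$d)
    x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
    R <- array(rnorm(length(l$fwd(x))), dim = dim(l$fwd(x)))
    run <- function() sum(l$fwd(x, TRUE) * R)
    run()
    zero_grads(l)
    dx <- l$bwd(R)
    # weights
    fd_check(run, function() l$par$w,
             function(v) { l$par$w <- array(v, dim(l$par$w)) }, l$grd$w)
    # bias
    fd_check(run, function() l$par$b, function(v) { l$par$b <- v }, l$grd$b)
    # input
    xv <- x
    fd_check(function() sum(l$fwd(xv, TRUE) * R),
             function() xv, function(v) { xv <<- array(v, dim(x)) },
             dx)
  }
})

test_that("batch-norm layer gradients pass finite differences", {
  set.seed(11)
  l <- layer_bn(3L)
  l$par$gamma <- runif(3, 0.5, 1.5)
  l$par$beta <- rnorm(3, sd = 0.3)
  x <- array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  R <- array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  run <- function() sum(l$fwd(x, TRUE) * R)
  run()
  zero_grads(l)
  dx <- l$bwd(R)
  fd_check(run, function() l$par$gamma, function(v) { l$par$gamma <- v },
           l$grd$gamma, tol = 1e-4)
  fd_check(run, function() l$par$beta, function(v) { l$par$beta <- v },
           l$grd$beta, tol = 1e-4)
  xv <- x
  fd_check(function() sum(l$fwd(xv, TRUE) * R), function() xv,
           function(v) { xv <<- array(v, dim(x)) }, dx, tol = 1e-4)
})

test_that("composite block gradients pass finite differences", {
  set.seed(12)
  # residual unit with projection (stride 2, channel change)
  ru <- layer_res_unit(2L, 3L, stride = 2L)
  x <- array(abs(rnorm(6 * 6 * 2 * 2)) + 0.1, c(6, 6, 2, 2))
  y <- ru$fwd(x, TRUE)
  R <- array(rnorm(length(y)), dim = dim(y))
  run <- function() sum(ru$fwd(x, TRUE) * R)
  run(); zero_grads(ru); dxa <- ru$bwd(R)
  cl <- collect_layers(ru)
  for (l in cl[c(1, 3, 5)]) {
    fd_check(run, function() l$par$w,
             function(v) { l$par$w <- array(v, dim(l$par$w)) }, l$grd$w,
             tol = 1e-4, n_probe = 4)
  }
  xv <- x
  fd_check(function() sum(ru$fwd(xv, TRUE) * R), function() xv,
           function(v) { xv <<- array(v, dim(x)) }, dxa, tol = 1e-4,
           n_probe = 4)

  # attention gate: gradients w.r.t. both inputs and one kernel bank
  ag <- layer_attention_gate(2L, 3L, ic = 2L)
  h <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  g <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  yh <- ag$fwd(h, g, TRUE)
  Rh <- array(rnorm(length(yh)), dim = dim(yh))
  runh <- function() sum(ag$fwd(h, g, TRUE) * Rh)
  runh(); zero_grads(ag); gr <- ag$bwd(Rh)
  wh <- ag$children$Wh
  fd_check(runh, function() wh$par$w,
           function(v) { wh$par$w <- array(v, dim(wh$par$w)) }, wh$grd$w,
           tol = 1e-4, n_probe = 4)
  hv <- h
  fd_check(function() sum(ag$fwd(hv, g, TRUE) * Rh), function() hv,
           function(v) { hv <<- array(v, dim(h)) }, gr$dh, tol = 1e-4,
           n_probe = 4)
  gv <- g
  fd_check(function() sum(ag$fwd(h, gv, TRUE) * Rh), function() gv,
           function(v) { gv <<- array(v, dim(g)) }, gr$dg, tol = 1e-4,
           n_probe = 4)

  # dilated bridge
  br <- layer_bridge(2L, 2L)
  xb <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  yb <- br$fwd(xb, TRUE)
  Rb <- array(rnorm(length(yb)), dim = dim(yb))
  runb <- function() sum(br$fwd(xb, TRUE) * Rb)
  runb(); zero_grads(br); dxb <- br$bwd(Rb)
  xbv <- xb
  fd_check(function() sum(br$fwd(xbv, TRUE) * Rb), function() xbv,
           function(v) { xbv <<- array(v, dim(xb)) }, dxb, tol = 1e-4,
           n_probe = 4)
})

test_that("whole-network Dice-loss gradient passes finite differences", {
  set.seed(13)
  cfg <- model_config(input_side = 32L, width = 2 / 32, seed = 3L)
  m <- build_model(cfg)
  x <- array(runif(32 * 32 * 1 * 2), c(32, 32, 1, 2))
  gold <- array((matrix(runif(32 * 32 * 2), 32) > 0.7) * 1, c(32, 32, 1, 2))
  loss_fn <- function() {
    p <- forward(m, x, training = TRUE)
    mean(vapply(1:2, function(k) dice_loss(gold[, , , k], p[, , , k]),
                numeric(1)))
  }
  p <- forward(m, x, training = TRUE)
  zero_grads(m$net)
  backward(m, p, rdaunet:::dice_loss_grad(gold, p))
  layers <- collect_layers(m$net)
  probe <- layers[round(seq(1, length(layers), length.out = 5))]
  for (l in probe) {
    nm <- names(l$par)[1]
    fd_check(loss_fn, function() l$par[[nm]],
             function(v) {
               l$par[[nm]] <- if (is.null(dim(l$par[[nm]]))) v
               else array(v, dim(l$par[[nm]]))
             },
             l$grd[[nm]], eps = 1e-4, tol = 5e-3, n_probe = 3)
  }
})
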