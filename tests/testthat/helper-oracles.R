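# Independent straight-line oracles: naive loop implementations of the
# block equations and metrics, kept deliberately separate from the package's
# vectorised/compiled code paths.

# Triple-loop same-padded strided/dilated cross-correlation.
oracle_conv <- function(x, w, b = NULL, stride = 1, dil = 1) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  K <- dim(w)[1]; Cout <- dim(w)[4]
  eff <- (K - 1) * dil + 1
  Ho <- ceiling(H / stride); Wo <- ceiling(W / stride)
  pt <- max(0, (Ho - 1) * stride + eff - H) %/% 2
  pl <- max(0, (Wo - 1) * stride + eff - W) %/% 2
  y <- array(0, c(Ho, Wo, Cout))
  for (oi in 1:Ho) for (oj in 1:Wo) for (o in 1:Cout) {
    acc <- if (is.null(b)) 0 else b[o]
    for (ki in 1:K) for (kj in 1:K) for (c in 1:Cin) {
      ii <- (oi - 1) * stride - pt + (ki - 1) * dil + 1
      jj <- (oj - 1) * stride - pl + (kj - 1) * dil + 1
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + x[ii, jj, c] * w[ki, kj, c, o]
    }
    y[oi, oj, o] <- acc
  }
  y
}

oracle_bn <- function(x, bn, eps = 1e-5) {
  y <- x
  for (c in seq_len(dim(x)[3]))
    y[, , c] <- (x[, , c] - bn$mean[c]) / sqrt(bn$var[c] + eps) *
      bn$gamma[c] + bn$beta[c]
  y
}

oracle_relu <- function(x) pmax(x, 0)

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

# Inference evaluation of the residual unit: conv-BN-ReLU-conv-BN (+ 1x1
# shortcut when present), ReLU after the addition.
oracle_residual_unit <- function(x, spec, w) {
  f <- oracle_conv(x, w$conv1, stride = spec$stride_s)
  f <- oracle_bn(f, w$bn1)
  f <- oracle_relu(f)
  f <- oracle_conv(f, w$conv2)
  f <- oracle_bn(f, w$bn2)
  s <- if (is.null(w$shortcut)) x else
    oracle_conv(x, w$shortcut, stride = spec$stride_s)
  oracle_relu(f + s)
}

oracle_dilated_conv <- function(x, spec, w) {
  oracle_relu(oracle_conv(x, w$kernel, w$bias, dil = spec$dilation_r))
}

# Per-pixel evaluation of the attention-gate chain with 1x1 kernels.
oracle_attention_gate <- function(h, g, w) {
  H <- dim(h)[1]; W <- dim(h)[2]
  Ch <- dim(h)[3]; Cg <- dim(g)[3]
  ic <- dim(w$W_h)[4]
  Wh <- matrix(w$W_h, nrow = Ch); Wg <- matrix(w$W_g, nrow = Cg)
  Wi <- matrix(w$W_int, nrow = ic); Wk <- matrix(w$W_k, nrow = ic)
  out <- h
  alpha <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    t1 <- oracle_relu(drop(h[i, j, ] %*% Wh) + drop(g[i, j, ] %*% Wg) + w$b_hg)
    u <- drop(t1 %*% Wi) + w$b_int
    a <- oracle_sigmoid(drop(u %*% Wk) + w$b_k)
    alpha[i, j] <- a
    out[i, j, ] <- a * h[i, j, ]
  }
  attr(out, "alpha") <- alpha
  out
}

# Per-pixel loop confusion counts and metric formulas.
oracle_metrics <- function(gold, pred) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(nrow(gold))) for (j in seq_len(ncol(gold))) {
    if (gold[i, j] == 1 && pred[i, j] == 1) tp <- tp + 1
    else if (gold[i, j] == 0 && pred[i, j] == 1) fp <- fp + 1
    else if (gold[i, j] == 1 && pred[i, j] == 0) fn <- fn + 1
    else tn <- tn + 1
  }
  div <- function(a, b) if (b > 0) a / b else 0
  pc <- div(tp, tp + fp); sen <- div(tp, tp + fn)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       acc = div(tp + tn, tp + fp + fn + tn), pc = pc, sen = sen,
       sp = div(tn, tn + fp),
       f1 = if (pc + sen > 0) 2 * pc * sen / (pc + sen) else 0,
       dice = div(2 * tp, 2 * tp + fp + fn),
       iou = div(tp, tp + fp + fn))
}

# Exhaustive-threshold trapezoidal ROC/PR AUC on pooled pixels.
oracle_auc <- function(gold, prob) {
  g <- as.numeric(gold); p <- as.numeric(prob)
  ths <- sort(unique(p), decreasing = TRUE)
  tpr <- 0; fpr <- 0; prec <- 1
  for (t in ths) {
    pred <- p >= t
    tpr <- c(tpr, sum(pred & g == 1) / sum(g == 1))
    fpr <- c(fpr, sum(pred & g == 0) / sum(g == 0))
    prec <- c(prec, sum(pred & g == 1) / max(1, sum(pred)))
  }
  list(roc = sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2),
       pr = sum(diff(tpr) * (prec[-1] + prec[-length(prec)]) / 2))
}

# Central-difference Jacobian of a scalar-to-scalar or vec-to-vec map.
numeric_jacobian <- function(f, x, eps = 1e-6) {
  y0 <- f(x)
  J <- matrix(0, length(y0), length(x))
  for (k in seq_along(x)) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + eps
    xm[k] <- xm[k] - eps
    J[, k] <- (f(xp) - f(xm)) / (2 * eps)
  }
  J
}

# Quick deterministic phantom pair for augmentation/pipeline tests.
toy_sample <- function(side = 32, seed = 1) {
  generate_phantom(phantom_spec(side = side, center = c(0.5, 0.5),
                                axes = c(0.25, 0.18), speckle_looks = 2,
                                seed = seed))
}
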