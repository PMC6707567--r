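# Block-level contracts: residual units, dilated convolution, receptive
# field accounting, dilated bridge, attention gate.

test_that("receptive_field_side reproduces the printed dilation sequence", {
  expect_identical(vapply(c(1L, 2L, 4L, 8L, 16L, 32L),
                          function(r) receptive_field_side(3L, r), integer(1)),
                   c(3L, 7L, 15L, 31L, 63L, 127L))
  expect_identical(receptive_field_side(3L, 2L), 7L)
  expect_error(receptive_field_side(3L, 0L))
})

test_that("residual unit with zero main branch and identity shortcut is identity", {
  set.seed(1)
  spec <- residual_unit_spec(3L, stride_s = 1L)
  w <- residual_unit_weights(spec, 3L)
  expect_null(w$shortcut)
  w$conv1[] <- 0
  w$conv2[] <- 0
  x <- array(runif(6 * 6 * 3), c(6, 6, 3))   # non-negative, so the final
  expect_equal(residual_unit(x, spec, w), x) # ReLU is transparent
})

test_that("residual unit geometry follows the stride/filter schedule", {
  set.seed(2)
  spec <- residual_unit_spec(128L, stride_s = 2L)
  w <- residual_unit_weights(spec, 64L)
  x <- array(rnorm(64 * 64 * 64), c(64, 64, 64))
  y <- residual_unit(x, spec, w)
  expect_identical(dim(y), c(32L, 32L, 128L))
  # decoder-style unit keeps resolution
  spec1 <- residual_unit_spec(8L, stride_s = 1L, role = "decoder")
  w1 <- residual_unit_weights(spec1, 4L)
  y1 <- residual_unit(array(rnorm(10 * 10 * 4), c(10, 10, 4)), spec1, w1)
  expect_identical(dim(y1), c(10L, 10L, 8L))
  expect_error(residual_unit_spec(8L, stride_s = 2L, role = "decoder"),
               "stride 1")
})

test_that("residual unit matches the straight-line oracle", {
  for (trial in 1:20) {
    set.seed(100 + trial)
    cin <- sample(1:4, 1)
    n <- sample(1:4, 1)
    s <- sample(1:2, 1)
    side <- sample(c(1, 4, 7, 8), 1)
    spec <- residual_unit_spec(n, stride_s = s)
    w <- residual_unit_weights(spec, cin)
    w$bn1$mean <- rnorm(n, sd = 0.2); w$bn1$var <- runif(n, 0.5, 2)
    w$bn2$mean <- rnorm(n, sd = 0.2); w$bn2$var <- runif(n, 0.5, 2)
    w$bn1$beta <- rnorm(n, sd = 0.2); w$bn2$gamma <- runif(n, 0.5, 2)
    x <- array(rnorm(side * side * cin), c(side, side, cin))
    expect_lt(max(abs(residual_unit(x, spec, w) -
                        oracle_residual_unit(x, spec, w))), 1e-10)
  }
})

test_that("residual unit Jacobian equals 1 + main-branch Jacobian", {
  set.seed(7)
  spec <- residual_unit_spec(1L, stride_s = 1L)
  w <- residual_unit_weights(spec, 1L)
  w$bn1$beta <- 0.6   # keep both ReLUs in their active region near the probe
  w$bn2$beta <- 0.8
  main_branch <- function(xv) {
    x <- array(xv, c(1, 1, 1))
    f <- oracle_bn(oracle_conv(x, w$conv1), w$bn1)
    f <- oracle_relu(f)
    as.numeric(oracle_bn(oracle_conv(f, w$conv2), w$bn2))
  }
  unit <- function(xv)
    as.numeric(residual_unit(array(xv, c(1, 1, 1)), spec, w))
  x0 <- 0.9
  stopifnot(main_branch(x0) + x0 > 0)  # post-add ReLU active
  j_unit <- numeric_jacobian(unit, x0)[1, 1]
  j_main <- numeric_jacobian(main_branch, x0)[1, 1]
  expect_lt(abs(j_unit - (1 + j_main)), 1e-4)
})

test_that("dilated convolution keeps spatial size and matches the loop oracle", {
  set.seed(3)
  spec <- dilated_conv_spec(3L, 2L, 2L)
  w <- list(kernel = array(rnorm(3 * 3 * 1 * 2), c(3, 3, 1, 2)),
            bias = rnorm(2))
  x <- array(rnorm(16), c(4, 4, 1))
  y <- dilated_conv(x, spec, w)
  expect_identical(dim(y), c(4L, 4L, 2L))
  for (trial in 1:10) {
    set.seed(300 + trial)
    r <- sample(c(1, 2, 4), 1)
    x <- array(rnorm(25), c(5, 5, 1))
    sp <- dilated_conv_spec(3L, r, 1L)
    wt <- list(kernel = array(rnorm(9), c(3, 3, 1, 1)), bias = rnorm(1))
    expect_lt(max(abs(dilated_conv(x, sp, wt) -
                        oracle_dilated_conv(x, sp, wt))), 1e-10)
  }
  expect_error(dilated_conv_spec(3L, 0L), "dilation")
})

test_that("dilation rate 1 collapses to standard same-padded convolution", {
  for (trial in 1:10) {
    set.seed(400 + trial)
    cin <- sample(1:3, 1)
    x <- array(rnorm(36 * cin), c(6, 6, cin))
    w <- array(rnorm(9 * cin * 2), c(3, 3, cin, 2))
    b <- rnorm(2)
    sp <- dilated_conv_spec(3L, 1L, 2L)
    got <- dilated_conv(x, sp, list(kernel = w, bias = b))
    ref <- oracle_relu(oracle_conv(x, w, b))
    expect_lt(max(abs(got - ref)), 1e-6)
  }
})

test_that("dilated bridge sums six branches and upsamples by two", {
  set.seed(4)
  rates <- c(1L, 2L, 4L, 8L, 16L, 32L)
  specs <- lapply(rates, function(r) dilated_conv_spec(3L, r, 3L))
  weights <- lapply(rates, function(r)
    list(kernel = array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3)),
         bias = rnorm(3)))
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  y <- dilated_bridge(x, specs, weights)
  expect_identical(dim(y), c(8L, 8L, 3L))
  # composition: sum of the six dilated_conv outputs, then duplicated 2x2
  acc <- Reduce(`+`, Map(function(s, w) dilated_conv(x, s, w), specs, weights))
  expect_equal(y, upsample_nearest(acc, 2L)[, , , 1])
  # zero weights and biases: all-zero output
  wz <- lapply(weights, function(w) list(kernel = w$kernel * 0, bias = w$bias * 0))
  expect_true(all(dilated_bridge(x, specs, wz) == 0))
  # wrong rate set is rejected
  expect_error(dilated_bridge(x, specs[c(1:5, 1)], weights), "rates")
})

test_that("attention gate obeys the sigmoid-coefficient contract", {
  set.seed(5)
  spec <- attention_gate_spec(3L)
  w <- attention_gate_weights(spec, 4L, 2L)
  h <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  g <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  y <- attention_gate(h, g, spec, w)
  a <- attr(y, "alpha")
  expect_identical(dim(y), dim(h))
  expect_true(all(a > 0 & a < 1))
  expect_true(all(abs(y) <= abs(h) + 1e-12))
  # W_k = 0, b_k = 0 halves h exactly
  w0 <- w; w0$W_k[] <- 0; w0$b_k <- 0
  expect_equal(attention_gate(h, g, spec, w0), h / 2, ignore_attr = TRUE)
  # equal-resolution precondition
  g_bad <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  expect_error(attention_gate(h, g_bad, spec, w), "spatial")
})

test_that("attention gate matches the per-pixel oracle", {
  for (trial in 1:10) {
    set.seed(500 + trial)
    ch <- sample(1:4, 1); cg <- sample(1:4, 1); ic <- sample(1:3, 1)
    spec <- attention_gate_spec(ic)
    w <- attention_gate_weights(spec, ch, cg)
    w$b_hg <- rnorm(ic, sd = 0.3); w$b_int <- rnorm(ic, sd = 0.3)
    w$b_k <- rnorm(1, sd = 0.3)
    h <- array(rnorm(2 * 2 * ch), c(2, 2, ch))
    g <- array(rnorm(2 * 2 * cg), c(2, 2, cg))
    expect_lt(max(abs(attention_gate(h, g, spec, w) -
                        oracle_attention_gate(h, g, w))), 1e-10)
  }
})
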