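# Synthetic B-mode phantom generator.

test_that("phantom generation is deterministic in the seed", {
  sp <- phantom_spec(side = 48, lesion_kind = "malignant_like", seed = 50)
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$mask, p2$mask)
  p3 <- generate_phantom(phantom_spec(side = 48,
                                      lesion_kind = "malignant_like",
                                      seed = 51))
  expect_false(identical(p1$image, p3$image))
})

test_that("noiseless limit reproduces the blurred piecewise-constant map", {
  sp <- phantom_spec(side = 24, speckle_looks = Inf, blur_sigma = 1.2,
                     seed = 52)
  p <- generate_phantom(sp)
  # independent blur: direct 2-d convolution with the truncated Gaussian,
  # replicated edges
  ref_map <- sp$background_intensity +
    (sp$lesion_intensity - sp$background_intensity) * p$mask
  rad <- ceiling(3 * sp$blur_sigma)
  k <- exp(-(-rad:rad)^2 / (2 * sp$blur_sigma^2))
  k <- k / sum(k)
  n <- 24
  ref <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    acc <- 0
    for (a in -rad:rad) for (b in -rad:rad) {
      ii <- min(max(i + a, 1), n)
      jj <- min(max(j + b, 1), n)
      acc <- acc + k[a + rad + 1] * k[b + rad + 1] * ref_map[ii, jj]
    }
    ref[i, j] <- acc
  }
  expect_lt(max(abs(p$image - pmin(pmax(ref, 0), 1))), 1e-12)
})

test_that("smooth-boundary mask is the exact discrete rotated ellipse", {
  sp <- phantom_spec(side = 40, center = c(0.45, 0.55), axes = c(0.2, 0.12),
                     rotation = 30, boundary_irregularity = 0, seed = 53)
  p <- generate_phantom(sp)
  th <- 30 * pi / 180
  ref <- matrix(0, 40, 40)
  for (i in 1:40) for (j in 1:40) {
    dy <- i - 0.45 * 40
    dx <- j - 0.55 * 40
    u <- (cos(th) * dx + sin(th) * dy) / (0.12 * 40)
    v <- (-sin(th) * dx + cos(th) * dy) / (0.2 * 40)
    if (u^2 + v^2 <= 1) ref[i, j] <- 1
  }
  expect_identical(p$mask, ref)
  expect_gt(sum(ref), 0)
})

test_that("lesions are hypoechoic in every generated sample", {
  ds <- generate_dataset(12, side = 48, seed = 54)
  for (s in ds) {
    expect_gt(sum(s$mask), 0)
    expect_lt(mean(s$image[s$mask == 1]), mean(s$image[s$mask == 0]))
  }
})

test_that("speckle contrast decreases monotonically with the number of looks", {
  contrast <- function(looks) {
    vals <- vapply(1:6, function(i) {
      p <- generate_phantom(phantom_spec(side = 48, center = c(0.2, 0.2),
                                         axes = c(0.08, 0.08),
                                         speckle_looks = looks,
                                         blur_sigma = 0, seed = 60 + i))
      bg <- p$image[25:48, 25:48]   # far from the lesion
      stats::sd(bg) / mean(bg)
    }, numeric(1))
    mean(vals)
  }
  cs <- vapply(c(1, 2, 4, 8), contrast, numeric(1))
  expect_true(all(diff(cs) < 0))
})

test_that("boundary complexity separates benign-like from malignant-like", {
  ds <- generate_dataset(10, side = 64, mix = 0.5, seed = 55)
  man <- attr(ds, "manifest")
  expect_equal(sum(man$lesion_kind == "benign_like"), 5)
  compactness <- function(mask) {
    # perimeter^2 / area with perimeter = boundary pixel count
    inner <- mask[2:(nrow(mask) - 1), 2:(ncol(mask) - 1)] *
      mask[1:(nrow(mask) - 2), 2:(ncol(mask) - 1)] *
      mask[3:nrow(mask), 2:(ncol(mask) - 1)] *
      mask[2:(nrow(mask) - 1), 1:(ncol(mask) - 2)] *
      mask[2:(nrow(mask) - 1), 3:ncol(mask)]
    per <- sum(mask[2:(nrow(mask) - 1), 2:(ncol(mask) - 1)]) - sum(inner)
    per^2 / max(1, sum(mask))
  }
  cx <- vapply(ds, function(s) compactness(s$mask), numeric(1))
  benign <- man$lesion_kind == "benign_like"
  expect_gt(mean(cx[!benign]), mean(cx[benign]))
})

test_that("degenerate specs and sizes are rejected", {
  expect_error(phantom_spec(axes = c(0, 0.1)), "degenerate")
  expect_error(phantom_spec(lesion_intensity = 0.7,
                            background_intensity = 0.5), "hypoechoic")
  expect_error(generate_dataset(0), ">= 1")
})

test_that("dataset manifests and splits are seed-reproducible and disjoint", {
  d1 <- generate_dataset(8, side = 32, seed = 56)
  d2 <- generate_dataset(8, side = 32, seed = 56)
  expect_identical(attr(d1, "manifest"), attr(d2, "manifest"))
  expect_identical(d1[[5]]$image, d2[[5]]$image)
  sp <- split_dataset(d1, c(0.5, 0.25, 0.25), seed = 3)
  idx <- attr(sp, "indices")
  expect_length(unlist(idx), 8)
  expect_identical(sort(unname(unlist(idx))), 1:8)
})
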