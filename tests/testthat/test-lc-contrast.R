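test_that("skeletonization keeps the in-mask argmax of every slice", {
  tv <- toy_volume()
  sk <- skeletonize_lc(tv$volume, tv$mask, "left")
  expect_equal(nrow(sk$entries), 3)
  expect_equal(sk$entries$slice, tv$planted$slice)
  expect_equal(sk$entries$coord1, tv$planted$row)
  expect_equal(sk$entries$coord2, tv$planted$col)
  expect_equal(sk$entries$intensity, tv$planted$intensity)
})

test_that("argmax ties break to the smallest row-major coordinate pair", {
  data <- array(100, dim = c(8, 8, 1))
  mask <- array(FALSE, dim = c(8, 8, 1))
  mask[2:6, 2:6, 1] <- TRUE
  data[5, 3, 1] <- 150
  data[3, 6, 1] <- 150   # tie; smaller row wins
  sk <- skeletonize_lc(lc_volume(data, c(1, 1, 1)), mask, "left")
  expect_equal(unname(c(sk$entries$coord1, sk$entries$coord2)), c(3, 6))
  data[3, 2, 1] <- 150   # same row, smaller column wins
  sk <- skeletonize_lc(lc_volume(data, c(1, 1, 1)), mask, "left")
  expect_equal(unname(c(sk$entries$coord1, sk$entries$coord2)), c(3, 2))
})

test_that("skeleton intensities equal a brute-force in-mask slice maximum", {
  for (seed in 1:20) {
    rv <- random_masked_volume(seed)
    sk <- skeletonize_lc(rv$volume, rv$mask, "left")
    bf <- brute_force_skeleton(rv$volume, rv$mask)
    expect_equal(sk$entries$slice, bf$slice)
    expect_equal(sk$entries$intensity, bf$intensity)
  }
})

test_that("skeletonization rejects empty masks and grid mismatches", {
  tv <- toy_volume()
  expect_error(skeletonize_lc(tv$volume, array(FALSE, dim(tv$volume$data)), "left"),
               "empty")
  expect_error(skeletonize_lc(tv$volume, array(TRUE, c(4, 4, 2)), "left"),
               "grid")
})

test_that("reference mean averages exactly size^2 voxels and rejects clipping", {
  data <- array(100, dim = c(32, 32, 3))
  vol <- lc_volume(data, c(1, 1, 1))
  spec <- reference_region_spec(data.frame(slice = 1:3, row = 16, col = 16))
  expect_equal(reference_mean(vol, 1, spec), 100)
  # patch holding 1..225 -> mean 113
  data2 <- data
  data2[9:23, 9:23, 2] <- matrix(1:225, 15, 15)
  vol2 <- lc_volume(data2, c(1, 1, 1))
  expect_equal(reference_mean(vol2, 2, spec), mean(1:225))
  expect_equal(mean(1:225), 113)
  # clipped square is an error, not a partial mean
  edge <- reference_region_spec(data.frame(slice = 1, row = 4, col = 16))
  expect_error(reference_mean(vol, 1, edge), "exceeds the grid")
  expect_error(reference_mean(vol, 3, reference_region_spec(
    data.frame(slice = 1, row = 16, col = 16))), "no reference center")
})

test_that("per-slice contrast follows (LC - ref)/ref with sign preserved", {
  mk <- function(lc_val) {
    data <- array(100, dim = c(32, 32, 4))
    mask <- array(FALSE, dim = c(32, 32, 4))
    for (k in 1:4) {
      # mask interior sits below the centerline so the argmax is planted
      data[25:27, 15:17, k] <- lc_val - 5
      data[26, 16, k] <- lc_val
      mask[25:27, 15:17, k] <- TRUE
    }
    vol <- lc_volume(data, c(1, 1, 1))
    spec <- reference_region_spec(data.frame(slice = 1:4, row = 10, col = 16))
    lc_contrast(vol, skeletonize_lc(vol, mask, "left"), spec)
  }
  expect_equal(mk(120)$side_contrast, 0.2)
  expect_equal(mk(100)$side_contrast, 0)
  expect_equal(mk(90)$side_contrast, -0.1)
  expect_equal(mk(120)$table$contrast, rep(0.2, 4))
})

test_that("contrast errors on a nonpositive reference mean", {
  data <- array(-5, dim = c(32, 32, 1))
  mask <- array(FALSE, dim = c(32, 32, 1))
  data[26, 16, 1] <- 10; mask[26, 16, 1] <- TRUE
  vol <- lc_volume(data, c(1, 1, 1))
  spec <- reference_region_spec(data.frame(slice = 1, row = 10, col = 16))
  expect_error(lc_contrast(vol, skeletonize_lc(vol, mask, "left"), spec),
               "undefined")
})

test_that("contrast is scale invariant and shift covariant", {
  gen <- generate_lc_volume(lc_volume_spec(noise_sd = 2), seed = 11)
  base <- lc_contrast(gen$volume,
                      skeletonize_lc(gen$volume, gen$masks$left, "left"),
                      gen$ref_spec)
  for (k in c(0.5, 3)) {
    scaled <- lc_volume(gen$volume$data * k, gen$volume$voxel_size)
    res <- lc_contrast(scaled, skeletonize_lc(scaled, gen$masks$left, "left"),
                       gen$ref_spec)
    expect_equal(res$table$contrast, base$table$contrast, tolerance = 1e-12)
  }
  shift <- 50
  shifted <- lc_volume(gen$volume$data + shift, gen$volume$voxel_size)
  res <- lc_contrast(shifted, skeletonize_lc(shifted, gen$masks$left, "left"),
                     gen$ref_spec)
  expected <- (base$table$lc_intensity - base$table$ref_mean) /
    (base$table$ref_mean + shift)
  expect_equal(res$table$contrast, expected, tolerance = 1e-12)
})

test_that("bilateral contrast is the mean of the sides and needs both", {
  mk_res <- function(val, side) {
    structure(list(side = side, table = NULL, side_contrast = val),
              class = "lc_contrast_result")
  }
  expect_equal(bilateral_contrast(mk_res(0.2, "left"), mk_res(0.1, "right")), 0.15)
  expect_equal(bilateral_contrast(mk_res(0.07, "left"), mk_res(0.07, "right")), 0.07)
  set.seed(99)
  for (i in 1:100) {
    l <- rnorm(1); r <- rnorm(1)
    expect_equal(bilateral_contrast(mk_res(l, "left"), mk_res(r, "right")),
                 mean(c(l, r)))
  }
  expect_error(bilateral_contrast(mk_res(0.2, "left"), NULL), "both side")
})

test_that("contrast density integrates to 1 and tracks the sample mode", {
  set.seed(7)
  x <- rnorm(1000, mean = 0.12, sd = 0.03)
  d <- contrast_density(x)
  expect_equal(sum(d$y) * diff(d$x[1:2]), 1, tolerance = 1e-3)
  mode_x <- d$x[which.max(d$y)]
  expect_lt(abs(mode_x - mean(x)), 0.25 * sd(x))
  # degenerate sample with a fixed bandwidth is a single Gaussian bump
  d2 <- contrast_density(c(0.1, 0.1), bandwidth = 0.02)
  expect_equal(d2$x[which.max(d2$y)], 0.1, tolerance = 1e-2)
  expect_error(contrast_density(numeric(0)), "empty")
  expect_error(contrast_density(c(0.1, 0.1)), "distinct")
})
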