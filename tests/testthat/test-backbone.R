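test_that("feature extraction obeys the ReLU and shape contracts", {
  zero <- matrix(0, 32, 32)
  fs <- extract_features(zero, backbone_spec("vgg11", tap_blocks = c(1, 2)))
  expect_true(all(fs$block1 == 0))   # zero biases keep zeros zero
  expect_true(all(fs$block2 == 0))

  img <- rand_img(32, seed = 21)
  fs <- extract_features(img, backbone_spec("vgg19", tap_blocks = c(1, 2)))
  expect_identical(dim(fs$block1)[1:2], c(32L, 32L))
  expect_identical(dim(fs$block2)[1:2], c(16L, 16L))
  expect_identical(dim(fs$block1)[3], 64L)
  expect_identical(dim(fs$block2)[3], 128L)
  expect_true(all(fs$block1 >= 0) && all(fs$block2 >= 0))

  # pooling schedule: block b side = ceiling(side / 2^(b-1))
  fs5 <- extract_features(rand_img(40, seed = 1),
                          backbone_spec("vgg11", tap_blocks = 1:5))
  sides <- vapply(fs5, function(x) dim(x)[1], integer(1))
  expect_identical(unname(sides), as.integer(ceiling(40 / 2^(0:4))))

  expect_error(backbone_spec("vgg13"), "variant")
  expect_error(backbone_spec(tap_blocks = integer(0)), "tap_blocks")
})

test_that("feature extraction is deterministic for a fixed fixture seed", {
  img <- rand_img(32, seed = 22)
  spec <- backbone_spec("vgg11", seed = 99L, tap_blocks = 1L)
  a <- extract_features(img, spec)
  b <- extract_features(img, spec)
  expect_identical(a, b)
  other <- extract_features(img, backbone_spec("vgg11", seed = 100L))
  expect_false(identical(a$block1, other$block1))
})

test_that("activity maps are the channel mean or sum of the stack", {
  fs <- array(0, c(4, 4, 2))
  fs[, , 1] <- 0.2; fs[, , 2] <- 0.4
  expect_equal(unclass(activity_map(fs, "mean")),
               matrix(0.3, 4, 4), ignore_attr = TRUE)
  expect_equal(unclass(activity_map(fs, "sum")),
               matrix(0.6, 4, 4), ignore_attr = TRUE)

  fs <- withr::with_seed(23, array(runif(8 * 8 * 4), c(8, 8, 4)))
  oracle_sum <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) oracle_sum[i, j] <- sum(fs[i, j, ])
  expect_equal(activity_map(fs, "sum"), oracle_sum, ignore_attr = TRUE)
  expect_equal(activity_map(fs, "mean"), oracle_sum / 4,
               ignore_attr = TRUE)
})

test_that("transposed convolution matches the scatter-add oracle", {
  # identity kernel: exact identity for the default K=3,S=1,P=1 geometry
  img <- rand_img(8, seed = 24)
  expect_identical(transposed_conv(img, transconv_spec()), img)

  # single impulse through an all-ones kernel scatters a 3x3 block
  imp <- matrix(0, 7, 7); imp[4, 4] <- 1
  ones <- transconv_spec(init = "smoothing")
  ones$kernel <- matrix(1, 3, 3)
  out <- transposed_conv(imp, ones)
  expect_equal(out, tconv_oracle(imp, ones$kernel))
  expect_equal(sum(out), 9)
  expect_true(all(out[3:5, 3:5] == 1))

  for (seed in 1:10) {
    img <- rand_img(8, seed = seed)
    spec <- transconv_spec(init = "random", seed = seed)
    expect_lt(max(abs(transposed_conv(img, spec) -
                      tconv_oracle(img, spec$kernel))), 1e-6)
  }

  # stride-2 geometry against the same oracle
  spec2 <- transconv_spec(K = 4L, S = 2L, P = 1L, init = "random",
                          seed = 3L)
  img <- rand_img(5, seed = 31)
  expect_lt(max(abs(transposed_conv(img, spec2) -
                    tconv_oracle(img, spec2$kernel, S = 2L, P = 1L))),
            1e-12)
  expect_identical(dim(transposed_conv(img, spec2)),
                   c((5L - 1L) * 2L - 2L + 4L, (5L - 1L) * 2L - 2L + 4L))

  expect_error(transposed_conv(matrix(0.5, 2, 2),
                               transconv_spec(K = 1L, P = 2L)),
               "output size")
})

test_that("upsampling preserves range (bilinear) and value set (nearest)", {
  m <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
  expect_identical(upsample_to(m, 2, 2), m)
  expect_equal(upsample_to(matrix(0.7, 3, 3), 9, 9, "bilinear"),
               matrix(0.7, 9, 9))

  near <- upsample_to(m, 4, 4, "nearest")
  expect_equal(near, m[rep(1:2, each = 2), rep(1:2, each = 2)])

  big <- upsample_to(rand_img(8, seed = 25), 32, 32, "bilinear")
  expect_true(min(big) >= 0 && max(big) <= 1)
  expect_error(upsample_to(m, 1, 4), "at least")
})

test_that("parameter counting follows the conv stack arithmetic", {
  # vgg11 block 1: one 3x3 conv, 3 -> 64 channels
  expect_equal(backbone_param_count(backbone_spec("vgg11")),
               9 * 3 * 64 + 64)
  # adding depth strictly grows the count
  counts <- vapply(1:5, function(b)
    backbone_param_count(backbone_spec("vgg19", tap_blocks = b)),
    numeric(1))
  expect_true(all(diff(counts) > 0))
})
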