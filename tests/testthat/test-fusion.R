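test_that("softmax weight maps are convex and match the scalar oracle", {
  a <- matrix(0.4, 6, 6)
  w <- weight_maps(list(a, a))
  expect_equal(w[[1]], matrix(0.5, 6, 6))
  expect_equal(w[[2]], matrix(0.5, 6, 6))

  # activities (a, a + ln 2) give weights (1/3, 2/3)
  w2 <- weight_maps(list(a, a + log(2)))
  expect_equal(w2[[1]], matrix(1 / 3, 6, 6))
  expect_equal(w2[[2]], matrix(2 / 3, 6, 6))

  acts <- lapply(1:3, function(s) rand_img(8, seed = 30 + s) * 5)
  w3 <- weight_maps(acts)
  oracle <- softmax_oracle(acts)
  for (z in 1:3) expect_equal(w3[[z]], oracle[[z]], tolerance = 1e-12)
  expect_lt(max(abs(Reduce(`+`, w3) - 1)), 1e-6)

  # shift invariance keeps huge activities finite
  wbig <- weight_maps(list(a + 1e4, a + 1e4 + 1))
  expect_true(all(is.finite(unlist(wbig))))

  expect_error(weight_maps(list(a)), "at least two")
  expect_error(weight_maps(list(a, matrix(0, 3, 3))), "shape")
})

test_that("per-layer fusion follows both operator readings", {
  cfg <- fusion_config(backbone = backbone_spec("vgg11"))
  src <- rand_img(8, seed = 33)
  half <- matrix(0.5, 8, 8)

  expect_identical(fuse_layer(list(src, src), list(half, half), cfg), src)

  c1 <- matrix(0.2, 8, 8); c2 <- matrix(0.8, 8, 8)
  expect_equal(fuse_layer(list(c1, c2), list(half, half), cfg),
               matrix(0.5, 8, 8))

  # loop oracle in both modes, with a random weight split
  wa <- rand_img(8, seed = 34); wb <- 1 - wa
  s2 <- rand_img(8, seed = 35)
  apply_oracle <- matrix(0, 8, 8); had_oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    apply_oracle[i, j] <- wa[i, j] * src[i, j] + wb[i, j] * s2[i, j]
    had_oracle[i, j] <- wa[i, j] * src[i, j]^2 + wb[i, j] * s2[i, j]^2
  }
  expect_equal(fuse_layer(list(src, s2), list(wa, wb), cfg),
               apply_oracle)
  cfg_h <- fusion_config(backbone = backbone_spec("vgg11"),
                         operator = "hadamard")
  expect_equal(fuse_layer(list(src, s2), list(wa, wb), cfg_h),
               pmin(had_oracle, 1))

  expect_error(fuse_layer(list(src), list(wa, wb), cfg), "per source")
})

test_that("max-selection reconstruction is a per-pixel maximum", {
  img <- rand_img(8, seed = 36)
  expect_identical(fuse_max(list(img)), img)
  expect_equal(fuse_max(list(matrix(0.3, 4, 4), matrix(0.7, 4, 4))),
               matrix(0.7, 4, 4))

  imgs <- lapply(1:3, function(s) rand_img(8, seed = 40 + s))
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    oracle[i, j] <- max(vapply(imgs, function(m) m[i, j], numeric(1)))
  expect_equal(fuse_max(imgs), oracle)

  # monotone in the number of layers
  expect_true(all(fuse_max(imgs) >= fuse_max(imgs[1:2])))
  expect_error(fuse_max(list()), "at least one")
})

test_that("end-to-end fusion keeps the identity, symmetry and convex-hull
           properties", {
  pair <- make_phantom_pair(phantom_spec(size = 64, seed = 50))
  A <- pair$structural
  B <- to_luminance(pair$functional)
  cfg <- fusion_config(backbone = backbone_spec("vgg11"))

  expect_identical(fuse_pair(A, A, cfg), A)
  expect_identical(fuse_pair(A, B, cfg), fuse_pair(B, A, cfg))

  fused <- fuse_pair(A, B, cfg)
  lo <- pmin(A, B); hi <- pmax(A, B)
  expect_true(all(fused >= lo - 1e-12))
  expect_true(all(fused <= hi + 1e-12))

  # multi-block fusion dominates its single-block restriction
  cfg2 <- fusion_config(backbone = backbone_spec("vgg11",
                                                 tap_blocks = c(1, 3)))
  expect_true(all(fuse_pair(A, B, cfg2) >= fuse_pair(A, B, cfg) - 1e-12))

  expect_error(fuse_images(list(A)), "at least two")
  expect_error(fuse_pair(A, matrix(0.5, 32, 32)), "shape")
})

test_that("three-source fusion stays within the sources' convex hull", {
  imgs <- lapply(1:3, function(s)
    make_phantom_pair(phantom_spec(size = 64, seed = 60 + s))$structural)
  cfg <- fusion_config(backbone = backbone_spec("vgg11"))
  fused <- fuse_images(imgs, cfg)
  expect_true(all(fused <= Reduce(pmax, imgs) + 1e-12))
  expect_true(all(fused >= Reduce(pmin, imgs) - 1e-12))
})
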