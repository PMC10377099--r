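#' Phantom specification
#'
#' Parameters of the synthetic structural/functional slice pair: image
#' side, RNG seed, the misalignment applied to the functional rendering
#' (pixel shift and rotation, returned as ground truth for registration
#' tests), additive Gaussian noise level, and the number of functional
#' "uptake" hotspots.
#'
#' Defaults emulate a clean, pre-registered acquisition: 128 x 128 slices,
#' no misalignment, mild sensor noise (sigma 0.01 on the \[0, 1\] scale),
#' three hotspots.
#'
#' @param size image side, >= 32 (default 128).
#' @param seed integer RNG seed.
#' @param shift_px integer `c(dx, dy)` translation of the functional slice.
#' @param rotation_deg rotation of the functional slice, degrees CCW.
#' @param noise_sigma Gaussian noise sd in `[0, 0.5)`.
#' @param n_hotspots number of uptake blobs, >= 0.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 128L, seed = 1L, shift_px = c(0L, 0L),
                         rotation_deg = 0, noise_sigma = 0.01,
                         n_hotspots = 3L) {
  size <- as.integer(size)
  if (is.na(size) || size < 32L)
    stop("phantom size must be >= 32", call. = FALSE)
  if (!is.numeric(noise_sigma) || noise_sigma < 0 || noise_sigma >= 0.5)
    stop("noise_sigma must lie in [0, 0.5)", call. = FALSE)
  n_hotspots <- as.integer(n_hotspots)
  if (is.na(n_hotspots) || n_hotspots < 0L)
    stop("n_hotspots must be >= 0", call. = FALSE)
  structure(list(size = size, seed = as.integer(seed),
                 shift_px = as.integer(shift_px),
                 rotation_deg = rotation_deg,
                 noise_sigma = noise_sigma, n_hotspots = n_hotspots),
            class = "phantom_spec")
}

# Filled ellipse mask centered at (cy, cx) with semi-axes (ry, rx), rotated
# by theta radians.
ellipse_mask <- function(size, cy, cx, ry, rx, theta = 0) {
  yy <- matrix(seq_len(size), size, size) - cy
  xx <- matrix(seq_len(size), size, size, byrow = TRUE) - cx
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  (u / rx)^2 + (v / ry)^2 <= 1
}

# black -> red -> yellow -> white ramp, the classic "hot" rendering of
# functional uptake
hot_colormap <- function(u) {
  r <- clip01(3 * u)
  g <- clip01(3 * u - 1)
  b <- clip01(3 * u - 2)
  out <- array(0, c(dim(u), 3L))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}

#' Generate one structural/functional phantom pair
#'
#' The structural slice is an elliptical "skull + tissue" phantom: a bright
#' sharp skull ring, mid-gray tissue with sinusoidal texture, dark
#' ventricles and a few random sharp-edged lesions — high-frequency,
#' MRI-like content. The functional slice is a smooth uptake field (broad
#' background metabolism plus Gaussian hotspots) over the same geometry,
#' rendered through a hot colormap, then misaligned by the spec's
#' shift/rotation and degraded with seeded Gaussian noise (the structural
#' slice receives the same noise level, no misalignment). The applied
#' misalignment is returned as ground truth.
#'
#' Fully deterministic under the spec's seed; global RNG state is left
#' untouched.
#'
#' @param spec [phantom_spec()].
#' @return list with `structural` (image2d matrix), `functional`
#'   (H x W x 3 color array) and `truth` (list with `shift_px`,
#'   `rotation_deg`).
#' @export
make_phantom_pair <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec"))
    stop("make_phantom_pair needs a phantom_spec", call. = FALSE)
  n <- spec$size
  c0 <- (n + 1) / 2
  withr::with_seed(spec$seed, {
    jit <- stats::runif(4, -0.03, 0.03) * n
    skull_out <- ellipse_mask(n, c0 + jit[1], c0 + jit[2],
                              0.44 * n, 0.36 * n)
    skull_in <- ellipse_mask(n, c0 + jit[1], c0 + jit[2],
                             0.40 * n, 0.32 * n)
    brain <- ellipse_mask(n, c0 + jit[1], c0 + jit[2], 0.38 * n, 0.30 * n)

    structural <- matrix(0, n, n)
    structural[skull_out & !skull_in] <- 0.95
    yy <- matrix(seq_len(n), n, n)
    xx <- matrix(seq_len(n), n, n, byrow = TRUE)
    texture <- 0.45 + 0.12 * sin(2 * pi * yy / 9) * cos(2 * pi * xx / 11)
    structural[brain] <- texture[brain]
    vent <- ellipse_mask(n, c0 + jit[1] - 0.04 * n, c0 + jit[2],
                         0.10 * n, 0.05 * n, theta = 0.4) |
            ellipse_mask(n, c0 + jit[1] - 0.04 * n, c0 + jit[2],
                         0.10 * n, 0.05 * n, theta = -0.4)
    structural[vent & brain] <- 0.12
    for (k in seq_len(3)) {
      lc <- c0 + stats::runif(2, -0.2, 0.2) * n
      lr <- stats::runif(2, 0.02, 0.05) * n
      les <- ellipse_mask(n, lc[1], lc[2], lr[1], lr[2],
                          stats::runif(1, 0, pi))
      structural[les & brain] <- stats::runif(1, 0.7, 0.9)
    }

    # smooth uptake: broad base metabolism + Gaussian hotspots
    uptake <- matrix(0, n, n)
    base <- exp(-(((yy - c0 - jit[1]) / (0.30 * n))^2 +
                  ((xx - c0 - jit[2]) / (0.24 * n))^2))
    uptake <- 0.45 * base
    if (spec$n_hotspots > 0L) {
      for (k in seq_len(spec$n_hotspots)) {
        hc <- c0 + stats::runif(2, -0.18, 0.18) * n
        hs <- stats::runif(1, 0.04, 0.09) * n
        amp <- stats::runif(1, 0.5, 0.9)
        uptake <- uptake +
          amp * exp(-(((yy - hc[1])^2 + (xx - hc[2])^2) / (2 * hs^2)))
      }
    }
    uptake[!brain] <- 0
    mx <- max(uptake)
    if (mx > 0) uptake <- uptake / mx

    functional <- hot_colormap(uptake)
    if (spec$rotation_deg != 0)
      for (ch in 1:3)
        functional[, , ch] <- img_rotate(functional[, , ch],
                                         spec$rotation_deg)
    if (any(spec$shift_px != 0L))
      for (ch in 1:3)
        functional[, , ch] <- img_shift(functional[, , ch],
                                        spec$shift_px[1], spec$shift_px[2])
    if (spec$noise_sigma > 0) {
      structural <- clip01(structural +
        matrix(stats::rnorm(n * n, sd = spec$noise_sigma), n, n))
      functional <- clip01(functional +
        array(stats::rnorm(3 * n * n, sd = spec$noise_sigma), c(n, n, 3L)))
    }
    list(structural = as_image2d(structural),
         functional = as_color_image(functional),
         truth = list(shift_px = spec$shift_px,
                      rotation_deg = spec$rotation_deg))
  })
}

#' Generate a deterministic batch of phantom pairs
#'
#' Pairs use seeds `base_seed`, `base_seed + 1`, ... so any batch is
#' reproducible and any single pair can be regenerated in isolation.
#'
#' @param n number of pairs, >= 1.
#' @param base_seed seed of the first pair.
#' @param ... further arguments passed to [phantom_spec()].
#' @return list of `n` phantom pairs.
#' @export
make_batch <- function(n, base_seed = 1L, ...) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L)
    stop("batch size must be >= 1", call. = FALSE)
  lapply(seq_len(n) - 1L, function(i)
    make_phantom_pair(phantom_spec(seed = base_seed + i, ...)))
}
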