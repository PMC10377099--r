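vgg_layouts <- list(
  vgg11 = list(convs = c(1L, 1L, 2L, 2L, 2L)),
  vgg16 = list(convs = c(2L, 2L, 3L, 3L, 3L)),
  vgg19 = list(convs = c(2L, 2L, 4L, 4L, 4L))
)
vgg_channels <- c(64L, 128L, 256L, 512L, 512L)

#' Backbone specification
#'
#' Describes the fixed-weight VGG-style convolutional feature extractor:
#' which variant (number of 3 x 3 conv layers per block), where the weights
#' come from, and which of the five convolution blocks are tapped for
#' features. Each block is a run of same-padded 3 x 3 convolutions with
#' ReLU, followed by 2 x 2 max pooling; the tap is the ReLU output of the
#' block's last convolution, before that block's pool, so block b features
#' have side `ceiling(side / 2^(b - 1))`.
#'
#' Weight sources: `"fixture"` builds the chosen topology with seeded
#' He-initialized kernels and zero biases, fully deterministic and offline —
#' the fusion algebra only needs a fixed nonlinear feature map, not trained
#' filters. `"file"` loads weights exported to an `.rds` (a list with one
#' `list(w, b)` per conv layer, kernels 3 x 3 x in x out), the hook for real
#' pretrained VGG filters.
#'
#' @param variant `"vgg11"`, `"vgg16"` or `"vgg19"`.
#' @param weights `"fixture"` or `"file"`.
#' @param seed integer seed for fixture weights.
#' @param tap_blocks integer subset of 1:5, non-empty.
#' @param weights_file path to the `.rds` weight list when
#'   `weights = "file"`.
#' @return object of class `backbone_spec`.
#' @export
backbone_spec <- function(variant = "vgg19", weights = "fixture",
                          seed = 42L, tap_blocks = 1L,
                          weights_file = NULL) {
  if (identical(weights, "pretrained"))
    stop("downloaded pretrained weights are not bundled; export them and ",
         "use weights = \"file\"", call. = FALSE)
  if (!variant %in% names(vgg_layouts))
    stop("unknown backbone variant: ", variant, call. = FALSE)
  if (!weights %in% c("fixture", "file"))
    stop("weights must be \"fixture\" or \"file\"", call. = FALSE)
  tap_blocks <- sort(unique(as.integer(tap_blocks)))
  if (length(tap_blocks) == 0L || any(is.na(tap_blocks)) ||
      any(tap_blocks < 1L | tap_blocks > 5L))
    stop("tap_blocks must be a non-empty subset of 1:5", call. = FALSE)
  structure(list(variant = variant, weights = weights,
                 seed = as.integer(seed), tap_blocks = tap_blocks,
                 weights_file = weights_file),
            class = "backbone_spec")
}

# He-initialized conv stacks; biases zero so an all-zero input stays zero
# through every block.
fixture_weights <- function(spec, max_block) {
  convs <- vgg_layouts[[spec$variant]]$convs
  withr::with_seed(spec$seed, {
    layers <- list()
    in_ch <- 3L
    for (b in seq_len(max_block)) {
      out_ch <- vgg_channels[b]
      for (k in seq_len(convs[b])) {
        fan_in <- 9L * in_ch
        w <- array(stats::rnorm(9L * in_ch * out_ch, sd = sqrt(2 / fan_in)),
                   dim = c(3L, 3L, in_ch, out_ch))
        layers[[length(layers) + 1L]] <-
          list(w = w, b = numeric(out_ch), block = b)
        in_ch <- out_ch
      }
    }
    layers
  })
}

load_backbone_weights <- function(spec, max_block) {
  if (spec$weights == "fixture") return(fixture_weights(spec, max_block))
  if (is.null(spec$weights_file) || !file.exists(spec$weights_file))
    stop("weights_file not found: ", spec$weights_file, call. = FALSE)
  layers <- readRDS(spec$weights_file)
  Filter(function(l) l$block <= max_block, layers)
}

# Same-padded multi-channel 3x3 correlation via im2col + one BLAS gemm.
# x: H x W x Cin, w: 3 x 3 x Cin x Cout.
conv2d_block <- function(x, w, b) {
  h <- dim(x)[1]; wd <- dim(x)[2]; cin <- dim(x)[3]
  cout <- dim(w)[4]
  xp <- array(0, c(h + 2L, wd + 2L, cin))
  xp[2:(h + 1L), 2:(wd + 1L), ] <- x
  cols <- matrix(0, h * wd, 9L * cin)
  k <- 0L
  for (j in 1:3) for (i in 1:3) {
    k <- k + 1L
    cols[, seq.int(k, by = 9L, length.out = cin)] <-
      xp[i:(i + h - 1L), j:(j + wd - 1L), , drop = FALSE]
  }
  wm <- matrix(aperm(w, c(1, 2, 3, 4)), 9L * cin, cout)
  out <- cols %*% wm
  out <- sweep(out, 2L, b, `+`)
  out[out < 0] <- 0   # ReLU
  array(out, c(h, wd, cout))
}

# 2x2 stride-2 max pooling, ceil mode (odd sides keep their last row/col).
maxpool2 <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]; ch <- dim(x)[3]
  ho <- ceiling(h / 2); wo <- ceiling(w / 2)
  xp <- array(-Inf, c(2L * ho, 2L * wo, ch))
  xp[1:h, 1:w, ] <- x
  i1 <- seq.int(1L, 2L * ho, by = 2L)
  j1 <- seq.int(1L, 2L * wo, by = 2L)
  pmax(pmax(xp[i1, j1, , drop = FALSE], xp[i1 + 1L, j1, , drop = FALSE]),
       pmax(xp[i1, j1 + 1L, , drop = FALSE],
            xp[i1 + 1L, j1 + 1L, , drop = FALSE]))
}

#' Extract per-block deep feature stacks
#'
#' Runs the image through the backbone and returns, for each tapped block,
#' the ReLU output of that block's last convolution as an H_y x W_y x V
#' array (a "feature stack", with attributes `layer_id` and `channels`).
#' Grayscale input is replicated to 3 channels before the first
#' convolution; fixture weights consume the raw \[0, 1\] intensities.
#' Deterministic for a fixed weight source.
#'
#' @param img image2d matrix.
#' @param spec [backbone_spec()].
#' @return named list `block<i>` of feature arrays, one per tap block.
#' @export
extract_features <- function(img, spec = backbone_spec()) {
  img <- as_image2d(img)
  max_block <- max(spec$tap_blocks)
  layers <- load_backbone_weights(spec, max_block)
  convs <- vgg_layouts[[spec$variant]]$convs
  x <- array(rep(img, 3L), c(dim(img), 3L))
  out <- list()
  li <- 0L
  for (b in seq_len(max_block)) {
    for (k in seq_len(convs[b])) {
      li <- li + 1L
      x <- conv2d_block(x, layers[[li]]$w, layers[[li]]$b)
    }
    if (b %in% spec$tap_blocks) {
      fs <- x
      attr(fs, "layer_id") <- b
      attr(fs, "channels") <- dim(x)[3]
      out[[paste0("block", b)]] <- fs
    }
    if (b < max_block) x <- maxpool2(x)
  }
  out
}

#' Collapse a feature stack to a single-channel activity map
#'
#' The per-pixel activity level of a source at one block: the sum or mean
#' of the stack over its channels. The mean (default) keeps activity
#' scales comparable across blocks with different channel counts.
#'
#' @param fs feature array from [extract_features()].
#' @param mode `"mean"` or `"sum"`.
#' @return non-negative matrix with the stack's spatial shape, carrying the
#'   `layer_id` attribute.
#' @export
activity_map <- function(fs, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  if (!is.array(fs) || length(dim(fs)) != 3L)
    stop("feature stack must be an H x W x V array", call. = FALSE)
  am <- rowSums(fs, dims = 2L)
  if (mode == "mean") am <- am / dim(fs)[3]
  attr(am, "layer_id") <- attr(fs, "layer_id")
  am
}

#' Transposed-convolution layer specification
#'
#' The enhancement layer applied to each source before weighting: a single
#' 2D transposed convolution with kernel side `K`, stride `S` and padding
#' `P`. With the defaults K = 3, S = 1, P = 1 the output shape equals the
#' input shape. The kernel is untrained; `init` selects it:
#' `"identity"` (center 1 — an exact no-op for the default geometry, the
#' strict baseline), `"smoothing"` (normalized 3 x 3 binomial kernel), or
#' `"random"` (seeded Gaussian, unit-normalized).
#'
#' @param K kernel side, >= 1.
#' @param S stride, >= 1.
#' @param P zero padding removed from each output border, >= 0.
#' @param init `"identity"`, `"smoothing"` or `"random"`.
#' @param seed seed for `init = "random"`.
#' @return object of class `transconv_spec` (kernel materialized in
#'   `$kernel`).
#' @export
transconv_spec <- function(K = 3L, S = 1L, P = 1L,
                           init = c("identity", "smoothing", "random"),
                           seed = 1L) {
  init <- match.arg(init)
  K <- as.integer(K); S <- as.integer(S); P <- as.integer(P)
  if (is.na(K) || K < 1L || is.na(S) || S < 1L || is.na(P) || P < 0L)
    stop("transposed-conv spec needs K >= 1, S >= 1, P >= 0", call. = FALSE)
  kernel <- switch(init,
    identity = {
      k <- matrix(0, K, K)
      k[(K + 1L) %/% 2L, (K + 1L) %/% 2L] <- 1
      k
    },
    smoothing = {
      v <- choose(K - 1L, 0:(K - 1L))
      k <- outer(v, v)
      k / sum(k)
    },
    random = withr::with_seed(seed, {
      k <- matrix(stats::rnorm(K * K), K, K)
      k / sqrt(sum(k^2))
    })
  )
  structure(list(K = K, S = S, P = P, init = init, seed = as.integer(seed),
                 kernel = kernel),
            class = "transconv_spec")
}

#' Transposed convolution of a single-channel image
#'
#' Scatters each input value through the kernel onto a stride-`S` output
#' grid and crops `P` border pixels: output size `(H - 1) S - 2P + K` per
#' side. For the default K = 3, S = 1, P = 1 geometry the output shape
#' equals the input shape, and the identity kernel makes the layer an exact
#' identity.
#'
#' @param img numeric matrix (any finite values; feature-domain use is
#'   allowed, so no \[0, 1\] restriction here).
#' @param spec [transconv_spec()].
#' @return numeric matrix of the transposed-conv output size.
#' @export
transposed_conv <- function(img, spec = transconv_spec()) {
  if (!is.matrix(img) || !is.numeric(img) || any(!is.finite(img)))
    stop("transposed_conv needs a finite numeric matrix", call. = FALSE)
  K <- spec$K; S <- spec$S; P <- spec$P
  h <- nrow(img); w <- ncol(img)
  ho <- (h - 1L) * S - 2L * P + K
  wo <- (w - 1L) * S - 2L * P + K
  if (ho < 1L || wo < 1L)
    stop("transposed-conv spec yields a non-positive output size",
         call. = FALSE)
  full <- matrix(0, (h - 1L) * S + K, (w - 1L) * S + K)
  ri <- seq.int(1L, by = S, length.out = h)
  ci <- seq.int(1L, by = S, length.out = w)
  for (ki in seq_len(K)) for (kj in seq_len(K)) {
    if (spec$kernel[ki, kj] == 0) next
    full[ri + ki - 1L, ci + kj - 1L] <-
      full[ri + ki - 1L, ci + kj - 1L] + spec$kernel[ki, kj] * img
  }
  full[(P + 1L):(P + ho), (P + 1L):(P + wo), drop = FALSE]
}

#' Upsample an activity or weight map to a target shape
#'
#' Resamples a block-resolution map up to image resolution. Bilinear
#' interpolation preserves the value range; nearest-neighbor preserves the
#' value set. Downsampling is refused — weight maps are only ever lifted to
#' the full-resolution fusion grid.
#'
#' @param map numeric matrix.
#' @param target_h,target_w target dimensions, each >= the source dimension.
#' @param mode `"bilinear"` or `"nearest"`.
#' @return numeric matrix of shape `target_h` x `target_w`.
#' @export
upsample_to <- function(map, target_h, target_w,
                        mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  if (!is.matrix(map) || !is.numeric(map))
    stop("upsample_to needs a numeric matrix", call. = FALSE)
  if (target_h < nrow(map) || target_w < ncol(map))
    stop("upsample target must be at least the source size", call. = FALSE)
  if (target_h == nrow(map) && target_w == ncol(map)) return(map)
  attrs <- attributes(map)[c("layer_id")]
  out <- from_ebi(EBImage::resize(
    to_ebi(map), w = target_w, h = target_h,
    filter = if (mode == "bilinear") "bilinear" else "none"))
  attr(out, "layer_id") <- attrs$layer_id
  out
}

#' Parameter count of the tapped sub-network
#'
#' Number of convolution weights and biases in the backbone up to (and
#' including) the deepest tapped block — the model-size objective used in
#' the Pareto selection demo.
#'
#' @param spec [backbone_spec()].
#' @return integer parameter count.
#' @export
backbone_param_count <- function(spec) {
  convs <- vgg_layouts[[spec$variant]]$convs
  in_ch <- 3L
  total <- 0
  for (b in seq_len(max(spec$tap_blocks))) {
    out_ch <- vgg_channels[b]
    for (k in seq_len(convs[b])) {
      total <- total + 9 * in_ch * out_ch + out_ch
      in_ch <- out_ch
    }
  }
  total
}
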