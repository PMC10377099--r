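#' Fusion configuration
#'
#' Bundles every tunable of the fusion pipeline: the backbone and its tap
#' blocks, the transposed-convolution enhancement layer, how feature stacks
#' collapse to activity maps, how block-resolution maps are lifted to image
#' resolution, and which reading of the per-layer fusion rule is used.
#'
#' The `operator` choices: `"apply"` (default) fuses
#' `sum_z W_z * TransConv(I_z)` — convex weights applied to the enhanced
#' sources, which makes fusing an image with itself an exact identity under
#' the identity kernel; `"hadamard"` fuses
#' `sum_z W_z * I_z * TransConv(I_z)`, the literal elementwise-product
#' reading, kept for fidelity (it squares intensities, so it darkens and
#' breaks the self-fusion identity).
#'
#' @param backbone [backbone_spec()].
#' @param transconv [transconv_spec()].
#' @param activity_mode `"mean"` or `"sum"` channel collapse.
#' @param upsample_mode `"bilinear"` or `"nearest"` weight-map lifting.
#' @param operator `"apply"` or `"hadamard"`.
#' @param tap_blocks optional override of `backbone$tap_blocks`.
#' @return object of class `fusion_config`.
#' @export
fusion_config <- function(backbone = backbone_spec(),
                          transconv = transconv_spec(),
                          activity_mode = c("mean", "sum"),
                          upsample_mode = c("bilinear", "nearest"),
                          operator = c("apply", "hadamard"),
                          tap_blocks = NULL) {
  if (!is.null(tap_blocks))
    backbone <- backbone_spec(backbone$variant, backbone$weights,
                              backbone$seed, tap_blocks,
                              backbone$weights_file)
  structure(list(backbone = backbone, transconv = transconv,
                 activity_mode = match.arg(activity_mode),
                 upsample_mode = match.arg(upsample_mode),
                 operator = match.arg(operator)),
            class = "fusion_config")
}

#' Softmax weight maps from per-source activity maps
#'
#' Converts the activity maps of all sources at one block into per-source
#' weight maps with a per-pixel softmax:
#' `W_z = exp(a_z) / sum_j exp(a_j)`. The per-pixel maximum is subtracted
#' before exponentiation (softmax shift invariance makes this exact), so
#' large activities cannot overflow. At every pixel the weights across
#' sources sum to 1.
#'
#' @param acts list (length >= 2) of same-shaped activity matrices, one per
#'   source.
#' @return list of weight matrices in input order.
#' @export
weight_maps <- function(acts) {
  if (!is.list(acts) || length(acts) < 2L)
    stop("weight_maps needs at least two activity maps", call. = FALSE)
  d <- dim(acts[[1]])
  if (!all(vapply(acts, function(a) identical(dim(a), d), logical(1))))
    stop("activity maps must share one shape", call. = FALSE)
  mx <- Reduce(pmax, acts)
  ex <- lapply(acts, function(a) exp(a - mx))
  denom <- Reduce(`+`, ex)
  lapply(ex, function(e) {
    w <- e / denom
    attributes(w) <- list(dim = d)   # drop inherited layer_id etc.
    w
  })
}

#' Fuse sources at one block with their weight maps
#'
#' The per-block fusion rule: each source is enhanced by the
#' transposed-convolution layer and combined under its per-pixel weights
#' (see [fusion_config()] for the two operator readings). Weight maps must
#' already be at source resolution — [fuse_pair()] lifts them with
#' [upsample_to()]. The result is clipped to \[0, 1\] since non-identity
#' kernels can push values out of range.
#'
#' @param sources list of image2d matrices.
#' @param weights list of weight matrices, one per source, same shape.
#' @param cfg [fusion_config()].
#' @return fused image2d matrix.
#' @export
fuse_layer <- function(sources, weights, cfg = fusion_config()) {
  if (length(sources) != length(weights))
    stop("one weight map per source is required", call. = FALSE)
  d <- dim(sources[[1]])
  acc <- matrix(0, d[1], d[2])
  for (z in seq_along(sources)) {
    src <- as_image2d(sources[[z]])
    if (!identical(dim(src), d) || !identical(dim(weights[[z]]), d))
      stop("sources and weight maps must share one shape", call. = FALSE)
    enh <- transposed_conv(src, cfg$transconv)
    if (!identical(dim(enh), d))
      stop("transposed-conv spec must preserve shape inside fusion",
           call. = FALSE)
    term <- if (cfg$operator == "apply") weights[[z]] * enh
            else weights[[z]] * src * enh
    acc <- acc + term
  }
  clip01(acc)
}

#' Max-selection reconstruction across blocks
#'
#' Reconstructs the final fused image from the per-block fused images by
#' keeping, at each pixel, the largest value any block produced
#' (equivalently: a 0/1 layer weight selecting the maximal layer per
#' pixel).
#'
#' @param layer_images non-empty list of same-shaped image2d matrices.
#' @return image2d matrix of per-pixel maxima.
#' @export
fuse_max <- function(layer_images) {
  if (!is.list(layer_images) || length(layer_images) == 0L)
    stop("fuse_max needs at least one layer image", call. = FALSE)
  d <- dim(layer_images[[1]])
  if (!all(vapply(layer_images, function(x) identical(dim(x), d),
                  logical(1))))
    stop("layer images must share one shape", call. = FALSE)
  Reduce(pmax, layer_images)
}

#' Fuse a set of co-registered sources end to end
#'
#' The full pipeline for each tapped block: extract deep features for every
#' source, collapse them to activity maps, lift the maps to image
#' resolution, convert to softmax weight maps, and fuse the
#' transposed-conv-enhanced sources under those weights; then reconstruct
#' across blocks by per-pixel max selection. Deterministic for fixture
#' weights. [fuse_pair()] is the two-modality convenience wrapper.
#'
#' @param sources list (length >= 2) of same-shaped image2d matrices,
#'   already preprocessed/registered.
#' @param cfg [fusion_config()].
#' @return fused image2d matrix.
#' @export
fuse_images <- function(sources, cfg = fusion_config()) {
  if (!is.list(sources) || length(sources) < 2L)
    stop("fusion needs at least two sources", call. = FALSE)
  sources <- lapply(sources, as_image2d)
  d <- dim(sources[[1]])
  if (!all(vapply(sources, function(x) identical(dim(x), d), logical(1))))
    stop("sources must share one shape", call. = FALSE)
  feats <- lapply(sources, extract_features, spec = cfg$backbone)
  fuse_with_features(sources, feats, cfg)
}

# fusion core reused when feature stacks are precomputed (ablation sweeps,
# candidate grids): feats must cover every tap block of cfg
fuse_with_features <- function(sources, feats, cfg) {
  d <- dim(sources[[1]])
  per_block <- lapply(cfg$backbone$tap_blocks, function(b) {
    key <- paste0("block", b)
    acts <- lapply(feats, function(f) {
      am <- activity_map(f[[key]], cfg$activity_mode)
      upsample_to(am, d[1], d[2], cfg$upsample_mode)
    })
    fuse_layer(sources, weight_maps(acts), cfg)
  })
  fuse_max(per_block)
}

#' @rdname fuse_images
#' @param structural,functional the two modality slices (image2d matrices;
#'   pass pseudo-color functional input through [to_luminance()] first).
#' @export
fuse_pair <- function(structural, functional, cfg = fusion_config()) {
  fuse_images(list(structural, functional), cfg)
}
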