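#' Build the offline hyperparameter candidate grid
#'
#' Exercises the Pareto machinery without any training data: a grid over
#' the fusion tunables that actually change the pipeline — tapped block
#' (1..5), activity collapse (mean/sum) and enhancement kernel
#' (identity/smoothing) — scored on a small phantom batch with two
#' minimize-directed proxy objectives:
#'
#' * `1 - mean SSIM` of the fused image against the two sources (a fusion
#'   quality loss on the unit scale), and
#' * the parameter count of the tapped sub-network (model size).
#'
#' Feature stacks are extracted once per source and reused across the grid.
#'
#' @param n_pairs phantoms in the scoring batch.
#' @param base_seed seed of the first phantom.
#' @param variant backbone variant for the grid.
#' @param size phantom side length.
#' @return list of [objective_point()]s (one per grid cell) with
#'   `params = list(tap_block, activity_mode, transconv_init)`.
#' @export
demo_candidates <- function(n_pairs = 3L, base_seed = 7L,
                            variant = "vgg11", size = 64L) {
  batch <- make_batch(n_pairs, base_seed, size = size)
  spec_all <- backbone_spec(variant, tap_blocks = 1:5)
  pre <- lapply(batch, function(p) {
    sources <- list(structural = p$structural,
                    functional = to_luminance(p$functional))
    feats <- lapply(sources, extract_features, spec = spec_all)
    list(sources = sources, feats = feats)
  })
  grid <- expand.grid(tap_block = 1:5,
                      activity_mode = c("mean", "sum"),
                      transconv_init = c("identity", "smoothing"),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(g) {
    row <- grid[g, ]
    cfg <- fusion_config(
      backbone = backbone_spec(variant, tap_blocks = row$tap_block),
      transconv = transconv_spec(init = row$transconv_init),
      activity_mode = row$activity_mode)
    qual <- vapply(pre, function(p) {
      fused <- fuse_with_features(p$sources, p$feats, cfg)
      mean(c(img_ssim(fused, p$sources$structural),
             img_ssim(fused, p$sources$functional)))
    }, numeric(1))
    objective_point(
      params = as.list(row),
      objectives = c(1 - mean(qual), backbone_param_count(cfg$backbone)),
      directions = "minimize")
  })
}
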