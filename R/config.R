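#' Run configuration
#'
#' A run configuration is a plain nested list (so it round-trips losslessly
#' through YAML or JSON) with four sections: `fusion` (everything
#' [fusion_config()] takes, in serialized form), `preprocessing`
#' (per-modality ordered op lists for [preprocess()]), `io` (input/output
#' paths) and `seed`. `resolve_config()` materializes every default so the
#' logged config alone reproduces a run.
#'
#' @param cfg nested list (possibly partial).
#' @return fully resolved nested list with class `run_config`.
#' @export
resolve_config <- function(cfg = list()) {
  f <- cfg$fusion %||% list()
  bb <- f$backbone %||% list()
  tc <- f$transconv %||% list()
  seed <- as.integer(cfg$seed %||% 42L)
  resolved <- list(
    seed = seed,
    fusion = list(
      backbone = list(
        variant = bb$variant %||% "vgg19",
        weights = bb$weights %||% "fixture",
        seed = as.integer(bb$seed %||% seed),
        tap_blocks = as.integer(unlist(bb$tap_blocks %||% 1L)),
        weights_file = bb$weights_file
      ),
      transconv = list(
        K = as.integer(tc$K %||% 3L),
        S = as.integer(tc$S %||% 1L),
        P = as.integer(tc$P %||% 1L),
        init = tc$init %||% "identity",
        seed = as.integer(tc$seed %||% seed)
      ),
      activity_mode = f$activity_mode %||% "mean",
      upsample_mode = f$upsample_mode %||% "bilinear",
      operator = f$operator %||% "apply"
    ),
    preprocessing = list(
      structural = cfg$preprocessing$structural %||% list(),
      functional = cfg$preprocessing$functional %||% list()
    ),
    io = cfg$io %||% list()
  )
  class(resolved) <- "run_config"
  resolved
}

#' Build the fusion_config object described by a run configuration
#'
#' @param cfg resolved run configuration from [resolve_config()].
#' @return [fusion_config()] object.
#' @export
as_fusion_config <- function(cfg) {
  f <- cfg$fusion
  fusion_config(
    backbone = backbone_spec(f$backbone$variant, f$backbone$weights,
                             f$backbone$seed, f$backbone$tap_blocks,
                             f$backbone$weights_file),
    transconv = transconv_spec(f$transconv$K, f$transconv$S, f$transconv$P,
                               f$transconv$init, f$transconv$seed),
    activity_mode = f$activity_mode,
    upsample_mode = f$upsample_mode,
    operator = f$operator
  )
}

#' Read / write run configurations (YAML or JSON by extension)
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return `load_run_config`: resolved `run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path))
    stop("cannot read config: no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path,
                                                     simplifyVector = TRUE)
         else stop("config must be .yaml/.yml or .json", call. = FALSE)
  resolve_config(raw)
}

#' @rdname load_run_config
#' @param cfg resolved run configuration.
#' @export
save_run_config <- function(cfg, path) {
  lst <- unclass(cfg)
  lst$fusion$backbone$weights_file <-
    lst$fusion$backbone$weights_file %||% NULL
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(lst, path)
  else jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                            null = "null")
  invisible(path)
}
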