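#' Mean squared error between two images
#'
#' @param a,b same-shaped image2d matrices.
#' @return mean of squared per-pixel differences.
#' @export
img_mse <- function(a, b) {
  a <- as_image2d(a); b <- as_image2d(b)
  if (!identical(dim(a), dim(b)))
    stop("images must share one shape", call. = FALSE)
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 log10(max_val^2 / MSE)`; identical images give `Inf` (serialized as
#' `"inf"` in reports).
#'
#' @param a,b same-shaped image2d matrices.
#' @param max_val peak signal value (1 for the \[0, 1\] working range).
#' @return PSNR in dB.
#' @export
img_psnr <- function(a, b, max_val = 1.0) {
  m <- img_mse(a, b)
  if (m == 0) return(Inf)
  10 * log10(max_val^2 / m)
}

gaussian_window <- function(side = 11L, sigma = 1.5) {
  half <- (side - 1) / 2
  g <- exp(-(seq(-half, half)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# valid-mode correlation with a square window (used by SSIM local moments)
filter_valid <- function(x, k) {
  side <- nrow(k)
  h <- nrow(x) - side + 1L
  w <- ncol(x) - side + 1L
  out <- matrix(0, h, w)
  for (i in seq_len(side)) for (j in seq_len(side))
    out <- out + k[i, j] * x[i:(i + h - 1L), j:(j + w - 1L)]
  out
}

#' Structural similarity index
#'
#' Mean local SSIM with the standard 11 x 11 Gaussian window (sigma 1.5)
#' and stabilizing constants `C1 = (K1 L)^2`, `C2 = (K2 L)^2`. Local
#' moments are computed in valid mode (no padding), as in the original
#' formulation, and averaged over the valid region.
#'
#' @param a,b same-shaped image2d matrices, each side >= 11.
#' @param K1,K2 stabilizing constants (defaults 0.01, 0.03).
#' @param L dynamic range (1 for \[0, 1\] images).
#' @return SSIM in \[-1, 1\]; 1 iff the images are identical.
#' @export
img_ssim <- function(a, b, K1 = 0.01, K2 = 0.03, L = 1.0) {
  a <- as_image2d(a); b <- as_image2d(b)
  if (!identical(dim(a), dim(b)))
    stop("images must share one shape", call. = FALSE)
  if (min(dim(a)) < 11L)
    stop("SSIM needs images at least 11 pixels per side", call. = FALSE)
  w <- gaussian_window(11L, 1.5)
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  mu_a <- filter_valid(a, w)
  mu_b <- filter_valid(b, w)
  sig_a <- filter_valid(a * a, w) - mu_a^2
  sig_b <- filter_valid(b * b, w) - mu_b^2
  sig_ab <- filter_valid(a * b, w) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * sig_ab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (sig_a + sig_b + C2)
  mean(num / den)
}

#' Shannon entropy of an image in bits
#'
#' Entropy `-sum p_i log2 p_i` of the histogram of intensities over
#' `bins` equal-width bins on \[0, 1\] (final bin right-inclusive, 256 bins
#' matching the 8-bit convention); empty bins contribute 0.
#'
#' @param img image2d matrix.
#' @param bins number of histogram bins, >= 2.
#' @return entropy in bits, in `[0, log2(bins)]`.
#' @export
img_entropy <- function(img, bins = 256L) {
  img <- as_image2d(img)
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L)
    stop("entropy needs at least 2 bins", call. = FALSE)
  idx <- pmin(floor(as.vector(img) * bins) + 1L, bins)
  p <- tabulate(idx, nbins = bins) / length(img)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Score a fused image against its sources
#'
#' The evaluation harness: one row per source with the SSIM, PSNR and MSE
#' of the fused image against that source, plus the entropy of the fused
#' image itself (identical in every row — it is a property of the fused
#' image alone). No ground-truth fused image exists, so fused-vs-source
#' scoring is the reference design.
#'
#' @param fused image2d matrix.
#' @param sources named list of image2d matrices (names become
#'   `reference_id`; unnamed lists get `source1`, `source2`, ...).
#' @return data.frame with columns `reference_id`, `ssim`, `psnr`, `mse`,
#'   `entropy`.
#' @export
evaluate_fusion <- function(fused, sources) {
  fused <- as_image2d(fused)
  if (!is.list(sources) || length(sources) == 0L)
    stop("evaluate_fusion needs at least one source", call. = FALSE)
  ids <- names(sources)
  if (is.null(ids) || any(ids == ""))
    ids <- paste0("source", seq_along(sources))
  ent <- img_entropy(fused)
  rows <- lapply(seq_along(sources), function(i) {
    s <- as_image2d(sources[[i]])
    data.frame(reference_id = ids[i],
               ssim = img_ssim(fused, s),
               psnr = img_psnr(fused, s),
               mse = img_mse(fused, s),
               entropy = ent,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize a quality report
#'
#' Long-format writer for [evaluate_fusion()] output: columns `metric`,
#' `reference_id`, `value`, written as CSV or JSON by extension. Infinite
#' PSNR (identical images) is serialized as the string `"inf"`.
#'
#' @param report data.frame from [evaluate_fusion()].
#' @param path output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  long <- do.call(rbind, lapply(c("ssim", "psnr", "mse", "entropy"),
    function(m) data.frame(metric = m,
                           reference_id = report$reference_id,
                           value = report[[m]],
                           stringsAsFactors = FALSE)))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    out <- long
    out$value <- ifelse(is.infinite(out$value), "inf",
                        trimws(format(out$value, digits = 12)))
    utils::write.csv(out, path, row.names = FALSE)
  } else if (ext == "json") {
    out <- long
    out$value <- ifelse(is.infinite(out$value), "inf",
                        as.character(out$value))
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE)
  } else {
    stop("report path must end in .csv or .json", call. = FALSE)
  }
  invisible(path)
}
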