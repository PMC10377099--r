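#' Working image representations
#'
#' `fusionet` represents a single-modality slice as a plain numeric matrix
#' (rows = image rows, origin top-left, y increasing downward) with values in
#' \[0, 1\] — an "image2d". Pseudo-colored functional slices are H x W x 3
#' arrays in RGB order with the same value range ("color image"). All
#' user-facing operations validate these contracts on entry.
#'
#' @param x numeric matrix (grayscale) or H x W x 3 array (color).
#' @param clip if `TRUE`, clamp values into \[0, 1\] instead of erroring on
#'   small numerical excursions.
#' @return the validated (and possibly clipped) image.
#' @export
as_image2d <- function(x, clip = FALSE) {
  if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 1L)
    x <- x[, , 1L]
  if (!is.matrix(x) || !is.numeric(x))
    stop("image2d must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(x)))
    stop("image2d contains non-finite values", call. = FALSE)
  if (clip) x <- clip01(x)
  if (any(x < 0 | x > 1))
    stop("image2d values must lie in [0, 1]", call. = FALSE)
  x
}

#' @rdname as_image2d
#' @export
as_color_image <- function(x, clip = FALSE) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L ||
      !is.numeric(x))
    stop("color image must be a numeric H x W x 3 array", call. = FALSE)
  if (any(!is.finite(x)))
    stop("color image contains non-finite values", call. = FALSE)
  if (clip) x <- clip01(x)
  if (any(x < 0 | x > 1))
    stop("color image values must lie in [0, 1]", call. = FALSE)
  x
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Convert a pseudo-colored image to luminance
#'
#' Collapses an RGB rendering (e.g. a hot-colormap functional slice) to a
#' grayscale image using ITU-R BT.601 luminance weights
#' 0.299 R + 0.587 G + 0.114 B, so that pseudo-color inputs can enter the
#' grayscale fusion path.
#'
#' @param img H x W x 3 numeric array in \[0, 1\], RGB order.
#' @return image2d matrix.
#' @export
to_luminance <- function(img) {
  img <- as_color_image(img)
  clip01(0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
}

# EBImage stores images as [x = column, y = row]; these two helpers convert
# between that layout and the package's row-major matrices.
to_ebi <- function(m) EBImage::Image(t(m))
from_ebi <- function(e) t(EBImage::imageData(e))

#' Read a 2D slice from an image file
#'
#' Reads PNG and TIFF images (8/16-bit, rescaled to \[0, 1\]) and single
#' slices from NIfTI volumes. Grayscale files give an image2d matrix; RGB(A)
#' files give an H x W x 3 color array (alpha dropped). NIfTI volumes are
#' sliced along `slice_axis` at `slice_index` and min-max rescaled to
#' \[0, 1\].
#'
#' @param path file path (.png, .tif/.tiff, .nii, .nii.gz).
#' @param slice_axis axis (1, 2 or 3) along which to slice a NIfTI volume.
#' @param slice_index 1-based slice index along `slice_axis`.
#' @return image2d matrix or H x W x 3 array.
#' @export
read_image <- function(path, slice_axis = 3L, slice_index = NULL) {
  if (!file.exists(path))
    stop("cannot read image: no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    if (length(dim(arr)) == 2L) {
      sl <- arr
    } else {
      if (is.null(slice_index))
        slice_index <- ceiling(dim(arr)[slice_axis] / 2)
      idx <- rep(list(quote(expr = )), length(dim(arr)))
      idx[[slice_axis]] <- slice_index
      sl <- do.call(`[`, c(list(arr), idx, list(drop = TRUE)))
      if (length(dim(sl)) != 2L) sl <- sl[, , 1L]
    }
    rng <- range(sl)
    if (diff(rng) > 0) sl <- (sl - rng[1]) / diff(rng) else sl <- sl * 0
    return(as_image2d(as.matrix(sl)))
  }
  e <- EBImage::readImage(path)
  d <- dim(e)
  if (length(d) == 2L) return(as_image2d(from_ebi(e), clip = TRUE))
  nch <- d[3]
  if (nch >= 3L) {
    out <- array(0, c(d[2], d[1], 3L))
    for (c in 1:3) out[, , c] <- t(EBImage::imageData(e)[, , c])
    return(as_color_image(out, clip = TRUE))
  }
  as_image2d(t(EBImage::imageData(e)[, , 1L]), clip = TRUE)
}

#' Write an image to a 16-bit PNG
#'
#' All intermediate and fused images are written at 16-bit depth so the
#' \[0, 1\] working precision survives a round-trip (quantization error at
#' most 1/65535). TIFF output goes through the tiff writer at the same
#' depth; PNG output uses the package's own minimal encoder (filter-0
#' scanlines, zlib stream) because the installed PNG writers are 8-bit
#' only.
#'
#' @param img image2d matrix or H x W x 3 color array in \[0, 1\].
#' @param path output path (.png; .tif/.tiff also accepted).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  type <- tolower(tools::file_ext(path))
  if (!type %in% c("png", "tif", "tiff"))
    stop("write_image supports png/tiff output, got: ", path, call. = FALSE)
  color <- length(dim(img)) == 3L
  img <- if (color) as_color_image(img, clip = TRUE)
         else as_image2d(img, clip = TRUE)
  if (type == "png") return(write_png16(img, path))
  e <- if (color) EBImage::Image(aperm(img, c(2, 1, 3)),
                                 colormode = "Color")
       else to_ebi(img)
  EBImage::writeImage(e, path, type = "tiff", bits.per.sample = 16L)
  invisible(path)
}

# --- minimal 16-bit PNG encoder (grayscale / RGB, filter 0) ----------------

crc32_table <- local({
  poly <- -306674912L   # 0xEDB88320 as a signed 32-bit integer
  vapply(0:255, function(n) {
    crc <- as.integer(n)
    for (k in 1:8)
      crc <- if (bitwAnd(crc, 1L) != 0L)
        bitwXor(poly, bitwShiftR(crc, 1L)) else bitwShiftR(crc, 1L)
    crc
  }, integer(1))
})

png_crc32 <- function(bytes) {
  crc <- -1L
  idx <- as.integer(bytes)
  for (b in idx)
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   crc32_table[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  bitwXor(crc, -1L)
}

int_be <- function(x) {
  x <- as.integer(x)
  as.raw(c(bitwAnd(bitwShiftR(x, 24L), 255L),
           bitwAnd(bitwShiftR(x, 16L), 255L),
           bitwAnd(bitwShiftR(x, 8L), 255L),
           bitwAnd(x, 255L)))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(int_be(length(data)), body, int_be(png_crc32(body)))
}

write_png16 <- function(img, path) {
  color <- length(dim(img)) == 3L
  h <- dim(img)[1]; w <- dim(img)[2]
  # samples in scanline order: pixels left-to-right per row, channels
  # interleaved per pixel for RGB
  v <- if (color) as.vector(aperm(img, c(3L, 2L, 1L)))
       else as.vector(t(img))
  v <- as.integer(round(v * 65535))
  bytes <- matrix(as.raw(rbind(v %/% 256L, v %% 256L)),
                  nrow = 2L * w * (if (color) 3L else 1L))
  scan <- as.vector(rbind(matrix(as.raw(0L), 1L, h), bytes))
  ihdr <- c(int_be(w), int_be(h), as.raw(c(16L, if (color) 2L else 0L,
                                           0L, 0L, 0L)))
  out <- c(as.raw(c(137L, 80L, 78L, 71L, 13L, 10L, 26L, 10L)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(scan, "gzip")),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
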