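#' Flat structuring element for grayscale morphology
#'
#' Square flat structuring element of side `2 * radius + 1` used by
#' [img_dilate()] and [img_erode()]. The default 3 x 3 box is the usual
#' "predefined neighborhood" for light cleanup of modality slices before
#' fusion.
#'
#' @param radius integer >= 1; half-width of the square mask.
#' @param mask optional odd-sided square logical matrix overriding the box;
#'   its center element must be `TRUE`.
#' @return object of class `structuring_element`.
#' @export
structuring_element <- function(radius = 1L, mask = NULL) {
  if (is.null(mask)) {
    radius <- as.integer(radius)
    if (is.na(radius) || radius < 1L)
      stop("structuring element radius must be >= 1", call. = FALSE)
    side <- 2L * radius + 1L
    mask <- matrix(TRUE, side, side)
  } else {
    if (!is.matrix(mask) || nrow(mask) != ncol(mask) ||
        nrow(mask) %% 2L == 0L)
      stop("mask must be an odd-sided square matrix", call. = FALSE)
    mask <- mask != 0
    radius <- (nrow(mask) - 1L) %/% 2L
    if (!mask[radius + 1L, radius + 1L])
      stop("structuring element center must be TRUE", call. = FALSE)
  }
  if (!any(mask))
    stop("structuring element is empty", call. = FALSE)
  structure(list(mask = mask, radius = radius),
            class = "structuring_element")
}

as_se <- function(se) {
  if (!inherits(se, "structuring_element"))
    stop("expected a structuring_element", call. = FALSE)
  se
}

#' Grayscale morphological dilation and erosion
#'
#' Standard grayscale morphology over a flat structuring element: dilation
#' replaces each pixel with the neighborhood maximum, erosion with the
#' neighborhood minimum. Neighbors outside the frame are ignored, so
#' morphology never invents values at the border. Typical use is mild
#' cleanup of the structural slice (dilation) and of the functional slice
#' (erosion) prior to fusion.
#'
#' @param img image2d matrix.
#' @param se [structuring_element()].
#' @return image2d matrix, same shape.
#' @export
img_dilate <- function(img, se = structuring_element()) {
  img <- as_image2d(img)
  se <- as_se(se)
  from_ebi(EBImage::dilate(to_ebi(img), t(se$mask * 1)))
}

#' @rdname img_dilate
#' @export
img_erode <- function(img, se = structuring_element()) {
  img <- as_image2d(img)
  se <- as_se(se)
  from_ebi(EBImage::erode(to_ebi(img), t(se$mask * 1)))
}

#' Translate an image by whole pixels
#'
#' Shifts content `dx` pixels rightward and `dy` pixels downward; vacated
#' regions are zero-filled. Used to undo the horizontal misregistration of
#' the structural slice.
#'
#' @param img image2d matrix.
#' @param dx,dy integer pixel offsets (positive = right / down).
#' @return image2d matrix, same shape.
#' @export
img_shift <- function(img, dx = 0L, dy = 0L) {
  img <- as_image2d(img)
  dx <- as.integer(dx); dy <- as.integer(dy)
  if (is.na(dx) || is.na(dy) || abs(dx) >= ncol(img) || abs(dy) >= nrow(img))
    stop("shift magnitude must be smaller than the image size",
         call. = FALSE)
  if (dx == 0L && dy == 0L) return(img)
  from_ebi(EBImage::translate(to_ebi(img), c(dx, dy), bg.col = 0))
}

#' Rotate an image about its center
#'
#' Bilinear rotation by `angle_deg` degrees, counter-clockwise positive (in
#' screen terms, with y increasing downward), same output shape,
#' out-of-frame fill 0. Used to undo the rotational misregistration of the
#' functional slice.
#'
#' @param img image2d matrix.
#' @param angle_deg rotation angle in degrees.
#' @return image2d matrix, same shape.
#' @export
img_rotate <- function(img, angle_deg) {
  img <- as_image2d(img)
  if (!is.finite(angle_deg))
    stop("rotation angle must be finite", call. = FALSE)
  if (angle_deg %% 360 == 0) return(img)
  # EBImage rotates clockwise in this package's row/col convention
  out <- EBImage::rotate(to_ebi(img), -angle_deg,
                         output.dim = c(ncol(img), nrow(img)), bg.col = 0)
  clip01(from_ebi(out))
}

#' Kernel sharpening
#'
#' 2D correlation of the image with a 3 x 3 kernel, reflect-padded at the
#' borders so edge pixels see mirrored content rather than invented zeros,
#' clipped to \[0, 1\]. The default kernel is the standard Laplacian
#' sharpener (sums to 1, so flat regions are untouched and edges gain
#' contrast).
#'
#' @param img image2d matrix.
#' @param kernel 3 x 3 numeric matrix.
#' @return image2d matrix, same shape.
#' @export
img_sharpen <- function(img,
                        kernel = matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0),
                                        3, 3)) {
  img <- as_image2d(img)
  if (!is.matrix(kernel) || any(dim(kernel) != c(3L, 3L)) ||
      !is.numeric(kernel))
    stop("sharpening kernel must be a 3 x 3 numeric matrix", call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  pad <- rbind(img[1, , drop = FALSE], img, img[h, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, w, drop = FALSE])
  out <- matrix(0, h, w)
  for (i in 1:3) for (j in 1:3)
    out <- out + kernel[i, j] * pad[i:(i + h - 1), j:(j + w - 1)]
  clip01(out)
}

#' Apply a preprocessing recipe to one modality
#'
#' Runs an ordered list of preprocessing steps. Each step is a list with an
#' `op` field (`"dilate"`, `"erode"`, `"shift"`, `"rotate"`, `"sharpen"`)
#' and that op's parameters (`radius`, `dx`/`dy`, `angle_deg`, `kernel`).
#' The conventional order — morphology, then geometry, then sharpening —
#' is whatever order the recipe lists.
#'
#' @param img image2d matrix.
#' @param steps list of step descriptions (possibly empty).
#' @return preprocessed image2d matrix.
#' @export
preprocess <- function(img, steps = list()) {
  img <- as_image2d(img)
  for (s in steps) {
    op <- s$op
    img <- switch(
      op,
      dilate = img_dilate(img, structuring_element(s$radius %||% 1L)),
      erode = img_erode(img, structuring_element(s$radius %||% 1L)),
      shift = img_shift(img, s$dx %||% 0L, s$dy %||% 0L),
      rotate = img_rotate(img, s$angle_deg %||% 0),
      sharpen = if (is.null(s$kernel)) img_sharpen(img)
                else img_sharpen(img, matrix(unlist(s$kernel), 3, 3,
                                             byrow = TRUE)),
      stop("unknown preprocessing op: ", op, call. = FALSE))
  }
  img
}

`%||%` <- function(a, b) if (is.null(a)) b else a
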