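#' Calibrated intensity image or z-stack
#'
#' Wraps raw intensity data together with its physical calibration. 2-D data
#' is stored as a (row, col) matrix; a z-stack as a (z, row, col) array with
#' page order equal to z order.
#'
#' @param data Numeric matrix (2-D image) or 3-D array `(z, row, col)`.
#' @param pixel_size_nm Lateral pixel size in nanometres.
#' @param z_spacing_nm Spacing between z planes in nanometres (stacks only).
#'
#' @return An object of class `image_stack` with elements `data`,
#'   `pixel_size_nm`, `z_spacing_nm` and `is3d`.
#' @export
#' @examples
#' img <- image_stack(matrix(runif(100), 10), pixel_size_nm = 95)
#' dim(img$data)
image_stack <- function(data, pixel_size_nm = 95, z_spacing_nm = NULL) {
  is3d <- length(dim(data)) == 3L
  if (!is3d && !is.matrix(data)) {
    stop("`data` must be a matrix or a (z, row, col) array", call. = FALSE)
  }
  storage.mode(data) <- "double"
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  if (is3d && dim(data)[1] < 2) {
    stop("a z-stack needs at least 2 planes", call. = FALSE)
  }
  stopifnot(pixel_size_nm > 0)
  if (is3d && is.null(z_spacing_nm)) {
    stop("`z_spacing_nm` is required for a z-stack", call. = FALSE)
  }
  if (!is.null(z_spacing_nm)) stopifnot(z_spacing_nm > 0)
  structure(list(data = data, pixel_size_nm = pixel_size_nm,
                 z_spacing_nm = z_spacing_nm, is3d = is3d),
            class = "image_stack")
}

#' Maximum-intensity projection of a stack
#'
#' Returns the 2-D frame on which network extraction operates: the stack's
#' per-pixel maximum over z, or the image itself when already 2-D.
#'
#' @param img An [image_stack()] (or plain matrix, returned unchanged).
#' @return A numeric matrix.
#' @export
project_max <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(inherits(img, "image_stack"))
  if (!img$is3d) return(img$data)
  apply(img$data, c(2, 3), max)
}

#' Region-of-interest mask
#'
#' @param mask Logical (or 0/1 numeric) matrix marking the analysed region,
#'   e.g. a manually drawn cell outline.
#' @param provenance Free-text note on where the mask came from.
#'
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, provenance = "supplied") {
  mask <- as_logical_matrix(mask, "mask")
  if (!any(mask)) stop("ROI mask has no foreground pixels", call. = FALSE)
  ncomp <- max(cpp_label8(mask))
  if (ncomp > 1) {
    warning(sprintf("ROI mask has %d connected regions; expected one", ncomp),
            call. = FALSE)
  }
  structure(list(mask = mask, provenance = provenance), class = "roi_mask")
}

#' Full-frame ROI covering an image
#'
#' @param img An [image_stack()] or matrix giving the frame size.
#' @return An [roi_mask()] that is true everywhere.
#' @export
full_roi <- function(img) {
  d <- if (inherits(img, "image_stack")) {
    if (img$is3d) dim(img$data)[2:3] else dim(img$data)
  } else {
    dim(img)
  }
  roi_mask(matrix(TRUE, d[1], d[2]), provenance = "full frame")
}

#' Rotate an image or mask
#'
#' Rotates by `angle` radians counter-clockwise (y axis up), enlarging the
#' canvas so nothing is clipped. Intensity images should use bilinear
#' interpolation; binary images nearest-neighbour.
#'
#' @param img Numeric or logical matrix.
#' @param angle Rotation angle in radians.
#' @param interp `"bilinear"` or `"nearest"`.
#' @param fill Value used outside the source frame.
#' @return A matrix (logical if the input was logical).
#' @export
rotate_image <- function(img, angle, interp = c("bilinear", "nearest"),
                         fill = 0) {
  interp <- match.arg(interp)
  was_logical <- is.logical(img)
  m <- img
  storage.mode(m) <- "double"
  out <- cpp_rotate(m, angle, interp == "bilinear", fill)
  if (was_logical) out > 0.5 else out
}
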