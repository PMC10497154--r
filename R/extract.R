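#' Top-hat background subtraction
#'
#' Subtracts the grayscale morphological opening of the image (erosion then
#' dilation with a ball- or disc-shaped structuring element) from the image
#' itself. This removes smooth background and uneven illumination while
#' preserving features narrower than the structuring element, analogous to a
#' rolling-ball background filter.
#'
#' @param image Numeric matrix (or [image_stack()], projected first).
#' @param radius_px Structuring-element radius in pixels; must be well above
#'   the width of the widest filament to preserve (2-3 times is typical).
#' @param shape `"ball"` (non-flat) or `"disc"` (flat).
#' @param height Ball height in intensity units. The default (`NULL`) is
#'   one tenth of the image's intensity range: a gently curved, nearly
#'   flat ball, which is how a sphere whose height is small relative to
#'   the data's dynamic range behaves. Pass an explicit height to control
#'   the curvature directly.
#' @return Numeric matrix of the same size, non-negative everywhere.
#' @export
#' @examples
#' img <- matrix(1, 40, 40); img[20, 10:30] <- 2
#' th <- tophat_subtract(img, 5)
#' range(th)
tophat_subtract <- function(image, radius_px = 15,
                            shape = c("ball", "disc"), height = NULL) {
  shape <- match.arg(shape)
  image <- as_numeric_matrix(image, "image")
  stopifnot(radius_px >= 1)
  if (min(dim(image)) < 2 * radius_px) {
    stop("image is smaller than the structuring element (need >= 2x radius per side)",
         call. = FALSE)
  }
  if (shape == "ball" && is.null(height)) {
    height <- 0.1 * diff(range(image))
  }
  se <- disc_offsets(radius_px, height = if (shape == "ball") height)
  opened <- cpp_gray_dilate(cpp_gray_erode(image, se$di, se$dj, se$h),
                            se$di, se$dj, se$h)
  pmax(image - opened, 0)
}

# scale-normalised Gaussian-derivative Hessian at one scale (sigma in px)
gauss_hessian <- function(image, sigma) {
  g0 <- gauss_kernel(sigma, 0L)
  g1 <- gauss_kernel(sigma, 1L)
  g2 <- gauss_kernel(sigma, 2L)
  s2 <- sigma^2
  list(
    xx = s2 * cpp_conv_sep(image, g0, g2),  # d2/dx2, x = column
    yy = s2 * cpp_conv_sep(image, g2, g0),
    xy = s2 * cpp_conv_sep(image, g1, g1)
  )
}

#' Tubular (vesselness) enhancement
#'
#' Multi-scale Hessian ridge filter for bright curvilinear structures on a
#' dark background (Frangi formulation). At each scale the Hessian is
#' computed with Gaussian derivatives, its eigenvalues ordered by magnitude,
#' and pixels with one small and one large negative eigenvalue (a ridge
#' profile) are boosted; blobs and flat background are suppressed. The
#' response is the maximum over scales.
#'
#' @param image Numeric matrix, typically the top-hat filtered frame.
#' @param scales_px Target structure thicknesses in pixels. The analysis
#'   sigma at each scale is `scale / 4`, so that profiles whose width is
#'   near the stated thickness respond most strongly.
#' @param beta Ridge-vs-blob sensitivity (default 0.5).
#' @param c Structural sensitivity; `NULL` sets it per scale to half the
#'   maximal Hessian norm.
#' @return Non-negative numeric matrix of vesselness responses.
#' @export
enhance_tubular <- function(image, scales_px = seq(4, 14, by = 2),
                            beta = 0.5, c = NULL) {
  image <- as_numeric_matrix(image, "image")
  stopifnot(length(scales_px) >= 1, all(scales_px > 0))
  best <- matrix(0, nrow(image), ncol(image))
  for (sc in scales_px) {
    H <- gauss_hessian(image, sc / 4)
    tr2 <- (H$xx + H$yy) / 2
    disc <- sqrt(((H$xx - H$yy) / 2)^2 + H$xy^2)
    e1 <- tr2 + disc
    e2 <- tr2 - disc
    # order by |eigenvalue|: l2 is the large-magnitude one
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1)
    l2 <- ifelse(swap, e1, e2)
    S2 <- l1^2 + l2^2
    cc <- c %||% (0.5 * sqrt(max(S2)))
    if (cc <= 0) next
    Rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    v <- exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * cc^2)))
    v[l2 >= 0] <- 0  # bright ridges have a strongly negative l2
    best <- pmax(best, v)
  }
  best
}

#' Percentile threshold within a region of interest
#'
#' Binarises an image at the given percentile of the intensity distribution
#' of the in-ROI pixels; pixels strictly above the threshold (and inside the
#' ROI) become foreground. Restricting the distribution to the ROI makes the
#' percentile transferable across crop sizes.
#'
#' @param image Numeric matrix.
#' @param mask [roi_mask()] or logical matrix of the same size.
#' @param percentile Percentile in `[0, 100)`.
#' @return Logical matrix; always false outside the ROI.
#' @export
percentile_threshold <- function(image, mask, percentile = 90) {
  image <- as_numeric_matrix(image, "image")
  mask <- as_logical_matrix(mask, "mask")
  stopifnot(all(dim(image) == dim(mask)), percentile >= 0, percentile < 100)
  vals <- image[mask]
  if (length(vals) == 0) stop("ROI mask is empty", call. = FALSE)
  if (max(vals) == min(vals)) {
    warning("degenerate (constant) intensity distribution inside the ROI; nothing thresholded",
            call. = FALSE)
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  thr <- as.numeric(quantile(vals, percentile / 100, names = FALSE))
  image > thr & mask
}

#' Remove small connected components
#'
#' Deletes 8-connected foreground components with fewer than `min_px`
#' pixels; components of exactly `min_px` pixels are kept.
#'
#' @param binary Logical matrix.
#' @param min_px Minimum component size in pixels.
#' @return Logical matrix.
#' @export
remove_small_components <- function(binary, min_px = 20) {
  binary <- as_logical_matrix(binary, "binary")
  if (min_px <= 1 || !any(binary)) return(binary)
  lab <- cpp_label8(binary)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(binary), ncol(binary))
}

#' Topology-preserving skeletonisation
#'
#' Iteratively deletes simple boundary pixels (pixels whose removal changes
#' neither the number of 8-connected components nor the number of holes,
#' i.e. preserves the Euler number) until only a single-pixel-thick backbone
#' remains. Line endpoints are preserved. Idempotent.
#'
#' @param binary Logical matrix.
#' @return Logical matrix: the single-pixel-thick skeleton, a subset of the
#'   input foreground.
#' @export
#' @examples
#' bar <- matrix(FALSE, 10, 40); bar[4:6, 5:35] <- TRUE
#' sum(skeletonise(bar) & !bar)  # subset of input: 0
skeletonise <- function(binary) {
  cpp_thin(as_logical_matrix(binary, "binary"))
}

#' Orientation of the ROI's major axis
#'
#' Fits the mask's second central moments (equivalently, an ellipse) and
#' returns the angle of the major axis relative to the horizontal image
#' axis, counter-clockwise with y up, in `(-pi/2, pi/2]`. An isotropic mask
#' (equal principal moments) is degenerate: the angle is reported as 0 with
#' a warning.
#'
#' @param mask [roi_mask()] or logical matrix.
#' @param warn Emit the degeneracy warning (default `TRUE`).
#' @return Angle in radians.
#' @export
roi_orientation <- function(mask, warn = TRUE) {
  mask <- as_logical_matrix(mask, "mask")
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("ROI mask is empty", call. = FALSE)
  x <- idx[, 2] - mean(idx[, 2])
  y <- -(idx[, 1] - mean(idx[, 1]))  # y up
  mu20 <- mean(x^2)
  mu02 <- mean(y^2)
  mu11 <- mean(x * y)
  scale <- mu20 + mu02
  if (scale == 0 ||
      (abs(mu20 - mu02) < 1e-9 * scale && abs(mu11) < 1e-9 * scale)) {
    if (warn) {
      warning("ROI is isotropic (no preferred axis); orientation set to 0",
              call. = FALSE)
    }
    return(0)
  }
  ang <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  ang
}

#' Extract the filament-network skeleton from an image
#'
#' Runs the full extraction pipeline: top-hat background subtraction,
#' tubular enhancement, in-ROI percentile thresholding, small-object
#' removal and topology-preserving skeletonisation, with the frame rotated
#' so the ROI's major axis is horizontal. Because rotating a binary skeleton
#' fragments it while rotating the intensity image loses edge sharpness, the
#' rotation is applied both before and after skeletonisation along two
#' parallel paths whose results are combined by pixel-wise OR and re-thinned.
#'
#' For a z-stack the pipeline operates on the maximum-intensity projection;
#' the stack itself is only used later for z-position estimates.
#'
#' @param image [image_stack()] or numeric matrix.
#' @param mask [roi_mask()] or logical matrix; `NULL` uses the full frame.
#' @param params [extraction_params()].
#' @param warn_degenerate Warn when the ROI has no preferred axis.
#' @return An object of class `skeleton` with elements `grid` (logical
#'   matrix, single-pixel thick, in the rotated frame), `angle` (radians the
#'   content was rotated by), `mask` (ROI in the rotated frame), `binary`
#'   (the cleaned pre-skeleton binary in the rotated frame, used for width
#'   measurement), `pixel_size_nm` and `params`.
#' @export
#' @examples
#' sc <- simulate_scene(scene_params(n_filaments = 3, noise_max = 0), seed = 1)
#' sk <- extract_skeleton(sc$image, params = extraction_params(rotate = FALSE))
#' sum(sk$grid) > 0
extract_skeleton <- function(image, mask = NULL,
                             params = extraction_params(),
                             warn_degenerate = TRUE) {
  if (is.matrix(image)) image <- image_stack(image, pixel_size_nm = 95)
  stopifnot(inherits(image, "image_stack"),
            inherits(params, "extraction_params"))
  img2d <- project_max(image)
  if (is.null(mask)) mask <- full_roi(img2d)
  if (!inherits(mask, "roi_mask")) mask <- roi_mask(mask)
  m <- mask$mask
  stopifnot(all(dim(img2d) == dim(m)))

  th <- tophat_subtract(img2d, params$tophat_radius_px,
                        shape = params$tophat_shape,
                        height = params$ball_height)
  angle <- if (params$rotate) {
    roi_orientation(m, warn = warn_degenerate)
  } else 0

  run_single <- function(filtered, roi) {
    v <- enhance_tubular(filtered, params$vesselness_scales_px,
                         beta = params$frangi_beta, c = params$frangi_c)
    b <- percentile_threshold(v, roi, params$threshold_percentile)
    b <- remove_small_components(b, params$min_object_px)
    list(binary = b, skeleton = cpp_thin(b))
  }

  if (abs(angle) < 1e-9) {
    res <- run_single(th, m)
    grid <- res$skeleton
    binary <- res$binary
    out_mask <- m
  } else {
    # path A: extract in the native frame, rotate the skeleton
    resA <- run_single(th, m)
    skA <- rotate_image(resA$skeleton, -angle, interp = "nearest")
    # path B: rotate the filtered intensity image, then extract
    thB <- rotate_image(th, -angle, interp = "bilinear")
    out_mask <- rotate_image(m, -angle, interp = "nearest")
    resB <- run_single(thB, out_mask)
    grid <- cpp_thin((skA | resB$skeleton) & out_mask)
    binary <- (resB$binary |
                 rotate_image(resA$binary, -angle, interp = "nearest")) &
      out_mask
  }
  if (!any(grid)) {
    warning("extraction produced an empty skeleton", call. = FALSE)
  }
  structure(list(grid = grid, angle = angle, mask = out_mask, binary = binary,
                 pixel_size_nm = image$pixel_size_nm,
                 z_spacing_nm = image$z_spacing_nm, params = params),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("skeleton: %d px on a %d x %d grid (rotated by %.3f rad)\n",
              sum(x$grid), nrow(x$grid), ncol(x$grid), x$angle))
  invisible(x)
}
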