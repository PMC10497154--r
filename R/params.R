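#' Parameters controlling network extraction
#'
#' Bundles every tunable of the skeleton-extraction pipeline. The defaults
#' are the values found to work well for spinning-disc confocal images of
#' GFP-Lifeact labelled actin at 95 nm/pixel and are a sensible starting
#' point for comparable assays.
#'
#' @param tophat_radius_px Radius (pixels) of the structuring element used by
#'   the top-hat background filter. Should be 2-3 times the width of the
#'   thickest filament of interest.
#' @param threshold_percentile Percentile (0-100, exclusive) of the in-ROI
#'   intensity distribution of the tubularity-enhanced image used as the
#'   binarisation threshold; pixels strictly above it are kept. The most
#'   sensitive parameter of the pipeline; 87-92 is the useful range.
#' @param min_object_px Connected components (8-connectivity) smaller than
#'   this are discarded before skeletonisation. Components of exactly this
#'   size are kept.
#' @param vesselness_scales_px Target filament thicknesses in pixels for the
#'   multi-scale tubular enhancement; the response is maximised over scales.
#' @param rotate Logical; rotate the frame so the ROI's major axis is
#'   horizontal, running the dual (rotate-before / rotate-after) workflow.
#' @param tophat_shape `"ball"` (non-flat spherical structuring element,
#'   the default) or `"disc"` (flat).
#' @param ball_height Height of the ball structuring element in intensity
#'   units; `NULL` (default) adapts it to one tenth of the image's
#'   intensity range, a nearly flat ball. Ignored for
#'   `tophat_shape = "disc"`.
#' @param frangi_beta Blob-vs-ridge sensitivity of the tubular enhancement.
#' @param frangi_c Structural (second-order) sensitivity; `NULL` (default)
#'   sets it per scale to half the maximal Hessian norm of the image.
#'
#' @return An object of class `extraction_params`.
#' @export
#' @examples
#' p <- extraction_params(threshold_percentile = 92)
#' p$threshold_percentile
extraction_params <- function(tophat_radius_px = 15,
                              threshold_percentile = 90,
                              min_object_px = 20,
                              vesselness_scales_px = seq(4, 14, by = 2),
                              rotate = TRUE,
                              tophat_shape = c("ball", "disc"),
                              ball_height = NULL,
                              frangi_beta = 0.5,
                              frangi_c = NULL) {
  tophat_shape <- match.arg(tophat_shape)
  stopifnot(
    tophat_radius_px >= 1,
    threshold_percentile > 0, threshold_percentile < 100,
    min_object_px >= 0,
    length(vesselness_scales_px) >= 1,
    all(vesselness_scales_px > 0),
    all(diff(vesselness_scales_px) > 0) || length(vesselness_scales_px) == 1,
    frangi_beta > 0
  )
  structure(list(
    tophat_radius_px = tophat_radius_px,
    threshold_percentile = threshold_percentile,
    min_object_px = min_object_px,
    vesselness_scales_px = vesselness_scales_px,
    rotate = isTRUE(rotate),
    tophat_shape = tophat_shape,
    ball_height = ball_height,
    frangi_beta = frangi_beta,
    frangi_c = frangi_c
  ), class = "extraction_params")
}

#' Parameters for curvature measurement
#'
#' @param lambda_nm Physical sampling length over which Menger curvature is
#'   evaluated (flanking points are picked this far along the path). 475 nm
#'   corresponds to five pixels at 95 nm/pixel: large enough to suppress
#'   pixel-level noise, small enough to remain a local estimate.
#' @param pixel_size_nm Lateral pixel size in nanometres.
#'
#' @return An object of class `curvature_params`.
#' @export
curvature_params <- function(lambda_nm = 475, pixel_size_nm = 95) {
  stopifnot(pixel_size_nm > 0, lambda_nm >= 2 * pixel_size_nm)
  structure(list(lambda_nm = lambda_nm, pixel_size_nm = pixel_size_nm),
            class = "curvature_params")
}

#' @export
print.extraction_params <- function(x, ...) {
  cat("Extraction parameters:\n")
  cat(sprintf("  top-hat: %s, radius %g px (height %s)\n", x$tophat_shape,
              x$tophat_radius_px, x$ball_height %||% "auto"))
  cat(sprintf("  tubular scales: %s px; beta %g\n",
              paste(x$vesselness_scales_px, collapse = ", "), x$frangi_beta))
  cat(sprintf("  threshold: %gth percentile (in-ROI)\n",
              x$threshold_percentile))
  cat(sprintf("  min object: %d px; rotation %s\n", x$min_object_px,
              if (x$rotate) "on" else "off"))
  invisible(x)
}
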