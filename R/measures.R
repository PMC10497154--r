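# Quantitative network measures computed from a labelled network, the
# pre-skeleton binary, the ROI mask and (optionally) the z-stack.

#' @rdname compute_measures
#' @export
measure_codes <- function() {
  c("cellSize", "orientation", "skelDensity", "Structures", "branchRatio",
    "cellBPDensity", "filWidth", "filLenXY", "filLenXYZ",
    "filamentAng.angXY", "filamentAng.angZ", "avgLen", "curvatureSigned",
    "curvature", "deviation", "branchAng.angXY", "branchAng.angZ")
}

#' ROI size in pixels
#' @param mask [roi_mask()] or logical matrix.
#' @return Number of true pixels.
#' @export
roi_size <- function(mask) sum(as_logical_matrix(mask, "mask"))

#' Skeleton density
#'
#' Number of skeleton pixels divided by the ROI size. With `depth_nm` the
#' per-volume variant (skeleton pixels per ROI pixel per nm of imaged
#' depth) is returned instead.
#'
#' @param skeleton `skeleton` object or logical matrix.
#' @param mask [roi_mask()] or logical matrix.
#' @param depth_nm Optional imaged depth for the per-volume variant.
#' @return A ratio in `[0, 1]` (per-area), or per-(pixel nm) if `depth_nm`
#'   is given.
#' @export
skeleton_density <- function(skeleton, mask, depth_nm = NULL) {
  d <- sum(as_logical_matrix(skeleton, "skeleton")) / roi_size(mask)
  if (!is.null(depth_nm)) d <- d / depth_nm
  d
}

#' Sizes of disconnected structures
#'
#' Pixel counts of the 8-connected components of the skeleton.
#'
#' @param skeleton `skeleton` object or logical matrix.
#' @return Integer vector of component sizes (empty for an empty skeleton).
#' @export
structure_sizes <- function(skeleton) {
  g <- as_logical_matrix(skeleton, "skeleton")
  if (!any(g)) return(integer(0))
  lab <- cpp_label8(g)
  tabulate(lab[lab > 0])
}

#' Branch ratio
#'
#' Number of branch points divided by the number of labelled filaments.
#'
#' @param network A `labelled_network`.
#' @return A non-negative ratio (0 when there are no filaments).
#' @export
branch_ratio <- function(network) {
  stopifnot(inherits(network, "labelled_network"))
  if (network$n_filaments == 0) return(0)
  nrow(network$branch_points) / network$n_filaments
}

#' Branch-point density
#'
#' Number of branch points divided by the ROI size (per area). An
#' alternative normalisation by the total length of filaments that contain
#' at least one branch point is available via `per = "branched_length"`;
#' the per-volume variant divides the per-area value by `depth_nm`.
#'
#' @param network A `labelled_network`.
#' @param mask [roi_mask()] or logical matrix.
#' @param per `"area"` (default) or `"branched_length"`.
#' @param depth_nm Optional imaged depth for the per-volume variant.
#' @param pixel_size_nm Pixel size, used by the length-based variant.
#' @return A non-negative ratio.
#' @export
branch_point_density <- function(network, mask, per = c("area", "branched_length"),
                                 depth_nm = NULL, pixel_size_nm = 95) {
  stopifnot(inherits(network, "labelled_network"))
  per <- match.arg(per)
  nbp <- nrow(network$branch_points)
  if (per == "area") {
    d <- nbp / roi_size(mask)
    if (!is.null(depth_nm)) d <- d / depth_nm
    return(d)
  }
  if (nbp == 0) return(0)
  branched <- unique(unlist(lapply(network$junctions, `[[`, "labels")))
  len <- sum(vapply(branched, function(id) {
    filament_length_2d(network$filaments[[id]], pixel_size_nm)
  }, 0))
  if (len == 0) 0 else nbp / len
}

#' 2-D filament length
#'
#' Length along the traced path: each pixel counts 1 and each diagonal step
#' adds a further `sqrt(2) - 1`, so a diagonal step costs `sqrt(2)` in
#' total; the result is scaled to nanometres.
#'
#' @param path Ordered two-column (row, col) pixel matrix.
#' @param pixel_size_nm Pixel size in nm.
#' @return Length in nm.
#' @export
#' @examples
#' filament_length_2d(cbind(5, 1:10), 95)  # 10 px, no diagonals: 950 nm
filament_length_2d <- function(path, pixel_size_nm = 95) {
  n <- nrow(path)
  if (n == 0) return(0)
  diag_steps <- if (n > 1) {
    sum(abs(diff(path[, 1])) == 1 & abs(diff(path[, 2])) == 1)
  } else 0
  (n + (sqrt(2) - 1) * diag_steps) * pixel_size_nm
}

#' Estimate z positions along a path from a stack
#'
#' For each path pixel, the z position is that of the brightest plane at
#' that (row, col), times the z spacing; ties take the lowest plane. The
#' first plane is at z = 0.
#'
#' @param path Ordered (row, col) pixel matrix.
#' @param stack An [image_stack()]; a 2-D image yields all-zero z with the
#'   `"flat"` attribute set.
#' @return Numeric vector of z positions in nm.
#' @export
estimate_z <- function(path, stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (!stack$is3d) {
    z <- rep(0, nrow(path))
    attr(z, "flat") <- TRUE
    return(z)
  }
  zs <- stack$z_spacing_nm
  z <- vapply(seq_len(nrow(path)), function(i) {
    (which.max(stack$data[, path[i, 1], path[i, 2]]) - 1) * zs
  }, 0)
  attr(z, "flat") <- FALSE
  z
}

#' 2-D filament angle
#'
#' Angle of the line connecting the filament endpoints, relative to the
#' horizontal axis (counter-clockwise, y up), in `[-pi/2, pi/2]`; a
#' vertical filament is assigned `+pi/2`.
#'
#' @param path Ordered (row, col) pixel matrix.
#' @return Angle in radians.
#' @export
filament_angle_2d <- function(path) {
  n <- nrow(path)
  if (n < 2) return(0)
  dx <- path[n, 2] - path[1, 2]
  dy <- -(path[n, 1] - path[1, 1])  # y up
  if (dx == 0 && dy == 0) return(0)
  ang <- atan2(dy, dx)
  if (ang > pi / 2) ang <- ang - pi
  if (ang <= -pi / 2) ang <- ang + pi
  if (abs(ang + pi / 2) < 1e-12) ang <- pi / 2
  ang
}

#' Filament angle from the imaging plane, and 3-D length
#'
#' `filament_angle_3d()` computes the elevation of the filament out of the
#' imaging plane from the endpoint z displacement and the endpoint 2-D
#' separation. `filament_length_3d()` converts a 2-D length to 3-D by
#' dividing by the cosine of that angle. Because the z estimate is coarse,
#' the angle is capped at 85 degrees before the division; capped values
#' carry the `"capped"` attribute.
#'
#' @param path Ordered (row, col) pixel matrix.
#' @param z z positions along the path in nm (from [estimate_z()]).
#' @param pixel_size_nm Pixel size in nm.
#' @return Angle in radians in `[0, pi/2)`.
#' @export
filament_angle_3d <- function(path, z, pixel_size_nm = 95) {
  n <- nrow(path)
  if (n < 2) return(0)
  dz <- abs(z[length(z)] - z[1])
  run <- sqrt(sum((path[n, ] - path[1, ])^2)) * pixel_size_nm
  ang <- atan2(dz, run)
  cap <- 85 * pi / 180
  if (ang > cap) {
    ang <- cap
    attr(ang, "capped") <- TRUE
  }
  ang
}

#' @rdname filament_angle_3d
#' @param length_2d_nm 2-D filament length in nm.
#' @param angle_z Elevation angle in radians.
#' @export
filament_length_3d <- function(length_2d_nm, angle_z) {
  length_2d_nm / cos(min(abs(angle_z), 85 * pi / 180))
}

#' Menger curvature of three points
#'
#' The reciprocal of the circumradius of the circle through three points:
#' `4 * Area / (|p1p2| |p2p3| |p1p3|)`, signed by the turn orientation
#' (positive for a left turn in the y-up frame) and 0 for collinear points.
#' Points are given as (row, col) or (x, y) pairs in physical units; the
#' result has units of 1/length.
#'
#' @param p1,p2,p3 Numeric length-2 vectors, (row, col) in physical units.
#' @return Signed curvature.
#' @export
#' @examples
#' menger_curvature(c(0, 0), c(1, 1), c(0, 2))  # |k| = 1
menger_curvature <- function(p1, p2, p3) {
  # convert (row, col) to (x, y) with y up so the sign convention is the
  # mathematical one
  a <- c(p2[2] - p1[2], -(p2[1] - p1[1]))
  b <- c(p3[2] - p1[2], -(p3[1] - p1[1]))
  cross <- a[1] * b[2] - a[2] * b[1]
  d12 <- sqrt(sum((p2 - p1)^2))
  d23 <- sqrt(sum((p3 - p2)^2))
  d13 <- sqrt(sum((p3 - p1)^2))
  if (d12 == 0 || d23 == 0 || d13 == 0 || cross == 0) return(0)
  2 * cross / (d12 * d23 * d13)
}

#' Filament curvature over a physical length scale
#'
#' For every interior path pixel, flanking points are picked as close to
#' `lambda_nm` away along the path as possible (the endpoint itself when
#' closer than that), and the Menger curvature of the triple is evaluated.
#' The signed curvature is the absolute value of the mean of the signed
#' values (so opposite bends cancel); the unsigned curvature is the mean of
#' their magnitudes.
#'
#' @param path Ordered (row, col) pixel matrix.
#' @param params [curvature_params()].
#' @return Named numeric vector `c(signed =, unsigned =)`, both in 1/nm;
#'   `NA` for paths shorter than 3 pixels.
#' @export
filament_curvature <- function(path, params = curvature_params()) {
  n <- nrow(path)
  if (n < 3) return(c(signed = NA_real_, unsigned = NA_real_))
  step <- max(1L, round(params$lambda_nm / params$pixel_size_nm))
  pp <- path * params$pixel_size_nm
  ks <- vapply(2:(n - 1), function(i) {
    j1 <- max(1L, i - step)
    j2 <- min(n, i + step)
    menger_curvature(pp[j1, ], pp[i, ], pp[j2, ])
  }, 0)
  c(signed = abs(mean(ks)), unsigned = mean(abs(ks)))
}

#' Filament deviation from a straight line
#'
#' Mean distance of the filament's pixels from the straight line through
#' its endpoints, in nm — a measure of non-linearity.
#'
#' @param path Ordered (row, col) pixel matrix.
#' @param pixel_size_nm Pixel size in nm.
#' @return Deviation in nm (0 for a straight filament).
#' @export
filament_deviation <- function(path, pixel_size_nm = 95) {
  n <- nrow(path)
  if (n < 2) return(0)
  a <- path[1, ]
  b <- path[n, ]
  v <- b - a
  len <- sqrt(sum(v^2))
  if (len == 0) {
    d <- sqrt(rowSums((path - matrix(a, n, 2, byrow = TRUE))^2))
    return(mean(d) * pixel_size_nm)
  }
  d <- abs(v[2] * (path[, 1] - a[1]) - v[1] * (path[, 2] - a[2])) / len
  mean(d) * pixel_size_nm
}

#' Filament width from the pre-skeleton binary
#'
#' At every path pixel the local tangent is estimated from the path and the
#' run of contiguous foreground pixels of the pre-skeletonisation binary is
#' counted along the perpendicular ray through the pixel (capped to avoid
#' leaking into adjacent structures); the filament width is the average
#' over the path.
#'
#' @param path Ordered (row, col) pixel matrix.
#' @param binary Logical matrix: the cleaned binary before skeletonisation.
#' @param max_halfwidth_px Ray cap in pixels per side (default 30).
#' @return Mean width in pixels (at least 1 for a path on foreground).
#' @export
filament_width <- function(path, binary, max_halfwidth_px = 30) {
  binary <- as_logical_matrix(binary, "binary")
  n <- nrow(path)
  nr <- nrow(binary)
  nc <- ncol(binary)
  widths <- vapply(seq_len(n), function(i) {
    a <- path[max(1L, i - 2L), ]
    b <- path[min(n, i + 2L), ]
    tg <- b - a
    tl <- sqrt(sum(tg^2))
    if (tl == 0) tg <- c(0, 1) else tg <- tg / tl
    pp <- c(-tg[2], tg[1])  # perpendicular
    w <- if (binary[path[i, 1], path[i, 2]]) 1L else 0L
    for (sgn in c(1, -1)) {
      for (t in seq_len(max_halfwidth_px)) {
        r <- round(path[i, 1] + sgn * t * pp[1])
        cc <- round(path[i, 2] + sgn * t * pp[2])
        if (r < 1 || r > nr || cc < 1 || cc > nc || !binary[r, cc]) break
        w <- w + 1L
      }
    }
    as.numeric(w)
  }, 0)
  mean(widths)
}

# unit direction away from a junction, re-estimated from a stored direction
branch_main_dirs <- function(junction) {
  if (is.null(junction$main)) return(NULL)
  junction$main$dirs
}

#' 2-D branch angle at a junction
#'
#' The angle a motor travelling along the main filament would have to
#' deviate by to take the branch instead of continuing straight on: for
#' each unpaired branch at the junction, the angle between the branch's
#' local direction leaving the junction and the straight continuation of
#' the main (merged) filament, minimised over the two travel directions.
#' Junctions without a branch (e.g. simple crossings) yield no angle.
#'
#' @param junction One element of a `labelled_network`'s `junctions` list.
#' @return Numeric vector of angles in `[0, pi]`, one per branch (length 0
#'   when there is none).
#' @export
branch_angle_2d <- function(junction) {
  md <- branch_main_dirs(junction)
  if (is.null(md) || length(junction$branches) == 0) return(numeric(0))
  vapply(junction$branches, function(b) {
    if (all(b$dir == 0)) return(NA_real_)
    devs <- vapply(md, function(u) {
      # continuing straight past the junction means travelling along -u
      dot <- -sum(u * b$dir)
      acos(pmin(1, pmax(-1, dot)))
    }, 0)
    min(devs)
  }, 0)
}

#' 3-D branch angle at a junction
#'
#' As [branch_angle_2d()] but using the far endpoints of the main arms and
#' the branch with their estimated z positions: the pairwise 3-D distances
#' between the three endpoints and the junction give the interior angle at
#' the junction by the law of cosines, and the branch angle is its
#' deviation from a straight continuation (`pi` minus the largest interior
#' angle between the branch and a main arm). Degenerate (zero-length) arms
#' are omitted with a warning.
#'
#' @param junction One element of a `labelled_network`'s `junctions` list.
#' @param network The `labelled_network`.
#' @param stack An [image_stack()] for z estimation (2-D gives the planar
#'   angle).
#' @param pixel_size_nm Pixel size in nm.
#' @return Numeric vector of angles in `[0, pi]`, one per branch.
#' @export
branch_angle_3d <- function(junction, network, stack, pixel_size_nm = 95) {
  if (is.null(junction$main) || length(junction$branches) == 0) {
    return(numeric(0))
  }
  jpx <- junction$rep
  jz <- estimate_z(matrix(jpx, 1), stack)
  p3 <- function(frag_end) {
    path <- network$fragment_paths[[frag_end$frag]]
    epx <- if (frag_end$end == 1L) path[nrow(path), ] else path[1, ]  # far end
    z <- estimate_z(matrix(epx, 1), stack)
    c(epx * pixel_size_nm, z)
  }
  j3 <- c(jpx * pixel_size_nm, jz)
  m1 <- p3(list(frag = junction$main$frag[1], end = junction$main$end[1]))
  m2 <- p3(list(frag = junction$main$frag[2], end = junction$main$end[2]))
  vapply(junction$branches, function(b) {
    b3 <- p3(b)
    angs <- vapply(list(m1, m2), function(m) {
      # law of cosines at the junction
      da <- sqrt(sum((b3 - j3)^2))
      db <- sqrt(sum((m - j3)^2))
      dc <- sqrt(sum((b3 - m)^2))
      if (da == 0 || db == 0) return(NA_real_)
      acos(pmin(1, pmax(-1, (da^2 + db^2 - dc^2) / (2 * da * db))))
    }, 0)
    if (all(is.na(angs))) {
      warning("degenerate zero-length arm at a junction; branch angle omitted",
              call. = FALSE)
      return(NA_real_)
    }
    pi - max(angs, na.rm = TRUE)
  }, 0)
}

#' Compute the full set of network measures
#'
#' Evaluates the seventeen per-cell and per-filament measures from a
#' labelled network: ROI size, cell orientation, skeleton density,
#' structure sizes, branch ratio, branch-point density, filament widths,
#' 2-D/3-D lengths and angles, average length, signed and unsigned
#' curvature, deviation and 2-D/3-D branch angles. Lengths are in nm,
#' angles in radians, curvatures in 1/nm.
#'
#' @param network A `labelled_network` from [label_filaments()].
#' @param mask ROI in the measurement (rotated) frame; defaults to the one
#'   carried by the network.
#' @param stack Optional [image_stack()] for z-dependent measures; a 2-D
#'   input yields flat (zero) z everywhere.
#' @param cparams [curvature_params()].
#' @param binary Pre-skeleton binary for width measurement; defaults to the
#'   one carried by the network.
#' @return An object of class `measure_set`: `cell` (scalar measures),
#'   `Structures`, `filaments` (one row per filament), `branches` (one row
#'   per branch angle) and `extras` (per-volume densities, mean filament
#'   intensity and other auxiliaries outside the seventeen).
#'   [as_measure_list()] flattens it to exactly the seventeen named
#'   entries.
#' @export
compute_measures <- function(network, mask = NULL, stack = NULL,
                             cparams = NULL, binary = NULL) {
  stopifnot(inherits(network, "labelled_network"))
  px <- network$pixel_size_nm %||% 95
  cparams <- cparams %||% curvature_params(pixel_size_nm = px)
  mask <- mask %||% network$mask
  if (is.null(mask)) mask <- matrix(TRUE, nrow(network$labels), ncol(network$labels))
  mask <- as_logical_matrix(mask, "mask")
  binary <- binary %||% network$binary
  if (is.null(stack)) {
    stack <- image_stack(matrix(0, nrow(network$labels), ncol(network$labels)),
                         pixel_size_nm = px)
  }
  nf <- network$n_filaments
  depth_nm <- if (stack$is3d) dim(stack$data)[1] * stack$z_spacing_nm else NULL

  nav <- rep(NA_real_, nf)
  fil <- data.frame(label = seq_len(nf), filWidth = nav, filLenXY = nav,
                    filLenXYZ = nav, angXY = nav, angZ = nav,
                    curvatureSigned = nav, curvature = nav, deviation = nav,
                    meanIntensity = nav, capped = rep(FALSE, nf))
  img2d <- project_max(stack)
  for (k in seq_len(nf)) {
    p <- network$filaments[[k]]
    fil$filLenXY[k] <- filament_length_2d(p, px)
    z <- estimate_z(p, stack)
    az <- filament_angle_3d(p, z, px)
    fil$capped[k] <- isTRUE(attr(az, "capped"))
    fil$angZ[k] <- as.numeric(az)
    fil$filLenXYZ[k] <- filament_length_3d(fil$filLenXY[k], fil$angZ[k])
    fil$angXY[k] <- filament_angle_2d(p)
    kk <- filament_curvature(p, cparams)
    fil$curvatureSigned[k] <- kk[["signed"]]
    fil$curvature[k] <- kk[["unsigned"]]
    fil$deviation[k] <- filament_deviation(p, px)
    if (!is.null(binary)) fil$filWidth[k] <- filament_width(p, binary)
    if (all(dim(img2d) == dim(network$labels))) {
      fil$meanIntensity[k] <- mean(img2d[p])
    }
  }

  branches <- data.frame(junction = integer(0), branch_label = integer(0),
                         angXY = numeric(0), angZ = numeric(0))
  for (q in seq_along(network$junctions)) {
    jn <- network$junctions[[q]]
    a2 <- branch_angle_2d(jn)
    if (length(a2) == 0) next
    a3 <- branch_angle_3d(jn, network, stack, px)
    branches <- rbind(branches, data.frame(
      junction = q,
      branch_label = jn$branch_labels,
      angXY = a2,
      angZ = a3
    ))
  }

  cell <- list(
    cellSize = roi_size(mask),
    orientation = network$angle %||% 0,
    skelDensity = skeleton_density(network$grid, mask),
    branchRatio = branch_ratio(network),
    cellBPDensity = branch_point_density(network, mask, pixel_size_nm = px),
    avgLen = if (nf > 0) mean(fil$filLenXYZ, na.rm = TRUE) else NA_real_
  )
  extras <- list(
    skelDensityVol = if (!is.null(depth_nm)) {
      skeleton_density(network$grid, mask, depth_nm)
    } else NULL,
    cellBPDensityVol = if (!is.null(depth_nm)) {
      branch_point_density(network, mask, depth_nm = depth_nm,
                           pixel_size_nm = px)
    } else NULL,
    bpDensityBranchedLength = branch_point_density(
      network, mask, per = "branched_length", pixel_size_nm = px),
    meanIntensity = fil$meanIntensity,
    n_capped_angles = sum(fil$capped)
  )
  structure(list(cell = cell, Structures = structure_sizes(network$grid),
                 filaments = fil, branches = branches, extras = extras,
                 pixel_size_nm = px),
            class = "measure_set")
}

#' @rdname compute_measures
#' @param x A `measure_set`.
#' @param drop_na Drop undefined entries (short-path curvatures, omitted
#'   branch angles) from the list outputs.
#' @return `as_measure_list()`: a named list with exactly the seventeen
#'   measures, scalars as length-1 numerics and list measures as vectors.
#' @export
as_measure_list <- function(x, drop_na = TRUE) {
  stopifnot(inherits(x, "measure_set"))
  f <- x$filaments
  strip <- function(v) if (drop_na) v[!is.na(v)] else v
  out <- list(
    cellSize = x$cell$cellSize,
    orientation = x$cell$orientation,
    skelDensity = x$cell$skelDensity,
    Structures = x$Structures,
    branchRatio = x$cell$branchRatio,
    cellBPDensity = x$cell$cellBPDensity,
    filWidth = strip(f$filWidth),
    filLenXY = f$filLenXY,
    filLenXYZ = f$filLenXYZ,
    filamentAng.angXY = f$angXY,
    filamentAng.angZ = f$angZ,
    avgLen = x$cell$avgLen,
    curvatureSigned = strip(f$curvatureSigned),
    curvature = strip(f$curvature),
    deviation = f$deviation,
    branchAng.angXY = strip(x$branches$angXY),
    branchAng.angZ = strip(x$branches$angZ)
  )
  out[measure_codes()]
}

#' @export
print.measure_set <- function(x, ...) {
  cat(sprintf("measure set: %d filaments, %d structures, %d branch angles\n",
              nrow(x$filaments), length(x$Structures), nrow(x$branches)))
  cat(sprintf("  cellSize %d px, skelDensity %.4f, branchRatio %.3f, avgLen %.0f nm\n",
              x$cell$cellSize, x$cell$skelDensity, x$cell$branchRatio,
              x$cell$avgLen %||% NA))
  invisible(x)
}
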