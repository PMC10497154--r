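# File I/O: TIFF images and stacks, ROI masks (image or polygon sidecar),
# result writers with JSON provenance sidecars, and YAML/JSON config.

#' Read a TIFF image or z-stack
#'
#' Reads a single- or multi-page TIFF into an [image_stack()]. Integer
#' data keeps its native scale; pages are taken in file order as z order.
#' RGB input is rejected: the pipeline expects a single channel.
#'
#' @param path TIFF file path.
#' @param pixel_size_nm Lateral pixel size in nm (required; TIFF tags are
#'   not relied upon).
#' @param z_spacing_nm z spacing in nm (required for multi-page input).
#' @return An [image_stack()].
#' @export
read_image <- function(path, pixel_size_nm = 95, z_spacing_nm = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) == 3) {
    stop("expected a single-channel image; got ", dim(pages[[1]])[3],
         " channels", call. = FALSE)
  }
  if (length(pages) == 1) {
    return(image_stack(pages[[1]], pixel_size_nm))
  }
  arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  image_stack(arr, pixel_size_nm, z_spacing_nm)
}

# even-odd polygon rasterisation on pixel centres
rasterise_polygon <- function(vertices, dim) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2)
  if (nrow(vertices) < 3) stop("polygon needs at least 3 vertices", call. = FALSE)
  # vertices are 0-based (row, col); pixel centres at integer coordinates
  vr <- vertices[, 1]
  vc <- vertices[, 2]
  n <- length(vr)
  nxt <- c(2:n, 1)
  mask <- matrix(FALSE, dim[1], dim[2])
  eps <- 1e-6
  for (r in seq_len(dim[1])) {
    # evaluate the even-odd rule just above and just below the scanline so
    # pixels whose centre lies exactly on a polygon edge are included
    for (y in (r - 1) + c(-eps, eps)) {
      crosses <- (vr <= y & vr[nxt] > y) | (vr[nxt] <= y & vr > y)
      if (!any(crosses)) next
      xs <- vc[crosses] + (y - vr[crosses]) /
        (vr[nxt][crosses] - vr[crosses]) * (vc[nxt][crosses] - vc[crosses])
      xs <- sort(xs)
      for (k in seq(1, length(xs) - 1, by = 2)) {
        c0 <- ceiling(xs[k] - eps) + 1
        c1 <- floor(xs[k + 1] + eps) + 1
        if (c1 >= c0) mask[r, max(1, c0):min(dim[2], c1)] <- TRUE
      }
    }
  }
  mask
}

#' Read a region-of-interest mask
#'
#' Accepts a binary TIFF or PNG of the same (row, col) shape as the image,
#' a JSON polygon sidecar (`{"polygon": [[row, col], ...]}`, 0-based pixel
#' coordinates, even-odd fill), or a vertex matrix directly.
#'
#' @param x File path (`.tif`, `.tiff`, `.png`, `.json`) or a two-column
#'   vertex matrix.
#' @param dim Frame size `c(rows, cols)`; required for polygon input and
#'   used to validate image input.
#' @return An [roi_mask()].
#' @export
read_roi <- function(x, dim = NULL) {
  if (is.matrix(x)) {
    stopifnot(!is.null(dim))
    return(roi_mask(rasterise_polygon(x, dim), provenance = "polygon"))
  }
  ext <- tolower(tools::file_ext(x))
  if (ext == "json") {
    spec <- jsonlite::fromJSON(x)
    verts <- spec$polygon %||% spec
    verts <- as.matrix(verts)
    if (nrow(verts) == 0) stop("empty polygon", call. = FALSE)
    stopifnot(!is.null(dim))
    return(roi_mask(rasterise_polygon(verts, dim), provenance = x))
  }
  m <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(x)
  } else if (ext == "png") {
    png::readPNG(x)
  } else {
    stop("unsupported ROI format: ", ext, call. = FALSE)
  }
  if (length(base::dim(m)) == 3) m <- m[, , 1]
  if (!is.null(dim) && !all(base::dim(m) == dim)) {
    stop(sprintf("ROI shape (%d x %d) does not match image (%d x %d)",
                 nrow(m), ncol(m), dim[1], dim[2]), call. = FALSE)
  }
  roi_mask(m > 0.5, provenance = x)
}

provenance <- function(extra = list()) {
  c(list(package = "actnet",
         version = as.character(utils::packageVersion("actnet"))),
    extra)
}

#' Write a skeleton as an 8-bit TIFF with a JSON sidecar
#'
#' The sidecar records the rotation angle, the extraction parameters used
#' and the package version, so a run can be reproduced exactly.
#'
#' @param skeleton A `skeleton` object.
#' @param path Output TIFF path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_skeleton <- function(skeleton, path) {
  stopifnot(inherits(skeleton, "skeleton"))
  tiff::writeTIFF(skeleton$grid * 1, path, bits.per.sample = 8)
  side <- provenance(list(
    rotation_angle_rad = skeleton$angle,
    pixel_size_nm = skeleton$pixel_size_nm,
    params = unclass(skeleton$params)
  ))
  jsonlite::write_json(side, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write filament labels as a 16-bit TIFF plus a filament table
#'
#' @param network A `labelled_network`.
#' @param path Output TIFF path; the per-filament path table is written
#'   next to it as CSV (filament id, point order, row, col).
#' @return `path`, invisibly.
#' @export
write_labels <- function(network, path) {
  stopifnot(inherits(network, "labelled_network"))
  tiff::writeTIFF(network$labels / 65535, path, bits.per.sample = 16)
  tabs <- lapply(seq_len(network$n_filaments), function(k) {
    p <- network$filaments[[k]]
    data.frame(filament = k, point = seq_len(nrow(p)), row = p[, 1],
               col = p[, 2])
  })
  tab <- if (length(tabs) > 0) do.call(rbind, tabs) else {
    data.frame(filament = integer(0), point = integer(0), row = integer(0),
               col = integer(0))
  }
  write.csv(tab, paste0(tools::file_path_sans_ext(path), "_paths.csv"),
            row.names = FALSE)
  invisible(path)
}

#' Write the measure set as CSV and JSON
#'
#' Produces a one-row per-cell CSV of the scalar measures, a per-filament
#' CSV, a per-branch CSV, and a JSON file holding the full seventeen-entry
#' measure list. Lengths are nm, angles radians, curvatures 1/nm;
#' coordinates are 0-based (row, col) in the rotated frame.
#'
#' @param measures A `measure_set` from [compute_measures()].
#' @param prefix Output path prefix; files `<prefix>_cell.csv`,
#'   `<prefix>_filaments.csv`, `<prefix>_branches.csv` and
#'   `<prefix>.json` are written.
#' @return `prefix`, invisibly.
#' @export
write_measures <- function(measures, prefix) {
  stopifnot(inherits(measures, "measure_set"))
  cell <- as.data.frame(measures$cell)
  cell$nStructures <- length(measures$Structures)
  cell$meanStructureSize <- if (length(measures$Structures) > 0) {
    mean(measures$Structures)
  } else NA_real_
  write.csv(cell, paste0(prefix, "_cell.csv"), row.names = FALSE)
  fil <- measures$filaments
  names(fil)[names(fil) == "angXY"] <- "filamentAng.angXY"
  names(fil)[names(fil) == "angZ"] <- "filamentAng.angZ"
  write.csv(fil, paste0(prefix, "_filaments.csv"), row.names = FALSE)
  br <- measures$branches
  names(br)[names(br) == "angXY"] <- "branchAng.angXY"
  names(br)[names(br) == "angZ"] <- "branchAng.angZ"
  write.csv(br, paste0(prefix, "_branches.csv"), row.names = FALSE)
  jsonlite::write_json(c(provenance(), as_measure_list(measures)),
                       paste0(prefix, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a YAML or JSON run configuration
#'
#' Recognised top-level sections: `extraction` ([extraction_params()]
#' fields), `curvature` ([curvature_params()] fields), `scene`
#' ([scene_params()] fields) and `calibration` (`pixel_size_nm`,
#' `z_spacing_nm`). Unknown fields are an error, so typos do not pass
#' silently.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A list with `extraction`, `curvature`, `scene` parameter
#'   objects and `calibration` values, each built from the defaults with
#'   the file's overrides applied.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path)
  } else {
    stop("config must be YAML or JSON", call. = FALSE)
  }
  build <- function(section, ctor) {
    args <- cfg[[section]] %||% list()
    known <- names(formals(ctor))
    bad <- setdiff(names(args), known)
    if (length(bad) > 0) {
      stop("unknown ", section, " config fields: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    do.call(ctor, args)
  }
  list(
    extraction = build("extraction", extraction_params),
    curvature = build("curvature", curvature_params),
    scene = build("scene", scene_params),
    calibration = list(
      pixel_size_nm = cfg$calibration$pixel_size_nm %||% 95,
      z_spacing_nm = cfg$calibration$z_spacing_nm
    )
  )
}
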