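# Synthetic micrograph generator with exact filament ground truth:
# spline filaments rendered on a supersampled grid, blurred with the
# point-spread function, block-mean downscaled, and overlaid with
# PSF-blurred impulse noise of tunable amplitude.

#' Gaussian PSF width from numerical aperture
#'
#' Gaussian approximation to the Airy disc of a diffraction-limited lens:
#' `sigma = 0.21 * wavelength / NA`.
#'
#' @param na Numerical aperture.
#' @param wavelength_nm Emission wavelength in nm (509 nm for GFP).
#' @return PSF sigma in nm.
#' @export
#' @examples
#' psf_sigma_from_na(1.35, 509)  # ~79 nm
psf_sigma_from_na <- function(na, wavelength_nm = 509) {
  stopifnot(na > 0, wavelength_nm > 0)
  0.21 * wavelength_nm / na
}

#' Parameters of a synthetic scene
#'
#' The defaults reproduce the benchmarking conditions used throughout the
#' package: 200 x 200 frames at 95 nm/pixel rendered at 19x supersampling
#' (5 nm effective fine pixel, so that a single actin filament is one fine
#' pixel wide), 10 filaments per frame, a PSF mimicking a 1.35 NA lens at
#' the GFP emission wavelength, and sparse blurred impulse noise.
#'
#' @param size_px Coarse frame size, `c(rows, cols)`.
#' @param pixel_size_nm Coarse pixel size in nm.
#' @param supersample Supersampling factor (fine pixel = pixel_size /
#'   supersample; must divide exactly, which integer factors do).
#' @param n_filaments Number of filaments per frame.
#' @param thickness_nm Filament thickness: 5 (actin), 15 (intermediate
#'   filament) or 25 (microtubule); any value at least one fine pixel works.
#' @param brightness Per-pixel filament intensity before blurring.
#' @param noise_max Maximum impulse amplitude; each impulse is scaled by an
#'   independent uniform draw in (0, noise_max].
#' @param noise_density Fraction of coarse pixels receiving an impulse.
#' @param na,wavelength_nm Lens numerical aperture and emission wavelength,
#'   from which the PSF sigma is derived unless `psf_sigma_nm` is given.
#' @param psf_sigma_nm PSF sigma in nm (overrides `na`).
#' @param midpoint_frac Maximum perpendicular midpoint displacement as a
#'   fraction of the chord length (sets how curved filaments are).
#' @param min_sep_frac Minimum endpoint separation as a fraction of the
#'   frame diagonal (closer endpoint pairs are resampled).
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(size_px = c(200, 200),
                         pixel_size_nm = 95,
                         supersample = 19,
                         n_filaments = 10,
                         thickness_nm = 5,
                         brightness = 1,
                         noise_max = 0.1,
                         noise_density = 0.05,
                         na = 1.35,
                         wavelength_nm = 509,
                         psf_sigma_nm = NULL,
                         midpoint_frac = 0.2,
                         min_sep_frac = 0.25) {
  if (length(size_px) == 1) size_px <- c(size_px, size_px)
  fine_px <- pixel_size_nm / supersample
  stopifnot(
    all(size_px >= 16), supersample >= 1, supersample == round(supersample),
    n_filaments >= 0, thickness_nm >= fine_px, brightness > 0,
    noise_max >= 0, noise_density >= 0, noise_density <= 1,
    midpoint_frac >= 0, min_sep_frac > 0, min_sep_frac < 1
  )
  structure(list(
    size_px = as.integer(size_px), pixel_size_nm = pixel_size_nm,
    supersample = as.integer(supersample), n_filaments = as.integer(n_filaments),
    thickness_nm = thickness_nm, brightness = brightness,
    noise_max = noise_max, noise_density = noise_density,
    na = na, wavelength_nm = wavelength_nm,
    psf_sigma_nm = psf_sigma_nm %||% psf_sigma_from_na(na, wavelength_nm),
    midpoint_frac = midpoint_frac, min_sep_frac = min_sep_frac,
    fine_px_nm = fine_px
  ), class = "scene_params")
}

#' Draw one random curved filament
#'
#' Samples two endpoints uniformly inside the fine-grid frame (resampling
#' until they are at least the configured distance apart), displaces their
#' midpoint perpendicular to the chord by a uniform random fraction of the
#' chord length, and interpolates a smooth (natural cubic) spline through
#' the three points, parameterised by cumulative chord length.
#'
#' @param params [scene_params()].
#' @param n_samples Number of dense samples; defaults to roughly one per
#'   half fine pixel of estimated arclength.
#' @return A list: `points` (dense (row, col) samples on the fine grid),
#'   `knots`, `arclength_nm` and `displacement` (signed midpoint offset,
#'   fine px). Uses the current RNG state.
#' @export
sample_filament <- function(params = scene_params(), n_samples = NULL) {
  nrf <- params$size_px[1] * params$supersample
  ncf <- params$size_px[2] * params$supersample
  min_sep <- params$min_sep_frac * sqrt(nrf^2 + ncf^2)
  repeat {
    p1 <- c(runif(1, 1, nrf), runif(1, 1, ncf))
    p2 <- c(runif(1, 1, nrf), runif(1, 1, ncf))
    if (sqrt(sum((p2 - p1)^2)) >= min_sep) break
  }
  chord <- sqrt(sum((p2 - p1)^2))
  u <- (p2 - p1) / chord
  perp <- c(-u[2], u[1])
  disp <- runif(1, -params$midpoint_frac, params$midpoint_frac) * chord
  mid <- (p1 + p2) / 2 + disp * perp
  knots <- rbind(p1, mid, p2)
  tt <- c(0, cumsum(sqrt(rowSums(diff(knots)^2))))
  # pilot pass to estimate arclength, then resample at ~0.5 fine px spacing
  dense <- function(np) {
    ts <- seq(0, tt[3], length.out = np)
    cbind(spline(tt, knots[, 1], xout = ts, method = "natural")$y,
          spline(tt, knots[, 2], xout = ts, method = "natural")$y)
  }
  pilot <- dense(256)
  arc <- sum(sqrt(rowSums(diff(pilot)^2)))
  np <- n_samples %||% max(64, ceiling(arc / 0.5))
  pts <- dense(np)
  pts[, 1] <- pmin(pmax(pts[, 1], 1), nrf)
  pts[, 2] <- pmin(pmax(pts[, 2], 1), ncf)
  arc <- sum(sqrt(rowSums(diff(pts)^2)))
  list(points = pts, knots = knots, arclength_nm = arc * params$fine_px_nm,
       displacement = disp)
}

#' Render the clean (noise-free) image of a set of filaments
#'
#' Rasterises each filament one fine pixel thick (dilated to the configured
#' physical thickness when wider), applies the Gaussian PSF on the fine
#' grid, and downscales by exact block averaging. The ground truth is the
#' set of coarse pixels containing at least one centreline sample.
#'
#' @param filaments List of filaments from [sample_filament()].
#' @param params [scene_params()].
#' @return A list: `image` (coarse numeric matrix) and `truth` (coarse
#'   logical matrix of centreline pixels).
#' @export
render_clean <- function(filaments, params = scene_params()) {
  f <- params$supersample
  nrc <- params$size_px[1]
  ncc <- params$size_px[2]
  half_w <- (params$thickness_nm / params$fine_px_nm - 1) / 2
  offs <- if (half_w >= 0.5) {
    d <- disc_offsets(half_w + 0.25)
    cbind(d$di, d$dj)
  } else {
    matrix(0L, 1, 2)
  }
  pr <- integer(0)
  pc <- integer(0)
  tr <- integer(0)
  tc <- integer(0)
  for (fl in filaments) {
    ctr <- round(fl$points)
    keep <- !duplicated(ctr)
    ctr <- ctr[keep, , drop = FALSE]
    tr <- c(tr, ctr[, 1])
    tc <- c(tc, ctr[, 2])
    for (q in seq_len(nrow(offs))) {
      pr <- c(pr, ctr[, 1] + offs[q, 1])
      pc <- c(pc, ctr[, 2] + offs[q, 2])
    }
  }
  img <- cpp_render_scene(as.integer(pr), as.integer(pc), params$brightness,
                          params$psf_sigma_nm / params$fine_px_nm, f, nrc, ncc)
  truth <- matrix(FALSE, nrc, ncc)
  if (length(tr) > 0) {
    truth[cbind(pmin(pmax((tr - 1L) %/% f + 1L, 1L), nrc),
                pmin(pmax((tc - 1L) %/% f + 1L, 1L), ncc))] <- TRUE
  }
  list(image = img, truth = truth)
}

# background pixels for SNR purposes: away from any filament
snr_background_mask <- function(truth, margin = 2L) {
  !chebyshev_dilate(truth, margin)
}

#' Realised signal-to-noise ratio of a scene
#'
#' SNR is defined per image as the mean intensity on the ground-truth
#' centreline pixels minus the mean background intensity, divided by the
#' standard deviation of the background, where background pixels are those
#' more than 2 pixels (Chebyshev) from any centreline pixel.
#'
#' @param image Coarse intensity matrix.
#' @param truth Coarse logical ground-truth matrix.
#' @return SNR (infinite for a noise-free image).
#' @export
scene_snr <- function(image, truth) {
  bg <- snr_background_mask(truth)
  s <- mean(image[truth])
  b <- image[bg]
  sdb <- sd(b)
  if (!is.finite(sdb) || sdb == 0) return(Inf)
  (s - mean(b)) / sdb
}

#' Add blurred impulse noise to a clean scene
#'
#' Sparse salt-type impulses with independent uniform amplitudes in
#' `(0, noise_max]` are placed on the coarse grid, blurred with the same
#' PSF as the filaments, and added to the clean image.
#'
#' @param clean Clean coarse image from [render_clean()].
#' @param truth Ground-truth matrix (for the realised-SNR computation).
#' @param params [scene_params()].
#' @return A list: `image` (noisy frame) and `snr` (realised SNR). Uses
#'   the current RNG state.
#' @export
add_noise <- function(clean, truth, params = scene_params()) {
  if (params$noise_max <= 0 || params$noise_density <= 0) {
    return(list(image = clean, snr = Inf))  # no noise: SNR flagged infinite
  }
  n <- length(clean)
  hit <- runif(n) < params$noise_density
  noise <- matrix(0, nrow(clean), ncol(clean))
  noise[hit] <- runif(sum(hit), 0, params$noise_max)
  sig_c <- params$psf_sigma_nm / params$pixel_size_nm
  k <- gauss_kernel(sig_c)
  noise <- cpp_conv_sep(noise, k, k)
  img <- clean + noise
  list(image = img, snr = scene_snr(img, truth))
}

#' Generate one synthetic scene
#'
#' Draws the filaments, renders the clean frame, adds noise, and packages
#' the result with its exact ground truth. A scene is a pure function of
#' `(params, seed)`.
#'
#' @param params [scene_params()].
#' @param seed Integer seed.
#' @return An object of class `synthetic_scene`: `image`, `truth`,
#'   `filaments` (spline definitions and arclengths), `snr`, `params`,
#'   `seed`.
#' @export
#' @examples
#' sc <- simulate_scene(scene_params(n_filaments = 2, noise_max = 0), seed = 7)
#' sc$snr
simulate_scene <- function(params = scene_params(), seed = 1L) {
  set.seed(as.integer(seed))
  fils <- replicate(params$n_filaments, sample_filament(params),
                    simplify = FALSE)
  cl <- render_clean(fils, params)
  nz <- add_noise(cl$image, cl$truth, params)
  structure(list(image = nz$image, truth = cl$truth, clean = cl$image,
                 filaments = fils, snr = nz$snr, params = params,
                 seed = as.integer(seed)),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic scene: %d x %d px, %d filaments, SNR %.2f (seed %d)\n",
              nrow(x$image), ncol(x$image), length(x$filaments), x$snr,
              x$seed))
  invisible(x)
}

#' Generate a reproducible batch of scenes
#'
#' @param conditions A data frame whose columns override [scene_params()]
#'   fields (e.g. `noise_max`, `n_filaments`); one row per condition.
#'   `NULL` means a single default condition.
#' @param n_per Scenes per condition.
#' @param seed Master seed; per-scene seeds are drawn from it, so the whole
#'   batch (and its manifest) is reproducible.
#' @param params Base [scene_params()].
#' @param keep_scenes Keep the scene objects (memory-heavy for large
#'   batches); the manifest is always returned.
#' @return A list with `manifest` (data frame: condition, scene, seed,
#'   realised snr) and, if requested, `scenes`.
#' @export
generate_dataset <- function(conditions = NULL, n_per = 100, seed = 1L,
                             params = scene_params(), keep_scenes = TRUE) {
  if (is.null(conditions)) conditions <- data.frame(row.names = 1)
  ncond <- nrow(conditions)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, ncond * n_per)
  manifest <- NULL
  scenes <- list()
  idx <- 0L
  for (ci in seq_len(ncond)) {
    p <- params
    for (nm in names(conditions)) p[[nm]] <- conditions[ci, nm]
    class(p) <- "scene_params"
    for (si in seq_len(n_per)) {
      idx <- idx + 1L
      sc <- simulate_scene(p, seed = seeds[idx])
      manifest <- rbind(manifest, data.frame(
        condition = ci, scene = si, seed = seeds[idx], snr = sc$snr))
      if (keep_scenes) scenes[[idx]] <- sc
    }
  }
  out <- list(manifest = manifest, conditions = conditions)
  if (keep_scenes) out$scenes <- scenes
  out
}

#' Calibrate the noise amplitude to a target mean SNR
#'
#' The mapping from `noise_max` to realised SNR is non-linear and
#' stochastic, so the amplitude producing a requested mean SNR is found by
#' a short Monte-Carlo secant search using common random numbers (the same
#' probe seeds at every candidate amplitude).
#'
#' @param target_snr Requested mean SNR over images.
#' @param params Base [scene_params()].
#' @param n_probe Probe images per candidate amplitude.
#' @param seed Seed for the probe images.
#' @param max_iter Secant iterations.
#' @param tol Relative tolerance on the achieved mean SNR.
#' @return The calibrated `noise_max`, with attribute `"snr"` (achieved
#'   probe mean).
#' @export
calibrate_noise <- function(target_snr, params = scene_params(),
                            n_probe = 8, seed = 1L, max_iter = 8,
                            tol = 0.02) {
  stopifnot(target_snr > 0)
  set.seed(as.integer(seed))
  probe_seeds <- sample.int(.Machine$integer.max - 1L, n_probe)
  mean_snr <- function(nm) {
    p <- params
    p$noise_max <- nm
    class(p) <- "scene_params"
    mean(vapply(probe_seeds, function(s) simulate_scene(p, s)$snr, 0))
  }
  nm <- if (params$noise_max > 0) params$noise_max else 0.1
  s <- mean_snr(nm)
  for (it in seq_len(max_iter)) {
    if (abs(s - target_snr) / target_snr < tol) break
    # realised SNR is close to inversely proportional to the amplitude
    nm_new <- nm * s / target_snr
    s_new <- mean_snr(nm_new)
    nm <- nm_new
    s <- s_new
  }
  structure(nm, snr = s)
}
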