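# Scoring an extracted skeleton against ground truth with a pixel
# tolerance, and the robustness sweeps (SNR, network density, threshold,
# numerical aperture).

#' Match a predicted skeleton against ground truth
#'
#' Set-based matching with a Chebyshev pixel tolerance: a predicted pixel
#' is a true positive if any truth pixel lies within `tolerance_px` of it,
#' otherwise a false positive; a truth pixel with no predicted pixel
#' within the tolerance is a false negative. Sensitivity (TPR) is
#' `TP / (TP + FN)` and precision (PPV) is `TP / (TP + FP)`.
#'
#' @param predicted Logical matrix or `skeleton` object.
#' @param truth Logical matrix of ground-truth centreline pixels.
#' @param tolerance_px Matching tolerance in pixels (default 1, i.e. the
#'   8-neighbourhood).
#' @return An object of class `match_result`: `tp`, `fp`, `fn`, `tpr`,
#'   `ppv`, `tolerance_px`. An empty truth leaves `tpr` as `NA`; an empty
#'   prediction leaves `ppv` as `NA` with `tpr = 0`.
#' @export
#' @examples
#' a <- matrix(FALSE, 9, 9); a[5, 2:8] <- TRUE
#' match_skeletons(a, a)$tpr
match_skeletons <- function(predicted, truth, tolerance_px = 1) {
  predicted <- as_logical_matrix(predicted, "predicted")
  truth <- as_logical_matrix(truth, "truth")
  stopifnot(all(dim(predicted) == dim(truth)), tolerance_px >= 0)
  dil_t <- chebyshev_dilate(truth, tolerance_px)
  dil_p <- chebyshev_dilate(predicted, tolerance_px)
  tp <- sum(predicted & dil_t)
  fp <- sum(predicted & !dil_t)
  fn <- sum(truth & !dil_p)
  tpr <- if (sum(truth) == 0) NA_real_ else tp / (tp + fn)
  ppv <- if (sum(predicted) == 0) NA_real_ else tp / (tp + fp)
  if (sum(predicted) == 0 && sum(truth) > 0) tpr <- 0
  structure(list(tp = tp, fp = fp, fn = fn, tpr = tpr, ppv = ppv,
                 tolerance_px = tolerance_px),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match: TP %d FP %d FN %d | TPR %.3f PPV %.3f (tol %g px)\n",
              x$tp, x$fp, x$fn, x$tpr, x$ppv, x$tolerance_px))
  invisible(x)
}

#' Run a robustness sweep over generation/extraction conditions
#'
#' For each condition (a row of `conditions`, whose columns may override
#' any [scene_params()] field, any [extraction_params()] field, or `na` to
#' set the PSF), generates `n_images` scenes with per-scene seeds derived
#' from the master seed, extracts skeletons at the configured parameters,
#' scores them against the exact ground truth at the pixel tolerance, and
#' summarises sensitivity and precision per condition.
#'
#' @param conditions Data frame of conditions (one per row); `NULL` runs
#'   the single base condition.
#' @param n_images Scenes per condition.
#' @param scene Base [scene_params()].
#' @param extraction Base [extraction_params()].
#' @param tolerance_px Matching tolerance in pixels.
#' @param seed Master seed.
#' @return An object of class `sweep_result`: `results` (one row per
#'   image: condition, seed, realised snr, tp/fp/fn, tpr, ppv, and any
#'   error message for failed images — failures are recorded, never
#'   dropped) and `summary` (per-condition mean, sd and quartiles of TPR
#'   and PPV).
#' @export
run_sweep <- function(conditions = NULL, n_images = 100,
                      scene = scene_params(),
                      extraction = extraction_params(),
                      tolerance_px = 1, seed = 1L) {
  if (is.null(conditions)) conditions <- data.frame(row.names = 1)
  ncond <- nrow(conditions)
  set.seed(as.integer(seed))
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, ncond * n_images),
                  nrow = ncond)
  scene_fields <- names(scene)
  extr_fields <- names(extraction)
  rows <- vector("list", ncond * n_images)
  idx <- 0L
  for (ci in seq_len(ncond)) {
    sp <- scene
    ep <- extraction
    for (nm in names(conditions)) {
      val <- conditions[ci, nm]
      if (nm == "na") {
        sp$na <- val
        sp$psf_sigma_nm <- psf_sigma_from_na(val, sp$wavelength_nm)
      } else if (nm %in% scene_fields) {
        sp[[nm]] <- val
      } else if (nm %in% extr_fields) {
        ep[[nm]] <- val
      } else {
        stop("unknown condition column: ", nm, call. = FALSE)
      }
    }
    class(sp) <- "scene_params"
    class(ep) <- "extraction_params"
    for (si in seq_len(n_images)) {
      idx <- idx + 1L
      row <- data.frame(condition = ci, image = si, seed = seeds[ci, si],
                        snr = NA_real_, tp = NA_integer_, fp = NA_integer_,
                        fn = NA_integer_, tpr = NA_real_, ppv = NA_real_,
                        error = NA_character_)
      res <- tryCatch({
        sc <- simulate_scene(sp, seed = seeds[ci, si])
        sk <- muffle_warnings(
          extract_skeleton(image_stack(sc$image, sp$pixel_size_nm),
                           params = ep, warn_degenerate = FALSE),
          "empty skeleton")
        m <- match_skeletons(sk$grid, sc$truth, tolerance_px)
        row$snr <- sc$snr
        row$tp <- m$tp
        row$fp <- m$fp
        row$fn <- m$fn
        row$tpr <- m$tpr
        row$ppv <- m$ppv
        row
      }, error = function(e) {
        row$error <- conditionMessage(e)
        row
      })
      rows[[idx]] <- res
    }
  }
  results <- do.call(rbind, rows)
  results <- cbind(results,
                   conditions[results$condition, , drop = FALSE],
                   row.names = NULL)
  summ <- do.call(rbind, lapply(seq_len(ncond), function(ci) {
    r <- results[results$condition == ci & is.na(results$error), ]
    q <- function(v, p) as.numeric(quantile(v, p, na.rm = TRUE, names = FALSE))
    data.frame(condition = ci, n = nrow(r),
               snr_mean = mean(r$snr, na.rm = TRUE),
               tpr_mean = mean(r$tpr, na.rm = TRUE),
               tpr_sd = sd(r$tpr, na.rm = TRUE),
               tpr_q25 = q(r$tpr, 0.25), tpr_q50 = q(r$tpr, 0.5),
               tpr_q75 = q(r$tpr, 0.75),
               ppv_mean = mean(r$ppv, na.rm = TRUE),
               ppv_sd = sd(r$ppv, na.rm = TRUE),
               ppv_q25 = q(r$ppv, 0.25), ppv_q50 = q(r$ppv, 0.5),
               ppv_q75 = q(r$ppv, 0.75),
               failed = sum(!is.na(results$error[results$condition == ci])))
  }))
  summ <- cbind(summ, conditions[summ$condition, , drop = FALSE],
                row.names = NULL)
  structure(list(results = results, summary = summ, conditions = conditions,
                 seed = seed, tolerance_px = tolerance_px),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("robustness sweep:\n")
  print(x$summary[, intersect(c(names(x$conditions), "n", "snr_mean",
                                "tpr_mean", "ppv_mean", "failed"),
                              names(x$summary))])
  invisible(x)
}
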