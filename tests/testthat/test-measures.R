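# The quantitative network measures against closed forms and brute-force
# oracles.

test_that("ROI size and densities scale as expected", {
  full <- matrix(TRUE, 10, 10)
  expect_equal(roi_size(full), 100)
  half <- full
  half[, 6:10] <- FALSE
  expect_equal(roi_size(half), 50)

  sk <- matrix(FALSE, 40, 50)
  sk[10, 1:25] <- TRUE
  sk[30, 1:25] <- TRUE
  mask <- matrix(TRUE, 40, 50)
  expect_equal(skeleton_density(matrix(FALSE, 40, 50), mask), 0)
  expect_equal(skeleton_density(sk, mask), 50 / 2000)
  # invariance under a 90-degree rotation of both grids
  expect_equal(skeleton_density(t(sk), t(mask)), skeleton_density(sk, mask))
  # doubling the ROI with unchanged skeleton halves the density
  wide <- cbind(mask, mask)
  expect_equal(skeleton_density(cbind(sk, matrix(FALSE, 40, 50)), wide),
               skeleton_density(sk, mask) / 2)
  # per-volume variant
  expect_equal(skeleton_density(sk, mask, depth_nm = 550),
               skeleton_density(sk, mask) / 550)
})

test_that("structure sizes list 8-connected component pixel counts", {
  g <- matrix(FALSE, 20, 20)
  g[5, 3:12] <- TRUE
  g[15, 1:20] <- TRUE
  expect_equal(sort(structure_sizes(g)), c(10, 20))
  expect_equal(mean(structure_sizes(g)), 15)
  expect_equal(structure_sizes(matrix(FALSE, 5, 5)), integer(0))
  expect_length(structure_sizes(g[1:10, ]), 1)
})

test_that("branch ratio and branch-point density follow their definitions", {
  net <- label_filaments(make_tee())
  expect_equal(branch_ratio(net), 0.5)  # 1 branch point, 2 filaments
  line <- label_filaments({
    g <- matrix(FALSE, 9, 9)
    g[5, 2:8] <- TRUE
    g
  })
  expect_equal(branch_ratio(line), 0)

  mask <- matrix(TRUE, 25, 40)
  expect_equal(branch_point_density(net, mask), 1 / 1000)
  expect_equal(branch_point_density(line, mask), 0)
  # alternative length-based normalisation is exposed but off by default
  alt <- branch_point_density(net, mask, per = "branched_length")
  expect_gt(alt, 0)
  expect_equal(branch_point_density(net, mask, depth_nm = 1000),
               branch_point_density(net, mask) / 1000)
})

test_that("2-D length weights diagonal steps by sqrt(2)", {
  horiz <- cbind(5, 1:10)
  expect_equal(filament_length_2d(horiz, 95), 950)
  diag5 <- cbind(1:5, 1:5)  # 4 diagonal steps
  expect_equal(filament_length_2d(diag5, 95), (5 + 4 * (sqrt(2) - 1)) * 95)
  expect_equal(filament_length_2d(cbind(3, 3), 95), 95)
})

test_that("z estimation picks the brightest plane with low-index ties", {
  arr <- array(0, c(5, 8, 8))
  arr[4, , ] <- 2  # plane 4 brightest everywhere
  st <- image_stack(arr, 95, z_spacing_nm = 550)
  path <- cbind(4, 1:8)
  expect_equal(estimate_z(path, st), rep(3 * 550, 8), ignore_attr = TRUE)

  arr2 <- array(1, c(3, 5, 5))  # all ties: lowest plane wins
  st2 <- image_stack(arr2, 95, z_spacing_nm = 550)
  expect_equal(estimate_z(cbind(2, 1:4), st2), rep(0, 4),
               ignore_attr = TRUE)

  flat <- image_stack(matrix(0, 8, 8), 95)
  zf <- estimate_z(path, flat)
  expect_true(all(zf == 0))
  expect_true(attr(zf, "flat"))

  # a filament rendered brighter in successive planes recovers monotone z
  arr3 <- array(0, c(4, 10, 10))
  for (i in 1:10) arr3[ceiling(i / 3), 5, i] <- 5
  st3 <- image_stack(arr3, 95, z_spacing_nm = 500)
  z3 <- estimate_z(cbind(5, 1:10), st3)
  expect_true(all(diff(z3) >= 0))
})

test_that("filament angles follow the y-up sign convention", {
  expect_equal(filament_angle_2d(cbind(5, 1:10)), 0)
  # endpoints (0,0) -> (10,10) in (x, y-up): rows decrease as cols increase
  p <- cbind(11:1, 1:11)
  expect_equal(filament_angle_2d(p), pi / 4)
  expect_equal(filament_angle_2d(cbind(1:10, 5)), pi / 2)
})

test_that("3-D angle and length follow the cosine relation", {
  path <- cbind(5, 1:11)
  z0 <- rep(0, 11)
  expect_equal(filament_angle_3d(path, z0, 95), 0)
  l2 <- filament_length_2d(path, 95)
  expect_equal(filament_length_3d(l2, 0), l2)
  expect_equal(filament_length_3d(l2, 60 * pi / 180), 2 * l2)
  # z rise 550 nm over a 950 nm 2-D run
  z <- seq(0, 550, length.out = 11)
  ang <- filament_angle_3d(cbind(5, 1:11), z, 95)
  expect_equal(ang, atan(550 / 950), tolerance = 1e-12)
  # near-vertical displacement is capped at 85 degrees
  angc <- filament_angle_3d(rbind(c(5, 5), c(5, 6)), c(0, 1e6), 95)
  expect_equal(as.numeric(angc), 85 * pi / 180)
  expect_true(attr(angc, "capped"))
})

test_that("Menger curvature equals the inverse circumradius", {
  expect_equal(menger_curvature(c(0, 0), c(0, 5), c(0, 10)), 0)
  k <- menger_curvature(c(0, 0), c(1, 1), c(2, 0))
  expect_equal(abs(k), 1 / oracle_circumradius(c(0, 0), c(1, 1), c(2, 0)))
  expect_equal(abs(k), 1)
  # three points on a circle of radius 2
  ang <- c(0.3, 1.1, 2.0)
  pts <- lapply(ang, function(a) 2 * c(sin(a), cos(a)))
  k2 <- menger_curvature(pts[[1]], pts[[2]], pts[[3]])
  expect_equal(abs(k2), 0.5, tolerance = 1e-12)
  # the row-mirrored triple turns the opposite way: sign flips
  expect_equal(menger_curvature(c(0, 0), c(-1, 1), c(-2, 0)), -k)
})

test_that("filament curvature recovers an arc radius and cancels on an S", {
  cp <- curvature_params(lambda_nm = 475, pixel_size_nm = 95)
  straight <- cbind(7, 1:30)
  expect_equal(unname(filament_curvature(straight, cp)), c(0, 0))

  r <- 30  # pixels, well above the 5-px sampling scale
  arc <- make_arc_path(r, from = 0.2, to = pi - 0.2, ctr = c(40, 40))
  k <- filament_curvature(arc, cp)
  expect_equal(unname(k[["unsigned"]]), 1 / (r * 95), tolerance = 0.15)
  expect_equal(unname(k[["signed"]]), 1 / (r * 95), tolerance = 0.15)

  # symmetric S: signed cancels, unsigned does not
  s1 <- make_arc_path(20, from = 0.3, to = pi / 2, ctr = c(30, 10))
  off <- s1[nrow(s1), ]
  s2 <- make_arc_path(20, from = -pi / 2, to = -0.3, ctr = off + c(-20 + 1, 0))
  s2 <- s2[nrow(s2):1, , drop = FALSE]
  sp <- rbind(s1, s2[-1, ])
  ks <- filament_curvature(sp, cp)
  expect_lt(ks[["signed"]], 0.3 * ks[["unsigned"]])

  expect_true(all(is.na(filament_curvature(cbind(1, 1:2), cp))))
})

test_that("deviation matches point-to-line oracles", {
  expect_equal(filament_deviation(cbind(5, 1:20), 95), 0)

  # right-angle V: brute-force mean point-line distance
  v <- rbind(cbind(10:1, 1:10), cbind(2:10, 11:19))
  a <- v[1, ]
  b <- v[nrow(v), ]
  vv <- b - a
  d <- abs(vv[2] * (v[, 1] - a[1]) - vv[1] * (v[, 2] - a[2])) /
    sqrt(sum(vv^2))
  expect_equal(filament_deviation(v, 95), mean(d) * 95)

  # semicircular arc of radius r: mean distance to the diameter is 2r/pi
  r <- 40
  arc <- make_arc_path(r, from = 0, to = pi, ctr = c(50, 50))
  expect_equal(filament_deviation(arc, 1), 2 * r / pi, tolerance = 0.05)
})

test_that("width is the perpendicular run length through the binary", {
  line <- matrix(FALSE, 11, 30)
  line[6, 3:28] <- TRUE
  path <- cbind(6, 3:28)
  expect_equal(filament_width(path, line), 1)

  bar3 <- matrix(FALSE, 11, 30)
  bar3[5:7, 3:28] <- TRUE
  expect_equal(filament_width(path, bar3), 3)

  # width 2 on one half, 4 on the other: average 3
  bar24 <- matrix(FALSE, 12, 32)
  bar24[6:7, 3:17] <- TRUE
  bar24[5:8, 18:30] <- TRUE
  p24 <- cbind(6, 3:30)
  w <- filament_width(p24, bar24)
  expect_equal(w, mean(c(rep(2, 15), rep(4, 13))), tolerance = 0.15)
})

test_that("branch angles measure the deviation a motor would take", {
  net <- label_filaments(make_tee())
  expect_equal(branch_angle_2d(net$junctions[[1]]), pi / 2, tolerance = 1e-9)

  # 45-degree stem on a straight main filament
  g <- matrix(FALSE, 21, 21)
  g[11, 2:20] <- TRUE
  for (t in 1:8) g[11 - t, 11 + t] <- TRUE
  net45 <- label_filaments(g)
  expect_equal(branch_angle_2d(net45$junctions[[1]]), pi / 4,
               tolerance = 0.05)

  # branch collinear with the continuation: deviation 0
  g0 <- matrix(FALSE, 15, 25)
  g0[8, 2:12] <- TRUE
  g0[8, 14:24] <- TRUE
  g0[8, 13] <- TRUE
  g0[9:14, 13] <- TRUE   # stem makes (8,13) a junction
  net0 <- label_filaments(g0)
  a <- branch_angle_2d(net0$junctions[[1]])
  expect_equal(length(a), 1)
  expect_equal(a, pi / 2, tolerance = 0.1)  # the stem deviates by 90 deg

  # flat stack: the 3-D angle reduces to the planar geometry
  flat <- image_stack(matrix(0, 15, 15), 95)
  a3 <- branch_angle_3d(net$junctions[[1]], net, flat, 95)
  expect_equal(a3, pi / 2, tolerance = 0.05)

  # branch rising in z: matches a direct 3-D vector computation
  arr <- array(0, c(4, 15, 15))
  arr[1, , ] <- 1e-3
  stem <- which(net$labels == net$junctions[[1]]$branch_labels[1],
                arr.ind = TRUE)
  for (i in seq_len(nrow(stem))) arr[min(4, i), stem[i, 1], stem[i, 2]] <- 5
  st <- image_stack(arr, 95, z_spacing_nm = 550)
  a3z <- branch_angle_3d(net$junctions[[1]], net, st, 95)
  # oracle: deviation = pi - max interior angle from the 3-D endpoint vectors
  jn <- net$junctions[[1]]
  jp <- c(jn$rep * 95, estimate_z(matrix(jn$rep, 1), st))
  ends3 <- lapply(c(jn$main$frag, jn$branches[[1]]$frag), function(fr) {
    p <- net$fragment_paths[[fr]]
    e <- p[which.max(pmax(abs(p[, 1] - jn$rep[1]), abs(p[, 2] - jn$rep[2]))), ]
    c(e * 95, estimate_z(matrix(e, 1), st))
  })
  intang <- vapply(1:2, function(i) {
    u <- ends3[[i]] - jp
    v <- ends3[[3]] - jp
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }, 0)
  expect_equal(a3z, pi - max(intang), tolerance = 1e-9)
})

test_that("compute_measures emits the seventeen measures coherently", {
  expect_length(measure_codes(), 17)

  net <- label_filaments(make_tee())
  ms <- compute_measures(net, binary = make_tee())
  ml <- as_measure_list(ms)
  expect_identical(names(ml), measure_codes())

  # hand-worked toy values on the T
  expect_equal(ml$cellSize, 225)
  expect_equal(ml$orientation, 0)
  expect_equal(ml$skelDensity, 19 / 225)
  expect_equal(ml$Structures, 19)
  expect_equal(ml$branchRatio, 0.5)
  expect_equal(ml$cellBPDensity, 1 / 225)
  main <- net$junctions[[1]]$main_labels[1]
  expect_equal(sort(ml$filLenXY), sort(c(13 * 95, 5 * 95)))
  expect_equal(ml$filLenXYZ, ml$filLenXY)  # flat input
  expect_equal(ml$avgLen, mean(ml$filLenXYZ))
  expect_equal(sort(abs(ml$filamentAng.angXY)), c(0, pi / 2))
  expect_true(all(ml$filamentAng.angZ == 0))
  expect_true(all(ml$curvatureSigned <= ml$curvature + 1e-12))
  expect_equal(ml$deviation, c(0, 0))
  expect_equal(ml$branchAng.angXY, pi / 2, tolerance = 1e-9)
  expect_equal(ml$branchAng.angZ, pi / 2, tolerance = 0.05)
  # the stem is one pixel wide everywhere; the main filament picks up the
  # stem's pixels where its perpendicular crosses the junction
  expect_equal(min(ml$filWidth), 1)
  expect_lt(max(ml$filWidth), 2)
})

test_that("an empty network yields empty measures without error", {
  net <- label_filaments(matrix(FALSE, 20, 20))
  ms <- compute_measures(net)
  ml <- as_measure_list(ms)
  expect_identical(names(ml), measure_codes())
  expect_equal(ml$skelDensity, 0)
  expect_equal(ml$branchRatio, 0)
  expect_length(ml$filLenXY, 0)
})

test_that("measures are invariant under a 90-degree frame rotation", {
  sc <- simulate_scene(scene_params(n_filaments = 6, noise_max = 0.05),
                       seed = 31)
  g <- extract_skeleton(sc$image,
                        params = extraction_params(rotate = FALSE))$grid
  net <- label_filaments(g)
  ms <- compute_measures(net)
  rot <- t(g)[ncol(g):1, , drop = FALSE]  # exact 90-degree rotation
  net_r <- label_filaments(rot)
  ms_r <- compute_measures(net_r)
  expect_equal(ms_r$cell$skelDensity, ms$cell$skelDensity)
  expect_equal(ms_r$cell$branchRatio, ms$cell$branchRatio)
  expect_equal(sort(ms_r$Structures), sort(ms$Structures))
  expect_equal(sort(ms_r$filaments$filLenXY), sort(ms$filaments$filLenXY),
               tolerance = 1e-9)
  # junction bridges may pick between equal-length pixel chains in an
  # orientation-dependent way, shifting a path pixel or two
  expect_equal(sort(ms_r$filaments$deviation), sort(ms$filaments$deviation),
               tolerance = 5e-3)
})

test_that("filament invariants hold on extracted synthetic networks", {
  sc <- simulate_scene(scene_params(n_filaments = 5, noise_max = 0.05),
                       seed = 31)
  sk <- extract_skeleton(sc$image, params = extraction_params(rotate = FALSE))
  net <- label_filaments(sk)
  ms <- compute_measures(net)
  f <- ms$filaments
  expect_true(all(f$filLenXYZ >= f$filLenXY - 1e-9))
  ok <- !is.na(f$curvatureSigned)
  expect_true(all(f$curvatureSigned[ok] <= f$curvature[ok] + 1e-12))
  expect_true(all(f$deviation >= 0))
  expect_true(all(f$filWidth >= 1))
})

test_that("ground-truth spline length and curvature are recovered", {
  sc <- simulate_scene(scene_params(n_filaments = 1, noise_max = 0), seed = 15)
  sk <- extract_skeleton(sc$image, params = extraction_params(rotate = FALSE))
  net <- label_filaments(sk)
  expect_equal(net$n_filaments, 1)
  ms <- compute_measures(net)
  truth_nm <- sc$filaments[[1]]$arclength_nm
  expect_equal(ms$filaments$filLenXY[1], truth_nm, tolerance = 0.05)

  # mean ground-truth curvature from the dense spline samples (1/nm)
  pts <- sc$filaments[[1]]$points * sc$params$fine_px_nm
  idx <- seq(1, nrow(pts), by = 40)
  pp <- pts[idx, ]
  kt <- vapply(2:(nrow(pp) - 1), function(i) {
    abs(menger_curvature(pp[i - 1, ], pp[i, ], pp[i + 1, ]))
  }, 0)
  km <- compute_measures(net,
                         cparams = curvature_params(pixel_size_nm = 95))
  expect_equal(km$filaments$curvature[1], mean(kt), tolerance = 0.15)
})
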