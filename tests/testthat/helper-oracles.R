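# Fixture builders and independent brute-force oracles used across tests.

# --- fixtures -------------------------------------------------------------

make_tee <- function(n = 15) {
  g <- matrix(FALSE, n, n)
  mid <- (n + 1) %/% 2
  g[mid, 2:(n - 1)] <- TRUE
  g[(mid + 1):(n - 1), mid] <- TRUE
  g
}

make_x <- function(n = 21) {
  g <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    g[i, i] <- TRUE
    g[i, n + 1 - i] <- TRUE
  }
  g
}

make_ring <- function(n = 21, r = 7) {
  g <- matrix(FALSE, n, n)
  ctr <- (n + 1) / 2
  for (t in seq(0, 2 * pi, length.out = 720)) {
    g[round(ctr + r * sin(t)), round(ctr + r * cos(t))] <- TRUE
  }
  g
}

# digitised circular arc of radius r px spanning the given angles
make_arc_path <- function(r, from = 0, to = pi, ctr = c(0, 0)) {
  pts <- NULL
  for (t in seq(from, to, length.out = max(720, round(20 * r)))) {
    p <- round(c(ctr[1] - r * sin(t), ctr[2] + r * cos(t)))
    if (is.null(pts) || any(p != pts[nrow(pts), ])) pts <- rbind(pts, p)
  }
  unname(pts)
}

random_blob <- function(n = 30, seed = 1) {
  set.seed(seed)
  g <- matrix(runif(n * n) < 0.35, n, n)
  # smooth into blobby shapes
  for (i in 1:2) g <- actnet:::chebyshev_dilate(g, 1) & !(matrix(runif(n * n) < 0.2, n, n))
  g
}

# --- oracles --------------------------------------------------------------

# direct erosion-then-dilation grayscale opening with a flat disc
oracle_opening_disc <- function(img, radius) {
  nr <- nrow(img)
  nc <- ncol(img)
  offs <- expand.grid(di = -radius:radius, dj = -radius:radius)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2, ]
  er <- matrix(Inf, nr, nc)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    ii <- i + offs$di
    jj <- j + offs$dj
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    er[i, j] <- min(img[cbind(ii[ok], jj[ok])])
  }
  di <- matrix(-Inf, nr, nc)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    ii <- i + offs$di
    jj <- j + offs$dj
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    di[i, j] <- max(er[cbind(ii[ok], jj[ok])])
  }
  di
}

# Euler-style topology summary: 8-connected components and 4-connected
# holes (background regions not touching the frame border)
oracle_topology <- function(bin) {
  comps <- max(actnet:::cpp_label8(bin))
  # 4-connected background labelling via two-pass flood fill in R
  nr <- nrow(bin)
  nc <- ncol(bin)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j0 in seq_len(nc)) for (i0 in seq_len(nr)) {
    if (bin[i0, j0] || lab[i0, j0] > 0) next
    nxt <- nxt + 1L
    stack <- list(c(i0, j0))
    lab[i0, j0] <- nxt
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] < 1 || q[1] > nr || q[2] < 1 || q[2] > nc) next
        if (!bin[q[1], q[2]] && lab[q[1], q[2]] == 0) {
          lab[q[1], q[2]] <- nxt
          stack[[length(stack) + 1]] <- q
        }
      }
    }
  }
  border_labs <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  holes <- length(setdiff(unique(lab[lab > 0]), border_labs))
  list(components = comps, holes = holes)
}

has_2x2_block <- function(bin) {
  nr <- nrow(bin)
  nc <- ncol(bin)
  any(bin[-nr, -nc] & bin[-1, -nc] & bin[-nr, -1] & bin[-1, -1])
}

# all-pairs Chebyshev matching counts
oracle_match <- function(pred, truth, tol) {
  pp <- which(pred, arr.ind = TRUE)
  tt <- which(truth, arr.ind = TRUE)
  cheb <- function(a, B) {
    if (nrow(B) == 0) return(Inf)
    min(pmax(abs(B[, 1] - a[1]), abs(B[, 2] - a[2])))
  }
  tp <- sum(apply(pp, 1, cheb, B = tt) <= tol)
  fp <- nrow(pp) - tp
  fn <- sum(apply(tt, 1, cheb, B = pp) > tol)
  list(tp = tp, fp = fp, fn = fn)
}

# circumradius of three points (abc / 4K)
oracle_circumradius <- function(p1, p2, p3) {
  a <- sqrt(sum((p2 - p3)^2))
  b <- sqrt(sum((p1 - p3)^2))
  cc <- sqrt(sum((p1 - p2)^2))
  s <- (a + b + cc) / 2
  K <- sqrt(max(0, s * (s - a) * (s - b) * (s - cc)))
  if (K == 0) Inf else a * b * cc / (4 * K)
}

# Hessian eigenvalues of an analytic image sampled on a grid, by finite
# differences after Gaussian smoothing done directly in R
oracle_gaussian_ridge <- function(n, sigma_ridge, horizontal = TRUE) {
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(r, cc) {
    d <- if (horizontal) r - ctr else cc - ctr
    exp(-0.5 * (d / sigma_ridge)^2)
  })
}

oracle_gaussian_blob <- function(n, sigma) {
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(r, cc) {
    exp(-0.5 * ((r - ctr)^2 + (cc - ctr)^2) / sigma^2)
  })
}

expect_partition_conserved <- function(net, grid) {
  fil_px <- sum(vapply(seq_len(max(net$labels, 0)),
                       function(k) sum(net$labels == k), 0))
  bp_px <- sum(net$branch_points$n_px)
  expect_identical(as.integer(fil_px + bp_px), as.integer(sum(grid)))
}
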