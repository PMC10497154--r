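# Filament labelling: break the skeleton at branch points, label the
# fragments, then rejoin the straightest continuation at every junction so
# that a filament keeps one label across its branches.

# encode (row, col) pixels so neighbours can be looked up with match()
PX_BASE <- 1000003L

px_code <- function(px) px[, 1] + px[, 2] * PX_BASE

NB8 <- cbind(
  dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
  dc = c(-1, 0, 1, -1, 1, -1, 0, 1)
)

# Order a set of pixels into a traversable path. Returns the path, the
# number of degree-1 pixels found, and whether the walk covered everything.
order_path <- function(px) {
  n <- nrow(px)
  if (n == 1) {
    return(list(path = px, n_endpoints = 1L, complete = TRUE))
  }
  codes <- px_code(px)
  nbr_of <- function(i) {
    cand <- codes[i] + NB8[, "dr"] + NB8[, "dc"] * PX_BASE
    idx <- match(cand, codes)
    idx[!is.na(idx)]
  }
  adj <- lapply(seq_len(n), nbr_of)
  deg <- lengths(adj)
  endpoints <- which(deg == 1)
  start <- if (length(endpoints) > 0) endpoints[1] else which.min(codes)
  visited <- logical(n)
  path_idx <- integer(n)
  cur <- start
  visited[cur] <- TRUE
  path_idx[1] <- cur
  k <- 1L
  while (k < n) {
    nb <- adj[[cur]]
    nb <- nb[!visited[nb]]
    if (length(nb) == 0) break
    if (length(nb) > 1) {
      # prefer 4-adjacent continuation, then lowest index, for determinism
      d4 <- abs(px[nb, 1] - px[cur, 1]) + abs(px[nb, 2] - px[cur, 2]) == 1
      nb <- if (any(d4)) nb[d4] else nb
      nb <- nb[order(codes[nb])]
    }
    cur <- nb[1]
    visited[cur] <- TRUE
    k <- k + 1L
    path_idx[k] <- cur
  }
  complete <- k == n
  if (!complete) {
    path_idx <- c(path_idx[seq_len(k)], which(!visited))
  }
  list(path = px[path_idx, , drop = FALSE],
       n_endpoints = length(endpoints), complete = complete)
}

# local direction of a fragment at one of its ends, pointing inwards
end_direction <- function(path, end, window = 5L) {
  n <- nrow(path)
  if (end == 1L) {
    a <- path[1, ]
    b <- path[min(n, 1L + window), ]
  } else {
    a <- path[n, ]
    b <- path[max(1L, n - window), ]
  }
  v <- c(b[1] - a[1], b[2] - a[2])
  len <- sqrt(sum(v^2))
  if (len == 0) c(0, 0) else v / len
}

#' Find branch points of a skeleton
#'
#' A branch point is a skeleton pixel with three or more skeleton neighbours
#' (8-connectivity). Thinning frequently emits small clusters of mutually
#' adjacent qualifying pixels at a junction; each cluster is merged into one
#' junction whose representative is the cluster pixel nearest its centroid.
#'
#' @param skeleton A `skeleton` object or single-pixel-thick logical matrix.
#' @return A data frame with one row per junction: `row`, `col` (the
#'   representative pixel) and `n_px` (pixels in the cluster). The full
#'   cluster pixel sets are attached as the `"pixels"` attribute.
#' @export
find_branch_points <- function(skeleton) {
  grid <- as_logical_matrix(skeleton, "skeleton")
  nb <- cpp_neighbour_count(grid)
  bp <- grid & nb >= 3
  if (!any(bp)) {
    out <- data.frame(row = integer(0), col = integer(0), n_px = integer(0))
    attr(out, "pixels") <- list()
    return(out)
  }
  lab <- cpp_label8(bp)
  ncl <- max(lab)
  pixels <- vector("list", ncl)
  rep_rc <- matrix(0L, ncl, 2)
  n_px <- integer(ncl)
  for (q in seq_len(ncl)) {
    px <- which(lab == q, arr.ind = TRUE)
    ctr <- colMeans(px)
    d2 <- (px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2
    rep_rc[q, ] <- as.integer(px[which.min(d2), ])
    pixels[[q]] <- unname(px)
    n_px[q] <- nrow(px)
  }
  out <- data.frame(row = rep_rc[, 1], col = rep_rc[, 2], n_px = n_px)
  attr(out, "pixels") <- pixels
  out
}

# shortest 8-connected chain through a junction cluster linking pixel a to b
bridge_pixels <- function(cluster_px, a, b) {
  nodes <- rbind(a, cluster_px, b)
  codes <- px_code(nodes)
  n <- nrow(nodes)
  prev <- rep(NA_integer_, n)
  dist <- rep(Inf, n)
  dist[1] <- 0
  queue <- 1L
  while (length(queue) > 0) {
    cur <- queue[1]
    queue <- queue[-1]
    cand <- codes[cur] + NB8[, "dr"] + NB8[, "dc"] * PX_BASE
    for (idx in match(cand, codes)) {
      if (is.na(idx) || is.finite(dist[idx])) next
      dist[idx] <- dist[cur] + 1
      prev[idx] <- cur
      queue <- c(queue, idx)
    }
  }
  if (!is.finite(dist[n])) return(matrix(0L, 0, 2))
  chain <- integer(0)
  cur <- n
  while (!is.na(prev[cur])) {
    chain <- c(cur, chain)
    cur <- prev[cur]
  }
  chain <- chain[-length(chain)]  # drop b itself; a was never appended
  nodes[chain, , drop = FALSE]
}

#' Label individual filaments across branch points
#'
#' Partitions a single-pixel-thick skeleton into individually labelled
#' filaments. Branch-point pixels are temporarily removed, the remaining
#' fragments are connected-component labelled, and at every junction the
#' local directions of the incident fragments are compared: the pair whose
#' directions are closest to a straight continuation is merged into one
#' filament. Pairing repeats while two or more unpaired fragment ends remain
#' at the junction (so a simple crossing yields two filaments that both pass
#' through it); fragments left unpaired are branches. Final labels are
#' consecutive integers starting at 1.
#'
#' @param skeleton A `skeleton` object (from [extract_skeleton()]) or a
#'   single-pixel-thick logical matrix.
#' @param direction_window Path steps used to estimate a fragment's local
#'   direction at a junction (default 5, matching the curvature scale).
#' @return An object of class `labelled_network`: `labels` (integer matrix,
#'   0 background), `filaments` (list of ordered pixel paths, junction
#'   pixels included where a filament crosses one), `junctions` (list with
#'   representative pixel, cluster pixels, the merged main pair and any
#'   branch ends with their local directions), `branch_points` (data frame
#'   of representatives), plus the grid and calibration carried over.
#' @export
#' @examples
#' tee <- matrix(FALSE, 15, 15)
#' tee[8, 2:14] <- TRUE   # main filament
#' tee[9:14, 8] <- TRUE   # perpendicular stem
#' net <- label_filaments(tee)
#' net$n_filaments  # 2: the two collinear arms merge, the stem stays
label_filaments <- function(skeleton, direction_window = 5L) {
  grid <- as_logical_matrix(skeleton, "skeleton")
  sk <- if (inherits(skeleton, "skeleton")) skeleton else NULL
  bps <- find_branch_points(grid)
  cluster_px <- attr(bps, "pixels")
  n_junc <- nrow(bps)

  bp_mask <- matrix(FALSE, nrow(grid), ncol(grid))
  for (px in cluster_px) bp_mask[px] <- TRUE
  frag_lab <- cpp_label8(grid & !bp_mask)
  n_frag <- max(frag_lab)

  if (n_frag == 0) {
    net <- list(labels = frag_lab, filaments = list(), n_filaments = 0L,
                junctions = list(), branch_points = bps, grid = grid,
                n_fragments = 0L, fragment_labels = frag_lab,
                fragment_paths = list(),
                angle = if (!is.null(sk)) sk$angle else 0,
                pixel_size_nm = if (!is.null(sk)) sk$pixel_size_nm else NULL,
                z_spacing_nm = if (!is.null(sk)) sk$z_spacing_nm else NULL,
                binary = if (!is.null(sk)) sk$binary else NULL,
                mask = if (!is.null(sk)) sk$mask else NULL)
    class(net) <- "labelled_network"
    return(net)
  }

  frag_path <- vector("list", n_frag)
  for (k in seq_len(n_frag)) {
    frag_path[[k]] <- order_path(which(frag_lab == k, arr.ind = TRUE))$path
  }
  frag_len <- vapply(frag_path, nrow, 0L)

  # assign fragment ends to the nearest adjacent junction
  ends <- NULL  # frag, end, junction, plus direction rows
  if (n_junc > 0) {
    cl_codes <- lapply(cluster_px, px_code)
    for (k in seq_len(n_frag)) {
      p <- frag_path[[k]]
      n <- nrow(p)
      for (e in unique(c(1L, 2L)[c(TRUE, n > 1)])) {
        epx <- if (e == 1L) p[1, ] else p[n, ]
        cand <- px_code(matrix(rep(epx, each = 9) +
                                 cbind(c(0, NB8[, "dr"]), c(0, NB8[, "dc"])),
                               ncol = 2))
        hit <- which(vapply(cl_codes, function(cc) any(cand %in% cc), TRUE))
        if (length(hit) > 0) {
          ends <- rbind(ends, c(frag = k, end = e, junction = hit[1]))
        }
      }
    }
  }

  # union-find over fragments
  parent <- seq_len(n_frag)
  uf_find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }

  merges <- list()
  junction_info <- vector("list", n_junc)
  w <- as.integer(direction_window)
  for (q in seq_len(n_junc)) {
    pool <- if (is.null(ends)) integer(0) else which(ends[, "junction"] == q)
    dirs <- lapply(pool, function(r) {
      d <- end_direction(frag_path[[ends[r, "frag"]]], ends[r, "end"], w)
      if (all(d == 0)) {  # single-pixel fragment: point away from the junction
        epx <- frag_path[[ends[r, "frag"]]][1, ]
        v <- c(epx[1] - bps$row[q], epx[2] - bps$col[q])
        l <- sqrt(sum(v^2))
        d <- if (l > 0) v / l else c(1, 0)
      }
      d
    })
    main_pair <- NULL
    local_merges <- list()
    avail <- seq_along(pool)
    if (length(avail) < 2 && length(avail) > 0) {
      warning("junction with a single incident fragment; nothing to merge",
              call. = FALSE)
    }
    while (length(avail) >= 2) {
      best <- NULL
      pairs <- utils::combn(avail, 2)
      # deviation from a straight continuation: directions (pointing away
      # from the junction) of a collinear pair are antiparallel
      score <- apply(pairs, 2, function(pr) {
        dot <- -sum(dirs[[pr[1]]] * dirs[[pr[2]]])
        acos(pmin(1, pmax(-1, dot)))
      })
      comb_len <- apply(pairs, 2, function(pr) {
        frag_len[ends[pool[pr[1]], "frag"]] + frag_len[ends[pool[pr[2]], "frag"]]
      })
      ord <- order(score, -comb_len, pairs[1, ], pairs[2, ])
      merged <- FALSE
      for (cix in ord) {
        f1 <- ends[pool[pairs[1, cix]], "frag"]
        f2 <- ends[pool[pairs[2, cix]], "frag"]
        if (uf_find(f1) == uf_find(f2)) next  # would close a loop
        parent[uf_find(f1)] <- uf_find(f2)
        rec <- list(junction = q,
                    frag = c(f1, f2),
                    end = c(ends[pool[pairs[1, cix]], "end"],
                            ends[pool[pairs[2, cix]], "end"]),
                    dirs = list(dirs[[pairs[1, cix]]], dirs[[pairs[2, cix]]]))
        merges[[length(merges) + 1]] <- rec
        local_merges[[length(local_merges) + 1]] <- rec
        if (is.null(main_pair)) main_pair <- rec
        avail <- setdiff(avail, pairs[, cix])
        merged <- TRUE
        break
      }
      if (!merged) break
    }
    branch_ends <- lapply(avail, function(a) {
      list(frag = ends[pool[a], "frag"], end = ends[pool[a], "end"],
           dir = dirs[[a]])
    })
    junction_info[[q]] <- list(
      rep = c(bps$row[q], bps$col[q]),
      pixels = cluster_px[[q]],
      n_px = bps$n_px[q],
      main = main_pair,
      merges = local_merges,
      branches = branch_ends
    )
  }

  # contiguous final labels, ordered by the smallest fragment id per class
  root <- vapply(seq_len(n_frag), uf_find, 0L)
  class_ids <- sort(unique(root))
  remap <- setNames(seq_along(class_ids), class_ids)
  final_of_frag <- remap[as.character(root)]
  n_fil <- length(class_ids)

  labels <- matrix(0L, nrow(grid), ncol(grid))
  sel <- frag_lab > 0
  labels[sel] <- as.integer(final_of_frag[frag_lab[sel]])

  # stitch ordered paths through the junctions
  filaments <- vector("list", n_fil)
  for (fid in seq_len(n_fil)) {
    members <- which(final_of_frag == fid)
    if (length(members) == 1) {
      filaments[[fid]] <- frag_path[[members]]
      next
    }
    # adjacency between member fragments via their merges
    conns <- Filter(function(m) all(m$frag %in% members), merges)
    used <- matrix(FALSE, length(members), 2,
                   dimnames = list(members, NULL))
    for (m in conns) {
      used[as.character(m$frag[1]), m$end[1]] <- TRUE
      used[as.character(m$frag[2]), m$end[2]] <- TRUE
    }
    free <- which(!used, arr.ind = TRUE)
    if (nrow(free) == 0) {  # a loop of fragments: break it arbitrarily
      start_frag <- members[1]
      start_end <- 1L
      warning("cyclic filament; cycle broken at an arbitrary pixel",
              call. = FALSE)
    } else {
      start_frag <- members[free[1, 1]]
      start_end <- free[1, 2]
    }
    path <- NULL
    cur <- start_frag
    entry <- start_end
    remaining <- conns
    repeat {
      p <- frag_path[[cur]]
      if (entry == 2L) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
      path <- rbind(path, p)
      exit_end <- if (entry == 1L) 2L else 1L
      hit <- which(vapply(remaining, function(m) {
        any(m$frag == cur & m$end == exit_end)
      }, TRUE))
      if (length(hit) == 0) break
      m <- remaining[[hit[1]]]
      remaining <- remaining[-hit[1]]
      side <- if (m$frag[1] == cur && m$end[1] == exit_end) 1L else 2L
      nxt <- m$frag[3 - side]
      nxt_end <- m$end[3 - side]
      exit_px <- path[nrow(path), ]
      nxt_path <- frag_path[[nxt]]
      entry_px <- if (nxt_end == 1L) nxt_path[1, ] else nxt_path[nrow(nxt_path), ]
      br <- bridge_pixels(junction_info[[m$junction]]$pixels, exit_px, entry_px)
      if (nrow(br) > 0) path <- rbind(path, br)
      cur <- nxt
      entry <- nxt_end
    }
    filaments[[fid]] <- unname(path)
  }

  # annotate junctions with final labels
  for (q in seq_len(n_junc)) {
    ji <- junction_info[[q]]
    if (!is.null(ji$main)) {
      junction_info[[q]]$main_labels <-
        unname(final_of_frag[ji$main$frag])
    }
    junction_info[[q]]$branch_labels <-
      vapply(ji$branches, function(b) unname(final_of_frag[b$frag]), 0L)
    inc <- if (is.null(ends)) integer(0) else {
      unique(unname(final_of_frag[ends[ends[, "junction"] == q, "frag"]]))
    }
    junction_info[[q]]$labels <- inc
  }

  net <- list(labels = labels, filaments = filaments, n_filaments = n_fil,
              junctions = junction_info, branch_points = bps, grid = grid,
              n_fragments = n_frag,
              fragment_labels = frag_lab,
              fragment_paths = frag_path,
              angle = if (!is.null(sk)) sk$angle else 0,
              pixel_size_nm = if (!is.null(sk)) sk$pixel_size_nm else NULL,
              z_spacing_nm = if (!is.null(sk)) sk$z_spacing_nm else NULL,
              binary = if (!is.null(sk)) sk$binary else NULL,
              mask = if (!is.null(sk)) sk$mask else NULL)
  class(net) <- "labelled_network"
  net
}

#' @export
print.labelled_network <- function(x, ...) {
  cat(sprintf("labelled network: %d filaments, %d branch points on %d x %d\n",
              x$n_filaments, nrow(x$branch_points), nrow(x$labels),
              ncol(x$labels)))
  invisible(x)
}

#' Ordered pixel path of a filament
#'
#' Returns the pixels of one filament ordered from one endpoint to the
#' other (consecutive pixels are 8-adjacent). For a [label_filaments()]
#' result the stitched path (including junction pixels a filament crosses)
#' is returned; for a plain label matrix the path is traced on the spot.
#' A cyclic filament is broken at an arbitrary pixel with a warning; a
#' label whose pixels cannot be traversed as a single path is an error.
#'
#' @param x A `labelled_network` or an integer label matrix.
#' @param id Filament label (positive integer).
#' @return A two-column matrix of (row, col) pixel coordinates.
#' @export
trace_path <- function(x, id) {
  if (inherits(x, "labelled_network")) {
    stopifnot(id >= 1, id <= x$n_filaments)
    return(x$filaments[[id]])
  }
  px <- which(x == id, arr.ind = TRUE)
  if (nrow(px) == 0) stop("no pixels carry label ", id, call. = FALSE)
  res <- order_path(unname(px))
  if (!res$complete) {
    stop("label ", id, " is not traversable as a single path", call. = FALSE)
  }
  if (res$n_endpoints == 0) {
    warning("cyclic filament; cycle broken at an arbitrary pixel",
            call. = FALSE)
  }
  res$path
}
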