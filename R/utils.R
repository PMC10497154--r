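# internal helpers

# 1-D Gaussian (or Gaussian-derivative) kernel sampled on integers
gauss_kernel <- function(sigma, order = 0L, radius = NULL) {
  stopifnot(sigma > 0)
  if (is.null(radius)) radius <- max(1L, ceiling(4 * sigma))
  x <- seq(-radius, radius)
  g <- exp(-0.5 * (x / sigma)^2)
  g <- g / sum(g)
  switch(as.character(order),
    "0" = g,
    "1" = -(x / sigma^2) * g,
    "2" = ((x^2 - sigma^2) / sigma^4) * g,
    stop("order must be 0, 1 or 2")
  )
}

as_logical_matrix <- function(x, arg = "x") {
  if (inherits(x, "skeleton")) x <- x$grid
  if (inherits(x, "roi_mask")) x <- x$mask
  if (!is.matrix(x)) stop(sprintf("`%s` must be a matrix", arg), call. = FALSE)
  if (!is.logical(x)) {
    storage.mode(x) <- "double"
    x <- x > 0.5
  }
  x
}

as_numeric_matrix <- function(x, arg = "x") {
  if (inherits(x, "image_stack")) x <- project_max(x)
  if (!is.matrix(x)) stop(sprintf("`%s` must be a matrix", arg), call. = FALSE)
  storage.mode(x) <- "double"
  x
}

# offsets of a disc of the given pixel radius, with ball heights if non-flat
disc_offsets <- function(radius, height = NULL) {
  r <- floor(radius)
  d <- expand.grid(di = -r:r, dj = -r:r)
  keep <- d$di^2 + d$dj^2 <= radius^2
  d <- d[keep, , drop = FALSE]
  if (is.null(height)) {
    h <- rep(0, nrow(d))
  } else {
    h <- height / radius * sqrt(pmax(0, radius^2 - d$di^2 - d$dj^2))
  }
  list(di = as.integer(d$di), dj = as.integer(d$dj), h = as.numeric(h))
}

chebyshev_dilate <- function(bin, radius) {
  if (radius <= 0) return(bin)
  cpp_cheb_dilate(bin, as.integer(radius))
}

muffle_warnings <- function(expr, pattern) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl(pattern, conditionMessage(w))) invokeRestart("muffleWarning")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
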