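# Brute-force oracles and small fixture builders, independent of the
# package's own geometry code paths.

# All fixed 4-connected polyominoes of n cells, as lists of (row, col)
# matrices normalized to min row/col = 1. Grown cell-by-cell with
# canonical-form deduplication.
enumerate_polyominoes <- function(n_max) {
  canon <- function(cells) {
    cells <- cells[order(cells[, 1L], cells[, 2L]), , drop = FALSE]
    cells[, 1L] <- cells[, 1L] - min(cells[, 1L]) + 1L
    cells[, 2L] <- cells[, 2L] - min(cells[, 2L]) + 1L
    paste(cells[, 1L], cells[, 2L], sep = ",", collapse = ";")
  }
  from_key <- function(key) {
    prs <- strsplit(strsplit(key, ";")[[1L]], ",")
    m <- t(vapply(prs, function(p) as.integer(p), integer(2)))
    m
  }
  out <- list()
  current <- c(canon(matrix(c(1L, 1L), 1L)))
  out[[1L]] <- current
  for (n in seq_len(n_max - 1L)) {
    nxt <- character(0)
    for (key in current) {
      cells <- from_key(key)
      for (i in seq_len(nrow(cells))) for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
        cand <- cells[i, ] + d
        if (!any(cells[, 1L] == cand[1L] & cells[, 2L] == cand[2L]))
          nxt <- c(nxt, canon(rbind(cells, cand)))
      }
    }
    current <- unique(nxt)
    out[[n + 1L]] <- current
  }
  lapply(unlist(out), from_key)
}

polyomino_raster <- function(cells, pad = 1L) {
  m <- matrix(0L, max(cells[, 1L]) + 2L * pad, max(cells[, 2L]) + 2L * pad)
  m[cbind(cells[, 1L] + pad, cells[, 2L] + pad)] <- 1L
  m
}

# Crack perimeter by direct enumeration: each cell contributes one unit edge
# per missing 4-neighbor.
oracle_crack_perimeter <- function(cells) {
  has <- function(r, c) any(cells[, 1L] == r & cells[, 2L] == c)
  p <- 0L
  for (i in seq_len(nrow(cells))) {
    r <- cells[i, 1L]; c <- cells[i, 2L]
    p <- p + sum(!c(has(r - 1L, c), has(r + 1L, c), has(r, c - 1L), has(r, c + 1L)))
  }
  p
}

# Convex-hull pixel count by half-plane enumeration over all point pairs:
# a lattice point is in the hull iff it satisfies every half-plane that
# contains all region points. Collinear regions degenerate to the segment.
oracle_hull_count <- function(cells, eps = 1e-9) {
  pts <- cells
  n <- nrow(pts)
  if (n <= 2L) return(n)
  cross <- function(a, b, p)
    (b[2L] - a[2L]) * (p[, 1L] - a[1L]) - (b[1L] - a[1L]) * (p[, 2L] - a[2L])
  grid <- as.matrix(expand.grid(row = min(pts[, 1L]):max(pts[, 1L]),
                                col = min(pts[, 2L]):max(pts[, 2L])))
  collinear <- TRUE
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    cr <- cross(pts[i, ], pts[j, ], pts)
    if (any(abs(cr) > eps)) collinear <- FALSE
  }
  if (collinear) return(n)
  inside <- rep(TRUE, nrow(grid))
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    cr <- cross(pts[i, ], pts[j, ], pts)
    if (all(cr >= -eps)) inside <- inside & (cross(pts[i, ], pts[j, ], grid) >= -eps)
    if (all(cr <= eps)) inside <- inside & (cross(pts[i, ], pts[j, ], grid) <= eps)
  }
  sum(inside)
}

# Direct dense 2-D Gaussian convolution with half-sample symmetric padding,
# the oracle for the separable implementation.
oracle_gauss_blur <- function(m, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k1 <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  nr <- nrow(m); nc <- ncol(m)
  reflect <- function(i, n) {  # half-sample symmetric index
    i <- ((i - 1L) %% (2L * n))
    ifelse(i < n, i + 1L, 2L * n - i)
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r)
      acc <- acc + K[di + r + 1L, dj + r + 1L] *
        m[reflect(i + di, nr), reflect(j + dj, nc)]
    out[i, j] <- acc
  }
  out
}

# A small two-group cohort used by several tests.
test_cohort_spec <- function(seed = 1L, n_images = 3L, mean_cells = 8L,
                             shape = c(320L, 320L), noise_sd = 0.01) {
  cohort_spec(groups = list(
    wt  = list(n_images = n_images, cells_per_image_mean = mean_cells,
               shape_mixture = c(amoeboid = 0.5, ramified = 0.5)),
    het = list(n_images = n_images, cells_per_image_mean = mean_cells,
               shape_mixture = c(amoeboid = 0.5, ramified = 0.5))),
    image_shape_px = shape, noise_sd = noise_sd, seed = seed)
}
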