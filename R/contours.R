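# Cell boundary contours. The outer boundary of a labeled region is traced
# along pixel "cracks" (the edges between foreground and background pixels),
# giving a closed polygon whose vertices sit on pixel corners. Pixel (i, j)
# occupies the unit square [i-0.5, i+0.5] x [j-0.5, j+0.5] in (row, col)
# coordinates. Counter-clockwise means positive shoelace area with x = col,
# y = row.

# Trace the outer crack boundary of a single-component binary region.
# Returns list(vertices = closed (row, col) polygon, pixels = the owning
# foreground pixel of each traversed edge).
trace_crack_boundary <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  fg <- which(binary > 0)
  if (!length(fg)) stop_param("empty region has no contour")
  ri <- (fg - 1L) %% nr + 1L
  ci <- (fg - 1L) %/% nr + 1L
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[cbind(ri + 1L, ci + 1L)] <- TRUE
  at <- function(i, j) pad[i + 1L, j + 1L]

  # Directed boundary edges keep the region on the right; corner (a, b) sits
  # at (row, col) = (a + 0.5, b + 0.5), a in 0..nr, b in 0..nc.
  edges <- vector("list", 4L * length(fg)); np <- 0L
  for (idx in seq_along(fg)) {
    i <- ri[idx]; j <- ci[idx]
    if (!at(i - 1L, j)) { np <- np + 1L; edges[[np]] <- c(i - 1L, j - 1L, i - 1L, j, i, j) }
    if (!at(i, j + 1L)) { np <- np + 1L; edges[[np]] <- c(i - 1L, j, i, j, i, j) }
    if (!at(i + 1L, j)) { np <- np + 1L; edges[[np]] <- c(i, j, i, j - 1L, i, j) }
    if (!at(i, j - 1L)) { np <- np + 1L; edges[[np]] <- c(i, j - 1L, i - 1L, j - 1L, i, j) }
  }
  E <- do.call(rbind, edges[seq_len(np)])
  key <- function(a, b) a * (nc + 1L) + b + 1L
  from_key <- key(E[, 1L], E[, 2L])
  out_by_corner <- split(seq_len(np), from_key)

  # start at the top-left corner of the first foreground pixel in reading
  # order; that corner has exactly one outgoing edge
  first <- order(ri, ci)[1L]
  start <- c(ri[first] - 1L, ci[first] - 1L)
  used <- logical(np)
  verts <- matrix(0L, np + 1L, 2L)
  own <- integer(np)
  cur <- start; dir <- NULL; nv <- 0L
  repeat {
    cand <- out_by_corner[[as.character(key(cur[1L], cur[2L]))]]
    cand <- cand[!used[cand]]
    if (!length(cand)) stop_param("contour tracing failed (open boundary)")
    if (length(cand) > 1L) {
      # pinch corner (diagonally touching pixels): take the left turn so the
      # whole 8-connected region stays inside one loop
      dirs <- cbind(E[cand, 3L] - E[cand, 1L], E[cand, 4L] - E[cand, 2L])
      left <- c(-dir[2L], dir[1L])  # left of travel in (row, col), row down
      sc <- dirs %*% left
      cand <- cand[order(-sc)][1L]
    }
    e <- E[cand, ]
    used[cand] <- TRUE
    dir <- c(e[3L] - e[1L], e[4L] - e[2L])
    nv <- nv + 1L
    verts[nv, ] <- c(e[1L], e[2L])
    own[nv] <- cand
    cur <- c(e[3L], e[4L])
    if (cur[1L] == start[1L] && cur[2L] == start[2L]) break
  }
  v <- verts[seq_len(nv), , drop = FALSE] + 0.5  # corner index -> coordinate
  v <- rbind(v, v[1L, ])
  pixels <- cbind(E[own[seq_len(nv)], 5L], E[own[seq_len(nv)], 6L])
  if (polygon_signed_area(v) < 0) {
    v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
    pixels <- pixels[rev(seq_len(nrow(pixels))), , drop = FALSE]
  }
  list(vertices = v, pixels = pixels)
}

#' Extract the outer boundary contour of one labeled region
#'
#' Traces the crack boundary (pixel-edge outline) of a region as a simple
#' closed polygon in (row, col) coordinates, oriented counter-clockwise
#' (positive shoelace area with x = col, y = row). The enclosed area of the
#' polygon equals the region's pixel count when the region has no holes.
#'
#' @param region logical/0-1 matrix containing exactly one connected
#'   component of at least 3 pixels, holes already filled.
#' @return A closed polygon: an (m+1) x 2 matrix of (row, col) vertices with
#'   the first vertex repeated at the end.
#' @export
extract_contour <- function(region) {
  if (sum(region > 0) < 3L)
    stop_param("region must have at least 3 pixels")
  lab <- label_components(region > 0, 8L)
  if (max(lab) != 1L)
    stop_param("region must be a single connected component")
  trace_crack_boundary(region > 0)$vertices
}

#' Resample a closed contour to equally spaced arc-length points
#'
#' Points are placed at arc-length positions `0, L/n, 2L/n, ...` along the
#' polygon, starting from the vertex at maximal distance from the vertex
#' centroid (ties broken by the smaller polar angle about the centroid).
#' Orientation is preserved.
#'
#' @param contour closed or open polygon matrix of (row, col) vertices.
#' @param n_points number of output points (default 50).
#' @return An `n_points` x 2 matrix of (row, col) coordinates (closure
#'   implicit: the last point connects back to the first).
#' @export
resample_contour <- function(contour, n_points = 50L) {
  v <- as.matrix(contour)
  if (nrow(v) >= 2L && all(v[1L, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3L) stop_param("contour must have at least 3 distinct vertices")
  ctr <- colMeans(v)
  d <- sqrt((v[, 1L] - ctr[1L])^2 + (v[, 2L] - ctr[2L])^2)
  if (max(d) <= 0) stop_param("degenerate zero-length contour")
  cand <- which(d >= max(d) * (1 - 1e-9))
  if (length(cand) > 1L) {
    ang <- atan2(-(v[cand, 1L] - ctr[1L]), v[cand, 2L] - ctr[2L])
    cand <- cand[which.min(ang)]
  }
  start <- cand[1L]
  v <- v[c(start:nrow(v), seq_len(start - 1L)), , drop = FALSE]
  vc <- rbind(v, v[1L, ])
  seg <- sqrt(diff(vc[, 1L])^2 + diff(vc[, 2L])^2)
  L <- sum(seg)
  if (L <= 0) stop_param("degenerate zero-length contour")
  s <- c(0, cumsum(seg))
  targets <- (seq_len(n_points) - 1L) * L / n_points
  out <- matrix(0, n_points, 2L)
  k <- 1L
  for (i in seq_len(n_points)) {
    t <- targets[i]
    while (s[k + 1L] < t && k < length(seg)) k <- k + 1L
    f <- if (seg[k] > 0) (t - s[k]) / seg[k] else 0
    out[i, ] <- vc[k, ] + f * (vc[k + 1L, ] - vc[k, ])
  }
  out
}

# Principal-axis angle and axis ratio of a point set (x = col, y = row).
contour_moments <- function(pts) {
  x <- pts[, 2L] - mean(pts[, 2L])
  y <- pts[, 1L] - mean(pts[, 1L])
  cxx <- mean(x * x); cyy <- mean(y * y); cxy <- mean(x * y)
  theta <- 0.5 * atan2(2 * cxy, cxx - cyy)
  tr <- cxx + cyy
  det <- cxx * cyy - cxy^2
  disc <- sqrt(max(0, tr^2 / 4 - det))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  list(theta = theta, l1 = l1, l2 = l2,
       aspect = if (l2 > 0) sqrt(l1 / l2) else Inf)
}

#' Register contours by translation and rotation
#'
#' Each contour is translated to zero centroid and rotated so its
#' second-moment major axis is horizontal; the 180-degree ambiguity is
#' resolved by placing the point farthest from the centroid in the right
#' half-plane (positive column). No scale normalization is applied: shape
#' modes are meant to separate on size as well as shape (a `normalize_scale`
#' switch in [shape_modes()] reduces them to pure shape). Nearly circular
#' contours (no defined axis) are left unrotated. Registration is
#' idempotent.
#'
#' @param contours a list of n x 2 contour matrices (all with the same
#'   number of points), or a single matrix.
#' @return Registered contours of the same form.
#' @export
register_contours <- function(contours) {
  single <- is.matrix(contours)
  lst <- if (single) list(contours) else contours
  out <- lapply(lst, function(v) {
    v <- as.matrix(v)
    v[, 1L] <- v[, 1L] - mean(v[, 1L])
    v[, 2L] <- v[, 2L] - mean(v[, 2L])
    m <- contour_moments(v)
    if (m$l1 > 0 && (m$l1 - m$l2) / m$l1 > 1e-9) {
      th <- -m$theta
      x <- v[, 2L] * cos(th) - v[, 1L] * sin(th)
      y <- v[, 2L] * sin(th) + v[, 1L] * cos(th)
      v <- cbind(y, x)
    }
    d2 <- v[, 1L]^2 + v[, 2L]^2
    if (v[which.max(d2), 2L] < 0) v <- -v  # rotate by 180 degrees
    colnames(v) <- NULL
    v
  })
  if (single) out[[1L]] else out
}
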