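#' Circularity of a region
#'
#' `4 * pi * area / perimeter^2`: 1 for a perfect circle, decreasing toward 0
#' for elongated or branched shapes. Dimensionless, so the unit of area and
#' perimeter cancels as long as both use the same length unit. Values for
#' rasterized shapes can slightly exceed 1 under some perimeter estimators
#' and are reported unclamped.
#'
#' @param area region area (> 0), any length unit squared.
#' @param perimeter region perimeter (> 0), same length unit.
#' @return Circularity value(s); vectorized.
#' @export
circularity <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(!is.finite(perimeter)) ||
      any(area <= 0) || any(perimeter <= 0))
    stop_param("area and perimeter must be positive")
  4 * pi * area / perimeter^2
}

# Pixel-count of the convex hull of a region's pixel centers: lattice centers
# inside (or on) the hull polygon. Collinear regions fall back to their own
# pixel count (solidity 1).
convex_hull_px <- function(rows, cols) {
  pts <- cbind(rows, cols)
  if (nrow(pts) < 3L) return(nrow(pts))
  hull_idx <- grDevices::chull(cols, rows)
  hull <- pts[hull_idx, , drop = FALSE]
  if (nrow(hull) < 3L || abs(polygon_signed_area(hull)) < 1e-12)
    return(nrow(unique(pts)))
  grid <- expand.grid(row = min(rows):max(rows), col = min(cols):max(cols))
  sum(points_in_convex(as.matrix(grid), hull, tol = 1e-9))
}

# Perimeter estimators. "crack": number of exposed pixel edges (each length
# 1). "weighted": length of the ordered boundary-pixel walk, axial steps 1,
# diagonal steps sqrt(2).
perimeter_crack <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- binary > 0
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  sum(core & !pad[1:nr, 2:(nc + 1L)]) + sum(core & !pad[3:(nr + 2L), 2:(nc + 1L)]) +
    sum(core & !pad[2:(nr + 1L), 1:nc]) + sum(core & !pad[2:(nr + 1L), 3:(nc + 2L)])
}

perimeter_weighted <- function(binary) {
  tr <- trace_crack_boundary(binary > 0)
  px <- tr$pixels
  keep <- c(TRUE, rowSums(abs(diff(px))) > 0)
  px <- px[keep, , drop = FALSE]
  n <- nrow(px)
  if (n < 2L) return(0)
  if (all(px[n, ] == px[1L, ])) { px <- px[-n, , drop = FALSE]; n <- n - 1L }
  if (n < 2L) return(0)
  steps <- sqrt(rowSums((px[c(2:n, 1L), , drop = FALSE] - px)^2))
  sum(steps)
}

#' Measure geometric features of every cell in a labeled mask
#'
#' For each label: pixel area (and area in um^2 from the mask's pixel
#' scale), perimeter, circularity (`4*pi*A/P^2`), solidity (pixel count over
#' convex-hull pixel count), aspect ratio (major over minor axis of the
#' second-central-moment best-fit ellipse, with the 1/12 per-pixel variance
#' term so single-pixel-wide regions stay finite), and centroid. Regions of
#' fewer than 3 pixels cannot form a hull; they are flagged `degenerate` and
#' should be excluded from downstream statistics (the count of such regions
#' is attached as attribute `n_degenerate`).
#'
#' @param mask a `labeled_mask` from [segment()]/[clean_mask()], or an
#'   integer label matrix.
#' @param image optional [micrograph()] supplying metadata and pixel scale
#'   when `mask` is a bare matrix.
#' @param perimeter `"weighted"` (default) or `"crack"`, see [seg_config()].
#' @return A data.frame with one row per cell, columns `image_id`, `label`,
#'   `area_px`, `area_um2`, `perimeter_px`, `circularity`, `solidity`,
#'   `aspect_ratio`, `centroid_row`, `centroid_col`, `degenerate`.
#' @export
measure_cells <- function(mask, image = NULL, perimeter = c("weighted", "crack")) {
  perimeter <- match.arg(perimeter)
  lab <- if (inherits(mask, "labeled_mask")) mask$labels else mask
  px_per_um <- if (inherits(mask, "labeled_mask")) mask$px_per_um
               else if (!is.null(image)) image$px_per_um else 1
  meta <- if (inherits(mask, "labeled_mask")) mask$meta
          else if (!is.null(image)) image$meta else list()
  image_id <- if (!is.null(meta$image_id)) meta$image_id else NA_character_
  labels <- setdiff(sort(unique(as.vector(lab))), 0L)
  nr <- nrow(lab)
  rec <- vector("list", length(labels))
  n_degen <- 0L
  for (k in seq_along(labels)) {
    l <- labels[k]
    pos <- which(lab == l)
    rows <- (pos - 1L) %% nr + 1L
    cols <- (pos - 1L) %/% nr + 1L
    a <- length(pos)
    degenerate <- a < 3L
    if (degenerate) {
      n_degen <- n_degen + 1L
      rec[[k]] <- data.frame(image_id = image_id, label = l, area_px = a,
                             area_um2 = a / px_per_um^2, perimeter_px = NA_real_,
                             circularity = NA_real_, solidity = NA_real_,
                             aspect_ratio = NA_real_,
                             centroid_row = mean(rows), centroid_col = mean(cols),
                             degenerate = TRUE)
      next
    }
    sub <- matrix(FALSE, max(rows) - min(rows) + 3L, max(cols) - min(cols) + 3L)
    sub[cbind(rows - min(rows) + 2L, cols - min(cols) + 2L)] <- TRUE
    per <- if (perimeter == "crack") perimeter_crack(sub) else perimeter_weighted(sub)
    hull_px <- convex_hull_px(rows, cols)
    # second central moments with the unit-pixel variance term
    cxx <- stats::var(cols) * (a - 1) / a + 1 / 12
    cyy <- stats::var(rows) * (a - 1) / a + 1 / 12
    cxy <- stats::cov(cols, rows) * (a - 1) / a
    tr2 <- (cxx + cyy) / 2
    disc <- sqrt(max(0, tr2^2 - (cxx * cyy - cxy^2)))
    ar <- sqrt((tr2 + disc) / max(tr2 - disc, .Machine$double.eps))
    rec[[k]] <- data.frame(image_id = image_id, label = l, area_px = a,
                           area_um2 = a / px_per_um^2, perimeter_px = per,
                           circularity = if (per > 0) circularity(a, per) else NA_real_,
                           solidity = a / hull_px,
                           aspect_ratio = ar,
                           centroid_row = mean(rows), centroid_col = mean(cols),
                           degenerate = FALSE)
  }
  out <- if (length(rec)) do.call(rbind, rec) else
    data.frame(image_id = character(), label = integer(), area_px = integer(),
               area_um2 = numeric(), perimeter_px = numeric(),
               circularity = numeric(), solidity = numeric(),
               aspect_ratio = numeric(), centroid_row = numeric(),
               centroid_col = numeric(), degenerate = logical())
  rownames(out) <- NULL
  attr(out, "n_degenerate") <- n_degen
  attr(out, "px_per_um") <- px_per_um
  out
}

#' Extract every cell's outer boundary contour from a labeled mask
#'
#' @param mask a `labeled_mask` or integer label matrix (holes filled).
#' @param min_px labels with fewer pixels are skipped.
#' @return Named list (by label) of closed crack-boundary polygons.
#' @export
cell_contours <- function(mask, min_px = 3L) {
  lab <- if (inherits(mask, "labeled_mask")) mask$labels else mask
  labels <- setdiff(sort(unique(as.vector(lab))), 0L)
  nr <- nrow(lab)
  out <- list()
  for (l in labels) {
    pos <- which(lab == l)
    if (length(pos) < min_px) next
    rows <- (pos - 1L) %% nr + 1L
    cols <- (pos - 1L) %/% nr + 1L
    sub <- matrix(FALSE, max(rows) - min(rows) + 3L, max(cols) - min(cols) + 3L)
    sub[cbind(rows - min(rows) + 2L, cols - min(cols) + 2L)] <- TRUE
    v <- trace_crack_boundary(sub)$vertices
    v[, 1L] <- v[, 1L] + min(rows) - 2L
    v[, 2L] <- v[, 2L] + min(cols) - 2L
    out[[as.character(l)]] <- v
  }
  out
}

#' Cell density of a labeled mask
#'
#' Cell count divided by the field area, the quantification used for
#' immunofluorescence cell counting (cells counted and averaged to the area
#' of the region of interest). Density is reported per mm^2 by default;
#' counts per um^2 for single cells in a confocal field are vanishingly
#' small numbers.
#'
#' @param mask a `labeled_mask` or integer label matrix.
#' @param field_area area of the field in `unit`; default: the full raster
#'   area converted with the mask's pixel scale.
#' @param unit `"mm2"`, `"um2"` or `"px2"`.
#' @param region optional region-of-interest name carried into the record.
#' @return A one-row data.frame: `image_id`, `region`, `n_cells`,
#'   `field_area`, `unit`, `density`.
#' @export
cell_density <- function(mask, field_area = NULL, unit = c("mm2", "um2", "px2"),
                         region = NA_character_) {
  unit <- match.arg(unit)
  lab <- if (inherits(mask, "labeled_mask")) mask$labels else mask
  px_per_um <- if (inherits(mask, "labeled_mask")) mask$px_per_um else 1
  meta <- if (inherits(mask, "labeled_mask")) mask$meta else list()
  if (is.null(field_area)) {
    area_px <- nrow(lab) * ncol(lab)
    field_area <- switch(unit,
      px2 = area_px,
      um2 = area_px / px_per_um^2,
      mm2 = area_px / px_per_um^2 / 1e6)
  }
  if (!is.numeric(field_area) || field_area <= 0)
    stop_param("field_area must be positive")
  n <- n_cells(lab)
  data.frame(image_id = if (!is.null(meta$image_id)) meta$image_id else NA_character_,
             region = region, n_cells = n, field_area = field_area,
             unit = unit, density = n / field_area)
}

#' Mean area covered per cell
#'
#' The arithmetic mean of per-cell areas in um^2, used to separate amoeboid
#' (compact, smaller footprint per cell at high density) from ramified
#' morphology at the population level.
#'
#' @param records data.frame from [measure_cells()].
#' @return Mean of `area_um2` over non-degenerate cells.
#' @export
mean_area_per_cell <- function(records) {
  ok <- records[!records$degenerate, , drop = FALSE]
  if (!nrow(ok)) stop_param("no non-degenerate cells to average")
  mean(ok$area_um2)
}
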