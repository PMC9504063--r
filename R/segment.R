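#' Segmentation configuration
#'
#' Defaults reproduce the reference pipeline: a light Gaussian blur
#' (sigma 0.25 px), the mean threshold, removal of objects smaller than
#' 800 um^2 (265 px at 0.575 px/um), hole filling, and clearing of cells that
#' touch the image border. 8-connectivity keeps thin diagonal microglial
#' branches attached to their soma.
#'
#' @param blur_sigma_px Gaussian blur sigma in pixels (>= 0).
#' @param threshold_method one of the methods of [threshold_value()].
#' @param min_cell_area_um2 minimum object area in square micrometers.
#' @param connectivity pixel connectivity for component labeling, 4 or 8.
#' @param perimeter perimeter estimator used downstream by
#'   [measure_cells()]: `"weighted"` (boundary-pixel walk, diagonal steps
#'   count sqrt(2)) or `"crack"` (count of exposed pixel edges).
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(blur_sigma_px = 0.25, threshold_method = "mean",
                       min_cell_area_um2 = 800, connectivity = 8,
                       perimeter = c("weighted", "crack")) {
  if (blur_sigma_px < 0) stop_param("blur_sigma_px must be >= 0")
  if (min_cell_area_um2 <= 0) stop_param("min_cell_area_um2 must be > 0")
  if (!connectivity %in% c(4, 8)) stop_param("connectivity must be 4 or 8")
  structure(list(blur_sigma_px = blur_sigma_px,
                 threshold_method = match.arg(threshold_method, THRESHOLD_METHODS),
                 min_cell_area_um2 = min_cell_area_um2,
                 connectivity = as.integer(connectivity),
                 perimeter = match.arg(perimeter)),
            class = "seg_config")
}

#' Convert an area in square micrometers to a pixel-count cutoff
#'
#' The small-object cutoff is physical: an area in um^2 times the square of
#' the pixel scale, rounded half up (800 um^2 at 0.575 px/um gives
#' 800 * 0.575^2 = 264.5, i.e. a 265-px cutoff).
#'
#' @param area_um2 area in square micrometers, > 0.
#' @param px_per_um pixel scale, > 0.
#' @return Integer pixel count, >= 1.
#' @export
px_threshold_from_um2 <- function(area_um2, px_per_um) {
  if (!is.numeric(area_um2) || length(area_um2) != 1L || area_um2 <= 0)
    stop_param("area_um2 must be a positive scalar")
  if (!is.numeric(px_per_um) || length(px_per_um) != 1L || px_per_um <= 0)
    stop_param("px_per_um must be a positive scalar")
  # guard the half-up rule against floating-point droop (800 * 0.575^2 is
  # 264.5 mathematically but fractionally below it in doubles)
  max(1L, as.integer(round_half_up(round(area_um2 * px_per_um^2, 9))))
}

# Connected-component labeling. EBImage::bwlabel is 4-connected; for
# 8-connectivity, labels that touch diagonally are merged with a union-find
# pass. Components are renumbered 1..n in raster-scan (reading) order.
label_components <- function(binary, connectivity = 8L) {
  lab <- EBImage::bwlabel(matrix(as.numeric(binary), nrow(binary)))
  lab <- matrix(as.integer(lab), nrow(binary))
  n <- max(lab)
  if (n == 0L) return(lab)
  if (connectivity == 8L && n > 1L) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]   # down-right diagonal
    a2 <- lab[-1L, -nc]; b2 <- lab[-nr, -1L]   # up-right diagonal
    prs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
    prs <- prs[prs[, 1L] > 0L & prs[, 2L] > 0L & prs[, 1L] != prs[, 2L], , drop = FALSE]
    if (nrow(prs)) {
      prs <- unique(prs)
      for (i in seq_len(nrow(prs))) {
        ra <- find(prs[i, 1L]); rb <- find(prs[i, 2L])
        if (ra != rb) parent[rb] <- ra
      }
      roots <- vapply(seq_len(n), find, integer(1))
      lab[lab > 0L] <- roots[lab[lab > 0L]]
    }
  }
  relabel_raster_order(lab)
}

# Renumber positive labels 1..n by first appearance in reading order
# (row-major scan).
relabel_raster_order <- function(lab) {
  pos <- which(lab > 0L)
  if (!length(pos)) return(lab)
  nr <- nrow(lab)
  rows <- (pos - 1L) %% nr + 1L
  cols <- (pos - 1L) %/% nr + 1L
  reading <- (rows - 1L) * ncol(lab) + cols
  firsts <- tapply(reading, lab[pos], min)
  old <- as.integer(names(firsts))[order(firsts)]
  map <- integer(max(lab))
  map[old] <- seq_along(old)
  lab[pos] <- map[lab[pos]]
  lab
}

new_labeled_mask <- function(labels, provenance, px_per_um, meta = list()) {
  structure(list(labels = labels, provenance = provenance,
                 px_per_um = px_per_um, meta = meta),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("labeled_mask: %d x %d px, %d cells\n",
              nrow(x$labels), ncol(x$labels), max(x$labels)))
  p <- x$provenance
  if (length(p))
    cat(sprintf("  blur sigma %.3g | %s threshold %.5g | min area %d px | border cleared: %s\n",
                p$blur_sigma, p$threshold_method, p$threshold_value,
                p$min_area_px, p$border_cleared))
  invisible(x)
}

#' Number of cells in a labeled mask
#' @param mask a `labeled_mask` or an integer label matrix.
#' @return Count of distinct positive labels.
#' @export
n_cells <- function(mask) {
  lab <- if (inherits(mask, "labeled_mask")) mask$labels else mask
  length(setdiff(unique(as.vector(lab)), 0L))
}

#' Clean a binary mask into labeled cells
#'
#' Applies, in this order: (1) removal of components smaller than the
#' physically derived pixel cutoff, (2) filling of enclosed background holes,
#' (3) removal of components touching the raster border (partial cells at
#' the field edge distort shape statistics). Remaining components are
#' labeled 1..n in reading order. The order matters: a sub-threshold ring is
#' removed before hole filling could inflate it past the cutoff.
#'
#' @param binary logical (or 0/1) matrix, foreground = cell signal.
#' @param config a [seg_config()].
#' @param px_per_um pixel scale used to derive the pixel cutoff.
#' @return A `labeled_mask` (provenance partially filled; [segment()]
#'   completes it).
#' @export
clean_mask <- function(binary, config = seg_config(), px_per_um = 0.575) {
  cutoff <- px_threshold_from_um2(config$min_cell_area_um2, px_per_um)
  lab <- label_components(binary > 0, config$connectivity)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L], max(lab))
    keep <- which(areas >= cutoff)
    lab[!(lab %in% keep)] <- 0L
    if (max(lab) > 0L) {
      filled <- EBImage::fillHull(matrix(as.numeric(lab > 0L), nrow(lab)))
      lab <- label_components(filled > 0, config$connectivity)
      border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
      border <- border[border > 0L]
      if (length(border)) lab[lab %in% border] <- 0L
      lab <- relabel_raster_order(lab)
    }
  }
  new_labeled_mask(lab,
                   provenance = list(blur_sigma = NA_real_,
                                     threshold_method = NA_character_,
                                     threshold_value = NA_real_,
                                     min_area_px = cutoff,
                                     border_cleared = TRUE,
                                     connectivity = config$connectivity),
                   px_per_um = px_per_um)
}

#' Segment a micrograph into labeled cells
#'
#' The full threshold segmentation pipeline: Gaussian blur, global threshold
#' (mean by default), strict binarization, then [clean_mask()] (size filter,
#' hole fill, border clearing). Provenance of every stage is recorded on the
#' returned mask.
#'
#' @param image a [micrograph()].
#' @param config a [seg_config()].
#' @return A `labeled_mask` aligned to `image`.
#' @export
segment <- function(image, config = seg_config()) {
  if (!inherits(image, "micrograph")) stop_param("image must be a micrograph")
  blurred <- gaussian_blur(image, config$blur_sigma_px)
  thr <- threshold_value(blurred, config$threshold_method)
  mask <- clean_mask(binarize(blurred, thr), config, image$px_per_um)
  mask$provenance$blur_sigma <- config$blur_sigma_px
  mask$provenance$threshold_method <- config$threshold_method
  mask$provenance$threshold_value <- thr
  mask$meta <- image$meta
  mask
}
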