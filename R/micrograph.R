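#' Construct a micrograph
#'
#' A micrograph couples a 2-D intensity raster with its pixel-to-micrometer
#' scale and acquisition metadata. Pixel values are non-negative reals;
#' fluorescence images read from TIFF are scaled to \[0, 1\].
#'
#' @param pixels numeric matrix of intensities (rows = image rows).
#' @param px_per_um pixels per micrometer (default 0.575, the 63x confocal
#'   calibration this pipeline was built around).
#' @param meta named list of acquisition metadata (genotype, sex, age_label,
#'   region, image_id); free-form, carried through to feature tables.
#' @return An object of class `micrograph`.
#' @export
micrograph <- function(pixels, px_per_um = 0.575, meta = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_param("pixels must be a numeric matrix")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop_param("micrograph must be at least 2x2 pixels")
  if (!is.numeric(px_per_um) || length(px_per_um) != 1L || px_per_um <= 0)
    stop_param("px_per_um must be a positive scalar")
  if (any(pixels < 0)) stop_param("pixel intensities must be >= 0")
  structure(list(pixels = pixels, px_per_um = px_per_um, meta = meta),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("micrograph: %d x %d px (%.1f x %.1f um at %.3f px/um)\n",
              nrow(x$pixels), ncol(x$pixels),
              nrow(x$pixels) / x$px_per_um, ncol(x$pixels) / x$px_per_um,
              x$px_per_um))
  if (length(x$meta))
    cat("meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$pixels)

#' Read a micrograph from TIFF
#'
#' Multi-channel (RGB) images are reduced to the stained channel rather than
#' to luminance: fluorescence channels are independent signals, not color
#' mixtures. Iba-1 staining is conventionally imaged in green.
#'
#' @param path TIFF file path.
#' @param px_per_um pixel scale.
#' @param channel channel to keep for multi-channel input: `"green"`
#'   (default), `"red"`, `"blue"`, or a channel index.
#' @param meta metadata list, as in [micrograph()].
#' @return A [micrograph()].
#' @export
read_micrograph <- function(path, px_per_um = 0.575, channel = "green",
                            meta = list()) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) {
    idx <- if (is.character(channel))
      match(match.arg(channel, c("red", "green", "blue")), c("red", "green", "blue"))
    else as.integer(channel)
    if (is.na(idx) || idx < 1L || idx > dim(px)[3L])
      stop_param("channel ", channel, " not present in ", path)
    px <- px[, , idx]
  }
  if (is.null(meta$image_id)) meta$image_id <- sub("\\.[^.]*$", "", basename(path))
  micrograph(px, px_per_um = px_per_um, meta = meta)
}

#' Write a micrograph to 16-bit grayscale TIFF
#'
#' @param image a [micrograph()] with intensities in \[0, 1\].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(image, path) {
  px <- image$pixels
  if (max(px) > 1) stop_param("intensities must be in [0, 1] for TIFF export")
  tiff::writeTIFF(px, path, bits.per.sample = 16L)
  invisible(path)
}

# Label rasters round-trip through 16-bit TIFF as label/65535.
write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535L) stop_param("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
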