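# Global threshold selection. The default pipeline uses the mean threshold;
# the remaining six methods exist for the try-all comparison panel that
# motivated that choice. Histogram-based methods work on a 256-bin histogram
# spanning the image range; the returned threshold is a bin-center intensity.
# Binarization is strict: pixel > threshold -> foreground.

THRESHOLD_METHODS <- c("isodata", "li", "mean", "minimum", "otsu", "triangle", "yen")

#' Compute a global threshold
#'
#' @param image a [micrograph()] or numeric matrix.
#' @param method one of `"isodata"`, `"li"`, `"mean"`, `"minimum"`, `"otsu"`,
#'   `"triangle"`, `"yen"`. The mean method is the arithmetic mean of all
#'   pixel intensities; the rest are the standard histogram algorithms.
#' @return A single threshold value; pixels strictly above it are foreground.
#' @export
threshold_value <- function(image, method = "mean") {
  method <- match.arg(method, THRESHOLD_METHODS)
  x <- if (inherits(image, "micrograph")) image$pixels else image
  if (method == "mean") return(mean(x))
  rng <- range(x)
  if (rng[1] == rng[2])
    stop_param("constant image: ", method, " threshold is undefined")
  nb <- 256L
  breaks <- seq(rng[1], rng[2], length.out = nb + 1L)
  h <- tabulate(pmin(nb, findInterval(x, breaks, rightmost.closed = TRUE)), nb)
  centers <- (breaks[-1L] + breaks[-(nb + 1L)]) / 2
  switch(method,
    otsu     = {
      i <- thr_otsu_bin(h, centers)
      # midpoint between the two classes: strict x > threshold then
      # reproduces the optimal split exactly
      bins <- pmin(nb, findInterval(x, breaks, rightmost.closed = TRUE))
      (max(x[bins <= i]) + min(x[bins > i])) / 2
    },
    isodata  = thr_isodata(h, centers),
    li       = thr_li(x),
    minimum  = thr_minimum(h, centers),
    triangle = thr_triangle(h, centers),
    yen      = thr_yen(h, centers))
}

# index of the last bin of the low class maximizing between-class variance
thr_otsu_bin <- function(h, centers) {
  p <- h / sum(h)
  w1 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[length(mu)]
  w2 <- 1 - w1
  ok <- w1 > 0 & w2 > 0
  bcv <- rep(-Inf, length(h))
  bcv[ok] <- (mu_t * w1[ok] - mu[ok])^2 / (w1[ok] * w2[ok])
  which.max(bcv)
}

thr_isodata <- function(h, centers) {
  t <- sum(h * centers) / sum(h)
  for (i in 1:200) {
    lo <- centers <= t
    if (!any(h[lo]) || !any(h[!lo])) break
    t_new <- (sum(h[lo] * centers[lo]) / sum(h[lo]) +
              sum(h[!lo] * centers[!lo]) / sum(h[!lo])) / 2
    if (abs(t_new - t) < 1e-12) { t <- t_new; break }
    t <- t_new
  }
  t
}

# Li & Tam minimum cross-entropy iteration on raw intensities.
thr_li <- function(x) {
  shift <- if (min(x) <= 0) -min(x) + 1e-6 else 0
  v <- as.numeric(x) + shift
  t <- mean(v)
  for (i in 1:200) {
    lo <- v <= t
    if (!any(lo) || all(lo)) break
    m1 <- mean(v[lo]); m2 <- mean(v[!lo])
    t_new <- (m1 - m2) / (log(m1) - log(m2))
    if (!is.finite(t_new)) break
    if (abs(t_new - t) < 1e-9) { t <- t_new; break }
    t <- t_new
  }
  t - shift
}

# Smooth the histogram until bimodal; threshold at the valley between the
# two remaining maxima (Prewitt & Mendelsohn's minimum method).
thr_minimum <- function(h, centers) {
  sm <- as.numeric(h)
  n <- length(sm)
  n_max <- function(y) {
    prev <- c(-Inf, y[-n]); nxt <- c(y[-1L], -Inf)
    which(y > prev & y >= nxt)
  }
  for (i in 1:10000) {
    peaks <- n_max(sm)
    if (length(peaks) <= 2L) break
    sm <- (c(sm[1L], sm[-n]) + sm + c(sm[-1L], sm[n])) / 3
  }
  peaks <- n_max(sm)
  if (length(peaks) < 2L)
    stop_param("minimum threshold: histogram never became bimodal")
  seg <- sm[peaks[1L]:peaks[2L]]
  centers[peaks[1L] + which.min(seg) - 1L]
}

# Zack, Rogers & Latt: the bin maximizing distance from the line joining the
# histogram peak to the far tail end.
thr_triangle <- function(h, centers) {
  pk <- which.max(h)
  nz <- which(h > 0)
  lo <- nz[1L]; hi <- nz[length(nz)]
  # use the longer tail
  if ((pk - lo) < (hi - pk)) { a <- pk; b <- hi } else { a <- hi; b <- lo }
  xs <- seq(a, b, by = if (b >= a) 1L else -1L)
  x1 <- a; y1 <- h[a]; x2 <- b; y2 <- h[b]
  d <- abs((y2 - y1) * xs - (x2 - x1) * h[xs] + x2 * y1 - y2 * x1)
  centers[xs[which.max(d)]]
}

thr_yen <- function(h, centers) {
  p <- h / sum(h)
  p1 <- cumsum(p)
  p1sq <- cumsum(p^2)
  p2sq <- p1sq[length(p1sq)] - p1sq
  ok <- p1 > 0 & p1 < 1 & p1sq > 0 & p2sq > 0
  crit <- rep(-Inf, length(h))
  crit[ok] <- log(p1sq[ok] * p2sq[ok] / (p1[ok]^2 * (1 - p1[ok])^2))
  centers[which.max(-crit)]
}

#' Binarize at a threshold
#'
#' Strict comparison: pixels greater than the threshold are foreground, so a
#' constant image yields an empty mask under its own mean.
#'
#' @param image a [micrograph()] or numeric matrix.
#' @param threshold threshold value.
#' @return Logical matrix.
#' @export
binarize <- function(image, threshold) {
  x <- if (inherits(image, "micrograph")) image$pixels else image
  x > threshold
}

#' Try-all-thresholds comparison panel
#'
#' Runs every supported threshold method on one image, for the qualitative
#' side-by-side comparison used to select a segmentation method. Methods that
#' are undefined on the image (e.g. histogram methods on a constant raster)
#' are annotated rather than raised.
#'
#' @param image a [micrograph()] or numeric matrix.
#' @param file optional PNG path; when given, the original image plus each
#'   method's binary mask are drawn side by side.
#' @return A named list, one entry per method, each with elements
#'   `threshold`, `mask` (logical matrix) and `error` (string or `NA`).
#' @export
threshold_panel <- function(image, file = NULL) {
  x <- if (inherits(image, "micrograph")) image$pixels else image
  out <- lapply(THRESHOLD_METHODS, function(m) {
    t <- tryCatch(threshold_value(x, m), error = function(e) e)
    if (inherits(t, "error"))
      list(threshold = NA_real_, mask = NULL, error = conditionMessage(t))
    else
      list(threshold = t, mask = x > t, error = NA_character_)
  })
  names(out) <- THRESHOLD_METHODS
  if (!is.null(file)) {
    grDevices::png(file, width = 1600, height = 800)
    on.exit(grDevices::dev.off())
    op <- graphics::par(mfrow = c(2, 4), mar = c(1, 1, 2, 1))
    on.exit(graphics::par(op), add = TRUE)
    draw <- function(m, title) {
      graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                      col = grDevices::gray.colors(256, 0, 1),
                      axes = FALSE, main = title)
    }
    draw(x / max(max(x), 1e-12), "original")
    for (m in THRESHOLD_METHODS) {
      e <- out[[m]]
      if (is.null(e$mask)) {
        graphics::plot.new(); graphics::title(main = paste(m, "-", e$error))
      } else draw(e$mask * 1, sprintf("%s (t=%.4g)", m, e$threshold))
    }
  }
  out
}
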