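# Boundary shape-mode modeling: every cell outline is resampled to a fixed
# number of equal-arc points, registered (translation + rotation, optionally
# scale), embedded by PCA, and clustered by k-means into k shape modes (SMs).
# The model is fitted on a training split and applied to held-out cells.

#' Stratified train/test split
#'
#' Disjoint, exhaustive split with about `train_fraction` of each group in
#' the training set (per-group size `round(train_fraction * n_g)`). Groups
#' with fewer than 2 members go wholly to the test set (with a message).
#'
#' @param ids vector of cell identifiers.
#' @param groups optional grouping factor for stratification (one global
#'   split when omitted).
#' @param train_fraction fraction of each group to train on (default 0.8).
#' @param seed integer seed; the same seed reproduces the same split.
#' @return `list(train = ids, test = ids)`.
#' @export
split_train_test <- function(ids, groups = NULL, train_fraction = 0.8, seed = 1L) {
  n <- length(ids)
  if (n < 5L) stop_param("need at least 5 cells to split")
  if (is.null(groups)) groups <- rep("all", n)
  if (length(groups) != n) stop_param("groups must match ids in length")
  train <- logical(n)
  idx_by_g <- split(seq_len(n), groups)
  seeds <- derive_seeds(seed, length(idx_by_g))
  for (gi in seq_along(idx_by_g)) {
    idx <- idx_by_g[[gi]]
    if (length(idx) < 2L) {
      message("group '", names(idx_by_g)[gi], "' has < 2 cells; assigned to test")
      next
    }
    n_train <- as.integer(round_half_up(train_fraction * length(idx)))
    n_train <- min(max(n_train, 1L), length(idx) - 1L)
    pick <- with_seed(seeds[gi], sample(idx, n_train))
    train[pick] <- TRUE
  }
  list(train = ids[train], test = ids[!train])
}

# flatten a registered n x 2 contour into a length-2n vector (rows, cols)
flatten_contour <- function(v) c(v[, 1L], v[, 2L])
unflatten_contour <- function(x) {
  n <- length(x) / 2L
  cbind(x[seq_len(n)], x[n + seq_len(n)])
}

prepare_contours <- function(contours, n_points, normalize_scale) {
  reg <- register_contours(lapply(contours, resample_contour, n_points = n_points))
  if (normalize_scale)
    reg <- lapply(reg, function(v) v / sqrt(mean(v[, 1L]^2 + v[, 2L]^2)))
  do.call(rbind, lapply(reg, flatten_contour))
}

# Contours as centered complex vectors (point j = col_j + i * row_j), the
# natural currency for planar Procrustes alignment.
contours_to_complex <- function(contours, n_points, normalize_scale) {
  lapply(contours, function(v) {
    w <- register_contours(resample_contour(v, n_points = n_points))
    z <- complex(real = w[, 2L], imaginary = w[, 1L])
    if (normalize_scale) z <- z / sqrt(mean(Mod(z)^2))
    z
  })
}

complex_to_contour <- function(z) cbind(Im(z), Re(z))

# Full planar Procrustes alignment of one contour to a reference: search all
# cyclic point shifts, each with its closed-form optimal rotation
# (translation already removed, scale never touched). The initial
# major-axis registration is ambiguous for near-symmetric (e.g. 4-branch)
# outlines; this alignment establishes point correspondence so that PCA
# variance reflects shape, not registration phase.
procrustes_align <- function(z, ref) {
  n <- length(z)
  best <- z; bd <- -Inf
  for (s in 0:(n - 1L)) {
    zs <- z[(s:(n + s - 1L)) %% n + 1L]
    cr <- sum(ref * Conj(zs))
    if (Mod(cr) > bd) { bd <- Mod(cr); best <- zs * (cr / Mod(cr)) }
  }
  best
}

# Iteratively align a set of contours to their evolving mean shape.
# Returns the aligned set and the final reference.
procrustes_align_set <- function(Z, ref = NULL, iterations = 4L) {
  if (is.null(ref)) ref <- Z[[1L]]
  for (it in seq_len(iterations)) {
    Z <- lapply(Z, procrustes_align, ref = ref)
    ref <- Reduce(`+`, Z) / length(Z)
  }
  Z <- lapply(Z, procrustes_align, ref = ref)
  list(Z = Z, ref = ref)
}

# k-means++ seeding: spread initial centers with probability proportional to
# squared distance from the nearest already-chosen center.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    i <- sample.int(n, 1L, prob = p)
    centers[j + 1L, ] <- X[i, ]
    d2 <- pmin(d2, rowSums((X - matrix(X[i, ], n, ncol(X), byrow = TRUE))^2))
  }
  centers
}

#' Fit a shape-mode model to cell boundary contours
#'
#' Contours are resampled to `n_points` equal-arc points, registered
#' (translation and rotation; see [register_contours()]), then brought into
#' point correspondence by iterative Procrustes alignment to the mean shape
#' (all cyclic start-point shifts, each with its closed-form optimal
#' rotation; scale untouched) -- without this, registration phase rather
#' than shape dominates the variance for branched outlines. The aligned
#' contours are stacked as `2*n_points`-dimensional vectors and
#' mean-centered. PCA retains the
#' smallest number of leading components reaching `variance_kept` cumulative
#' explained variance, and k-means (k-means++ seeding, `restarts` restarts,
#' best within-cluster sum of squares kept) partitions the retained PC
#' scores into `k` shape modes. Modes are renumbered by increasing mean
#' aspect ratio of their member contours so SM labels are stable across
#' runs; an average-linkage dendrogram over the mode centroids records their
#' relatedness.
#'
#' @param contours list of closed boundary polygons (e.g. from
#'   [cell_contours()]), or already-resampled contour matrices.
#' @param k number of shape modes (default 5).
#' @param n_points contour points per cell (default 50).
#' @param seed integer seed controlling k-means restarts.
#' @param variance_kept cumulative explained-variance cutoff for the PCA
#'   embedding (default 0.95).
#' @param normalize_scale divide each registered contour by its RMS radius,
#'   making modes size-invariant (default `FALSE`: size stays informative).
#' @param restarts k-means restarts (default 50).
#' @return An object of class `shape_mode_model`.
#' @seealso [predict.shape_mode_model()], [sm_frequency()]
#' @export
shape_modes <- function(contours, k = 5L, n_points = 50L, seed = 1L,
                        variance_kept = 0.95, normalize_scale = FALSE,
                        restarts = 50L) {
  n <- length(contours)
  if (n < k) stop_param("fewer contours (", n, ") than shape modes (", k, ")")
  if (n < 5L * k)
    warning("training set smaller than 5 cells per shape mode", call. = FALSE)
  Z <- contours_to_complex(contours, n_points, normalize_scale)
  al <- procrustes_align_set(Z)
  X <- do.call(rbind, lapply(al$Z, function(z) flatten_contour(complex_to_contour(z))))
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  evar <- pca$sdev^2 / sum(pca$sdev^2)
  m <- which(cumsum(evar) >= variance_kept)[1L]
  if (is.na(m)) m <- length(evar)
  m <- max(m, min(2L, length(evar)))
  # canonicalize component signs (largest-magnitude loading positive):
  # eigenvector sign is arbitrary and would otherwise leak into centroids
  for (j in seq_len(m)) {
    v <- pca$rotation[, j]
    if (v[which.max(abs(v))] < 0) {
      pca$rotation[, j] <- -v
      pca$x[, j] <- -pca$x[, j]
    }
  }
  scores <- pca$x[, seq_len(m), drop = FALSE]

  best <- NULL
  seeds <- derive_seeds(seed, restarts)
  for (r in seq_len(restarts)) {
    km <- with_seed(seeds[r], {
      init <- kmeanspp_centers(scores, k)
      tryCatch(stats::kmeans(scores, centers = init, iter.max = 100L),
               error = function(e) NULL)
    })
    if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
      best <- km
  }
  if (is.null(best)) stop_param("k-means failed on all restarts")

  # stable mode identity: renumber clusters by increasing mean aspect ratio
  aspect <- vapply(seq_len(n), function(i)
    contour_moments(unflatten_contour(X[i, ]))$aspect, numeric(1))
  mean_ar <- vapply(seq_len(k), function(j) mean(aspect[best$cluster == j]), numeric(1))
  ord <- order(mean_ar)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  cluster <- relabel[best$cluster]
  centers <- best$centers[ord, , drop = FALSE]
  rownames(centers) <- paste0("SM", seq_len(k))

  linkage <- if (k > 2L) stats::hclust(stats::dist(centers), method = "average")
             else NULL
  structure(list(
    n_points = as.integer(n_points), k = as.integer(k),
    mean_shape = unflatten_contour(pca$center),
    align_ref = al$ref,
    basis = pca$rotation[, seq_len(m), drop = FALSE],
    explained_variance = evar, n_components_used = m,
    centers = centers, linkage = linkage,
    cluster = cluster, mean_aspect_ratio = sort(mean_ar),
    tot_withinss = best$tot.withinss,
    variance_kept = variance_kept, normalize_scale = normalize_scale,
    seed = as.integer(seed), n_train = n), class = "shape_mode_model")
}

#' Assign shape modes to new contours
#'
#' Projects each contour (resampled and registered exactly as in fitting)
#' onto the model's retained principal components and assigns the shape
#' mode of the nearest centroid (Euclidean distance in PC space; ties go to
#' the lower SM index).
#'
#' @param object a fitted [shape_modes()] model.
#' @param contours list of closed boundary polygons, or contour matrices
#'   with the model's `n_points` points.
#' @param cell_ids optional identifiers (default: names of `contours` or
#'   their indices).
#' @param ... unused.
#' @return A data.frame with columns `cell_id` and `sm`.
#' @export
predict.shape_mode_model <- function(object, contours, cell_ids = NULL, ...) {
  if (!length(contours)) return(data.frame(cell_id = character(), sm = integer()))
  npts <- vapply(contours, nrow, integer(1))
  resampled <- npts == object$n_points
  if (any(!resampled & npts < 3L))
    stop_param("contours must have >= 3 points or exactly n_points = ",
               object$n_points)
  Z <- contours_to_complex(contours, object$n_points, object$normalize_scale)
  Z <- lapply(Z, procrustes_align, ref = object$align_ref)
  X <- do.call(rbind, lapply(Z, function(z) flatten_contour(complex_to_contour(z))))
  scores <- sweep(X, 2L, flatten_contour(object$mean_shape)) %*% object$basis
  d2 <- vapply(seq_len(object$k), function(j)
    rowSums(sweep(scores, 2L, object$centers[j, ])^2), numeric(nrow(scores)))
  d2 <- matrix(d2, nrow = nrow(scores))
  sm <- apply(d2, 1L, which.min)  # which.min takes the first (lower) index on ties
  if (is.null(cell_ids))
    cell_ids <- if (!is.null(names(contours))) names(contours)
                else as.character(seq_along(contours))
  data.frame(cell_id = as.character(cell_ids), sm = as.integer(sm))
}

#' Shape-mode frequency table with row variances
#'
#' Per-group percentages of cells in each shape mode (rows sum to 100) and
#' the sample variance (n-1 denominator, the spreadsheet VAR convention) of
#' each group's k percentages -- high variance means the group concentrates
#' in few modes.
#'
#' @param sm integer shape-mode assignments (or the data.frame returned by
#'   [predict.shape_mode_model()]).
#' @param groups grouping vector aligned to `sm`.
#' @param k number of shape modes (default: max of `sm`).
#' @return `list(freq, variance, n)`: percentage matrix (groups x SMs),
#'   per-group variance, and per-group cell counts.
#' @export
sm_frequency <- function(sm, groups, k = NULL) {
  if (is.data.frame(sm)) sm <- sm$sm
  if (length(sm) != length(groups)) stop_param("sm and groups lengths differ")
  if (is.null(k)) k <- max(sm)
  tab <- table(factor(groups), factor(sm, levels = seq_len(k)))
  n <- rowSums(tab)
  freq <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
                 dimnames = list(rownames(tab), paste0("SM", seq_len(k))))
  freq <- sweep(freq, 1L, pmax(n, 1L), "/") * 100
  list(freq = freq, variance = apply(freq, 1L, stats::var), n = n)
}

#' Join shape-mode assignments with per-cell features
#'
#' Produces the per-SM feature table (perimeter, area, circularity, aspect
#' ratio, solidity) used to characterize what each mode captures, ready for
#' Kruskal-Wallis/Dunn comparisons across modes.
#'
#' @param assignment data.frame from [predict.shape_mode_model()] with
#'   `cell_id` matching `records$cell_id` (or `records$label` as character).
#' @param records feature data.frame from [measure_cells()].
#' @return `records` rows for assigned cells with an `sm` column appended.
#' @export
sm_feature_table <- function(assignment, records) {
  if (!nrow(assignment)) return(cbind(records[0, ], sm = integer()))
  key <- if (!is.null(records$cell_id)) as.character(records$cell_id)
         else as.character(records$label)
  idx <- match(assignment$cell_id, key)
  if (anyNA(idx))
    stop_param("no feature record for cell_id ",
               paste(assignment$cell_id[is.na(idx)], collapse = ", "))
  out <- records[idx, , drop = FALSE]
  out$sm <- assignment$sm
  rownames(out) <- NULL
  out
}

#' @export
print.shape_mode_model <- function(x, ...) {
  cat(sprintf("shape_mode_model: %d modes, %d-point contours, fitted on %d cells\n",
              x$k, x$n_points, x$n_train))
  cat(sprintf("  PCA: %d components retained (%.1f%% variance; cutoff %.0f%%)\n",
              x$n_components_used,
              100 * sum(x$explained_variance[seq_len(x$n_components_used)]),
              100 * x$variance_kept))
  cat(sprintf("  scale %s | seed %d | within-SS %.4g\n",
              if (x$normalize_scale) "normalized" else "retained",
              x$seed, x$tot_withinss))
  invisible(x)
}

#' @export
summary.shape_mode_model <- function(object, ...) {
  cl <- table(factor(object$cluster, levels = seq_len(object$k)))
  out <- data.frame(sm = seq_len(object$k),
                    n_train = as.integer(cl),
                    train_pct = 100 * as.integer(cl) / object$n_train,
                    mean_aspect_ratio = object$mean_aspect_ratio)
  class(out) <- c("summary.shape_mode_model", "data.frame")
  out
}

#' Centroid shapes of the fitted modes
#'
#' Back-projects each k-means centroid from PC space to a contour, i.e. the
#' representative outline of each shape mode.
#'
#' @param object a `shape_mode_model`.
#' @param ... unused.
#' @return List of `n_points` x 2 contour matrices, one per mode.
#' @export
coef.shape_mode_model <- function(object, ...) {
  lapply(seq_len(object$k), function(j) {
    x <- flatten_contour(object$mean_shape) + object$basis %*% object$centers[j, ]
    unflatten_contour(as.numeric(x))
  })
}

#' @export
fitted.shape_mode_model <- function(object, ...) object$cluster

#' Plot a shape-mode model
#'
#' Draws each mode's centroid outline side by side (and the centroid
#' dendrogram when available).
#'
#' @param x a `shape_mode_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.shape_mode_model <- function(x, ...) {
  shapes <- coef(x)
  op <- graphics::par(mfrow = c(1, x$k + as.integer(!is.null(x$linkage))),
                      mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (j in seq_len(x$k)) {
    v <- shapes[[j]]
    v <- rbind(v, v[1L, ])
    graphics::plot(v[, 2L], -v[, 1L], type = "l", asp = 1, axes = FALSE,
                   xlab = "", ylab = "", main = paste0("SM", j), ...)
  }
  if (!is.null(x$linkage)) graphics::plot(x$linkage, main = "centroid linkage",
                                          xlab = "", sub = "")
  invisible(x)
}

#' Serialize a shape-mode model to JSON
#'
#' Writes every numeric component (mean shape, alignment reference, PCA
#' basis and variances, centroids, configuration, seed) to one JSON file;
#' [read_shape_mode_model()] restores a model that assigns identically.
#'
#' @param model a `shape_mode_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_shape_mode_model <- function(model, path) {
  obj <- list(n_points = model$n_points, k = model$k,
              mean_shape = model$mean_shape,
              align_ref = list(re = Re(model$align_ref), im = Im(model$align_ref)),
              basis = model$basis,
              explained_variance = model$explained_variance,
              n_components_used = model$n_components_used,
              centers = model$centers,
              mean_aspect_ratio = model$mean_aspect_ratio,
              tot_withinss = model$tot_withinss,
              variance_kept = model$variance_kept,
              normalize_scale = model$normalize_scale,
              seed = model$seed, n_train = model$n_train)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a shape-mode model from JSON
#'
#' @param path file written by [write_shape_mode_model()].
#' @return A `shape_mode_model` (without the training-only dendrogram and
#'   cluster vector).
#' @export
read_shape_mode_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$mean_shape <- matrix(obj$mean_shape, ncol = 2L)
  obj$align_ref <- complex(real = obj$align_ref$re, imaginary = obj$align_ref$im)
  obj$basis <- matrix(obj$basis, ncol = obj$n_components_used)
  obj$centers <- matrix(obj$centers, nrow = obj$k)
  rownames(obj$centers) <- paste0("SM", seq_len(obj$k))
  obj$linkage <- if (obj$k > 2L) stats::hclust(stats::dist(obj$centers),
                                               method = "average") else NULL
  structure(obj, class = "shape_mode_model")
}

#' Heat-map colors for shape-mode frequencies
#'
#' The conventional 3-color green-white-purple scale anchored at
#' 0 / 18 / 36 percent.
#'
#' @param freq percentage matrix from [sm_frequency()].
#' @param anchors scale anchors in percent.
#' @return Matrix of hex colors shaped like `freq`.
#' @export
sm_heat_colors <- function(freq, anchors = c(0, 18, 36)) {
  ramp <- grDevices::colorRamp(c("#2ca25f", "#ffffff", "#756bb1"))
  z <- pmin(pmax((freq - anchors[1]) / (anchors[3] - anchors[1]), 0), 1)
  cols <- ramp(as.vector(z))
  matrix(grDevices::rgb(cols[, 1], cols[, 2], cols[, 3], maxColorValue = 255),
         nrow(freq), ncol(freq), dimnames = dimnames(freq))
}
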