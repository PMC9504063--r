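# Seeded synthetic micrographs with ground truth. Cells are stamped as an
# elliptical soma plus optional random-walk branches (dilated to a branch
# width), emulating the amoeboid-to-ramified morphology continuum of Iba-1
# stained microglia in 63x confocal fields. Every stage downstream of image
# acquisition can thus be validated against known cell placements, shape
# classes and densities.

#' Specify a synthetic cell shape class
#'
#' @param soma_radius_um equivalent radius of the (elliptical) soma, um.
#' @param n_branches number of processes; 0 gives a pure ellipse (amoeboid).
#' @param branch_length_um length of each process, um.
#' @param branch_width_um full width of each process, um.
#' @param tortuosity 0..1, angular jitter of the branch random walk (0 =
#'   straight rays).
#' @param elongation soma ellipse aspect ratio (>= 1; 1 = circular).
#' @return An object of class `shape_class_spec`.
#' @export
shape_class_spec <- function(soma_radius_um, n_branches = 0L,
                             branch_length_um = 1, branch_width_um = 1,
                             tortuosity = 0.3, elongation = 1) {
  if (soma_radius_um <= 0) stop_param("soma_radius_um must be > 0")
  if (n_branches < 0 || n_branches != round(n_branches))
    stop_param("n_branches must be a non-negative integer")
  if (branch_length_um <= 0) stop_param("branch_length_um must be > 0")
  if (branch_width_um <= 0) stop_param("branch_width_um must be > 0")
  if (tortuosity < 0 || tortuosity > 1) stop_param("tortuosity must be in [0, 1]")
  if (elongation < 1) stop_param("elongation must be >= 1")
  structure(list(soma_radius_um = soma_radius_um,
                 n_branches = as.integer(n_branches),
                 branch_length_um = branch_length_um,
                 branch_width_um = branch_width_um,
                 tortuosity = tortuosity, elongation = elongation),
            class = "shape_class_spec")
}

#' Built-in shape classes
#'
#' `amoeboid_class()`: a compact ellipse of about 1600 um^2 (the literature
#' size of a microglial cell). `ramified_class()`: a smaller soma with four
#' tortuous processes, about 1300 um^2 total.
#' @param elongation soma aspect ratio.
#' @rdname builtin_classes
#' @export
amoeboid_class <- function(elongation = 1.2)
  shape_class_spec(soma_radius_um = 22.6, n_branches = 0L, elongation = elongation)

#' @rdname builtin_classes
#' @export
ramified_class <- function()
  shape_class_spec(soma_radius_um = 16, n_branches = 4L, branch_length_um = 28,
                   branch_width_um = 6, tortuosity = 0.3, elongation = 1.1)

#' Rasterize one synthetic cell
#'
#' Draws the soma ellipse at a random orientation, then grows each branch as
#' a unit-step random walk from the soma boundary (initial direction radial,
#' per-step heading jitter proportional to `tortuosity`), dilating the walk
#' to the branch width. The stamp is a single 8-connected component.
#' Deterministic for a fixed seed.
#'
#' @param spec a [shape_class_spec()].
#' @param px_per_um pixel scale (default 0.575).
#' @param rng_seed integer seed.
#' @return Logical matrix cropped to the cell's bounding box.
#' @export
render_cell <- function(spec, px_per_um = 0.575, rng_seed = 1L) {
  if (!inherits(spec, "shape_class_spec")) stop_param("spec must be a shape_class_spec")
  if (px_per_um <= 0) stop_param("px_per_um must be > 0")
  with_seed(rng_seed, {
    r_px <- spec$soma_radius_um * px_per_um
    a <- r_px * sqrt(spec$elongation)   # semi-axes preserving pi*r^2 area
    b <- r_px / sqrt(spec$elongation)
    branch_px <- spec$branch_length_um * px_per_um
    half_w <- spec$branch_width_um * px_per_um / 2
    ext <- ceiling(a + branch_px + half_w) + 3L
    n <- 2L * ext + 1L
    ctr <- ext + 1L
    phi <- stats::runif(1, 0, pi)  # soma orientation
    yy <- matrix(seq_len(n) - ctr, n, n)
    xx <- t(yy)
    xr <- xx * cos(phi) + yy * sin(phi)
    yr <- -xx * sin(phi) + yy * cos(phi)
    stamp <- (xr / a)^2 + (yr / b)^2 <= 1
    if (spec$n_branches > 0L) {
      base_ang <- stats::runif(1, 0, 2 * pi) +
        seq(0, 2 * pi, length.out = spec$n_branches + 1L)[-1L]
      n_steps <- max(1L, as.integer(round(branch_px)))
      rad <- max(1L, as.integer(ceiling(half_w)))
      disc <- {
        d <- expand.grid(dr = -rad:rad, dc = -rad:rad)
        d[d$dr^2 + d$dc^2 <= max(half_w, 0.5)^2 + 1e-9, ]
      }
      for (bidx in seq_len(spec$n_branches)) {
        ang <- base_ang[bidx]
        # boundary of the rotated ellipse along direction ang
        ca <- cos(ang - phi); sa <- sin(ang - phi)
        rho <- 1 / sqrt((ca / a)^2 + (sa / b)^2)
        pos <- c(ctr + rho * sin(ang), ctr + rho * cos(ang))  # (row, col)
        heading <- ang
        for (s in seq_len(n_steps)) {
          heading <- heading + stats::rnorm(1, 0, spec$tortuosity * 0.5)
          pos <- pos + c(sin(heading), cos(heading))
          pr <- round(pos[1L]) + disc$dr
          pc <- round(pos[2L]) + disc$dc
          ok <- pr >= 1L & pr <= n & pc >= 1L & pc <= n
          stamp[cbind(pr[ok], pc[ok])] <- TRUE
        }
      }
    }
    rows <- range(which(rowSums(stamp) > 0))
    cols <- range(which(colSums(stamp) > 0))
    stamp[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  })
}

#' Specify a synthetic cohort
#'
#' @param groups named list; each element is a list with fields
#'   `n_images`, `cells_per_image_mean`, and `shape_mixture` (named numeric
#'   probabilities over `classes`, summing to 1).
#' @param classes named list of [shape_class_spec()] objects.
#' @param image_shape_px `c(height, width)` of each field.
#' @param px_per_um pixel scale (default 0.575, the 63x confocal
#'   calibration).
#' @param background_level baseline intensity in \[0, 1). The default 0.05,
#'   with the default noise, keeps the mean threshold comfortably above the
#'   background even in sparse fields -- the regime bright fluorescence
#'   staining operates in. A global mean threshold degrades sharply when
#'   the background-to-threshold margin shrinks below the noise scale.
#' @param foreground_level added intensity on cell pixels (default 0.8,
#'   giving the bimodal histogram the mean threshold relies on).
#' @param noise_sd Gaussian noise standard deviation (default 0.01).
#' @param blur_sigma_px optional optical (PSF-like) blur applied before
#'   noise.
#' @param min_gap_px minimum spacing between cell bounding boxes and from
#'   the border, so cells stay separable (the counting method does not split
#'   touching cells).
#' @param seed cohort seed; per-image seeds are derived from it for exact
#'   replay of any single image.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups,
                        classes = list(amoeboid = amoeboid_class(),
                                       ramified = ramified_class()),
                        image_shape_px = c(512L, 512L), px_per_um = 0.575,
                        background_level = 0.05, foreground_level = 0.8,
                        noise_sd = 0.01, blur_sigma_px = 1, min_gap_px = 4L,
                        seed = 1L) {
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    stop_param("groups must be uniquely named")
  if (px_per_um <= 0) stop_param("px_per_um must be > 0")
  if (background_level < 0 || background_level >= 1)
    stop_param("background_level must be in [0, 1)")
  if (noise_sd < 0) stop_param("noise_sd must be >= 0")
  for (g in names(groups)) {
    gr <- groups[[g]]
    if (is.null(gr$n_images) || gr$n_images < 1)
      stop_param("group '", g, "': n_images must be >= 1")
    mix <- gr$shape_mixture
    if (is.null(mix) || is.null(names(mix)) || !all(names(mix) %in% names(classes)))
      stop_param("group '", g, "': shape_mixture must be named over classes")
    if (abs(sum(mix) - 1) > 1e-9)
      stop_param("group '", g, "': shape_mixture must sum to 1")
  }
  structure(list(groups = groups, classes = classes,
                 image_shape_px = as.integer(image_shape_px),
                 px_per_um = px_per_um, background_level = background_level,
                 foreground_level = foreground_level, noise_sd = noise_sd,
                 blur_sigma_px = blur_sigma_px, min_gap_px = as.integer(min_gap_px),
                 seed = as.integer(seed)), class = "cohort_spec")
}

image_seed_table <- function(spec) {
  counts <- vapply(spec$groups, function(g) as.integer(g$n_images), integer(1))
  seeds <- derive_seeds(spec$seed, sum(counts))
  data.frame(group = rep(names(spec$groups), counts),
             image_index = unlist(lapply(counts, seq_len), use.names = FALSE),
             seed = seeds)
}

#' Generate one synthetic micrograph with ground truth
#'
#' Draws the number of cells (Poisson with the group mean), samples each
#' cell's shape class from the group mixture, renders it, and places it by
#' rejection sampling (up to 100 tries per cell) so that expanded bounding
#' boxes do not overlap and never touch the border. The intensity image is
#' background + foreground amplitude on cell pixels, optionally blurred,
#' plus Gaussian noise, clipped to \[0, 1\].
#'
#' @param spec a [cohort_spec()].
#' @param group_label group name in `spec$groups`.
#' @param image_index image number within the group (determines the derived
#'   seed, so any single image can be replayed).
#' @return `list(image = micrograph, truth = list(mask, class_labels,
#'   planted_density, n_cells))`; `planted_density` is cells per mm^2.
#' @export
generate_image <- function(spec, group_label, image_index = 1L) {
  if (!group_label %in% names(spec$groups))
    stop_param("unknown group '", group_label, "'")
  tab <- image_seed_table(spec)
  row <- tab[tab$group == group_label & tab$image_index == image_index, ]
  if (!nrow(row)) stop_param("image_index ", image_index, " out of range")
  gr <- spec$groups[[group_label]]
  h <- spec$image_shape_px[1L]; w <- spec$image_shape_px[2L]
  gap <- spec$min_gap_px
  with_seed(row$seed, {
    n_target <- if (gr$cells_per_image_mean > 0)
      stats::rpois(1L, gr$cells_per_image_mean) else 0L
    mask <- matrix(0L, h, w)
    occupied <- matrix(FALSE, h, w)  # expanded bounding boxes
    class_labels <- integer(0)
    placed <- 0L
    mix <- gr$shape_mixture
    for (ci in seq_len(n_target)) {
      cls <- sample(names(mix), 1L, prob = mix)
      stamp <- render_cell(spec$classes[[cls]], spec$px_per_um,
                           rng_seed = sample.int(.Machine$integer.max, 1L))
      sh <- nrow(stamp); sw <- ncol(stamp)
      if (sh + 2L * gap >= h || sw + 2L * gap >= w)
        stop_param("cell stamp (", sh, "x", sw, ") too large for the field")
      done <- FALSE
      for (try in 1:100) {
        r0 <- sample.int(h - sh - 2L * gap, 1L) + gap
        c0 <- sample.int(w - sw - 2L * gap, 1L) + gap
        rr <- (r0 - gap):(r0 + sh - 1L + gap)
        cc <- (c0 - gap):(c0 + sw - 1L + gap)
        if (!any(occupied[rr, cc])) {
          placed <- placed + 1L
          sel <- which(stamp)
          mask[r0:(r0 + sh - 1L), c0:(c0 + sw - 1L)][sel] <- placed
          occupied[rr, cc] <- TRUE
          class_labels[placed] <- match(cls, names(spec$classes))
          done <- TRUE
          break
        }
      }
      if (!done)
        stop(sprintf("could not place cell %d of %d (placed %d) after 100 tries",
                     ci, n_target, placed))
    }
    img <- spec$background_level + spec$foreground_level * (mask > 0)
    if (spec$blur_sigma_px > 0) img <- gaussian_blur(img, spec$blur_sigma_px)
    if (spec$noise_sd > 0) img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    img <- matrix(pmin(pmax(img, 0), 1), h, w)
    names(class_labels) <- as.character(seq_len(placed))
    field_mm2 <- h * w / spec$px_per_um^2 / 1e6
    list(image = micrograph(img, spec$px_per_um,
                            meta = list(group = group_label,
                                        image_id = sprintf("%s_%03d", group_label,
                                                           image_index))),
         truth = list(mask = mask, class_labels = class_labels,
                      planted_density = placed / field_mm2, n_cells = placed))
  })
}

#' Generate a full synthetic cohort
#'
#' Renders every image of every group under one seed hierarchy. With `dir`
#' set, writes 16-bit grayscale TIFF images, TIFF label masks, a
#' `manifest.json` (cohort seed plus per-image derived seeds, for exact
#' replay) and a `truth.csv` table (image_id, cell_label, class, centroid,
#' area_px); otherwise returns everything in memory.
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory.
#' @return Invisibly (or directly when `dir` is `NULL`) a list with
#'   `manifest` (data.frame: group, image_index, image_id, seed, n_cells,
#'   planted_density) and, in-memory, `images` and `truths` lists.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  tab <- image_seed_table(spec)
  images <- truths <- vector("list", nrow(tab))
  truth_rows <- vector("list", nrow(tab))
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(tab))) {
    gi <- generate_image(spec, tab$group[i], tab$image_index[i])
    images[[i]] <- gi$image; truths[[i]] <- gi$truth
    id <- gi$image$meta$image_id
    if (!is.null(dir)) {
      write_micrograph(gi$image, file.path(dir, paste0(id, ".tiff")))
      write_label_tiff(gi$truth$mask, file.path(dir, paste0(id, "_mask.tiff")))
    }
    tr <- gi$truth
    if (tr$n_cells > 0) {
      nr <- nrow(tr$mask)
      cent <- t(vapply(seq_len(tr$n_cells), function(l) {
        pos <- which(tr$mask == l)
        c(mean((pos - 1L) %% nr + 1L), mean((pos - 1L) %/% nr + 1L), length(pos))
      }, numeric(3)))
      truth_rows[[i]] <- data.frame(
        image_id = id, cell_label = seq_len(tr$n_cells),
        class = names(spec$classes)[tr$class_labels],
        centroid_row = cent[, 1L], centroid_col = cent[, 2L],
        area_px = as.integer(cent[, 3L]))
    }
  }
  manifest <- cbind(tab,
                    image_id = vapply(images, function(im) im$meta$image_id, character(1)),
                    n_cells = vapply(truths, function(t) t$n_cells, integer(1)),
                    planted_density = vapply(truths, function(t) t$planted_density,
                                             numeric(1)))
  truth_df <- if (length(tr <- Filter(Negate(is.null), truth_rows)))
    do.call(rbind, tr) else NULL
  if (!is.null(dir)) {
    jsonlite::write_json(list(seed = spec$seed,
                              px_per_um = spec$px_per_um,
                              image_shape_px = spec$image_shape_px,
                              images = manifest),
                         file.path(dir, "manifest.json"), auto_unbox = TRUE,
                         digits = NA)
    if (!is.null(truth_df))
      utils::write.csv(truth_df, file.path(dir, "truth.csv"), row.names = FALSE)
    invisible(list(manifest = manifest, dir = dir))
  } else {
    list(manifest = manifest, images = images, truths = truths,
         truth_table = truth_df)
  }
}
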