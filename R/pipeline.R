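#' Run the full morphology pipeline on a synthetic cohort
#'
#' End to end: generate (or accept) a cohort, segment every micrograph with
#' the default threshold pipeline, measure per-cell features and per-image
#' densities, extract boundary contours, make a stratified 80:20
#' train/test split, fit the shape-mode model on the training cells, assign
#' a mode to every cell, and tabulate test-set mode frequencies per group.
#' All randomness flows from `seed`, so a re-run with the same inputs is
#' bit-identical, including the CSVs written to `out_dir`.
#'
#' @param cohort a [cohort_spec()], or the in-memory result of
#'   [generate_cohort()].
#' @param out_dir optional directory; when given, writes `cells.csv`
#'   (features plus `sm` and `split` columns), `density.csv`,
#'   `sm_frequency.csv` and `provenance.json`.
#' @param config a [seg_config()].
#' @param k,n_points,train_fraction shape-mode parameters.
#' @param seed integer seed for the split and the model fit.
#' @return List with `cells`, `density`, `sm_frequency` (test-split
#'   [sm_frequency()]), `model`, and `manifest`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL, config = seg_config(),
                         k = 5L, n_points = 50L, train_fraction = 0.8,
                         seed = 1L) {
  if (inherits(cohort, "cohort_spec")) cohort <- generate_cohort(cohort)
  images <- cohort$images
  all_cells <- list(); all_density <- list(); contours <- list()
  cell_groups <- character(0)
  for (im in images) {
    mask <- segment(im, config)
    cells <- measure_cells(mask, perimeter = config$perimeter)
    dens <- cell_density(mask)
    dens$group <- im$meta$group
    cs <- cell_contours(mask)
    if (nrow(cells)) {
      cells$cell_id <- paste0(im$meta$image_id, ":", cells$label)
      cells$group <- im$meta$group
      ok <- !cells$degenerate
      ids <- cells$cell_id[ok][match(names(cs), as.character(cells$label[ok]))]
      names(cs) <- ids
      contours <- c(contours, cs)
      cell_groups <- c(cell_groups, rep(im$meta$group, length(cs)))
    }
    all_cells[[length(all_cells) + 1L]] <- cells
    all_density[[length(all_density) + 1L]] <- dens
  }
  cells <- do.call(rbind, all_cells)
  density <- do.call(rbind, all_density)
  names(cell_groups) <- names(contours)

  split <- split_train_test(names(contours), groups = cell_groups,
                            train_fraction = train_fraction, seed = seed)
  model <- shape_modes(contours[split$train], k = k, n_points = n_points,
                       seed = seed)
  assign_all <- predict(model, contours)
  cells$sm <- assign_all$sm[match(cells$cell_id, assign_all$cell_id)]
  cells$split <- ifelse(cells$cell_id %in% split$train, "train",
                        ifelse(cells$cell_id %in% split$test, "test", NA))
  test_idx <- match(split$test, assign_all$cell_id)
  freq <- sm_frequency(assign_all$sm[test_idx], cell_groups[split$test], k = k)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    num <- function(df) { for (c in names(df)) if (is.numeric(df[[c]]))
      df[[c]] <- signif(df[[c]], 12); df }
    utils::write.csv(num(cells), file.path(out_dir, "cells.csv"), row.names = FALSE)
    utils::write.csv(num(density), file.path(out_dir, "density.csv"),
                     row.names = FALSE)
    freq_df <- data.frame(group = rownames(freq$freq), freq$freq,
                          variance = signif(freq$variance, 12), n = freq$n,
                          row.names = NULL)
    freq_df[paste0("SM", seq_len(k))] <-
      lapply(freq_df[paste0("SM", seq_len(k))], signif, 12)
    utils::write.csv(freq_df, file.path(out_dir, "sm_frequency.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(seed = seed, k = k, n_points = n_points,
                              train_fraction = train_fraction,
                              blur_sigma = config$blur_sigma_px,
                              threshold_method = config$threshold_method,
                              min_cell_area_um2 = config$min_cell_area_um2,
                              connectivity = config$connectivity),
                         file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cells = cells, density = density, sm_frequency = freq, model = model,
       manifest = cohort$manifest)
}
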