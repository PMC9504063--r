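# Comparative cycle-threshold (2^-ddCt) relative expression analysis.
# dCt = mean target Ct - mean reference Ct per sample; ddCt subtracts the
# control group's mean dCt; fold change = 2^-ddCt.

#' Assemble a Ct table
#'
#' @param data data.frame with columns `sample_id`, `group`, `gene`, and
#'   replicate cycle-threshold columns `ct1`, `ct2`, `ct3` (up to three; NA
#'   replicates are dropped per well).
#' @param reference_gene housekeeping gene used for normalization (default
#'   `"GAPDH"`).
#' @param control_group group whose mean dCt anchors ddCt (default the
#'   first group level).
#' @return An object of class `ct_table`.
#' @export
ct_table <- function(data, reference_gene = "GAPDH", control_group = NULL) {
  need <- c("sample_id", "group", "gene")
  if (!all(need %in% names(data)))
    stop_param("data must have columns ", paste(need, collapse = ", "))
  ct_cols <- intersect(c("ct1", "ct2", "ct3"), names(data))
  if (!length(ct_cols)) stop_param("no replicate Ct columns (ct1..ct3) found")
  cts <- as.matrix(data[ct_cols])
  if (any(cts <= 0, na.rm = TRUE)) stop_param("replicate Cts must be positive")
  if (!reference_gene %in% data$gene)
    stop_param("reference gene '", reference_gene, "' absent from table")
  if (is.null(control_group)) control_group <- as.character(data$group[1L])
  if (!control_group %in% data$group)
    stop_param("control group '", control_group, "' absent from table")
  structure(list(data = data, ct_cols = ct_cols,
                 reference_gene = reference_gene,
                 control_group = control_group), class = "ct_table")
}

#' Relative expression by the comparative Ct method
#'
#' For every sample and target gene: replicate Cts are averaged per well
#' set, dCt is the target mean minus the reference-gene mean for the same
#' sample, ddCt subtracts the control group's mean dCt for that gene, and
#' the fold change is `2^-ddCt`. By construction the fold change evaluated
#' at the control group's mean dCt is exactly 1 (equivalently, the control
#' group's geometric-mean fold is 1).
#'
#' @param table a [ct_table()].
#' @return data.frame with one row per sample x target gene: `sample_id`,
#'   `group`, `gene`, `dct`, `ddct`, `fold_change`.
#' @export
ddct_fold_change <- function(table) {
  if (!inherits(table, "ct_table")) stop_param("table must be a ct_table")
  d <- table$data
  mean_ct <- rowMeans(as.matrix(d[table$ct_cols]), na.rm = TRUE)
  ref <- d$gene == table$reference_gene
  ref_by_sample <- tapply(mean_ct[ref], d$sample_id[ref], mean)
  targets <- d[!ref, , drop = FALSE]
  tmean <- mean_ct[!ref]
  miss <- setdiff(unique(targets$sample_id), names(ref_by_sample))
  if (length(miss))
    stop_param("no reference-gene rows for sample ", paste(miss, collapse = ", "))
  dct <- tmean - ref_by_sample[as.character(targets$sample_id)]
  out <- data.frame(sample_id = targets$sample_id, group = targets$group,
                    gene = targets$gene, dct = as.numeric(dct))
  ctrl <- out$group == table$control_group
  if (!any(ctrl)) stop_param("control group has no target-gene rows")
  ctrl_mean <- tapply(out$dct[ctrl], out$gene[ctrl], mean)
  miss_g <- setdiff(unique(out$gene), names(ctrl_mean))
  if (length(miss_g))
    stop_param("control group missing for gene ", paste(miss_g, collapse = ", "))
  out$ddct <- out$dct - as.numeric(ctrl_mean[as.character(out$gene)])
  out$fold_change <- 2^(-out$ddct)
  rownames(out) <- NULL
  out
}

#' Simulate a Ct table with planted fold changes
#'
#' Generates triplicate-well Ct values from a simple model: reference-gene
#' Cts around `ref_ct`, target dCt of `base_dct` in the control group,
#' shifted by `-log2(fold)` in each other group, with between-sample and
#' replicate noise. Used to validate recovery of planted expression
#' differences.
#'
#' @param fold named vector of planted fold changes per group (control
#'   group's entry is ignored / treated as 1).
#' @param control_group name of the control group.
#' @param n_samples samples per group.
#' @param gene,reference_gene gene names.
#' @param ref_ct mean reference-gene Ct.
#' @param base_dct control-group mean dCt.
#' @param sample_sd between-sample dCt standard deviation.
#' @param replicate_sd within-well replicate standard deviation.
#' @param seed integer seed.
#' @return A [ct_table()].
#' @export
simulate_ct_table <- function(fold, control_group = names(fold)[1L],
                              n_samples = 6L, gene = "CXCL1",
                              reference_gene = "GAPDH", ref_ct = 18,
                              base_dct = 6, sample_sd = 0.15,
                              replicate_sd = 0.2, seed = 1L) {
  with_seed(seed, {
    rows <- list()
    for (g in names(fold)) {
      shift <- if (g == control_group) 0 else -log2(fold[[g]])
      for (s in seq_len(n_samples)) {
        sid <- paste0(g, "_s", s)
        ref_mean <- ref_ct + stats::rnorm(1, 0, sample_sd)
        tgt_mean <- ref_mean + base_dct + shift + stats::rnorm(1, 0, sample_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, group = g, gene = reference_gene,
          ct1 = ref_mean + stats::rnorm(1, 0, replicate_sd),
          ct2 = ref_mean + stats::rnorm(1, 0, replicate_sd),
          ct3 = ref_mean + stats::rnorm(1, 0, replicate_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, group = g, gene = gene,
          ct1 = tgt_mean + stats::rnorm(1, 0, replicate_sd),
          ct2 = tgt_mean + stats::rnorm(1, 0, replicate_sd),
          ct3 = tgt_mean + stats::rnorm(1, 0, replicate_sd))
      }
    }
    ct_table(do.call(rbind, rows), reference_gene = reference_gene,
             control_group = control_group)
  })
}
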