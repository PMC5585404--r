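# In-code fixtures: tiny datasets and databases built at test time.

make_dataset <- function(values, n_origin, n_target, id = "ds1",
                         conversion = "conv", genes = NULL) {
  values <- as.matrix(values)
  genes <- genes %||% sprintf("G%03d", seq_len(nrow(values)))
  samples <- c(sprintf("o%d", seq_len(n_origin)), sprintf("t%d", seq_len(n_target)))
  dimnames(values) <- list(genes, samples)
  groups <- stats::setNames(rep(c("origin", "target"), c(n_origin, n_target)), samples)
  expression_dataset(id, values, groups, conversion = conversion)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A de_result-shaped data frame built directly from calls (for consensus
# tests that do not need real expression data).
fake_de <- function(genes, directions, fcs = NULL, id = "ds1", conversion = "conv") {
  fcs <- fcs %||% ifelse(directions == "up", 4, ifelse(directions == "down", 0.25, 1))
  de <- data.frame(gene = genes, fc_linear = fcs, log2fc = log2(fcs),
                   p_value = ifelse(directions == "none", 0.5, 0.01),
                   testable = TRUE, direction = directions,
                   stringsAsFactors = FALSE)
  attr(de, "dataset_id") <- id
  attr(de, "conversion") <- conversion
  class(de) <- c("de_result", "data.frame")
  de
}

# Direction table assembled from a calls matrix (genes x datasets) and a
# conversion label per dataset.
fake_table <- function(calls, conversions, fcs = NULL) {
  genes <- rownames(calls) %||% sprintf("G%03d", seq_len(nrow(calls)))
  ids <- colnames(calls) %||% sprintf("ds%d", seq_len(ncol(calls)))
  de_list <- lapply(seq_len(ncol(calls)), function(j) {
    fake_de(genes, calls[, j], fcs = if (!is.null(fcs)) fcs[, j],
            id = ids[j], conversion = conversions[j])
  })
  direction_table(de_list)
}

# Down-scaled study with the same 1/1/3/1/3 dataset layout as the default
# nine-dataset design (the specificity tolerance needs >= 3 single-dataset
# conversions to exclude cross-conversion specific genes).
small_study_config <- function(seed = 11, noise = 0, n_genes = 400) {
  cfg <- study_config(
    n_genes = n_genes,
    conversions = data.frame(name = c("a", "b", "c", "d", "e"),
                             n_datasets = c(1L, 1L, 3L, 1L, 3L),
                             replicates_per_group = 3L,
                             stringsAsFactors = FALSE),
    common_up = 6, common_down = 6, specific_per_conversion = 6,
    n_decoy_tfs = 4, decoy_regulon_size = 20,
    noise_sd_log2 = noise, n_decoy_terms = 10, seed = seed)
  cfg$tf_regulons$size <- 24L
  cfg
}
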