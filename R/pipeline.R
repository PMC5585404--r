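# End-to-end orchestration: simulate or ingest datasets, then
# DE -> consensus -> specificity -> GRN -> enrichment -> clustering, writing
# per-stage artifacts plus a checksummed manifest.

#' Pipeline configuration
#'
#' Either `datasets` (a list of [expression_dataset()], each carrying a
#' `conversion` label) together with `regulon_db`/`term_db`, or `study` (a
#' [study_config()]) from which everything is simulated.
#'
#' @param datasets List of [expression_dataset()] objects, or `NULL`.
#' @param study A [study_config()] for synthetic mode, or `NULL`.
#' @param regulon_db,term_db [gene_set_db()] objects (ignored in synthetic
#'   mode, which generates its own).
#' @param out_dir Output directory for stage artifacts and the manifest.
#' @param de_thresholds A [de_thresholds()].
#' @param merge_min_same,common_min_same Vote counts for the within-conversion
#'   merge and the cross-study common vote; `NULL` means (n - 1)-of-n,
#'   resolved per conversion / per study at run time.
#' @param merge_forbid_opposite,common_forbid_opposite Opposite-call vetoes
#'   for the two votes (both default `TRUE`; see the methods vignette).
#' @param strict_fc_min Fold-change gate of the strict common tier.
#' @param spec_rule A [specificity_rule()].
#' @param detf_fc_min Fold-change gate for DE-TF filtering.
#' @param alpha Significance threshold used for TF and term enrichment.
#' @param stages Character subset of `c("specificity", "grn", "enrichment",
#'   "clustering")` to run in addition to the always-on DE and consensus
#'   stages.
#' @param seed Integer seed (used only by synthetic mode).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(datasets = NULL, study = NULL,
                            regulon_db = NULL, term_db = NULL,
                            out_dir = NULL,
                            de_thresholds = convmine::de_thresholds(),
                            merge_min_same = NULL, merge_forbid_opposite = TRUE,
                            common_min_same = NULL, common_forbid_opposite = TRUE,
                            strict_fc_min = 1.5,
                            spec_rule = specificity_rule(),
                            detf_fc_min = 1.5, alpha = 0.05,
                            stages = c("specificity", "grn", "enrichment", "clustering"),
                            seed = 1) {
  if (is.null(datasets) && is.null(study)) stopf("supply `datasets` or `study`")
  stages <- if (length(stages)) match.arg(stages, several.ok = TRUE) else character()
  structure(list(datasets = datasets, study = study, regulon_db = regulon_db,
                 term_db = term_db, out_dir = out_dir,
                 de_thresholds = de_thresholds,
                 merge_min_same = merge_min_same,
                 merge_forbid_opposite = merge_forbid_opposite,
                 common_min_same = common_min_same,
                 common_forbid_opposite = common_forbid_opposite,
                 strict_fc_min = strict_fc_min, spec_rule = spec_rule,
                 detf_fc_min = detf_fc_min, alpha = alpha, stages = stages,
                 seed = seed),
            class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full conversion-mining study
#'
#' Executes, in order: per-dataset differential expression; the direction
#' table; per-conversion consensus merging; the cross-study common signature
#' (plus its strict fold-change tier); conversion-specific signatures; TF
#' enrichment, DE-TF filtering, GRN/core-network construction and out-degree
#' ranking per conversion; ontology enrichment of the common up and down
#' lists; and clustering of the common-signature log2 fold-change matrix.
#' When `cfg$out_dir` is set, every stage writes TSV/SIF/CDT artifacts and a
#' JSON manifest with an md5 checksum per artifact; identical config + seed
#' gives identical checksums.
#'
#' @param cfg A [pipeline_config()].
#' @return List of class `study_results`: `de`, `table`, `merged`, `common`,
#'   `specific`, `grn` (per conversion: `enrichment`, `de_tfs`, `network`,
#'   `core`, `ranking`), `term_enrichment`, `clustering`, `truth` (synthetic
#'   mode only), and `manifest` (data frame `path`, `md5`) when files were
#'   written.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  regulon_db <- cfg$regulon_db
  term_db <- cfg$term_db
  truth <- NULL
  datasets <- cfg$datasets
  if (!is.null(cfg$study)) {
    gen <- with_stage("simulate", generate_study(cfg$study))
    datasets <- gen$datasets
    regulon_db <- gen$regulons
    term_db <- gen$terms
    truth <- gen$truth
  }

  de <- with_stage("diffexpr",
                   lapply(datasets, run_de, thresholds = cfg$de_thresholds))
  table <- with_stage("consensus", direction_table(de))
  conv_names <- unique(table$datasets$conversion)

  merged <- with_stage("consensus", {
    stats::setNames(lapply(conv_names, function(cn) {
      n <- sum(table$datasets$conversion == cn)
      rule <- vote_rule(cfg$merge_min_same %||% max(1L, n - 1L),
                        forbid_opposite = cfg$merge_forbid_opposite)
      merge_conversion(table, cn, rule)
    }), conv_names)
  })

  n_all <- nrow(table$datasets)
  common <- with_stage("consensus", common_signature(
    table,
    rule = vote_rule(cfg$common_min_same %||% (n_all - 1L),
                     forbid_opposite = cfg$common_forbid_opposite),
    strict_fc_min = cfg$strict_fc_min))

  specific <- NULL
  if ("specificity" %in% cfg$stages) {
    specific <- with_stage("specificity", {
      stats::setNames(lapply(conv_names, function(cn)
        specific_signature(merged[[cn]], table, cfg$spec_rule, conversion = cn)),
        conv_names)
    })
  }

  grn_res <- NULL
  if ("grn" %in% cfg$stages) {
    if (is.null(regulon_db)) stopf("stage 'grn' needs a regulon database")
    grn_res <- with_stage("grn", {
      universe <- intersect(regulon_db$universe, table$genes)
      stats::setNames(lapply(conv_names, function(cn) {
        degs <- merged[[cn]]$gene
        enr <- suppressWarnings(tf_enrichment(degs, regulon_db, universe,
                                              alpha = cfg$alpha))
        detfs <- filter_de_tfs(enr, merged[[cn]], fc_min = cfg$detf_fc_min,
                               alpha = cfg$alpha)
        net <- build_grn(detfs, degs, regulon_db)
        core <- build_core_network(detfs, regulon_db)
        list(enrichment = enr, de_tfs = detfs, network = net, core = core,
             ranking = out_degree_ranking(net),
             core_ranking = out_degree_ranking(core))
      }), conv_names)
    })
  }

  terms_res <- NULL
  if ("enrichment" %in% cfg$stages) {
    if (is.null(term_db)) stopf("stage 'enrichment' needs a term database")
    terms_res <- with_stage("enrichment", {
      universe <- intersect(term_db$universe, table$genes)
      list(
        common_up = suppressWarnings(term_enrichment(
          common$all$gene[common$all$direction == "up"], term_db, universe,
          alpha = cfg$alpha)),
        common_down = suppressWarnings(term_enrichment(
          common$all$gene[common$all$direction == "down"], term_db, universe,
          alpha = cfg$alpha)))
    })
  }

  clust <- NULL
  if ("clustering" %in% cfg$stages) {
    clust <- with_stage("clustering", {
      sig <- if (nrow(common$strict) >= 2L) common$strict else common$all
      if (nrow(sig) < 2L) NULL else {
        lfc <- log2(table$fc[sig$gene, , drop = FALSE])
        genes_tree <- cluster_matrix(lfc, axis = "genes")
        arrays_tree <- if (ncol(lfc) >= 2L) cluster_matrix(t(lfc), axis = "arrays") else NULL
        list(genes = genes_tree, arrays = arrays_tree)
      }
    })
  }

  res <- structure(
    list(de = de, table = table, merged = merged, common = common,
         specific = specific, grn = grn_res, term_enrichment = terms_res,
         clustering = clust, truth = truth, regulon_db = regulon_db,
         term_db = term_db, config = cfg, manifest = NULL),
    class = "study_results")
  if (!is.null(cfg$out_dir)) res$manifest <- write_study_artifacts(res, cfg$out_dir)
  res
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Write every stage artifact under `dir` and return the checksummed manifest.
write_study_artifacts <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (d in res$de) {
    paths <- c(paths, write_tsv(as.data.frame(d),
                                file.path(dir, paste0("de_", attr(d, "dataset_id"), ".tsv"))))
  }
  for (cn in names(res$merged)) {
    paths <- c(paths, write_tsv(res$merged[[cn]],
                                file.path(dir, paste0("degs_", cn, ".tsv"))))
  }
  paths <- c(paths,
             write_tsv(res$common$all, file.path(dir, "common_signature.tsv")),
             write_tsv(res$common$strict, file.path(dir, "common_signature_strict.tsv")))
  for (cn in names(res$specific %||% list())) {
    paths <- c(paths, write_tsv(res$specific[[cn]],
                                file.path(dir, paste0("specific_", cn, ".tsv"))))
  }
  for (cn in names(res$grn %||% list())) {
    g <- res$grn[[cn]]
    paths <- c(paths,
               write_tsv(g$enrichment, file.path(dir, paste0("tf_enrichment_", cn, ".tsv"))),
               write_tsv(g$de_tfs, file.path(dir, paste0("de_tfs_", cn, ".tsv"))),
               write_tsv(g$ranking, file.path(dir, paste0("ranking_", cn, ".tsv"))))
    sif <- file.path(dir, paste0("grn_", cn, ".sif"))
    write_sif(g$network, sif)
    core <- file.path(dir, paste0("core_", cn, ".sif"))
    write_sif(g$core, core)
    paths <- c(paths, sif, core)
  }
  for (nm in names(res$term_enrichment %||% list())) {
    paths <- c(paths, write_tsv(res$term_enrichment[[nm]],
                                file.path(dir, paste0("terms_", nm, ".tsv"))))
  }
  if (!is.null(res$clustering)) {
    stem <- file.path(dir, "common_signature_cluster")
    write_cdt_gtr(res$clustering$genes, stem)
    paths <- c(paths, paste0(stem, ".cdt"), paste0(stem, ".gtr"))
  }
  manifest <- data.frame(path = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$path), , drop = FALSE]
  rownames(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  manifest
}

prf <- function(truth_set, found_set) {
  tp <- length(intersect(truth_set, found_set))
  fp <- length(setdiff(found_set, truth_set))
  fn <- length(setdiff(truth_set, found_set))
  if (tp + fp + fn == 0L) {
    return(c(tp = 0, fp = 0, fn = 0, precision = 1, recall = 1, f1 = 1))
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  c(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
    f1 = 2 * tp / (2 * tp + fp + fn))
}

keyed <- function(genes, directions) paste(genes, directions, sep = ":")

#' Score pipeline output against the planted ground truth
#'
#' Precision/recall/F1 for the common signature (direction-aware), each
#' conversion's DEG list and specific signature, and DE-TF recovery, plus the
#' top-5 out-degree hit rate of the planted master TFs (reported in the
#' `recall` column of the `master_tf_top5` rows).
#'
#' @param res A `study_results` from [run_study()].
#' @param truth A `ground_truth`; defaults to the one attached to `res` in
#'   synthetic mode.
#' @param top_k Ranking depth for the master-TF hit rate (default 5).
#' @return Data frame `metric`, `conversion`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
evaluate_against_truth <- function(res, truth = res$truth, top_k = 5) {
  if (is.null(truth)) stopf("no ground truth available")
  bad <- setdiff(res$table$genes, truth$universe)
  if (length(bad)) {
    stopf("gene universe mismatch: %d measured gene(s) not in the truth universe",
          length(bad))
  }
  rows <- list()
  add <- function(metric, conversion, scores) {
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, conversion = conversion, t(scores),
      stringsAsFactors = FALSE)
  }
  truth_common <- c(keyed(truth$common_up, "up"), keyed(truth$common_down, "down"))
  add("common_signature", NA_character_,
      prf(truth_common, keyed(res$common$all$gene, res$common$all$direction)))
  add("common_signature_strict", NA_character_,
      prf(truth_common, keyed(res$common$strict$gene, res$common$strict$direction)))
  for (cn in names(res$merged)) {
    ct <- conversion_truth(truth, cn)
    add("degs", cn, prf(c(keyed(ct$up, "up"), keyed(ct$down, "down")),
                        keyed(res$merged[[cn]]$gene, res$merged[[cn]]$direction)))
  }
  for (cn in names(res$specific %||% list())) {
    sp <- truth$specific[[cn]]
    add("specific_signature", cn,
        prf(c(keyed(sp$up, "up"), keyed(sp$down, "down")),
            keyed(res$specific[[cn]]$gene, res$specific[[cn]]$direction)))
  }
  for (cn in names(res$grn %||% list())) {
    add("de_tfs", cn, prf(truth$de_tfs[[cn]], res$grn[[cn]]$de_tfs$tf))
    top <- utils::head(res$grn[[cn]]$ranking, top_k)$tf
    add("master_tf_top5", cn, prf(truth$de_tfs[[cn]],
                                  intersect(truth$de_tfs[[cn]], top)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
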