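# Cross-dataset consensus: a genes x datasets table of direction calls is the
# substrate for (a) merging replicate datasets of one conversion into a
# conversion-level DEG list (e.g. 2-of-3 with no opposite call, 3-of-4) and
# (b) voting a common signature across all datasets of a study (8-of-9 style).

#' Build a direction table from per-dataset DE results
#'
#' @param de_list List of `de_result` objects from [run_de()], all over the
#'   same gene universe (genes are intersected and sorted).
#' @param conversions Optional character vector of conversion labels parallel
#'   to `de_list`; defaults to each result's `conversion` attribute.
#' @return Object of class `direction_table`: `genes`, `datasets` (data frame
#'   of `dataset_id`, `conversion`), `calls` and `fc` matrices (genes x
#'   datasets).
#' @export
direction_table <- function(de_list, conversions = NULL) {
  if (length(de_list) == 0L) stopf("`de_list` must be non-empty")
  ids <- vapply(de_list, function(d) attr(d, "dataset_id") %||% NA_character_, "")
  if (anyNA(ids)) ids[is.na(ids)] <- paste0("dataset", which(is.na(ids)))
  if (anyDuplicated(ids)) stopf("duplicate dataset ids: %s", ids[duplicated(ids)][1L])
  conversions <- conversions %||%
    vapply(de_list, function(d) attr(d, "conversion") %||% NA_character_, "")
  genes <- sort(Reduce(intersect, lapply(de_list, `[[`, "gene")))
  if (length(genes) == 0L) stopf("datasets share no genes")
  calls <- matrix(vapply(de_list, function(d) d$direction[match(genes, d$gene)],
                         character(length(genes))),
                  nrow = length(genes))
  fc <- matrix(vapply(de_list, function(d) d$fc_linear[match(genes, d$gene)],
                      numeric(length(genes))),
               nrow = length(genes))
  dimnames(calls) <- dimnames(fc) <- list(genes, ids)
  structure(list(genes = genes,
                 datasets = data.frame(dataset_id = ids, conversion = conversions,
                                       stringsAsFactors = FALSE),
                 calls = calls, fc = fc),
            class = "direction_table")
}

#' @export
print.direction_table <- function(x, ...) {
  cat(sprintf("<direction_table> %d genes x %d datasets (%d conversions)\n",
              length(x$genes), nrow(x$datasets),
              length(unique(x$datasets$conversion))))
  invisible(x)
}

#' Consensus voting rule
#'
#' @param min_same Number of datasets that must share the identical direction.
#' @param forbid_opposite If `TRUE`, a single opposite call vetoes the
#'   consensus (the "no opposite differential expression" clause).
#' @param fc_min Optional linear fold-change magnitude every *supporting*
#'   dataset must additionally meet (e.g. 1.5 for the strict signature tier).
#' @return A list of class `vote_rule`.
#' @export
vote_rule <- function(min_same, forbid_opposite = TRUE, fc_min = NULL) {
  min_same <- assert_count(min_same, "min_same")
  if (!is.null(fc_min) && (!is.numeric(fc_min) || fc_min < 1)) {
    stopf("`fc_min` must be >= 1 or NULL")
  }
  structure(list(min_same = min_same, forbid_opposite = isTRUE(forbid_opposite),
                 fc_min = fc_min),
            class = "vote_rule")
}

opposite_dir <- c(up = "down", down = "up")

#' Vote a consensus direction for one gene
#'
#' Returns `"up"` or `"down"` iff at least `min_same` datasets call that
#' direction, no dataset calls the opposite when `forbid_opposite` is set, and
#' (when `fc_min` is set) every supporting dataset's fold-change magnitude
#' meets it. If both directions would qualify (possible only when
#' `min_same <= n/2`) the gene is returned as `"none"`.
#'
#' @param calls Character vector of `"up"`/`"down"`/`"none"`, one per dataset.
#' @param rule A [vote_rule()].
#' @param fcs Optional numeric vector of linear fold changes parallel to
#'   `calls`; required when the rule carries `fc_min`.
#' @return A single direction string.
#' @export
vote <- function(calls, rule, fcs = NULL) {
  if (length(calls) == 0L) stopf("empty call vector")
  if (rule$min_same > length(calls)) return("none")
  if (!is.null(rule$fc_min) && is.null(fcs)) {
    stopf("rule has `fc_min` but no fold changes were supplied")
  }
  winners <- character()
  for (d in c("up", "down")) {
    support <- calls == d
    if (sum(support) < rule$min_same) next
    if (rule$forbid_opposite && any(calls == opposite_dir[[d]])) next
    if (!is.null(rule$fc_min) && !all(fc_magnitude(fcs[support]) >= rule$fc_min)) next
    winners <- c(winners, d)
  }
  if (length(winners) == 1L) winners else "none"
}

table_subset <- function(table, which_cols) {
  list(calls = table$calls[, which_cols, drop = FALSE],
       fc = table$fc[, which_cols, drop = FALSE])
}

#' Merge a conversion's datasets into one conversion-level DEG list
#'
#' Single-dataset conversions pass their calls through; multi-dataset
#' conversions apply [vote()] per gene. The conversion-level fold change
#' reported for each gene is the geometric mean of its per-dataset fold
#' changes within the conversion.
#'
#' @param table A [direction_table()].
#' @param conversion Conversion name present in `table$datasets$conversion`.
#' @param rule A [vote_rule()]; defaults to (n - 1)-of-n with opposite calls
#'   forbidden, the rule used for the 2-of-3 and 3-of-4 merges.
#' @return Data frame of class `deg_list` with columns `gene`, `direction`,
#'   `fc_linear`, `n_support`, only genes with a non-`none` consensus, sorted
#'   by gene; attribute `conversion`.
#' @export
merge_conversion <- function(table, conversion, rule = NULL) {
  sel <- table$datasets$conversion == conversion
  if (!any(sel)) stopf("unknown conversion '%s'", conversion)
  sub <- table_subset(table, sel)
  n <- sum(sel)
  rule <- rule %||% vote_rule(max(1L, n - 1L), forbid_opposite = TRUE)
  if (n == 1L) {
    dir <- sub$calls[, 1L]
  } else {
    dir <- vapply(seq_along(table$genes),
                  function(i) vote(sub$calls[i, ], rule, sub$fc[i, ]), "")
  }
  fc_geo <- 2^rowMeans(log2(sub$fc))
  n_support <- vapply(seq_along(table$genes),
                      function(i) sum(sub$calls[i, ] == dir[i]), 0L)
  keep <- dir != "none"
  out <- data.frame(gene = table$genes[keep], direction = dir[keep],
                    fc_linear = fc_geo[keep], n_support = n_support[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "conversion") <- conversion
  class(out) <- c("deg_list", "data.frame")
  out
}

#' Common signature across all datasets of a study
#'
#' Votes every gene across all datasets (the 8-of-9-style cross-conversion
#' vote) and additionally reports the strict tier in which every supporting
#' dataset must also show a linear fold change beyond `strict_fc_min`.
#'
#' @param table A [direction_table()] with at least two datasets.
#' @param rule A [vote_rule()] without a fold-change gate; defaults to
#'   (n - 1)-of-n with opposite calls forbidden (see the methods vignette for
#'   why the veto is the default).
#' @param strict_fc_min Fold-change gate of the strict tier (default 1.5).
#' @return List with elements `all` and `strict`, each a sorted data frame of
#'   `gene`, `direction`, `n_support`; `strict$gene` is a subset of
#'   `all$gene`.
#' @export
common_signature <- function(table, rule = NULL, strict_fc_min = 1.5) {
  n <- nrow(table$datasets)
  if (n < 2L) stopf("common signature needs at least two datasets")
  rule <- rule %||% vote_rule(n - 1L, forbid_opposite = TRUE)
  strict_rule <- vote_rule(rule$min_same, rule$forbid_opposite, fc_min = strict_fc_min)
  dir_all <- vapply(seq_along(table$genes),
                    function(i) vote(table$calls[i, ], rule, table$fc[i, ]), "")
  dir_strict <- vapply(seq_along(table$genes),
                       function(i) vote(table$calls[i, ], strict_rule, table$fc[i, ]), "")
  shape <- function(dir) {
    keep <- dir != "none"
    ns <- vapply(which(keep), function(i) sum(table$calls[i, ] == dir[i]), 0L)
    out <- data.frame(gene = table$genes[keep], direction = dir[keep],
                      n_support = ns, stringsAsFactors = FALSE)
    out <- out[order(out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(all = shape(dir_all), strict = shape(dir_strict))
}

#' Direction concordance of a TF's targets between two studies
#'
#' Over the TF's regulon targets that are called differential (non-`none`) in
#' both conversion-level DEG lists (e.g. the human and the mouse study of the
#' same conversion), the fraction with identical direction.
#'
#' @param tf TF symbol present in `db`.
#' @param calls_a,calls_b `deg_list` data frames (gene, direction) from
#'   [merge_conversion()].
#' @param db A [gene_set_db()] of TF regulons.
#' @return Fraction in \[0, 1\], or `NA` with attribute `undefined = TRUE`
#'   when no target is called in both lists.
#' @export
cross_species_concordance <- function(tf, calls_a, calls_b, db) {
  tf <- normalize_symbols(tf)
  if (!tf %in% names(db$sets)) stopf("unknown TF '%s'", tf)
  targets <- db$sets[[tf]]
  a <- calls_a$direction[match(targets, calls_a$gene)]
  b <- calls_b$direction[match(targets, calls_b$gene)]
  shared <- !is.na(a) & !is.na(b) & a != "none" & b != "none"
  if (!any(shared)) {
    return(structure(NA_real_, undefined = TRUE))
  }
  mean(a[shared] == b[shared])
}
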