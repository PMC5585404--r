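# TF-target analysis: hypergeometric over-representation of regulon targets
# among DEGs, DE-TF filtering by the TF's own fold change, directed GRN and
# core-network construction, and out-degree hub ranking.

#' Over-representation of TF regulon targets among DEGs
#'
#' For each TF in the regulon database, the upper-tail hypergeometric
#' probability P(X >= overlap) of drawing that many of its targets in the DEG
#' list, with population `N = |universe|`, successes `K = |regulon ∩
#' universe|`, and draws `n = |degs ∩ universe|`. TFs with p < `alpha` are
#' flagged enriched. A Holm-adjusted column is reported alongside the raw
#' p-values (the enrichment flag uses the raw value, consensus across
#' datasets being the pipeline's robustness mechanism).
#'
#' @param degs Character vector of DEG symbols (genes outside the universe are
#'   dropped with a warning).
#' @param db A [gene_set_db()] of TF regulons.
#' @param universe Gene universe; default is the database universe. In the
#'   pipeline this is intersected with the measured genes.
#' @param alpha Enrichment threshold on the raw p-value (default 0.05).
#' @return Data frame `tf`, `overlap`, `regulon_size`, `p_value`, `p_holm`,
#'   `enriched`, sorted by p-value then TF.
#' @export
tf_enrichment <- function(degs, db, universe = db$universe, alpha = 0.05) {
  universe <- unique(normalize_symbols(universe))
  if (length(universe) == 0L) stopf("empty gene universe")
  degs <- unique(normalize_symbols(degs))
  outside <- setdiff(degs, universe)
  if (length(outside)) {
    warnf("%d DEG(s) outside the universe dropped (e.g. %s)",
          length(outside), outside[1L])
    degs <- intersect(degs, universe)
  }
  N <- length(universe)
  n <- length(degs)
  rows <- lapply(names(db$sets), function(tf) {
    reg <- intersect(db$sets[[tf]], universe)
    K <- length(reg)
    ov <- length(intersect(reg, degs))
    p <- if (K == 0L) 1 else stats::phyper(ov - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(tf = tf, overlap = ov, regulon_size = K, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p_value)
  out$enriched <- out$p_value < alpha
  out <- out[order(out$p_value, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter enriched TFs to differentially expressed TFs (DE-TFs)
#'
#' A TF is a DE-TF iff its target enrichment p-value is below `alpha` and its
#' own linear fold-change magnitude in the conversion is at least `fc_min`.
#' The TF's direction (up/down) is retained as a node annotation; it does not
#' affect edge construction.
#'
#' @param enr Enrichment table from [tf_enrichment()].
#' @param de `deg_list`-style data frame with columns `gene`, `direction`,
#'   `fc_linear` giving each gene's conversion-level call (TFs absent from it
#'   cannot pass the fold-change gate).
#' @param fc_min Fold-change gate (default 1.5).
#' @param alpha Enrichment p-value gate (default 0.05).
#' @return Data frame `tf`, `direction`, `fc_linear`, `p_value`, sorted by TF.
#' @export
filter_de_tfs <- function(enr, de, fc_min = 1.5, alpha = 0.05) {
  i <- match(enr$tf, de$gene)
  fc <- de$fc_linear[i]
  dir <- de$direction[i]
  keep <- enr$p_value < alpha & !is.na(fc) & fc_magnitude(fc) >= fc_min &
    !is.na(dir) & dir != "none"
  out <- data.frame(tf = enr$tf[keep], direction = dir[keep],
                    fc_linear = fc[keep], p_value = enr$p_value[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a directed gene regulatory network
#'
#' @param tf,target Character vectors of equal length giving the edges, or see
#'   [build_grn()] for construction from DEGs and a regulon database.
#' @param tf_direction Optional named character vector annotating each DE-TF
#'   node with its expression direction.
#' @return Object of class `grn` with `nodes`, `edges` (data frame `tf`,
#'   `target`, deduplicated, sorted) and `tf_direction`.
#' @export
grn <- function(tf = character(), target = character(), tf_direction = character()) {
  stopifnot(length(tf) == length(target))
  edges <- unique(data.frame(tf = normalize_symbols(tf),
                             target = normalize_symbols(target),
                             stringsAsFactors = FALSE))
  edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$tf, edges$target))),
                 edges = edges, tf_direction = tf_direction),
            class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("<grn> %d nodes, %d edges, %d source TFs\n",
              length(x$nodes), nrow(x$edges), length(unique(x$edges$tf))))
  invisible(x)
}

#' Build the conversion GRN from DE-TFs, DEGs and the regulon database
#'
#' Edges run from each DE-TF to every member of its regulon that is in the
#' DEG list; a self-loop is kept only when the TF itself is a DEG.
#'
#' @param de_tfs Character vector of DE-TF symbols, or the data frame from
#'   [filter_de_tfs()] (its `direction` column becomes the node annotation).
#' @param degs Character vector of DEG symbols.
#' @param db A [gene_set_db()] of regulons; `de_tfs` must be keys of it.
#' @return A [grn()].
#' @export
build_grn <- function(de_tfs, degs, db) {
  dirs <- character()
  if (is.data.frame(de_tfs)) {
    dirs <- stats::setNames(de_tfs$direction, normalize_symbols(de_tfs$tf))
    de_tfs <- de_tfs$tf
  }
  de_tfs <- normalize_symbols(de_tfs)
  unknown <- setdiff(de_tfs, names(db$sets))
  if (length(unknown)) stopf("DE-TF(s) absent from the regulon database: %s",
                             paste(unknown, collapse = ", "))
  degs <- unique(normalize_symbols(degs))
  tf <- character(); target <- character()
  for (t in de_tfs) {
    tg <- intersect(db$sets[[t]], degs)
    tf <- c(tf, rep(t, length(tg)))
    target <- c(target, tg)
  }
  g <- grn(tf, target, tf_direction = dirs)
  # DE-TFs with no DEG target still are nodes of the conversion network
  g$nodes <- sort(unique(c(g$nodes, de_tfs)))
  g
}

#' Build the core regulatory network between DE-TFs
#'
#' The GRN restricted to edges whose source and target are both DE-TFs,
#' exposing the regulatory hierarchy among the regulators themselves.
#'
#' @inheritParams build_grn
#' @return A [grn()].
#' @export
build_core_network <- function(de_tfs, db) {
  dirs <- character()
  if (is.data.frame(de_tfs)) {
    dirs <- stats::setNames(de_tfs$direction, normalize_symbols(de_tfs$tf))
    de_tfs <- de_tfs$tf
  }
  de_tfs <- normalize_symbols(de_tfs)
  g <- if (length(de_tfs)) build_grn(de_tfs, de_tfs, db) else grn()
  g$tf_direction <- dirs
  g$nodes <- sort(unique(c(g$nodes, de_tfs)))
  g
}

#' Rank TFs by out-degree (hub ranking)
#'
#' Out-degree counts a TF's outgoing edges — its number of regulated DEG
#' targets; the TFs with the most targets are the hub ("most central")
#' regulators. Ties share the minimum rank and are ordered alphabetically for
#' determinism.
#'
#' @param g A [grn()].
#' @param top_k Number of top TFs to return (default all; the headline
#'   reporting convention is the top five).
#' @return Data frame `tf`, `out_degree`, `rank`, non-increasing in
#'   `out_degree`.
#' @export
out_degree_ranking <- function(g, top_k = Inf) {
  srcs <- unique(c(g$edges$tf, names(g$tf_direction)))
  if (length(srcs) == 0L) {
    return(data.frame(tf = character(), out_degree = integer(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  deg <- vapply(srcs, function(t) sum(g$edges$tf == t), 0L)
  ord <- order(-deg, srcs)
  deg <- deg[ord]; srcs <- srcs[ord]
  rank <- match(deg, deg)  # min-rank for ties on the sorted vector
  out <- data.frame(tf = srcs, out_degree = as.integer(deg), rank = rank,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  utils::head(out, top_k)
}
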