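# External representations: TSV expression matrices + group maps, GMT gene-set
# databases (TF regulons and ontology terms), SIF edge lists, and CDT/GTR
# cluster files. All outputs are UTF-8 with LF line endings; writers sort where
# the format permits so that write/read round-trips are bit-stable.

# ---------------------------------------------------------------------------
# ExpressionDataset

#' Construct an expression dataset
#'
#' Bundles one experiment's genes x samples intensity matrix (linear scale,
#' non-negative) with its origin/target sample grouping. Gene symbols are
#' case-normalized to uppercase so that mouse and human symbols unify.
#'
#' @param dataset_id Single string identifying the dataset (e.g. a GEO series).
#' @param values Numeric matrix, genes in rows, samples in columns. Row names
#'   are gene symbols, column names sample ids.
#' @param groups Named character vector mapping every sample id to `"origin"`
#'   or `"target"`.
#' @param organism Organism label (free text).
#' @param conversion Optional conversion label (e.g. `"fibroblast_to_osteoblast"`)
#'   used when datasets are combined across a study.
#' @return An object of class `expression_dataset` with fields `dataset_id`,
#'   `organism`, `conversion`, `genes`, `samples`, `values`, `groups`.
#' @export
expression_dataset <- function(dataset_id, values, groups,
                               organism = "unknown", conversion = NA_character_) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  genes <- normalize_symbols(rownames(values))
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples)) {
    stopf("`values` must have gene row names and sample column names")
  }
  if (anyDuplicated(genes)) {
    stopf("dataset %s: duplicate gene symbols after case normalization: %s",
          dataset_id, paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stopf("dataset %s: expression values must be finite and non-negative", dataset_id)
  }
  rownames(values) <- genes
  missing <- setdiff(samples, names(groups))
  if (length(missing)) {
    stopf("dataset %s: sample(s) missing from the groups map: %s",
          dataset_id, paste(missing, collapse = ", "))
  }
  groups <- groups[samples]
  if (!all(groups %in% c("origin", "target"))) {
    stopf("dataset %s: groups must be 'origin' or 'target'", dataset_id)
  }
  if (!any(groups == "origin") || !any(groups == "target")) {
    stopf("dataset %s: need at least one origin and one target sample", dataset_id)
  }
  structure(
    list(dataset_id = as.character(dataset_id), organism = organism,
         conversion = conversion, genes = genes, samples = samples,
         values = values, groups = groups),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s (%s): %d genes x %d samples (%d origin / %d target)\n",
              x$dataset_id, x$organism, length(x$genes), length(x$samples),
              sum(x$groups == "origin"), sum(x$groups == "target")))
  invisible(x)
}

#' Read a tab-delimited expression matrix with its sample group map
#'
#' The matrix file has gene symbols in the first column and a header row of
#' sample ids; the groups file is two tab-separated columns (sample id,
#' `origin`/`target`) with no header. Duplicate gene symbols (multi-probe
#' genes) are collapsed by element-wise row mean with a warning.
#'
#' @inheritParams expression_dataset
#' @param path Path to the expression matrix TSV.
#' @param groups_path Path to the two-column groups TSV.
#' @return An [expression_dataset()].
#' @export
read_expression_matrix <- function(path, groups_path,
                                   dataset_id = sub("\\.[^.]*$", "", basename(path)),
                                   organism = "unknown",
                                   conversion = NA_character_) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2L) stopf("%s: expected gene column plus >=1 sample column", path)
  gene_col <- raw[[1L]]
  num <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(num) <- "double")
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stopf("%s: non-numeric value at gene '%s', sample '%s'",
          path, gene_col[bad[1L]], colnames(num)[bad[2L]])
  }
  genes <- normalize_symbols(gene_col)
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    warnf("%s: %d duplicated gene symbol(s) collapsed by row mean (e.g. %s)",
          path, length(dups), dups[1L])
    num <- rowsum(num, genes) / as.vector(table(genes)[sort(unique(genes))])
    genes <- rownames(num)
  }
  rownames(num) <- genes
  grp <- utils::read.delim(groups_path, header = FALSE, sep = "\t",
                           colClasses = "character", quote = "")
  if (ncol(grp) < 2L) stopf("%s: expected two columns (sample, group)", groups_path)
  groups <- stats::setNames(grp[[2L]], grp[[1L]])
  expression_dataset(dataset_id, num, groups, organism = organism,
                     conversion = conversion)
}

#' Write an expression dataset as a matrix TSV plus a groups TSV
#'
#' Inverse of [read_expression_matrix()].
#'
#' @param ds An [expression_dataset()].
#' @param path,groups_path Output paths.
#' @export
write_expression_matrix <- function(ds, path, groups_path) {
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("gene", ds$samples), collapse = "\t"), con)
  body <- apply(format(ds$values, trim = TRUE, digits = 15), 1L, paste, collapse = "\t")
  writeLines(paste(ds$genes, body, sep = "\t"), con)
  gcon <- file(groups_path, open = "wb")
  on.exit(close(gcon), add = TRUE)
  writeLines(paste(ds$samples, ds$groups, sep = "\t"), gcon)
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Gene-set databases (GMT)

#' Construct a gene-set database (TF regulons or ontology terms)
#'
#' A single container serves both protein-DNA regulon databases (TF ->
#' bound targets) and ontology term databases (term -> annotated genes):
#' a named list of member sets, an optional description per set, and a gene
#' universe against which enrichment is scored.
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param descriptions Optional character vector parallel to `sets`.
#' @param universe Character vector of scorable gene symbols; defaults to the
#'   union of all members.
#' @return Object of class `gene_set_db` with fields `sets`, `descriptions`,
#'   `universe`.
#' @export
gene_set_db <- function(sets, descriptions = NULL, universe = NULL) {
  if (length(sets) == 0L) {
    return(structure(list(sets = stats::setNames(list(), character()),
                          descriptions = character(), universe = character()),
                     class = "gene_set_db"))
  }
  if (is.null(names(sets)) || any(names(sets) == "")) stopf("all sets must be named")
  if (anyDuplicated(names(sets))) {
    stopf("duplicate set name(s): %s",
          paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  sets <- lapply(sets, function(s) sort(unique(normalize_symbols(s))))
  if (any(lengths(sets) == 0L)) stopf("every set must be non-empty")
  universe <- sort(unique(normalize_symbols(universe %||% unlist(sets, use.names = FALSE))))
  outside <- setdiff(unlist(sets, use.names = FALSE), universe)
  if (length(outside)) {
    stopf("set member(s) outside the supplied universe: %s",
          paste(utils::head(outside, 3L), collapse = ", "))
  }
  descriptions <- descriptions %||% stats::setNames(rep("", length(sets)), names(sets))
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions, universe = universe),
            class = "gene_set_db")
}

#' @export
print.gene_set_db <- function(x, ...) {
  cat(sprintf("<gene_set_db> %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then members, tab-separated. Used as
#' the carrier for TF-target (regulon) databases and ontology term databases.
#'
#' @param path Path to the GMT file.
#' @param universe Optional explicit gene universe; default is the union of all
#'   members.
#' @return A [gene_set_db()]. An empty file yields an empty database with a
#'   warning.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warnf("%s: empty GMT file; returning an empty database", path)
    return(gene_set_db(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stopf("%s: line %d has fewer than 3 tab-separated fields", path, short[1L])
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stopf("%s: duplicate set name '%s'", path, nm[duplicated(nm)][1L])
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  desc <- stats::setNames(vapply(fields, `[[`, "", 2L), nm)
  gene_set_db(sets, descriptions = desc, universe = universe)
}

#' Write a gene-set database as GMT
#'
#' Sets are written in alphabetical order with sorted members, so output is
#' bit-stable and `read_gmt(write_gmt(db))` round-trips.
#'
#' @param db A [gene_set_db()].
#' @param path Output path.
#' @export
write_gmt <- function(db, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (nm in sort(names(db$sets))) {
    writeLines(paste(c(nm, db$descriptions[[nm]], db$sets[[nm]]), collapse = "\t"), con)
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# SIF edge lists

#' Write a gene regulatory network as a SIF edge list
#'
#' One line per edge, `TF<TAB>regulates<TAB>TARGET`, sorted by (TF, target)
#' for bit-stable output. The format is directly loadable by common network
#' viewers.
#'
#' @param grn A [grn()] object.
#' @param path Output path.
#' @export
write_sif <- function(grn, path) {
  stopifnot(inherits(grn, "grn"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  e <- grn$edges
  if (nrow(e)) {
    e <- e[order(e$tf, e$target), , drop = FALSE]
    writeLines(paste(e$tf, "regulates", e$target, sep = "\t"), con)
  }
  invisible(NULL)
}

#' Read a SIF edge list back into a network
#'
#' @param path Path to a SIF file written by [write_sif()].
#' @return A [grn()] holding the edge set (TF direction annotations are not
#'   part of the format and come back empty).
#' @export
read_sif <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(grn(character(), character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 3L)) stopf("%s: SIF lines must have 3 fields", path)
  grn(tf = vapply(f, `[[`, "", 1L), target = vapply(f, `[[`, "", 3L))
}

# ---------------------------------------------------------------------------
# CDT/GTR cluster files

#' Write a clustering result as CDT + GTR files
#'
#' Emits the clustered data table (`<stem>.cdt`, rows in leaf order) and the
#' gene-tree join list (`<stem>.gtr`, one line per merge with the similarity at
#' the join), the file pair understood by TreeView-style viewers.
#'
#' @param tree A `cluster_result` from [cluster_matrix()] (axis `"genes"`).
#' @param path_stem Output path without extension.
#' @export
write_cdt_gtr <- function(tree, path_stem) {
  stopifnot(inherits(tree, "cluster_result"))
  mat <- tree$data
  n <- length(tree$labels)
  gid <- sprintf("GENE%dX", seq_len(n) - 1L)
  node_name <- function(id) if (id < 0) gid[-id] else sprintf("NODE%dX", id)
  gcon <- file(paste0(path_stem, ".gtr"), open = "wb")
  for (k in seq_len(nrow(tree$merge))) {
    writeLines(paste(sprintf("NODE%dX", k),
                     node_name(tree$merge[k, 1L]), node_name(tree$merge[k, 2L]),
                     format(tree$similarity[k], digits = 10), sep = "\t"), gcon)
  }
  close(gcon)
  ccon <- file(paste0(path_stem, ".cdt"), open = "wb")
  writeLines(paste(c("GID", "NAME", colnames(mat) %||% paste0("COL", seq_len(ncol(mat)))),
                   collapse = "\t"), ccon)
  for (i in tree$order) {
    writeLines(paste(c(gid[i], tree$labels[i],
                       format(mat[i, ], trim = TRUE, digits = 10)),
                     collapse = "\t"), ccon)
  }
  close(ccon)
  invisible(NULL)
}
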