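# Synthetic multi-conversion expression studies with planted ground truth:
# log-normal intensities, shared up/down signatures planted with the same
# sign in every conversion, conversion-specific signatures planted with the
# opposite sign elsewhere, and TF regulons whose targets overlap each
# conversion's DEG set at a configured fraction.

#' Configuration of a synthetic conversion study
#'
#' Defaults emulate a nine-dataset fibroblast conversion panel: five
#' conversions with 1/1/3/1/3 independent datasets, 3 replicates per group,
#' a few tens of planted signature genes, a log2 effect of 2 and per-sample
#' log2 noise of 0.5 (i.i.d. Gaussian on the log scale, i.e. log-normal
#' intensities).
#'
#' @param n_genes Total number of genes (master and decoy TFs included).
#' @param conversions Data frame with columns `name`, `n_datasets`,
#'   `replicates_per_group`.
#' @param common_up,common_down Counts of planted shared signature genes
#'   (same sign in every conversion).
#' @param specific_per_conversion Count of planted conversion-specific genes
#'   (their sign at home, the opposite sign in all other conversions).
#' @param tf_regulons Data frame `tf`, `conversion`, `size`, `de_fraction`,
#'   `tf_effect_log2` describing the planted master regulators; default one
#'   up-regulated master TF per conversion with a regulon of 80 genes, half of
#'   them drawn from the conversion's planted DEG set.
#' @param n_decoy_tfs,decoy_regulon_size Unplanted TFs with uniformly random
#'   regulons, to exercise the enrichment and fold-change gates.
#' @param effect_log2 Planted |log2 fold change| of signature genes.
#' @param noise_sd_log2 Per-sample Gaussian noise s.d. on the log2 scale.
#' @param baseline_log2_mean,baseline_log2_sd Baseline expression distribution
#'   on the log2 scale.
#' @param n_decoy_terms Decoy ontology terms in the generated term database.
#' @param seed Integer seed; identical seeds give bit-identical studies.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_genes = 5000,
                         conversions = data.frame(
                           name = c("osteoblast", "mbp", "endothelial",
                                    "phagocyte", "cardiomyocyte"),
                           n_datasets = c(1L, 1L, 3L, 1L, 3L),
                           replicates_per_group = 3L,
                           stringsAsFactors = FALSE),
                         common_up = 20, common_down = 25,
                         specific_per_conversion = 15,
                         tf_regulons = NULL,
                         n_decoy_tfs = 15, decoy_regulon_size = 80,
                         effect_log2 = 2.0, noise_sd_log2 = 0.5,
                         baseline_log2_mean = 7, baseline_log2_sd = 2,
                         n_decoy_terms = 30, seed = 1) {
  stopifnot(is.data.frame(conversions),
            all(c("name", "n_datasets", "replicates_per_group") %in% names(conversions)))
  if (anyDuplicated(conversions$name)) stopf("conversion names must be unique")
  n_genes <- assert_count(n_genes, "n_genes")
  common_up <- assert_count(common_up, "common_up")
  common_down <- assert_count(common_down, "common_down")
  specific_per_conversion <- assert_count(specific_per_conversion, "specific_per_conversion")
  if (!is.numeric(effect_log2) || effect_log2 <= 0) stopf("`effect_log2` must be > 0")
  if (!is.numeric(noise_sd_log2) || noise_sd_log2 < 0) stopf("`noise_sd_log2` must be >= 0")
  tf_regulons <- tf_regulons %||% data.frame(
    tf = paste0("TF", toupper(conversions$name)),
    conversion = conversions$name,
    size = 80L, de_fraction = 0.5, tf_effect_log2 = 2.0,
    stringsAsFactors = FALSE)
  n_planted <- common_up + common_down +
    specific_per_conversion * nrow(conversions) +
    nrow(tf_regulons) + n_decoy_tfs
  if (n_planted > n_genes) {
    stopf("planted genes (%d) exceed n_genes (%d)", n_planted, n_genes)
  }
  if (any(tf_regulons$size > n_genes)) stopf("regulon size exceeds n_genes")
  structure(list(n_genes = n_genes, conversions = conversions,
                 common_up = common_up, common_down = common_down,
                 specific_per_conversion = specific_per_conversion,
                 tf_regulons = tf_regulons, n_decoy_tfs = n_decoy_tfs,
                 decoy_regulon_size = decoy_regulon_size,
                 effect_log2 = effect_log2, noise_sd_log2 = noise_sd_log2,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 n_decoy_terms = n_decoy_terms,
                 seed = assert_count(seed, "seed", positive = FALSE)),
            class = "study_config")
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic multi-conversion study
#'
#' Each dataset draws per-gene baseline log2 means, shifts the target-group
#' mean by the planted signed effect for genes differential in its
#' conversion, adds i.i.d. per-sample Gaussian noise on the log2 scale, and
#' exponentiates to linear intensities. Shared signature genes carry the same
#' sign in every conversion; specific genes carry their home sign at home and
#' the opposite sign in all other conversions; each master TF is shifted only
#' in its home conversion and its regulon is built to overlap that
#' conversion's planted DEG set at the configured fraction.
#'
#' @param cfg A [study_config()].
#' @return List with elements `datasets` (list of [expression_dataset()]),
#'   `regulons` ([gene_set_db()]), `terms` ([gene_set_db()]), and `truth`
#'   (class `ground_truth`: `common_up`, `common_down`, `specific` per
#'   conversion, `de_tfs` per conversion, `decoy_tfs`, `universe`).
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  with_seed(cfg$seed, generate_study_impl(cfg))
}

generate_study_impl <- function(cfg) {
  convs <- cfg$conversions
  master_tfs <- normalize_symbols(cfg$tf_regulons$tf)
  decoy_tfs <- if (cfg$n_decoy_tfs > 0) sprintf("TFDECOY%02d", seq_len(cfg$n_decoy_tfs)) else character()
  n_plain <- cfg$n_genes - length(master_tfs) - length(decoy_tfs)
  genes <- c(sprintf("G%05d", seq_len(n_plain)), master_tfs, decoy_tfs)
  plain <- genes[seq_len(n_plain)]

  # disjoint planted sets drawn from the plain-gene pool
  pool <- sample(plain)
  take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; sort(out) }
  common_up <- take(cfg$common_up)
  common_down <- take(cfg$common_down)
  specific <- lapply(seq_len(nrow(convs)), function(i) {
    g <- take(cfg$specific_per_conversion)
    up <- sort(sample(g, floor(length(g) / 2)))
    list(up = up, down = sort(setdiff(g, up)))
  })
  names(specific) <- convs$name

  # signed log2 shift per gene and conversion
  delta <- matrix(0, length(genes), nrow(convs),
                  dimnames = list(genes, convs$name))
  e <- cfg$effect_log2
  delta[common_up, ] <- e
  delta[common_down, ] <- -e
  for (cn in convs$name) {
    for (other in convs$name) {
      s <- if (other == cn) 1 else -1
      delta[specific[[cn]]$up, other] <- s * e
      delta[specific[[cn]]$down, other] <- -s * e
    }
  }
  for (r in seq_len(nrow(cfg$tf_regulons))) {
    delta[normalize_symbols(cfg$tf_regulons$tf[r]), cfg$tf_regulons$conversion[r]] <-
      cfg$tf_regulons$tf_effect_log2[r]
  }

  datasets <- list()
  for (ci in seq_len(nrow(convs))) {
    cn <- convs$name[ci]
    reps <- convs$replicates_per_group[ci]
    for (k in seq_len(convs$n_datasets[ci])) {
      id <- sprintf("%s_ds%d", cn, k)
      baseline <- stats::rnorm(length(genes), cfg$baseline_log2_mean, cfg$baseline_log2_sd)
      noise <- function() matrix(stats::rnorm(length(genes) * reps, 0, cfg$noise_sd_log2),
                                 length(genes), reps)
      ori <- baseline + noise()
      tgt <- baseline + delta[, cn] + noise()
      vals <- 2^cbind(ori, tgt)
      samples <- c(sprintf("%s_origin_%d", id, seq_len(reps)),
                   sprintf("%s_target_%d", id, seq_len(reps)))
      dimnames(vals) <- list(genes, samples)
      groups <- stats::setNames(rep(c("origin", "target"), each = reps), samples)
      datasets[[id]] <- expression_dataset(id, vals, groups,
                                           organism = "synthetic", conversion = cn)
    }
  }

  truth <- structure(
    list(common_up = common_up, common_down = common_down, specific = specific,
         de_tfs = stats::setNames(lapply(convs$name, function(cn)
           master_tfs[cfg$tf_regulons$conversion == cn]), convs$name),
         decoy_tfs = decoy_tfs, universe = sort(genes),
         effect_log2 = e, conversions = convs$name),
    class = "ground_truth")

  # regulons: planted fraction of each master regulon drawn from its home
  # conversion's DEG pool, the remainder (and all decoy regulons) from
  # never-differential genes
  planted_all <- unique(c(common_up, common_down,
                          unlist(lapply(specific, unlist), use.names = FALSE)))
  neutral <- setdiff(plain, planted_all)
  sets <- list()
  for (r in seq_len(nrow(cfg$tf_regulons))) {
    tf <- normalize_symbols(cfg$tf_regulons$tf[r])
    size <- cfg$tf_regulons$size[r]
    deg_pool <- conversion_truth_genes(truth, cfg$tf_regulons$conversion[r],
                                       include_tfs = FALSE)
    n_de <- round(cfg$tf_regulons$de_fraction[r] * size)
    if (n_de > length(deg_pool)) {
      stopf("regulon of %s needs %d DE targets but only %d planted DE genes exist",
            tf, n_de, length(deg_pool))
    }
    if (size - n_de > length(neutral)) stopf("regulon of %s larger than the neutral pool", tf)
    sets[[tf]] <- c(sample(deg_pool, n_de), sample(neutral, size - n_de))
  }
  for (dtf in decoy_tfs) {
    sets[[dtf]] <- sample(neutral, min(cfg$decoy_regulon_size, length(neutral)))
  }
  regulons <- gene_set_db(sets, universe = genes)

  terms <- generate_term_db(truth, n_decoy_terms = cfg$n_decoy_terms,
                            seed = cfg$seed + 7L)

  list(datasets = datasets, regulons = regulons, terms = terms, truth = truth)
}

# All genes planted differential in `conversion` (ignoring direction).
conversion_truth_genes <- function(truth, conversion, include_tfs = TRUE) {
  ct <- conversion_truth(truth, conversion, include_tfs = include_tfs)
  sort(c(ct$up, ct$down))
}

#' Planted per-conversion differential genes with their expected direction
#'
#' Resolves the planted design for one conversion: shared genes keep their
#' sign, home-specific genes keep theirs, specific genes of other conversions
#' appear with the opposite sign, and (optionally) the conversion's master
#' TFs appear as up-regulated.
#'
#' @param truth A `ground_truth` from [generate_study()].
#' @param conversion Conversion name.
#' @param include_tfs Include the conversion's planted master TFs (default
#'   `TRUE`).
#' @return List with sorted character vectors `up` and `down`.
#' @export
conversion_truth <- function(truth, conversion, include_tfs = TRUE) {
  if (!conversion %in% truth$conversions) stopf("unknown conversion '%s'", conversion)
  up <- c(truth$common_up, truth$specific[[conversion]]$up)
  down <- c(truth$common_down, truth$specific[[conversion]]$down)
  for (other in setdiff(truth$conversions, conversion)) {
    up <- c(up, truth$specific[[other]]$down)   # opposite sign away from home
    down <- c(down, truth$specific[[other]]$up)
  }
  if (include_tfs) up <- c(up, truth$de_tfs[[conversion]])
  list(up = sort(unique(up)), down = sort(unique(down)))
}

#' Generate an ontology-style term database from planted truth
#'
#' One term per planted signature (the signature plus a little random
#' padding) and a configurable number of decoy terms drawn uniformly from the
#' universe.
#'
#' @param truth A `ground_truth` from [generate_study()].
#' @param n_decoy_terms Number of decoy terms.
#' @param seed Integer seed.
#' @param padding Random extra genes added to each signature term.
#' @param decoy_size_range Inclusive size range for decoy terms.
#' @return A [gene_set_db()] over `truth$universe`.
#' @export
generate_term_db <- function(truth, n_decoy_terms = 30, seed = 1,
                             padding = 5, decoy_size_range = c(10, 50)) {
  with_seed(seed, {
    uni <- truth$universe
    pad <- function(sig) sort(unique(c(sig, sample(setdiff(uni, sig), padding))))
    sets <- list(COMMON_UP = pad(truth$common_up),
                 COMMON_DOWN = pad(truth$common_down))
    desc <- c(COMMON_UP = "planted shared up signature",
              COMMON_DOWN = "planted shared down signature")
    for (cn in names(truth$specific)) {
      nm <- paste0("SPECIFIC_", toupper(cn))
      sets[[nm]] <- pad(unlist(truth$specific[[cn]], use.names = FALSE))
      desc[nm] <- paste("planted specific signature of", cn)
    }
    for (i in seq_len(n_decoy_terms)) {
      nm <- sprintf("DECOY_TERM%03d", i)
      sets[[nm]] <- sort(sample(uni, sample(decoy_size_range[1]:decoy_size_range[2], 1)))
      desc[nm] <- "decoy term"
    }
    gene_set_db(sets, descriptions = desc, universe = uni)
  })
}

#' Write a generated study to disk
#'
#' Emits one expression TSV + groups TSV per dataset, the regulon and term
#' GMT files, and a plain-text truth manifest.
#'
#' @param study Result of [generate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (ds in study$datasets) {
    m <- file.path(dir, paste0(ds$dataset_id, ".tsv"))
    g <- file.path(dir, paste0(ds$dataset_id, ".groups.tsv"))
    write_expression_matrix(ds, m, g)
    paths <- c(paths, m, g)
  }
  write_gmt(study$regulons, file.path(dir, "regulons.gmt"))
  write_gmt(study$terms, file.path(dir, "terms.gmt"))
  truth_rows <- c(
    paste("common_up", study$truth$common_up, sep = "\t"),
    paste("common_down", study$truth$common_down, sep = "\t"),
    unlist(lapply(names(study$truth$specific), function(cn) {
      c(paste(paste0("specific_up_", cn), study$truth$specific[[cn]]$up, sep = "\t"),
        paste(paste0("specific_down_", cn), study$truth$specific[[cn]]$down, sep = "\t"))
    })),
    unlist(lapply(names(study$truth$de_tfs), function(cn) {
      paste(paste0("de_tf_", cn), study$truth$de_tfs[[cn]], sep = "\t")
    })))
  writeLines(truth_rows, file.path(dir, "truth.tsv"))
  paths <- c(paths, file.path(dir, c("regulons.gmt", "terms.gmt", "truth.tsv")))
  invisible(paths)
}
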