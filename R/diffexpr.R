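# Per-dataset differential expression between origin and target cells:
# linear fold change, Welch test on log2 intensities, and a three-way
# direction call (up / down / none).

#' Differential-expression thresholds
#'
#' @param p_max Maximum p-value for a testable gene to be called (default
#'   0.05, the conventional cutoff for these conversion studies).
#' @param fc_min Minimum linear fold-change magnitude (default 1.5) used for
#'   untestable genes in `fc_only` mode and for downstream fold-change gates.
#' @param single_sample_mode How to call genes in datasets where a group has a
#'   single sample (no within-group variance): `"fc_only"` calls by fold
#'   change alone, `"strict"` always returns `none`.
#' @return A list of class `de_thresholds`.
#' @export
de_thresholds <- function(p_max = 0.05, fc_min = 1.5,
                          single_sample_mode = c("fc_only", "strict")) {
  if (!is.numeric(p_max) || p_max <= 0 || p_max > 1) stopf("`p_max` must be in (0, 1]")
  if (!is.numeric(fc_min) || fc_min < 1) stopf("`fc_min` must be >= 1")
  structure(list(p_max = p_max, fc_min = fc_min,
                 single_sample_mode = match.arg(single_sample_mode)),
            class = "de_thresholds")
}

# Group means on the linear scale, floored at a small pseudocount so ratios
# are finite on sparse or synthetic data.
group_means <- function(ds) {
  ori <- ds$values[, ds$groups == "origin", drop = FALSE]
  tgt <- ds$values[, ds$groups == "target", drop = FALSE]
  if (ncol(ori) == 0L || ncol(tgt) == 0L) stopf("both groups need at least one sample")
  floor_at <- 1e-6 * stats::median(ds$values)
  if (floor_at <= 0) floor_at <- 1e-12
  list(origin = pmax(rowMeans(ori), floor_at),
       target = pmax(rowMeans(tgt), floor_at),
       n_origin = ncol(ori), n_target = ncol(tgt))
}

#' Per-gene fold change between target and origin cells
#'
#' Fold change is the ratio of the target-group mean to the origin-group mean,
#' computed on the linear intensity scale; group means are floored at a small
#' pseudocount (1e-6 of the global matrix median) before division.
#'
#' @param ds An [expression_dataset()].
#' @return Data frame with columns `gene`, `fc_linear`, `log2fc`.
#' @export
fold_change <- function(ds) {
  gm <- group_means(ds)
  fc <- gm$target / gm$origin
  data.frame(gene = ds$genes, fc_linear = fc, log2fc = log2(fc),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene Welch test p-values on log2 intensities
#'
#' Welch's unequal-variance two-sample t test comparing target vs origin on
#' the log2 scale, vectorized over genes. When either group has exactly one
#' sample the gene is untestable: `p_value` is `NA` and `testable` is `FALSE`.
#' Degenerate zero-variance genes get p = 1 when the group means are equal and
#' p = 0 otherwise (the limit of the statistic).
#'
#' @param ds An [expression_dataset()].
#' @return Data frame with columns `gene`, `p_value`, `testable`.
#' @export
p_values <- function(ds) {
  ori <- ds$values[, ds$groups == "origin", drop = FALSE]
  tgt <- ds$values[, ds$groups == "target", drop = FALSE]
  if (ncol(ori) == 0L || ncol(tgt) == 0L) stopf("both groups need at least one sample")
  testable <- ncol(ori) >= 2L && ncol(tgt) >= 2L
  if (!testable) {
    return(data.frame(gene = ds$genes, p_value = NA_real_, testable = FALSE,
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  floor_at <- 1e-6 * stats::median(ds$values)
  if (floor_at <= 0) floor_at <- 1e-12
  lo <- log2(pmax(ori, floor_at))
  lt <- log2(pmax(tgt, floor_at))
  n1 <- ncol(lo); n2 <- ncol(lt)
  m1 <- rowMeans(lo); m2 <- rowMeans(lt)
  v1 <- rowSums((lo - m1)^2) / (n1 - 1L)
  v2 <- rowSums((lt - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  d <- m2 - m1
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- ifelse(se2 == 0, ifelse(d == 0, 1, 0),
              2 * stats::pt(-abs(d / sqrt(se2)), df))
  data.frame(gene = ds$genes, p_value = p, testable = TRUE,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Three-way direction calls from fold change and p-value
#'
#' Testable genes are called `up` when p <= `p_max` and log2 fold change is
#' positive, `down` when p <= `p_max` and it is negative, otherwise `none`.
#' Untestable genes (single-sample groups) are called by fold-change magnitude
#' alone in `fc_only` mode, and always `none` in `strict` mode.
#'
#' @param de A `de_result` data frame (see [run_de()]) or any data frame with
#'   columns `fc_linear`, `log2fc`, `p_value`, `testable`.
#' @param thresholds A [de_thresholds()] object.
#' @return Character vector of `"up"`/`"down"`/`"none"`, one per gene.
#' @export
call_directions <- function(de, thresholds = de_thresholds()) {
  dir <- rep("none", nrow(de))
  t_ok <- de$testable & !is.na(de$p_value) & de$p_value <= thresholds$p_max
  dir[t_ok & de$log2fc > 0] <- "up"
  dir[t_ok & de$log2fc < 0] <- "down"
  if (thresholds$single_sample_mode == "fc_only") {
    u_ok <- !de$testable & fc_magnitude(de$fc_linear) >= thresholds$fc_min
    dir[u_ok & de$log2fc > 0] <- "up"
    dir[u_ok & de$log2fc < 0] <- "down"
  }
  dir
}

#' Full per-dataset differential-expression result
#'
#' Combines [fold_change()], [p_values()] and [call_directions()] into one
#' table.
#'
#' @inheritParams fold_change
#' @inheritParams call_directions
#' @return A data frame of class `de_result` with columns `gene`, `fc_linear`,
#'   `log2fc`, `p_value`, `testable`, `direction`, plus attributes
#'   `dataset_id` and `conversion`.
#' @export
run_de <- function(ds, thresholds = de_thresholds()) {
  fc <- fold_change(ds)
  pv <- p_values(ds)
  de <- cbind(fc, pv[, c("p_value", "testable")])
  de$direction <- call_directions(de, thresholds)
  attr(de, "dataset_id") <- ds$dataset_id
  attr(de, "conversion") <- ds$conversion
  class(de) <- c("de_result", "data.frame")
  de
}

#' Write a per-dataset DE table as TSV
#'
#' @param de A `de_result` from [run_de()].
#' @param path Output path.
#' @export
write_de_table <- function(de, path) {
  out <- as.data.frame(de)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
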