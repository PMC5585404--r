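# Conversion-specific signatures: genes differential in the target conversion
# whose pattern is opposite in (almost) all other datasets, tolerating a small
# number of identical-pattern exceptions (the fine-tuning rule).

#' Specificity rule
#'
#' @param min_opposite Number of *other* datasets that must show the opposite
#'   direction. `NULL` (default) resolves at evaluation time to
#'   `n_other - max_identical`, the "at least seven out of nine other data
#'   sets" reading.
#' @param max_identical Number of other datasets allowed to show the identical
#'   direction (default 2, the exception-tolerance clause).
#' @param fc_min Fold-change magnitude each supporting dataset of the target
#'   conversion must meet (default 1.5).
#' @param fc_on_opposite If `TRUE`, the fold-change gate is applied to the
#'   opposite calls in other datasets too (default `FALSE`).
#' @return A list of class `specificity_rule`.
#' @export
specificity_rule <- function(min_opposite = NULL, max_identical = 2,
                             fc_min = 1.5, fc_on_opposite = FALSE) {
  if (!is.null(min_opposite)) min_opposite <- assert_count(min_opposite, "min_opposite", positive = FALSE)
  max_identical <- assert_count(max_identical, "max_identical", positive = FALSE)
  if (!is.null(fc_min) && (!is.numeric(fc_min) || fc_min < 1)) {
    stopf("`fc_min` must be >= 1 or NULL")
  }
  structure(list(min_opposite = min_opposite, max_identical = max_identical,
                 fc_min = fc_min, fc_on_opposite = isTRUE(fc_on_opposite)),
            class = "specificity_rule")
}

# Decide inclusion for a single gene given its call vector over the other
# datasets; exported logic lives in specific_signature().
specific_vote <- function(target_direction, other_calls, rule,
                          other_fcs = NULL) {
  opp <- opposite_dir[[target_direction]]
  is_opp <- other_calls == opp
  if (rule$fc_on_opposite && !is.null(rule$fc_min) && !is.null(other_fcs)) {
    is_opp <- is_opp & fc_magnitude(other_fcs) >= rule$fc_min
  }
  n_opp <- sum(is_opp)
  n_ident <- sum(other_calls == target_direction)
  min_opp <- rule$min_opposite %||% max(0L, length(other_calls) - rule$max_identical)
  c(include = n_opp >= min_opp && n_ident <= rule$max_identical,
    opposite_count = n_opp, identical_count = n_ident)
}

#' Conversion-specific signature
#'
#' A gene is specific to the target conversion iff (a) it is in the
#' conversion-level DEG list, with every supporting dataset of the home
#' conversion passing the fold-change gate; (b) among the datasets of all
#' *other* conversions, at least `min_opposite` show the opposite direction;
#' and (c) at most `max_identical` show the identical direction. `none` calls
#' count toward neither bound.
#'
#' @param target_degs `deg_list` from [merge_conversion()] for the target
#'   conversion.
#' @param table The study-wide [direction_table()].
#' @param rule A [specificity_rule()].
#' @param conversion Target conversion name; defaults to the `conversion`
#'   attribute of `target_degs`.
#' @return Data frame `gene`, `direction`, `opposite_count`,
#'   `identical_count`, sorted by gene; attributes `conversion`, `n_up`,
#'   `n_down`.
#' @export
specific_signature <- function(target_degs, table, rule = specificity_rule(),
                               conversion = attr(target_degs, "conversion")) {
  if (is.null(conversion) || !conversion %in% table$datasets$conversion) {
    stopf("unknown target conversion '%s'", conversion %||% "<NULL>")
  }
  home <- table$datasets$conversion == conversion
  n_other <- sum(!home)
  min_opp <- rule$min_opposite %||% max(0L, n_other - rule$max_identical)
  # max_identical is an allowance, not a requirement, so only the opposite
  # count constrains feasibility
  if (min_opp > n_other) {
    stopf("rule infeasible: min_opposite (%d) exceeds the %d other datasets",
          min_opp, n_other)
  }
  other <- table_subset(table, !home)
  home_sub <- table_subset(table, home)
  rows <- lapply(seq_len(nrow(target_degs)), function(r) {
    g <- target_degs$gene[r]
    d <- target_degs$direction[r]
    i <- match(g, table$genes)
    if (is.na(i)) return(NULL)
    if (!is.null(rule$fc_min)) {
      support <- home_sub$calls[i, ] == d
      if (any(support) && !all(fc_magnitude(home_sub$fc[i, support]) >= rule$fc_min)) {
        return(NULL)
      }
    }
    v <- specific_vote(d, other$calls[i, ], rule, other$fc[i, ])
    if (!v[["include"]]) return(NULL)
    data.frame(gene = g, direction = d,
               opposite_count = as.integer(v[["opposite_count"]]),
               identical_count = as.integer(v[["identical_count"]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(gene = character(), direction = character(),
                                                opposite_count = integer(),
                                                identical_count = integer(),
                                                stringsAsFactors = FALSE))))
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "conversion") <- conversion
  attr(out, "n_up") <- sum(out$direction == "up")
  attr(out, "n_down") <- sum(out$direction == "down")
  out
}
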