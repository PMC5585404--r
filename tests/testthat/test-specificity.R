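make_spec_table <- function(target_call, other_calls) {
  calls <- cbind(home = target_call,
                 matrix(other_calls, nrow = 1,
                        dimnames = list(NULL, paste0("o", seq_along(other_calls)))))
  rownames(calls) <- "GX"
  fake_table(calls, conversions = c("home", paste0("c", seq_along(other_calls))))
}

run_spec <- function(target_call, other_calls, rule) {
  tb <- make_spec_table(target_call, other_calls)
  degs <- merge_conversion(tb, "home")
  specific_signature(degs, tb, rule, conversion = "home")
}

test_that("the exception-tolerance rule admits and rejects as stated", {
  rule <- specificity_rule(min_opposite = 7, max_identical = 2)
  hit <- run_spec("up", c(rep("down", 7), "up"), rule)
  expect_equal(hit$gene, "GX")
  expect_equal(hit$opposite_count, 7L)
  expect_equal(hit$identical_count, 1L)
  miss <- run_spec("up", c(rep("down", 5), rep("up", 3)), rule)
  expect_equal(nrow(miss), 0)
  # none calls count toward neither bound
  nones <- run_spec("up", c(rep("down", 7), "none"),
                    specificity_rule(min_opposite = 7, max_identical = 0))
  expect_equal(nrow(nones), 1)
})

test_that("an infeasible rule for the study's dataset count errors", {
  tb <- make_spec_table("up", rep("down", 3))
  degs <- merge_conversion(tb, "home")
  expect_error(specific_signature(degs, tb,
                                  specificity_rule(min_opposite = 4, max_identical = 2),
                                  conversion = "home"),
               "infeasible")
  # the headline rule (7 opposite, 2 identical allowed) is legal over 8 others
  expect_no_error(run_spec("up", rep("down", 8),
                           specificity_rule(min_opposite = 7, max_identical = 2)))
})

test_that("inclusion matches the exhaustive counting oracle for <= 6 others", {
  for (n_other in c(3L, 5L)) {
    grids <- expand.grid(rep(list(c("up", "down", "none")), n_other),
                         stringsAsFactors = FALSE)
    rule <- specificity_rule(min_opposite = n_other - 2L, max_identical = 1L)
    for (r in seq_len(nrow(grids))) {
      others <- unlist(grids[r, ], use.names = FALSE)
      got <- nrow(run_spec("up", others, rule)) == 1L
      want <- specific_oracle("up", others, n_other - 2L, 1L)
      if (got != want) {
        fail(sprintf("mismatch at others = %s", paste(others, collapse = ",")))
      }
    }
    succeed()
  }
})

test_that("specific lists are disjoint and respond monotonically to the rule", {
  st <- generate_study(small_study_config(seed = 41, noise = 0.5))
  de <- lapply(st$datasets, run_de)
  tb <- direction_table(de)
  convs <- unique(tb$datasets$conversion)
  degs <- lapply(convs, function(cn) merge_conversion(tb, cn))
  names(degs) <- convs
  rule <- specificity_rule(min_opposite = 4, max_identical = 2)  # 2 < 4
  lists <- lapply(convs, function(cn)
    specific_signature(degs[[cn]], tb, rule, conversion = cn)$gene)
  for (i in seq_along(lists)) {
    for (j in seq_along(lists)) {
      if (i < j) expect_length(intersect(lists[[i]], lists[[j]]), 0)
    }
  }
  relaxed <- specific_signature(degs[["b"]], tb,
                                specificity_rule(min_opposite = 4, max_identical = 3),
                                conversion = "b")$gene
  stricter <- specific_signature(degs[["b"]], tb,
                                 specificity_rule(min_opposite = 5, max_identical = 2),
                                 conversion = "b")$gene
  base <- specific_signature(degs[["b"]], tb, rule, conversion = "b")$gene
  expect_true(all(base %in% relaxed))
  expect_true(all(stricter %in% base))
})

test_that("planted specific genes are recovered; planted common genes never are", {
  st <- generate_study(small_study_config(seed = 43, noise = 0))
  de <- lapply(st$datasets, run_de)
  tb <- direction_table(de)
  for (cn in names(st$truth$specific)) {
    degs <- merge_conversion(tb, cn)
    sp <- specific_signature(degs, tb, specificity_rule(), conversion = cn)
    truth <- st$truth$specific[[cn]]
    expect_setequal(sp$gene, c(truth$up, truth$down))
    expect_length(intersect(sp$gene, c(st$truth$common_up, st$truth$common_down)), 0)
  }
})
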