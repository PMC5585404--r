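test_that("vote applies the m-of-n count, the opposite veto and the fc gate", {
  expect_equal(vote(c(rep("down", 8), "none"), vote_rule(8)), "down")
  expect_equal(vote(c("up", "up", "down"), vote_rule(2, forbid_opposite = TRUE)),
               "none")
  expect_equal(vote(c("up", "up", "down"), vote_rule(2, forbid_opposite = FALSE)),
               "up")
  expect_equal(vote(rep("none", 4), vote_rule(2)), "none")
  expect_error(vote(character(), vote_rule(1)), "empty")
  # fc gate applies to every supporting dataset
  fcs <- c(rep(1 / 4, 8), 1 / 1.2)
  calls <- c(rep("down", 8), "none")   # the weak-fc dataset is the non-supporter
  expect_equal(vote(calls, vote_rule(8, FALSE, fc_min = 1.5), fcs), "down")
  calls[9] <- "down"                   # now it supports, and fails the gate
  expect_equal(vote(calls, vote_rule(8, FALSE, fc_min = 1.5), fcs), "none")
})

test_that("vote is permutation-invariant and monotone in agreeing evidence", {
  withr::local_seed(404)
  for (i in 1:50) {
    n <- sample(3:7, 1)
    calls <- sample(c("up", "down", "none"), n, replace = TRUE)
    fcs <- exp(rnorm(n))
    rule <- vote_rule(sample(seq_len(n), 1), sample(c(TRUE, FALSE), 1),
                      fc_min = 1.5)
    perm <- sample(n)
    expect_equal(vote(calls[perm], rule, fcs[perm]), vote(calls, rule, fcs))
    v <- vote(calls, rule, fcs)
    if (v != "none") {
      expect_equal(vote(c(calls, v), rule, c(fcs, 4)), v)
    }
  }
})

test_that("merge_conversion passes single datasets through and votes multi-dataset ones", {
  calls <- cbind(ds1 = c("up", "down", "none"))
  rownames(calls) <- c("A", "B", "C")
  tb <- fake_table(calls, conversions = "solo")
  m <- merge_conversion(tb, "solo")
  expect_equal(m$gene, c("A", "B"))
  expect_equal(m$direction, c("up", "down"))
  expect_error(merge_conversion(tb, "nope"), "unknown conversion")

  calls4 <- matrix("none", 2, 4,
                   dimnames = list(c("A", "B"), paste0("d", 1:4)))
  calls4["A", 1:3] <- "up"
  calls4["B", 1:2] <- "up"
  tb4 <- fake_table(calls4, conversions = rep("quad", 4))
  m4 <- merge_conversion(tb4, "quad", vote_rule(3))
  expect_equal(m4$gene, "A")
  expect_equal(m4$direction, "up")
})

test_that("the common signature and its strict fold-change tier nest correctly", {
  calls <- matrix("down", 3, 9, dimnames = list(c("A", "B", "C"), paste0("d", 1:9)))
  calls["B", 1:2] <- "none"        # only 7/9 support
  fcs <- matrix(1 / 4, 3, 9, dimnames = dimnames(calls))
  fcs["C", 5] <- 1 / 1.2           # weak fold change in one supporter
  tb <- fake_table(calls, conversions = paste0("c", 1:9), fcs = fcs)
  sig <- common_signature(tb, vote_rule(8, forbid_opposite = FALSE))
  expect_setequal(sig$all$gene, c("A", "C"))
  expect_equal(sig$strict$gene, "A")
  expect_true(all(sig$strict$gene %in% sig$all$gene))
})

test_that("planted common genes survive the study-wide vote", {
  st <- generate_study(small_study_config(seed = 31, noise = 0))
  de <- lapply(st$datasets, run_de)
  tb <- direction_table(de)
  sig <- common_signature(tb)
  expect_setequal(sig$all$gene, c(st$truth$common_up, st$truth$common_down))
  expect_setequal(sig$strict$gene, sig$all$gene)
})

test_that("concordance of regulon targets between studies behaves at the extremes", {
  db <- gene_set_db(list(TFX = c("G1", "G2", "G3")), universe = paste0("G", 1:5))
  a <- data.frame(gene = c("G1", "G2", "G3"), direction = c("up", "down", "none"))
  expect_equal(cross_species_concordance("TFX", a, a, db), 1.0)
  b <- a
  b$direction <- c("down", "up", "none")
  expect_equal(cross_species_concordance("TFX", a, b, db), 0.0)
  expect_error(cross_species_concordance("TFZ", a, a, db), "unknown TF")
  none <- data.frame(gene = "G1", direction = "none")
  out <- cross_species_concordance("TFX", a, none, db)
  expect_true(is.na(out))
  expect_true(attr(out, "undefined"))
})

test_that("replicate datasets of one planted design agree on regulon target directions", {
  # same planted regulon directions, independent noise realizations: split a
  # 3-dataset conversion into two disjoint "studies" and compare calls
  st <- generate_study(small_study_config(seed = 61, noise = 0.5))
  de <- lapply(st$datasets, run_de)
  m1 <- merge_conversion(direction_table(de["c_ds1"]), "c")
  m2 <- merge_conversion(direction_table(de[c("c_ds2", "c_ds3")]), "c",
                         vote_rule(2, forbid_opposite = TRUE))
  conc <- cross_species_concordance(st$truth$de_tfs$c, m1, m2, st$regulons)
  expect_gte(conc, 0.9)
})
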