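test_that("regulon over-representation matches the enumerated upper tail", {
  uni <- paste0("G", 1:10)
  db <- gene_set_db(list(TFA = uni[1:4]), universe = uni)
  enr <- tf_enrichment(uni[c(1, 2, 3, 9, 10)], db)  # N=10, K=4, n=5, overlap=3
  expect_equal(enr$p_value, 66 / 252, tolerance = 1e-12)
  expect_equal(enr$p_value, enum_hyper(10, 4, 5, 3)[["upper"]], tolerance = 1e-12)
  # overlap 0 -> tail probability 1; regulon inside degs = universe -> 1
  expect_equal(tf_enrichment(uni[9:10], db)$p_value, 1)
  expect_equal(tf_enrichment(uni, db)$p_value, 1)
  expect_error(tf_enrichment("G1", db, universe = character()), "empty")
  expect_warning(tf_enrichment(c("G1", "NOTHERE"), db), "dropped")
})

test_that("enrichment p responds monotonically to regulon edits", {
  uni <- paste0("G", 1:12)
  degs <- uni[1:5]
  p_of <- function(reg) tf_enrichment(degs, gene_set_db(list(TF = reg), universe = uni))$p_value
  for (reg_size in 2:5) {
    reg <- uni[6:(5 + reg_size)]          # no DEG members yet
    for (g in degs[1:3]) {
      expect_lte(p_of(c(reg, g)), p_of(reg))       # adding a DEG: p never rises
    }
    expect_gte(p_of(c(reg, uni[12])), p_of(reg))   # adding a non-DEG: p never falls
  }
})

test_that("DE-TF filtering needs both the enrichment and fold-change gates", {
  enr <- data.frame(tf = c("A", "B", "C", "D"),
                    overlap = 3, regulon_size = 5,
                    p_value = c(0.03, 0.03, 0.20, 0.03))
  de <- data.frame(gene = c("A", "B", "C"),
                   direction = c("up", "up", "up"),
                   fc_linear = c(1.6, 1.2, 3.0))
  out <- filter_de_tfs(enr, de)
  expect_equal(out$tf, "A")          # B fails fc, C fails p, D is not expressed DE
  expect_equal(out$direction, "up")
  # down-regulated TFs pass via the reciprocal magnitude
  de$fc_linear[1] <- 1 / 1.6
  de$direction[1] <- "down"
  expect_equal(filter_de_tfs(enr, de)$direction, "down")
})

test_that("GRN edges are the regulon-DEG intersection with the self-loop rule", {
  uni <- c("A", paste0("G", 1:9))
  db <- gene_set_db(list(A = c("G1", "G2", "G5"), B = c("A", "G1")), universe = uni)
  g <- build_grn("A", c("G1", "G5", "G7"), db)
  expect_equal(g$edges, data.frame(tf = c("A", "A"), target = c("G1", "G5")))
  expect_equal(nrow(build_grn(character(), c("G1"), db)$edges), 0)
  expect_error(build_grn("NOPE", "G1", db), "absent")
  # self-loop kept only when the TF is itself a DEG
  db2 <- gene_set_db(list(A = c("A", "G1")), universe = uni)
  expect_true("A" %in% build_grn("A", c("A", "G1"), db2)$edges$target)
  expect_false("A" %in% build_grn("A", c("G1"), db2)$edges$target)
})

test_that("the core network keeps only TF-TF edges and nests in the full GRN", {
  uni <- c("A", "B", paste0("G", 1:9))
  db <- gene_set_db(list(A = c("B", "G9"), B = c("G1")), universe = uni)
  core <- build_core_network(c("A", "B"), db)
  expect_equal(core$edges, data.frame(tf = "A", target = "B"))
  degs <- c("A", "B", "G1", "G9")
  full <- build_grn(c("A", "B"), degs, db)
  expect_true(all(paste(core$edges$tf, core$edges$target) %in%
                    paste(full$edges$tf, full$edges$target)))
  # a TF regulating all other DE-TFs ranks first in the core ranking
  db3 <- gene_set_db(list(M = c("A", "B"), A = c("G1"), B = c("G2")),
                     universe = uni)
  rk <- out_degree_ranking(build_core_network(c("M", "A", "B"), db3))
  expect_equal(rk$tf[1], "M")
})

test_that("out-degree ranking sorts, breaks ties alphabetically and conserves edges", {
  g <- grn(c("A", "A", "B"), c("G1", "G2", "G1"))
  rk <- out_degree_ranking(g)
  expect_equal(rk, data.frame(tf = c("A", "B"), out_degree = c(2L, 1L),
                              rank = c(1L, 2L)))
  expect_equal(nrow(out_degree_ranking(grn())), 0)
  tie <- grn(c("Z", "M", "Z", "M"), c("G1", "G1", "G2", "G2"))
  rk2 <- out_degree_ranking(tie)
  expect_equal(rk2$tf, c("M", "Z"))
  expect_equal(rk2$rank, c(1L, 1L))
  expect_equal(sum(rk2$out_degree), nrow(tie$edges))
})

test_that("the planted master regulator's DE targets all appear as edges", {
  st <- generate_study(small_study_config(seed = 47, noise = 0))
  de <- lapply(st$datasets, run_de)
  tb <- direction_table(de)
  degs <- merge_conversion(tb, "c")
  enr <- tf_enrichment(degs$gene, st$regulons,
                       intersect(st$regulons$universe, tb$genes))
  detfs <- filter_de_tfs(enr, degs)
  tf <- st$truth$de_tfs$c
  expect_true(tf %in% detfs$tf)
  g <- build_grn(detfs, degs$gene, st$regulons)
  planted_targets <- intersect(st$regulons$sets[[tf]], degs$gene)
  expect_setequal(g$edges$target[g$edges$tf == tf], planted_targets)
  rk <- out_degree_ranking(g, top_k = 5)
  expect_true(tf %in% rk$tf)
})
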