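test_that("identical seeds give bit-identical studies", {
  cfg <- small_study_config(seed = 5, noise = 0.4)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$datasets[["c_ds2"]]$values, s2$datasets[["c_ds2"]]$values)
  expect_identical(s1$regulons$sets, s2$regulons$sets)
  expect_identical(s1$terms$sets, s2$terms$sets)
  expect_identical(s1$truth, s2$truth)
})

test_that("planted effects land on the group means with the planted sign", {
  cfg <- small_study_config(seed = 9, noise = 0.3)
  st <- generate_study(cfg)
  e <- cfg$effect_log2
  # 5 sigma of a difference of two 3-replicate means
  tol <- 5 * cfg$noise_sd_log2 * sqrt(2 / 3)
  for (ds in st$datasets) {
    lg <- log2(ds$values)
    diff <- rowMeans(lg[, ds$groups == "target"]) - rowMeans(lg[, ds$groups == "origin"])
    expect_true(all(abs(diff[st$truth$common_down] + e) < tol))
    expect_true(all(abs(diff[st$truth$common_up] - e) < tol))
    # specific genes: home sign at home, opposite sign elsewhere
    home_up <- st$truth$specific[[ds$conversion]]$up
    expect_true(all(diff[home_up] > 0))
    other <- setdiff(names(st$truth$specific), ds$conversion)[1]
    expect_true(all(diff[st$truth$specific[[other]]$up] < 0))
  }
})

test_that("the noiseless limit gives exact linear fold changes", {
  st <- generate_study(small_study_config(seed = 2, noise = 0))
  fc <- fold_change(st$datasets[[1]])
  up <- fc$fc_linear[match(st$truth$common_up, fc$gene)]
  expect_equal(up, rep(2^2, length(up)))
})

test_that("planted sets are disjoint and infeasible regulons error", {
  cfg <- small_study_config(seed = 3)
  st <- generate_study(cfg)
  tr <- st$truth
  sets <- c(list(tr$common_up, tr$common_down, unlist(tr$de_tfs)),
            unlist(lapply(tr$specific, unname), recursive = FALSE))
  all_g <- unlist(sets)
  expect_equal(anyDuplicated(all_g), 0L)
  bad <- cfg
  bad$tf_regulons$size <- 1000L
  expect_error(generate_study(bad), "regulon")
})

test_that("regulons hit each conversion's DEG pool at the configured fraction", {
  cfg <- small_study_config(seed = 13)
  st <- generate_study(cfg)
  for (cn in names(st$truth$de_tfs)) {
    tf <- st$truth$de_tfs[[cn]]
    pool <- conversion_truth(st$truth, cn, include_tfs = FALSE)
    ov <- length(intersect(st$regulons$sets[[tf]], c(pool$up, pool$down)))
    expect_equal(ov, round(0.5 * cfg$tf_regulons$size[1]))
  }
})

test_that("signature terms contain their signatures; decoys are truth-independent", {
  cfg <- small_study_config(seed = 21)
  st <- generate_study(cfg)
  expect_true(all(st$truth$common_down %in% st$terms$sets$COMMON_DOWN))
  expect_true(all(st$truth$specific$b$up %in% st$terms$sets$SPECIFIC_B))
  # mean Jaccard of decoy terms with the common signature, over seeds
  sig <- c(st$truth$common_up, st$truth$common_down)
  jac <- vapply(1:100, function(s) {
    db <- generate_term_db(st$truth, n_decoy_terms = 5, seed = s)
    decoys <- db$sets[grep("DECOY", names(db$sets))]
    mean(vapply(decoys, function(d)
      length(intersect(d, sig)) / length(union(d, sig)), 0))
  }, 0)
  # uniform decoy draws give E[Jaccard] ~= size*|sig|/N / (|sig| + size) ~ 0.02;
  # anything truth-coupled would sit far above that
  expect_lt(mean(jac), 0.05)
  expect_identical(generate_term_db(st$truth, 5, seed = 4)$sets,
                   generate_term_db(st$truth, 5, seed = 4)$sets)
})

test_that("raising the planted effect never hurts common-signature recovery", {
  f1_at <- function(effect) {
    cfg <- small_study_config(seed = 17, noise = 0.6)
    cfg$effect_log2 <- effect
    res <- run_study(pipeline_config(study = cfg,
                                     stages = c("specificity")))
    ev <- evaluate_against_truth(res)
    ev$f1[ev$metric == "common_signature"]
  }
  f1s <- vapply(c(0.5, 1.0, 2.0), f1_at, 0)
  expect_true(all(diff(f1s) >= 0))
})

test_that("write_study emits matrices, databases and a truth manifest", {
  dir <- withr::local_tempdir()
  st <- generate_study(small_study_config(seed = 1))
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "a_ds1.tsv")))
  expect_true(file.exists(file.path(dir, "regulons.gmt")))
  back <- read_gmt(file.path(dir, "regulons.gmt"),
                   universe = st$regulons$universe)
  expect_equal(back$sets[sort(names(back$sets))],
               st$regulons$sets[sort(names(st$regulons$sets))])
  truth_lines <- readLines(file.path(dir, "truth.tsv"))
  expect_true(any(grepl("^common_up\t", truth_lines)))
})
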