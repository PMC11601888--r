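test_that("schema has 57 features with the published category structure", {
  sch <- feature_schema()
  expect_equal(nrow(sch), 57)
  expect_equal(as.integer(table(sch$category)[c("C1", "C2", "C3")]),
               c(8, 46, 3))
  sub <- table(sch$subcategory)
  expect_equal(as.integer(sub[c("SE", "TE", "Accessibility", "3D")]),
               c(12, 23, 10, 1))
  expect_equal(as.integer(sub[c("TF", "Histone", "Methylation", "SNP")]),
               c(3, 1, 2, 2))
  # a broken schema is rejected before any computation
  bad <- data.table::copy(sch)[1, subcategory := "TF"]
  expect_error(validate_schema(bad), "SNP")
  expect_error(build_feature_matrix(worked_micro_example()$network,
                                    schema = sch[-1]), "57")
})

test_that("micro example features are the hand-computed values", {
  ex <- worked_micro_example()
  M <- build_feature_matrix(ex$network)
  expect_equal(dim(M), c(3, 57))
  A <- M["lncA", ]
  expect_equal(unname(A["tf_chip_count"]), 2)        # SOX2 + NANOG
  expect_equal(unname(A["tf_chip_core_count"]), 2)   # both core
  expect_equal(unname(A["tf_motif_count"]), 0)
  expect_equal(unname(A["histone_act_type_count"]), 2)
  expect_equal(unname(A["meth_count"]), 1)
  expect_equal(unname(A["meth_signal_norm"]), 1)     # the only lncRNA with any
  expect_equal(unname(A["se_d_count"]), 1)           # SE 40 kb away
  expect_equal(unname(A["se_i_count"]), 1)           # wired by the pair
  expect_equal(unname(A["se_i_rank_best"]), 1)       # single SE in pool
  expect_equal(unname(A["interaction_frequency"]), 3)
  expect_equal(unname(A["te_se_combined_count"]), 1)
  B <- M["lncB", ]
  expect_equal(unname(B["histone_act_type_count"]), 1)  # H3K4me3 twice
  expect_equal(unname(B["mrna_count"]), 2)
  expect_true(all(M["lncC", ] == 0))
})

test_that("per-lncRNA operations follow the distinctness rules", {
  ex <- worked_micro_example()
  net <- ex$network
  expect_equal(tf_count(net, "lncA", "chip_all"), 2)
  expect_equal(tf_count(net, "lncA", "chip_core",
                        core_tfs = c("SOX2", "MYC")), 1)
  expect_equal(tf_count(net, "lncC", "chip_all"), 0)
  expect_error(tf_count(net, "nosuch"), "unknown lncRNA")
  expect_equal(histone_type_count(net, "lncB"), 1)
  expect_equal(histone_type_count(net, "lncB",
                                  activating_marks = "H3K27me3"), 0)
  expect_equal(downstream_counts(net, "lncB"),
               c(n_mRNA = 2, n_miRNA = 0, n_protein = 0))
  expect_equal(interaction_frequency(net, "lncA"), 3)
  expect_equal(interaction_frequency(net, "lncC"), 0)
})

test_that("methylation normalization is cohort-relative min-max", {
  pr <- derive_promoters(data.table::data.table(
    id = c("l1", "l2"), chrom = "chr1", strand = "+",
    tss = c(10000, 50000)), 2000)
  sites <- intervals("chr1", c(9000, 9100, 49000), c(9002, 9102, 49002),
                     name = c("m1", "m2", "m3"), signal = c(2, 2, 8))
  net <- integrate_network(assign_proximal(pr, sites, "methylation"))
  expect_equal(site_features(net, "l1", "methylation"),
               c(count = 2, normalized_signal = 0.5))
  expect_equal(site_features(net, "l2", "methylation"),
               c(count = 1, normalized_signal = 1.0))
})

test_that("normalized rank follows (M - r + 1)/M against the kind pool", {
  ex <- worked_micro_example()
  net <- ex$network
  net$pools$enhancer_se <- c(10, 5, 1)
  # linked SE has signal 50 -> but rank against pool [10,5,1]: all <= 50
  f <- element_features(net, "lncA", "enhancer_se", "distance_assigned")
  expect_equal(unname(f["rank_best"]), 1)
  net$pools$enhancer_se <- c(10, 50, 100)
  f <- element_features(net, "lncA", "enhancer_se", "distance_assigned")
  expect_equal(unname(f["rank_best"]), 2 / 3)  # 50 ranks 2nd of 3
  # no linked elements -> all statistics zero
  f0 <- element_features(net, "lncC", "enhancer_se", "distance_assigned")
  expect_true(all(f0 == 0))
})

test_that("count features equal brute-force recounts from the edge list", {
  net <- default_network()
  M <- default_features()
  edges <- as.data.frame(net$edges)
  ids <- rownames(M)[seq(1, 200, by = 10)]  # 20 lncRNAs
  for (id in ids) {
    expect_equal(M[id, "tf_chip_count"],
                 bf_distinct_count(edges, id, "tf_chip"))
    expect_equal(M[id, "tf_chip_core_count"],
                 bf_distinct_count(edges, id, "tf_chip",
                                   names_in = CORE_TFS))
    expect_equal(M[id, "meth_count"],
                 bf_distinct_count(edges, id, "methylation"))
    expect_equal(M[id, "se_d_count"],
                 bf_distinct_count(edges, id, "enhancer_se",
                                   "distance_assigned"))
    expect_equal(M[id, "te_i_count"],
                 bf_distinct_count(edges, id, "enhancer_te",
                                   "chromatin_interaction"))
    expect_equal(M[id, "mrna_count"],
                 bf_distinct_count(edges, id, "mRNA"))
    expect_equal(M[id, "histone_act_type_count"],
                 bf_distinct_count(edges, id, "histone",
                                   names_in = ACTIVATING_MARKS))
  }
})

test_that("feature matrix invariants hold on the default world", {
  M <- default_features()
  sch <- attr(M, "schema")
  expect_false(anyNA(M))
  expect_true(all(M[, sch$name[sch$statistic %in%
    c("count", "distinct_count", "core_count", "type_count",
      "constituent_count", "prom_overlap_count", "sample_count",
      "combined_count")]] >= 0))
  norm_cols <- c("meth_signal_norm", sch$name[grepl("rank|dist_norm",
                                                    sch$name)])
  expect_true(all(M[, norm_cols] >= 0 & M[, norm_cols] <= 1))
  # row order permutation permutes rows only
  ids <- rev(rownames(M))
  M2 <- build_feature_matrix(default_network(), lncrna_ids = ids)
  expect_equal(M2[rownames(M), ], M[, ], ignore_attr = TRUE)
})

test_that("adding a regulator edge never decreases count features", {
  ex <- worked_micro_example()
  M0 <- build_feature_matrix(ex$network)
  extra <- assign_proximal(ex$promoters,
                           intervals("chr1", 9200, 9400, name = "KLF4",
                                     signal = 2), "tf_chip", "s9")
  net2 <- integrate_network(c(list(ex$network$edges), list(extra)),
                            lncrna_ids = ex$network$lncrnas,
                            pools = ex$network$pools)
  M1 <- build_feature_matrix(net2)
  count_stats <- c("count", "distinct_count", "core_count", "type_count",
                   "constituent_count", "combined_count")
  sch <- attr(M0, "schema")
  cols <- sch$name[sch$statistic %in% count_stats]
  expect_true(all(M1["lncA", cols] >= M0["lncA", cols]))
})

test_that("ranks are invariant to positive rescaling of all signals", {
  ex <- worked_micro_example()
  net <- ex$network
  net$pools$enhancer_se <- c(10, 50, 100)
  f1 <- element_features(net, "lncA", "enhancer_se", "distance_assigned")
  net2 <- net
  net2$edges <- data.table::copy(net$edges)[, signal := signal * 7.3]
  net2$pools$enhancer_se <- net$pools$enhancer_se * 7.3
  f2 <- element_features(net2, "lncA", "enhancer_se", "distance_assigned")
  expect_equal(f2[c("rank_mean", "rank_best")],
               f1[c("rank_mean", "rank_best")])
})

test_that("feature TSV round trip preserves the matrix", {
  M <- default_features()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_features(M, path)
  back <- read_features(path)
  expect_equal(back, M, ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(M))
})
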