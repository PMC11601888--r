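prom2 <- derive_promoters(data.table::data.table(
  id = c("lnc1", "lnc2"), chrom = "chr1", strand = "+",
  tss = c(10000, 10100)), 2000)

test_that("assign_proximal respects half-open overlap semantics", {
  # promoter lnc1 = [8000, 12000)
  el <- intervals("chr1", c(11500, 12000), c(12500, 12500),
                  name = c("in", "out"), signal = 1)
  e <- assign_proximal(prom2[1], el, "tf_chip", "s1")
  expect_equal(e$partner_id, "in")  # [12000, 12500) does not touch
  # one edge per (promoter, element) pair
  both <- assign_proximal(prom2, el[1], "histone")
  expect_equal(nrow(both), 2)
  expect_setequal(both$lncrna_id, c("lnc1", "lnc2"))
  expect_error(assign_proximal(prom2, el, "nope"), "unknown element kind")
})

test_that("assign_by_interaction needs opposite anchors and sums pair frequencies", {
  el <- intervals("chr1", 50000, 52000, name = "E", signal = 4)
  # element on anchor A, promoter on anchor B -> edge
  ap <- funlnc:::anchor_pairs_new(
    intervals("chr1", c(50500, 50600, 49000), c(51500, 51600, 49500),
              name = c("a1", "a2", "a3")),
    intervals("chr1", c(9000, 9500, 48000), c(9800, 9900, 48500),
              name = c("b1", "b2", "b3")),
    c("p1", "p2", "p3"), c(2, 5, 9))
  e <- assign_by_interaction(prom2[1], el, ap, "enhancer_te", "s1")
  expect_equal(nrow(e), 1)            # two pairs collapse to one edge
  expect_equal(e$frequency, 7)        # 2 + 5; pair p3 touches neither side
  expect_equal(e$signal, 4)
  expect_equal(e$manner, "chromatin_interaction")

  # element and promoter on the SAME anchor only -> no edge
  ap_same <- funlnc:::anchor_pairs_new(
    intervals("chr1", 8000, 52000, name = "a"),
    intervals("chr2", 100, 200, name = "b"),
    "p", 1)
  expect_equal(nrow(assign_by_interaction(prom2[1], el, ap_same,
                                          "enhancer_te")), 0)
})

test_that("assign_distance uses midpoint distance with overlap short-circuit", {
  # lnc1 TSS 10000; SE midpoint at 50000 -> distance 40 kb
  se_near <- intervals("chr1", 49000, 51000, name = "near", signal = 1)
  se_far <- intervals("chr1", 69000, 71000, name = "far", signal = 1)
  expect_equal(assign_distance(prom2[1], se_near, "enhancer_se",
                               max_dist = 50000)$partner_id, "near")
  expect_equal(nrow(assign_distance(prom2[1], se_far, "enhancer_se",
                                    max_dist = 50000)), 0)
  # overlapping the promoter wins whatever max_dist
  se_over <- intervals("chr1", 11000, 90000, name = "over", signal = 1)
  expect_equal(assign_distance(prom2[1], se_over, "enhancer_se",
                               max_dist = 1000)$partner_id, "over")
  expect_error(assign_distance(prom2, se_near, "enhancer_se", max_dist = 0),
               "max_dist")
})

test_that("build_downstream deduplicates and maps manners", {
  pt <- data.table::data.table(
    lncrna_id = c("l1", "l1", "l1", "l2"),
    partner_id = c("g1", "g1", "m1", "p1"),
    partner_kind = c("mRNA", "mRNA", "miRNA", "protein"))
  e <- build_downstream(pt)
  expect_equal(nrow(e), 3)
  expect_equal(sort(unique(e$manner)), c("annotated", "targeted"))
  expect_equal(e[e$partner_kind == "protein"]$manner, "annotated")
  expect_equal(nrow(build_downstream(pt[0])), 0)
})

test_that("integrate_network unions, deduplicates and counts conservatively", {
  e1 <- assign_proximal(prom2, intervals("chr1", 9000, 9100, name = "x"),
                        "tf_chip")
  e2 <- build_downstream(data.table::data.table(
    lncrna_id = "lnc1", partner_id = "g1", partner_kind = "mRNA"))
  net <- integrate_network(list(e1, e2))
  expect_equal(nrow(net$edges), nrow(e1) + nrow(e2))
  # idempotence: re-adding identical lists does not inflate counts
  net2 <- integrate_network(list(e1, e2, e1, e2))
  expect_equal(net2$edges, net$edges)
  # order independence
  net3 <- integrate_network(list(e2, e1))
  expect_equal(net3$edges, net$edges)
  # per-kind counts sum to the total
  expect_equal(sum(net$counts$N), nrow(net$edges))
})

test_that("network TSV round trip preserves edges", {
  net <- integrate_network(list(
    assign_proximal(prom2, intervals("chr1", 9000, 9100, name = "x",
                                     signal = 2.5), "tf_chip"),
    build_downstream(data.table::data.table(
      lncrna_id = "lnc1", partner_id = "g1", partner_kind = "mRNA"))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- read_network(path, lncrna_ids = net$lncrnas)
  expect_equal(back$edges, net$edges)
})

test_that("proximal and interaction assignment match the O(n^2) oracle", {
  for (seed in c(101, 202, 303)) {
    set.seed(seed)
    proms <- random_promoters(8)
    els <- random_intervals(50)
    got <- assign_proximal(proms, els, "tf_chip")
    exp <- bf_proximal_pairs(intervals_df(proms), intervals_df(els))
    got_keys <- sort(paste(got$lncrna_id, got$partner_id))
    exp_keys <- sort(paste(
      S4Vectors::mcols(proms)$id[exp$pidx],
      S4Vectors::mcols(els)$name[exp$eidx]))
    expect_equal(got_keys, exp_keys)

    a <- random_intervals(12)
    b <- random_intervals(12)
    ap <- funlnc:::anchor_pairs_new(a, b, sprintf("p%d", 1:12),
                                    sample(1:5, 12, replace = TRUE))
    got_i <- assign_by_interaction(proms, els, ap, "enhancer_te")
    exp_i <- bf_interaction_links(intervals_df(proms), intervals_df(els),
                                  intervals_df(a), intervals_df(b),
                                  ap$frequency)
    expect_equal(nrow(got_i), nrow(exp_i))
    if (nrow(exp_i)) {
      key <- function(id, el, f) sort(paste(id, el, f))
      expect_equal(
        key(got_i$lncrna_id, got_i$partner_id, got_i$frequency),
        key(S4Vectors::mcols(proms)$id[exp_i$pidx],
            S4Vectors::mcols(els)$name[exp_i$eidx], exp_i$freq))
    }
  }
})

test_that("interaction_edges counts a pair once per touched promoter", {
  ap <- funlnc:::anchor_pairs_new(
    intervals("chr1", c(9000, 9100), c(9500, 9600), name = c("a1", "a2")),
    intervals("chr1", c(11000, 90000), c(11500, 90500),
              name = c("b1", "b2")),
    c("p1", "p2"), c(3, 2))
  # p1 touches lnc1's promoter with both anchors -> one edge, freq 3
  # p2 touches with anchor A only -> one edge, freq 2
  e <- interaction_edges(prom2[1], ap)
  expect_equal(sort(e$frequency), c(2, 3))
  expect_equal(sum(e$frequency), 5)
})

test_that("stitch_enhancers merges within gap and ranks SE by signal", {
  peaks <- intervals("chr1", c(1000, 3000, 40000), c(2000, 4000, 41000),
                     name = c("p1", "p2", "p3"), signal = c(5, 7, 100))
  st <- stitch_enhancers(peaks, stitch_dist = 5000, se_fraction = 0.5)
  expect_equal(length(st$se) + length(st$te), 2)  # first two merged
  expect_equal(S4Vectors::mcols(st$se)$signal[1], 100)
  expect_equal(S4Vectors::mcols(st$te)$signal[1], 12)
})
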