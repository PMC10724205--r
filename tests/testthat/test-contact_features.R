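mk_contacts <- function(bins_a, bins_b, cpm, chrom = "chr1", bin = 5000) {
  data.table::data.table(
    chrom_a = chrom, start_a = bins_a * bin, end_a = (bins_a + 1) * bin,
    chrom_b = chrom, start_b = bins_b * bin, end_b = (bins_b + 1) * bin,
    raw_count = pmax(1L, as.integer(cpm)), aqua_cpm = cpm,
    distance = abs(bins_b - bins_a) * bin, is_cis = TRUE)
}

test_that("build_feature_graph keeps strictly-above-threshold edges", {
  ct <- mk_contacts(c(0, 2, 4), c(10, 12, 14), c(0.5, 1.0, 2.0))
  g <- build_feature_graph(ct, 1.0)
  expect_equal(nrow(g$edges), 1L)  # strict '>': 1.0 excluded
  expect_equal(g$edges$aqua_cpm, 2.0)
  expect_equal(nrow(build_feature_graph(ct, 0)$edges), 3L)
  g0 <- build_feature_graph(ct[0], 0)
  expect_equal(nrow(g0$edges), 0L)
  expect_equal(nrow(g0$anchors), 0L)
  expect_error(build_feature_graph(ct[, -"aqua_cpm"], 0), "aqua_cpm")
})

test_that("extract_features classifies loop / cluster / peak", {
  # single edge A-B -> loop
  f1 <- extract_features(build_feature_graph(mk_contacts(0, 10, 2), 0))
  expect_equal(f1$features$kind, "loop")
  # A-B, B-C share anchor B -> one cluster, 2 loops, 3 anchors
  f2 <- extract_features(build_feature_graph(
    mk_contacts(c(0, 10), c(10, 20), c(2, 2)), 0))
  expect_equal(f2$features$kind, "cluster")
  expect_equal(f2$features$n_loops, 2L)
  expect_equal(f2$features$n_anchors, 3L)
  # disjoint A-B, C-D plus a 1D peak elsewhere -> 2 loops + 1 peak
  pk <- genomic_intervals("chr1", 500000, 500400, score = 3.3)
  f3 <- extract_features(build_feature_graph(
    mk_contacts(c(0, 40), c(10, 50), c(2, 2)), 0), pol2_anchor_peaks = pk)
  expect_equal(sort(f3$features$kind), c("loop", "loop", "peak"))
  expect_equal(f3$features[f3$features$kind == "peak", ]$total_signal, 3.3)
  # a 1D peak whose bin is already in the graph does not become a peak
  pk2 <- genomic_intervals("chr1", 100, 300)
  f4 <- extract_features(build_feature_graph(mk_contacts(0, 10, 2), 0),
                         pol2_anchor_peaks = pk2)
  expect_false("peak" %in% f4$features$kind)
})

test_that("self edges count as edges", {
  ct <- mk_contacts(c(5, 5), c(5, 9), c(2, 2))  # self 5x5 plus 5-9
  f <- extract_features(build_feature_graph(ct, 0))
  expect_equal(f$features$kind, "cluster")
  expect_equal(f$features$n_loops, 2L)
})

test_that("partition property and BFS-oracle equivalence on random graphs", {
  set.seed(23)
  for (rep in 1:25) {
    n_anchor <- sample(10:200, 1)
    n_edge <- sample(5:500, 1)
    a <- sample(n_anchor, n_edge, replace = TRUE)
    b <- sample(n_anchor, n_edge, replace = TRUE)
    cpm <- round(stats::runif(n_edge, 0, 5), 3)
    thr <- stats::runif(1, 0, 4)
    ct <- mk_contacts(a, b, cpm)
    gr <- build_feature_graph(ct, thr)
    ft <- extract_features(gr)
    # each kept edge in exactly one feature; counts partition the edge set
    expect_equal(sum(ft$features$n_loops), nrow(gr$edges))
    expect_equal(nrow(ft$edges), nrow(gr$edges))
    expect_false(anyNA(ft$edges$feature_id))
    # oracle comparison on the same kept edges
    oracle <- bfs_partition(gr$edges$anchor_a, gr$edges$anchor_b,
                            gr$anchors$key)
    expect_identical(unname(feature_partition(ft)), unname(oracle))
    # classification consistent with edge counts
    expect_true(all((ft$features$n_loops == 1) ==
                      (ft$features$kind == "loop")))
    expect_true(all((ft$features$n_loops >= 2) ==
                      (ft$features$kind == "cluster")))
  }
})

test_that("threshold monotone in edges; cluster count documented non-monotone", {
  # raising the threshold can split one cluster into loops
  ct <- mk_contacts(c(0, 10), c(10, 20), c(2, 5))
  lo <- extract_features(build_feature_graph(ct, 1))
  hi <- extract_features(build_feature_graph(ct, 3))
  expect_equal(lo$features$kind, "cluster")
  expect_equal(hi$features$kind, "loop")       # cluster split, loop count up
  expect_lt(sum(hi$features$n_loops), sum(lo$features$n_loops))
  set.seed(31)
  ct2 <- mk_contacts(sample(50, 200, TRUE), sample(50, 200, TRUE),
                     stats::runif(200, 0, 4))
  edges <- vapply(seq(0, 4, by = 0.5), function(th)
    nrow(build_feature_graph(ct2, th)$edges), numeric(1))
  expect_true(all(diff(edges) <= 0))
})

test_that("rank_features sorts ascending with stable deterministic ties", {
  f <- data.table::data.table(
    feature_id = c("F1", "F2", "F3"), kind = "loop", chrom = "chr1",
    span_start = 0, span_end = 1, span = c(5, 1, 3),
    n_anchors = 2L, n_loops = 1L, total_signal = c(3, 1, 2))
  r <- rank_features(f)
  expect_equal(r$feature_id, c("F2", "F3", "F1"))
  expect_equal(r$rank, 1:3)
  # all-equal signals: id order preserved via tie-break
  f$total_signal <- 1; f$span <- 1
  expect_equal(rank_features(f)$feature_id, c("F1", "F2", "F3"))
  # oracle: rank permutation equals argsort
  set.seed(13)
  n <- 1000
  fr <- data.table::data.table(
    feature_id = sprintf("F%04d", 1:n), kind = "loop", chrom = "chr1",
    span_start = 0, span_end = 1, span = sample(1e5, n),
    n_anchors = 2L, n_loops = 1L, total_signal = stats::runif(n))
  expect_equal(rank_features(fr)$feature_id,
               fr$feature_id[order(fr$total_signal, fr$span, fr$feature_id)])
})

test_that("cluster_stats computes spans, P3F counts and the cohort mean", {
  ct <- mk_contacts(c(2, 2, 10), c(4, 6, 12), c(2, 2, 2))
  ft <- extract_features(build_feature_graph(ct, 0))
  # cluster anchors span [10000, 35000) -> 25 kb; loop excluded
  p3f <- genomic_intervals("chr1", c(11000, 21000, 60000),
                           c(11400, 21400, 60400))
  cs <- cluster_stats(ft, p3f)
  expect_equal(nrow(cs$clusters), 1L)
  expect_equal(cs$clusters$span_kb, 25)
  expect_equal(cs$clusters$n_p3f, 2L)
  expect_equal(cs$cohort$n_clusters, 1L)
  expect_equal(cs$cohort$mean_loops, 2)
  # cluster with no P3F overlap drops out of the cohort
  cs2 <- cluster_stats(ft, genomic_intervals("chr9", 0, 100))
  expect_equal(cs2$cohort$n_clusters, 0L)
})

test_that("planted clusters are recovered exactly without background", {
  g <- tiny_genome(seed = 9)
  arch <- tiny_arch(seed = 9, background_rate = 0, n_cpg_promoter_loops = 0L)
  sc <- generate_contacts(g, arch, "control")
  nc <- normalize_condition(sc)
  ft <- extract_features(build_feature_graph(nc$contacts, 0))
  expect_equal(sum(ft$features$kind == "cluster"), 20L)
  truth <- sc$truth$clusters
  rec <- feature_partition(ft)
  tr <- sort(vapply(seq_len(nrow(truth)), function(i)
    paste(sort(anchor_key(truth$chrom[i],
                          as.numeric(strsplit(truth$anchors[i],
                                              ",")[[1]]) * 5000)),
          collapse = ","), ""))
  expect_identical(unname(rec), unname(tr))
})
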