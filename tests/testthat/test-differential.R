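mk_edges <- function(units, cpm, category = NA_character_,
                     distance = NA_real_) {
  ab <- strsplit(units, "|", fixed = TRUE)
  data.table::data.table(
    anchor_a = vapply(ab, `[`, "", 1L),
    anchor_b = vapply(ab, `[`, "", 2L),
    aqua_cpm = cpm, category = category, distance = distance)
}

test_that("l2fc closed forms", {
  expect_equal(l2fc(3, 3), 0)
  expect_equal(l2fc(4, 1, eps = 1e-12), 2, tolerance = 1e-9)
  expect_equal(l2fc(0, 3, eps = 1), -2)  # log2(1/4)
  expect_error(l2fc(1, 1, eps = 0), "eps")
  # antisymmetry
  set.seed(5)
  a <- stats::runif(50, 0, 100); b <- stats::runif(50, 0, 100)
  expect_equal(l2fc(a, b), -l2fc(b, a))
})

test_that("delta_table joins unit universes with zero fill", {
  ec <- mk_edges(c("chr1:0|chr1:50000", "chr1:0|chr1:90000"), c(4, 2))
  et <- mk_edges(c("chr1:0|chr1:50000", "chr1:5000|chr1:70000"), c(8, 6))
  dr <- delta_table(ec, et, eps = 0.5)
  expect_equal(nrow(dr$units), 3L)
  gone <- dr$units[dr$units$unit_id == "chr1:0|chr1:90000", ]
  expect_equal(gone$signal_trt, 0)
  expect_equal(gone$l2fc, log2(0.5 / 2.5))
  new <- dr$units[dr$units$unit_id == "chr1:5000|chr1:70000", ]
  expect_equal(new$signal_ctrl, 0)
  # all-equal conditions -> all-zero l2fc and zero medians
  dr0 <- delta_table(ec, ec)
  expect_true(all(dr0$units$l2fc == 0))
  # disjoint universes are an error
  expect_error(delta_table(ec, mk_edges("chr9:0|chr9:50000", 1)),
               "disjoint")
})

test_that("delta antisymmetry under condition swap", {
  set.seed(41)
  ids <- sprintf("chr1:%d|chr1:%d", 1:30 * 5000, 1:30 * 5000 + 100000)
  ec <- mk_edges(ids, stats::runif(30, 0, 50))
  et <- mk_edges(ids, stats::runif(30, 0, 50))
  d1 <- delta_table(ec, et)$units
  d2 <- delta_table(et, ec)$units
  expect_equal(d1$l2fc, -d2$l2fc)
})

test_that("long_range_filter is inclusive at both window edges", {
  lp <- data.table::data.table(distance = c(24999, 25000, 1e6, 3e6, 3000001))
  out <- long_range_filter(lp)
  expect_equal(out$distance, c(25000, 1e6, 3e6))
  expect_error(long_range_filter(lp, 10, 5), "min_d")
})

test_that("rank_plot_table orders by l2fc with documented conventions", {
  u <- data.table::data.table(unit_id = c("u1", "u2", "u3"),
                              l2fc = c(-1, 2, 0))
  r <- rank_plot_table(u)
  expect_equal(r$table$l2fc, c(-1, 0, 2))
  expect_equal(r$table$rank, 1:3)
  # all zeros: frac below 0 is 0, frac at-or-below 0 is 1
  rz <- rank_plot_table(data.table::data.table(unit_id = c("a", "b"),
                                               l2fc = c(0, 0)))
  expect_equal(rz$frac_below_zero, 0)
  expect_equal(rz$frac_at_or_below_zero, 1)
  # argsort oracle
  set.seed(43)
  ur <- data.table::data.table(unit_id = sprintf("u%03d", 1:200),
                               l2fc = round(stats::rnorm(200), 4))
  rr <- rank_plot_table(ur)
  expect_equal(rr$table$unit_id, ur$unit_id[order(ur$l2fc, ur$unit_id)])
})

test_that("APA mean property: n copies of one submatrix reproduce it", {
  flank <- 3; dim <- 2 * flank + 1; bin <- 5000
  base <- matrix(stats::runif(dim^2, 0, 4), dim, dim)
  centers <- cbind(a = c(20, 60, 100), b = c(40, 80, 120))
  cc <- list()
  for (i in seq_len(nrow(centers))) {
    ga <- rep(centers[i, "a"] + (-flank:flank), each = dim)
    gb <- rep(centers[i, "b"] + (-flank:flank), times = dim)
    cc[[i]] <- data.table::data.table(
      chrom_a = "chr1", start_a = ga * bin, end_a = (ga + 1) * bin,
      chrom_b = "chr1", start_b = gb * bin, end_b = (gb + 1) * bin,
      raw_count = 1L, aqua_cpm = as.vector(t(base)),
      distance = abs(gb - ga) * bin, is_cis = TRUE)
  }
  loops <- data.table::data.table(chrom_a = "chr1",
                                  start_a = centers[, "a"] * bin,
                                  chrom_b = "chr1",
                                  start_b = centers[, "b"] * bin)
  res <- apa(data.table::rbindlist(cc), loops, bin_size = bin, flank = flank)
  expect_equal(res$matrix, base)
  expect_equal(res$n_loops_used, 3L)
})

test_that("APA centers, skipping and delta", {
  bin <- 5000; flank <- 2
  ct <- data.table::data.table(
    chrom_a = "chr1", start_a = 10 * bin, end_a = 11 * bin,
    chrom_b = "chr1", start_b = 30 * bin, end_b = 31 * bin,
    raw_count = 10L, aqua_cpm = 10, distance = 20 * bin, is_cis = TRUE)
  loops <- data.table::data.table(chrom_a = "chr1", start_a = 10 * bin,
                                  chrom_b = "chr1", start_b = 30 * bin)
  res <- apa(ct, loops, bin_size = bin, flank = flank)
  expect_equal(res$center, 10)
  expect_equal(res$background, 0)
  expect_gt(res$enrichment, 1e9)  # eps-guarded, effectively infinite
  # loop at the chromosome start is skipped
  edge_loop <- data.table::data.table(chrom_a = "chr1", start_a = 0,
                                      chrom_b = "chr1", start_b = 30 * bin)
  expect_error(apa(ct, edge_loop, bin_size = bin, flank = flank),
               "skipped")
  both <- rbind(loops, edge_loop)
  res2 <- apa(ct, both, bin_size = bin, flank = flank)
  expect_equal(res2$n_loops_used, 1L)
  expect_equal(res2$n_loops_skipped, 1L)
  expect_error(apa(ct, loops[0], bin_size = bin, flank = flank), "no cis")
  # delta APA: treated - control, and antisymmetry
  ct2 <- data.table::copy(ct); ct2$aqua_cpm <- 4
  r1 <- apa(ct, loops, bin_size = bin, flank = flank)
  r2 <- apa(ct2, loops, bin_size = bin, flank = flank)
  d12 <- apa_delta(r1, r2)
  expect_equal(d12$matrix[flank + 1, flank + 1], 6)
  expect_equal(d12$matrix, -apa_delta(r2, r1)$matrix)
})

test_that("null calibration on planted units from independent draws", {
  g <- tiny_genome(seed = 8)
  arch <- tiny_arch(seed = 8, collapse_distal_factor = 1,
                    collapse_cpg_gain_factor = 1)
  s1 <- generate_contacts(g, arch, "control", count_seed = 801L)
  s2 <- generate_contacts(g, arch, "control", count_seed = 802L)
  e1 <- normalize_condition(s1)$contacts
  e2 <- normalize_condition(s2)$contacts
  e1[, `:=`(anchor_a = anchor_key(chrom_a, start_a),
            anchor_b = anchor_key(chrom_b, start_b))]
  e2[, `:=`(anchor_a = anchor_key(chrom_a, start_a),
            anchor_b = anchor_key(chrom_b, start_b))]
  dr <- delta_table(e1, e2)
  tl <- s1$truth$loops
  planted <- dr$units[dr$units$unit_id %in% truth_unit_ids(tl), ]
  expect_gte(nrow(planted), 20)
  expect_lt(abs(stats::median(planted$l2fc)), 0.1)
})
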