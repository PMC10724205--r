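plus_gene <- data.table::data.table(gene_id = "gp", chrom = "chr1",
                                    strand = "+", tss = 1000, tes = 3000)
minus_gene <- data.table::data.table(gene_id = "gm", chrom = "chr1",
                                     strand = "-", tss = 9000, tes = 7000)
uniform <- coverage_track("chr1", 0, 20000, 1)

test_that("gene_regions applies the region scheme on both strands", {
  rp <- gene_regions(plus_gene)
  expect_equal(rp$regions$promoter, c(200, 970))
  expect_equal(rp$regions$tssr, c(970, 1300))
  expect_equal(rp$regions$body, c(1300, 3000))
  expect_equal(rp$regions$tesr, c(3000, 7000))
  rm <- gene_regions(minus_gene)
  lens <- vapply(rm$regions, diff, numeric(1))
  expect_equal(unname(lens), c(770, 330, 1700, 4000))  # mirrored lengths
  expect_equal(rm$regions$tssr, c(8700, 9030))
  expect_equal(rm$regions$tesr, c(3000, 7000))
  # clipping at chromosome start
  g0 <- data.table::data.table(gene_id = "g0", chrom = "chr1", strand = "+",
                               tss = 100, tes = 5000)
  r0 <- gene_regions(g0)
  expect_equal(r0$regions$promoter[1], 0)
  expect_true(r0$clipped)
  # short gene flagged
  gs <- data.table::data.table(gene_id = "gs", chrom = "chr1", strand = "+",
                               tss = 1000, tes = 1200)
  expect_true(gene_regions(gs)$metrics_undefined)
})

test_that("worked example: uniform coverage gives PULR 0.7, TR 330/1700", {
  expect_equal(pulr(uniform, plus_gene), 0.7)
  expect_equal(traveling_ratio(uniform, plus_gene), 330 / 1700)
  # strand mirror is identical
  expect_equal(pulr(uniform, minus_gene), 0.7)
  expect_equal(traveling_ratio(uniform, minus_gene), 330 / 1700)
  # narrow numerator variant omits the body
  expect_equal(pulr(uniform, plus_gene,
                    pulr_numerator = "promoter_tssr_only"),
               (770 + 330) / 4000)
})

test_that("scale invariance and pause-peak arithmetic", {
  doubled <- coverage_track("chr1", 0, 20000, 2)
  expect_equal(traveling_ratio(doubled, plus_gene),
               traveling_ratio(uniform, plus_gene))
  expect_equal(pulr(doubled, plus_gene), pulr(uniform, plus_gene))
  # tssr coverage 10, elsewhere 1: tr = 3300/1700
  pause <- coverage_track("chr1", c(0, 970, 1300), c(970, 1300, 20000),
                          c(1, 10, 1))
  expect_equal(traveling_ratio(pause, plus_gene), 3300 / 1700)
  # halving tesr doubles pulr
  halftes <- coverage_track("chr1", c(0, 3000, 7000), c(3000, 7000, 20000),
                            c(1, 0.5, 1))
  expect_equal(pulr(halftes, plus_gene), 1.4)
})

test_that("additivity: region signals match a brute-force per-base sum", {
  set.seed(37)
  steps <- coverage_track("chr1", 0:39 * 500, 1:40 * 500,
                          round(stats::runif(40, 0, 5), 2))
  m <- gene_metrics(steps, plus_gene)
  pre_tes <- m$signal_promoter + m$signal_tssr + m$signal_body
  expect_equal(pre_tes, brute_signal(steps, "chr1", 200, 3000))
  expect_equal(m$signal_tesr, brute_signal(steps, "chr1", 3000, 7000))
})

test_that("zero denominators yield NA, never Inf", {
  nosig <- coverage_track("chr1", 0, 1300, 1)  # nothing past the TSSR
  m <- gene_metrics(nosig, plus_gene)
  expect_true(is.na(m$tr))
  expect_true(is.na(m$pulr))
})

test_that("compare_metrics recovers planted TESR depletion exactly", {
  m0 <- gene_metrics(uniform, plus_gene)
  half <- coverage_track("chr1", c(0, 3000, 7000), c(3000, 7000, 20000),
                         c(1, 0.5, 1))
  m1 <- gene_metrics(half, plus_gene)
  cmp <- compare_metrics(m0, m1)
  expect_equal(cmp$table$pulr_ratio, 2)
  expect_equal(cmp$median_pulr_ratio, 2)
  # identical conditions give ratio 1, missing genes excluded+counted
  cmp0 <- compare_metrics(m0, m0)
  expect_equal(cmp0$table$pulr_ratio, 1)
  m2 <- data.table::copy(m0); m2$gene_id <- "other"
  cmp2 <- compare_metrics(m0, m2)
  expect_equal(nrow(cmp2$table), 0L)
  expect_equal(cmp2$n_excluded, 2L)
})

test_that("synthetic coverage recovers the planted PULR ratio", {
  g <- tiny_genome(seed = 4)
  arch <- tiny_arch(seed = 4, tesr_depletion_factor = 0.5,
                    tssr_gain_factor = 1)
  c0 <- generate_coverage(g, arch, "control")
  c1 <- generate_coverage(g, arch, "treated")
  m0 <- gene_metrics(c0$track, g$genes)
  m1 <- gene_metrics(c1$track, g$genes)
  cmp <- compare_metrics(m0, m1)
  expect_equal(cmp$median_pulr_ratio, 2, tolerance = 1e-12)
  # matches the analytically recorded truth
  expected <- merge(c0$truth[, .(gene_id, p0 = expected_pulr)],
                    c1$truth[, .(gene_id, p1 = expected_pulr)],
                    by = "gene_id")
  expect_equal(sort(cmp$table$pulr_ratio),
               sort(expected$p1 / expected$p0))
  # Poisson-noised coverage stays within 5% at depth 20
  c0n <- generate_coverage(g, arch, "control", noise = "poisson",
                           depth = 20, count_seed = 401L)
  c1n <- generate_coverage(g, arch, "treated", noise = "poisson",
                           depth = 20, count_seed = 402L)
  cmpn <- compare_metrics(gene_metrics(c0n$track, g$genes),
                          gene_metrics(c1n$track, g$genes))
  expect_lt(abs(cmpn$median_pulr_ratio / 2 - 1), 0.05)
})

test_that("decile_rank_join assigns deciles and finds planted trends", {
  sig <- data.table::data.table(gene_id = sprintf("g%02d", 1:10),
                                signal = 10:1)
  ex <- data.table::data.table(gene_id = sprintf("g%02d", 1:10),
                               l2fc = 0)
  dj <- decile_rank_join(sig, ex)
  expect_equal(sort(dj$table$decile), 1:10)  # one gene per decile
  expect_equal(dj$table[dj$table$gene_id == "g01", ]$decile, 10L)
  # all-equal signals: deterministic id-order tie rule
  sig2 <- data.table::copy(sig); sig2$signal <- 1
  dj2 <- decile_rank_join(sig2, ex)
  expect_equal(dj2$table$decile, 1:10)  # sorted by gene_id
  # planted monotone trend: l2fc = -0.5 * decile + noise
  set.seed(47)
  n <- 500
  sig3 <- data.table::data.table(gene_id = sprintf("g%04d", 1:n),
                                 signal = seq_len(n))
  dec <- ceiling(seq_len(n) / (n / 10))
  ex3 <- data.table::data.table(gene_id = sprintf("g%04d", 1:n),
                                l2fc = -0.5 * dec + stats::rnorm(n, 0, 0.2))
  dj3 <- decile_rank_join(sig3, ex3)
  expect_true(all(diff(dj3$summary$median_l2fc) < 0))
  # mismatched universes warn
  expect_warning(decile_rank_join(sig, ex[1:3]), "mismatch")
})
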