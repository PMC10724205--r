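#' Evaluate with a fixed RNG state, then restore it
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic genome configuration
#'
#' Defaults describe a miniature but structurally realistic regulatory
#' genome: one 20-Mb chromosome, 100 genes in non-overlapping slots,
#' half of the promoters CpG-island promoters, 14 candidate enhancers
#' per gene within ~60 kb upstream, 30% of enhancers P3F-bound and
#' every P3F peak nested in a p300 peak (plus extra p300-only
#' enhancers, mirroring near-complete P3F/p300 co-occupancy).
#'
#' @param n_chroms,chrom_length genome shape.
#' @param n_genes genes total (spread over chromosomes).
#' @param fraction_cpg_promoters fraction of genes whose TSS sits in a
#'   CpG island; applied exactly (`round(fraction * n_genes)` genes).
#' @param n_enhancers_per_gene candidate enhancer sites per gene.
#' @param p3f_fraction fraction of enhancers carrying a P3F peak.
#' @param p300_extra_fraction fraction of the remaining enhancers
#'   carrying a p300-only peak (p300 always co-occurs with P3F).
#' @param gene_length_range,enhancer_max_offset placement geometry (bp).
#' @param seed RNG seed.
#' @return validated config list of class `synthetic_genome_config`.
#' @export
synthetic_genome_config <- function(n_chroms = 1L, chrom_length = 2e7,
                                    n_genes = 100L,
                                    fraction_cpg_promoters = 0.5,
                                    n_enhancers_per_gene = 14L,
                                    p3f_fraction = 0.3,
                                    p300_extra_fraction = 0.2,
                                    gene_length_range = c(5000, 20000),
                                    enhancer_max_offset = 80000,
                                    seed = 1L) {
  stopifnot(n_chroms >= 1L, chrom_length > 0, n_genes >= 1L,
            fraction_cpg_promoters >= 0, fraction_cpg_promoters <= 1,
            n_enhancers_per_gene >= 1L,
            p3f_fraction >= 0, p3f_fraction <= 1)
  slot <- chrom_length / ceiling(n_genes / n_chroms)
  if (slot / 2 < enhancer_max_offset + 10000 ||
      slot / 2 < max(gene_length_range) + 10000)
    stop("chromosome too short to place ", n_genes,
         " non-overlapping gene neighbourhoods")
  structure(as.list(environment())[names(formals(synthetic_genome_config))],
            class = "synthetic_genome_config")
}

#' Generate a miniature genome with annotations
#'
#' Lays one gene per slot (slots tile each chromosome), alternating
#' strand deterministically from the RNG. CpG islands (500-2000 bp)
#' are centred on the TSS of an exact `round(fraction * n_genes)`
#' random subset of genes. Enhancer sites are placed upstream of each
#' TSS at distinct 5-kb bins up to `enhancer_max_offset` away; a
#' random `p3f_fraction` of them get a P3F peak (400 bp), every P3F
#' peak is nested inside a p300 peak (800 bp), and a further
#' `p300_extra_fraction` of the rest get p300 alone. Deterministic for
#' a fixed config (byte-identical BED output).
#'
#' @param config a [synthetic_genome_config()].
#' @return list of class `synthetic_genome`: `chrom_sizes` (named
#'   vector), `genes`, `cpg` (intervals), `p3f`, `p300`, `enhancers`
#'   (intervals with `gene_id`, `has_p3f`, `has_p300`), `config`.
#' @export
generate_genome <- function(config) {
  cfg <- config
  with_seed(cfg$seed, {
    chroms <- paste0("chr", seq_len(cfg$n_chroms))
    chrom_sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)
    per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
    slot <- cfg$chrom_length / per_chrom
    genes <- list(); enh <- list()
    gi <- 0L
    for (ch in chroms) {
      for (k in seq_len(per_chrom)) {
        gi <- gi + 1L
        if (gi > cfg$n_genes) break
        slot_start <- (k - 1) * slot
        glen <- round(stats::runif(1, cfg$gene_length_range[1],
                                   cfg$gene_length_range[2]))
        strand <- sample(c("+", "-"), 1L)
        # TSS near slot centre; enhancers fit upstream inside the slot
        tss <- round(slot_start + slot / 2)
        if (strand == "+") { start <- tss; end <- tss + glen }
        else { start <- tss - glen; end <- tss }
        gene_id <- sprintf("g%04d", gi)
        genes[[gi]] <- data.table::data.table(
          gene_id = gene_id, chrom = ch, strand = strand,
          tss = if (strand == "+") start else end,
          tes = if (strand == "+") end else start)
        # upstream enhancer bins (distinct, 5-kb grid)
        # offsets start at 3 bins (>= 10 kb interval gap) so every
        # enhancer anchor is distal under the 5-kb TSS window
        pool <- 3:floor(cfg$enhancer_max_offset / 5000)
        offs <- sample(pool, min(cfg$n_enhancers_per_gene, length(pool)))
        dir <- if (strand == "+") -1 else 1
        centers <- tss + dir * offs * 5000
        enh[[gi]] <- data.table::data.table(
          gene_id = gene_id, chrom = ch,
          start = centers - 200, end = centers + 200)
      }
    }
    genes <- data.table::rbindlist(genes)
    enh <- data.table::rbindlist(enh)
    n_cpg <- round(cfg$fraction_cpg_promoters * cfg$n_genes)
    cpg_genes <- if (n_cpg > 0)
      sort(sample(genes$gene_id, n_cpg)) else character()
    genes[, cpg_promoter := gene_id %in% cpg_genes]
    cpgdt <- genes[cpg_promoter == TRUE]
    cpg <- if (nrow(cpgdt)) {
      w <- round(stats::runif(nrow(cpgdt), 500, 2000))
      genomic_intervals(cpgdt$chrom, pmax(0, cpgdt$tss - floor(w / 2)),
                        cpgdt$tss + ceiling(w / 2), name = cpgdt$gene_id)
    } else genomic_intervals(character(), numeric(), numeric())
    enh[, has_p3f := stats::runif(.N) < cfg$p3f_fraction]
    enh[, has_p300 := has_p3f |
          (stats::runif(.N) < cfg$p300_extra_fraction)]
    p3f <- enh[has_p3f == TRUE]
    p300 <- enh[has_p300 == TRUE]
    mk <- function(x, pad) if (nrow(x))
      genomic_intervals(x$chrom, x$start - pad, x$end + pad, name = x$gene_id)
    else genomic_intervals(character(), numeric(), numeric())
    structure(list(chrom_sizes = chrom_sizes, genes = genes[],
                   cpg = cpg, p3f = mk(p3f, 0), p300 = mk(p300, 200),
                   enhancers = enh[], config = cfg),
              class = "synthetic_genome")
  })
}

#' Planted contact architecture configuration
#'
#' Defaults state the architecture the analysis is built to detect:
#' 50 clusters averaging 7.7 loops over ~73-kb spans on a 5-kb anchor
#' grid, a Poisson contact rate of 50 raw pairs per planted loop,
#' mouse spike-in at a 1:10 ratio, and a treated condition that halves
#' distal P3F-anchored contacts while doubling CpG-promoter to
#' CpG-promoter contacts (the collapse phenotype). Background contacts
#' decay as distance^-1; the background level is a free parameter the
#' source data do not constrain.
#'
#' @param n_clusters planted clusters.
#' @param loops_per_cluster_mean Poisson mean of loops per cluster
#'   (floored at 2; a cluster has at least 2 edges).
#' @param cluster_span_mean target genomic span of a cluster (bp).
#' @param anchor_bin contact grid (bp).
#' @param contact_rate expected raw pairs per planted loop (lambda).
#' @param background_rate expected background pairs per expected
#'   planted pair (0 disables background).
#' @param distance_decay_exponent background decay alpha.
#' @param spikein_fraction expected spikein/human pair ratio rho.
#' @param collapse_distal_factor gamma_d in (0,1]; multiplies treated
#'   distal P3F-anchored loop rates.
#' @param collapse_cpg_gain_factor gamma_c >= 1; multiplies treated
#'   CpG-promoter x CpG-promoter loop rates.
#' @param tesr_depletion_factor gamma_t in (0,1]; multiplies treated
#'   TESR coverage.
#' @param tssr_gain_factor multiplies treated TSSR coverage (pile-up
#'   at the pause site).
#' @param n_cpg_promoter_loops planted promoter-promoter loops between
#'   CpG genes. The default (150) is sized a priori so that a category
#'   median of per-loop log2 ratios, whose per-unit noise at the
#'   default Poisson rate 50 is `sqrt(2/50)/log(2) ~ 0.29`, has a
#'   three-sigma margin inside a +/-0.1 null-calibration band
#'   (`3 * 1.253 * 0.29 / sqrt(n) <= 0.1` requires `n >= ~120`).
#' @param seed RNG seed (architecture layout; condition-specific count
#'   draws derive from it).
#' @return validated config list of class `architecture_config`.
#' @export
architecture_config <- function(n_clusters = 50L,
                                loops_per_cluster_mean = 7.7,
                                cluster_span_mean = 73000,
                                anchor_bin = 5000,
                                contact_rate = 50,
                                background_rate = 0.5,
                                distance_decay_exponent = 1,
                                spikein_fraction = 0.1,
                                collapse_distal_factor = 0.5,
                                collapse_cpg_gain_factor = 2,
                                tesr_depletion_factor = 0.5,
                                tssr_gain_factor = 2,
                                n_cpg_promoter_loops = 150L,
                                seed = 1L) {
  stopifnot(n_clusters >= 0L, loops_per_cluster_mean > 0,
            anchor_bin > 0, contact_rate > 0, background_rate >= 0,
            spikein_fraction > 0,
            collapse_distal_factor > 0, collapse_distal_factor <= 1,
            collapse_cpg_gain_factor >= 1,
            tesr_depletion_factor > 0, tesr_depletion_factor <= 1)
  structure(as.list(environment())[names(formals(architecture_config))],
            class = "architecture_config")
}

# The architecture (which loops exist, where) is drawn once from
# arch$seed so both conditions share it; only the Poisson counts are
# condition specific.
plant_architecture <- function(genome, arch) {
  with_seed(arch$seed, {
    bin <- arch$anchor_bin
    g <- genome$genes
    if (arch$n_clusters > nrow(g))
      stop("more clusters requested than genes available")
    cluster_genes <- sort(sample(g$gene_id, arch$n_clusters))
    loops <- list()
    li <- 0L
    for (gid in cluster_genes) {
      gr <- g[gene_id == gid]
      k <- min(max(2L, stats::rpois(1, arch$loops_per_cluster_mean)),
               sum(genome$enhancers$gene_id == gid))
      eh <- genome$enhancers[gene_id == gid]
      # prefer enhancers inside the target span, then fill outwards
      mid <- (eh$start + eh$end) / 2
      d <- abs(mid - gr$tss)
      ord <- order(d > arch$cluster_span_mean, stats::runif(nrow(eh)))
      pick <- eh[ord[seq_len(k)]]
      hub_bin <- floor(gr$tss / bin)
      for (j in seq_len(nrow(pick))) {
        li <- li + 1L
        eb <- floor((pick$start[j] + pick$end[j]) / 2 / bin)
        loops[[li]] <- data.table::data.table(
          loop_id = sprintf("L%05d", li), kind = "cluster_loop",
          cluster_gene = gid, chrom = gr$chrom,
          bin_a = min(hub_bin, eb), bin_b = max(hub_bin, eb),
          enhancer_has_p3f = pick$has_p3f[j],
          enhancer_has_p300 = pick$has_p300[j],
          cpg_by_cpg = FALSE)
      }
    }
    # promoter-promoter loops between CpG-island genes (long-range window)
    cpg_g <- g[cpg_promoter == TRUE]
    n_pp <- arch$n_cpg_promoter_loops
    if (n_pp > 0L && nrow(cpg_g) >= 2L) {
      made <- 0L; guard <- 0L
      while (made < n_pp && guard < 50L * n_pp) {
        guard <- guard + 1L
        pr <- cpg_g[sample(.N, 2L)]
        if (pr$chrom[1] != pr$chrom[2]) next
        ba <- floor(pr$tss[1] / bin); bb <- floor(pr$tss[2] / bin)
        dd <- abs(bb - ba) * bin
        if (dd < 25000 || dd > 3e6) next
        li <- li + 1L; made <- made + 1L
        loops[[li]] <- data.table::data.table(
          loop_id = sprintf("L%05d", li), kind = "cpg_promoter_loop",
          cluster_gene = NA_character_, chrom = pr$chrom[1],
          bin_a = min(ba, bb), bin_b = max(ba, bb),
          enhancer_has_p3f = FALSE, enhancer_has_p300 = FALSE,
          cpg_by_cpg = TRUE)
      }
    }
    loops <- data.table::rbindlist(loops)
    loops <- unique(loops, by = c("chrom", "bin_a", "bin_b"))
    loops[, distance := (bin_b - bin_a) * bin]
    loops[]
  })
}

planted_modifier <- function(loops, arch, condition, proximal_window = 5000) {
  if (condition == "control") return(rep(1, nrow(loops)))
  mod <- rep(1, nrow(loops))
  distal <- loops$distance > proximal_window
  mod[loops$kind == "cluster_loop" & loops$enhancer_has_p3f & distal] <-
    arch$collapse_distal_factor
  mod[loops$cpg_by_cpg] <- arch$collapse_cpg_gain_factor
  mod
}

#' Generate spike-in-bearing HiChIP valid pairs with planted clusters
#'
#' Plants the configured architecture (shared across conditions for a
#' given `arch$seed`), then draws per-loop raw pair counts as
#' `Poisson(lambda * modifier)` where the treated condition applies
#' `collapse_distal_factor` to distal P3F-anchored cluster loops and
#' `collapse_cpg_gain_factor` to CpG-promoter pair loops. Background
#' pairs land between random positions with distance density
#' proportional to `d^-alpha`. Spike-in pairs are emitted on mock
#' `mm_chr*` chromosomes with an expected spikein/human ratio of
#' `spikein_fraction`, calibrated against the condition-independent
#' baseline human expectation (constant chromatin input: collapse does
#' not leak into the normalizer). Pair positions sit at bin midpoints
#' so binning at `anchor_bin` recovers the planted anchors exactly.
#'
#' @param genome a [generate_genome()] result.
#' @param arch an [architecture_config()].
#' @param condition `"control"` or `"treated"`.
#' @param count_seed RNG seed for the count draws; defaults to
#'   `arch$seed * 10 + (1|2)` by condition. Pass your own to obtain
#'   independent replicates of the same stated world.
#' @param path optional output file; when given, pairs are also written
#'   in allValidPairs dialect (1-based positions).
#' @return list of class `synthetic_contacts`: `pairs` (valid-pairs
#'   table as [read_valid_pairs()] returns), `truth` (planted loop
#'   table with per-loop `modifier` and `raw_count`, plus `clusters`
#'   summary), `condition`.
#' @export
generate_contacts <- function(genome, arch,
                              condition = c("control", "treated"),
                              count_seed = NULL, path = NULL) {
  condition <- match.arg(condition)
  loops <- plant_architecture(genome, arch)
  if (nrow(loops[kind == "cluster_loop"]) == 0L && arch$n_clusters > 0L)
    warning("no planted cluster loops")
  if (is.null(count_seed))
    count_seed <- arch$seed * 10L + switch(condition, control = 1L,
                                           treated = 2L)
  bin <- arch$anchor_bin
  with_seed(count_seed, {
    mod <- planted_modifier(loops, arch, condition)
    cnt <- stats::rpois(nrow(loops), arch$contact_rate * mod)
    loops <- data.table::copy(loops)
    loops[, `:=`(modifier = mod, raw_count = cnt)]
    # materialize planted pairs at bin midpoints
    rep_idx <- rep(seq_len(nrow(loops)), cnt)
    half <- floor(bin / 2)
    planted <- data.table::data.table(
      chrom_a = loops$chrom[rep_idx],
      pos_a = loops$bin_a[rep_idx] * bin + half,
      chrom_b = loops$chrom[rep_idx],
      pos_b = loops$bin_b[rep_idx] * bin + half)
    expected_planted <- arch$contact_rate * nrow(loops)  # baseline, mod = 1
    # background: distance ~ d^-alpha on [2 kb, L/4]
    n_bg <- stats::rpois(1, arch$background_rate * expected_planted)
    bg <- NULL
    if (n_bg > 0) {
      ch <- sample(names(genome$chrom_sizes), n_bg, replace = TRUE)
      L <- unname(genome$chrom_sizes[ch])
      d <- sample_decay_distance(n_bg, 2000, max(L) / 4,
                                 arch$distance_decay_exponent)
      d <- pmin(d, L - 2001)
      p1 <- floor(stats::runif(n_bg, 0, L - d - 1))
      bg <- data.table::data.table(chrom_a = ch, pos_a = p1,
                                   chrom_b = ch, pos_b = p1 + round(d))
    }
    human <- data.table::rbindlist(list(planted, bg))
    # spike-in calibrated to the baseline human expectation
    expected_human_baseline <-
      expected_planted * (1 + arch$background_rate)
    n_sp <- stats::rpois(1, arch$spikein_fraction * expected_human_baseline)
    sp <- NULL
    if (n_sp > 0) {
      Lm <- genome$chrom_sizes[[1]]
      p1 <- floor(stats::runif(n_sp, 0, Lm - 100000))
      p2 <- p1 + round(stats::runif(n_sp, 2000, 90000))
      sp <- data.table::data.table(chrom_a = "mm_chr1", pos_a = p1,
                                   chrom_b = "mm_chr1", pos_b = p2)
    }
    all <- data.table::rbindlist(list(human, sp))
    n <- nrow(all)
    pairs <- data.table::data.table(
      read_id = sprintf("r%07d", seq_len(n)),
      genome_tag = c(rep("human", nrow(human)),
                     rep("spikein", if (is.null(sp)) 0L else nrow(sp))),
      chrom_a = all$chrom_a, pos_a = as.numeric(all$pos_a),
      strand_a = sample(c("+", "-"), n, replace = TRUE),
      chrom_b = all$chrom_b, pos_b = as.numeric(all$pos_b),
      strand_b = sample(c("+", "-"), n, replace = TRUE),
      is_duplicate = FALSE)
    pairs <- canonicalize_pairs(pairs)
    if (!is.null(path)) write_valid_pairs(pairs, path)
    clusters <- loops[kind == "cluster_loop",
                      .(n_loops = .N,
                        anchors = paste(sort(unique(c(bin_a, bin_b))),
                                        collapse = ","),
                        chrom = chrom[1L]),
                      by = cluster_gene]
    structure(list(pairs = pairs[], condition = condition,
                   truth = list(loops = loops[], clusters = clusters[],
                                count_seed = count_seed)),
              class = "synthetic_contacts")
  })
}

# inverse-CDF sampling of d ~ d^-alpha on [dmin, dmax]
sample_decay_distance <- function(n, dmin, dmax, alpha) {
  u <- stats::runif(n)
  if (abs(alpha - 1) < 1e-12) {
    exp(log(dmin) + u * (log(dmax) - log(dmin)))
  } else {
    a <- 1 - alpha
    (dmin^a + u * (dmax^a - dmin^a))^(1 / a)
  }
}

#' Write valid pairs in allValidPairs dialect
#' @param pairs valid-pairs table (0-based positions; written 1-based).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_valid_pairs <- function(pairs, path) {
  out <- data.table::data.table(
    V1 = pairs$read_id, V2 = pairs$chrom_a,
    V3 = format(pairs$pos_a + 1, scientific = FALSE, trim = TRUE),
    V4 = pairs$strand_a, V5 = pairs$chrom_b,
    V6 = format(pairs$pos_b + 1, scientific = FALSE, trim = TRUE),
    V7 = pairs$strand_b)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Generate piecewise-constant Pol2 coverage per condition
#'
#' Each gene gets levels: promoter `p`, TSSR `s` (pause peak, `s > b`),
#' body `b`, TESR `t`; the treated condition multiplies `t` by
#' `tesr_depletion_factor` and `s` by `tssr_gain_factor`, so the
#' planted PULR ratio treated/control is analytically known and
#' recorded in the truth table. Optional Poisson noise draws window
#' counts at the given mean depth. Signals of overlapping regions are
#' summed (and flagged), though the default genome places genes apart.
#'
#' @param genome a [generate_genome()].
#' @param arch an [architecture_config()].
#' @param condition `"control"` or `"treated"`.
#' @param levels base levels `c(promoter, tssr, body, tesr)`.
#' @param noise `"none"` or `"poisson"`.
#' @param depth mean reads per bp at level 1 (Poisson noise).
#' @param noise_bin window width (bp) for Poisson draws.
#' @param count_seed RNG seed for the noise draws.
#' @return list of class `synthetic_coverage`: `track`
#'   (a [coverage_track()]), `truth` (per-gene levels and expected
#'   TR/PULR), `condition`.
#' @export
generate_coverage <- function(genome, arch,
                              condition = c("control", "treated"),
                              levels = c(promoter = 1, tssr = 4,
                                         body = 1, tesr = 1),
                              noise = c("none", "poisson"),
                              depth = 20, noise_bin = 100,
                              count_seed = NULL) {
  condition <- match.arg(condition)
  noise <- match.arg(noise)
  if (is.null(count_seed))
    count_seed <- arch$seed * 10L + switch(condition, control = 3L,
                                           treated = 4L)
  lv <- levels
  if (condition == "treated") {
    lv[["tesr"]] <- lv[["tesr"]] * arch$tesr_depletion_factor
    lv[["tssr"]] <- lv[["tssr"]] * arch$tssr_gain_factor
  }
  g <- genome$genes
  pieces <- list(); truth <- list()
  for (i in seq_len(nrow(g))) {
    gr <- gene_regions(g[i], chrom_size = genome$chrom_sizes[[g$chrom[i]]])
    for (nm in names(gr$regions)) {
      rg <- gr$regions[[nm]]
      if (rg[2] > rg[1])
        pieces[[length(pieces) + 1L]] <- data.table::data.table(
          chrom = gr$chrom, start = rg[1], end = rg[2], value = lv[[nm]])
    }
    lens <- vapply(gr$regions, function(r) max(0, r[2] - r[1]), numeric(1))
    exp_pulr <- if (lens[["tesr"]] > 0 && lv[["tesr"]] > 0)
      (lv[["promoter"]] * lens[["promoter"]] + lv[["tssr"]] * lens[["tssr"]] +
         lv[["body"]] * lens[["body"]]) / (lv[["tesr"]] * lens[["tesr"]])
    else NA_real_
    exp_tr <- if (lens[["body"]] > 0 && lv[["body"]] > 0)
      (lv[["tssr"]] * lens[["tssr"]]) / (lv[["body"]] * lens[["body"]])
    else NA_real_
    truth[[i]] <- data.table::data.table(
      gene_id = g$gene_id[i], condition = condition,
      level_promoter = lv[["promoter"]], level_tssr = lv[["tssr"]],
      level_body = lv[["body"]], level_tesr = lv[["tesr"]],
      expected_pulr = exp_pulr, expected_tr = exp_tr,
      flagged = gr$metrics_undefined || gr$clipped)
  }
  steps <- flatten_sum_steps(data.table::rbindlist(pieces))
  overlapped <- attr(steps, "had_overlap")
  if (noise == "poisson") {
    steps <- with_seed(count_seed, poissonize_steps(steps, depth, noise_bin))
  }
  track <- coverage_track(steps$chrom, steps$start, steps$end, steps$value)
  tt <- data.table::rbindlist(truth)
  tt[, overlap_flagged := overlapped]
  structure(list(track = track, truth = tt[], condition = condition),
            class = "synthetic_coverage")
}

# sum overlapping step pieces into disjoint steps
flatten_sum_steps <- function(pieces) {
  out <- list(); had <- FALSE
  for (ch in sort(unique(pieces$chrom))) {
    p <- pieces[chrom == ch]
    bp <- sort(unique(c(p$start, p$end)))
    s <- bp[-length(bp)]; e <- bp[-1L]
    v <- numeric(length(s))
    for (j in seq_len(nrow(p))) {
      hit <- s >= p$start[j] & s < p$end[j]
      v[hit] <- v[hit] + p$value[j]
      if (any(v[hit] > p$value[j])) had <- TRUE
    }
    keep <- v > 0
    if (any(keep))
      out[[ch]] <- data.table::data.table(chrom = ch, start = s[keep],
                                          end = e[keep], value = v[keep])
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "had_overlap", had)
  res
}

# replace each step by noise_bin windows with Poisson-drawn mean coverage
poissonize_steps <- function(steps, depth, noise_bin) {
  out <- list()
  for (j in seq_len(nrow(steps))) {
    s <- steps$start[j]; e <- steps$end[j]; v <- steps$value[j]
    b <- seq(s, e, by = noise_bin)
    if (b[length(b)] < e) b <- c(b, e)
    ws <- b[-length(b)]; we <- b[-1L]
    lam <- v * depth * (we - ws)
    val <- stats::rpois(length(lam), lam) / (depth * (we - ws))
    out[[j]] <- data.table::data.table(chrom = steps$chrom[j],
                                       start = ws, end = we, value = val)
  }
  data.table::rbindlist(out)
}
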