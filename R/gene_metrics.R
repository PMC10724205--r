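#' Split a gene into promoter / TSSR / body / TESR windows
#'
#' Region scheme (plus strand, 0-based half-open, offsets from the TSS
#' and TES points):
#' promoter `[tss-800, tss-30)`, TSSR `[tss-30, tss+300)`,
#' body `[tss+300, tes)`, TESR `[tes, tes+4000)`.
#' Minus-strand genes use the exact interval reflection about the
#' TSS/TES points, which preserves every region length:
#' promoter `[tss+30, tss+800)`, TSSR `[tss-300, tss+30)`,
#' body `[tes, tss-300)`, TESR `[tes-4000, tes)`.
#' A nonempty body requires gene length > 300 bp; shorter genes are
#' flagged `metrics_undefined`. Regions clipped at position 0 (or at
#' the chromosome end when `chrom_size` is given) carry `clipped=TRUE`.
#'
#' @param gene one-row gene table (`gene_id`, `chrom`, `strand`,
#'   `tss`, `tes`).
#' @param chrom_size optional chromosome length for right clipping.
#' @return list with `gene_id`, `chrom`, `strand`, interval list
#'   `regions` (`promoter`, `tssr`, `body`, `tesr`, each `c(start,
#'   end)`), `metrics_undefined`, `clipped`.
#' @export
gene_regions <- function(gene, chrom_size = NULL) {
  tss <- gene$tss; tes <- gene$tes; strand <- gene$strand
  glen <- abs(tes - tss)
  undefined <- glen <= 300
  if (strand == "+") {
    r <- list(promoter = c(tss - 800, tss - 30),
              tssr = c(tss - 30, tss + 300),
              body = c(tss + 300, tes),
              tesr = c(tes, tes + 4000))
  } else if (strand == "-") {
    r <- list(promoter = c(tss + 30, tss + 800),
              tssr = c(tss - 300, tss + 30),
              body = c(tes, tss - 300),
              tesr = c(tes - 4000, tes))
  } else stop("unknown strand: ", strand)
  clipped <- FALSE
  for (nm in names(r)) {
    if (r[[nm]][1] < 0) { r[[nm]][1] <- 0; clipped <- TRUE }
    if (!is.null(chrom_size) && r[[nm]][2] > chrom_size) {
      r[[nm]][2] <- chrom_size; clipped <- TRUE
    }
    if (r[[nm]][2] <= r[[nm]][1]) {
      r[[nm]] <- c(r[[nm]][1], r[[nm]][1])  # empty region, 0 signal
      if (nm %in% c("body", "tesr")) undefined <- TRUE
    }
  }
  list(gene_id = gene$gene_id, chrom = gene$chrom, strand = strand,
       regions = r, metrics_undefined = undefined, clipped = clipped)
}

region_signal <- function(track, chrom, region) {
  if (region[2] <= region[1]) return(0)
  track_signal(track, chrom, region[1], region[2])
}

#' Gene-level Pol2 metrics from a coverage track
#'
#' Per gene: region signal areas (coverage x bp) and the two ratios.
#' The traveling ratio `tr = signal_tssr / signal_body` (paused over
#' elongating Pol2). The Pol2 unloading ratio
#' `pulr = (promoter + TSSR + body) / TESR` by default ("everything
#' before the TES over what lies past it"); set
#' `pulr_numerator = "promoter_tssr_only"` for the narrow variant that
#' omits the gene body. Ratios with a zero denominator (or flagged
#' genes) are `NA`, never `Inf`.
#'
#' @param coverage a `coverage_track`.
#' @param genes gene table.
#' @param pulr_numerator `"pre_tes"` (default) or `"promoter_tssr_only"`.
#' @param chrom_sizes optional named vector for clipping.
#' @return `data.table`: `gene_id`, `signal_promoter`, `signal_tssr`,
#'   `signal_body`, `signal_tesr`, `tr`, `pulr`, `flagged`.
#' @export
gene_metrics <- function(coverage, genes,
                         pulr_numerator = c("pre_tes", "promoter_tssr_only"),
                         chrom_sizes = NULL) {
  pulr_numerator <- match.arg(pulr_numerator)
  genes <- data.table::as.data.table(genes)
  res <- lapply(seq_len(nrow(genes)), function(i) {
    gr <- gene_regions(genes[i],
                       chrom_size = if (!is.null(chrom_sizes))
                         chrom_sizes[[genes$chrom[i]]] else NULL)
    s <- vapply(gr$regions, function(rg)
      region_signal(coverage, gr$chrom, rg), numeric(1))
    num <- if (pulr_numerator == "pre_tes")
      s[["promoter"]] + s[["tssr"]] + s[["body"]]
    else s[["promoter"]] + s[["tssr"]]
    data.table::data.table(
      gene_id = gr$gene_id,
      signal_promoter = s[["promoter"]], signal_tssr = s[["tssr"]],
      signal_body = s[["body"]], signal_tesr = s[["tesr"]],
      tr = if (gr$metrics_undefined || s[["body"]] <= 0) NA_real_
      else s[["tssr"]] / s[["body"]],
      pulr = if (gr$metrics_undefined || s[["tesr"]] <= 0) NA_real_
      else num / s[["tesr"]],
      flagged = gr$metrics_undefined || gr$clipped
    )
  })
  data.table::rbindlist(res)
}

#' Traveling ratio of one gene
#' @inheritParams gene_metrics
#' @param gene one-row gene table.
#' @return numeric TR (or `NA`).
#' @export
traveling_ratio <- function(coverage, gene) {
  gene_metrics(coverage, gene)$tr[1]
}

#' Pol2 unloading ratio of one gene
#' @inheritParams gene_metrics
#' @param gene one-row gene table.
#' @return numeric PULR (or `NA`).
#' @export
pulr <- function(coverage, gene,
                 pulr_numerator = c("pre_tes", "promoter_tssr_only")) {
  gene_metrics(coverage, gene, pulr_numerator = pulr_numerator)$pulr[1]
}

#' Compare gene metrics between two conditions
#'
#' Per-gene ratios `pulr_trt / pulr_ctrl` and `tr_trt / tr_ctrl` over
#' the shared gene universe; genes missing or undefined in either
#' condition are excluded and counted.
#'
#' @param metrics_ctrl,metrics_trt outputs of [gene_metrics()].
#' @return list: `table` (per-gene ratios), `n_excluded`,
#'   `median_pulr_ratio`, `median_tr_ratio`.
#' @export
compare_metrics <- function(metrics_ctrl, metrics_trt) {
  m <- merge(metrics_ctrl, metrics_trt, by = "gene_id",
             suffixes = c("_ctrl", "_trt"))
  n_universe <- length(union(metrics_ctrl$gene_id, metrics_trt$gene_id))
  ok <- !is.na(m$pulr_ctrl) & !is.na(m$pulr_trt) &
    m$pulr_ctrl > 0
  tab <- m[ok, .(gene_id,
                 pulr_ctrl, pulr_trt,
                 pulr_ratio = pulr_trt / pulr_ctrl,
                 tr_ctrl, tr_trt,
                 tr_ratio = ifelse(!is.na(tr_ctrl) & !is.na(tr_trt) &
                                     tr_ctrl > 0, tr_trt / tr_ctrl,
                                   NA_real_))]
  list(table = tab[],
       n_excluded = n_universe - nrow(tab),
       median_pulr_ratio = stats::median(tab$pulr_ratio),
       median_tr_ratio = stats::median(tab$tr_ratio, na.rm = TRUE))
}

#' Join per-gene enhancer signal deciles to expression fold changes
#'
#' Ranks genes by their p300 enhancer signal, assigns deciles (decile
#' 10 = highest signal; ties and all-equal signals fall back to
#' deterministic `gene_id` order) and summarizes expression L2FC per
#' decile (median, quartiles).
#'
#' @param gene_signal table (`gene_id`, `signal`).
#' @param expression_l2fc table (`gene_id`, `l2fc`).
#' @return list: `table` (per-gene decile + l2fc), `summary`
#'   (per-decile `n`, `q25`, `median_l2fc`, `q75`).
#' @export
decile_rank_join <- function(gene_signal, expression_l2fc) {
  gs <- data.table::as.data.table(gene_signal)
  ex <- data.table::as.data.table(expression_l2fc)
  shared <- intersect(gs$gene_id, ex$gene_id)
  if (length(shared) < 0.5 * max(nrow(gs), nrow(ex)))
    warning("gene id mismatch over 50% between signal and expression tables")
  m <- merge(gs, ex, by = "gene_id")
  data.table::setorder(m, signal, gene_id)
  m[, decile := ceiling(.I / (.N / 10))]
  m[, decile := pmin(pmax(decile, 1L), 10L)]
  summary <- m[, .(n = .N,
                   q25 = stats::quantile(l2fc, 0.25, names = FALSE),
                   median_l2fc = stats::median(l2fc),
                   q75 = stats::quantile(l2fc, 0.75, names = FALSE)),
               by = decile]
  data.table::setorder(summary, decile)
  list(table = m[], summary = summary[])
}
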