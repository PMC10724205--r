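#' Annotate anchors with TF occupancy, CpG overlap and TSS proximity
#'
#' Per anchor: counts of P3F and p300 peaks overlapping it (>= 1 bp,
#' half-open semantics), binary CpG-island overlap, distance to the
#' nearest gene TSS and the resulting proximal/distal class
#' (`proximal` iff distance <= window, inclusive).
#'
#' @param anchors interval table of anchors.
#' @param p3f,p300,cpg interval tables (any may be `NULL`/empty).
#' @param genes gene-model table (`chrom`, `tss`); empty means every
#'   anchor is distal with infinite distance (flagged by `Inf`).
#' @param window proximity window in bp (default 5000, "<= 5 kb").
#' @return the anchors with columns `n_p3f`, `n_p300`, `overlaps_cpg`,
#'   `nearest_tss_distance`, `tss_class`.
#' @export
annotate_anchors <- function(anchors, p3f = NULL, p300 = NULL, cpg = NULL,
                             genes = NULL, window = 5000) {
  out <- data.table::copy(data.table::as.data.table(anchors))
  out[, n_p3f := overlap_count(out, p3f)]
  out[, n_p300 := overlap_count(out, p300)]
  out[, overlaps_cpg := overlaps_any(out, cpg)]
  out[, nearest_tss_distance := nearest_tss_distance(out, genes)]
  out[, tss_class := ifelse(nearest_tss_distance <= window,
                            "proximal", "distal")]
  out[]
}

#' Distance from each anchor to the nearest TSS
#'
#' Interval-to-point distance under the half-open convention: a TSS
#' inside `[start, end)` gives 0; a TSS at or beyond the open end gives
#' `tss - end`. Anchors on chromosomes without genes get `Inf`.
#'
#' @param anchors interval table.
#' @param genes table with `chrom` and `tss` columns.
#' @return numeric vector of distances (bp).
#' @export
nearest_tss_distance <- function(anchors, genes) {
  n <- nrow(anchors)
  if (is.null(genes) || nrow(genes) == 0L) return(rep(Inf, n))
  out <- rep(Inf, n)
  g <- data.table::as.data.table(genes)
  for (ch in unique(anchors$chrom)) {
    tss <- g[chrom == ch, tss]
    if (length(tss) == 0L) next
    idx <- which(anchors$chrom == ch)
    for (i in idx) {
      out[i] <- min(interval_point_distance(anchors$start[i],
                                            anchors$end[i], tss))
    }
  }
  out
}

#' Classify a single anchor's TSS proximity
#' @param anchor one-row interval table.
#' @param genes gene table.
#' @param window proximity window (bp), inclusive.
#' @return list with `distance` and `class`.
#' @export
classify_tss_proximity <- function(anchor, genes, window = 5000) {
  d <- nearest_tss_distance(anchor, genes)[1]
  list(distance = d, class = if (d <= window) "proximal" else "distal")
}

#' Category label of an anchor for loop classification
#'
#' Combines CpG overlap, TF occupancy and TSS proximity into the
#' compact labels used by the differential category splits, e.g.
#' `"CpG-TSS"`, `"P3F-enh"`, `"p300-enh"`, `"enh"`, `"TSS"`.
#' @param ann annotated anchor table.
#' @return character labels.
#' @export
anchor_category <- function(ann) {
  base <- ifelse(ann$tss_class == "proximal", "TSS", "enh")
  tf <- ifelse(ann$n_p3f > 0, "P3F-",
               ifelse(ann$n_p300 > 0, "p300-", ""))
  cpg <- ifelse(ann$overlaps_cpg, "CpG-", "")
  paste0(cpg, tf, base)
}

#' Symmetric loop category from two anchor labels
#'
#' Joins the two anchors' category labels with `" x "` after sorting,
#' so the label is invariant under anchor swap.
#' @param cat_a,cat_b anchor category labels.
#' @return character loop categories.
#' @export
loop_category <- function(cat_a, cat_b) {
  lo <- pmin(cat_a, cat_b)
  hi <- pmax(cat_a, cat_b)
  paste(lo, hi, sep = " x ")
}

#' Annotate features with TF, CpG and gene content
#'
#' Attaches per-anchor annotations to a `topo_features` object and
#' computes per-feature summaries:
#' * `n_p3f_total`: TF peaks counted over loop-end anchors (each edge
#'   contributes its two ends; shared anchors count once per feature),
#' * `fraction_loop_ends_in_cpg`: CpG-overlapping loop ends over
#'   `2 * n_loops` (each edge contributes two ends, counted per edge),
#' * `n_genes`, `gene_ids`: genes whose TSS falls in the feature span.
#'
#' @param features a `topo_features` object.
#' @param p3f,p300,cpg interval tables.
#' @param genes gene-model table.
#' @param window TSS proximity window (bp).
#' @return the `topo_features` object with `anchors` annotated, edges
#'   carrying `category`, and `features` extended with the summaries.
#' @export
annotate_features <- function(features, p3f = NULL, p300 = NULL,
                              cpg = NULL, genes = NULL, window = 5000) {
  ann <- annotate_anchors(features$anchors, p3f, p300, cpg, genes, window)
  ann[, category := anchor_category(ann)]
  e <- data.table::copy(features$edges)
  if (nrow(e)) {
    ia <- match(e$anchor_a, ann$key)
    ib <- match(e$anchor_b, ann$key)
    e[, category := loop_category(ann$category[ia], ann$category[ib])]
    e[, cpg_a := ann$overlaps_cpg[ia]]
    e[, cpg_b := ann$overlaps_cpg[ib]]
    e[, p3f_ends := ann$n_p3f[ia] + ann$n_p3f[ib]]
    ends_cpg <- e[, .(n_cpg_ends = sum(cpg_a) + sum(cpg_b),
                      n_loops = .N), by = feature_id]
    ends_cpg[, fraction_loop_ends_in_cpg := n_cpg_ends / (2 * n_loops)]
  } else {
    ends_cpg <- data.table::data.table(feature_id = character(),
                                       fraction_loop_ends_in_cpg = numeric())
  }
  f <- data.table::copy(features$features)
  p3ftot <- ann[, .(n_p3f_total = sum(n_p3f)), by = feature_id]
  f <- merge(f, p3ftot, by = "feature_id", all.x = TRUE)
  f <- merge(f, ends_cpg[, .(feature_id, fraction_loop_ends_in_cpg)],
             by = "feature_id", all.x = TRUE)
  f[is.na(n_p3f_total), n_p3f_total := 0L]
  gin <- genes_in_features(features, genes)
  f <- merge(f, gin, by = "feature_id", all.x = TRUE)
  f[is.na(n_genes), n_genes := 0L]
  data.table::setorder(f, feature_id)
  structure(list(features = f[], edges = e[], anchors = ann[]),
            class = class(features))
}

#' Genes whose TSS lies within each feature span
#'
#' Point-in-span test, half-open: a TSS at the span end coordinate is
#' excluded.
#'
#' @param features a `topo_features` object.
#' @param genes gene table (`gene_id`, `chrom`, `tss`).
#' @return `data.table` (`feature_id`, `n_genes`, `gene_ids`
#'   comma-joined).
#' @export
genes_in_features <- function(features, genes) {
  f <- features$features
  if (is.null(genes) || nrow(genes) == 0L || nrow(f) == 0L)
    return(data.table::data.table(feature_id = f$feature_id,
                                  n_genes = 0L, gene_ids = ""))
  g <- data.table::as.data.table(genes)
  res <- lapply(seq_len(nrow(f)), function(i) {
    hit <- g[chrom == f$chrom[i] & tss >= f$span_start[i] &
               tss < f$span_end[i], gene_id]
    data.table::data.table(feature_id = f$feature_id[i],
                           n_genes = length(hit),
                           gene_ids = paste(sort(hit), collapse = ","))
  })
  data.table::rbindlist(res)
}
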