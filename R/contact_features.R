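#' Threshold contacts into an anchor graph
#'
#' Keeps contact edges whose `aqua_cpm` is strictly above the
#' preselected threshold ("above" read as `>`), and materializes the
#' node set as the anchors participating in at least one passing edge.
#' Self edges (intra-bin contacts that survived the short-range filter)
#' are kept.
#'
#' @param contacts normalized contacts (with `aqua_cpm`).
#' @param aqua_cpm_threshold numeric >= 0.
#' @param cis_only drop trans edges before graph construction (default
#'   `TRUE`; distance-windowed analyses are cis by definition).
#' @return list of class `feature_graph`: `edges` (passing contact
#'   rows, with `anchor_a`/`anchor_b` string keys) and `anchors`
#'   (`data.table` of unique anchor bins with keys).
#' @export
build_feature_graph <- function(contacts, aqua_cpm_threshold = 0,
                                cis_only = TRUE) {
  if (aqua_cpm_threshold < 0) stop("threshold must be >= 0")
  if (!"aqua_cpm" %in% names(contacts))
    stop("contacts are not normalized (no aqua_cpm); run aqua_normalize()")
  e <- contacts[contacts$aqua_cpm > aqua_cpm_threshold]
  if (cis_only) e <- e[e$is_cis]
  e <- data.table::copy(e)
  e[, anchor_a := anchor_key(chrom_a, start_a)]
  e[, anchor_b := anchor_key(chrom_b, start_b)]
  anchors <- unique(data.table::rbindlist(list(
    e[, .(key = anchor_a, chrom = chrom_a, start = start_a, end = end_a)],
    e[, .(key = anchor_b, chrom = chrom_b, start = start_b, end = end_b)]
  )))
  data.table::setorder(anchors, chrom, start)
  structure(list(edges = e[], anchors = anchors[]), class = "feature_graph")
}

anchor_key <- function(chrom, start) paste0(chrom, ":", format(start, scientific = FALSE, trim = TRUE))

#' Connected components by union-find
#'
#' The clustering rule of the peak3D procedure: thresholded contacts
#' are merged whenever either of their ends is shared. Implemented as
#' weighted union-find with path halving.
#'
#' @param edge_a,edge_b integer node indices (1-based) per edge.
#' @param n_nodes number of nodes.
#' @return integer vector of component labels (1..k, ordered by first
#'   node occurrence).
#' @keywords internal
union_find_components <- function(edge_a, edge_b, n_nodes) {
  parent <- seq_len(n_nodes)
  size <- rep(1L, n_nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_along(edge_a)) {
    ra <- find(edge_a[i]); rb <- find(edge_b[i])
    if (ra != rb) {
      if (size[ra] < size[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
      parent[rb] <- ra
      size[ra] <- size[ra] + size[rb]
    }
  }
  roots <- vapply(seq_len(n_nodes), find, integer(1))
  match(roots, unique(roots))
}

#' Extract topological features (peaks, loops, clusters)
#'
#' Computes connected components of the anchor graph and classifies
#' each component by edge count: exactly 1 edge is a `loop`, 2 or more
#' a `cluster`. One-dimensional Pol2 peaks whose bin participates in no
#' passing edge become 0-edge `peak` features. Feature ids are assigned
#' in coordinate-sorted order (chrom, leftmost anchor start), making
#' all downstream tables deterministic.
#'
#' @param graph a [build_feature_graph()] result.
#' @param pol2_anchor_peaks optional interval table of 1D Pol2 peaks;
#'   each peak overlapping no graph anchor yields a `peak` feature. Its
#'   `score` column (if present) is used as the peak's 1D signal.
#' @param bin_size bin width used to snap 1D peaks onto the anchor grid
#'   (default 5000).
#' @return list of class `topo_features`: `features` (per-feature
#'   table: `feature_id`, `kind`, `chrom`, `span_start`, `span_end`,
#'   `span`, `n_anchors`, `n_loops`, `total_signal`), `edges` (per-edge
#'   table with `feature_id`), `anchors` (per-anchor with `feature_id`).
#' @export
extract_features <- function(graph, pol2_anchor_peaks = NULL,
                             bin_size = 5000) {
  e <- graph$edges
  anchors <- data.table::copy(graph$anchors)
  if (nrow(anchors)) {
    ia <- match(e$anchor_a, anchors$key)
    ib <- match(e$anchor_b, anchors$key)
    comp <- union_find_components(ia, ib, nrow(anchors))
    anchors[, comp := comp]
    e <- data.table::copy(e)
    e[, comp := comp[ia]]
    feats <- anchors[, .(chrom = chrom[1L],
                         span_start = min(start), span_end = max(end),
                         n_anchors = .N), by = comp]
    nl <- e[, .(n_loops = .N, total_signal = sum(aqua_cpm)), by = comp]
    feats <- merge(feats, nl, by = "comp", all.x = TRUE)
    feats[is.na(n_loops), `:=`(n_loops = 0L, total_signal = 0)]
  } else {
    feats <- data.table::data.table(comp = integer(), chrom = character(),
                                    span_start = numeric(), span_end = numeric(),
                                    n_anchors = integer(), n_loops = integer(),
                                    total_signal = numeric())
    e <- data.table::copy(e)
    e[, comp := integer(0)]
  }
  feats[, kind := ifelse(n_loops >= 2L, "cluster", "loop")]
  # 0-edge peak features from 1D peaks not absorbed by the graph
  if (!is.null(pol2_anchor_peaks) && nrow(pol2_anchor_peaks)) {
    pk <- data.table::as.data.table(pol2_anchor_peaks)
    pk[, bin := floor((start + end) / 2 / bin_size)]
    pk[, key := anchor_key(chrom, bin * bin_size)]
    pk <- pk[!key %in% anchors$key]
    if (nrow(pk)) {
      pfeats <- pk[, .(comp = NA_integer_, chrom,
                       span_start = bin * bin_size,
                       span_end = (bin + 1) * bin_size,
                       n_anchors = 1L, n_loops = 0L,
                       total_signal = if ("score" %in% names(pk)) score else 0,
                       kind = "peak")]
      feats <- data.table::rbindlist(list(feats, pfeats), use.names = TRUE)
    }
  }
  data.table::setorder(feats, chrom, span_start, span_end)
  feats[, feature_id := sprintf("F%05d", .I)]
  feats[, span := span_end - span_start]
  if (nrow(e)) e[, feature_id := feats$feature_id[match(comp, feats$comp)]]
  else e[, feature_id := character(0)]
  if (nrow(anchors))
    anchors[, feature_id := feats$feature_id[match(comp, feats$comp)]]
  else anchors[, feature_id := character(0)]
  feats[, comp := NULL]
  data.table::setcolorder(feats, c("feature_id", "kind", "chrom",
                                   "span_start", "span_end", "span",
                                   "n_anchors", "n_loops", "total_signal"))
  structure(list(features = feats[], edges = e[], anchors = anchors[]),
            class = "topo_features")
}

#' @export
print.topo_features <- function(x, ...) {
  k <- table(factor(x$features$kind, levels = c("peak", "loop", "cluster")))
  cat(sprintf("topo_features: %d peaks, %d loops, %d clusters (%d edges)\n",
              k[["peak"]], k[["loop"]], k[["cluster"]], nrow(x$edges)))
  invisible(x)
}

#' Rank features by total signal
#'
#' Orders features by increasing total AQuA-normalized signal (the
#' hockey-stick x-axis), with deterministic tie-breaking by span then
#' feature id.
#'
#' @param features per-feature table (from `extract_features()$features`).
#' @return the table ordered ascending with a `rank` column (1 =
#'   lowest signal).
#' @export
rank_features <- function(features) {
  out <- data.table::copy(data.table::as.data.table(features))
  data.table::setorder(out, total_signal, span, feature_id)
  out[, rank := .I]
  out[]
}

#' Per-cluster statistics and TF cohort means
#'
#' For every cluster: loop count, span in kb, and the number of TF
#' (e.g. P3F) peaks overlapping any of its anchors. Cohort means are
#' reported over clusters containing at least one TF peak — the
#' "clusters with P3F" summary (loops per cluster, TF peaks per
#' cluster, mean span).
#'
#' @param features a `topo_features` object.
#' @param p3f_peaks interval table of TF peaks.
#' @return list: `clusters` (per-cluster table with `n_p3f`),
#'   `cohort` (one-row summary over clusters with `n_p3f >= 1`:
#'   `n_clusters`, `mean_loops`, `mean_p3f_peaks`, `mean_span_kb`).
#' @export
cluster_stats <- function(features, p3f_peaks) {
  cl <- features$features[kind == "cluster"]
  if (nrow(cl) == 0L) {
    return(list(clusters = cl,
                cohort = data.table::data.table(n_clusters = 0L,
                                                mean_loops = NA_real_,
                                                mean_p3f_peaks = NA_real_,
                                                mean_span_kb = NA_real_)))
  }
  anc <- features$anchors[feature_id %in% cl$feature_id]
  anc[, n_p3f := overlap_count(anc, p3f_peaks)]
  np <- anc[, .(n_p3f = sum(n_p3f)), by = feature_id]
  cl <- merge(cl, np, by = "feature_id", all.x = TRUE)
  cl[is.na(n_p3f), n_p3f := 0L]
  cl[, span_kb := span / 1000]
  coh <- cl[n_p3f >= 1L]
  cohort <- data.table::data.table(
    n_clusters = nrow(coh),
    mean_loops = if (nrow(coh)) mean(coh$n_loops) else NA_real_,
    mean_p3f_peaks = if (nrow(coh)) mean(coh$n_p3f) else NA_real_,
    mean_span_kb = if (nrow(coh)) mean(coh$span_kb) else NA_real_
  )
  list(clusters = cl[], cohort = cohort)
}
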