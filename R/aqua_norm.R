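#' Remove short-range cis ligation artefacts
#'
#' Drops cis pairs whose end-to-end distance is `min_distance` bp or
#' less ("1000 bp or less" removed by default, to filter spurious MNase
#' ligation products). Trans pairs are always kept. PCR duplicates are
#' kept by default: punctate pull-down duplicates pile at real peaks
#' rather than behaving as random noise.
#'
#' @param pairs canonical valid-pairs table.
#' @param min_distance cis pairs with `pos_b - pos_a <= min_distance`
#'   are removed (boundary removed). Default 1000.
#' @param drop_duplicates also drop pairs flagged `is_duplicate`
#'   (default `FALSE`).
#' @return filtered pairs, with attribute `counters` (`n_in`,
#'   `n_short_removed`, `n_dup_removed`, `n_out`).
#' @export
filter_pairs <- function(pairs, min_distance = 1000, drop_duplicates = FALSE) {
  cis <- pairs$chrom_a == pairs$chrom_b
  short <- cis & (pairs$pos_b - pairs$pos_a) <= min_distance
  dup <- if (drop_duplicates) pairs$is_duplicate & !short else
    rep(FALSE, nrow(pairs))
  keep <- !short & !dup
  out <- pairs[keep]
  data.table::setattr(out, "counters",
                      c(n_in = nrow(pairs), n_short_removed = sum(short),
                        n_dup_removed = sum(dup), n_out = sum(keep)))
  out
}

#' Spike-in statistics for AQuA normalization
#'
#' Counts human and spike-in valid pairs (after filtering). The
#' spike-in genome is carried in at a fixed chromatin input ratio
#' (1:10 mouse:human by design), so its pair total is a cross-sample
#' denominator.
#'
#' @param pairs valid pairs carrying `genome_tag`.
#' @param sample_id label stored in the result.
#' @return list of class `spikein_stats`: `sample_id`,
#'   `human_valid_pairs`, `spikein_valid_pairs`, `ratio`.
#' @export
spikein_stats <- function(pairs, sample_id = "sample") {
  h <- sum(pairs$genome_tag == "human")
  s <- sum(pairs$genome_tag == "spikein")
  if (s == 0L) stop("zero spike-in pairs: AQuA normalization undefined")
  if (h == 0L) stop("zero human pairs")
  structure(list(sample_id = sample_id, human_valid_pairs = h,
                 spikein_valid_pairs = s, ratio = s / h),
            class = "spikein_stats")
}

#' @export
print.spikein_stats <- function(x, ...) {
  cat(sprintf("spikein_stats [%s]: human=%d spikein=%d ratio=%.4f\n",
              x$sample_id, x$human_valid_pairs, x$spikein_valid_pairs,
              x$ratio))
  invisible(x)
}

#' Bin valid pairs into contact records
#'
#' Assigns each end to its `floor(pos / bin_size)` bin and aggregates
#' pairs per ordered bin pair. Anchors are materialized as
#' `[k*bin_size, (k+1)*bin_size)`. Contact distance is the absolute
#' difference of bin midpoints (0 for trans contacts).
#'
#' @param pairs filtered human valid pairs.
#' @param bin_size bin width in bp (default 5000, the paper-scale
#'   contact-map resolution).
#' @return contacts `data.table`: `chrom_a`, `start_a`, `end_a`,
#'   `chrom_b`, `start_b`, `end_b`, `raw_count`, `distance`, `is_cis`.
#' @export
bin_contacts <- function(pairs, bin_size = 5000) {
  if (bin_size <= 0) stop("bin_size must be positive")
  hp <- pairs[pairs$genome_tag == "human"]
  if (nrow(hp) == 0L) {
    return(data.table::data.table(
      chrom_a = character(), start_a = numeric(), end_a = numeric(),
      chrom_b = character(), start_b = numeric(), end_b = numeric(),
      raw_count = integer(), distance = numeric(), is_cis = logical()))
  }
  dt <- data.table::data.table(
    chrom_a = hp$chrom_a, bin_a = floor(hp$pos_a / bin_size),
    chrom_b = hp$chrom_b, bin_b = floor(hp$pos_b / bin_size)
  )
  # canonical order can flip at bin level even for canonical pairs
  swap <- dt$chrom_b < dt$chrom_a |
    (dt$chrom_a == dt$chrom_b & dt$bin_b < dt$bin_a)
  if (any(swap)) {
    tmpc <- dt$chrom_a[swap]; tmpb <- dt$bin_a[swap]
    dt[swap, `:=`(chrom_a = chrom_b, bin_a = bin_b)]
    dt[swap, `:=`(chrom_b = tmpc, bin_b = tmpb)]
  }
  ct <- dt[, .(raw_count = .N), by = .(chrom_a, bin_a, chrom_b, bin_b)]
  ct[, `:=`(start_a = bin_a * bin_size, end_a = (bin_a + 1) * bin_size,
            start_b = bin_b * bin_size, end_b = (bin_b + 1) * bin_size)]
  ct[, is_cis := chrom_a == chrom_b]
  ct[, distance := ifelse(is_cis, abs(bin_b - bin_a) * bin_size, 0)]
  ct[, c("bin_a", "bin_b") := NULL]
  data.table::setcolorder(ct, c("chrom_a", "start_a", "end_a",
                                "chrom_b", "start_b", "end_b",
                                "raw_count", "distance", "is_cis"))
  data.table::setorder(ct, chrom_a, start_a, chrom_b, start_b)
  ct[]
}

#' AQuA (RRPM) normalization of contacts
#'
#' Scales raw contact counts by the spike-in pair total:
#' `aqua_cpm = raw_count * 1e6 / spikein_valid_pairs`
#' (reference-reads-per-million). Because the spike-in chromatin enters
#' every sample at the same input ratio, the denominator is comparable
#' across samples and conditions; the statistic is invariant under
#' joint rescaling of sequencing depth.
#'
#' @param contacts contact table from [bin_contacts()].
#' @param stats a [spikein_stats()] object.
#' @return contacts with an `aqua_cpm` column added.
#' @export
aqua_normalize <- function(contacts, stats) {
  if (!inherits(stats, "spikein_stats")) stop("stats must be spikein_stats")
  out <- data.table::copy(contacts)
  out[, aqua_cpm := raw_count * 1e6 / stats$spikein_valid_pairs]
  out[]
}

#' 1D AQuA-scaled anchor signal
#'
#' Sums `aqua_cpm` over all contacts touching each anchor bin (both
#' ends; a self contact counts once). Used to score 0-loop "peak"
#' features and anchors.
#'
#' @param contacts normalized contacts.
#' @return `data.table` (`chrom`, `start`, `end`, `aqua_cpm`).
#' @export
anchor_signal <- function(contacts) {
  a <- contacts[, .(chrom = chrom_a, start = start_a, end = end_a, aqua_cpm)]
  b <- contacts[!(chrom_a == chrom_b & start_a == start_b),
                .(chrom = chrom_b, start = start_b, end = end_b, aqua_cpm)]
  ab <- data.table::rbindlist(list(a, b))
  out <- ab[, .(aqua_cpm = sum(aqua_cpm)), by = .(chrom, start, end)]
  data.table::setorder(out, chrom, start)
  out[]
}

#' Scale a coverage track by a spike-in denominator
#' @param track a `coverage_track`.
#' @param stats a [spikein_stats()] object.
#' @return track with `value * 1e6 / spikein_valid_pairs`.
#' @export
aqua_scale_track <- function(track, stats) {
  if (!inherits(stats, "spikein_stats")) stop("stats must be spikein_stats")
  coverage_track(track$chrom, track$start, track$end,
                 track$value * 1e6 / stats$spikein_valid_pairs)
}

#' Base-wise difference of two coverage tracks
#'
#' Computes `treated - control` as a piecewise-constant track over the
#' union of both tracks' step boundaries (a "delta track": control
#' subtracted from treated). Values may be negative; zero-valued pieces
#' are dropped.
#'
#' @param track_treated,track_control coverage tracks on the same
#'   genome (chromosome names must intersect unless one track is empty).
#' @return a signed `coverage_track`.
#' @export
delta_track <- function(track_treated, track_control) {
  ct <- data.table::as.data.table(track_control)
  tt <- data.table::as.data.table(track_treated)
  if (nrow(ct) && nrow(tt) &&
      length(intersect(unique(ct$chrom), unique(tt$chrom))) == 0L)
    stop("chromosome names of the two tracks do not overlap")
  chroms <- sort(union(unique(ct$chrom), unique(tt$chrom)))
  pieces <- list()
  for (ch in chroms) {
    t1 <- tt[chrom == ch]; t0 <- ct[chrom == ch]
    bp <- sort(unique(c(t1$start, t1$end, t0$start, t0$end)))
    if (length(bp) < 2L) next
    s <- bp[-length(bp)]; e <- bp[-1L]
    v1 <- step_value_at(t1, s)
    v0 <- step_value_at(t0, s)
    d <- v1 - v0
    keep <- d != 0
    if (any(keep))
      pieces[[ch]] <- data.table::data.table(chrom = ch, start = s[keep],
                                             end = e[keep], value = d[keep])
  }
  if (!length(pieces)) return(coverage_track(signed = TRUE))
  out <- data.table::rbindlist(pieces)
  coverage_track(out$chrom, out$start, out$end, out$value, signed = TRUE)
}

# value of a single-chromosome step table at each query position (0 off-step)
step_value_at <- function(steps, pos) {
  if (nrow(steps) == 0L) return(numeric(length(pos)))
  idx <- findInterval(pos, steps$start)
  v <- numeric(length(pos))
  ok <- idx >= 1L
  ok[ok] <- pos[ok] < steps$end[idx[ok]]
  v[ok] <- steps$value[idx[ok]]
  v
}
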