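#' Genomic interval tables
#'
#' Throughout pol2topo a set of genomic intervals is a plain `data.table`
#' with columns `chrom` (character), `start` and `end` (integer-like,
#' 0-based half-open, `end > start`), plus optional `name` and `score`.
#' These helpers construct and validate that representation.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 0-based half-open coordinates; `end > start` required.
#' @param name,score optional per-interval annotation columns.
#' @return A `data.table` with class `genomic_intervals` prepended.
#' @examples
#' genomic_intervals("chr1", 10, 20)
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, score = NULL) {
  dt <- data.table::data.table(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end)
  )
  if (!is.null(name)) dt[, name := as.character(name)]
  if (!is.null(score)) dt[, score := as.numeric(score)]
  validate_intervals(dt)
  data.table::setorder(dt, chrom, start, end)
  data.table::setattr(dt, "class", c("genomic_intervals", class(dt)))
  dt[]
}

validate_intervals <- function(dt) {
  if (nrow(dt) == 0L) return(invisible(dt))
  if (any(!is.finite(dt$start)) || any(!is.finite(dt$end)))
    stop("non-finite interval coordinates")
  if (any(dt$start < 0)) stop("interval start < 0")
  bad <- which(dt$end <= dt$start)
  if (length(bad))
    stop("empty or inverted interval(s) at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  invisible(dt)
}

#' Interval lengths
#' @param x a `genomic_intervals` table.
#' @return numeric vector `end - start`.
#' @export
interval_length <- function(x) x$end - x$start

#' Count overlapping peaks per query interval
#'
#' For each query interval, counts reference intervals on the same
#' chromosome that overlap it by at least 1 bp under half-open semantics
#' (`[a,b)` and `[c,d)` overlap iff `a < d && c < b`).
#'
#' @param query,peaks interval tables (`chrom`, `start`, `end`).
#' @return integer vector of counts, one per row of `query`.
#' @export
overlap_count <- function(query, peaks) {
  nq <- nrow(query)
  if (nq == 0L) return(integer(0))
  if (is.null(peaks) || nrow(peaks) == 0L) return(integer(nq))
  out <- integer(nq)
  pk <- data.table::as.data.table(peaks)[, .(chrom, start, end)]
  qs <- split(seq_len(nq), query$chrom)
  for (ch in names(qs)) {
    p <- pk[chrom == ch]
    if (nrow(p) == 0L) next
    idx <- qs[[ch]]
    # event sweep would be overkill at these sizes; vectorized per chrom
    for (i in idx) {
      out[i] <- sum(p$start < query$end[i] & query$start[i] < p$end)
    }
  }
  out
}

#' Do intervals overlap at least one peak?
#' @inheritParams overlap_count
#' @return logical vector.
#' @export
overlaps_any <- function(query, peaks) overlap_count(query, peaks) > 0L

#' Distance from an interval to a point
#'
#' Half-open convention: a point `p` inside `[s,e)` has distance 0; for
#' `p >= e` the distance is measured from the open end boundary, `p - e`;
#' for `p < s` it is `s - p`.
#'
#' @param start,end interval coordinates (vectors recycle).
#' @param p point coordinate(s).
#' @return numeric distances.
#' @export
interval_point_distance <- function(start, end, p) {
  pmax(start - p, p - end, 0)
}

#' Piecewise-constant coverage track
#'
#' A coverage track is a `data.table` (`chrom`, `start`, `end`, `value`)
#' of non-overlapping, sorted steps with finite `value >= 0` (signed
#' tracks produced by [delta_track()] relax the sign constraint).
#' Regions not covered by a step have value 0.
#'
#' @param chrom,start,end,value step definition vectors.
#' @param signed allow negative values (delta tracks).
#' @return a `coverage_track` data.table.
#' @export
coverage_track <- function(chrom = character(), start = numeric(),
                           end = numeric(), value = numeric(),
                           signed = FALSE) {
  dt <- data.table::data.table(
    chrom = as.character(chrom), start = as.numeric(start),
    end = as.numeric(end), value = as.numeric(value)
  )
  if (nrow(dt)) {
    validate_intervals(dt)
    if (any(!is.finite(dt$value))) stop("non-finite coverage value")
    if (!signed && any(dt$value < 0)) stop("negative coverage value")
    data.table::setorder(dt, chrom, start)
    ov <- dt[, any(start[-1] < end[-.N]), by = chrom]$V1
    if (any(ov)) stop("overlapping coverage steps within a chromosome")
  }
  data.table::setattr(dt, "class", c("coverage_track", class(dt)))
  dt[]
}

#' Area under a coverage track over an interval
#'
#' `signal = sum(value * overlap_length)` over all steps intersecting the
#' query; well defined (0) for queries off the covered region.
#'
#' @param track a `coverage_track`.
#' @param chrom,start,end query interval (0-based half-open). Vectorized.
#' @return numeric signal area(s), coverage units times bp.
#' @export
track_signal <- function(track, chrom, start, end) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  out <- numeric(n)
  if (nrow(track) == 0L) return(out)
  for (i in seq_len(n)) {
    hit <- which(track$chrom == chrom[i] &
                   track$start < end[i] & track$end > start[i])
    if (length(hit) == 0L) next
    ov <- pmin(track$end[hit], end[i]) - pmax(track$start[hit], start[i])
    out[i] <- sum(track$value[hit] * ov)
  }
  out
}
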