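#' Log2 fold change with pseudocount
#'
#' `log2((trt + eps) / (ctrl + eps))`; antisymmetric under condition
#' swap and finite for `eps > 0`.
#'
#' @param signal_trt,signal_ctrl non-negative signals (vectors).
#' @param eps pseudocount, same units as the signals (default 0.5 CPM).
#' @return numeric L2FC.
#' @export
l2fc <- function(signal_trt, signal_ctrl, eps = 0.5) {
  if (eps <= 0) stop("eps must be > 0")
  log2((signal_trt + eps) / (signal_ctrl + eps))
}

#' Per-unit differential contact table
#'
#' Joins two conditions over the union of their edge universes (an edge
#' is keyed by its two anchors; a unit absent in one condition gets
#' signal 0 — collapse means disappearance, dropping would bias toward
#' null) and computes per-unit L2FC and the M-A mean. When annotated
#' edges are supplied, each unit carries its loop `category` and
#' per-category summaries (n, median, quartiles of L2FC) are attached.
#'
#' @param edges_ctrl,edges_trt edge tables with `anchor_a`, `anchor_b`,
#'   `aqua_cpm` (and optionally `category`, `distance`).
#' @param eps pseudocount for [l2fc()].
#' @return list of class `delta_result`: `units` (per-unit table with
#'   `unit_id`, `signal_ctrl`, `signal_trt`, `l2fc`, `mean_a`,
#'   `category`, `distance`), `summary` (per-category `n`, `q25`,
#'   `median_l2fc`, `q75`, `frac_sign_negative`, `frac_sign_positive`).
#' @export
delta_table <- function(edges_ctrl, edges_trt, eps = 0.5) {
  u0 <- unit_signals(edges_ctrl)
  u1 <- unit_signals(edges_trt)
  if (nrow(u0) && nrow(u1) &&
      length(intersect(u0$unit_id, u1$unit_id)) == 0L)
    stop("unit universes are disjoint; check that both conditions used ",
         "the same bin size")
  units <- merge(u0, u1, by = "unit_id", all = TRUE,
                 suffixes = c("_ctrl", "_trt"))
  for (cc in c("signal_ctrl", "signal_trt"))
    units[is.na(units[[cc]]), (cc) := 0]
  units[, category := data.table::fcoalesce(category_ctrl, category_trt)]
  units[, distance := data.table::fcoalesce(distance_ctrl, distance_trt)]
  units[, c("category_ctrl", "category_trt",
            "distance_ctrl", "distance_trt") := NULL]
  units[, l2fc := l2fc(signal_trt, signal_ctrl, eps)]
  units[, mean_a := 0.5 * log2((signal_trt + eps) * (signal_ctrl + eps))]
  data.table::setorder(units, unit_id)
  summary <- units[, .(
    n = .N,
    q25 = stats::quantile(l2fc, 0.25, names = FALSE),
    median_l2fc = stats::median(l2fc),
    q75 = stats::quantile(l2fc, 0.75, names = FALSE),
    frac_sign_negative = mean(l2fc < 0),
    frac_sign_positive = mean(l2fc > 0)
  ), by = category]
  data.table::setorder(summary, category)
  structure(list(units = units[], summary = summary[]),
            class = "delta_result")
}

unit_signals <- function(edges) {
  e <- data.table::as.data.table(edges)
  if (nrow(e) == 0L)
    return(data.table::data.table(unit_id = character(),
                                  signal = numeric(),
                                  category = character(),
                                  distance = numeric()))
  out <- data.table::data.table(
    unit_id = paste(e$anchor_a, e$anchor_b, sep = "|"),
    signal = e$aqua_cpm,
    category = if ("category" %in% names(e)) e$category else NA_character_,
    distance = if ("distance" %in% names(e)) e$distance else NA_real_
  )
  out[, .(signal = sum(signal), category = category[1L],
          distance = distance[1L]), by = unit_id]
}

#' Long-range contact window
#'
#' Keeps cis loops whose anchor distance lies in `[min_d, max_d]`
#' (inclusive at both ends; default 25 kb to 3 Mb).
#'
#' @param loops table with a `distance` column.
#' @param min_d,max_d window bounds in bp.
#' @return filtered table.
#' @export
long_range_filter <- function(loops, min_d = 25000, max_d = 3000000) {
  if (min_d > max_d) stop("min_d > max_d")
  loops[loops$distance >= min_d & loops$distance <= max_d]
}

#' Rank table of per-unit L2FC
#'
#' Orders units by ascending L2FC (stable tie-break by `unit_id`) and
#' reports the cumulative fractions strictly below and at-or-below 0
#' (with all-zero input, `frac_below_zero` is 0 and `frac_at_or_below`
#' is 1 by this convention).
#'
#' @param units per-unit table with `l2fc` and `unit_id`.
#' @return list: `table` (ordered with `rank`), `frac_below_zero`,
#'   `frac_at_or_below_zero`.
#' @export
rank_plot_table <- function(units) {
  out <- data.table::copy(data.table::as.data.table(units))
  if (any(!is.finite(out$l2fc))) stop("non-finite l2fc")
  data.table::setorder(out, l2fc, unit_id)
  out[, rank := .I]
  list(table = out[],
       frac_below_zero = mean(out$l2fc < 0),
       frac_at_or_below_zero = mean(out$l2fc <= 0))
}

#' Aggregate peak analysis (APA)
#'
#' For each loop, extracts the `(2*flank+1)^2` submatrix of binned
#' `aqua_cpm` centred on the loop's (anchor_a, anchor_b) bin pair and
#' averages the submatrices element-wise. Matrix rows index anchor-a
#' offsets, columns anchor-b offsets. Loops whose window would cross a
#' chromosome edge are skipped and counted. Enrichment is the centre
#' value over the mean of the four corner quadrants (side
#' `max(1, floor(flank/2))`), epsilon-guarded.
#'
#' @param contacts normalized contacts binned at `bin_size`.
#' @param loops table of cis loops (`chrom_a`, `start_a`, `chrom_b`,
#'   `start_b`).
#' @param bin_size bin width of `contacts`.
#' @param flank number of bins on each side of the centre (default 10).
#' @param chrom_sizes optional named vector of chromosome lengths for
#'   edge clipping; without it only the `start >= 0` edge is enforced.
#' @param eps guard added to the background denominator.
#' @return list of class `apa_matrix`: `matrix`, `n_loops_used`,
#'   `n_loops_skipped`, `center`, `background`, `enrichment`,
#'   `bin_size`, `flank`.
#' @export
apa <- function(contacts, loops, bin_size = 5000, flank = 10,
                chrom_sizes = NULL, eps = 1e-9) {
  loops <- data.table::as.data.table(loops)
  loops <- loops[loops$chrom_a == loops$chrom_b]
  if (nrow(loops) == 0L) stop("no cis loops supplied to APA")
  dim <- 2L * flank + 1L
  acc <- matrix(0, dim, dim)
  used <- 0L; skipped <- 0L
  cc <- data.table::as.data.table(contacts)
  cc <- cc[, .(chrom = chrom_a, bin_a = start_a %/% bin_size,
               bin_b = start_b %/% bin_size, aqua_cpm)]
  data.table::setkey(cc, chrom, bin_a, bin_b)
  for (i in seq_len(nrow(loops))) {
    ch <- loops$chrom_a[i]
    ca <- loops$start_a[i] %/% bin_size
    cb <- loops$start_b[i] %/% bin_size
    if (ca - flank < 0L || cb - flank < 0L) { skipped <- skipped + 1L; next }
    if (!is.null(chrom_sizes)) {
      nb <- chrom_sizes[[ch]] %/% bin_size
      if ((ca + flank) >= nb || (cb + flank) >= nb) {
        skipped <- skipped + 1L; next
      }
    }
    win <- cc[.(ch)][bin_a >= ca - flank & bin_a <= ca + flank &
                       bin_b >= cb - flank & bin_b <= cb + flank]
    sub <- matrix(0, dim, dim)
    if (nrow(win)) {
      ri <- win$bin_a - (ca - flank) + 1L
      ci <- win$bin_b - (cb - flank) + 1L
      for (j in seq_len(nrow(win)))
        sub[ri[j], ci[j]] <- sub[ri[j], ci[j]] + win$aqua_cpm[j]
    }
    acc <- acc + sub
    used <- used + 1L
  }
  if (used == 0L) stop("all loops skipped (chromosome-edge clipping)")
  m <- acc / used
  q <- max(1L, flank %/% 2L)
  corners <- c(m[1:q, 1:q], m[1:q, (dim - q + 1L):dim],
               m[(dim - q + 1L):dim, 1:q],
               m[(dim - q + 1L):dim, (dim - q + 1L):dim])
  center <- m[flank + 1L, flank + 1L]
  background <- mean(corners)
  structure(list(matrix = m, n_loops_used = used, n_loops_skipped = skipped,
                 center = center, background = background,
                 enrichment = center / (background + eps),
                 bin_size = bin_size, flank = flank),
            class = "apa_matrix")
}

#' Difference of two APA matrices
#'
#' Element-wise `treated - control`; both runs must share geometry.
#' @param apa_trt,apa_ctrl `apa_matrix` objects.
#' @return an `apa_matrix` holding the delta (enrichment fields `NA`).
#' @export
apa_delta <- function(apa_trt, apa_ctrl) {
  if (apa_trt$flank != apa_ctrl$flank ||
      apa_trt$bin_size != apa_ctrl$bin_size)
    stop("APA geometries differ")
  structure(list(matrix = apa_trt$matrix - apa_ctrl$matrix,
                 n_loops_used = NA_integer_, n_loops_skipped = NA_integer_,
                 center = apa_trt$center - apa_ctrl$center,
                 background = NA_real_, enrichment = NA_real_,
                 bin_size = apa_trt$bin_size, flank = apa_trt$flank),
            class = "apa_matrix")
}

#' @export
print.apa_matrix <- function(x, ...) {
  cat(sprintf("apa_matrix %dx%d (bin %d bp): center=%.3f background=%.3f enrichment=%.2f (loops used=%s skipped=%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$bin_size, x$center,
              x$background, x$enrichment, x$n_loops_used, x$n_loops_skipped))
  invisible(x)
}
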