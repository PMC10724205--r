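#' Read HiC-Pro style allValidPairs records
#'
#' Parses the tab-separated allValidPairs dialect: `readID chr1 pos1
#' strand1 chr2 pos2 strand2 [trailing columns ignored]`. Positions in
#' the file are 1-based and are converted to 0-based on read. Each pair
#' is tagged `human` or `spikein` from its chromosome-name prefix and
#' stored in canonical order (`chrom_a, pos_a) <= (chrom_b, pos_b)`).
#' Pairs whose two ends map to different genomes (trans-genome chimeras)
#' are dropped and counted.
#'
#' @param path allValidPairs file (TSV, no header).
#' @param spikein_prefixes chromosome-name prefixes marking the spike-in
#'   genome; anything else is `human`. Default `c("mm_", "dm_")` (mouse
#'   HiChIP spike-in, Drosophila ChIP spike-in).
#' @param on_unknown unused placeholder kept for config symmetry; any
#'   non-spike-in prefix is treated as human.
#' @return A `data.table` of valid pairs (`read_id`, `genome_tag`,
#'   `chrom_a`, `pos_a`, `strand_a`, `chrom_b`, `pos_b`, `strand_b`,
#'   `is_duplicate`), with attribute `counters` (named integer vector:
#'   `n_read`, `n_mixed_genome_dropped`).
#' @export
read_valid_pairs <- function(path, spikein_prefixes = c("mm_", "dm_"),
                             on_unknown = c("drop", "fail")) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- data.table::fread(path, header = FALSE, sep = "\t",
                           fill = TRUE, colClasses = "character")
  if (nrow(raw) == 0L) {
    vp <- empty_valid_pairs()
    data.table::setattr(vp, "counters",
                        c(n_read = 0L, n_mixed_genome_dropped = 0L))
    return(vp)
  }
  if (ncol(raw) < 7L) {
    bad <- which(!stats::complete.cases(raw))[1]
    stop("allValidPairs line with fewer than 7 fields at line ",
         if (is.na(bad)) 1L else bad)
  }
  short <- which(raw[[7]] == "" | is.na(raw[[7]]))
  if (length(short))
    stop("allValidPairs line with fewer than 7 fields at line ", short[1])
  pos1 <- suppressWarnings(as.numeric(raw[[3]]))
  pos2 <- suppressWarnings(as.numeric(raw[[6]]))
  if (anyNA(pos1) || anyNA(pos2))
    stop("non-integer position at line ",
         which(is.na(pos1) | is.na(pos2))[1])
  tag1 <- genome_tag_of(raw[[2]], spikein_prefixes)
  tag2 <- genome_tag_of(raw[[5]], spikein_prefixes)
  keep <- tag1 == tag2
  n_mixed <- sum(!keep)
  vp <- data.table::data.table(
    read_id = raw[[1]][keep],
    genome_tag = tag1[keep],
    chrom_a = raw[[2]][keep], pos_a = pos1[keep] - 1, strand_a = raw[[4]][keep],
    chrom_b = raw[[5]][keep], pos_b = pos2[keep] - 1, strand_b = raw[[7]][keep],
    is_duplicate = FALSE
  )
  vp <- canonicalize_pairs(vp)
  data.table::setattr(vp, "counters",
                      c(n_read = nrow(raw), n_mixed_genome_dropped = n_mixed))
  vp[]
}

empty_valid_pairs <- function() {
  data.table::data.table(
    read_id = character(), genome_tag = character(),
    chrom_a = character(), pos_a = numeric(), strand_a = character(),
    chrom_b = character(), pos_b = numeric(), strand_b = character(),
    is_duplicate = logical()
  )
}

genome_tag_of <- function(chrom, spikein_prefixes) {
  tag <- rep("human", length(chrom))
  for (p in spikein_prefixes) tag[startsWith(chrom, p)] <- "spikein"
  tag
}

#' Put valid pairs in canonical end order
#'
#' Ensures `(chrom_a, pos_a) <= (chrom_b, pos_b)` for every pair,
#' swapping ends (with their strands) where needed. Idempotent.
#'
#' @param vp a valid-pairs table.
#' @return the table with ends canonically ordered.
#' @export
canonicalize_pairs <- function(vp) {
  if (nrow(vp) == 0L) return(vp)
  swap <- vp$chrom_b < vp$chrom_a |
    (vp$chrom_b == vp$chrom_a & vp$pos_b < vp$pos_a)
  if (any(swap)) {
    ca <- vp$chrom_a[swap]; pa <- vp$pos_a[swap]; sa <- vp$strand_a[swap]
    vp[swap, `:=`(chrom_a = chrom_b, pos_a = pos_b, strand_a = strand_b)]
    vp[swap, `:=`(chrom_b = ca, pos_b = pa, strand_b = sa)]
  }
  vp
}

#' Read a BED3/BED6 file
#'
#' @param path BED file, 0-based half-open, tab-separated, no header.
#' @return a sorted `genomic_intervals` table; `name`/`score` columns are
#'   kept when present (BED6).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- data.table::fread(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (nrow(raw) == 0L) return(genomic_intervals(character(), numeric(), numeric()))
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  if (anyNA(start) || anyNA(end) ||
      any(start != floor(start)) || any(end != floor(end)))
    stop("non-integer BED coordinates at line ",
         which(is.na(start) | is.na(end))[1])
  bad <- which(end <= start)
  if (length(bad))
    stop("BED line with end <= start at line ", bad[1])
  genomic_intervals(
    raw[[1]], start, end,
    name = if (ncol(raw) >= 4L) raw[[4]] else NULL,
    score = if (ncol(raw) >= 5L) suppressWarnings(as.numeric(raw[[5]])) else NULL
  )
}

#' Read gene models
#'
#' Accepts either a 5-column TSV (`gene_id chrom strand start end`,
#' half-open 0-based span) or BED12 (exon structure ignored; only the
#' transcript span defines TSS/TES). `tss` is always the transcription
#' start in genome coordinates: for `-` strand genes `tss` is the span
#' end and `tes` the span start.
#'
#' @param path gene file.
#' @param format `"auto"` (default; BED12 detected by 12 columns),
#'   `"tsv"` or `"bed12"`.
#' @return `data.table` with `gene_id`, `chrom`, `strand`, `tss`, `tes`.
#' @export
read_genes <- function(path, format = c("auto", "tsv", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- data.table::fread(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (nrow(raw) == 0L)
    return(data.table::data.table(gene_id = character(), chrom = character(),
                                  strand = character(), tss = numeric(),
                                  tes = numeric()))
  if (format == "auto") format <- if (ncol(raw) >= 12L) "bed12" else "tsv"
  if (format == "bed12") {
    g <- data.table::data.table(gene_id = raw[[4]], chrom = raw[[1]],
                                strand = raw[[6]],
                                start = as.numeric(raw[[2]]),
                                end = as.numeric(raw[[3]]))
  } else {
    if (ncol(raw) < 5L) stop("gene TSV needs 5 columns")
    g <- data.table::data.table(gene_id = raw[[1]], chrom = raw[[2]],
                                strand = raw[[3]],
                                start = as.numeric(raw[[4]]),
                                end = as.numeric(raw[[5]]))
  }
  if (any(!g$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         g$strand[!g$strand %in% c("+", "-")][1])
  if (any(g$end <= g$start)) stop("gene with end <= start")
  g[, tss := ifelse(strand == "+", start, end)]
  g[, tes := ifelse(strand == "+", end, start)]
  g[, c("start", "end") := NULL]
  g[]
}

#' Read a bedGraph coverage file
#'
#' 4-column bedGraph (0-based half-open). Steps must not overlap within
#' a chromosome; values must be finite and non-negative.
#'
#' @param path bedGraph file.
#' @param signed allow negative values (for reading delta tracks back).
#' @return a [coverage_track()].
#' @export
read_bedgraph <- function(path, signed = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(coverage_track())
  raw <- data.table::fread(path, header = FALSE, sep = "\t")
  if (nrow(raw) == 0L) return(coverage_track())
  coverage_track(raw[[1]], as.numeric(raw[[2]]), as.numeric(raw[[3]]),
                 as.numeric(raw[[4]]), signed = signed)
}

#' Write a coverage track as bedGraph
#' @param track a `coverage_track`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  dt <- data.table::as.data.table(track)[, .(chrom, start, end, value)]
  data.table::setorder(dt, chrom, start)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write paired-anchor records as BEDPE
#'
#' Emits one tab-separated line per record with the six coordinate
#' fields `chrom_a start_a end_a chrom_b start_b end_b` followed by any
#' extra columns present. Output is sorted by (chrom_a, start_a,
#' chrom_b, start_b) and carries a header line for the extra columns
#' (`#`-prefixed), so that `read_bedpe(write_bedpe(x)) == x`.
#'
#' @param x `data.table` with at least the six anchor columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(x, path) {
  need <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b")
  if (!all(need %in% names(x))) stop("BEDPE needs columns: ",
                                     paste(need, collapse = ", "))
  dt <- data.table::as.data.table(x)
  data.table::setcolorder(dt, c(need, setdiff(names(dt), need)))
  data.table::setorder(dt, chrom_a, start_a, chrom_b, start_b)
  coord <- c("start_a", "end_a", "start_b", "end_b")
  dt[, (coord) := lapply(.SD, function(v)
    format(v, scientific = FALSE, trim = TRUE)), .SDcols = coord]
  header <- paste0("#", paste(names(dt), collapse = "\t"))
  con <- file(path, "w")
  writeLines(header, con)
  close(con)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a BEDPE file written by [write_bedpe()]
#' @param path BEDPE file.
#' @return `data.table` of paired-anchor records.
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  cols <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  dt <- if (length(lines) > 1L)
    data.table::fread(path, header = FALSE, sep = "\t", skip = 1L)
  else data.table::data.table()
  if (nrow(dt) == 0L) {
    dt <- data.table::as.data.table(
      stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    dt[, c("chrom_a", "chrom_b") := .(character(0), character(0))]
    data.table::setcolorder(dt, cols)
    return(dt[])
  }
  data.table::setnames(dt, cols)
  dt[]
}

#' Write / read a plain TSV table
#'
#' Thin wrappers with a fixed dialect (tab separator, header row) so
#' that every pipeline table round-trips exactly.
#'
#' @param x a data.frame.
#' @param path file path.
#' @return `path` invisibly (write); a `data.table` (read).
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path, sep = "\t")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  data.table::fread(path, header = TRUE, sep = "\t")
}

#' Write intervals as BED
#' @param x interval table (`chrom`, `start`, `end`, optional `name`, `score`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  dt <- data.table::as.data.table(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(dt))
  dt <- dt[, ..cols]
  data.table::setorder(dt, chrom, start, end)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
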