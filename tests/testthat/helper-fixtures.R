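# shared fixtures and independent oracles

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a 5-line allValidPairs fixture: 3 human + 2 mouse spike-in pairs
valid_pairs_fixture <- function() {
  write_lines_tmp(c(
    "r1\tchr1\t101\t+\tchr1\t60101\t-",
    "r2\tchr5\t901\t+\tchr5\t201\t-",        # non-canonical order on disk
    "r3\tchr2\t5001\t-\tchr3\t7001\t+",      # trans
    "r4\tmm_chr1\t100\t+\tmm_chr1\t9000\t+",
    "r5\tmm_chr2\t50\t-\tmm_chr2\t7050\t-"
  ))
}

# brute-force per-base area oracle for coverage tracks
brute_signal <- function(track, chrom, start, end) {
  total <- 0
  tr <- as.data.frame(track)
  for (p in seq(start, end - 1)) {
    row <- tr[tr$chrom == chrom & tr$start <= p & p < tr$end, ]
    if (nrow(row)) total <- total + sum(row$value)
  }
  total
}

# brute-force O(n^2) interval overlap counter
brute_overlap_count <- function(query, peaks) {
  vapply(seq_len(nrow(query)), function(i) {
    sum(peaks$chrom == query$chrom[i] &
          peaks$start < query$end[i] & query$start[i] < peaks$end)
  }, integer(1))
}

# independent breadth-first-search connected components; returns a
# canonical partition signature (sorted list of sorted member strings)
bfs_partition <- function(edge_a, edge_b, nodes) {
  adj <- vector("list", length(nodes))
  names(adj) <- nodes
  for (k in seq_along(edge_a)) {
    adj[[edge_a[k]]] <- c(adj[[edge_a[k]]], edge_b[k])
    adj[[edge_b[k]]] <- c(adj[[edge_b[k]]], edge_a[k])
  }
  seen <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (s in nodes) {
    if (seen[[s]]) next
    queue <- s; seen[[s]] <- TRUE; members <- character()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      members <- c(members, v)
      for (w in adj[[v]]) if (!seen[[w]]) {
        seen[[w]] <- TRUE
        queue <- c(queue, w)
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  sort(vapply(comps, paste, "", collapse = ","))
}

# partition signature of extract_features() output, comparable to
# bfs_partition(); graph-derived features only (peaks excluded)
feature_partition <- function(features) {
  anch <- features$anchors
  sp <- split(anch$key, anch$feature_id)
  sort(vapply(sp, function(x) paste(sort(x), collapse = ","), ""))
}

# tiny synthetic world used by several tests (fast: 40 genes, 1 chrom)
tiny_genome <- function(seed = 5) {
  generate_genome(synthetic_genome_config(
    n_genes = 40L, chrom_length = 8e6, seed = seed))
}

tiny_arch <- function(seed = 5, n_clusters = 20L,
                      n_cpg_promoter_loops = 40L, ...) {
  architecture_config(n_clusters = n_clusters,
                      n_cpg_promoter_loops = n_cpg_promoter_loops,
                      seed = seed, ...)
}

# normalize one condition of a synthetic contact set end to end
normalize_condition <- function(sc, bin_size = 5000) {
  fp <- filter_pairs(sc$pairs)
  st <- spikein_stats(fp, sample_id = sc$condition)
  ct <- aqua_normalize(bin_contacts(fp, bin_size), st)
  list(contacts = ct, stats = st)
}

# unit ids of planted loops, matching delta_table() keys
truth_unit_ids <- function(truops, bin = 5000) {
  paste0(truops$chrom, ":", truops$bin_a * bin, "|",
         truops$chrom, ":", truops$bin_b * bin)
}
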