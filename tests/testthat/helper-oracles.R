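# Independent reference implementations used as oracles. These deliberately
# take the dumbest correct route so they share no code with the package.

# Iterate jump-extension to fixpoint by re-scanning the whole contig each
# round: from the current interval, admit the farthest CAZy gene within
# `window` genes beyond either end; repeat until nothing changes.
oracle_extend <- function(is_cazy, seed_lo, seed_hi, window) {
  lo <- seed_lo
  hi <- seed_hi
  n <- length(is_cazy)
  repeat {
    changed <- FALSE
    right <- which(is_cazy & seq_len(n) > hi & seq_len(n) <= hi + window)
    if (length(right) > 0) {
      hi <- max(right)
      changed <- TRUE
    }
    left <- which(is_cazy & seq_len(n) < lo & seq_len(n) >= lo - window)
    if (length(left) > 0) {
      lo <- min(left)
      changed <- TRUE
    }
    if (!changed) break
  }
  c(lo, hi)
}

# Exhaustive per-k-mer LCA over raw sequences (no canonicalization sharing:
# reimplements reverse complement by hand).
oracle_revcomp <- function(x) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])), collapse = "")
}

oracle_kmer_map <- function(references, taxonomy, k) {
  parent <- setNames(taxonomy$parent_id, taxonomy$node_id)
  path_of <- function(node) {
    p <- node
    while (!is.na(parent[[p[1]]])) p <- c(parent[[p[1]]], p)
    p
  }
  lca_of <- function(nodes) {
    paths <- lapply(nodes, path_of)
    depth <- min(lengths(paths))
    last <- 0
    for (d in seq_len(depth)) {
      ids <- vapply(paths, `[[`, character(1), d)
      if (length(unique(ids)) == 1) last <- d else break
    }
    paths[[1]][last]
  }
  occurrences <- list()
  for (i in seq_len(nrow(references))) {
    s <- references$sequence[i]
    for (start in seq_len(nchar(s) - k + 1)) {
      km <- substr(s, start, start + k - 1)
      if (grepl("[^ACGT]", km)) next
      rc <- oracle_revcomp(km)
      canon <- if (km < rc) km else rc
      occurrences[[canon]] <- unique(c(occurrences[[canon]],
                                       references$taxon_id[i]))
    }
  }
  vapply(occurrences, lca_of, character(1))
}

# O(n^2) Hi-C link tally.
oracle_hic <- function(pairs, clusters, contigs) {
  cluster_ids <- sort(unique(clusters$cluster_id))
  out <- matrix(0, length(contigs), length(cluster_ids),
                dimnames = list(contigs, cluster_ids))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$contig_a[i]
    b <- pairs$contig_b[i]
    n <- pairs$n_pairs[i]
    if (a == b) next
    for (ends in list(c(a, b), c(b, a))) {
      if (!ends[1] %in% contigs) next
      k <- clusters$cluster_id[match(ends[2], clusters$contig_id)]
      if (!is.na(k)) out[ends[1], k] <- out[ends[1], k] + n
    }
  }
  out
}

# Median-unbiased quantile by the direct plotting-position formula
# (p + 1/3 interpolation), independent of stats::quantile.
oracle_quantile_type8 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n + 1 / 3) * p + 1 / 3
  h <- min(max(h, 1), n)
  fl <- floor(h)
  x[fl] + (h - fl) * (x[min(fl + 1, n)] - x[fl])
}
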