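#' Validate a taxonomy table
#'
#' The classifier's taxonomy is a rooted tree given as a node table:
#' `node_id`, `parent_id` (`NA` for the single root), `rank`, `name`.
#' Validation checks a single root, that every node reaches the root, and
#' that there are no cycles.
#'
#' @param taxonomy Node tibble.
#' @return `taxonomy`, invisibly, with ancestor paths attached as an
#'   attribute for reuse.
#' @export
validate_taxonomy <- function(taxonomy) {
  assert_cols(taxonomy, c("node_id", "parent_id", "rank"), "taxonomy")
  if (anyDuplicated(taxonomy$node_id) > 0) {
    abort("duplicate node_id in taxonomy")
  }
  roots <- taxonomy$node_id[is.na(taxonomy$parent_id)]
  if (length(roots) != 1) {
    abort("taxonomy must have exactly one root (parent_id = NA)")
  }
  paths <- tax_paths(taxonomy)
  invisible(structure(taxonomy, paths = paths))
}

# Root-to-node path (inclusive) for every node; errors on cycles or
# dangling parents.
tax_paths <- function(taxonomy) {
  parent <- setNames(taxonomy$parent_id, taxonomy$node_id)
  n <- nrow(taxonomy)
  paths <- vector("list", n)
  names(paths) <- taxonomy$node_id
  for (node in taxonomy$node_id) {
    path <- character()
    cur <- node
    while (!is.na(cur)) {
      if (cur %in% path || length(path) > n) {
        abort(sprintf("taxonomy contains a cycle through node %s", node))
      }
      if (!cur %in% names(parent)) {
        abort(sprintf("node %s has parent %s absent from the taxonomy",
                      node, cur))
      }
      path <- c(cur, path)
      cur <- unname(parent[cur])
    }
    paths[[node]] <- path
  }
  paths
}

# Lowest common ancestor of a set of nodes.
tax_lca <- function(paths, nodes) {
  nodes <- unique(nodes)
  if (length(nodes) == 1) return(nodes)
  common <- Reduce(function(a, b) {
    pb <- paths[[b]]
    m <- min(length(a), length(pb))
    same <- a[seq_len(m)] == pb[seq_len(m)]
    a[seq_len(if (all(same)) m else which.min(same) - 1)]
  }, nodes[-1], paths[[nodes[1]]])
  common[length(common)]
}

# Canonical k-mers of one sequence: lexicographic min of each k-mer and its
# reverse complement; k-mers containing non-ACGT symbols are skipped.
canonical_kmers <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(character())
  starts <- seq_len(n - k + 1)
  kmers <- substring(sequence, starts, starts + k - 1)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (length(kmers) == 0) return(character())
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers))
  )
  pmin(kmers, rc)
}

#' Build an exact k-mer LCA index
#'
#' Every canonical k-mer of every reference genome is stored with the
#' lowest common ancestor (LCA) of all genomes containing it, as in
#' Kraken-style classifiers. Adding a genome can only add keys or raise
#' existing values toward the root, and the index is independent of the
#' order in which genomes are given.
#'
#' @param references Tibble with `ref_id`, `taxon_id`, `sequence`
#'   (DNA over A/C/G/T/N; k-mers containing N are skipped).
#' @param taxonomy Node tibble (see [validate_taxonomy()]).
#' @param k Odd k-mer length, at least 11 (default 21).
#' @return A list of class `rumag_kmer_index` with elements `k`, `map`
#'   (named vector, canonical k-mer to node id) and `taxonomy`.
#' @export
build_kmer_index <- function(references, taxonomy, k = 21) {
  assert_cols(references, c("ref_id", "taxon_id", "sequence"), "references")
  if (k < 11 || k %% 2 == 0) {
    abort("`k` must be an odd length >= 11")
  }
  taxonomy <- validate_taxonomy(taxonomy)
  paths <- attr(taxonomy, "paths")
  missing <- setdiff(unique(references$taxon_id), taxonomy$node_id)
  if (length(missing) > 0) {
    abort(sprintf("taxon %s is absent from the taxonomy", missing[1]))
  }
  kmer_taxon <- purrr::map2(
    references$sequence, references$taxon_id,
    function(seq, taxon) {
      km <- unique(canonical_kmers(toupper(seq), k))
      tibble(kmer = km, taxon_id = rep(taxon, length(km)))
    }
  ) |>
    bind_rows() |>
    distinct()
  map <- kmer_taxon |>
    group_by(.data$kmer) |>
    summarise(
      taxon_id = tax_lca(paths, sort(unique(.data$taxon_id))),
      .groups = "drop"
    )
  structure(
    list(
      k = as.integer(k),
      map = setNames(map$taxon_id, map$kmer),
      taxonomy = as_tibble(taxonomy),
      paths = paths
    ),
    class = "rumag_kmer_index"
  )
}

#' @export
print.rumag_kmer_index <- function(x, ...) {
  cat(sprintf(
    "<rumag_kmer_index> k = %d, %d k-mers, %d taxonomy nodes\n",
    x$k, length(x$map), nrow(x$taxonomy)
  ))
  invisible(x)
}

#' Classify reads against a k-mer LCA index
#'
#' Each read's canonical k-mers are looked up in the index; every node with
#' at least one hit is a candidate, scored by the summed hit counts along
#' its root-to-node path. The deepest maximally-scoring candidate wins
#' (ties by depth, then lexicographic node id). Reads with no hits — or
#' shorter than `k`, which triggers a warning — are unclassified (`NA`).
#'
#' @param reads Character vector of read sequences, or a tibble with a
#'   `sequence` column (a `read_id` column is carried through).
#' @param index A [build_kmer_index()] result.
#' @return A tibble with `read_id`, `taxon_id` (`NA` when unclassified)
#'   and `n_hits` (k-mers found in the index).
#' @export
classify_reads <- function(reads, index) {
  if (is.character(reads)) {
    reads <- tibble(read_id = sprintf("read_%d", seq_along(reads)),
                    sequence = reads)
  }
  assert_cols(reads, "sequence", "reads")
  if (!"read_id" %in% names(reads)) {
    reads$read_id <- sprintf("read_%d", seq_len(nrow(reads)))
  }
  k <- index$k
  short <- nchar(reads$sequence) < k
  if (any(short)) {
    warn(sprintf("%d read(s) shorter than k = %d are unclassified",
                 sum(short), k))
  }
  per_read <- purrr::map(reads$sequence, function(s) {
    if (nchar(s) < k) return(list(taxon = NA_character_, n = 0L))
    km <- canonical_kmers(toupper(s), k)
    hit_nodes <- unname(index$map[km])
    hit_nodes <- hit_nodes[!is.na(hit_nodes)]
    if (length(hit_nodes) == 0) return(list(taxon = NA_character_, n = 0L))
    list(taxon = best_path_node(hit_nodes, index$paths),
         n = length(hit_nodes))
  })
  tibble(
    read_id = reads$read_id,
    taxon_id = vapply(per_read, `[[`, character(1), "taxon"),
    n_hits = vapply(per_read, `[[`, integer(1), "n")
  )
}

# Deepest maximally-scoring hit node under root-to-node path weighting.
best_path_node <- function(hit_nodes, paths) {
  counts <- table(hit_nodes)
  cand <- names(counts)
  scores <- vapply(cand, function(v) {
    sum(counts[intersect(names(counts), paths[[v]])])
  }, numeric(1))
  depth <- vapply(cand, function(v) length(paths[[v]]), numeric(1))
  ord <- order(-scores, -depth, cand)
  cand[ord][1]
}

#' @rdname classify_reads
#' @param read A single read sequence.
#' @return `classify_read()` returns the taxon id, or `NA` when
#'   unclassified.
#' @export
classify_read <- function(read, index) {
  classify_reads(read, index)$taxon_id[1]
}

#' Classification rate of a read set
#'
#' @param reads Reads as in [classify_reads()]; must be non-empty.
#' @param index A [build_kmer_index()] result.
#' @return Percent of reads classified to any rank (a single number).
#' @export
classification_rate <- function(reads, index) {
  n <- if (is.character(reads)) length(reads) else nrow(reads)
  if (n == 0) abort("empty read set")
  res <- classify_reads(reads, index)
  100 * mean(!is.na(res$taxon_id))
}

#' Database-augmentation experiment
#'
#' Rebuilds the k-mer database as the base reference set plus each named
#' addition (optionally cumulative, mirroring nested database designs) and
#' reports the classification rate of one read set against each database.
#' For nested databases the rate is weakly monotone increasing.
#'
#' @param reads Reads as in [classify_reads()].
#' @param base_refs Reference tibble (`ref_id`, `taxon_id`, `sequence`)
#'   forming the base database.
#' @param added_ref_sets Named list of reference tibbles to add.
#' @param taxonomy Node tibble covering all taxa.
#' @param k K-mer length (default 21).
#' @param cumulative Add the sets cumulatively in order (default `FALSE`:
#'   each set is added to the base on its own).
#' @return A tibble with `database` (`"base"` plus the set names),
#'   `n_refs` and `rate_pct`.
#' @export
augmentation_experiment <- function(reads, base_refs, added_ref_sets,
                                    taxonomy, k = 21, cumulative = FALSE) {
  if (length(added_ref_sets) > 0 &&
      (is.null(names(added_ref_sets)) || any(names(added_ref_sets) == ""))) {
    abort("`added_ref_sets` must be a named list")
  }
  dbs <- list(base = base_refs)
  acc <- base_refs
  for (nm in names(added_ref_sets)) {
    refs <- if (cumulative) {
      acc <- bind_rows(acc, added_ref_sets[[nm]])
      acc
    } else {
      bind_rows(base_refs, added_ref_sets[[nm]])
    }
    dbs[[nm]] <- refs
  }
  purrr::imap(dbs, function(refs, nm) {
    index <- build_kmer_index(refs, taxonomy, k = k)
    tibble(
      database = nm,
      n_refs = nrow(refs),
      rate_pct = classification_rate(reads, index)
    )
  }) |>
    bind_rows()
}
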