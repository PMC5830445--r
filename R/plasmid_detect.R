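#' Mean coverage of each genome bin
#'
#' @param coverage Contig-coverage tibble (`contig_id`, `genome_id`,
#'   `length`, `depth`).
#' @param weighted Length-weight the mean (default `FALSE`: plain
#'   arithmetic mean over contigs).
#' @return A tibble with `genome_id` and `mean_depth`.
#' @export
bin_mean_coverage <- function(coverage, weighted = FALSE) {
  assert_cols(coverage, c("contig_id", "genome_id", "depth"), "coverage")
  if (nrow(coverage) == 0) {
    abort("coverage table is empty: every genome needs at least one contig")
  }
  if (weighted) {
    assert_cols(coverage, "length", "coverage")
    coverage |>
      group_by(.data$genome_id) |>
      summarise(
        mean_depth = sum(.data$depth * .data$length) / sum(.data$length),
        .groups = "drop"
      )
  } else {
    coverage |>
      group_by(.data$genome_id) |>
      summarise(mean_depth = mean(.data$depth), .groups = "drop")
  }
}

#' Contigs with elevated copy number
#'
#' Flags contigs whose depth is strictly greater than `factor` times the
#' mean coverage of their genome — the multi-copy signature of plasmids.
#' The selection is invariant under uniform rescaling of all depths within
#' a genome.
#'
#' @param coverage Contig-coverage tibble.
#' @param factor Copy-number factor (default 2; strictly greater than).
#' @param weighted Passed to [bin_mean_coverage()].
#' @return The selected rows of `coverage`, with the genome `mean_depth`
#'   and `ratio = depth / mean_depth` added.
#' @export
high_copy_contigs <- function(coverage, factor = 2, weighted = FALSE) {
  means <- bin_mean_coverage(coverage, weighted = weighted)
  coverage |>
    inner_join(means, by = "genome_id") |>
    mutate(ratio = .data$depth / .data$mean_depth) |>
    filter(.data$depth > factor * .data$mean_depth)
}

#' Filter BLAST high-scoring pairs by length and query fraction
#'
#' Removes HSPs shorter than `min_len` bp or covering less than `min_qfrac`
#' of the query; boundary values survive (the removal criteria are strict
#' "less than").
#'
#' @param hits BLAST-hit tibble with `length` and `qlen`.
#' @param min_len Minimum alignment length in bp (default 500).
#' @param min_qfrac Minimum alignment length as a fraction of the query
#'   length (default 0.10).
#' @return The surviving rows.
#' @export
filter_hsps <- function(hits, min_len = 500, min_qfrac = 0.10) {
  assert_cols(hits, c("length", "qlen"), "hits")
  if (any(hits$qlen <= 0, na.rm = TRUE)) {
    abort("qlen must be > 0")
  }
  filter(
    hits,
    .data$length >= min_len,
    .data$length / .data$qlen >= min_qfrac
  )
}

#' Flag contigs with plasmid-annotated hits
#'
#' A contig is flagged when at least one of its (already filtered) hits
#' carries the word "plasmid" in the subject title, case-insensitively.
#'
#' @param hits Filtered BLAST-hit tibble with `qseqid`, `stitle`,
#'   `bitscore`.
#' @return One row per flagged contig: `contig_id` plus the fields of its
#'   best (highest-bitscore) plasmid hit.
#' @export
flag_plasmid_contigs <- function(hits) {
  assert_cols(hits, c("qseqid", "stitle"), "hits")
  plasmid <- filter(
    hits,
    stringr::str_detect(stringr::str_to_lower(.data$stitle),
                        stringr::fixed("plasmid"))
  )
  plasmid |>
    group_by(.data$qseqid) |>
    arrange(dplyr::desc(.data$bitscore), .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    rename(contig_id = "qseqid") |>
    arrange(.data$contig_id)
}

#' Count Hi-C links between contigs and genome clusters
#'
#' For each contig of interest and each cluster, sums the Hi-C read pairs
#' with one mate on the contig and the other on any member of the cluster.
#' Links of a contig to itself are excluded; cluster membership must be a
#' partition (a contig in two clusters is an error); unclustered contigs
#' contribute to no cell.
#'
#' @param pairs Tibble with `contig_a`, `contig_b`, `n_pairs` (each
#'   undirected pair appears once).
#' @param clusters Tibble with `contig_id`, `cluster_id`.
#' @param contigs Contigs forming the rows of the matrix; defaults to every
#'   contig appearing in `pairs`.
#' @return A tibble of class `rumag_hic_links` with `contig_id`,
#'   `cluster_id`, `n_links`, one row per (contig, cluster) combination.
#'   Plot with [autoplot()].
#' @export
hic_link_counts <- function(pairs, clusters, contigs = NULL) {
  assert_cols(pairs, c("contig_a", "contig_b", "n_pairs"), "pairs")
  assert_cols(clusters, c("contig_id", "cluster_id"), "clusters")
  if (anyDuplicated(clusters$contig_id) > 0) {
    dup <- clusters$contig_id[duplicated(clusters$contig_id)][1]
    abort(sprintf("contig %s is assigned to more than one cluster", dup))
  }
  if (any(pairs$n_pairs < 0)) {
    abort("n_pairs must be >= 0")
  }
  contigs <- contigs %||% sort(unique(c(pairs$contig_a, pairs$contig_b)))
  cluster_of <- setNames(clusters$cluster_id, clusters$contig_id)
  cluster_ids <- sort(unique(clusters$cluster_id))

  # orient every pair both ways so each endpoint can be the row contig
  both <- bind_rows(
    tibble(contig = pairs$contig_a, other = pairs$contig_b,
           n_pairs = pairs$n_pairs),
    tibble(contig = pairs$contig_b, other = pairs$contig_a,
           n_pairs = pairs$n_pairs)
  ) |>
    filter(.data$contig != .data$other) |>
    mutate(cluster_id = unname(cluster_of[.data$other])) |>
    filter(.data$contig %in% contigs, !is.na(.data$cluster_id)) |>
    group_by(contig_id = .data$contig, .data$cluster_id) |>
    summarise(n_links = sum(.data$n_pairs), .groups = "drop")

  grid <- tidyr::expand_grid(contig_id = contigs, cluster_id = cluster_ids)
  out <- grid |>
    left_join(both, by = c("contig_id", "cluster_id")) |>
    mutate(n_links = dplyr::coalesce(.data$n_links, 0))
  class(out) <- c("rumag_hic_links", class(out))
  out
}

#' @export
autoplot.rumag_hic_links <- function(object, trans = "log10", ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$cluster_id, y = .data$contig_id,
                 fill = .data$n_links + 1)
  ) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_continuous(trans = trans, name = "Hi-C links + 1") +
    ggplot2::labs(
      x = "genome cluster", y = "contig",
      title = "Hi-C links between putative plasmid contigs and genome clusters"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
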