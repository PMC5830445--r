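#' Filter genome bins on completeness and contamination
#'
#' The study-wide pass filter for draft genomes: a bin passes when its
#' marker-gene completeness is at least `min_completeness` percent and its
#' contamination is at most `max_contamination` percent, both bounds
#' inclusive.
#'
#' @param stats Bin-stats tibble with `genome_id`, `completeness`,
#'   `contamination` (percent scale, 0-100).
#' @param min_completeness Minimum completeness, percent (default 80).
#' @param max_contamination Maximum contamination, percent (default 10).
#' @return The passing rows of `stats`.
#' @export
filter_bins <- function(stats, min_completeness = 80, max_contamination = 10) {
  assert_cols(stats, c("genome_id", "completeness", "contamination"), "stats")
  check_percentages(stats)
  filter(
    stats,
    .data$completeness >= min_completeness,
    .data$contamination <= max_contamination
  )
}

check_percentages <- function(stats) {
  if (any(stats$completeness > 100 | stats$completeness < 0)) {
    abort("completeness must be on the 0-100 percent scale")
  }
  if (any(stats$contamination < 0)) {
    abort("contamination must be >= 0")
  }
  invisible(stats)
}

#' MIMAG-style quality tier of a genome bin
#'
#' `high_quality_draft` requires completeness strictly above 90% and
#' contamination strictly below 5% (the Bowers draft-quality criteria);
#' `pass_draft` is anything else that passes the default
#' [filter_bins()] bounds (completeness >= 80, contamination <= 10,
#' inclusive); the rest is `fail`. Tier is a pure function of the two
#' percentages.
#'
#' @param completeness,contamination Numeric vectors, percent scale.
#' @return Character vector in
#'   `c("high_quality_draft", "pass_draft", "fail")`.
#' @export
quality_tier <- function(completeness, contamination) {
  if (any(completeness > 100 | completeness < 0)) {
    abort("completeness must be on the 0-100 percent scale")
  }
  if (any(contamination < 0)) {
    abort("contamination must be >= 0")
  }
  dplyr::case_when(
    completeness > 90 & contamination < 5 ~ "high_quality_draft",
    completeness >= 80 & contamination <= 10 ~ "pass_draft",
    TRUE ~ "fail"
  )
}

#' Add a quality-tier column to a bin-stats table
#'
#' @param stats Bin-stats tibble.
#' @return `stats` with a `tier` column from [quality_tier()].
#' @export
add_quality_tier <- function(stats) {
  assert_cols(stats, c("completeness", "contamination"), "stats")
  mutate(stats, tier = quality_tier(.data$completeness, .data$contamination))
}

#' Remove contigs whose genus falls outside Bacteria/Archaea
#'
#' Contig-level taxonomic cleaning of a bin: each contig may carry a genus
#' call (e.g. the majority genus of its protein best hits); contigs whose
#' genus maps to a superkingdom other than Bacteria or Archaea are flagged
#' for removal. Contigs without a call, or with a genus absent from the
#' lookup, are kept.
#'
#' @param contigs Character vector of contig ids in the bin.
#' @param calls Tibble with `contig_id`, `genus` (at most one call per
#'   contig).
#' @param genus_lookup Tibble mapping `genus` to `superkingdom`
#'   (values such as `"Bacteria"`, `"Archaea"`, `"Eukaryota"`, `"Viruses"`).
#' @return A cleaning report tibble with `contig_id`, `genus`,
#'   `superkingdom`, `action` (`"kept"` or `"removed"`); one row per input
#'   contig, kept and removed rows partitioning the input.
#' @export
clean_bin <- function(contigs, calls, genus_lookup) {
  assert_cols(calls, c("contig_id", "genus"), "calls")
  assert_cols(genus_lookup, c("genus", "superkingdom"), "genus_lookup")
  if (anyDuplicated(calls$contig_id) > 0) {
    abort("each contig may have at most one genus call")
  }
  report <- tibble(contig_id = contigs) |>
    left_join(calls[c("contig_id", "genus")], by = "contig_id") |>
    left_join(distinct(genus_lookup[c("genus", "superkingdom")]),
              by = "genus") |>
    mutate(
      action = if_else(
        !is.na(.data$superkingdom) &
          !.data$superkingdom %in% c("Bacteria", "Archaea"),
        "removed", "kept"
      )
    )
  report
}

#' Count genomes resolved to at least each taxonomic rank
#'
#' Lineages fill top-down (a genome resolved to family also has order,
#' class, phylum, kingdom), so the count at a rank is the number of genomes
#' with a non-empty value there, and counts are monotone non-increasing
#' from kingdom to species.
#'
#' @param stats Bin-stats tibble carrying the lineage columns
#'   `kingdom` ... `species` (empty string = unresolved).
#' @return A tibble with `rank` (ordered kingdom to species) and
#'   `n_resolved`.
#' @export
taxonomy_resolution_summary <- function(stats) {
  ranks <- tax_ranks()
  assert_cols(stats, ranks, "stats")
  filled <- vapply(
    ranks,
    function(r) !is.na(stats[[r]]) & stats[[r]] != "",
    logical(nrow(stats))
  )
  filled <- matrix(filled, nrow = nrow(stats),
                   dimnames = list(NULL, ranks))
  # top-down fill: a filled rank below an empty one is a malformed lineage
  for (i in seq_len(nrow(filled))) {
    f <- filled[i, ]
    if (any(f) && any(f[seq_len(max(which(f)))] == FALSE)) {
      abort(sprintf(
        "genome %s has a gap in its lineage (a rank is filled below an empty one)",
        if ("genome_id" %in% names(stats)) stats$genome_id[i] else i
      ))
    }
  }
  tibble(
    rank = factor(ranks, levels = ranks),
    n_resolved = as.integer(colSums(filled))
  )
}

#' Phylum composition of the resolvable genomes
#'
#' Shares are computed over genomes with a non-empty phylum only.
#'
#' @param stats Bin-stats tibble with a `phylum` column.
#' @return A tibble with `phylum`, `n`, `pct`, sorted by descending share.
#' @export
phylum_breakdown <- function(stats) {
  assert_cols(stats, "phylum", "stats")
  resolved <- filter(stats, !is.na(.data$phylum), .data$phylum != "")
  resolved |>
    count(.data$phylum, name = "n") |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    arrange(dplyr::desc(.data$n))
}
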