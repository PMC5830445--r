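#' Count non-overlapping cohesin domains per protein
#'
#' Scaffoldin proteins — the backbone of a cellulosome — carry multiple
#' repeated cohesin domains. This counts cohesin hits per protein after
#' resolving overlaps: hits are taken greedily by descending bitscore
#' (ties by earlier envelope start, then label), and a hit is accepted only
#' if its envelope overlaps every previously accepted hit by at most
#' `max_overlap_frac` of the shorter envelope.
#'
#' @param domains Domain-hit tibble; only hits whose label is in
#'   `cohesin_labels` are considered. A `genome_id` column, if present, is
#'   carried through.
#' @param cohesin_labels Labels recognized as cohesin (default Pfam
#'   `PF00963`).
#' @param max_overlap_frac Maximum allowed pairwise envelope overlap,
#'   as a fraction of the shorter envelope (default 0.5).
#' @return A tibble with `protein_id` (and `genome_id` when available) and
#'   `n_cohesin`, one row per protein that has at least one cohesin hit.
#'   The count is invariant to the input row order.
#' @export
count_cohesin <- function(domains, cohesin_labels = "PF00963",
                          max_overlap_frac = 0.5) {
  assert_cols(domains, c("protein_id", "label", "env_start", "env_end"),
              "domains")
  hits <- filter(domains, .data$label %in% cohesin_labels)
  has_genome <- "genome_id" %in% names(hits)
  if (nrow(hits) == 0) {
    out <- tibble(protein_id = character(), n_cohesin = integer())
    if (has_genome) out$genome_id <- character()
    return(out)
  }
  counts <- hits |>
    group_by(.data$protein_id) |>
    summarise(
      n_cohesin = count_compatible(
        .data$env_start, .data$env_end,
        dplyr::coalesce(.data$bitscore, -Inf), .data$label,
        max_overlap_frac
      ),
      .groups = "drop"
    )
  if (has_genome) {
    counts <- left_join(
      counts, distinct(hits[c("protein_id", "genome_id")]),
      by = "protein_id"
    )
  }
  counts
}

# Greedy compatible-set size over envelopes, deterministic under input
# permutation via the (score desc, start, label) ordering.
count_compatible <- function(starts, ends, scores, labels, max_overlap_frac) {
  ord <- order(-scores, starts, labels)
  acc_s <- integer()
  acc_e <- integer()
  for (i in ord) {
    s <- starts[i]
    e <- ends[i]
    ok <- TRUE
    for (j in seq_along(acc_s)) {
      ov <- min(e, acc_e[j]) - max(s, acc_s[j]) + 1
      shorter <- min(e - s + 1, acc_e[j] - acc_s[j] + 1)
      if (ov > max_overlap_frac * shorter) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      acc_s <- c(acc_s, s)
      acc_e <- c(acc_e, e)
    }
  }
  length(acc_s)
}

#' Screen genomes for cellulosome candidates
#'
#' @param profiles Cohesin profiles from [count_cohesin()] with a
#'   `genome_id` column.
#' @param min_domains Minimum cohesin domains for a protein to count as a
#'   scaffoldin candidate; "multiple" means at least 2 (the default), since
#'   two-domain proteins are biologically meaningful candidates.
#' @return The candidate proteins (`genome_id`, `protein_id`, `n_cohesin`)
#'   from genomes carrying at least one protein at or above the threshold,
#'   sorted by genome and descending `n_cohesin`.
#' @export
screen_genomes <- function(profiles, min_domains = 2) {
  assert_cols(profiles, c("genome_id", "protein_id", "n_cohesin"), "profiles")
  hits <- filter(profiles, .data$n_cohesin >= min_domains)
  profiles |>
    semi_join(distinct(hits["genome_id"]), by = "genome_id") |>
    filter(.data$n_cohesin >= min_domains) |>
    arrange(.data$genome_id, dplyr::desc(.data$n_cohesin), .data$protein_id) |>
    select("genome_id", "protein_id", "n_cohesin")
}
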