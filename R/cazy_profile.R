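#' CAZy class of a family label
#'
#' The six classes of carbohydrate-active enzymes: GH (glycoside
#' hydrolases), GT (glycosyl transferases), PL (polysaccharide lyases),
#' CE (carbohydrate esterases), AA (auxiliary activities) and CB
#' (carbohydrate-binding modules; family prefix `CBM`).
#'
#' @param family Character vector of family labels (e.g. `"GH10"`,
#'   `"CBM48"`).
#' @return Character vector of classes in
#'   `c("GH", "GT", "PL", "CE", "AA", "CB")`; `NA` for labels that are not
#'   CAZy families.
#' @export
cazy_class <- function(family) {
  prefix <- stringr::str_extract(family, "^(GH|GT|PL|CE|AA|CBM)(?=\\d)")
  if_else(prefix == "CBM", "CB", prefix)
}

cazy_classes <- function() c("GH", "GT", "PL", "CE", "AA", "CB")

#' Filter CAZy domain hits with the dbCAN significance cut-offs
#'
#' Applies the dbCAN-recommended thresholds: alignments longer than 80
#' amino acids must have E-value below 1e-5, shorter alignments below
#' 1e-3, and in either case the HMM coverage must exceed 0.3. One
#' assignment is produced per surviving hit, so a protein with several
#' domains can carry several families.
#'
#' @param hits Domain-hit tibble with `evalue`, `ali_length`,
#'   `hmm_coverage` (hits from `read_domain_table()`; non-CAZy labels are
#'   dropped).
#' @param long_min_len Alignment length (aa) separating the two E-value
#'   regimes (default 80).
#' @param evalue_long,evalue_short E-value ceilings for long/short
#'   alignments (defaults 1e-5 and 1e-3).
#' @param min_coverage HMM coverage floor (default 0.3, strict).
#' @return Assignments: the surviving rows with `family` (the normalized
#'   label) and `cazy_class` columns added.
#' @export
apply_dbcan_filters <- function(hits, long_min_len = 80,
                                evalue_long = 1e-5, evalue_short = 1e-3,
                                min_coverage = 0.3) {
  assert_cols(hits, c("protein_id", "label", "evalue", "ali_length",
                      "hmm_coverage"), "hits")
  hits |>
    mutate(
      family = normalize_cazy_family(.data$label),
      cazy_class = cazy_class(.data$family)
    ) |>
    filter(
      !is.na(.data$cazy_class),
      .data$hmm_coverage > min_coverage,
      if_else(
        .data$ali_length > long_min_len,
        .data$evalue < evalue_long,
        .data$evalue < evalue_short
      )
    )
}

#' Per-genome CAZy class counts
#'
#' Counts assignments per genome and class, including multi-domain
#' multiplicity (a protein with a GH and a CE domain contributes to both
#' classes).
#'
#' @param assignments Assignment tibble from [apply_dbcan_filters()] with a
#'   `genome_id` column.
#' @param genomes Genomes to report; defaults to those present in
#'   `assignments`. Genomes with no assignment get an all-zero row.
#' @return A tibble with one row per genome and one column per class
#'   (`GH`, `GT`, `PL`, `CE`, `AA`, `CB`), zero-filled.
#' @export
class_counts <- function(assignments, genomes = NULL) {
  assert_cols(assignments, c("genome_id", "cazy_class"), "assignments")
  genomes <- genomes %||% sort(unique(assignments$genome_id))
  wide <- assignments |>
    count(.data$genome_id, .data$cazy_class) |>
    tidyr::pivot_wider(names_from = "cazy_class", values_from = "n",
                       values_fill = 0L)
  for (cls in cazy_classes()) {
    if (!cls %in% names(wide)) wide[[cls]] <- 0L
  }
  tibble(genome_id = genomes) |>
    left_join(wide, by = "genome_id") |>
    mutate(across(dplyr::all_of(cazy_classes()),
                  \(x) dplyr::coalesce(x, 0L))) |>
    select("genome_id", dplyr::all_of(cazy_classes()))
}

#' Totals over a class-count table
#'
#' @param counts Output of [class_counts()].
#' @return A one-row tibble of column sums over the six classes.
#' @export
class_totals <- function(counts) {
  assert_cols(counts, cazy_classes(), "counts")
  summarise(counts, across(dplyr::all_of(cazy_classes()), sum))
}

#' Best per-database identities for each protein
#'
#' Reduces one or more best-hit tables (one per reference database) to the
#' best percent identity per protein per database, plus the maximum across
#' databases.
#'
#' @param hits_by_db Named list of BLAST-style hit tibbles (`qseqid`,
#'   `pident`); names are the database labels.
#' @return A tibble with `protein_id`, one identity column per database
#'   (`NA` when the protein has no hit there) and `max_identity`.
#' @export
best_identities <- function(hits_by_db) {
  if (is.null(names(hits_by_db)) || any(names(hits_by_db) == "")) {
    abort("`hits_by_db` must be a named list of hit tables")
  }
  per_db <- purrr::imap(hits_by_db, function(hits, db) {
    assert_cols(hits, c("qseqid", "pident"), db)
    hits |>
      group_by(protein_id = .data$qseqid) |>
      summarise("{db}" := max(.data$pident), .groups = "drop")
  })
  wide <- purrr::reduce(per_db, dplyr::full_join, by = "protein_id")
  dbs <- names(hits_by_db)
  wide$max_identity <- do.call(
    pmax, c(unname(as.list(wide[dbs])), list(na.rm = TRUE))
  )
  wide
}

#' Novelty summary of a protein set
#'
#' A protein is "known" when its best identity against any reference
#' database reaches the threshold (inclusive: 95.0% counts at the default);
#' otherwise — including proteins with no hit in any database — it is
#' novel.
#'
#' @param identities Tibble from [best_identities()] (`protein_id`,
#'   `max_identity`).
#' @param protein_ids All proteins in the set under study; proteins absent
#'   from `identities` count as novel. Defaults to the proteins present in
#'   `identities`.
#' @param threshold Percent identity defining "known" (default 95).
#' @return A one-row tibble: `n_total`, `n_known`, `n_novel`, `pct_known`.
#' @export
novelty_summary <- function(identities, protein_ids = NULL, threshold = 95) {
  assert_cols(identities, c("protein_id", "max_identity"), "identities")
  protein_ids <- protein_ids %||% identities$protein_id
  known_ids <- identities$protein_id[
    !is.na(identities$max_identity) & identities$max_identity >= threshold
  ]
  n_total <- length(unique(protein_ids))
  n_known <- sum(unique(protein_ids) %in% known_ids)
  tibble(
    n_total = n_total,
    n_known = n_known,
    n_novel = n_total - n_known,
    pct_known = 100 * n_known / n_total
  )
}

#' Identity distribution per CAZy class
#'
#' Summarizes, for each class, the distribution of best-hit identities of
#' its proteins. A protein assigned to several classes contributes its
#' identity to each; within a class each protein counts once regardless of
#' how many domains placed it there. Quantiles use the median-unbiased
#' estimator (`type = 8`) so implementations agree across platforms.
#'
#' @param assignments Assignment tibble (`protein_id`, `cazy_class`).
#' @param identities Tibble from [best_identities()].
#' @return A tibble with `cazy_class`, `n_proteins`, `q25`, `median`,
#'   `q75`; classes with no proteins are absent. Proteins with no identity
#'   (no hit anywhere) are excluded from the quantiles but counted in
#'   `n_proteins`.
#' @export
identity_distribution_by_class <- function(assignments, identities) {
  assert_cols(assignments, c("protein_id", "cazy_class"), "assignments")
  assert_cols(identities, c("protein_id", "max_identity"), "identities")
  assignments |>
    distinct(.data$protein_id, .data$cazy_class) |>
    left_join(identities[c("protein_id", "max_identity")],
              by = "protein_id") |>
    group_by(.data$cazy_class) |>
    summarise(
      n_proteins = dplyr::n(),
      q25 = quantile(.data$max_identity, 0.25, type = 8, na.rm = TRUE,
                     names = FALSE),
      median = quantile(.data$max_identity, 0.5, type = 8, na.rm = TRUE,
                        names = FALSE),
      q75 = quantile(.data$max_identity, 0.75, type = 8, na.rm = TRUE,
                     names = FALSE),
      .groups = "drop"
    )
}

#' Plot per-class identity distributions
#'
#' Boxplots of best-hit percent identity per CAZy class, one protein one
#' observation.
#'
#' @param assignments Assignment tibble (`protein_id`, `cazy_class`).
#' @param identities Tibble from [best_identities()].
#' @return A ggplot object.
#' @export
plot_identity_by_class <- function(assignments, identities) {
  data <- assignments |>
    distinct(.data$protein_id, .data$cazy_class) |>
    inner_join(identities[c("protein_id", "max_identity")],
               by = "protein_id")
  ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data$cazy_class, y = .data$max_identity)
  ) +
    ggplot2::geom_boxplot(fill = "darkseagreen3") +
    ggplot2::labs(
      x = "CAZy class", y = "best hit identity (%)",
      title = "Amino-acid identity of CAZymes against reference databases"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-genome CAZy class counts
#'
#' @param counts Output of [class_counts()].
#' @return A ggplot heatmap (genomes by class, fill = count).
#' @export
plot_class_counts <- function(counts) {
  long <- tidyr::pivot_longer(counts, -"genome_id",
                              names_to = "cazy_class", values_to = "n")
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$cazy_class, y = .data$genome_id, fill = .data$n)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 name = "proteins") +
    ggplot2::labs(x = "CAZy class", y = "genome") +
    ggplot2::theme_minimal()
}
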