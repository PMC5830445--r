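#' Configuration for PUL calling
#'
#' Bundles the tunable thresholds of the polysaccharide-utilization-locus
#' caller. The susC/susD recognition sets default to the Pfam families
#' conventionally used for TonB-dependent transporter plugs/barrels
#' (susC-like: PF00593, PF07715) and SusD-like outer-membrane glycan-binding
#' lipoproteins (PF07980, PF12741, PF12771, PF14322); both are fully
#' overridable.
#'
#' @param window Moving-window size in genes for the extension search
#'   (default 5).
#' @param susC_labels,susD_labels Pfam accessions recognized as susC-like /
#'   susD-like.
#' @param max_seed_gap Maximum intergenic distance in bp allowed within a
#'   tandem pair (default `Inf`, i.e. adjacency in gene order is the only
#'   requirement).
#' @return A named list of class `rumag_pul_config`.
#' @export
pul_config <- function(window = 5,
                       susC_labels = c("PF00593", "PF07715"),
                       susD_labels = c("PF07980", "PF12741", "PF12771",
                                       "PF14322"),
                       max_seed_gap = Inf) {
  if (!is.numeric(window) || window < 1) {
    abort("`window` must be >= 1")
  }
  structure(
    list(
      window = as.integer(window),
      susC_labels = susC_labels,
      susD_labels = susD_labels,
      max_seed_gap = max_seed_gap
    ),
    class = "rumag_pul_config"
  )
}

#' Assign susC/susD roles to proteins from Pfam domain hits
#'
#' A protein is susC-like (susD-like) when it carries at least one domain
#' hit whose label is in the configured susC (susD) Pfam set. A protein
#' carrying labels from both sets takes the role of its higher-bitscore
#' label; ties (and missing bitscores) resolve to susC.
#'
#' @param domains Domain-hit tibble (see [read_domain_table()]), already
#'   score-filtered.
#' @param config A [pul_config()].
#' @return A tibble with `protein_id` and `role` in
#'   `c("susC_like", "susD_like", "none")`, one row per protein in
#'   `domains`.
#' @export
assign_sus_roles <- function(domains, config = pul_config()) {
  assert_cols(domains, c("protein_id", "label"), "domains")
  bs <- if ("bitscore" %in% names(domains)) domains$bitscore else NA_real_
  scored <- domains |>
    mutate(
      .bs = dplyr::coalesce(bs, -Inf),
      .sus = dplyr::case_when(
        .data$label %in% config$susC_labels ~ "susC_like",
        .data$label %in% config$susD_labels ~ "susD_like",
        TRUE ~ NA_character_
      )
    )
  roles <- scored |>
    filter(!is.na(.data$.sus)) |>
    group_by(.data$protein_id) |>
    summarise(
      role = {
        c_best <- suppressWarnings(max(.data$.bs[.data$.sus == "susC_like"],
                                       -Inf))
        d_best <- suppressWarnings(max(.data$.bs[.data$.sus == "susD_like"],
                                       -Inf))
        if (d_best > c_best) "susD_like" else "susC_like"
      },
      .groups = "drop"
    )
  tibble(protein_id = unique(domains$protein_id)) |>
    left_join(roles, by = "protein_id") |>
    mutate(role = dplyr::coalesce(.data$role, "none"))
}

# Order genes within each contig and attach a dense position index.
add_gene_pos <- function(genes) {
  genes |>
    arrange(.data$contig_id, .data$start, .data$end) |>
    group_by(.data$contig_id) |>
    mutate(pos = row_number()) |>
    ungroup()
}

#' Find tandem susC/susD seed pairs
#'
#' A seed pair is two genes consecutive in contig gene order (no intervening
#' gene), one susC-like and one susD-like, in either order and on either
#' strand.
#'
#' @param genes Gene table sorted by coordinate (see [read_gene_calls()]).
#' @param roles Role table from [assign_sus_roles()].
#' @param max_seed_gap Maximum intergenic bp between the two genes
#'   (default `Inf`).
#' @return A tibble with `contig_id`, `susC_gene`, `susD_gene`, `left_pos`
#'   (contig gene-order position of the left member). Overlapping chains
#'   such as C-D-C yield each adjacent pair.
#' @export
find_seed_pairs <- function(genes, roles, max_seed_gap = Inf) {
  assert_cols(genes, c("gene_id", "protein_id", "contig_id", "start", "end"),
              "genes")
  g <- add_gene_pos(genes) |>
    left_join(roles, by = "protein_id") |>
    mutate(role = dplyr::coalesce(.data$role, "none"))
  g |>
    dplyr::group_split(.data$contig_id) |>
    purrr::map(function(ann) {
      pairs <- find_contig_seeds(ann, max_seed_gap)
      if (nrow(pairs) > 0) pairs$contig_id <- ann$contig_id[1]
      pairs
    }) |>
    bind_rows() |>
    (\(x) if (nrow(x) == 0) {
      tibble(susC_gene = character(), susD_gene = character(),
             left_pos = integer(), contig_id = character())
    } else x)()
}

# Directional window extension over a logical CAZy mask.
# From boundary b, scan up to `window` genes outward; jump to the farthest
# CAZy-positive gene in the window and rescan; stop when a window holds none.
extend_boundary <- function(is_cazy, b, dir, window, n) {
  repeat {
    rng <- b + dir * seq_len(window)
    rng <- rng[rng >= 1 & rng <= n]
    if (length(rng) == 0) return(b)
    hits <- rng[is_cazy[rng]]
    if (length(hits) == 0) return(b)
    b <- hits[which.max(dir * hits)]
  }
}

#' Extend a seed pair into a full PUL by the gene-window search
#'
#' Each direction extends independently from the seed: scan up to `window`
#' genes outward from the current boundary; if any carries a CAZy-family
#' homologue the boundary jumps to the farthest such gene within the window
#' and the scan repeats from there; the search ends when a window contains
#' no CAZy gene or the contig ends. All genes between the final boundaries
#' are members; intervening genes without a CAZy label or sus role are
#' labelled `"unc"`.
#'
#' @param genes Gene table for one contig (any coordinate order; sorted
#'   internally).
#' @param domains Domain hits for the contig's proteins (`source` column
#'   distinguishes `"cazy"` from `"pfam"`).
#' @param seed Character vector `c(susC_gene_id, susD_gene_id)`; the two
#'   genes must be adjacent in contig gene order.
#' @param config A [pul_config()].
#' @return A one-row PUL tibble (same schema as [call_puls()]).
#' @export
extend_pul <- function(genes, domains, seed, config = pul_config()) {
  ann <- annotate_contig_genes(genes, domains, config)
  if (length(unique(ann$contig_id)) != 1) {
    abort("`extend_pul()` expects genes from a single contig")
  }
  pos_c <- ann$pos[match(seed[1], ann$gene_id)]
  pos_d <- ann$pos[match(seed[2], ann$gene_id)]
  if (is.na(pos_c) || is.na(pos_d) || abs(pos_c - pos_d) != 1) {
    abort("seed genes must be adjacent in contig gene order")
  }
  n <- nrow(ann)
  lo <- extend_boundary(ann$is_cazy, min(pos_c, pos_d), -1L, config$window, n)
  hi <- extend_boundary(ann$is_cazy, max(pos_c, pos_d), +1L, config$window, n)
  build_pul_rows(
    ann,
    intervals = tibble(lo = lo, hi = hi),
    seeds = list(tibble(susC_gene = seed[1], susD_gene = seed[2]))
  )
}

# Join gene table with per-gene CAZy flag/label and sus role.
annotate_contig_genes <- function(genes, domains, config) {
  g <- add_gene_pos(genes)
  roles <- assign_sus_roles(domains, config)
  cazy <- domains |>
    filter(.data$source == "cazy") |>
    mutate(.bs = dplyr::coalesce(.data$bitscore, -Inf)) |>
    group_by(.data$protein_id) |>
    arrange(dplyr::desc(.data$.bs), .data$label, .by_group = TRUE) |>
    summarise(cazy_label = first(.data$label), .groups = "drop")
  g |>
    left_join(roles, by = "protein_id") |>
    left_join(cazy, by = "protein_id") |>
    mutate(
      role = dplyr::coalesce(.data$role, "none"),
      is_cazy = !is.na(.data$cazy_label),
      label = dplyr::case_when(
        .data$role == "susC_like" ~ "susC",
        .data$role == "susD_like" ~ "susD",
        .data$is_cazy ~ .data$cazy_label,
        TRUE ~ "unc"
      )
    )
}

# Assemble PUL rows for one contig from annotated genes, member-position
# intervals and their seed lists.
build_pul_rows <- function(ann, intervals, seeds) {
  genome_id <- if ("genome_id" %in% names(ann)) ann$genome_id[1] else NA_character_
  contig_id <- ann$contig_id[1]
  rows <- purrr::pmap(
    list(intervals$lo, intervals$hi, seeds, seq_len(nrow(intervals))),
    function(lo, hi, seed_tbl, k) {
      members <- ann[ann$pos >= lo & ann$pos <= hi, , drop = FALSE]
      labels <- members$label
      tibble(
        pul_id = sprintf("%s_%s_pul%d", genome_id, contig_id, k),
        genome_id = genome_id,
        contig_id = contig_id,
        start = min(members$start),
        end = max(members$end),
        n_genes = nrow(members),
        n_seeds = nrow(seed_tbl),
        simple = nrow(members) == 2 &&
          sum(labels == "susC") == 1 && sum(labels == "susD") == 1,
        signature = architecture_signature(members),
        seeds = list(seed_tbl),
        genes = list(members[c("gene_id", "protein_id", "start", "end",
                               "strand", "pos", "role", "label")])
      )
    }
  )
  bind_rows(rows)
}

#' Call polysaccharide utilization loci across a genome
#'
#' Runs the full caller: susC/susD role assignment, tandem seed-pair
#' detection, window extension of every seed, and merging of extensions
#' whose gene ranges overlap on a contig (their genes are unioned and all
#' seeds recorded, so C-D-C chains are counted once). PUL identifiers are
#' deterministic: genome, contig, left-to-right index.
#'
#' @param genes Gene table for one genome (see [read_gene_calls()]).
#' @param domains Domain-hit tibble covering the genome's proteins; Pfam
#'   hits drive role assignment, CAZy hits drive extension.
#' @param config A [pul_config()].
#' @return A tibble of class `rumag_puls`, one row per PUL, with columns
#'   `pul_id`, `genome_id`, `contig_id`, `start`, `end`, `n_genes`,
#'   `n_seeds`, `simple`, `signature` and list-columns `seeds`, `genes`.
#'   `simple` flags loci that are exactly one susC/susD pair. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
call_puls <- function(genes, domains, config = pul_config()) {
  assert_cols(genes, c("gene_id", "protein_id", "contig_id", "start", "end",
                       "strand"), "genes")
  out <- genes |>
    dplyr::group_split(.data$contig_id) |>
    purrr::map(function(contig_genes) {
      ann <- annotate_contig_genes(contig_genes, domains, config)
      seeds <- find_contig_seeds(ann, config$max_seed_gap)
      if (nrow(seeds) == 0) return(NULL)
      n <- nrow(ann)
      ext <- seeds |>
        mutate(
          lo = purrr::map_int(.data$left_pos, function(p) {
            extend_boundary(ann$is_cazy, p, -1L, config$window, n)
          }),
          hi = purrr::map_int(.data$left_pos, function(p) {
            extend_boundary(ann$is_cazy, p + 1L, +1L, config$window, n)
          })
        )
      merged <- merge_extensions(ext)
      build_pul_rows(ann, merged, merged$seed_list)
    }) |>
    bind_rows()
  if (nrow(out) == 0) {
    out <- empty_pul_tbl()
  }
  class(out) <- c("rumag_puls", class(out))
  out
}

empty_pul_tbl <- function() {
  tibble(
    pul_id = character(), genome_id = character(), contig_id = character(),
    start = integer(), end = integer(), n_genes = integer(),
    n_seeds = integer(), simple = logical(), signature = character(),
    seeds = list(), genes = list()
  )
}

# Seed pairs over an annotated contig (positions already attached).
find_contig_seeds <- function(ann, max_seed_gap) {
  n <- nrow(ann)
  if (n < 2) {
    return(tibble(susC_gene = character(), susD_gene = character(),
                  left_pos = integer()))
  }
  left <- seq_len(n - 1)
  role_l <- ann$role[left]
  role_r <- ann$role[left + 1]
  gap <- ann$start[left + 1] - ann$end[left] - 1
  is_pair <- ((role_l == "susC_like" & role_r == "susD_like") |
                (role_l == "susD_like" & role_r == "susC_like")) &
    gap <= max_seed_gap
  idx <- left[is_pair]
  tibble(
    susC_gene = if_else(ann$role[idx] == "susC_like",
                        ann$gene_id[idx], ann$gene_id[idx + 1]),
    susD_gene = if_else(ann$role[idx] == "susC_like",
                        ann$gene_id[idx + 1], ann$gene_id[idx]),
    left_pos = ann$pos[idx]
  )
}

# Union overlapping [lo, hi] gene-position intervals; keep all seeds.
merge_extensions <- function(ext) {
  ext <- arrange(ext, .data$lo, .data$hi)
  lo <- integer()
  hi <- integer()
  seed_list <- list()
  for (i in seq_len(nrow(ext))) {
    s <- tibble(susC_gene = ext$susC_gene[i], susD_gene = ext$susD_gene[i])
    if (length(lo) > 0 && ext$lo[i] <= hi[length(hi)]) {
      hi[length(hi)] <- max(hi[length(hi)], ext$hi[i])
      seed_list[[length(seed_list)]] <-
        bind_rows(seed_list[[length(seed_list)]], s)
    } else {
      lo <- c(lo, ext$lo[i])
      hi <- c(hi, ext$hi[i])
      seed_list <- c(seed_list, list(s))
    }
  }
  tibble(lo = lo, hi = hi, seed_list = seed_list)
}

#' Per-genome PUL summary
#'
#' @param puls A `rumag_puls` tibble from [call_puls()] (PUL from several
#'   genomes may be concatenated with `bind_rows()`).
#' @return A tibble with one row per genome: `n_puls`, `min_genes`,
#'   `max_genes` (smallest/largest locus in genes), `n_simple` (loci that
#'   are a bare susC/susD pair) and `n_multi = n_puls - n_simple`.
#' @export
pul_summary <- function(puls) {
  assert_cols(puls, c("genome_id", "n_genes", "simple"), "puls")
  puls |>
    group_by(.data$genome_id) |>
    summarise(
      n_puls = dplyr::n(),
      min_genes = min(.data$n_genes),
      max_genes = max(.data$n_genes),
      n_simple = sum(.data$simple),
      n_multi = dplyr::n() - sum(.data$simple),
      .groups = "drop"
    )
}

#' Enzyme occurrence across PUL
#'
#' Counts, for every CAZy family appearing as a PUL member, the total
#' occurrences and the number of distinct loci carrying it. Structural
#' labels (`susC`, `susD`, `unc`) are excluded.
#'
#' @param puls A `rumag_puls` tibble.
#' @return A tibble with `label`, `occurrences`, `n_puls`, sorted by
#'   descending occurrences (ties broken by label).
#' @export
enzyme_occurrence <- function(puls) {
  assert_cols(puls, c("pul_id", "genes"), "puls")
  long <- tidyr::unnest(puls[c("pul_id", "genes")], "genes")
  long |>
    filter(!.data$label %in% c("susC", "susD", "unc")) |>
    group_by(.data$label) |>
    summarise(
      occurrences = dplyr::n(),
      n_puls = dplyr::n_distinct(.data$pul_id),
      .groups = "drop"
    ) |>
    arrange(dplyr::desc(.data$occurrences), .data$label)
}

#' Strand-aware architecture signature of a PUL
#'
#' Member genes are written in coordinate order, labels joined by `"-"`;
#' maximal runs of genes on the opposite strand from the reference strand
#' (the seed susC's strand) are split out as separate blocks joined by
#' `" | "`. Genes carrying both a sus role and a CAZy label print the sus
#' role; unannotated members print `"unc"`. The mapping is invertible via
#' [parse_signature()].
#'
#' @param genes Tibble of member genes in coordinate order with `label` and
#'   `strand` columns.
#' @param ref_strand Reference strand; defaults to the strand of the first
#'   `susC`-labelled member (first gene if none).
#' @return A single signature string.
#' @export
architecture_signature <- function(genes, ref_strand = NULL) {
  assert_cols(genes, c("label", "strand"), "genes")
  if (nrow(genes) == 0) return("")
  if (is.null(ref_strand)) {
    i <- which(genes$label == "susC")
    ref_strand <- if (length(i) > 0) genes$strand[i[1]] else genes$strand[1]
  }
  same <- genes$strand == ref_strand
  runs <- rle(same)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  blocks <- purrr::map2_chr(starts, ends, function(s, e) {
    paste(genes$label[s:e], collapse = "-")
  })
  paste(blocks, collapse = " | ")
}

#' Parse an architecture signature back to labelled genes
#'
#' Inverse of [architecture_signature()]: blocks are split on `" | "`,
#' labels on `"-"`. Strands are reconstructed relative to the block
#' containing the first `susC` (assigned the reference strand, `"+"` by
#' default); blocks alternate strand because runs are maximal.
#'
#' @param signature Signature string.
#' @param ref_strand Strand assigned to the susC block (default `"+"`).
#' @return A tibble with `label` and `strand`, in gene order.
#' @export
parse_signature <- function(signature, ref_strand = "+") {
  other <- if (ref_strand == "+") "-" else "+"
  blocks <- strsplit(signature, " | ", fixed = TRUE)[[1]]
  labels <- strsplit(blocks, "-", fixed = TRUE)
  anchor <- which(vapply(labels, function(x) "susC" %in% x, logical(1)))
  anchor <- if (length(anchor) > 0) anchor[1] else 1L
  purrr::imap(labels, function(lab, j) {
    tibble(
      label = lab,
      strand = if ((j - anchor) %% 2 == 0) ref_strand else other
    )
  }) |>
    bind_rows()
}

#' @export
tidy.rumag_puls <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble(
      pul_id = character(), genome_id = character(), contig_id = character(),
      gene_id = character(), protein_id = character(), start = integer(),
      end = integer(), strand = character(), pos = integer(),
      role = character(), label = character()
    ))
  }
  tidyr::unnest(
    as_tibble(x)[c("pul_id", "genome_id", "contig_id", "genes")],
    "genes"
  )
}

#' @export
glance.rumag_puls <- function(x, ...) {
  tibble(
    n_puls = nrow(x),
    n_genomes = dplyr::n_distinct(x$genome_id),
    n_simple = sum(x$simple),
    n_multi_pul_genomes = if (nrow(x) == 0) 0L else {
      sum(table(x$genome_id) > 1)
    },
    max_puls_per_genome = if (nrow(x) == 0) 0L else {
      max(table(x$genome_id))
    },
    mean_genes = if (nrow(x) == 0) NA_real_ else mean(x$n_genes)
  )
}

#' @export
autoplot.rumag_puls <- function(object, ...) {
  counts <- pul_summary(object)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$n_puls)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "steelblue",
                            colour = "grey20") +
    ggplot2::labs(
      x = "PUL per genome", y = "genomes",
      title = "Polysaccharide utilization loci per genome"
    ) +
    ggplot2::theme_minimal()
}
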