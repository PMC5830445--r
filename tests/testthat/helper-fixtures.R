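# Builders for in-code fixtures shared across the suite.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# A gene grid on one contig: labels drive the domain table.
# `labels` entries: "susC", "susD", a CAZy family ("GH10"), or "unc".
make_contig <- function(labels, strands = rep("+", length(labels)),
                        contig_id = "c1", genome_id = "G",
                        gene_len = 900L, gap = 100L) {
  n <- length(labels)
  starts <- 1L + (seq_len(n) - 1L) * (gene_len + gap)
  ids <- sprintf("%s_%s_g%02d", genome_id, contig_id, seq_len(n))
  genes <- tibble(
    gene_id = ids, protein_id = ids, genome_id = genome_id,
    contig_id = contig_id, start = starts, end = starts + gene_len - 1L,
    strand = strands
  )
  domains <- purrr::map2(ids, labels, function(id, lab) {
    if (lab == "susC") {
      make_hit(id, "pfam", "PF00593", bitscore = 250)
    } else if (lab == "susD") {
      make_hit(id, "pfam", "PF07980", bitscore = 220)
    } else if (lab == "unc") {
      make_hit(id, "pfam", "PF00077", bitscore = 50)
    } else {
      make_hit(id, "cazy", lab, bitscore = 150)
    }
  }) |>
    bind_rows()
  list(genes = genes, domains = domains)
}

make_hit <- function(protein_id, source = "cazy", label = "GH10",
                     evalue = 1e-30, bitscore = 100, ali_length = 200L,
                     hmm_coverage = 0.9, env_start = 1L, env_end = 200L) {
  tibble(
    protein_id = protein_id, source = source, label = label,
    evalue = evalue, bitscore = bitscore, ali_length = ali_length,
    hmm_coverage = hmm_coverage, env_start = env_start, env_end = env_end
  )
}

make_bin_stats <- function(genome_id, completeness, contamination,
                           lineage = list()) {
  out <- tibble(genome_id = genome_id, completeness = completeness,
                contamination = contamination)
  for (rank in c("kingdom", "phylum", "class", "order", "family", "genus",
                 "species")) {
    out[[rank]] <- lineage[[rank]] %||% ""
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Random annotated contig for oracle comparisons: every gene independently
# CAZy-positive; one adjacent susC/susD seed planted at a random position.
random_seeded_contig <- function(n_genes = 30, p_cazy = 0.3) {
  seed_left <- sample.int(n_genes - 1, 1)
  labels <- ifelse(runif(n_genes) < p_cazy,
                   sample(c("GH10", "GH43", "CE1", "GT2"), n_genes,
                          replace = TRUE),
                   "unc")
  labels[seed_left] <- "susC"
  labels[seed_left + 1] <- "susD"
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  fx <- make_contig(labels, strands)
  list(fx = fx, labels = labels, seed_left = seed_left)
}
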