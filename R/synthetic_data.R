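#' Configuration of the synthetic-data generator
#'
#' One seeded configuration drives every generator, so the whole synthetic
#' study is reproducible from a single integer. Defaults describe a small
#' rumen-like study: loci planted from the two architectures most often
#' seen in Bacteroidetes genomes (a bare susC/susD pair, and a two-strand
#' xylan-degradation layout), plasmids at 3x copy number, Illumina-like
#' 150 bp reads, and a best-hit identity mixture in which a small minority
#' of proteins (9%) closely match a reference database while the rest sit
#' near 65-72% identity.
#'
#' @param seed Integer seed; fully determines every generator's output.
#' @param n_genomes Number of genomes in community-level simulations.
#' @param genes_per_contig Genes per simulated contig (default 40).
#' @param window Gene window used when spacing planted loci so that planted
#'   truth is exactly recoverable (default 5, matching [pul_config()]).
#' @param planted_pul_specs Character vector of locus layouts in the
#'   [architecture_signature()] grammar; each is planted on its own contig.
#' @param decoy_cazy_rate Per-spacer-gene probability of carrying a decoy
#'   CAZy label (default 0.05). Decoys are never placed within `window`
#'   genes of a planted locus boundary unless `decoy_near_truth = TRUE`.
#' @param decoy_near_truth Allow decoys inside the exclusion zone
#'   (default `FALSE`).
#' @param plasmid_copy_numbers Copy number of each planted plasmid contig
#'   (default 3).
#' @param coverage_noise_cv Coefficient of variation of per-contig depth
#'   (default 0.1).
#' @param base_depth Mean chromosome depth (default 20).
#' @param n_contigs Chromosomal contigs per genome in coverage simulations
#'   (default 10).
#' @param identity_mixture List with `means`, `sds`, `weights` describing
#'   the best-hit percent-identity mixture on the 0-100 scale.
#' @param read_length Read length in bp (default 150).
#' @param error_rate Per-base substitution error rate (default 0.005).
#' @param n_reads Reads per community simulation (default 2000).
#' @return A named list of class `rumag_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genomes = 10,
                       genes_per_contig = 40,
                       window = 5,
                       planted_pul_specs = c(
                         "susC-susD",
                         "GH43-GH10 | GH67-GH35-susC-susD-unc-GH10"
                       ),
                       decoy_cazy_rate = 0.05,
                       decoy_near_truth = FALSE,
                       plasmid_copy_numbers = 3,
                       coverage_noise_cv = 0.1,
                       base_depth = 20,
                       n_contigs = 10,
                       identity_mixture = list(
                         means = c(68, 97),
                         sds = c(6, 1.5),
                         weights = c(0.91, 0.09)
                       ),
                       read_length = 150,
                       error_rate = 0.005,
                       n_reads = 2000) {
  stopifnot(
    decoy_cazy_rate >= 0, decoy_cazy_rate <= 1,
    error_rate >= 0, error_rate <= 1,
    coverage_noise_cv >= 0,
    all(plasmid_copy_numbers >= 1),
    abs(sum(identity_mixture$weights) - 1) < 1e-8
  )
  assert_scalar_number(seed, "seed", min = 0, max = 2^31 - 1)
  structure(
    list(
      seed = as.integer(seed), n_genomes = n_genomes,
      genes_per_contig = genes_per_contig, window = window,
      planted_pul_specs = planted_pul_specs,
      decoy_cazy_rate = decoy_cazy_rate,
      decoy_near_truth = decoy_near_truth,
      plasmid_copy_numbers = plasmid_copy_numbers,
      coverage_noise_cv = coverage_noise_cv, base_depth = base_depth,
      n_contigs = n_contigs, identity_mixture = identity_mixture,
      read_length = read_length, error_rate = error_rate, n_reads = n_reads
    ),
    class = "rumag_sim_config"
  )
}

# Run a generator on its own RNG stream without disturbing the caller's.
with_sim_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Pfam-looking labels for spacer genes; disjoint from the sus sets.
spacer_pfam_pool <- function() {
  sprintf("PF%05d", c(21, 35, 46, 77, 102, 356, 501, 702, 1042, 2086))
}

decoy_cazy_pool <- function() {
  c("GH2", "GH3", "GH5", "GH13", "GH26", "GH31", "GH51", "GH94",
    "GT2", "GT4", "PL1", "CE1", "CBM48")
}

#' Simulate an annotated genome with planted PUL
#'
#' Builds a gene grid with known truth: each configured locus layout is
#' planted on its own contig, flanked by at least `2 * window` spacer genes
#' to either side so the locus caller's window can never reach a contig
#' end or another locus. Spacer genes carry random non-CAZy Pfam labels;
#' with probability `decoy_cazy_rate` a spacer becomes a decoy CAZy gene,
#' but never within `window` genes of a planted boundary (unless
#' configured), so planted truth stays exactly recoverable.
#'
#' @param config A [sim_config()].
#' @param genome_id Genome identifier (default `"sim_genome"`).
#' @param seed Override of `config$seed`, e.g. to vary replicates.
#' @return A list with `genes` (gene table), `domains` (domain-hit table)
#'   and `truth` (one row per planted locus: `contig_id`, `signature`,
#'   `gene_ids` list-column of member genes in order, `start`, `end`).
#' @export
simulate_annotated_genome <- function(config = sim_config(),
                                      genome_id = "sim_genome",
                                      seed = config$seed) {
  layouts <- purrr::map(config$planted_pul_specs, parse_signature)
  ok <- vapply(layouts, function(l) {
    "susC" %in% l$label && "susD" %in% l$label
  }, logical(1))
  if (!all(ok)) {
    abort("every planted layout must contain both susC and susD")
  }
  with_sim_seed(seed, {
    per_contig <- purrr::imap(layouts, function(layout, i) {
      simulate_pul_contig(layout, config, genome_id,
                          contig_id = sprintf("contig_%d", i))
    })
    list(
      genes = bind_rows(purrr::map(per_contig, "genes")),
      domains = bind_rows(purrr::map(per_contig, "domains")),
      truth = bind_rows(purrr::map(per_contig, "truth"))
    )
  })
}

simulate_pul_contig <- function(layout, config, genome_id, contig_id) {
  w <- config$window
  n_layout <- nrow(layout)
  flank <- max(2L * w, ceiling((config$genes_per_contig - n_layout) / 2))
  n <- 2L * flank + n_layout
  pul_pos <- flank + seq_len(n_layout)

  strand <- sample(c("+", "-"), n, replace = TRUE)
  strand[pul_pos] <- layout$strand
  label <- rep(NA_character_, n)
  label[pul_pos] <- layout$label

  spacer <- setdiff(seq_len(n), pul_pos)
  is_decoy <- rep(FALSE, n)
  if (config$decoy_cazy_rate > 0) {
    eligible <- spacer
    if (!config$decoy_near_truth) {
      excl <- c(min(pul_pos) - seq_len(w), max(pul_pos) + seq_len(w))
      eligible <- setdiff(eligible, excl)
    }
    is_decoy[eligible] <-
      runif(length(eligible)) < config$decoy_cazy_rate
  }

  gene_len <- 900L
  gap <- 100L
  starts <- 1L + (seq_len(n) - 1L) * (gene_len + gap)
  gene_id <- sprintf("%s_%s_g%03d", genome_id, contig_id, seq_len(n))
  genes <- tibble(
    gene_id = gene_id, protein_id = gene_id, genome_id = genome_id,
    contig_id = contig_id, start = starts, end = starts + gene_len - 1L,
    strand = strand
  )

  domains <- purrr::map(seq_len(n), function(i) {
    lab <- label[i]
    if (!is.na(lab) && lab == "susC") {
      domain_row(gene_id[i], "pfam", "PF00593", bitscore = 250)
    } else if (!is.na(lab) && lab == "susD") {
      domain_row(gene_id[i], "pfam", "PF07980", bitscore = 220)
    } else if (!is.na(lab) && lab != "unc") {
      domain_row(gene_id[i], "cazy", lab, bitscore = 150)
    } else if (is_decoy[i]) {
      domain_row(gene_id[i], "cazy", sample(decoy_cazy_pool(), 1),
                 bitscore = 120)
    } else {
      domain_row(gene_id[i], "pfam", sample(spacer_pfam_pool(), 1),
                 bitscore = 80)
    }
  }) |>
    bind_rows()

  truth <- tibble(
    contig_id = contig_id,
    signature = architecture_signature(
      tibble(label = layout$label, strand = layout$strand)
    ),
    gene_ids = list(gene_id[pul_pos]),
    start = genes$start[min(pul_pos)],
    end = genes$end[max(pul_pos)]
  )
  list(genes = genes, domains = domains, truth = truth)
}

domain_row <- function(protein_id, source, label, bitscore) {
  tibble(
    protein_id = protein_id, source = source, label = label,
    evalue = 1e-30, bitscore = bitscore, ali_length = 200L,
    hmm_coverage = 0.9, env_start = 1L, env_end = 200L
  )
}

#' Simulate per-contig coverage with planted plasmids
#'
#' Chromosomal contigs draw depth from
#' `Normal(base_depth, cv * base_depth)` truncated at zero; each planted
#' plasmid contig draws from the same family around
#' `copy_number * base_depth`.
#'
#' @param config A [sim_config()].
#' @param genome_id Genome identifier.
#' @param seed Override of `config$seed`.
#' @return A list with `coverage` (contig-coverage tibble) and
#'   `truth_plasmids` (character vector of planted plasmid contig ids).
#' @export
simulate_coverage <- function(config = sim_config(),
                              genome_id = "sim_genome",
                              seed = config$seed) {
  with_sim_seed(seed, {
    cv <- config$coverage_noise_cv
    base <- config$base_depth
    n_chr <- config$n_contigs
    copies <- config$plasmid_copy_numbers
    chr <- tibble(
      contig_id = sprintf("%s_chr_%02d", genome_id, seq_len(n_chr)),
      genome_id = genome_id,
      length = sample(50000:300000, n_chr, replace = TRUE),
      depth = pmax(rnorm(n_chr, base, cv * base), 0)
    )
    pls <- tibble(
      contig_id = sprintf("%s_plasmid_%02d", genome_id,
                          seq_along(copies)),
      genome_id = genome_id,
      length = sample(2000:10000, length(copies), replace = TRUE),
      depth = pmax(rnorm(length(copies), copies * base,
                         cv * copies * base), 0)
    )
    list(
      coverage = bind_rows(chr, pls),
      truth_plasmids = pls$contig_id
    )
  })
}

#' Simulate a small taxonomy tree
#'
#' A three-rank tree (kingdom root, genera, species leaves) sufficient for
#' the toy classifier experiments.
#'
#' @param n_genera Number of genera (default 3).
#' @param species_per_genus Species leaves per genus (default 2).
#' @return A taxonomy node tibble (`node_id`, `parent_id`, `rank`, `name`).
#' @export
simulate_taxonomy <- function(n_genera = 3, species_per_genus = 2) {
  genera <- sprintf("g%02d", seq_len(n_genera))
  species <- purrr::map(genera, function(g) {
    sprintf("%s_s%02d", g, seq_len(species_per_genus))
  })
  bind_rows(
    tibble(node_id = "root", parent_id = NA_character_,
           rank = "kingdom", name = "Bacteria"),
    tibble(node_id = genera, parent_id = "root", rank = "genus",
           name = genera),
    tibble(node_id = unlist(species),
           parent_id = rep(genera, each = species_per_genus),
           rank = "species", name = unlist(species))
  )
}

random_dna <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
        collapse = "")
}

#' Simulate reference genomes for a taxonomy's species leaves
#'
#' @param taxonomy Taxonomy tibble (see [simulate_taxonomy()]).
#' @param seq_length Length of each reference sequence (default 5000).
#' @param seed RNG seed.
#' @return A reference tibble (`ref_id`, `taxon_id`, `sequence`), one row
#'   per species-rank node.
#' @export
simulate_references <- function(taxonomy, seq_length = 5000, seed = 1L) {
  leaves <- filter(taxonomy, .data$rank == "species")
  with_sim_seed(seed, {
    tibble(
      ref_id = leaves$node_id,
      taxon_id = leaves$node_id,
      sequence = vapply(seq_len(nrow(leaves)),
                        function(i) random_dna(seq_length), character(1))
    )
  })
}

#' Simulate community reads with per-read truth
#'
#' Reads are drawn from the references in proportion to `abundances`, with
#' uniform start positions and independent per-base substitution errors at
#' the configured rate.
#'
#' @param references Reference tibble (`ref_id`, `sequence`).
#' @param abundances Numeric vector (one per reference, summing to 1).
#' @param config A [sim_config()] supplying `read_length`, `error_rate`
#'   and `n_reads`.
#' @param seed Override of `config$seed`.
#' @return A tibble with `read_id`, `sequence`, `ref_id` (truth source)
#'   and `start`.
#' @export
simulate_community_reads <- function(references, abundances,
                                     config = sim_config(),
                                     seed = config$seed) {
  assert_cols(references, c("ref_id", "sequence"), "references")
  if (length(abundances) != nrow(references)) {
    abort("`abundances` must have one entry per reference")
  }
  if (abs(sum(abundances) - 1) > 1e-8) {
    abort("`abundances` must sum to 1")
  }
  len <- config$read_length
  if (any(nchar(references$sequence) < len)) {
    abort(sprintf("every reference must be at least read_length = %d bp",
                  len))
  }
  with_sim_seed(seed, {
    n <- config$n_reads
    src <- sample(seq_len(nrow(references)), n, replace = TRUE,
                  prob = abundances)
    starts <- vapply(src, function(i) {
      sample.int(nchar(references$sequence[i]) - len + 1L, 1L)
    }, integer(1))
    seqs <- substring(references$sequence[src], starts, starts + len - 1L)
    if (config$error_rate > 0) {
      seqs <- vapply(seqs, mutate_read, character(1),
                     error_rate = config$error_rate, USE.NAMES = FALSE)
    }
    tibble(
      read_id = sprintf("read_%05d", seq_len(n)),
      sequence = seqs,
      ref_id = references$ref_id[src],
      start = starts
    )
  })
}

mutate_read <- function(seq, error_rate) {
  n <- nchar(seq)
  k <- stats::rbinom(1, n, error_rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate best-hit identity tables
#'
#' Each protein draws its true best identity from the configured mixture
#' (by default a 91%/9% mixture of a "novel" component around 68% and a
#' "known" component around 97%); two synthetic databases then observe
#' that identity minus small independent deficits, so the maximum across
#' databases approximates the drawn value.
#'
#' @param protein_ids Character vector of proteins.
#' @param config A [sim_config()].
#' @param seed Override of `config$seed`.
#' @return A tibble shaped like [best_identities()] output: `protein_id`,
#'   per-database identity columns (`db1`, `db2`) and `max_identity`.
#' @export
simulate_best_identities <- function(protein_ids, config = sim_config(),
                                     seed = config$seed) {
  mix <- config$identity_mixture
  with_sim_seed(seed, {
    n <- length(protein_ids)
    comp <- sample(seq_along(mix$weights), n, replace = TRUE,
                   prob = mix$weights)
    ident <- pmin(pmax(rnorm(n, mix$means[comp], mix$sds[comp]), 0), 100)
    db2 <- pmax(ident - stats::rexp(n, rate = 1 / 5), 0)
    tibble(
      protein_id = protein_ids,
      db1 = ident,
      db2 = db2,
      max_identity = pmax(ident, db2)
    )
  })
}
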