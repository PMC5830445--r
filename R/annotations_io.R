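#' Read prokaryotic gene calls from a GFF3 file
#'
#' Extracts CDS features into a tidy gene table, the common currency of the
#' locus-calling and annotation functions. Coordinates stay 1-based inclusive
#' (the GFF3 convention) throughout the package; use
#' [convert_to_half_open()] at the boundary if a 0-based half-open consumer
#' needs them.
#'
#' @param path Path to a GFF3 file whose CDS features carry an identifier
#'   attribute (`ID` by default; prodigal-style outputs also use `ID`).
#' @param genome_id Genome the calls belong to. Defaults to the file name
#'   without extension.
#' @param id_attribute Attribute used as `protein_id` (default `"ID"`).
#'
#' @return A tibble with columns `gene_id`, `protein_id`, `genome_id`,
#'   `contig_id`, `start`, `end`, `strand`, sorted by
#'   (`contig_id`, `start`, `end`). Records with `start > end` are dropped
#'   with a warning; a strand other than `+`/`-` is an error.
#' @export
read_gene_calls <- function(path, genome_id = NULL,
                            id_attribute = "ID") {
  genome_id <- genome_id %||% tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(body) == 0) {
    return(empty_gene_tbl())
  }
  gff <- as_tibble(rtracklayer::readGFF(
    path,
    filter = list(type = "CDS"),
    tags = id_attribute
  ))
  if (nrow(gff) == 0) {
    return(empty_gene_tbl())
  }
  strand <- as.character(gff$strand)
  bad_strand <- !strand %in% c("+", "-")
  if (any(bad_strand)) {
    abort(sprintf(
      "unknown strand symbol %s for CDS on contig %s",
      unique(strand[bad_strand])[1], gff$seqid[which(bad_strand)[1]]
    ))
  }
  out <- tibble(
    gene_id = as.character(gff[[id_attribute]]),
    protein_id = as.character(gff[[id_attribute]]),
    genome_id = genome_id,
    contig_id = as.character(gff$seqid),
    start = as.integer(gff$start),
    end = as.integer(gff$end),
    strand = strand
  )
  malformed <- out$start > out$end
  if (any(malformed)) {
    warn(sprintf(
      "dropping %d CDS record(s) with start > end (first: %s)",
      sum(malformed), out$gene_id[which(malformed)[1]]
    ))
    out <- out[!malformed, , drop = FALSE]
  }
  arrange(out, .data$contig_id, .data$start, .data$end)
}

empty_gene_tbl <- function() {
  tibble(
    gene_id = character(), protein_id = character(), genome_id = character(),
    contig_id = character(), start = integer(), end = integer(),
    strand = character()
  )
}

#' Write gene calls back to GFF3
#'
#' Inverse of [read_gene_calls()]: emits one CDS line per gene with the
#' identifier in the `ID` attribute, so a write/read round trip returns the
#' same table.
#'
#' @param genes Gene table as returned by [read_gene_calls()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_calls <- function(genes, path) {
  assert_cols(genes, c("gene_id", "contig_id", "start", "end", "strand"),
              "genes")
  lines <- c(
    "##gff-version 3",
    sprintf(
      "%s\trumag\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
      genes$contig_id, genes$start, genes$end, genes$strand, genes$gene_id
    )
  )
  write_atomically(function(tmp) writeLines(lines, tmp), path)
}

#' Read a protein FASTA file
#'
#' @param path FASTA path.
#' @return A tibble with `protein_id` (first word of the header) and
#'   `sequence`.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  tibble(
    protein_id = sub("\\s.*$", "", names(aa)),
    sequence = as.character(aa)
  )
}

#' Read a protein domain-hit table
#'
#' Normalizes the tabular outputs of the common domain-annotation tools into
#' one hit per row. Three external dialects are supported, plus the package's
#' own normalized TSV:
#'
#' * `pfam_scan`: the 15-column whitespace table written by `pfam_scan.pl`.
#' * `hmmscan_domtbl`: `hmmscan --domtblout` (22 fixed columns plus a free
#'   description).
#' * `dbcan_tsv`: the 10-column table produced by dbCAN's hmmscan parser,
#'   or a minimal 2-column (protein, family) variant.
#' * `tsv`: a TSV with the normalized columns below, as written by
#'   [write_domain_table()].
#'
#' CAZy family labels are normalized by stripping the `.hmm` suffix
#' (`"GH67.hmm"` becomes `"GH67"`); subfamily labels such as `GH13_10` are
#' kept, with [cazy_base_family()] exposing the base family.
#'
#' @param path Path to the table.
#' @param dialect One of `"pfam_scan"`, `"hmmscan_domtbl"`, `"dbcan_tsv"`,
#'   `"tsv"`.
#' @param source Force hits to `"pfam"` or `"cazy"`. Defaults per dialect
#'   (`pfam_scan` is Pfam, `dbcan_tsv` is CAZy); for `hmmscan_domtbl` the
#'   source is inferred from the label prefix.
#' @return A tibble with columns `protein_id`, `source`, `label`, `evalue`,
#'   `bitscore`, `ali_length`, `hmm_coverage`, `env_start`, `env_end`, one
#'   row per non-comment input row, in input order.
#' @export
read_domain_table <- function(path,
                              dialect = c("pfam_scan", "hmmscan_domtbl",
                                          "dbcan_tsv", "tsv"),
                              source = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    hits <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
    assert_cols(hits, domain_hit_cols(), "domain table")
    return(as_tibble(hits)[domain_hit_cols()])
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- lines[keep]
  line_no <- seq_along(lines)[keep]
  if (length(rows) == 0) {
    return(empty_domain_tbl())
  }
  fields <- strsplit(trimws(rows), "\\s+")
  out <- switch(dialect,
    pfam_scan = parse_pfam_scan(fields, line_no),
    hmmscan_domtbl = parse_hmmscan_domtbl(fields, line_no),
    dbcan_tsv = parse_dbcan(fields, line_no)
  )
  if (!is.null(source)) {
    out$source <- match.arg(source, c("pfam", "cazy"))
  }
  out
}

domain_hit_cols <- function() {
  c("protein_id", "source", "label", "evalue", "bitscore", "ali_length",
    "hmm_coverage", "env_start", "env_end")
}

empty_domain_tbl <- function() {
  tibble(
    protein_id = character(), source = character(), label = character(),
    evalue = double(), bitscore = double(), ali_length = integer(),
    hmm_coverage = double(), env_start = integer(), env_end = integer()
  )
}

check_ncol <- function(fields, expected, line_no, dialect) {
  n <- lengths(fields)
  bad <- !n %in% expected
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "line %d: expected %s columns for the %s dialect, found %d",
      line_no[i], paste(expected, collapse = " or "), dialect, n[i]
    ))
  }
}

field_col <- function(fields, i) vapply(fields, `[[`, character(1), i)

parse_pfam_scan <- function(fields, line_no) {
  check_ncol(fields, 15, line_no, "pfam_scan")
  num <- function(i) as.numeric(field_col(fields, i))
  int <- function(i) as.integer(field_col(fields, i))
  hmm_len <- num(11)
  tibble(
    protein_id = field_col(fields, 1),
    source = "pfam",
    label = sub("\\.\\d+$", "", field_col(fields, 6)),
    evalue = num(13),
    bitscore = num(12),
    ali_length = int(3) - int(2) + 1L,
    hmm_coverage = (num(10) - num(9) + 1) / hmm_len,
    env_start = int(4),
    env_end = int(5)
  )
}

parse_hmmscan_domtbl <- function(fields, line_no) {
  n <- lengths(fields)
  if (any(n < 22)) {
    i <- which(n < 22)[1]
    abort(sprintf(
      "line %d: expected at least 22 columns for the hmmscan_domtbl dialect, found %d",
      line_no[i], n[i]
    ))
  }
  num <- function(i) as.numeric(field_col(fields, i))
  int <- function(i) as.integer(field_col(fields, i))
  label <- normalize_cazy_family(field_col(fields, 1))
  tibble(
    protein_id = field_col(fields, 4),
    source = if_else(is_cazy_family(label), "cazy", "pfam"),
    label = label,
    evalue = num(13),
    bitscore = num(14),
    ali_length = int(19) - int(18) + 1L,
    hmm_coverage = (num(17) - num(16) + 1) / num(3),
    env_start = int(20),
    env_end = int(21)
  )
}

parse_dbcan <- function(fields, line_no) {
  check_ncol(fields, c(2, 10), line_no, "dbcan_tsv")
  n <- lengths(fields)
  num <- function(i) as.numeric(field_col(fields, i))
  int <- function(i) as.integer(field_col(fields, i))
  if (all(n == 2)) {
    # Minimal pre-filtered (protein, family) table: scores are vacuous.
    return(tibble(
      protein_id = field_col(fields, 1),
      source = "cazy",
      label = normalize_cazy_family(field_col(fields, 2)),
      evalue = 0,
      bitscore = NA_real_,
      ali_length = NA_integer_,
      hmm_coverage = 1,
      env_start = NA_integer_,
      env_end = NA_integer_
    ))
  }
  check_ncol(fields, 10, line_no, "dbcan_tsv")
  tibble(
    protein_id = field_col(fields, 3),
    source = "cazy",
    label = normalize_cazy_family(field_col(fields, 1)),
    evalue = num(5),
    bitscore = NA_real_,
    ali_length = int(9) - int(8) + 1L,
    hmm_coverage = num(10),
    env_start = int(8),
    env_end = int(9)
  )
}

#' Write a normalized domain-hit table as TSV
#'
#' Round-trips through `read_domain_table(path, dialect = "tsv")`.
#'
#' @param hits Domain-hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(hits, path) {
  assert_cols(hits, domain_hit_cols(), "hits")
  write_atomically(
    function(tmp) readr::write_tsv(hits[domain_hit_cols()], tmp),
    path
  )
}

#' Normalize CAZy family labels
#'
#' Strips the `.hmm` suffix carried by dbCAN HMM names, so `"GH67.hmm"`
#' becomes `"GH67"`. Subfamily suffixes are retained.
#'
#' @param x Character vector of labels.
#' @return Normalized labels.
#' @export
normalize_cazy_family <- function(x) {
  sub("\\.hmm$", "", x)
}

#' Base CAZy family of a (possibly subfamily-level) label
#'
#' `"GH13_10"` has base family `"GH13"`; labels without a subfamily suffix
#' are returned unchanged.
#'
#' @param x Character vector of family labels.
#' @return Base family labels.
#' @export
cazy_base_family <- function(x) {
  sub("_\\d+$", "", x)
}

is_cazy_family <- function(x) {
  grepl("^(GH|GT|PL|CE|AA|CBM)\\d", x)
}

#' Column orders for BLAST tabular output
#'
#' `blast_columns_15()` is the extended 15-column order used for plasmid
#' annotation (`qseqid qlen sseqid sacc stitle slen qstart qend sstart send
#' length evalue bitscore pident staxid`); `blast_columns_12()` is the
#' standard `-outfmt 6` order.
#'
#' @return Character vector of column names.
#' @export
blast_columns_15 <- function() {
  c("qseqid", "qlen", "sseqid", "sacc", "stitle", "slen", "qstart", "qend",
    "sstart", "send", "length", "evalue", "bitscore", "pident", "staxid")
}

#' @rdname blast_columns_15
#' @export
blast_columns_12 <- function() {
  c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen", "qstart",
    "qend", "sstart", "send", "evalue", "bitscore")
}

blast_numeric_cols <- function() {
  c("qlen", "slen", "qstart", "qend", "sstart", "send", "length", "evalue",
    "bitscore", "pident", "mismatch", "gapopen")
}

#' Read BLAST tabular output (outfmt 6/7)
#'
#' Lines starting with `#` (outfmt 7 comments) are skipped and numeric
#' fields are typed. The column order is configurable because BLAST prints
#' whatever `-outfmt` requested; the plasmid-annotation workflow uses
#' [blast_columns_15()].
#'
#' @param path Path to the tabular file.
#' @param columns Ordered column names matching the file layout.
#' @return A tibble with one row per hit. If `stitle` is not among
#'   `columns` it is added as an empty string, and `qlen` defaults to `NA`,
#'   so downstream filters always find their columns.
#' @export
read_blast_tab <- function(path, columns = blast_columns_15()) {
  required <- c("qseqid", "length", "pident")
  missing <- setdiff(required, columns)
  if (length(missing) > 0) {
    abort(sprintf(
      "`columns` must include %s; missing: %s",
      paste(required, collapse = ", "), paste(missing, collapse = ", ")
    ))
  }
  hits <- readr::read_tsv(
    path,
    col_names = columns, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  hits <- as_tibble(hits)
  for (col in intersect(blast_numeric_cols(), names(hits))) {
    hits[[col]] <- as.numeric(hits[[col]])
  }
  if (!"stitle" %in% names(hits)) hits$stitle <- ""
  if (!"qlen" %in% names(hits)) hits$qlen <- NA_real_
  hits
}

#' Write BLAST-style tabular hits
#'
#' @param hits Tibble of hits.
#' @param path Output path.
#' @param columns Columns to write, in order.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path, columns = blast_columns_15()) {
  assert_cols(hits, columns, "hits")
  write_atomically(
    function(tmp) {
      readr::write_tsv(hits[columns], tmp, col_names = FALSE)
    },
    path
  )
}

#' Read per-genome bin statistics
#'
#' Expects a TSV with `genome_id`, `completeness`, `contamination` and
#' optionally `n_contigs`, `mean_coverage` and the lineage columns
#' `kingdom` ... `species` (absent ranks empty).
#'
#' @param path TSV path.
#' @return A tibble of bin statistics.
#' @export
read_bin_stats <- function(path) {
  stats <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(stats, c("genome_id", "completeness", "contamination"),
              "bin stats")
  for (rank in tax_ranks()) {
    if (!rank %in% names(stats)) stats[[rank]] <- ""
    stats[[rank]] <- dplyr::coalesce(as.character(stats[[rank]]), "")
  }
  as_tibble(stats)
}

#' Read per-contig coverage
#'
#' @param path TSV with columns `contig_id`, `genome_id`, `length`, `depth`.
#' @return A tibble of contig coverages.
#' @export
read_contig_coverage <- function(path) {
  cov <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(cov, c("contig_id", "genome_id", "length", "depth"),
              "coverage table")
  if (any(cov$depth < 0) || any(cov$length <= 0)) {
    abort("coverage table must have depth >= 0 and length > 0")
  }
  as_tibble(cov)
}

#' Read a pre-digested Hi-C contig-pair table
#'
#' @param path TSV with columns `contig_a`, `contig_b`, `n_pairs`.
#' @return A tibble of inter-contig link counts.
#' @export
read_hic_pairs <- function(path) {
  pairs <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(pairs, c("contig_a", "contig_b", "n_pairs"), "Hi-C pair table")
  as_tibble(pairs)
}

#' Convert 1-based inclusive coordinates to 0-based half-open
#'
#' The package keeps GFF3's 1-based inclusive convention internally; this
#' boundary converter emits BED-style `start0`/`end0` columns.
#'
#' @param x Tibble with `start` and `end` columns.
#' @return `x` with added `start0 = start - 1` and `end0 = end`.
#' @export
convert_to_half_open <- function(x) {
  assert_cols(x, c("start", "end"), "x")
  mutate(x, start0 = .data$start - 1L, end0 = .data$end)
}
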