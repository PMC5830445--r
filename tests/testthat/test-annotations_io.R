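gff_line <- function(contig, start, end, strand, id) {
  sprintf("%s\tprodigal\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
          contig, start, end, strand, id)
}

test_that("gene calls parse, sort and validate", {
  empty <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_equal(nrow(read_gene_calls(empty)), 0)

  unsorted <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    gff_line("c1", 5000, 5900, "+", "g3"),
    gff_line("c1", 100, 1000, "+", "g1"),
    gff_line("c1", 2000, 2900, "-", "g2")
  ), unsorted)
  genes <- read_gene_calls(unsorted, genome_id = "G")
  expect_equal(genes$gene_id, c("g1", "g2", "g3"))
  expect_equal(genes$start, c(100L, 2000L, 5000L))
  expect_equal(genes$genome_id, rep("G", 3))

  one_bp <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", gff_line("c1", 100, 100, "+", "tiny")),
             one_bp)
  expect_equal(read_gene_calls(one_bp)$end, 100L)

  malformed <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    gff_line("c1", 100, 1000, "+", "ok"),
    gff_line("c1", 900, 200, "+", "bad")
  ), malformed)
  expect_warning(kept <- read_gene_calls(malformed), "start > end")
  expect_equal(kept$gene_id, "ok")
})

test_that("unknown strand symbols are rejected", {
  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", gff_line("c1", 1, 90, "?", "g1")), bad)
  expect_error(read_gene_calls(bad), "strand")
})

test_that("gene calls round-trip through GFF3", {
  fx <- make_contig(c("susC", "susD", "GH10"), c("+", "+", "-"))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_calls(fx$genes, path)
  back <- read_gene_calls(path, genome_id = "G")
  expect_equal(back, fx$genes)
})

test_that("pfam_scan tables parse with hand-checked fields", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "# pfam_scan.pl output",
    "protA 10 109 5 120 PF00593.24 Plug Domain 3 82 90 151.2 1.2e-44 1 CL0193",
    "protB 1 60 1 70 PF07980.11 SusD_RagB Domain 1 60 60 88.0 3.1e-25 1 No_clan"
  ), path)
  hits <- read_domain_table(path, dialect = "pfam_scan")
  expect_equal(nrow(hits), 2)
  expect_equal(hits$label, c("PF00593", "PF07980"))  # versions stripped
  expect_equal(hits$source, c("pfam", "pfam"))
  expect_equal(hits$ali_length, c(100L, 60L))
  expect_equal(hits$hmm_coverage, c((82 - 3 + 1) / 90, 1))
  expect_equal(hits$env_start, c(5L, 1L))
  expect_equal(hits$bitscore, c(151.2, 88.0))
  expect_equal(hits$evalue, c(1.2e-44, 3.1e-25))
})

test_that("comment-only and malformed domain tables are handled", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# only", "# comments"), path)
  expect_equal(nrow(read_domain_table(path, dialect = "pfam_scan")), 0)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header", "protA 10 109 5"), bad)
  expect_error(read_domain_table(bad, dialect = "pfam_scan"), "line 2")
})

test_that("hmmscan domain tables normalize CAZy labels and infer source", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "#                            --- full sequence ---",
    paste("GH10.hmm - 300 protC - 450 1e-50 160.0 0.1 1 1",
          "1e-48 2.1e-45 155.0 0.1 11 290 30 320 25 330 0.95 desc here"),
    paste("PF00963.20 - 140 protD - 500 1e-20 70.0 0.0 1 2",
          "1e-18 5e-16 65.0 0.0 1 140 10 150 5 160 0.90 cohesin domain")
  ), path)
  hits <- read_domain_table(path, dialect = "hmmscan_domtbl")
  expect_equal(hits$label, c("GH10", "PF00963.20"))
  expect_equal(hits$source, c("cazy", "pfam"))
  expect_equal(hits$protein_id, c("protC", "protD"))
  expect_equal(hits$evalue, c(2.1e-45, 5e-16))
  expect_equal(hits$bitscore, c(155, 65))
  expect_equal(hits$ali_length, c(320L - 30L + 1L, 141L))
  expect_equal(hits$hmm_coverage[1], (290 - 11 + 1) / 300)
  expect_equal(hits$env_end, c(330L, 160L))
})

test_that("dbCAN tables parse in full and minimal dialects", {
  # 10-row fixture checked against an independent line-by-line parse
  set.seed(11)
  rows <- purrr::map_chr(1:10, function(i) {
    paste(sprintf("GH%d.hmm", i), 300, sprintf("prot%02d", i), 400,
          signif(10^-runif(1, 5, 40), 3), 11, 290, 30, 330,
          round(runif(1, 0.4, 1), 3), sep = "\t")
  })
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(rows, path)
  hits <- read_domain_table(path, dialect = "dbcan_tsv")
  expect_equal(nrow(hits), 10)
  fields <- strsplit(rows, "\t")
  expect_equal(hits$label, paste0("GH", 1:10))
  expect_equal(hits$protein_id, vapply(fields, `[[`, "", 3))
  expect_equal(hits$evalue, as.numeric(vapply(fields, `[[`, "", 5)))
  expect_equal(hits$hmm_coverage, as.numeric(vapply(fields, `[[`, "", 10)))
  expect_equal(hits$ali_length, rep(330L - 30L + 1L, 10))
  expect_true(all(hits$source == "cazy"))

  minimal <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protX\tGH67.hmm", "protY\tCBM48"), minimal)
  mini <- read_domain_table(minimal, dialect = "dbcan_tsv")
  expect_equal(mini$label, c("GH67", "CBM48"))
  expect_equal(mini$hmm_coverage, c(1, 1))
})

test_that("CAZy label helpers normalize and expose base families", {
  expect_equal(normalize_cazy_family("GH67.hmm"), "GH67")
  expect_equal(normalize_cazy_family("GH13_10"), "GH13_10")
  expect_equal(cazy_base_family(c("GH13_10", "GH10", "CBM48")),
               c("GH13", "GH10", "CBM48"))
})

test_that("domain tables round-trip through the native TSV", {
  fx <- make_contig(c("susC", "GH10", "unc"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_domain_table(fx$domains, path)
  expect_equal(read_domain_table(path, dialect = "tsv"), fx$domains)
})

test_that("BLAST tabular parsing covers both dialects and skips comments", {
  # reduced 12-column outfmt 6: stitle absent, filled as empty
  p12 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("q1", "s1", "98.5", "520", "6", "1", "1", "520", "101",
                   "620", "1e-100", "950", sep = "\t"), p12)
  h12 <- read_blast_tab(p12, columns = blast_columns_12())
  expect_equal(h12$stitle, "")
  expect_equal(h12$pident, 98.5)
  expect_equal(h12$length, 520)

  # 15-column extended dialect with comments (outfmt 7)
  p15 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# BLASTN 2.4.0+",
    "# Query: NODE_52225",
    paste("NODE_52225", "2785", "gi|123", "NC_1", "Ruminococcus albus plasmid pRUMAL02",
          "4100", "1", "900", "200", "1100", "900", "1e-180", "1600",
          "96.2", "1264", sep = "\t"),
    paste("NODE_99", "5000", "gi|456", "NC_2", "chromosome, complete genome",
          "2000000", "1", "400", "5", "405", "400", "1e-50", "700",
          "88.0", "1264", sep = "\t")
  ), p15)
  h15 <- read_blast_tab(p15)
  expect_equal(nrow(h15), 2)
  expect_equal(h15$stitle[1], "Ruminococcus albus plasmid pRUMAL02")
  expect_equal(h15$qlen, c(2785, 5000))
  expect_equal(h15$bitscore, c(1600, 700))

  # round trip
  out <- withr::local_tempfile(fileext = ".tsv")
  write_blast_tab(h15, out)
  expect_equal(read_blast_tab(out), h15)

  expect_error(read_blast_tab(p12, columns = c("qseqid", "sseqid")),
               "must include")
})

test_that("bin stats, coverage and Hi-C pair readers validate inputs", {
  bs <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble(
    genome_id = "RUG001", completeness = 95.2, contamination = 1.1,
    kingdom = "Bacteria", phylum = "Firmicutes"
  ), bs)
  stats <- read_bin_stats(bs)
  expect_equal(stats$species, "")  # absent ranks filled empty
  expect_equal(stats$phylum, "Firmicutes")

  cv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble(contig_id = "c1", genome_id = "G", length = -5,
                          depth = 3), cv)
  expect_error(read_contig_coverage(cv), "length > 0")

  hp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble(contig_a = "c1", contig_b = "c2", n_pairs = 4), hp)
  expect_equal(read_hic_pairs(hp)$n_pairs, 4)
})

test_that("coordinate conversion to half-open is a boundary-only shim", {
  fx <- make_contig(c("susC", "susD"))
  shifted <- convert_to_half_open(fx$genes)
  expect_equal(shifted$start0, fx$genes$start - 1L)
  expect_equal(shifted$end0, fx$genes$end)
  expect_equal(shifted$end0 - shifted$start0, fx$genes$end - fx$genes$start + 1L)
})
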