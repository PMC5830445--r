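test_that("sus roles follow the configured Pfam sets and bitscores", {
  domains <- bind_rows(
    make_hit("only_gh", "cazy", "GH10"),
    make_hit("susd_prot", "pfam", "PF12741", bitscore = 80),
    make_hit("both_d_wins", "pfam", "PF00593", bitscore = 50),
    make_hit("both_d_wins", "pfam", "PF07980", bitscore = 90),
    make_hit("both_tie", "pfam", "PF00593", bitscore = 70),
    make_hit("both_tie", "pfam", "PF14322", bitscore = 70)
  )
  roles <- assign_sus_roles(domains)
  role_of <- setNames(roles$role, roles$protein_id)
  expect_equal(unname(role_of["only_gh"]), "none")
  expect_equal(unname(role_of["susd_prot"]), "susD_like")
  expect_equal(unname(role_of["both_d_wins"]), "susD_like")
  expect_equal(unname(role_of["both_tie"]), "susC_like")  # tie -> susC
})

test_that("sus role assignment equals the set-membership oracle", {
  set.seed(201)
  cfg <- pul_config()
  pool <- c(cfg$susC_labels, cfg$susD_labels, "PF00001", "GH10", "GT2")
  domains <- purrr::map(1:20, function(i) {
    make_hit(sprintf("p%02d", i), "pfam", sample(pool, 1),
             bitscore = round(runif(1, 10, 100)))
  }) |> bind_rows()
  roles <- assign_sus_roles(domains)
  oracle <- vapply(roles$protein_id, function(p) {
    labs <- domains$label[domains$protein_id == p]
    if (any(labs %in% cfg$susC_labels)) "susC_like"
    else if (any(labs %in% cfg$susD_labels)) "susD_like"
    else "none"
  }, character(1))
  expect_equal(roles$role, unname(oracle))
})

test_that("seed pairs require strict adjacency, in either order", {
  pair <- make_contig(c("susC", "susD"))
  roles <- assign_sus_roles(pair$domains)
  expect_equal(nrow(find_seed_pairs(pair$genes, roles)), 1)

  gap <- make_contig(c("susC", "GH10", "susD"))
  expect_equal(
    nrow(find_seed_pairs(gap$genes, assign_sus_roles(gap$domains))), 0
  )

  chain <- make_contig(c("susD", "susC", "susD"))
  pairs <- find_seed_pairs(chain$genes, assign_sus_roles(chain$domains))
  expect_equal(nrow(pairs), 2)  # D-C and C-D share the middle susC
  expect_equal(pairs$susC_gene, rep(chain$genes$gene_id[2], 2))

  # strand does not matter for tandem pairing
  opp <- make_contig(c("susC", "susD"), strands = c("+", "-"))
  expect_equal(
    nrow(find_seed_pairs(opp$genes, assign_sus_roles(opp$domains))), 1
  )
})

test_that("a seed with no nearby CAZy gene stays a bare pair", {
  fx <- make_contig(c(rep("unc", 6), "susC", "susD", rep("unc", 6)))
  seed <- fx$genes$gene_id[7:8]
  pul <- extend_pul(fx$genes, fx$domains, seed)
  expect_equal(pul$n_genes, 2L)
  expect_true(pul$simple)
  expect_equal(pul$signature, "susC-susD")
})

test_that("extension spans a gap gene and rescans from the jump target", {
  # nine genes: GH43,GH10,gap,GH67,GH35,susC,susD,unc,GH10 within window
  labels <- c("GH43", "GH10", "unc", "GH67", "GH35", "susC", "susD",
              "unc", "GH10")
  fx <- make_contig(
    c(rep("unc", 10), labels, rep("unc", 10)),
    strands = c(rep("+", 10), "-", "-", rep("+", 7), rep("+", 10))
  )
  seed <- fx$genes$gene_id[c(16, 17)]
  pul <- extend_pul(fx$genes, fx$domains, seed)
  expect_equal(pul$n_genes, 9L)
  expect_equal(pul$genes[[1]]$gene_id, fx$genes$gene_id[11:19])
  expect_equal(pul$signature,
               "GH43-GH10 | unc-GH67-GH35-susC-susD-unc-GH10")
  expect_error(
    extend_pul(fx$genes, fx$domains, fx$genes$gene_id[c(16, 18)]),
    "adjacent"
  )
})

test_that("extension agrees with the fixpoint oracle on random contigs", {
  set.seed(202)
  for (i in 1:200) {
    rc <- random_seeded_contig(n_genes = 30, p_cazy = runif(1, 0.1, 0.5))
    window <- sample(1:6, 1)
    cfg <- pul_config(window = window)
    seed_ids <- rc$fx$genes$gene_id[rc$seed_left + 0:1]
    pul <- extend_pul(rc$fx$genes, rc$fx$domains, seed_ids, cfg)
    is_cazy <- !rc$labels %in% c("susC", "susD", "unc")
    bounds <- oracle_extend(is_cazy, rc$seed_left, rc$seed_left + 1, window)
    expect_equal(pul$genes[[1]]$pos, seq(bounds[1], bounds[2]))
  }
})

test_that("enlarging the window never shrinks a locus, and distant edits
           never change it", {
  set.seed(203)
  for (i in 1:25) {
    rc <- random_seeded_contig(n_genes = 40, p_cazy = 0.3)
    seed_ids <- rc$fx$genes$gene_id[rc$seed_left + 0:1]
    sizes <- vapply(1:6, function(w) {
      extend_pul(rc$fx$genes, rc$fx$domains, seed_ids,
                 pul_config(window = w))$n_genes
    }, integer(1))
    expect_true(all(diff(sizes) >= 0))

    # locality: flipping annotations > window beyond the boundary is inert
    w <- 4
    pul <- extend_pul(rc$fx$genes, rc$fx$domains, seed_ids,
                      pul_config(window = w))
    hi_pos <- max(pul$genes[[1]]$pos)
    far <- rc$fx$genes$gene_id[rc$fx$genes$gene_id %in%
                                 rc$fx$genes$gene_id[seq_len(40) > hi_pos + w]]
    if (length(far) > 0) {
      dom2 <- bind_rows(
        rc$fx$domains[!rc$fx$domains$protein_id %in% far, ],
        make_hit(far, "cazy", "GH99")
      )
      pul2 <- extend_pul(rc$fx$genes, dom2, seed_ids, pul_config(window = w))
      expect_equal(pul2$genes[[1]]$gene_id, pul$genes[[1]]$gene_id)
    }
  }
})

test_that("call_puls finds nothing without seeds and merges shared loci", {
  none <- make_contig(c("GH10", "unc", "GH43"))
  expect_equal(nrow(call_puls(none$genes, none$domains)), 0)

  # two seed pairs bridged by a CAZy gene between them: one merged locus
  shared <- make_contig(c(rep("unc", 6), "susC", "susD", "GH10", "susD",
                          "susC", rep("unc", 6)))
  puls <- call_puls(shared$genes, shared$domains)
  expect_equal(nrow(puls), 1)
  expect_gte(puls$n_seeds, 2)
  expect_equal(puls$genes[[1]]$gene_id, shared$genes$gene_id[7:11])

  # every locus satisfies its invariants
  expect_true(all(purrr::map_lgl(puls$genes, function(g) {
    all(diff(g$pos) == 1) && sum(g$label == "susC") >= 1 &&
      sum(g$label == "susD") >= 1
  })))
})

test_that("called loci equal planted truth on synthetic genomes", {
  for (s in 1:20) {
    cfg <- sim_config(seed = 300 + s, decoy_cazy_rate = 0.1)
    g <- simulate_annotated_genome(cfg, genome_id = sprintf("G%d", s))
    puls <- call_puls(g$genes, g$domains)
    expect_equal(nrow(puls), nrow(g$truth))
    called <- purrr::map(puls$genes, "gene_id")
    expect_equal(called, g$truth$gene_ids)
    expect_equal(puls$signature, g$truth$signature)
  }
})

test_that("PUL ids are deterministic and left-to-right", {
  shared <- make_contig(c(rep("unc", 6), "susC", "susD", rep("unc", 8),
                          "susD", "susC", rep("unc", 6)))
  puls <- call_puls(shared$genes, shared$domains)
  expect_equal(puls$pul_id, c("G_c1_pul1", "G_c1_pul2"))
  expect_identical(puls, call_puls(shared$genes, shared$domains))
})

test_that("per-genome summaries partition simple and multi loci", {
  bare <- make_contig(c(rep("unc", 6), "susC", "susD", rep("unc", 6)))
  puls <- call_puls(bare$genes, bare$domains)
  s <- pul_summary(puls)
  expect_equal(s$n_puls, 1L)
  expect_equal(s$n_simple, 1L)
  expect_equal(s$n_multi, 0L)

  set.seed(204)
  many <- purrr::map(1:6, function(i) {
    g <- simulate_annotated_genome(
      sim_config(seed = 400 + i), genome_id = sprintf("G%02d", i)
    )
    call_puls(g$genes, g$domains)
  }) |> bind_rows()
  s <- pul_summary(many)
  oracle <- as_tibble(many)[c("genome_id", "n_genes", "simple")] |>
    group_by(genome_id) |>
    summarise(n = n(), ns = sum(simple), .groups = "drop")
  expect_equal(s$n_puls, oracle$n)
  expect_equal(s$n_simple + s$n_multi, s$n_puls)
})

test_that("enzyme occurrence counts genes and distinct loci", {
  two_gh10 <- make_contig(c(rep("unc", 6), "GH10", "susC", "susD", "GH10",
                            rep("unc", 6)))
  puls <- call_puls(two_gh10$genes, two_gh10$domains)
  occ <- enzyme_occurrence(puls)
  expect_equal(occ$label, "GH10")
  expect_equal(occ$occurrences, 2L)
  expect_equal(occ$n_puls, 1L)

  # a fixture built so beta-glucosidase (GH3) ranks first
  stacked <- bind_rows(
    call_puls(two_gh10$genes, two_gh10$domains),
    {
      fx <- make_contig(c(rep("unc", 6), "GH3", "GH3", "susC", "susD",
                          "GH3", rep("unc", 6)), contig_id = "c2")
      call_puls(fx$genes, fx$domains)
    }
  )
  top <- enzyme_occurrence(stacked)
  expect_equal(top$label[1], "GH3")
  expect_equal(top$occurrences[1], 3L)
  expect_true(all(top$n_puls <= top$occurrences))
})

test_that("architecture signatures are strand-aware and invertible", {
  same <- make_contig(c("susC", "susD"))
  expect_equal(architecture_signature(
    tibble(label = c("susC", "susD"), strand = c("+", "+"))
  ), "susC-susD")

  xylan <- "GH43-GH10 | GH67-GH35-susC-susD-unc-GH10"
  parsed <- parse_signature(xylan)
  expect_equal(nrow(parsed), 8)
  expect_equal(parsed$strand, c("-", "-", rep("+", 6)))
  expect_equal(architecture_signature(parsed), xylan)

  # bijectivity on random label/strand sequences anchored at susC
  set.seed(205)
  for (i in 1:50) {
    n <- sample(3:10, 1)
    labels <- sample(c("GH10", "GH43", "CE1", "unc"), n, replace = TRUE)
    at <- sample(seq_len(n - 1), 1)
    labels[at] <- "susC"
    labels[at + 1] <- "susD"
    strands <- sample(c("+", "-"), n, replace = TRUE)
    strands[at + 1] <- strands[at]
    genes <- tibble(label = labels, strand = strands)
    sig <- architecture_signature(genes)
    back <- parse_signature(sig, ref_strand = strands[at])
    expect_equal(back$label, labels)
    expect_equal(back$strand, strands)
  }
})

test_that("tidy and glance expose the locus table in broom shape", {
  g <- simulate_annotated_genome(sim_config(seed = 7), genome_id = "G1")
  puls <- call_puls(g$genes, g$domains)
  long <- tidy(puls)
  expect_equal(sort(unique(long$pul_id)), sort(puls$pul_id))
  expect_equal(nrow(long), sum(puls$n_genes))
  gl <- glance(puls)
  expect_equal(gl$n_puls, nrow(puls))
  expect_s3_class(autoplot(puls), "ggplot")
})
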