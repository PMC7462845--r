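test_that("indel events: runs, intactness, shared-gap stripping", {
  # one 3-nt insertion relative to the reference
  ev <- gene_indel_events("ATG---AAA", "ATGCCCAAA")
  expect_equal(ev$count, 1L)
  expect_true(ev$intact)

  # frameshift: 1-nt deletion in the taxon row
  ev <- gene_indel_events("ATGAAA", "AT-AAA")
  expect_equal(ev$count, 1L)
  expect_false(ev$intact)

  # identical gap-free rows
  ev <- gene_indel_events("ATGAAA", "ATGAAA")
  expect_equal(ev$count, 0L)
  expect_true(ev$intact)

  # adjacent insertion + deletion are two separate maximal runs
  ev <- gene_indel_events("ATG---CCCAAA", "ATGCCC---AAA")
  expect_equal(ev$count, 2L)
  expect_true(ev$intact)

  # columns gapped in both rows are stripped before counting
  ev <- gene_indel_events("ATG---AAA", "ATG---AAA")
  expect_equal(ev$count, 0L)
  expect_equal(attr(ev, "n_shared_gap_columns"), 3L)

  # column mode counts gapped columns rather than events
  ev <- gene_indel_events("ATG------AAA", "ATGCCCCCCAAA", mode = "columns")
  expect_equal(ev$count, 6L)
})

test_that("per-taxon totals: additivity, per-taxon exclusion, reference zero", {
  aln <- codon_alignment(
    c(Ref = "ATGAAACCCTTTGGGTAC",
      X   = "ATG---CCCTTTGGGTAC",   # one event in g1, intact
      Y   = "ATG---CCCTT-GGGTAC"),  # event in g1 + frameshift in g2
    genes = data.frame(gene = c("g1", "g2"), start = c(1L, 10L),
                       end = c(9L, 18L), stringsAsFactors = FALSE))
  res <- indel_totals(aln, "Ref")
  expect_equal(res$total_indels[res$taxon == "X"], 1)
  expect_equal(res$n_genes_included[res$taxon == "X"], 2)
  # Y's frameshifted g2 is excluded for Y only
  expect_equal(res$total_indels[res$taxon == "Y"], 1)
  expect_equal(res$n_genes_excluded[res$taxon == "Y"], 1)
  expect_equal(attr(res, "excluded")$Y, "g2")

  # reference against itself would be all zero: check via identical taxon row
  aln2 <- codon_alignment(c(Ref = "ATGAAA", Z = "ATGAAA"))
  expect_equal(indel_totals(aln2, "Ref")$total_indels, 0)
  expect_error(indel_totals(aln2, "nope"), "input error")
})

test_that("totals are invariant to gene order in the concatenation", {
  set.seed(41)
  cfg <- simulation_config(seed = 3, n_taxa = 6, coupling = 1)
  b <- make_scenario(cfg)
  res1 <- indel_totals(b$aln, "Outgroup")
  swapped <- concatenate_genes(b$aln, rev(b$aln$genes$gene))
  res2 <- indel_totals(swapped, "Outgroup")
  m <- match(res1$taxon, res2$taxon)
  expect_equal(res1$total_indels, res2$total_indels[m])
})

test_that("simulated in-frame events are recovered without bias", {
  # small tree, 120 seeded replicates: mean recovered total within 2 SE of
  # the mean planted count (scaled-down version of the 200-replicate check)
  tr <- ape::read.tree(text = "((A:0.2,B:0.2):0.1,(C:0.15,D:0.15):0.15);")
  genes <- data.frame(gene = c("g1", "g2"), group = "G",
                      n_codons = c(200L, 150L))
  base <- simulate_codon_alignment(tr, rep(1, nrow(tr$edge)), genes,
                                   c(G = 0.2), seed = 1)
  recovered <- planted <- numeric(0)
  for (s in 1:120) {
    sim <- simulate_indels(base, tr, rep(1, nrow(tr$edge)), mu_indel = 10,
                           coupling = 1, seed = s)
    # count against an added gap-free reference row
    mat <- rbind(sim$aln$mat, Ref = base$mat[1, , drop = TRUE])
    aln <- codon_alignment(mat, base$genes)
    res <- indel_totals(aln, "Ref")
    recovered <- c(recovered, res$total_indels[match(tr$tip.label, res$taxon)])
    planted <- c(planted, sim$truth$n_indels[match(tr$tip.label,
                                                   sim$truth$taxon)])
  }
  # all planted runs are in-frame: recovered counts >= planted (the reference
  # row itself is an independent taxon row here, adding no gaps)
  expect_equal(recovered, planted)
  se <- stats::sd(planted) / sqrt(length(planted))
  depth <- ape::node.depth.edgelength(tr)[1:4]
  expect_lt(abs(mean(planted) - 10 * mean(depth)), 2 * se + 0.2)
})
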