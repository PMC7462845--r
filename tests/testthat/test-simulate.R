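test_that("config validation and mandatory seed", {
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(seed = 1, coupling = 2), "coupling")
  expect_error(simulation_config(seed = 1, tau = -1), "non-negative")
  cfg <- simulation_config(seed = 1)
  expect_equal(cfg$n_blocks, 42)
  expect_equal(cfg$n_taxa, 40)
})

test_that("tree simulation is reproducible with the right shape", {
  cfg <- simulation_config(seed = 5, n_taxa = 15)
  t1 <- simulate_tree(cfg)
  t2 <- simulate_tree(cfg)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(length(t1$tip.label), 16L)     # ingroup + outgroup
  expect_true("Outgroup" %in% t1$tip.label)
  expect_gt(sum(t1$edge.length), 0)
  # ingroup is ultrametric at the configured height
  ing <- ape::keep.tip(t1, paste0("t", 1:15))
  depths <- ape::node.depth.edgelength(ing)[1:15]
  expect_equal(max(depths), cfg$height, tolerance = 1e-8)
})

test_that("branch-rate multipliers: tau = 0 degenerate and centred logs", {
  tr <- simulate_tree(simulation_config(seed = 2, n_taxa = 10))
  expect_equal(simulate_branch_rates(tr, 0, seed = 2),
               rep(1, nrow(tr$edge)))
  m1 <- simulate_branch_rates(tr, 0.6, seed = 2)
  expect_identical(m1, simulate_branch_rates(tr, 0.6, seed = 2))
  set.seed(1)
  big <- stats::rlnorm(10000, 0, 0.6)
  expect_lt(abs(mean(log(big))), 2 * 0.6 / sqrt(10000))
})

test_that("alignment generator honours the codon model limits", {
  tr <- ape::read.tree(text = "((A:0.2,B:0.2):0.1,C:0.3);")
  genes <- data.frame(gene = c("gA", "gB"), group = c("zero", "free"),
                      n_codons = c(120L, 120L))
  aln <- simulate_codon_alignment(tr, rep(1, nrow(tr$edge)), genes,
                                  c(zero = 0, free = 0.5), seed = 9)
  # omega = 0 gene: zero nonsynonymous differences on every pair
  za <- concatenate_genes(aln, "gA")
  ss <- alignment_strings(za)
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    est <- ng86_pairwise(ss[[pair[1]]], ss[[pair[2]]])
    expect_equal(est$Nd, 0)
  }
  # no stop codons are ever emitted
  expect_false(any(grepl("\\*", translate_codons(alignment_strings(aln)))))
  # determinism
  aln2 <- simulate_codon_alignment(tr, rep(1, nrow(tr$edge)), genes,
                                   c(zero = 0, free = 0.5), seed = 9)
  expect_identical(alignment_strings(aln), alignment_strings(aln2))
})

test_that("rearrangement generator: identity limit, bounds, Poisson mean", {
  cfg <- simulation_config(seed = 4, n_taxa = 8)
  tr <- simulate_tree(cfg)
  mult <- simulate_branch_rates(tr, cfg$tau, seed = 4)

  # lambda = 0: every leaf keeps the identity, all taxa share one order
  r0 <- simulate_rearrangements(tr, mult, 10, lambda_inv = 0, coupling = 1,
                                seed = 4)
  expect_true(all(vapply(r0$perms, function(p) all(p$blocks == 1:10),
                         logical(1))))
  expect_equal(identical_order_groups(r0$perms)$n_shared, 9L)

  # HP distance to identity never exceeds the applied reversal count
  r1 <- simulate_rearrangements(tr, mult, 42, lambda_inv = 25, coupling = 1,
                                seed = 11)
  for (tx in names(r1$perms)) {
    expect_lte(reversal_distance_to_identity(r1$perms[[tx]])$d,
               r1$truth$n_reversals[r1$truth$taxon == tx])
  }

  # mean applied reversals on each root-to-leaf path matches the Poisson
  # intensity lambda * rate-weighted path length (120 seeded replicates,
  # scaled-down version of the 200-replicate check)
  wtree <- tr
  wtree$edge.length <- tr$edge.length * mult
  ntip <- length(tr$tip.label)
  wdepth <- ape::node.depth.edgelength(wtree)[seq_len(ntip)]
  names(wdepth) <- tr$tip.label
  totals <- sapply(1:120, function(s) {
    tru <- simulate_rearrangements(tr, mult, 42, lambda_inv = 25,
                                   coupling = 1, seed = 1000 + s)$truth
    sum(tru$n_reversals)
  })
  se <- stats::sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - 25 * sum(wdepth)), 2.5 * se)
})

test_that("indel generator emits only in-frame runs unless told otherwise", {
  cfg <- simulation_config(seed = 6, n_taxa = 6)
  tr <- simulate_tree(cfg)
  mult <- simulate_branch_rates(tr, cfg$tau, seed = 6)
  aln0 <- simulate_codon_alignment(tr, mult, cfg$genes, cfg$group_omega,
                                   seed = 6)
  sim <- simulate_indels(aln0, tr, mult, mu_indel = 0, coupling = 1, seed = 6)
  expect_equal(sum(sim$truth$n_indels), 0)
  expect_identical(alignment_strings(sim$aln), alignment_strings(aln0))

  sim2 <- simulate_indels(aln0, tr, mult, mu_indel = 120, coupling = 1,
                          seed = 6)
  runs <- apply(sim2$aln$mat, 1, function(row) {
    r <- rle(row == "-"); r$lengths[r$values]
  })
  expect_true(all(unlist(runs) %% 3 == 0))

  # frameshift injection produces excluded genes
  sim3 <- simulate_indels(aln0, tr, mult, mu_indel = 0, coupling = 1,
                          seed = 8, frameshift_rate = 2)
  mat <- rbind(sim3$aln$mat, Ref = aln0$mat[1, , drop = TRUE])
  res <- indel_totals(codon_alignment(mat, aln0$genes), "Ref")
  expect_gt(sum(res$n_genes_excluded), 0)
})

test_that("scenario bundles are reproducible byte-for-byte per seed", {
  cfg <- simulation_config(seed = 12, n_taxa = 6)
  d1 <- file.path(tempdir(), "bundle1"); d2 <- file.path(tempdir(), "bundle2")
  make_scenario(cfg, out_dir = d1)
  make_scenario(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})
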