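test_that("site counts match enumeration for hallmark codons and all codons", {
  # frozen values, computed by hand / enumeration oracle:
  # TTT: only position 3 change TTT->TTC is synonymous -> s = 1/3
  expect_equal(ng86_site_counts("TTT"),
               c(s = 1 / 3, n = 8 / 3, excluded = 0))
  # ATG (Met, single-codon family): s = 0
  expect_equal(ng86_site_counts("ATG"), c(s = 0, n = 3, excluded = 0))
  # TGG (Trp): two stop-producing changes (TAG, TGA) excluded -> s + n < 3
  expect_equal(ng86_site_counts("TGG"), c(s = 0, n = 7 / 3, excluded = 2))

  # property: agreement with the enumeration oracle over every sense codon
  tabs <- genetic_code_tables("11")
  for (cod in tabs$sense) {
    expect_equal(ng86_site_counts(cod), orc_site_counts(cod),
                 tolerance = 1e-12, label = cod)
  }
  expect_error(ng86_site_counts("TAA"), "sense")
  expect_error(ng86_site_counts("ATN"), "sense")
})

test_that("pathway-averaged differences match the enumeration oracle", {
  # frozen 2-difference case TTT -> GTA:
  #   TTT(F)->GTT(V)->GTA(V): nonsyn + syn ; TTT->TTA(L)->GTA: nonsyn + nonsyn
  #   average Sd = 0.5, Nd = 1.5
  est <- ng86_pairwise("TTT", "GTA")
  expect_equal(est$Sd, 0.5)
  expect_equal(est$Nd, 1.5)

  # frozen stop-skipping case TAT -> TGG: path via TAG (stop) is skipped,
  # only TAT(Y)->TGT(C)->TGG(W) remains: Sd = 0, Nd = 2
  est <- ng86_pairwise("TAT", "TGG")
  expect_equal(est$Sd, 0)
  expect_equal(est$Nd, 2)

  # property: random codon pairs agree with the oracle
  tabs <- genetic_code_tables("11")
  set.seed(11)
  for (k in 1:40) {
    pair <- sample(tabs$sense, 2)
    est <- ng86_pairwise(pair[1], pair[2])
    orc <- orc_pair_diffs(pair[1], pair[2])
    expect_equal(c(est$Sd, est$Nd), unname(orc), tolerance = 1e-12,
                 label = paste(pair, collapse = "-"))
  }
})

test_that("20-codon toy pair gives the hand-counted estimate", {
  # 17 identical AAA codons + AAA/AAG (syn), TTT/TTC (syn), ATG/ATA (nonsyn)
  a <- paste(c(rep("AAA", 17), "AAA", "TTT", "ATG"), collapse = "")
  b <- paste(c(rep("AAA", 17), "AAG", "TTC", "ATA"), collapse = "")
  est <- ng86_pairwise(a, b)
  expect_equal(est$Sd, 2)
  expect_equal(est$Nd, 1)
  # independent closed-form check of the JC correction
  S <- (sum(sapply(c(rep("AAA", 18), "TTT", "ATG"), orc_site_counts)["s", ]) +
        sum(sapply(c(rep("AAA", 18), "TTC", "ATA"), orc_site_counts)["s", ])) / 2
  expect_equal(est$S, S)
  expect_equal(est$dS, -0.75 * log(1 - 4 / 3 * (2 / S)))
})

test_that("degenerate and saturated inputs are flagged, not zeroed", {
  est <- ng86_pairwise("ATGAAA", "ATGAAA")
  expect_equal(est$Sd + est$Nd, 0)
  expect_equal(est$dS, 0)
  expect_true(est$omega_undefined)
  expect_true(is.na(est$omega))

  # gap/stop codons excluded from the comparison
  est <- ng86_pairwise("ATG---TGAAAA", "ATGAAATGGAAA")
  expect_equal(est$n_codons, 2L)
  expect_equal(est$n_excluded, 2L)
  expect_error(ng86_pairwise("ATG", "ATGAAA"), "length")
})

test_that("estimator is symmetric and additive over concatenation", {
  set.seed(5)
  tabs <- genetic_code_tables("11")
  mk <- function(n) paste(sample(tabs$sense, n, replace = TRUE), collapse = "")
  a1 <- mk(30); b1 <- mk(30); a2 <- mk(20); b2 <- mk(20)
  e12 <- ng86_pairwise(paste0(a1, a2), paste0(b1, b2))
  e1 <- ng86_pairwise(a1, b1); e2 <- ng86_pairwise(a2, b2)
  sym <- ng86_pairwise(paste0(b1, b2), paste0(a1, a2))
  expect_equal(e12$Sd, sym$Sd)
  expect_equal(e12$Nd, sym$Nd)
  expect_equal(e12$Sd, e1$Sd + e2$Sd)
  expect_equal(e12$Nd, e1$Nd + e2$Nd)
  expect_equal(e12$S, e1$S + e2$S)
  expect_equal(e12$N, e1$N + e2$N)
})

test_that("all-vs-all matrix agrees with per-pair calls and flags undefined", {
  aln <- strip_gapped_codon_columns(toy_gapped_alignment())
  rm_ <- pairwise_rate_matrix(aln)
  ss <- alignment_strings(aln)
  ref <- ng86_pairwise(ss[["A"]], ss[["B"]])
  expect_equal(rm_$dN["A", "B"], ref$dN)
  expect_equal(rm_$dS["A", "B"], ref$dS)
  expect_true(isSymmetric(rm_$dN))
  expect_equal(unname(diag(rm_$dS)), rep(0, 3))
})
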