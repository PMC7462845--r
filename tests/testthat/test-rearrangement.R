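test_that("signed permutation validation catches malformed orders", {
  expect_error(signed_permutation(c(2, 2, 3)), "duplicate block id 2")
  expect_error(signed_permutation(c(1, 3)), "missing block id")
  expect_error(signed_permutation(c(0, 1)), "0")
  p <- signed_permutation(c(-3, 1, 2), taxon = "T1")
  expect_equal(p$n, 3L)
})

test_that("LCB table parsing normalizes minus signs and validates rows", {
  perms <- parse_lcb_table(text = c("T1\t1 2 3", "T2\t− 3 2 − 1"))
  expect_equal(perms$T1$blocks, 1:3)
  expect_equal(perms$T2$blocks, c(-3L, 2L, -1L))
  expect_error(parse_lcb_table(text = c("T1\t2 2 3")), "duplicate block")
  expect_error(parse_lcb_table(text = c("T1\t1 2 3", "T2\t1 2")),
               "different block counts")
  expect_error(parse_lcb_table(text = "T1\t1 x 3"), "non-integer")
})

test_that("identical-order grouping counts shared taxa", {
  perms <- parse_lcb_table(text = c("A\t1 2 3", "B\t1 2 3", "C\t-3 2 1"))
  g <- identical_order_groups(perms)
  expect_equal(g$n_shared, 2L)
  expect_equal(sort(lengths(g$groups)), c(1L, 2L))
  allsame <- parse_lcb_table(text = c("A\t1 2", "B\t1 2", "C\t1 2"))
  expect_equal(identical_order_groups(allsame)$n_shared, 3L)
  distinct <- parse_lcb_table(text = c("A\t1 2", "B\t2 1", "C\t-1 2"))
  expect_equal(identical_order_groups(distinct)$n_shared, 0L)
  # reverse-complement equivalence only when asked
  rc <- parse_lcb_table(text = c("A\t1 2", "B\t-2 -1"))
  expect_equal(identical_order_groups(rc)$n_shared, 0L)
  expect_equal(identical_order_groups(rc, up_to_reflection = TRUE)$n_shared, 2L)
})

test_that("HP distance matches hallmark cases and its own decomposition", {
  expect_equal(reversal_distance_to_identity(1:5)$d, 0L)
  expect_equal(reversal_distance_to_identity(-1L)$d, 1L)
  s <- reversal_distance_to_identity(c(3, 2, 1))
  expect_equal(s$d, 3L)                 # frozen from the BFS oracle
  expect_equal(s$d, (s$n + 1) - s$c + s$h + s$f)

  set.seed(3)
  for (k in 1:25) {
    n <- sample(4:12, 1)
    p <- sample(n) * sample(c(-1, 1), n, replace = TRUE)
    st <- reversal_distance_to_identity(p)
    expect_equal(st$d, (st$n + 1) - st$c + st$h + st$f)
    expect_gte(st$d, 0L)
  }
})

test_that("HP equals the BFS oracle exhaustively for n <= 3", {
  for (n in 1:3) {
    dist <- bfs_all_distances(n)
    for (p in all_signed_perms(n)) {
      expect_identical(reversal_distance_to_identity(p)$d,
                       dist[[paste(p, collapse = ",")]],
                       label = paste(p, collapse = " "))
    }
  }
})

test_that("pairwise distance is a symmetric metric and reversal-bounded", {
  expect_equal(reversal_distance(c(2, 1), c(2, 1)), 0L)
  expect_error(reversal_distance(1:3, 1:4), "different block counts")

  set.seed(17)
  for (k in 1:15) {
    n <- sample(5:10, 1)
    a <- sample(n) * sample(c(-1, 1), n, replace = TRUE)
    b <- sample(n) * sample(c(-1, 1), n, replace = TRUE)
    cc <- sample(n) * sample(c(-1, 1), n, replace = TRUE)
    dab <- reversal_distance(a, b)
    expect_equal(dab, reversal_distance(b, a))
    expect_lte(dab, reversal_distance(a, cc) + reversal_distance(cc, b))
    expect_identical(dab == 0L, identical(a, b))
  }

  # k random reversals from identity give d <= k, with equality at k = 1
  set.seed(23)
  for (k in 1:10) {
    n <- 12
    p <- signed_permutation(1:n)
    nrev <- sample(1:6, 1)
    for (r in seq_len(nrev)) {
      ij <- sort(sample.int(n, 2, replace = TRUE))
      p <- apply_reversal(p, ij[1], ij[2])
    }
    expect_lte(reversal_distance_to_identity(p)$d, nrev)
  }
  one <- apply_reversal(signed_permutation(1:8), 3, 6)
  expect_equal(reversal_distance_to_identity(one)$d, 1L)
})

test_that("BFS oracle validates trivial cases and refuses large n", {
  expect_equal(bfs_oracle_distance(1:4, 1:4), 0L)
  expect_equal(bfs_oracle_distance(-1L, 1L), 1L)
  expect_equal(bfs_oracle_distance(c(3, 2, 1), 1:3), 3L)
  expect_error(bfs_oracle_distance(1:9, 1:9), "too large")
})

test_that("pairwise matrix is symmetric with zero diagonal", {
  perms <- parse_lcb_table(text = c("A\t1 2 3 4", "B\t1 2 3 4",
                                    "C\t-2 -1 3 4"))
  D <- pairwise_iv_matrix(perms)
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), rep(0L, 3))
  expect_equal(D["A", "B"], 0L)
  expect_equal(D["A", "C"], bfs_oracle_distance(c(-2, -1, 3, 4), 1:4))
})
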