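test_that("Brownian covariance equals hand-computed path lengths", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  V <- brownian_covariance(tr)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "C"], 0)
  expect_equal(unname(diag(V)), c(2, 2, 2))

  # two leaves joined at the root: no shared path
  V2 <- brownian_covariance(ape::read.tree(text = "(A:0.7,B:0.7);"))
  expect_equal(unname(V2), cbind(c(0.7, 0), c(0, 0.7)))

  # star tree: diagonal matrix
  V3 <- brownian_covariance(ape::read.tree(text = "(A:1,B:2,C:3);"))
  expect_equal(unname(V3), diag(c(1, 2, 3)))
  expect_error(brownian_covariance(tr, c("A", "Z")), "unknown taxa")
})

test_that("PGLS with identity covariance equals OLS; exact fits are exact", {
  set.seed(9)
  n <- 25
  x <- rnorm(n); y <- 2 * x + rnorm(n)
  X <- cbind("(Intercept)" = 1, x = x)
  fit <- pgls_fit(y, X, V = diag(n))
  ols <- stats::lm(y ~ x)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-8)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(vcov(ols)))), tolerance = 1e-8)
  expect_equal(fit$coefficients$p,
               unname(summary(ols)$coefficients[, 4]), tolerance = 1e-8)

  # y exactly linear in x: slope recovered exactly under any V
  tr <- ape::rtree(10)
  xs <- stats::setNames(rnorm(10), tr$tip.label)
  ys <- 3 + 2 * xs
  Xs <- cbind("(Intercept)" = 1, x = xs)
  rownames(Xs) <- tr$tip.label
  f2 <- pgls_fit(ys, Xs, tree = tr)
  expect_equal(f2$coefficients$estimate, c(3, 2), tolerance = 1e-10)
  expect_lt(f2$sigma2, 1e-16)

  expect_error(pgls_fit(y, cbind(1, x, x), V = diag(n)), "rank-deficient")
})

test_that("PGLS agrees with the nlme/ape reference implementation", {
  skip_if_not_installed("nlme")
  set.seed(12)
  tr <- ape::rphylo(20, 1, 0)
  V <- brownian_covariance(tr)
  L <- chol(V)
  y <- drop(t(L) %*% rnorm(20)) + 1.5
  x <- rnorm(20)
  names(y) <- names(x) <- tr$tip.label
  X <- cbind("(Intercept)" = 1, x = x)
  rownames(X) <- tr$tip.label
  fit <- pgls_fit(y, X, tree = tr)
  df <- data.frame(y = y, x = x, taxon = tr$tip.label)
  ref <- nlme::gls(y ~ x, data = df,
                   correlation = ape::corBrownian(1, tr, form = ~taxon))
  expect_equal(fit$coefficients$estimate, unname(coef(ref)), tolerance = 1e-6)
  sm <- summary(ref)$tTable
  expect_equal(fit$coefficients$p, unname(sm[, "p-value"]), tolerance = 1e-6)
})

test_that("Brownian-motion simulations recover a planted PGLS slope", {
  set.seed(77)
  tr <- ape::rphylo(40, 1, 0)
  V <- brownian_covariance(tr)
  L <- chol(V)
  hits <- 0; reps <- 60
  for (r in seq_len(reps)) {
    x <- stats::setNames(rnorm(40), tr$tip.label)
    eps <- drop(t(L) %*% rnorm(40)) * 0.8
    y <- 1 + 2 * x + eps
    X <- cbind("(Intercept)" = 1, x = x)
    rownames(X) <- tr$tip.label
    fit <- pgls_fit(y, X, tree = tr)
    co <- fit$coefficients[2, ]
    ci <- co$estimate + c(-1, 1) * stats::qt(0.975, fit$df.residual) * co$se
    if (ci[1] <= 2 && 2 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("Pearson test matches closed forms and holds its size", {
  expect_equal(pearson_test(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_test(c(1, 2, 3), c(6, 4, 2))$r, -1)
  r <- pearson_test(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$p, 2 * stats::pt(abs(r$r * sqrt(2 / (1 - r$r^2))), 2,
                                  lower.tail = FALSE))
  expect_true(pearson_test(c(1, 1, 1), c(1, 2, 3))$undefined)

  set.seed(99)
  rej <- mean(replicate(1000, pearson_test(rnorm(39), rnorm(39))$p < 0.05))
  expect_gte(rej, 0.036)
  expect_lte(rej, 0.064)
})

test_that("Bonferroni is capped, order-preserving and never decreases", {
  expect_equal(bonferroni(0.01, m = 40), 0.4)
  expect_equal(bonferroni(0.9, m = 2), 1)
  set.seed(4)
  ps <- runif(25)
  adj <- bonferroni(ps, m = 40)
  expect_true(all(adj >= ps))
  expect_true(all(adj <= 1))
  expect_false(is.unsorted(adj[order(ps)]))   # weak order preserved
  expect_equal(adj, stats::p.adjust(ps, "bonferroni", n = 40))
  expect_error(bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bonferroni(runif(10), m = 5), "family size")
})

test_that("focal-taxon correlations: exact coupling and skip logic", {
  set.seed(8)
  n <- 10
  taxa <- paste0("t", 1:n)
  iv <- matrix(sample(0:12, n * n, replace = TRUE), n,
               dimnames = list(taxa, taxa))
  iv[lower.tri(iv)] <- t(iv)[lower.tri(iv)]
  diag(iv) <- 0
  res <- focal_taxon_correlations(iv, iv)        # rate == iv exactly
  expect_equal(nrow(res), n)
  expect_true(all(abs(res$r - 1) < 1e-12))
  expect_true(all(res$significant))
  expect_equal(res$p_adj, pmin(1, res$p * n))

  # a focal row with < 3 defined pairs is skipped and logged
  rates <- iv
  rates["t1", ] <- NA; rates[, "t1"] <- NA
  res2 <- focal_taxon_correlations(rates, iv)
  expect_equal(attr(res2, "skipped"), "t1")
  expect_equal(nrow(res2), n - 1)
})

test_that("feature-rate table reports both methods and flags degeneracy", {
  set.seed(15)
  tr <- ape::rphylo(12, 1, 0)
  taxa <- tr$tip.label
  rates <- data.frame(taxon = taxa, dN = rnorm(12, 0.05, 0.01))
  features <- data.frame(taxon = taxa,
                         mirror = rates$dN,          # identical to the rate
                         flat = rep(5, 12),          # constant: undefined
                         noise = rnorm(12))
  res <- feature_rate_table(rates, features, tr)
  mir <- res[res$feature == "mirror", ]
  expect_equal(mir$pearson_r, 1, tolerance = 1e-10)
  expect_lt(mir$pearson_p_adj, 0.05)
  expect_equal(mir$pgls_slope, 1, tolerance = 1e-8)
  expect_true(is.na(res[res$feature == "flat", "pearson_r"]))

  # independently permuted feature: mostly non-significant
  set.seed(31)
  sig <- replicate(60, {
    features$perm <- sample(features$mirror)
    rr <- feature_rate_table(rates, features, tr, feature_cols = "perm")
    rr$pearson_p < 0.05
  })
  expect_gte(mean(!sig), 0.9)
})
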