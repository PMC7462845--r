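# The correlation stage: Pearson tests with Bonferroni correction for the
# per-focal-taxon rate-vs-inversion-distance analyses, and phylogenetic
# generalized least squares (Brownian covariance) for rate-vs-feature
# regressions on the pruned tree.

#' Brownian-motion covariance matrix from a tree
#'
#' `V[i, j]` is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip path lengths.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param taxa Ordered tip labels to keep (default: all tips, tree order).
#' @return Covariance matrix over `taxa`.
#' @export
brownian_covariance <- function(tree, taxa = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (is.null(taxa)) taxa <- tree$tip.label
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "), " (input error)")
  tree <- ape::keep.tip(tree, taxa)
  V <- ape::vcv.phylo(tree)
  V[taxa, taxa]
}

#' Phylogenetic generalized least squares
#'
#' Solves `beta = (X' V^-1 X)^-1 X' V^-1 y` with `V` the Brownian covariance
#' of the tree (or any supplied positive-definite matrix); with `V = I` this
#' is ordinary least squares. `sigma2` is the residual quadratic form over
#' `n - k`; coefficient p-values come from t with `n - k` df.
#'
#' @param y Named response vector (names = taxa) or unnamed vector matching
#'   the design rows.
#' @param X Design matrix including an intercept column, or a one-sided
#'   formula-like data.frame of predictors (an intercept is prepended).
#' @param tree Rooted `phylo` tree (used when `V` is `NULL`).
#' @param V Optional covariance matrix overriding the tree.
#' @return Object of class `pgls_fit`: `coefficients` (data.frame with
#'   estimate, se, t, p), `sigma2`, `logLik`, `df.residual`, `n`, `dropped`
#'   (taxa removed for missing values), `jittered` (TRUE if the covariance
#'   needed a diagonal jitter).
#' @export
pgls_fit <- function(y, X, tree = NULL, V = NULL) {
  if (is.data.frame(X)) X <- cbind("(Intercept)" = 1, as.matrix(X))
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))
  taxa <- names(y)
  if (is.null(taxa)) {
    if (nrow(X) != length(y)) stop("y and X sizes differ")
    taxa <- rownames(X)
  }
  keep <- stats::complete.cases(cbind(y, X))
  dropped <- if (!is.null(taxa)) taxa[!keep] else which(!keep)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y); k <- ncol(X)
  if (n <= k) stop("too few complete observations for the design")
  if (is.null(V)) {
    if (is.null(tree)) {
      V <- diag(n)
    } else {
      if (is.null(taxa)) stop("y must be named by taxon when a tree is used")
      V <- brownian_covariance(tree, taxa[keep])
    }
  } else {
    if (!is.null(taxa) && !is.null(dimnames(V)))
      V <- V[taxa[keep], taxa[keep]]
  }
  if (qr(X)$rank < k) {
    stop("rank-deficient design; collinear columns among: ",
         paste(colnames(X), collapse = ", "))
  }
  jittered <- FALSE
  ch <- try(chol(V), silent = TRUE)
  if (inherits(ch, "try-error")) {
    V <- V + diag(1e-10 * mean(diag(V)), n)
    ch <- chol(V)
    jittered <- TRUE
  }
  # whiten: L^-1 y, L^-1 X with V = L L'
  Li_y <- backsolve(ch, y, transpose = TRUE)
  Li_X <- backsolve(ch, X, transpose = TRUE)
  fit <- stats::lm.fit(Li_X, Li_y)
  beta <- fit$coefficients
  resid <- Li_y - Li_X %*% beta
  rss <- sum(resid^2)
  sigma2 <- rss / (n - k)
  XtViX_inv <- chol2inv(chol(crossprod(Li_X)))
  se <- sqrt(sigma2 * diag(XtViX_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - k, lower.tail = FALSE)
  logdetV <- 2 * sum(log(diag(ch)))
  ll <- -0.5 * (n * log(2 * pi * rss / n) + n + logdetV)
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = unname(beta),
                              se = unname(se), t = unname(tval),
                              p = unname(pval), stringsAsFactors = FALSE),
    sigma2 = sigma2, logLik = ll, df.residual = n - k, n = n,
    dropped = dropped, jittered = jittered),
    class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (n =", x$n, ", df =", x$df.residual, ")\n")
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Pearson correlation test
#'
#' Two-sided test of `r` via `t = r * sqrt((n - 2) / (1 - r^2))` with
#' `n - 2` df (as implemented by [stats::cor.test()]).
#'
#' @param x,y Numeric vectors; pairs with missing values are dropped.
#' @param label Optional label carried into the result.
#' @return Object of class `correlation_result`: `label`, `n`, `r`, `p`,
#'   `undefined` (TRUE if either variable has zero variance or `n < 3`).
#' @export
pearson_test <- function(x, y, label = NULL) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(label = label, n = n, r = NA_real_, p = NA_real_,
                          undefined = TRUE), class = "correlation_result"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(label = label, n = n, r = unname(ct$estimate),
                 p = ct$p.value, undefined = FALSE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (x$undefined) cat("Pearson: undefined (n =", x$n, ")\n")
  else cat(sprintf("Pearson%s: r = %.4f, n = %d, p = %.4g\n",
                   if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
                   x$r, x$n, x$p))
  invisible(x)
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)`; `m` may exceed the number of p-values supplied.
#'
#' @param ps Numeric vector of p-values in `[0, 1]`.
#' @param m Family size (default `length(ps)`).
#' @return Adjusted p-values, order-preserving.
#' @export
bonferroni <- function(ps, m = length(ps)) {
  if (any(ps < 0 | ps > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m < length(ps)) stop("family size m smaller than number of p-values")
  pmin(1, ps * m)
}

#' Per-focal-taxon correlations of pairwise rates with inversion distance
#'
#' For each focal taxon i, runs a Pearson test of `rate(i, j)` against
#' `iv(i, j)` over all j != i, then Bonferroni-adjusts within the family of
#' focal taxa (one family per rate type, family size = number of taxa by
#' default). Significance calls use the raw p-value against `alpha`, with
#' adjusted values reported alongside.
#'
#' @param rate_matrix Symmetric all-vs-all pairwise rate matrix (dN, dS or
#'   omega), `NA` where undefined.
#' @param iv_matrix Symmetric inversion-distance matrix over the same taxa.
#' @param alpha Significance level (default 0.05).
#' @param m Bonferroni family size (default: number of focal taxa).
#' @param min_pairs Focal rows with fewer defined pairs are skipped (logged
#'   in the `skipped` attribute); default 3.
#' @return `data.frame` with columns `focal`, `n`, `r`, `p`, `p_adj`,
#'   `significant` (raw p < alpha), `significant_adj`.
#' @export
focal_taxon_correlations <- function(rate_matrix, iv_matrix, alpha = 0.05,
                                     m = NULL, min_pairs = 3) {
  taxa <- rownames(rate_matrix)
  if (!identical(taxa, rownames(iv_matrix)))
    iv_matrix <- iv_matrix[taxa, taxa]
  if (is.null(m)) m <- length(taxa)
  rows <- list(); skipped <- character(0)
  for (tx in taxa) {
    others <- setdiff(taxa, tx)
    x <- rate_matrix[tx, others]
    y <- iv_matrix[tx, others]
    keep <- stats::complete.cases(x, y)
    if (sum(keep) < min_pairs) {
      skipped <- c(skipped, tx)
      next
    }
    ct <- pearson_test(x[keep], y[keep], label = tx)
    rows[[tx]] <- data.frame(focal = tx, n = ct$n, r = ct$r, p = ct$p,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_adj <- bonferroni(res$p, m = m)
  res$significant <- !is.na(res$p) & res$p < alpha
  res$significant_adj <- !is.na(res$p_adj) & res$p_adj < alpha
  attr(res, "skipped") <- skipped
  attr(res, "alpha") <- alpha
  attr(res, "family_size") <- m
  res
}

#' Rate-vs-feature report (Pearson and PGLS)
#'
#' One row per (rate type, feature) pair: the Pearson correlation and the
#' PGLS slope of `rate ~ feature` under Brownian covariance on the supplied
#' tree (outgroup already pruned by the caller). Both methods are reported
#' because both are in routine use for such regressions.
#'
#' @param rates `data.frame` with column `taxon` plus one column per rate
#'   type (e.g. `dN`, `dS`, `omega`).
#' @param features `data.frame` with column `taxon` plus one column per
#'   feature (e.g. plastome size, indels, IR/LSC/SSC lengths).
#' @param tree Rooted `phylo` tree over the taxa (for the PGLS covariance).
#' @param rate_cols,feature_cols Columns to test (defaults: all non-taxon).
#' @param alpha Significance level.
#' @param m Bonferroni family size (default: number of tests per rate type,
#'   i.e. `length(feature_cols)`).
#' @return `data.frame` with columns `rate`, `feature`, `n`, `pearson_r`,
#'   `pearson_p`, `pearson_p_adj`, `pgls_slope`, `pgls_se`, `pgls_p`,
#'   `significant` (raw Pearson p < alpha).
#' @export
feature_rate_table <- function(rates, features, tree,
                               rate_cols = NULL, feature_cols = NULL,
                               alpha = 0.05, m = NULL) {
  if (is.null(rate_cols)) rate_cols <- setdiff(names(rates), "taxon")
  if (is.null(feature_cols)) feature_cols <- setdiff(names(features), "taxon")
  if (is.null(m)) m <- length(feature_cols)
  common <- intersect(rates$taxon, features$taxon)
  common <- intersect(common, tree$tip.label)
  rows <- list()
  for (rc in rate_cols) {
    y_all <- stats::setNames(rates[[rc]][match(common, rates$taxon)], common)
    for (fc in feature_cols) {
      x_all <- stats::setNames(features[[fc]][match(common, features$taxon)],
                               common)
      ct <- pearson_test(x_all, y_all, label = paste(rc, fc, sep = "~"))
      pg <- tryCatch({
        X <- cbind("(Intercept)" = 1, feature = x_all)
        rownames(X) <- common
        fit <- pgls_fit(y_all, X, tree = tree)
        fit$coefficients[fit$coefficients$term == "feature", ]
      }, error = function(e) data.frame(estimate = NA_real_, se = NA_real_,
                                        p = NA_real_))
      rows[[length(rows) + 1L]] <- data.frame(
        rate = rc, feature = fc, n = ct$n,
        pearson_r = ct$r, pearson_p = ct$p,
        pgls_slope = pg$estimate, pgls_se = pg$se, pgls_p = pg$p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$pearson_p_adj <- NA_real_
  for (rc in rate_cols) {
    sel <- res$rate == rc
    res$pearson_p_adj[sel] <- bonferroni(res$pearson_p[sel], m = m)
  }
  res$significant <- !is.na(res$pearson_p) & res$pearson_p < alpha
  res
}
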