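# Goldman-Yang (1994) single-ratio codon model ("model 0"): rate matrix,
# transition probabilities via eigendecomposition of the symmetrized
# reversible generator, Felsenstein pruning over compressed site patterns,
# and bounded quasi-Newton maximum-likelihood fitting of (kappa, omega,
# tree_scale) with branch-length proportions fixed to the input tree.

#' GY94 codon rate matrix
#'
#' Builds the single-ratio codon substitution model: instantaneous rates are
#' nonzero only for single-base changes, proportional to the target codon
#' frequency, multiplied by `kappa` for transitions and by `omega` for
#' nonsynonymous changes, and scaled so the mean rate at equilibrium is 1.
#'
#' @param kappa Transition/transversion rate ratio (>= 0).
#' @param omega dN/dS ratio (>= 0).
#' @param pi Equilibrium frequencies over sense codons (named or in
#'   sense-codon order); default uniform. Must be non-negative and sum to 1.
#' @param code Genetic code id (default `"11"`).
#' @return An object of class `codon_model`: list with `Q` (scaled
#'   generator), `pi`, `kappa`, `omega`, `codons`, and the cached
#'   eigendecomposition used by [codon_pmat()].
#' @export
gy94_rate_matrix <- function(kappa, omega, pi = NULL, code = "11") {
  if (kappa < 0 || omega < 0) stop("kappa and omega must be >= 0")
  tab <- genetic_code_tables(code)
  sense <- tab$sense
  ns <- length(sense)
  if (is.null(pi)) pi <- rep(1 / ns, ns)
  if (!is.null(names(pi))) pi <- pi[sense]
  if (length(pi) != ns || any(is.na(pi)) || any(pi < 0) ||
      abs(sum(pi) - 1) > 1e-8)
    stop("pi must be a distribution over the ", ns, " sense codons")
  pi <- as.numeric(pi)
  names(pi) <- sense

  key <- paste0("gy94_struct_", code)
  if (is.null(.plastorate_cache[[key]])) {
    # structural template: for each ordered sense pair differing at one
    # position, whether the change is a transition and whether synonymous
    aa <- tab$aa
    pairs <- list()
    for (i in seq_len(ns)) {
      ci <- strsplit(sense[i], "")[[1]]
      for (nb in .codon_neighbours(sense[i])) {
        j <- match(nb$codon, sense)
        if (is.na(j)) next    # change to stop: rate 0
        pairs[[length(pairs) + 1L]] <-
          c(i, j, as.integer(nb$transition),
            as.integer(aa[sense[i]] == aa[nb$codon]))
      }
    }
    .plastorate_cache[[key]] <- do.call(rbind, pairs)
  }
  st <- .plastorate_cache[[key]]
  Q <- matrix(0, ns, ns, dimnames = list(sense, sense))
  rate <- pi[st[, 2]]
  rate <- rate * ifelse(st[, 3] == 1, kappa, 1)
  rate <- rate * ifelse(st[, 4] == 1, 1, omega)
  Q[st[, 1:2]] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale > 0) Q <- Q / scale

  # eigendecomposition of the symmetrized generator; guard zero frequencies
  pos <- pi > 0
  sp <- sqrt(ifelse(pos, pi, 1))
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(Q = Q, pi = pi, kappa = kappa, omega = omega,
                 codons = sense,
                 eig = list(values = eig$values,
                            U = eig$vectors, sp = sp)),
            class = "codon_model")
}

#' @export
print.codon_model <- function(x, ...) {
  cat(sprintf("GY94 codon model: kappa=%.4g omega=%.4g over %d sense codons\n",
              x$kappa, x$omega, length(x$codons)))
  invisible(x)
}

#' Transition probability matrix of a codon model
#'
#' @param model A [gy94_rate_matrix()].
#' @param t Branch length (expected substitutions per codon at scale 1).
#' @return The matrix `exp(Q t)`.
#' @export
codon_pmat <- function(model, t) {
  e <- model$eig
  P <- (e$U * rep(exp(e$values * t), each = nrow(e$U))) %*% t(e$U)
  P <- (1 / e$sp) * P * rep(e$sp, each = length(e$sp))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' F3x4 codon frequencies from an alignment
#'
#' Position-specific nucleotide frequencies multiplied across the three codon
#' positions, with stop-codon mass removed and the remainder renormalized
#' (CODEML's default frequency model).
#'
#' @param aln A [codon_alignment()].
#' @param code Genetic code id.
#' @return Named frequency vector over sense codons.
#' @export
f3x4_frequencies <- function(aln, code = "11") {
  tab <- genetic_code_tables(code)
  L <- ncol(aln$mat)
  posidx <- rep(1:3, length.out = L)
  freq <- matrix(0, 3, 4, dimnames = list(NULL, .BASES))
  for (p in 1:3) {
    v <- as.vector(aln$mat[, posidx == p, drop = FALSE])
    v <- v[v %in% .BASES]
    freq[p, ] <- tabulate(match(v, .BASES), 4)
  }
  if (any(rowSums(freq) == 0)) stop("empty alignment position class")
  freq <- freq / rowSums(freq)
  pi <- vapply(tab$sense, function(cod) {
    b <- strsplit(cod, "")[[1]]
    freq[1, b[1]] * freq[2, b[2]] * freq[3, b[3]]
  }, numeric(1))
  if (sum(pi) <= 0) stop("degenerate F3x4 frequencies")
  pi / sum(pi)
}

# alignment -> codon state matrix (taxa x codons) + pattern compression
.codon_state_matrix <- function(aln, code = "11") {
  states <- do.call(rbind, lapply(alignment_strings(aln), .codon_indices,
                                  code = code))
  rownames(states) <- aln$taxa
  states
}

.compress_patterns <- function(states) {
  key <- apply(states, 2, paste, collapse = "\r")
  uk <- unique(key)
  m <- match(key, uk)
  list(states = states[, match(uk, key), drop = FALSE],
       weights = as.numeric(tabulate(m, length(uk))))
}

#' Log-likelihood of an alignment under GY94 M0 on a fixed tree
#'
#' Felsenstein pruning over compressed codon site patterns with per-branch
#' transition matrices `exp(Q * t * tree_scale)`. Codon sites that are gapped
#' or ambiguous in a taxon are treated as missing data in that taxon.
#'
#' @param aln A [codon_alignment()] (gap-strip first for CODEML-like input).
#' @param tree A rooted `phylo` tree whose tips cover the alignment's taxa.
#' @param model A [gy94_rate_matrix()].
#' @param tree_scale Positive multiplier applied to all branch lengths.
#' @param code Genetic code id.
#' @return Log-likelihood (numeric scalar).
#' @export
m0_loglik <- function(aln, tree, model, tree_scale = 1, code = "11") {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  missing_taxa <- setdiff(aln$taxa, tree$tip.label)
  if (length(missing_taxa))
    stop("taxa missing from tree: ", paste(missing_taxa, collapse = ", "))
  tree <- ape::keep.tip(tree, aln$taxa)
  cp <- .compress_patterns(.codon_state_matrix(aln, code))
  .m0_loglik_patterns(cp, tree, model, tree_scale)
}

.m0_loglik_patterns <- function(cp, tree, model, tree_scale) {
  states <- cp$states
  weights <- cp$weights
  ns <- length(model$codons)
  npat <- ncol(states)
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tr$Nnode
  partial <- vector("list", nnode)           # ns x npat conditionals per node
  logscale <- vector("list", nnode)          # per-pattern log rescale factors
  tipstate <- states[tr$tip.label, , drop = FALSE]

  Pmats <- lapply(tr$edge.length, function(b)
    codon_pmat(model, b * tree_scale))

  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]
    child <- tr$edge[e, 2]
    P <- Pmats[[e]]
    if (child <= ntip) {
      st <- tipstate[child, ]
      msg <- matrix(1, ns, npat)
      obs <- !is.na(st)                      # NA state = missing data
      msg[, obs] <- P[, st[obs], drop = FALSE]
      ls <- numeric(npat)
    } else {
      msg <- P %*% partial[[child]]
      ls <- logscale[[child]]
    }
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- msg
      logscale[[parent]] <- ls
    } else {
      partial[[parent]] <- partial[[parent]] * msg
      logscale[[parent]] <- logscale[[parent]] + ls
    }
    mx <- apply(partial[[parent]], 2, max)
    mx[mx < 1e-300] <- 1e-300
    partial[[parent]] <- sweep(partial[[parent]], 2, mx, "/")
    logscale[[parent]] <- logscale[[parent]] + log(mx)
  }
  root <- tr$edge[nrow(tr$edge), 1]
  sitelik <- as.vector(model$pi %*% partial[[root]])
  sum(weights * (log(sitelik) + logscale[[root]]))
}

#' Fit the GY94 M0 model by maximum likelihood
#'
#' Maximizes the [m0_loglik()] over `kappa`, `omega` and a single tree scale,
#' keeping the input branch-length proportions fixed (a deliberate
#' simplification of CODEML model 0, which frees every branch). Optimization
#' is bounded quasi-Newton (`L-BFGS-B` on log parameters) from three
#' documented starts: (kappa, omega) = (1, 0.1), (2, 0.5), (5, 1).
#'
#' @param aln A [codon_alignment()]; gapped codon columns are stripped first.
#' @param tree Rooted `phylo` tree covering the alignment's taxa.
#' @param freq Codon frequency model: `"F3x4"` (default), `"F61"` (observed
#'   codon frequencies) or `"uniform"`.
#' @param code Genetic code id.
#' @param starts Matrix of starting values (columns kappa, omega, tree_scale).
#' @return Object of class `m0_fit`: `kappa`, `omega`, `tree_scale`, `lnL`,
#'   `pi`, `convergence` (0 = converged), `flags` (character vector, e.g.
#'   `"tree_scale_at_lower_bound"`).
#' @export
fit_m0 <- function(aln, tree, freq = c("F3x4", "F61", "uniform"),
                   code = "11", starts = NULL) {
  freq <- match.arg(freq)
  aln <- strip_gapped_codon_columns(aln)
  if (ncol(aln$mat) == 0) stop("no gap-free codon columns to fit")
  pi <- switch(freq,
               F3x4 = f3x4_frequencies(aln, code),
               F61 = .f61_frequencies(aln, code),
               uniform = NULL)
  missing_taxa <- setdiff(aln$taxa, tree$tip.label)
  if (length(missing_taxa))
    stop("taxa missing from tree: ", paste(missing_taxa, collapse = ", "))
  tree <- ape::keep.tip(tree, aln$taxa)
  cp <- .compress_patterns(.codon_state_matrix(aln, code))

  lower <- log(c(kappa = 0.01, omega = 1e-4, scale = 1e-6))
  upper <- log(c(kappa = 100, omega = 20, scale = 1e3))
  if (is.null(starts))
    starts <- cbind(kappa = c(1, 2, 5), omega = c(0.1, 0.5, 1),
                    scale = c(1, 1, 1))
  negll <- function(par) {
    m <- gy94_rate_matrix(exp(par[1]), exp(par[2]), pi, code)
    -.m0_loglik_patterns(cp, tree, m, exp(par[3]))
  }
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- try(stats::optim(log(starts[s, ]), negll, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(factr = 1e9, maxit = 200)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("M0 optimization failed from every start")
  par <- exp(best$par)
  flags <- character(0)
  if (best$convergence != 0) flags <- c(flags, "non_convergence")
  if (par[3] <= exp(lower[3]) * 1.01) flags <- c(flags, "tree_scale_at_lower_bound")
  if (par[2] >= exp(upper[2]) * 0.99) flags <- c(flags, "omega_at_upper_bound")
  structure(list(kappa = unname(par[1]), omega = unname(par[2]),
                 tree_scale = unname(par[3]), lnL = -best$value,
                 pi = pi, freq = freq, convergence = best$convergence,
                 counts = best$counts, flags = flags,
                 note = "branch-length proportions fixed to input tree; single scale optimized"),
            class = "m0_fit")
}

.f61_frequencies <- function(aln, code = "11") {
  tabs <- .ng86_tables(code)
  st <- .codon_state_matrix(aln, code)
  cnt <- tabulate(st[!is.na(st)], length(tabs$sense))
  if (sum(cnt) == 0) stop("no unambiguous codons")
  stats::setNames((cnt + 0.5) / sum(cnt + 0.5), tabs$sense)  # small pseudocount
}

#' @export
print.m0_fit <- function(x, ...) {
  cat(sprintf("M0 fit: kappa=%.3f omega=%.4f tree_scale=%.4f lnL=%.3f%s\n",
              x$kappa, x$omega, x$tree_scale, x$lnL,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}
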