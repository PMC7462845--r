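# Independent oracles and fixture builders used across the suite. These are
# deliberately written without reusing package internals: enumeration and
# direct summation, so they can disagree with the implementation.

# genetic code table for the oracles (Biostrings is the shared authority on
# the code itself; everything downstream is computed independently)
.orc_code <- function(code = "11") Biostrings::getGeneticCode(code)

.orc_bases <- c("T", "C", "A", "G")

# NG86 site fractions of a codon by direct enumeration of all 9 single-base
# changes; stop-producing changes count for neither class.
orc_site_counts <- function(codon, code = "11") {
  gc <- .orc_code(code)
  ch <- strsplit(codon, "")[[1]]
  s <- n <- excl <- 0
  for (pos in 1:3) {
    for (b in setdiff(.orc_bases, ch[pos])) {
      nb <- ch; nb[pos] <- b
      nbc <- paste(nb, collapse = "")
      if (gc[[nbc]] == "*") excl <- excl + 1
      else if (gc[[nbc]] == gc[[codon]]) s <- s + 1 / 3
      else n <- n + 1 / 3
    }
  }
  c(s = s, n = n, excluded = excl)
}

# pathway-averaged (Sd, Nd) for one codon pair by explicit path enumeration
orc_pair_diffs <- function(c1, c2, code = "11") {
  gc <- .orc_code(code)
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  dp <- which(a != b)
  if (!length(dp)) return(c(Sd = 0, Nd = 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (r in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], r)
    out
  }
  tots <- list()
  for (ord in perms(dp)) {
    cur <- a; sd <- nd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      cc <- paste(cur, collapse = ""); nc <- paste(nxt, collapse = "")
      if (gc[[nc]] == "*") { ok <- FALSE; break }
      if (gc[[cc]] == gc[[nc]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) tots[[length(tots) + 1]] <- c(sd, nd)
  }
  m <- colMeans(do.call(rbind, tots))
  c(Sd = m[1], Nd = m[2])
}

# Direct-summation codon-model log-likelihood for trees with <= 3 leaves:
# marginalize ancestral states by explicit nested sums.
orc_loglik_2taxa <- function(model, tA, tB, codA, codB) {
  PA <- codon_pmat(model, tA); PB <- codon_pmat(model, tB)
  tot <- 0
  for (s in seq_along(codA)) {
    ia <- match(codA[s], model$codons); ib <- match(codB[s], model$codons)
    tot <- tot + log(sum(model$pi * PA[, ia] * PB[, ib]))
  }
  tot
}

orc_loglik_3taxa <- function(model, tAB, tA, tB, tC, codA, codB, codC) {
  # tree ((A:tA, B:tB):tAB, C:tC);
  P0 <- codon_pmat(model, tAB)
  PA <- codon_pmat(model, tA); PB <- codon_pmat(model, tB)
  PC <- codon_pmat(model, tC)
  ns <- length(model$codons)
  tot <- 0
  for (s in seq_along(codA)) {
    ia <- match(codA[s], model$codons); ib <- match(codB[s], model$codons)
    ic <- match(codC[s], model$codons)
    lik <- 0
    for (r in 1:ns) {
      inner <- sum(P0[r, ] * (PA[, ia] * PB[, ib]))
      lik <- lik + unname(model$pi[r]) * PC[r, ic] * inner
    }
    tot <- tot + log(lik)
  }
  tot
}

# all signed permutations of 1..n
all_signed_perms <- function(n) {
  base <- as.matrix(expand.grid(rep(list(1:n), n)))
  base <- base[apply(base, 1, function(r) length(unique(r)) == n), ,
               drop = FALSE]
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  out <- vector("list", nrow(base) * nrow(signs))
  k <- 0
  for (i in seq_len(nrow(base))) {
    for (j in seq_len(nrow(signs))) {
      k <- k + 1
      out[[k]] <- as.integer(base[i, ] * signs[j, ])
    }
  }
  out
}

# distances of every signed permutation from the identity by full-space BFS
bfs_all_distances <- function(n) {
  key <- function(v) paste(v, collapse = ",")
  dist <- new.env(parent = emptyenv())
  id <- seq_len(n)
  assign(key(id), 0L, envir = dist)
  frontier <- list(id); d <- 0L
  revs <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  while (length(frontier)) {
    d <- d + 1L
    newf <- list()
    for (v in frontier) {
      for (r in seq_len(nrow(revs))) {
        i <- revs[r, 1]; j <- revs[r, 2]
        w <- v; w[i:j] <- -rev(w[i:j])
        kw <- key(w)
        if (is.null(dist[[kw]])) {
          dist[[kw]] <- d
          newf[[length(newf) + 1]] <- w
        }
      }
    }
    frontier <- newf
  }
  dist
}

# small fixture: alignment of 3 taxa, two genes, with gaps
toy_gapped_alignment <- function() {
  codon_alignment(
    c(A = "ATGAAATTT---CCC",
      B = "ATGAAGTTTGGGCCC",
      C = "ATG---TTCGGGCCA"),
    genes = data.frame(gene = c("g1", "g2"), start = c(1L, 10L),
                       end = c(9L, 15L), group = c("X", "Y"),
                       stringsAsFactors = FALSE))
}

lcb_fixture_path <- function() {
  system.file("extdata", "lcb_diatom40.tsv", package = "plastorate",
              mustWork = TRUE)
}

lnl_fixture_path <- function() {
  system.file("extdata", "codeml_m7m8_lnL.tsv", package = "plastorate",
              mustWork = TRUE)
}
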