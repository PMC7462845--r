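# Nei-Gojobori (1986) pairwise dN/dS with Jukes-Cantor correction.
#
# Site counting: for each codon position the fraction of single-base changes
# (to sense codons) that are synonymous; changes creating a stop codon count
# for neither class, so a codon one step from a stop has s + n < 3.
# Difference counting: codon pairs differing at k in {2,3} positions average
# the synonymous/nonsynonymous step classification over all k! mutational
# pathways, skipping pathways that pass through a stop codon.

#' NG86 synonymous/nonsynonymous site fractions of a codon
#'
#' @param codon A single sense codon (no gaps, no `N`).
#' @param code Genetic code id (default `"11"`).
#' @return Named numeric vector `c(s, n, excluded)` where `s + n + excluded/3
#'   = 3` and `excluded` is the number of single-base changes to stop codons.
#' @export
ng86_site_counts <- function(codon, code = "11") {
  tabs <- .ng86_tables(code)
  i <- tabs$idx[toupper(codon)]
  if (is.na(i))
    stop("'", codon, "' is not a sense codon under code ", code,
         " (domain error)")
  c(s = tabs$s_sites[i], n = tabs$n_sites[i], excluded = tabs$stop_excluded[i])
}

.jc_correct <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Pairwise dN/dS by the NG86 counting method
#'
#' Estimates synonymous (`dS`) and nonsynonymous (`dN`) substitutions per
#' site between two in-frame sequences, with Jukes-Cantor correction
#' `d = -(3/4) log(1 - (4/3) p)`. Codon sites where either sequence has a
#' gap, an ambiguous base or a stop codon are excluded and counted in
#' `n_excluded`.
#'
#' @param a,b Nucleotide strings of equal length divisible by 3.
#' @param code Genetic code id (default `"11"`).
#' @return An object of class `rate_estimate`: list with `S`, `N` (site
#'   counts, averaged over the two sequences), `Sd`, `Nd` (difference counts),
#'   `pS`, `pN`, `dS`, `dN`, `omega`, `n_codons` (compared codons),
#'   `n_excluded`, and logical flags `saturated_s`, `saturated_n`,
#'   `omega_undefined`. `omega` is `NA` (undefined, not 0) when `dS` is 0 or
#'   undefined.
#' @export
ng86_pairwise <- function(a, b, code = "11") {
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  tabs <- .ng86_tables(code)
  ia <- .codon_indices(a, code)
  ib <- .codon_indices(b, code)
  ok <- !is.na(ia) & !is.na(ib)
  n_excl <- sum(!ok)
  ia <- ia[ok]; ib <- ib[ok]
  if (length(ia) == 0) stop("no comparable codons (all gapped/ambiguous)")

  S <- (sum(tabs$s_sites[ia]) + sum(tabs$s_sites[ib])) / 2
  N <- (sum(tabs$n_sites[ia]) + sum(tabs$n_sites[ib])) / 2
  Sd <- sum(tabs$SD[cbind(ia, ib)])
  Nd <- sum(tabs$ND[cbind(ia, ib)])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- .jc_correct(pS)
  dN <- .jc_correct(pN)
  saturated_s <- is.finite(pS) && pS >= 0.75
  saturated_n <- is.finite(pN) && pN >= 0.75
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, omega = omega,
                 n_codons = length(ia), n_excluded = n_excl,
                 saturated_s = saturated_s, saturated_n = saturated_n,
                 omega_undefined = is.na(omega)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("NG86: %d codons  S=%.2f N=%.2f Sd=%.2f Nd=%.2f  dS=%s dN=%s omega=%s\n",
              x$n_codons, x$S, x$N, x$Sd, x$Nd,
              format(x$dS, digits = 4), format(x$dN, digits = 4),
              if (is.na(x$omega)) "undef" else format(x$omega, digits = 4)))
  invisible(x)
}

#' All-vs-all pairwise NG86 rate matrices
#'
#' Runs [ng86_pairwise()] on every taxon pair of an alignment. Each pair is
#' gap-stripped pairwise (only codons gap-free in *that* pair are compared),
#' matching how pairwise rate estimation is run gene by gene.
#'
#' @param aln A [codon_alignment()].
#' @param code Genetic code id.
#' @return List of symmetric matrices `dN`, `dS`, `omega` (taxa as
#'   dimnames; `NA` where undefined) plus `n_undefined_omega`.
#' @export
pairwise_rate_matrix <- function(aln, code = "11") {
  taxa <- aln$taxa
  n <- length(taxa)
  seqs <- alignment_strings(aln)
  idx <- lapply(seqs, .codon_indices, code = code)
  tabs <- .ng86_tables(code)
  dN <- dS <- om <- matrix(NA_real_, n, n, dimnames = list(taxa, taxa))
  diag(dN) <- diag(dS) <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ia <- idx[[i]]; ib <- idx[[j]]
      ok <- !is.na(ia) & !is.na(ib)
      ia2 <- ia[ok]; ib2 <- ib[ok]
      if (length(ia2) == 0) next
      S <- (sum(tabs$s_sites[ia2]) + sum(tabs$s_sites[ib2])) / 2
      N <- (sum(tabs$n_sites[ia2]) + sum(tabs$n_sites[ib2])) / 2
      pS <- sum(tabs$SD[cbind(ia2, ib2)]) / S
      pN <- sum(tabs$ND[cbind(ia2, ib2)]) / N
      dS[i, j] <- dS[j, i] <- .jc_correct(pS)
      dN[i, j] <- dN[j, i] <- .jc_correct(pN)
      if (!is.na(dS[i, j]) && dS[i, j] > 0 && !is.na(dN[i, j]))
        om[i, j] <- om[j, i] <- dN[i, j] / dS[i, j]
    }
  }
  list(dN = dN, dS = dS, omega = om,
       n_undefined_omega = sum(is.na(om[upper.tri(om)])))
}

#' Per-taxon rates relative to a reference taxon
#'
#' The outgroup-relative rate table: one [ng86_pairwise()] estimate per taxon
#' against the reference, on the requested gene set.
#'
#' @param aln A [codon_alignment()].
#' @param reference Reference (outgroup) taxon label.
#' @param genes Optional character vector of genes to concatenate first.
#' @param code Genetic code id.
#' @return `data.frame` with columns taxon, S, N, Sd, Nd, dS, dN, omega,
#'   n_codons, n_excluded, flags.
#' @export
rates_vs_reference <- function(aln, reference, genes = NULL, code = "11") {
  if (!reference %in% aln$taxa)
    stop("reference taxon '", reference, "' not in alignment")
  if (!is.null(genes)) aln <- concatenate_genes(aln, genes)
  seqs <- alignment_strings(aln)
  others <- setdiff(aln$taxa, reference)
  rows <- lapply(others, function(tx) {
    est <- ng86_pairwise(seqs[[reference]], seqs[[tx]], code = code)
    data.frame(taxon = tx, S = est$S, N = est$N, Sd = est$Sd, Nd = est$Nd,
               dS = est$dS, dN = est$dN, omega = est$omega,
               n_codons = est$n_codons, n_excluded = est$n_excluded,
               saturated = est$saturated_s || est$saturated_n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
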