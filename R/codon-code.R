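#' @keywords internal
"_PACKAGE"

# Package-local cache for per-genetic-code lookup tables (NG86 site fractions,
# pathway-averaged difference counts). Keyed by genetic-code id.
.plastorate_cache <- new.env(parent = emptyenv())

.BASES <- c("T", "C", "A", "G")

#' Genetic-code tables for codon-level analyses
#'
#' Returns the codon universe for a genetic code: all 64 codons (TCAG order,
#' as is conventional for codon models), the sense codons, the amino acid of
#' each codon, and which single-base changes are transitions.
#'
#' @param code Genetic code id as understood by [Biostrings::getGeneticCode()].
#'   The default `"11"` is the bacterial/plastid code used for plastid genes.
#' @return A list with elements `codons` (64), `aa` (named translation),
#'   `sense` (sense codons), `stops` (stop codons).
#' @export
genetic_code_tables <- function(code = "11") {
  gc <- Biostrings::getGeneticCode(code)
  codons <- apply(expand.grid(p3 = .BASES, p2 = .BASES, p1 = .BASES,
                              stringsAsFactors = FALSE)[, 3:1], 1, paste0,
                  collapse = "")
  aa <- gc[codons]
  names(aa) <- codons
  list(codons = codons,
       aa = aa,
       sense = codons[aa != "*"],
       stops = codons[aa == "*"])
}

.is_transition <- function(b1, b2) {
  (b1 %in% c("A", "G") & b2 %in% c("A", "G")) |
    (b1 %in% c("C", "T") & b2 %in% c("C", "T"))
}

# All 9 single-base neighbours of a codon, with per-position bookkeeping.
.codon_neighbours <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  out <- list()
  for (pos in 1:3) {
    for (b in setdiff(.BASES, ch[pos])) {
      nb <- ch
      nb[pos] <- b
      out[[length(out) + 1L]] <- list(codon = paste(nb, collapse = ""),
                                      pos = pos,
                                      transition = .is_transition(ch[pos], b))
    }
  }
  out
}

#' Translate codon sequences
#'
#' Translates an in-frame, gap-free nucleotide string under a chosen genetic
#' code. Codons containing `N` translate to `X`; internal stop codons are
#' reported via the `"stops"` attribute (1-based codon positions).
#'
#' @param x Character vector of nucleotide strings, each of length divisible
#'   by 3, alphabet `A,C,G,T,N`.
#' @param code Genetic code id (default `"11"`, bacterial/plastid).
#' @return Character vector of amino-acid strings with attribute `stops`
#'   (a list of integer vectors of internal stop positions).
#' @export
translate_codons <- function(x, code = "11") {
  tab <- genetic_code_tables(code)
  res <- character(length(x))
  stops <- vector("list", length(x))
  for (i in seq_along(x)) {
    s <- toupper(x[[i]])
    if (nchar(s) %% 3 != 0)
      stop("sequence length not divisible by 3 (framing error)")
    if (grepl("-", s, fixed = TRUE))
      stop("translate_codons() requires gap-free input")
    cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aa <- unname(tab$aa[cod])
    aa[is.na(aa)] <- "X"            # codons containing N (or other ambiguity)
    stops[[i]] <- which(aa == "*")
    res[i] <- paste(aa, collapse = "")
  }
  attr(res, "stops") <- stops
  res
}

# NG86 per-codon site fractions and pathway-averaged difference counts,
# computed once per genetic code and cached. Single-base changes that create
# a stop codon are excluded: they contribute to neither the synonymous nor
# the nonsynonymous site count (so s + n < 3 for codons one step from a stop),
# and mutational pathways passing through a stop are skipped.
.ng86_tables <- function(code = "11") {
  key <- paste0("ng86_", code)
  if (!is.null(.plastorate_cache[[key]])) return(.plastorate_cache[[key]])
  tab <- genetic_code_tables(code)
  sense <- tab$sense
  aa <- tab$aa
  ns <- length(sense)
  idx <- seq_len(ns)
  names(idx) <- sense

  s_sites <- n_sites <- stop_excluded <- numeric(ns)
  for (i in idx) {
    cod <- sense[i]
    for (nb in .codon_neighbours(cod)) {
      if (aa[nb$codon] == "*") {
        stop_excluded[i] <- stop_excluded[i] + 1
      } else if (aa[nb$codon] == aa[cod]) {
        s_sites[i] <- s_sites[i] + 1 / 3
      } else {
        n_sites[i] <- n_sites[i] + 1 / 3
      }
    }
  }

  # Pathway-averaged synonymous / nonsynonymous differences per codon pair.
  SD <- ND <- matrix(0, ns, ns, dimnames = list(sense, sense))
  blocked <- matrix(FALSE, ns, ns)
  step_class <- function(c1, c2) {
    # classify one single-base step; stop involvement handled by caller
    if (aa[c1] == aa[c2]) c(1, 0) else c(0, 1)
  }
  for (i in idx) {
    for (j in idx) {
      if (j <= i) next
      c1 <- strsplit(sense[i], "")[[1]]
      c2 <- strsplit(sense[j], "")[[1]]
      diffpos <- which(c1 != c2)
      k <- length(diffpos)
      if (k == 0) next
      perms <- .permutations(diffpos)
      tot <- c(0, 0)
      nvalid <- 0L
      tot_all <- c(0, 0)   # fallback: average over every pathway
      for (ord in perms) {
        cur <- c1
        contrib <- c(0, 0)
        valid <- TRUE
        for (p in ord) {
          nxt <- cur
          nxt[p] <- c2[p]
          cc <- paste(cur, collapse = "")
          nc <- paste(nxt, collapse = "")
          if (aa[nc] == "*" || aa[cc] == "*") {
            valid <- FALSE
            # count to/from stop as nonsynonymous for the fallback average
            contrib <- contrib + c(0, 1)
          } else {
            contrib <- contrib + step_class(cc, nc)
          }
          cur <- nxt
        }
        tot_all <- tot_all + contrib
        if (valid) {
          tot <- tot + contrib
          nvalid <- nvalid + 1L
        }
      }
      if (nvalid > 0) {
        avg <- tot / nvalid
      } else {
        avg <- tot_all / length(perms)
        blocked[i, j] <- blocked[j, i] <- TRUE
      }
      SD[i, j] <- SD[j, i] <- avg[1]
      ND[i, j] <- ND[j, i] <- avg[2]
    }
  }
  res <- list(sense = sense, idx = idx, s_sites = s_sites, n_sites = n_sites,
              stop_excluded = stop_excluded, SD = SD, ND = ND,
              blocked = blocked)
  .plastorate_cache[[key]] <- res
  res
}

# permutations of a small vector (k <= 3 here)
.permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Map codon strings to indices into the sense-codon list; NA for codons with
# gaps/ambiguity and for stop codons.
.codon_indices <- function(s, code = "11") {
  tabs <- .ng86_tables(code)
  n <- nchar(s)
  if (n %% 3 != 0) stop("sequence length not divisible by 3 (framing error)")
  cod <- substring(toupper(s), seq(1, n, 3), seq(3, n, 3))
  unname(tabs$idx[cod])
}
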