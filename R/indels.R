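# In-frame indel counting against a designated reference taxon.
#
# An indel event is a maximal run of '-' in either row of the pairwise
# reference/taxon view of a gene: a run in the taxon row is a deletion, a run
# in the reference row an insertion. A gene is "intact" for a taxon iff every
# gap-run length in both rows is divisible by 3 (no frameshift); only intact
# genes contribute to the per-taxon total.

.gap_runs <- function(chars) {
  r <- rle(chars == "-")
  if (!any(r$values)) return(integer(0))
  r$lengths[r$values]
}

#' Count indel events between a reference row and a taxon row
#'
#' Columns where both rows carry a gap are stripped before counting (they
#' carry no information about this pair) and reported via the
#' `n_shared_gap_columns` attribute.
#'
#' @param ref_row,taxon_row Aligned sequences (equal-length strings or
#'   character vectors of single characters).
#' @param mode `"events"` (count maximal gap runs; default) or `"columns"`
#'   (count gapped columns).
#' @return List with `count` (indel events across both rows), `intact`
#'   (logical: all runs in-frame), `runs_ref`, `runs_taxon` (run lengths).
#' @export
gene_indel_events <- function(ref_row, taxon_row,
                              mode = c("events", "columns")) {
  mode <- match.arg(mode)
  r <- if (length(ref_row) == 1) strsplit(ref_row, "")[[1]] else ref_row
  t_ <- if (length(taxon_row) == 1) strsplit(taxon_row, "")[[1]] else taxon_row
  if (length(r) != length(t_)) stop("rows differ in length")
  both <- r == "-" & t_ == "-"
  n_shared <- sum(both)
  if (n_shared) { r <- r[!both]; t_ <- t_[!both] }
  runs_ref <- .gap_runs(r)
  runs_taxon <- .gap_runs(t_)
  count <- if (mode == "events") length(runs_ref) + length(runs_taxon)
           else sum(runs_ref) + sum(runs_taxon)
  intact <- all(c(runs_ref, runs_taxon) %% 3 == 0)
  structure(list(count = count, intact = intact,
                 runs_ref = runs_ref, runs_taxon = runs_taxon),
            n_shared_gap_columns = n_shared,
            class = "indel_events")
}

#' Per-taxon in-frame indel totals against a reference
#'
#' For every non-reference taxon, sums [gene_indel_events()] counts over the
#' genes that are intact (all gap runs in-frame) for *that* taxon, producing
#' the single per-taxon value used in rate-vs-rearrangement correlations.
#'
#' @param aln A [codon_alignment()] with gene blocks.
#' @param reference_taxon Reference taxon label (e.g. the outgroup).
#' @param mode Passed to [gene_indel_events()].
#' @return `data.frame` with columns `taxon`, `total_indels`,
#'   `n_genes_included`, `n_genes_excluded`; attribute `per_gene` holds the
#'   taxon x gene count matrix (NA where a gene was excluded) and attribute
#'   `excluded` the excluded gene names per taxon.
#' @export
indel_totals <- function(aln, reference_taxon, mode = c("events", "columns")) {
  mode <- match.arg(mode)
  if (!reference_taxon %in% aln$taxa)
    stop("reference taxon '", reference_taxon, "' not in alignment (input error)")
  genes <- aln$genes
  taxa <- setdiff(aln$taxa, reference_taxon)
  counts <- matrix(NA_real_, length(taxa), nrow(genes),
                   dimnames = list(taxa, genes$gene))
  excluded <- stats::setNames(vector("list", length(taxa)), taxa)
  refmat <- aln$mat[reference_taxon, , drop = TRUE]
  for (g in seq_len(nrow(genes))) {
    span <- genes$start[g]:genes$end[g]
    refrow <- refmat[span]
    for (tx in taxa) {
      ev <- gene_indel_events(refrow, aln$mat[tx, span], mode = mode)
      if (ev$intact) {
        counts[tx, g] <- ev$count
      } else {
        excluded[[tx]] <- c(excluded[[tx]], genes$gene[g])
      }
    }
  }
  res <- data.frame(
    taxon = taxa,
    total_indels = rowSums(counts, na.rm = TRUE),
    n_genes_included = rowSums(!is.na(counts)),
    n_genes_excluded = rowSums(is.na(counts)),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "per_gene") <- counts
  attr(res, "excluded") <- excluded
  res
}
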