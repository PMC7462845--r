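# Codon alignments: construction, I/O, gap stripping, concatenation.
#
# A codon_alignment is a list with
#   taxa  : character vector of unique taxon labels
#   mat   : character matrix (taxa x alignment columns), alphabet A,C,G,T,N,-
#   genes : data.frame(gene, start, end[, group]); 1-based inclusive column
#           coordinates, codon-framed (start at a codon boundary, span %% 3 == 0),
#           non-overlapping, in increasing order.

#' Construct a codon alignment
#'
#' @param seqs Named character vector of aligned nucleotide strings (equal
#'   length, length divisible by 3) or a character matrix with row names.
#' @param genes Optional `data.frame` with columns `gene`, `start`, `end`
#'   (1-based inclusive alignment columns) and optionally `group`. If omitted,
#'   a single block spanning the alignment named `"all"` is used.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(seqs, genes = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
    mat[] <- toupper(mat)
    taxa <- rownames(mat)
  } else {
    taxa <- names(seqs)
    if (is.null(taxa)) stop("sequences must be named by taxon")
    seqs <- toupper(seqs)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1)
      stop("ragged alignment: sequences differ in length (framing error)")
    mat <- do.call(rbind, strsplit(unname(seqs), ""))
    rownames(mat) <- taxa
  }
  if (anyDuplicated(taxa)) stop("duplicate taxon label (input error)")
  L <- ncol(mat)
  if (L %% 3 != 0)
    stop("alignment length ", L, " not divisible by 3 (framing error)")
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    stop("unsupported characters in alignment: ", paste(bad, collapse = ", "),
         " (only A,C,G,T,N,- are accepted)")
  if (is.null(genes)) {
    genes <- data.frame(gene = "all", start = 1L, end = L,
                        stringsAsFactors = FALSE)
    if (L == 0) genes <- genes[0, ]
  }
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  .validate_gene_blocks(genes, L)
  structure(list(taxa = taxa, mat = mat, genes = genes),
            class = "codon_alignment")
}

.validate_gene_blocks <- function(genes, L) {
  if (!all(c("gene", "start", "end") %in% names(genes)))
    stop("gene table needs columns gene, start, end")
  if (anyDuplicated(genes$gene)) stop("duplicate gene name in gene table")
  if (nrow(genes) == 0) return(invisible(TRUE))
  if (any(genes$start < 1 | genes$end > L | genes$start > genes$end))
    stop("gene block outside alignment bounds")
  if (any((genes$start - 1) %% 3 != 0) ||
      any((genes$end - genes$start + 1) %% 3 != 0))
    stop("gene block not codon-framed (framing error)")
  o <- order(genes$start)
  if (any(genes$end[o][-nrow(genes)] >= genes$start[o][-1]))
    stop("overlapping gene blocks")
  invisible(TRUE)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$taxa), "taxa x", ncol(x$mat), "columns (",
      ncol(x$mat) / 3, "codons ),", nrow(x$genes), "gene block(s)\n")
  invisible(x)
}

#' Number of alignment columns
#' @param aln A `codon_alignment`.
#' @return Integer column count.
#' @export
alignment_length <- function(aln) ncol(aln$mat)

#' Extract aligned sequences as strings
#' @param aln A `codon_alignment`.
#' @return Named character vector of sequence strings.
#' @export
alignment_strings <- function(aln) {
  stats::setNames(apply(aln$mat, 1, paste, collapse = ""), aln$taxa)
}

#' Read a codon alignment from FASTA or relaxed PHYLIP
#'
#' @param path File path.
#' @param gene_table Optional path to a TSV with columns `gene`, `start`,
#'   `end` (1-based inclusive) and optionally `group`, or a `data.frame`.
#' @param format `"auto"` (sniff first non-blank character), `"fasta"` or
#'   `"phylip"` (sequential relaxed PHYLIP).
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path, gene_table = NULL,
                                 format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "phylip"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    seqs <- stats::setNames(as.character(ss), names(ss))
  } else {
    seqs <- .read_relaxed_phylip(path)
  }
  genes <- NULL
  if (!is.null(gene_table)) {
    genes <- if (is.data.frame(gene_table)) gene_table else
      utils::read.delim(gene_table, stringsAsFactors = FALSE)
  }
  codon_alignment(seqs, genes)
}

# Relaxed sequential PHYLIP: header "ntaxa ncols", then one record per taxon;
# label separated from sequence by whitespace, sequence may continue on
# following lines until ncols characters are read.
.read_relaxed_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- scan(text = lines[1], what = integer(), quiet = TRUE)
  if (length(hdr) != 2) stop("malformed PHYLIP header")
  ntax <- hdr[1]; ncols <- hdr[2]
  seqs <- character(0)
  i <- 2
  for (k in seq_len(ntax)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    lab <- parts[1]
    s <- paste(parts[-1], collapse = "")
    i <- i + 1
    while (nchar(s) < ncols) {
      s <- paste0(s, gsub("\\s", "", lines[i]))
      i <- i + 1
    }
    if (nchar(s) != ncols) stop("PHYLIP record for ", lab,
                                " has ", nchar(s), " columns, expected ", ncols)
    seqs[lab] <- s
  }
  seqs
}

#' Write a codon alignment
#'
#' @param aln A [codon_alignment()].
#' @param path Output file path.
#' @param format `"fasta"` or `"phylip"`.
#' @param gene_table_path Optional path to also write the gene table as TSV.
#' @return Invisibly, `path`.
#' @export
write_codon_alignment <- function(aln, path, format = c("fasta", "phylip"),
                                  gene_table_path = NULL) {
  format <- match.arg(format)
  seqs <- alignment_strings(aln)
  if (format == "fasta") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(seqs)) {
      writeLines(paste0(">", names(seqs)[i]), con)
      writeLines(seqs[[i]], con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(length(seqs), ncol(aln$mat)), con)
    writeLines(paste(names(seqs), seqs), con)
  }
  if (!is.null(gene_table_path))
    utils::write.table(aln$genes, gene_table_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove codon columns containing gaps
#'
#' Mirrors PAL2NAL's `-nogap` behaviour: a codon column (triplet of alignment
#' columns) is dropped in every taxon if any taxon carries a gap anywhere in
#' the triplet. Gene-block coordinates are remapped; genes whose columns are
#' all removed are dropped from the gene table.
#'
#' @param aln A [codon_alignment()].
#' @return A gap-free [codon_alignment()] with attribute `dropped_codons`
#'   (1-based codon positions removed). Warns if nothing survives.
#' @export
strip_gapped_codon_columns <- function(aln) {
  L <- ncol(aln$mat)
  ncod <- L / 3
  if (ncod == 0) return(aln)
  has_gap <- matrix(aln$mat == "-", nrow = nrow(aln$mat))
  codon_of_col <- rep(seq_len(ncod), each = 3)
  gap_by_codon <- vapply(seq_len(ncod), function(k) {
    any(has_gap[, codon_of_col == k])
  }, logical(1))
  keep <- which(!gap_by_codon)
  if (length(keep) == 0)
    warning("all codon columns contain a gap; empty alignment returned")
  keep_cols <- as.vector(t(outer((keep - 1) * 3, 1:3, `+`)))
  mat2 <- aln$mat[, keep_cols, drop = FALSE]

  # remap gene blocks: count surviving codons per gene
  genes <- aln$genes
  new_genes <- genes[0, ]
  cursor <- 0L
  for (g in seq_len(nrow(genes))) {
    cods <- ((genes$start[g] - 1) / 3 + 1):(genes$end[g] / 3)
    nkeep <- sum(cods %in% keep)
    if (nkeep > 0) {
      row <- genes[g, ]
      row$start <- cursor * 3L + 1L
      row$end <- (cursor + nkeep) * 3L
      new_genes <- rbind(new_genes, row)
      cursor <- cursor + nkeep
    }
  }
  out <- codon_alignment(mat2, new_genes)
  attr(out, "dropped_codons") <- which(gap_by_codon)
  out
}

#' Concatenate gene blocks into a new alignment
#'
#' @param aln A [codon_alignment()].
#' @param genes Character vector of gene names (order respected). Passing all
#'   genes of one functional group yields the group-level concatenation.
#' @return A [codon_alignment()] containing only the requested blocks.
#' @export
concatenate_genes <- function(aln, genes) {
  missing <- setdiff(genes, aln$genes$gene)
  if (length(missing))
    stop("unknown gene(s): ", paste(missing, collapse = ", "))
  cols <- integer(0)
  new_genes <- aln$genes[0, ]
  cursor <- 0L
  for (g in genes) {
    row <- aln$genes[aln$genes$gene == g, ]
    span <- row$start:row$end
    cols <- c(cols, span)
    row$start <- cursor + 1L
    row$end <- cursor + length(span)
    cursor <- cursor + length(span)
    new_genes <- rbind(new_genes, row)
  }
  codon_alignment(aln$mat[, cols, drop = FALSE], new_genes)
}

#' Read a gene-to-functional-group map
#'
#' @param path TSV with columns `gene` and `group`.
#' @return Named character vector mapping gene to group.
#' @export
read_group_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "group") %in% names(df)))
    stop("group map needs columns gene, group")
  stats::setNames(df$group, df$gene)
}

#' Genes of an alignment grouped by functional group
#'
#' Genes absent from the map are collected under `"ungrouped"`.
#'
#' @param aln A [codon_alignment()].
#' @param group_map Named character vector (gene -> group), e.g. from
#'   [read_group_map()]; if `NULL` the `group` column of the gene table is used.
#' @return Named list of character vectors of gene names per group.
#' @export
genes_by_group <- function(aln, group_map = NULL) {
  if (is.null(group_map)) {
    if (!"group" %in% names(aln$genes))
      stop("no group column in gene table and no group_map given")
    group_map <- stats::setNames(aln$genes$group, aln$genes$gene)
  }
  grp <- group_map[aln$genes$gene]
  grp[is.na(grp)] <- "ungrouped"
  split(aln$genes$gene, grp)
}
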