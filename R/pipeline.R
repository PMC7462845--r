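# Config-driven orchestration reproducing the analysis surfaces: rate tables,
# LRT table, gene-order groups and inversion-distance matrix, indel totals,
# and the correlation reports, with a run manifest for reproducibility.

#' Pipeline configuration
#'
#' Inputs may be file paths (FASTA/PHYLIP alignment, gene-table TSV, Newick
#' tree, LCB TSV, features TSV, log-likelihood TSV) or in-memory objects
#' (a [codon_alignment()], a `phylo`, a list of [signed_permutation()]s,
#' data.frames).
#'
#' @param alignment Codon alignment (path or object).
#' @param gene_table Optional gene table TSV path (when `alignment` is a
#'   path without block structure).
#' @param tree Rooted tree (path or `phylo`).
#' @param lcb LCB signed-order table (path or list of permutations).
#' @param features Per-taxon feature table (path or data.frame).
#' @param lnl_table Optional table of site-model log-likelihoods with columns
#'   `gene`, `lnL0`, `lnL1` (path or data.frame) for the LRT stage.
#' @param reference Reference/outgroup taxon label (default
#'   `"Triparma_laevis"`).
#' @param alpha Significance level.
#' @param bonferroni_m Optional Bonferroni family size for the focal tests
#'   (default: number of taxa).
#' @param fit_m0_groups If `TRUE`, fit the single-ratio codon model per
#'   functional group (slower); default `FALSE`.
#' @param out_dir Output directory (`NULL` for in-memory only).
#' @param seed Integer seed recorded in the manifest.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(alignment = NULL, gene_table = NULL, tree = NULL,
                            lcb = NULL, features = NULL, lnl_table = NULL,
                            reference = "Triparma_laevis", alpha = 0.05,
                            bonferroni_m = NULL, fit_m0_groups = FALSE,
                            out_dir = NULL, seed = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(alignment = alignment, gene_table = gene_table, tree = tree,
                 lcb = lcb, features = features, lnl_table = lnl_table,
                 reference = reference, alpha = alpha,
                 bonferroni_m = bonferroni_m, fit_m0_groups = fit_m0_groups,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

.load_input <- function(x, loader) {
  if (is.null(x) || !is.character(x)) x else loader(x)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stages (each skipped when its inputs are absent): outgroup-relative and
#' all-vs-all pairwise NG86 rates (plus optional per-group M0 fits); LRT
#' table from supplied log-likelihoods; gene-order identity groups and the
#' pairwise inversion-distance matrix; per-taxon indel totals; rate-vs-feature
#' Pearson/PGLS report on the outgroup-pruned tree and per-focal-taxon
#' rate-vs-inversion correlations. Deterministic given identical inputs.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with elements `rates_vs_ref`,
#'   `rate_matrices`, `m0_fits`, `lrt`, `order_groups`, `iv_matrix`,
#'   `indels`, `feature_report`, `focal` (list per rate type), `manifest`.
#'   Written as TSVs under `out_dir` when configured.
#' @export
run_all <- function(config) {
  aln <- .stage("load_alignment", .load_input(config$alignment, function(p)
    read_codon_alignment(p, gene_table = config$gene_table)))
  tree <- .stage("load_tree", .load_input(config$tree, ape::read.tree))
  perms <- .stage("load_lcb", .load_input(config$lcb, parse_lcb_table))
  features <- .stage("load_features", .load_input(config$features, function(p)
    utils::read.delim(p, stringsAsFactors = FALSE)))
  lnl <- .stage("load_lnl", .load_input(config$lnl_table, function(p)
    utils::read.delim(p, stringsAsFactors = FALSE)))
  warn <- character(0)
  res <- list()

  if (!is.null(aln)) {
    ref <- config$reference
    if (!ref %in% aln$taxa)
      stop("pipeline stage 'rates' failed: reference taxon '", ref,
           "' absent from alignment")
    res$rates_vs_ref <- .stage("rates_vs_ref",
                               rates_vs_reference(aln, reference = ref))
    res$rate_matrices <- .stage("rate_matrices", pairwise_rate_matrix(aln))
    res$indels <- .stage("indels", indel_totals(aln, ref))
    if (isTRUE(config$fit_m0_groups) && !is.null(tree) &&
        "group" %in% names(aln$genes)) {
      res$m0_fits <- .stage("m0_fits", {
        grp <- genes_by_group(aln)
        fits <- lapply(grp, function(gs)
          fit_m0(concatenate_genes(aln, gs), tree))
        data.frame(group = names(fits),
                   kappa = vapply(fits, `[[`, numeric(1), "kappa"),
                   omega = vapply(fits, `[[`, numeric(1), "omega"),
                   tree_scale = vapply(fits, `[[`, numeric(1), "tree_scale"),
                   lnL = vapply(fits, `[[`, numeric(1), "lnL"),
                   row.names = NULL, stringsAsFactors = FALSE)
      })
    }
  }
  if (!is.null(lnl)) res$lrt <- .stage("lrt", lrt_table(lnl))
  if (!is.null(perms)) {
    res$order_groups <- .stage("order_groups", identical_order_groups(perms))
    res$iv_matrix <- .stage("iv_matrix", pairwise_iv_matrix(perms))
  }

  if (!is.null(aln) && !is.null(tree) && !is.null(res$rates_vs_ref)) {
    # Fig 4-style: outgroup-relative rates vs features on the pruned tree
    rates_df <- res$rates_vs_ref[, c("taxon", "dN", "dS", "omega")]
    feat <- res$indels[, c("taxon", "total_indels")]
    if (!is.null(features)) {
      common <- intersect(feat$taxon, features$taxon)
      if (length(common) < nrow(feat))
        warn <- c(warn, "taxa dropped when merging feature table")
      feat <- merge(feat, features, by = "taxon")
    }
    pruned <- ape::keep.tip(tree, intersect(rates_df$taxon, tree$tip.label))
    res$feature_report <- .stage("feature_report",
      feature_rate_table(rates_df, feat, pruned, alpha = config$alpha))
  }
  if (!is.null(res$rate_matrices) && !is.null(res$iv_matrix)) {
    common <- intersect(rownames(res$rate_matrices$dN),
                        rownames(res$iv_matrix))
    common <- setdiff(common, config$reference)
    if (length(common) >= 3) {
      m <- if (is.null(config$bonferroni_m)) length(common) else
        config$bonferroni_m
      res$focal <- .stage("focal_correlations", lapply(
        stats::setNames(c("dN", "dS", "omega"), c("dN", "dS", "omega")),
        function(rt) focal_taxon_correlations(
          res$rate_matrices[[rt]][common, common],
          res$iv_matrix[common, common],
          alpha = config$alpha, m = m)))
    } else {
      warn <- c(warn, "too few shared taxa for focal correlations")
    }
  }

  res$manifest <- list(
    package_version = as.character(utils::packageVersion("plastorate")),
    seed = config$seed,
    alpha = config$alpha,
    reference = config$reference,
    config_hash = .config_hash(config),
    warnings = warn,
    timestamp_free = TRUE)   # no wall-clock in manifest: byte-stable reruns
  class(res) <- "pipeline_result"
  if (!is.null(config$out_dir)) .write_pipeline_outputs(res, config$out_dir)
  res
}

# md5 of the serialized config plus the md5 of every referenced input file
.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2)
  hashes <- unname(tools::md5sum(tmp))
  for (f in list(config$alignment, config$gene_table, config$tree, config$lcb,
                 config$features, config$lnl_table)) {
    if (is.character(f) && length(f) == 1 && file.exists(f))
      hashes <- c(hashes, unname(tools::md5sum(f)))
  }
  tmp2 <- tempfile()
  on.exit(unlink(tmp2), add = TRUE)
  writeLines(hashes, tmp2)
  unname(tools::md5sum(tmp2))
}

.write_pipeline_outputs <- function(res, out_dir) {
  sub <- function(d) {
    p <- file.path(out_dir, d)
    dir.create(p, recursive = TRUE, showWarnings = FALSE)
    p
  }
  wt <- function(df, path) utils::write.table(df, path, sep = "\t",
                                              quote = FALSE, row.names = FALSE)
  if (!is.null(res$rates_vs_ref)) {
    d <- sub("rates")
    wt(res$rates_vs_ref, file.path(d, "rates_vs_reference.tsv"))
    for (nm in c("dN", "dS", "omega"))
      utils::write.table(res$rate_matrices[[nm]],
                         file.path(d, paste0("pairwise_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, col.names = NA)
    if (!is.null(res$m0_fits)) wt(res$m0_fits, file.path(d, "m0_fits.tsv"))
  }
  if (!is.null(res$lrt)) wt(res$lrt, file.path(sub("rates"), "lrt.tsv"))
  if (!is.null(res$iv_matrix)) {
    d <- sub("rearrangement")
    write_iv_matrix(res$iv_matrix, file.path(d, "iv_matrix.tsv"))
    groups <- res$order_groups$groups
    df <- data.frame(
      group = rep(seq_along(groups), lengths(groups)),
      taxon = unlist(groups), stringsAsFactors = FALSE)
    wt(df, file.path(d, "order_groups.tsv"))
    writeLines(paste("n_shared", res$order_groups$n_shared, sep = "\t"),
               file.path(d, "order_groups_summary.tsv"))
  }
  if (!is.null(res$indels))
    wt(res$indels, file.path(sub("indels"), "indel_totals.tsv"))
  if (!is.null(res$feature_report))
    wt(res$feature_report, file.path(sub("correlations"),
                                     "feature_rate_table.tsv"))
  if (!is.null(res$focal)) {
    d <- sub("correlations")
    for (nm in names(res$focal))
      wt(res$focal[[nm]], file.path(d, paste0("focal_", nm, ".tsv")))
  }
  mf <- res$manifest
  writeLines(paste(names(mf), vapply(mf, function(x)
    paste(as.character(x), collapse = ","), character(1)), sep = "\t"),
    file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}
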