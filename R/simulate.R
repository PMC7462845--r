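# Synthetic data with the statistical structure the analysis assumes:
# an ultrametric birth-death time tree, lognormal per-branch rate multipliers
# (a relaxed clock, emulating lineage-specific acceleration), codon alignments
# evolved under group-specific GY94 omegas, inversion histories on a signed
# block permutation, and in-frame indel accumulation -- with a coupling knob
# that interpolates the rearrangement/indel Poisson intensity between
# branch-rate-proportional (coupling = 1) and multiplier-independent
# (coupling = 0).

#' Simulation configuration
#'
#' Defaults state the simulated world once: 40 ingroup taxa plus an outgroup,
#' tree height 0.25 expected substitutions per codon site root-to-tip (at
#' multiplier 1), lognormal branch-rate spread `tau = 0.6`, functional-group
#' omegas with photosynthesis genes under strong purifying selection (0.05)
#' and ribosomal/RNA-polymerase genes faster (0.3), `kappa = 2`, eight genes
#' of 150 codons, 42 blocks, 25 inversions and 120 in-frame indels per unit
#' rate-weighted branch length. See the methods vignette for the reasoning
#' behind each value.
#'
#' @param n_taxa Number of ingroup taxa.
#' @param birth,death Birth-death rates for the time tree.
#' @param height Root-to-tip tree height (expected substitutions per codon
#'   site at multiplier 1).
#' @param outgroup_frac Outgroup branch length as a fraction of `height`.
#' @param tau Lognormal (sdlog) spread of per-branch rate multipliers.
#' @param group_omega Named vector of per-functional-group omega.
#' @param kappa Transition/transversion ratio.
#' @param genes `data.frame(gene, group, n_codons)` describing the gene set.
#' @param n_blocks Number of LCBs in the signed permutation.
#' @param lambda_inv Inversions per unit rate-weighted branch length.
#' @param mu_indel In-frame indel events per unit rate-weighted branch length.
#' @param coupling In `[0, 1]`: 1 = rearrangement/indel intensity fully
#'   proportional to the branch rate multiplier, 0 = independent of it.
#' @param seed Mandatory integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 40,
                              birth = 1, death = 0,
                              height = 0.25,
                              outgroup_frac = 1,
                              tau = 0.6,
                              group_omega = c(PSA = 0.05, PSB = 0.05,
                                              PET = 0.05, ATP = 0.05,
                                              RPS = 0.3, RPL = 0.3, RPO = 0.3,
                                              RubisCo = 0.08),
                              kappa = 2,
                              genes = NULL,
                              n_blocks = 42,
                              lambda_inv = 25,
                              mu_indel = 120,
                              coupling = 1,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (coupling < 0 || coupling > 1) stop("coupling must lie in [0, 1]")
  if (tau < 0 || lambda_inv < 0 || mu_indel < 0 || height <= 0 || birth <= 0)
    stop("rates must be non-negative and height/birth positive")
  if (n_taxa < 3) stop("n_taxa must be >= 3")
  if (is.null(genes))
    genes <- data.frame(
      gene = c("psaA", "psbC", "petB", "atpA", "rps2", "rpl16", "rpoB", "rbcL"),
      group = c("PSA", "PSB", "PET", "ATP", "RPS", "RPL", "RPO", "RubisCo"),
      n_codons = 150L,
      stringsAsFactors = FALSE)
  missing_grp <- setdiff(unique(genes$group), names(group_omega))
  if (length(missing_grp))
    stop("no omega for group(s): ", paste(missing_grp, collapse = ", "))
  structure(list(n_taxa = n_taxa, birth = birth, death = death,
                 height = height, outgroup_frac = outgroup_frac, tau = tau,
                 group_omega = group_omega, kappa = kappa, genes = genes,
                 n_blocks = n_blocks, lambda_inv = lambda_inv,
                 mu_indel = mu_indel, coupling = coupling, seed = seed),
            class = "simulation_config")
}

# derive a reproducible sub-seed (< 2^31) for a named stage
.stage_seed <- function(seed, stage) {
  (seed * 1000003 + sum(utf8ToInt(stage)) * 7919) %% 2147483647
}

#' Simulate a rooted time tree with an outgroup
#'
#' Birth-death ultrametric ingroup tree rescaled to `height`, with an
#' outgroup tip (`"Outgroup"`) attached at the root on a branch of
#' `outgroup_frac * height`.
#'
#' @param config A [simulation_config()] (or arguments via `...` overriding
#'   it is not supported; edit the config).
#' @param seed Optional seed overriding `config$seed`.
#' @return Rooted `phylo` tree with tips `t1..tN` and `Outgroup`.
#' @export
simulate_tree <- function(config, seed = NULL) {
  seed <- if (is.null(seed)) config$seed else seed
  set.seed(.stage_seed(seed, "tree"))
  tr <- ape::rphylo(config$n_taxa, birth = config$birth, death = config$death)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * config$height / depth
  tr$tip.label <- paste0("t", seq_len(config$n_taxa))
  ing <- ape::write.tree(tr)
  ing <- sub(";$", "", ing)
  full <- paste0("(", ing, ":", format(0.02 * config$height, digits = 10),
                 ",Outgroup:", format(config$outgroup_frac * config$height,
                                      digits = 10), ");")
  ape::read.tree(text = full)
}

#' Simulate lognormal per-branch rate multipliers
#'
#' i.i.d. lognormal with mean log 0 and sd log `tau`; `tau = 0` gives all 1.
#'
#' @param tree A `phylo` tree.
#' @param tau Lognormal spread (sdlog, >= 0).
#' @param seed Integer seed.
#' @return Numeric vector of multipliers, one per edge of `tree`.
#' @export
simulate_branch_rates <- function(tree, tau, seed) {
  if (tau < 0) stop("tau must be >= 0")
  set.seed(.stage_seed(seed, "rates"))
  nb <- nrow(tree$edge)
  if (tau == 0) rep(1, nb) else stats::rlnorm(nb, meanlog = 0, sdlog = tau)
}

# sample child states along one branch given parent states and a P matrix
.evolve_states <- function(parent_states, P) {
  child <- integer(length(parent_states))
  for (s in unique(parent_states)) {
    idx <- which(parent_states == s)
    child[idx] <- sample.int(ncol(P), length(idx), replace = TRUE,
                             prob = P[s, ])
  }
  child
}

#' Simulate a codon alignment along a tree
#'
#' Root codons are drawn from the model's equilibrium frequencies and evolved
#' along each branch with transition matrices `exp(Q * b * multiplier)`;
#' each gene uses its functional group's omega. No stop codons are ever
#' emitted (the generator lives on sense codons).
#'
#' @param tree Rooted `phylo` tree.
#' @param multipliers Per-edge rate multipliers (e.g.
#'   [simulate_branch_rates()]).
#' @param genes `data.frame(gene, group, n_codons)`.
#' @param group_omega Named omega per group.
#' @param kappa Transition/transversion ratio.
#' @param pi Codon frequencies (default uniform over sense codons).
#' @param code Genetic code id.
#' @param seed Integer seed.
#' @return A [codon_alignment()] over the tree's tips with gene blocks and
#'   `group` column.
#' @export
simulate_codon_alignment <- function(tree, multipliers, genes, group_omega,
                                     kappa = 2, pi = NULL, code = "11",
                                     seed) {
  set.seed(.stage_seed(seed, "alignment"))
  tab <- genetic_code_tables(code)
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  # multipliers follow config/tree edge order; remap to postorder edge order
  key0 <- paste(tree$edge[, 1], tree$edge[, 2])
  keyP <- paste(tr$edge[, 1], tr$edge[, 2])
  mult <- multipliers[match(keyP, key0)]

  models <- lapply(stats::setNames(names(group_omega), names(group_omega)),
                   function(g) gy94_rate_matrix(kappa, group_omega[[g]],
                                                pi, code))
  total_codons <- sum(genes$n_codons)
  nnode <- ntip + tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]
  states <- matrix(NA_integer_, nnode, total_codons)
  gene_of_codon <- rep(seq_len(nrow(genes)), genes$n_codons)
  group_of_codon <- genes$group[gene_of_codon]

  pi_use <- models[[1]]$pi
  states[root, ] <- sample.int(length(tab$sense), total_codons,
                               replace = TRUE, prob = pi_use)
  # preorder = reversed postorder edges
  for (e in rev(seq_len(nrow(tr$edge)))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    t_branch <- tr$edge.length[e] * mult[e]
    for (g in names(models)) {
      sel <- group_of_codon == g
      if (!any(sel)) next
      P <- codon_pmat(models[[g]], t_branch)
      states[child, sel] <- .evolve_states(states[parent, sel], P)
    }
  }
  sense <- tab$sense
  seqs <- vapply(seq_len(ntip), function(i)
    paste(sense[states[i, ]], collapse = ""), character(1))
  names(seqs) <- tr$tip.label
  ends <- cumsum(genes$n_codons) * 3L
  gene_df <- data.frame(gene = genes$gene,
                        start = c(1L, utils::head(ends, -1) + 1L),
                        end = ends,
                        group = genes$group,
                        stringsAsFactors = FALSE)
  codon_alignment(seqs, gene_df)
}

# Coupling splits the Poisson intensity between a heritable layer (events on
# branches, intensity coupling * rate * b * m, inherited by descendants) and a
# lineage-independent layer (events drawn per leaf, intensity
# (1 - coupling) * rate * mean rate-weighted root-to-leaf depth). At
# coupling = 1 the process is fully branch-rate-proportional; at coupling = 0
# event counts are i.i.d. across leaves and carry no tree signal at all, so
# decoupled scenarios are a genuine null for rate-vs-rearrangement tests.
# (A naive interpolation inside the branch intensity would leave the shared
# path-length factor in both rates and rearrangements and is not a null.)
.branch_event_counts <- function(tree, multipliers, rate, coupling) {
  intensity <- coupling * rate * tree$edge.length * multipliers
  stats::rpois(length(intensity), intensity)
}

.leaf_event_counts <- function(tree, multipliers, rate, coupling) {
  ntip <- length(tree$tip.label)
  if (coupling >= 1 || rate == 0) return(integer(ntip))
  # mean rate-weighted root-to-leaf depth
  wtree <- tree
  wtree$edge.length <- tree$edge.length * multipliers
  depths <- ape::node.depth.edgelength(wtree)[seq_len(ntip)]
  stats::rpois(ntip, (1 - coupling) * rate * mean(depths))
}

#' Simulate inversion histories on a signed block permutation
#'
#' The root carries the identity order. Events come from two Poisson layers:
#' a heritable layer on branches with intensity
#' `coupling * lambda_inv * b * m` (descendants inherit), and a
#' lineage-independent layer per leaf with intensity
#' `(1 - coupling) * lambda_inv * mean(rate-weighted root-to-leaf depth)`.
#' Each event is a uniformly random reversal (uniform interval endpoints).
#' At `coupling = 1` rearrangement intensity is fully proportional to the
#' branch rate multiplier; at `coupling = 0` leaf event counts are i.i.d. and
#' carry no phylogenetic signal, a genuine null for rate-vs-distance tests.
#'
#' @param tree Rooted `phylo` tree.
#' @param multipliers Per-edge rate multipliers.
#' @param n_blocks Number of blocks (>= 2).
#' @param lambda_inv Inversions per unit rate-weighted branch length.
#' @param coupling Coupling in `[0, 1]`.
#' @param seed Integer seed.
#' @return List with `perms` (named list of [signed_permutation()] per tip)
#'   and `truth` (`data.frame(taxon, n_reversals)` = reversals applied on the
#'   root-to-tip path).
#' @export
simulate_rearrangements <- function(tree, multipliers, n_blocks = 42,
                                    lambda_inv, coupling, seed) {
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  set.seed(.stage_seed(seed, "rearrangements"))
  tr <- ape::reorder.phylo(tree, "postorder")
  key0 <- paste(tree$edge[, 1], tree$edge[, 2])
  keyP <- paste(tr$edge[, 1], tr$edge[, 2])
  mult <- multipliers[match(keyP, key0)]
  K <- .branch_event_counts(tr, mult, lambda_inv, coupling)
  Kleaf <- .leaf_event_counts(tr, mult, lambda_inv, coupling)
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]
  perm <- vector("list", nnode)
  nrev <- integer(nnode)
  perm[[root]] <- seq_len(n_blocks)
  rand_reversals <- function(p, k) {
    for (r in seq_len(k)) {
      ij <- sort(sample.int(n_blocks, 2, replace = TRUE))
      p[ij[1]:ij[2]] <- -rev(p[ij[1]:ij[2]])
    }
    p
  }
  for (e in rev(seq_len(nrow(tr$edge)))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    perm[[child]] <- rand_reversals(perm[[parent]], K[e])
    nrev[child] <- nrev[parent] + K[e]
  }
  perms <- lapply(seq_len(ntip), function(i) {
    p <- rand_reversals(perm[[i]], Kleaf[i])
    signed_permutation(p, taxon = tr$tip.label[i])
  })
  nrev[seq_len(ntip)] <- nrev[seq_len(ntip)] + Kleaf
  names(perms) <- tr$tip.label
  list(perms = perms,
       truth = data.frame(taxon = tr$tip.label,
                          n_reversals = nrev[seq_len(ntip)],
                          stringsAsFactors = FALSE))
}

#' Simulate in-frame indel events onto an alignment
#'
#' Events accumulate under the same two-layer coupled Poisson process as
#' inversions (rate `mu_indel`; see [simulate_rearrangements()] for the
#' coupling semantics); each event deletes 1, 2 or 3 codons
#' (lengths 3/6/9 nt with probability 70/20/10%) at a uniformly chosen codon
#' position inside a gene, and descendants inherit it. Events are emitted as
#' gap runs in the affected taxon's row, so every run length is divisible by
#' 3 and all genes stay intact by construction. `frameshift_rate` injects
#' additional out-of-frame (1 or 2 nt) gaps for testing exclusion logic.
#'
#' @param aln A gap-free [codon_alignment()] (e.g. from
#'   [simulate_codon_alignment()]).
#' @param tree Rooted `phylo` tree over the alignment's taxa.
#' @param multipliers Per-edge rate multipliers.
#' @param mu_indel Events per unit rate-weighted branch length.
#' @param coupling Coupling in `[0, 1]`.
#' @param seed Integer seed.
#' @param frameshift_rate Expected frameshift events per taxon (default 0).
#' @return List with `aln` (alignment with gaps applied), `truth`
#'   (`data.frame(taxon, n_indels)` = events on the root-to-tip path).
#' @export
simulate_indels <- function(aln, tree, multipliers, mu_indel, coupling, seed,
                            frameshift_rate = 0) {
  set.seed(.stage_seed(seed, "indels"))
  tr <- ape::reorder.phylo(tree, "postorder")
  key0 <- paste(tree$edge[, 1], tree$edge[, 2])
  keyP <- paste(tr$edge[, 1], tr$edge[, 2])
  mult <- multipliers[match(keyP, key0)]
  K <- .branch_event_counts(tr, mult, mu_indel, coupling)
  Kleaf <- .leaf_event_counts(tr, mult, mu_indel, coupling)
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]
  # events per node: list of (start_codon, len_codons)
  add_events <- function(ev, k) {
    for (r in seq_len(k)) {
      len <- sample(c(1L, 2L, 3L), 1, prob = c(0.7, 0.2, 0.1))
      # place the run inside one gene, away from existing runs so events
      # stay distinct maximal runs (collisions would merge counts)
      for (attempt in 1:50) {
        g <- sample.int(nrow(aln$genes), 1)
        gc0 <- (aln$genes$start[g] - 1) / 3 + 1
        gc1 <- aln$genes$end[g] / 3
        if (gc1 - gc0 + 1 < len + 2) next
        st <- sample(gc0:(gc1 - len + 1), 1)
        clash <- any(vapply(ev, function(x)
          st <= x[1] + x[2] && x[1] <= st + len, logical(1)))
        if (!clash) { ev[[length(ev) + 1L]] <- c(st, len); break }
      }
    }
    ev
  }
  events <- vector("list", nnode)
  events[[root]] <- list()
  for (e in rev(seq_len(nrow(tr$edge)))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    events[[child]] <- add_events(events[[parent]], K[e])
  }
  mat <- aln$mat
  truth <- integer(ntip)
  for (i in seq_len(ntip)) {
    ev <- add_events(events[[i]], Kleaf[i])
    truth[i] <- length(ev)
    for (x in ev) {
      cols <- ((x[1] - 1) * 3 + 1):((x[1] + x[2] - 1) * 3)
      mat[tr$tip.label[i], cols] <- "-"
    }
    if (frameshift_rate > 0) {
      nf <- stats::rpois(1, frameshift_rate)
      for (r in seq_len(nf)) {
        g <- sample.int(nrow(aln$genes), 1)
        col0 <- sample(aln$genes$start[g]:(aln$genes$end[g] - 1), 1)
        mat[tr$tip.label[i], col0:(col0 + sample(1:2, 1) - 1)] <- "-"
      }
    }
  }
  list(aln = codon_alignment(mat, aln$genes),
       truth = data.frame(taxon = tr$tip.label, n_indels = truth,
                          stringsAsFactors = FALSE))
}

#' Generate a complete synthetic dataset bundle
#'
#' Ties the generators together: tree, branch rates, codon alignment with
#' indels applied, signed block orders, a feature table (synthetic plastome
#' size and IR/LSC/SSC lengths), and a truth record (branch multipliers,
#' applied reversal and indel counts, the planted coupling). Optionally
#' writes everything to a directory as FASTA/Newick/TSV.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return List with `config`, `tree`, `multipliers`, `aln` (with indels),
#'   `aln_nogap` (pre-indel), `perms`, `features`, `truth`.
#' @export
make_scenario <- function(config, out_dir = NULL) {
  tree <- simulate_tree(config)
  mult <- simulate_branch_rates(tree, config$tau, config$seed)
  aln0 <- simulate_codon_alignment(tree, mult, config$genes,
                                   config$group_omega, config$kappa,
                                   seed = config$seed)
  ind <- simulate_indels(aln0, tree, mult, config$mu_indel, config$coupling,
                         seed = config$seed)
  rear <- simulate_rearrangements(tree, mult, config$n_blocks,
                                  config$lambda_inv, config$coupling,
                                  seed = config$seed)
  set.seed(.stage_seed(config$seed, "features"))
  taxa <- tree$tip.label
  ir <- round(stats::rnorm(length(taxa), 7000, 700))
  lsc <- round(stats::rnorm(length(taxa), 65000, 4000))
  ssc <- round(stats::rnorm(length(taxa), 40000, 3000))
  features <- data.frame(taxon = taxa,
                         plastome_size = ir + lsc + ssc,
                         ir_length = ir, lsc_length = lsc, ssc_length = ssc,
                         stringsAsFactors = FALSE)
  truth <- merge(rear$truth, ind$truth, by = "taxon")
  truth$coupling <- config$coupling
  edge_truth <- data.frame(parent = tree$edge[, 1], child = tree$edge[, 2],
                           length = tree$edge.length, multiplier = mult)
  bundle <- list(config = config, tree = tree, multipliers = mult,
                 aln = ind$aln, aln_nogap = aln0, perms = rear$perms,
                 features = features, truth = truth, edge_truth = edge_truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_codon_alignment(ind$aln, file.path(out_dir, "alignment.fasta"),
                          gene_table_path = file.path(out_dir, "genes.tsv"))
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    lcb <- vapply(rear$perms, function(p) paste(p$blocks, collapse = " "),
                  character(1))
    writeLines(paste(names(lcb), lcb, sep = "\t"),
               file.path(out_dir, "lcb_orders.tsv"))
    utils::write.table(features, file.path(out_dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(out_dir, "truth_taxa.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(edge_truth, file.path(out_dir, "truth_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  bundle
}
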