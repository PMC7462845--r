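# Signed permutations of locally collinear blocks (LCBs) and exact reversal
# (inversion) distances by the Hannenhalli-Pevzner breakpoint-graph formula
#   d = (n + 1) - c + h + f
# for a linear chromosome framed by 0 and n+1, with a breadth-first-search
# oracle for validation on small n.

#' Construct a signed permutation
#'
#' @param blocks Integer vector of signed block ids; absolute values must be
#'   exactly 1..n, each once, no zero.
#' @param taxon Optional taxon label.
#' @return Object of class `signed_permutation`.
#' @export
signed_permutation <- function(blocks, taxon = NULL) {
  blocks <- as.integer(blocks)
  if (any(blocks == 0)) stop("block id 0 is not allowed")
  n <- length(blocks)
  ab <- abs(blocks)
  if (anyDuplicated(ab)) {
    dup <- ab[duplicated(ab)][1]
    stop("duplicate block id ", dup, " (validation error)")
  }
  missing <- setdiff(seq_len(n), ab)
  if (length(missing))
    stop("missing block id(s): ", paste(missing, collapse = ", "),
         " (validation error)")
  structure(list(taxon = taxon, blocks = blocks, n = n),
            class = "signed_permutation")
}

#' @export
print.signed_permutation <- function(x, ...) {
  cat(if (is.null(x$taxon)) "signed_permutation:" else paste0(x$taxon, ":"),
      paste(x$blocks, collapse = " "), "\n")
  invisible(x)
}

.as_blocks <- function(p) if (inherits(p, "signed_permutation")) p$blocks else
  signed_permutation(p)$blocks

#' Parse a table of signed LCB orders
#'
#' One row per taxon: a label followed by whitespace-separated signed block
#' ids, tab- or whitespace-delimited. Unicode minus signs and a minus
#' separated from its digits by spaces are normalized; every row must be a
#' signed permutation of the same 1..n.
#'
#' @param path File path, or a character vector of lines via `text`.
#' @param text Optional character vector of lines (overrides `path`).
#' @return Named list of [signed_permutation()]s.
#' @export
parse_lcb_table <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  perms <- list()
  for (row in seq_along(lines)) {
    ln <- lines[row]
    # normalize unicode minus / non-breaking hyphen, then glue "- 5" -> "-5"
    ln <- gsub("[−‑–]", "-", ln)
    ln <- gsub("-[[:space:]]+", "-", ln)
    parts <- strsplit(trimws(ln), "[\t ]+")[[1]]
    taxon <- parts[1]
    vals <- suppressWarnings(as.integer(parts[-1]))
    if (any(is.na(vals)))
      stop("row ", row, " (", taxon, "): non-integer block id '",
           parts[-1][which(is.na(vals))[1]], "'")
    p <- tryCatch(signed_permutation(vals, taxon = taxon),
                  error = function(e)
                    stop("row ", row, " (", taxon, "): ", conditionMessage(e),
                         call. = FALSE))
    if (taxon %in% names(perms)) stop("duplicate taxon label: ", taxon)
    perms[[taxon]] <- p
  }
  ns <- vapply(perms, `[[`, integer(1), "n")
  if (length(unique(ns)) > 1)
    stop("rows have different block counts: ",
         paste(unique(ns), collapse = ", "), " (validation error)")
  perms
}

#' Group taxa with identical signed block order
#'
#' Partitions permutations by exact equality of the full signed sequence and
#' counts the taxa that share their order with at least one other taxon.
#'
#' @param perms List of [signed_permutation()]s (named by taxon).
#' @param up_to_reflection If `TRUE`, orders equal up to whole-molecule
#'   reversal (reverse + negate) are merged (off by default).
#' @return List with `groups` (list of character vectors of taxon labels) and
#'   `n_shared` (number of taxa in groups of size >= 2).
#' @export
identical_order_groups <- function(perms, up_to_reflection = FALSE) {
  canon <- vapply(perms, function(p) {
    b <- .as_blocks(p)
    k1 <- paste(b, collapse = " ")
    if (!up_to_reflection) return(k1)
    k2 <- paste(-rev(b), collapse = " ")
    min(k1, k2)
  }, character(1))
  taxa <- names(perms)
  if (is.null(taxa)) taxa <- vapply(perms, function(p)
    if (is.null(p$taxon)) "" else p$taxon, character(1))
  groups <- split(taxa, canon)
  names(groups) <- NULL
  sizes <- lengths(groups)
  list(groups = groups, n_shared = sum(sizes[sizes >= 2]))
}

#' Apply a reversal to a signed permutation
#'
#' Reverses the segment `i..j` and flips its signs.
#'
#' @param p A [signed_permutation()] or signed integer vector.
#' @param i,j Segment bounds (1-based, inclusive, `i <= j`).
#' @return A [signed_permutation()].
#' @export
apply_reversal <- function(p, i, j) {
  b <- .as_blocks(p)
  if (i < 1 || j > length(b) || i > j) stop("invalid reversal bounds")
  b[i:j] <- -rev(b[i:j])
  signed_permutation(b, taxon = if (inherits(p, "signed_permutation")) p$taxon)
}

# ---- Hannenhalli-Pevzner machinery -----------------------------------------

# Breakpoint graph of the framed permutation (0, p, n+1):
#  +x -> vertices 2x-1, 2x ; -x -> 2x, 2x-1 ; frame contributes 0 and 2n+1.
# Black edges join the doubled sequence at positions (2i+1, 2i+2) (1-based,
# i = 0..n); gray edges join values (2i, 2i+1). Alternating cycles are
# counted; cycles, component orientation, hurdles and the fortress indicator
# give d = (n+1) - c + h + f.

#' Breakpoint-graph statistics and reversal distance to the identity
#'
#' @param p A [signed_permutation()] or signed integer vector.
#' @return Object of class `breakpoint_stats`: `n`, `c` (cycles), `h`
#'   (hurdles), `f` (fortress indicator), `d` (reversal distance).
#' @export
reversal_distance_to_identity <- function(p) {
  b <- .as_blocks(p)
  n <- length(b)
  # doubled unsigned sequence u, positions 1..2n+2, values 0..2n+1
  u <- integer(2 * n + 2)
  u[1] <- 0L
  for (k in seq_len(n)) {
    x <- b[k]
    u[2 * k] <- if (x > 0) 2L * x - 1L else -2L * x
    u[2 * k + 1] <- if (x > 0) 2L * x else -2L * x - 1L
  }
  u[2 * n + 2] <- 2L * n + 1L
  pos <- integer(2 * n + 2)          # pos[v+1] = position of value v
  pos[u + 1L] <- seq_along(u)

  # black neighbour of each value: partner across positions (2i+1, 2i+2)
  black <- integer(2 * n + 2)
  for (i in 0:n) {
    v1 <- u[2 * i + 1]; v2 <- u[2 * i + 2]
    black[v1 + 1L] <- v2
    black[v2 + 1L] <- v1
  }
  # gray neighbour: value partner (2i <-> 2i+1)
  gray <- integer(2 * n + 2)
  for (i in 0:n) {
    gray[2 * i + 1L] <- 2L * i + 1L   # value 2i pairs with 2i+1
    gray[2 * i + 2L] <- 2L * i        # value 2i+1 pairs with 2i
  }

  # traverse alternating cycles; record cycle id per gray edge
  cyc_of_gray <- integer(n + 1)       # gray edge i joins values 2i, 2i+1
  visited <- logical(2 * n + 2)
  ncyc <- 0L
  for (v0 in 0:(2 * n + 1)) {
    if (visited[v0 + 1L]) next
    ncyc <- ncyc + 1L
    v <- v0
    repeat {
      visited[v + 1L] <- TRUE
      w <- black[v + 1L]              # follow black edge
      visited[w + 1L] <- TRUE
      g <- w %/% 2L                   # gray edge id of w: pairs (2g, 2g+1)
      cyc_of_gray[g + 1L] <- ncyc
      v <- gray[w + 1L]               # follow gray edge
      if (v == v0) break
    }
  }

  # gray edges with position spans and orientation
  gp <- t(vapply(0:n, function(i) {
    p1 <- pos[2 * i + 1L]; p2 <- pos[2 * i + 2L]
    c(min(p1, p2), max(p1, p2))
  }, integer(2)))
  oriented_edge <- (gp[, 2] - gp[, 1]) %% 2L == 0L
  trivial <- gp[, 2] - gp[, 1] == 1L  # adjacency (span of one black edge)

  # cycle sizes (number of gray edges) and nontrivial cycles
  cyc_sizes <- tabulate(cyc_of_gray, ncyc)
  nontrivial <- which(cyc_sizes >= 2)

  h <- 0L; f <- 0L
  if (length(nontrivial)) {
    # interleaving graph over nontrivial cycles -> components via union-find
    edges <- which(!trivial)
    parent <- seq_len(ncyc)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    union <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }
    if (length(edges) > 1) {
      for (a in seq_along(edges)[-length(edges)]) {
        ea <- edges[a]
        for (bidx in (a + 1):length(edges)) {
          eb <- edges[bidx]
          if (cyc_of_gray[ea] == cyc_of_gray[eb]) next
          a1 <- gp[ea, 1]; a2 <- gp[ea, 2]
          b1 <- gp[eb, 1]; b2 <- gp[eb, 2]
          if ((a1 < b1 && b1 < a2 && a2 < b2) ||
              (b1 < a1 && a1 < b2 && b2 < a2))
            union(cyc_of_gray[ea], cyc_of_gray[eb])
        }
      }
    }
    comp_of_cycle <- vapply(seq_len(ncyc), find, integer(1))

    # orientation per cycle, then per component
    cyc_oriented <- rep(FALSE, ncyc)
    for (e in which(oriented_edge)) cyc_oriented[cyc_of_gray[e]] <- TRUE

    comps <- unique(comp_of_cycle[nontrivial])
    comp_info <- lapply(comps, function(cid) {
      cycs <- nontrivial[comp_of_cycle[nontrivial] == cid]
      eidx <- which(cyc_of_gray %in% cycs)
      list(oriented = any(cyc_oriented[cycs]),
           lo = min(gp[eidx, 1]), hi = max(gp[eidx, 2]))
    })
    unor <- comp_info[!vapply(comp_info, `[[`, logical(1), "oriented")]
    if (length(unor)) {
      lo <- vapply(unor, `[[`, numeric(1), "lo")
      hi <- vapply(unor, `[[`, numeric(1), "hi")
      is_hurdle_in <- function(k, members) {
        others <- setdiff(members, k)
        if (!length(others)) return(TRUE)
        inside <- lo[others] > lo[k] & hi[others] < hi[k]
        all(inside) || !any(inside)   # greatest (contains all) or minimal
      }
      members <- seq_along(unor)
      hurdle <- vapply(members, is_hurdle_in, logical(1), members = members)
      h <- sum(hurdle)
      if (h %% 2L == 1L && h > 0L) {
        superhurdle <- vapply(which(hurdle), function(k) {
          nonh <- members[!hurdle]
          if (!length(nonh)) return(FALSE)
          any(vapply(nonh, function(m)
            is_hurdle_in(m, setdiff(members, k)), logical(1)))
        }, logical(1))
        if (all(superhurdle)) f <- 1L
      }
    }
  }
  d <- (n + 1L) - ncyc + h + f
  structure(list(n = n, c = ncyc, h = h, f = f, d = d),
            class = "breakpoint_stats")
}

#' @export
print.breakpoint_stats <- function(x, ...) {
  cat(sprintf("breakpoint graph: n=%d cycles=%d hurdles=%d fortress=%d  d=%d\n",
              x$n, x$c, x$h, x$f, x$d))
  invisible(x)
}

#' Reversal (inversion) distance between two signed permutations
#'
#' Relabels so that `b` becomes the identity (composition with the signed
#' inverse of `b`), then applies the Hannenhalli-Pevzner formula. Symmetric.
#'
#' @param a,b [signed_permutation()]s (or signed integer vectors) of equal n.
#' @return Integer reversal distance.
#' @export
reversal_distance <- function(a, b) {
  va <- .as_blocks(a); vb <- .as_blocks(b)
  if (length(va) != length(vb))
    stop("permutations have different block counts (input error)")
  reversal_distance_to_identity(.compose_with_inverse(va, vb))$d
}

# gamma = b^{-1} o a : the permutation a expressed in coordinates where b is
# the identity, propagating strand signs.
.compose_with_inverse <- function(a, b) {
  n <- length(b)
  inv <- integer(n)          # inv[|b_k|] = k * sign(b_k)
  inv[abs(b)] <- seq_len(n) * sign(b)
  as.integer(sign(a) * inv[abs(a)])
}

#' Exact reversal distance by breadth-first search (validation oracle)
#'
#' Bidirectional BFS over all `n(n+1)/2` reversals; exact but exponential,
#' guarded to `n <= 8`.
#'
#' @param a,b [signed_permutation()]s or signed integer vectors of equal n.
#' @param max_n State-space guard (default 8).
#' @return Integer minimum number of reversals.
#' @export
bfs_oracle_distance <- function(a, b, max_n = 8) {
  va <- .as_blocks(a); vb <- .as_blocks(b)
  if (length(va) != length(vb)) stop("permutations have different block counts")
  n <- length(va)
  if (n > max_n) stop("n = ", n, " too large for the BFS oracle (guard ",
                      max_n, ")")
  start <- .compose_with_inverse(va, vb)
  target <- seq_len(n)
  if (identical(start, target)) return(0L)

  # states as rows of a matrix; encoded to exact doubles base 2n
  enc <- function(M) {
    codes <- (abs(M) - 1) * 2 + (M < 0)
    as.vector(codes %*% (2 * n)^(0:(n - 1)))
  }
  revs <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  expand <- function(M) {
    out <- vector("list", nrow(revs))
    for (r in seq_len(nrow(revs))) {
      i <- revs[r, 1]; j <- revs[r, 2]
      W <- M
      W[, i:j] <- -W[, j:i, drop = FALSE]
      out[[r]] <- W
    }
    do.call(rbind, out)
  }
  side <- list(
    f = list(frontier = matrix(start, 1), codes = enc(matrix(start, 1)),
             dists = 0, depth = 0L),
    b = list(frontier = matrix(target, 1), codes = enc(matrix(target, 1)),
             dists = 0, depth = 0L))
  repeat {
    grow <- if (nrow(side$f$frontier) <= nrow(side$b$frontier)) "f" else "b"
    other <- if (grow == "f") "b" else "f"
    s <- side[[grow]]
    W <- expand(s$frontier)
    cw <- enc(W)
    keep <- !duplicated(cw)
    W <- W[keep, , drop = FALSE]; cw <- cw[keep]
    keep <- !(cw %in% s$codes)
    W <- W[keep, , drop = FALSE]; cw <- cw[keep]
    depth <- s$depth + 1L
    hit <- match(cw, side[[other]]$codes)
    if (any(!is.na(hit)))
      return(as.integer(depth + min(side[[other]]$dists[hit[!is.na(hit)]])))
    side[[grow]] <- list(frontier = W,
                         codes = c(s$codes, cw),
                         dists = c(s$dists, rep(depth, length(cw))),
                         depth = depth)
    if (nrow(W) == 0)
      stop("BFS frontiers exhausted without meeting (should not happen)")
  }
}

#' Pairwise inversion-distance matrix
#'
#' @param perms Named list of [signed_permutation()]s of equal n.
#' @return Symmetric integer matrix with zero diagonal, taxa as dimnames.
#' @export
pairwise_iv_matrix <- function(perms) {
  taxa <- names(perms)
  if (is.null(taxa)) taxa <- paste0("taxon", seq_along(perms))
  n <- length(perms)
  D <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- reversal_distance(perms[[i]], perms[[j]])
    }
  }
  D
}

#' Write / read an inversion-distance matrix as TSV
#'
#' @param D Symmetric matrix with taxon dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_iv_matrix <- function(D, path) {
  utils::write.table(D, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
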