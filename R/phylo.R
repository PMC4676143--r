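#' Poisson-corrected evolutionary distances with pairwise deletion
#'
#' For each pair of aligned sequences, columns where either row has a gap are
#' dropped (pairwise deletion); `p` is the fraction of the remaining shared
#' columns that differ, and the Poisson-corrected distance is
#' `d = -ln(1 - p)`. A pair with `p >= 1` gets an infinite distance (flagged
#' with a warning); a pair with no shared ungapped columns is an error.
#'
#' @param alignment Named character vector of equal-length gapped rows.
#' @return Symmetric numeric matrix of distances with zero diagonal.
#' @examples
#' a <- c(x = "AAAAAAAAAA", y = "AAAAAAAAAC")
#' poissonDistance(a)[1, 2] # -log(1 - 0.1)
#' @export
poissonDistance <- function(alignment) {
  alignment <- asAlignment(alignment)
  n <- length(alignment)
  ids <- names(alignment)
  rows <- strsplit(alignment, "")
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      ri <- rows[[i]]; rj <- rows[[j]]
      shared <- ri != "-" & rj != "-"
      ns <- sum(shared)
      if (ns == 0L)
        stop("no shared ungapped columns for pair ", ids[i], " / ", ids[j])
      p <- sum(ri[shared] != rj[shared]) / ns
      if (p >= 1) {
        warning("saturated pair (p >= 1): ", ids[i], " / ", ids[j])
        d[i, j] <- d[j, i] <- Inf
      } else {
        d[i, j] <- d[j, i] <- -log(1 - p)
      }
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Tie-breaking is
#' deterministic: among pairs of equal Q the lexicographically smallest pair
#' of cluster ids is joined (a cluster's id is its smallest member label).
#' Negative branch-length estimates are clamped to zero and the total
#' clamped deficit is recorded in the `"clamped"` attribute.
#'
#' @param dm Symmetric distance matrix with unique dimnames, >= 3 taxa,
#'   finite entries.
#' @return An unrooted [ape::phylo] tree (trifurcating root node).
#' @export
njTree <- function(dm) {
  if (!is.matrix(dm) || is.null(rownames(dm))) stop("need a named matrix")
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(dm))) stop("distance matrix has non-finite entries")
  if (anyDuplicated(rownames(dm))) stop("duplicate taxon ids")

  labels <- rownames(dm)
  # subtree Newick fragments and sort keys (smallest member label)
  sub <- vapply(labels, newickQuote, character(1))
  key <- labels
  D <- unname(dm)
  clamped <- 0
  clamp <- function(x) {
    if (x < 0) { clamped <<- clamped - x; 0 } else x
  }
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pairKeys <- apply(cand, 1L, function(ij) {
      k <- sort(c(key[ij[1L]], key[ij[2L]]))
      paste(k, collapse = "\r")
    })
    pick <- cand[order(pairKeys)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    bi <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    bj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    newSub <- sprintf("(%s:%.17g,%s:%.17g)", sub[i], bi, sub[j], bj)
    newKey <- min(key[i], key[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    sub <- c(sub[keep], newSub)
    key <- c(key[keep], newKey)
  }
  ba <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  bb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  bc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  ord <- order(key)
  b3 <- c(ba, bb, bc)[ord]
  s3 <- sub[ord]
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 s3[1L], b3[1L], s3[2L], b3[2L], s3[3L], b3[3L])
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

newickQuote <- function(x) {
  if (grepl("[(),:;\\s'\\[\\]]", x)) paste0("'", gsub("'", "''", x), "'") else x
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the taxa in two; the bipartition is canonicalised
#' as the side not containing the alphabetically first taxon, encoded as a
#' sorted, collapsed label string. Used for bootstrap support counting.
#'
#' @param tree An [ape::phylo] tree.
#' @return Character vector of bipartition signatures, named by the internal
#'   node each subtends.
#' @export
treeBipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1L]
  root <- ntip + 1L
  inner <- setdiff(unique(tree$edge[, 2L]), seq_len(ntip))
  sigs <- character(0)
  for (v in inner) {
    tips <- tipsUnder(tree, v, ntip)
    side <- sort(tree$tip.label[tips])
    if (ref %in% side)
      side <- sort(setdiff(tree$tip.label, side))
    if (length(side) < 2L || length(side) > ntip - 2L) next
    sigs <- c(sigs, stats::setNames(paste(side, collapse = "\r"), v))
  }
  sigs
}

tipsUnder <- function(tree, node, ntip) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= ntip) {
      out <- c(out, v)
    } else {
      stack <- c(stack, tree$edge[tree$edge[, 1L] == v, 2L])
    }
  }
  out
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the tree from the full alignment, then resamples alignment columns
#' with replacement `n` times, recomputes the Poisson distances and the NJ
#' tree for each replicate, and reports for every internal edge of the
#' original tree the percentage of replicates containing the same
#' bipartition. Replicates whose resampled distances are saturated or
#' undefined are dropped from the denominator.
#'
#' @param alignment Named character vector of gapped rows (>= 4 taxa for
#'   meaningful supports).
#' @param n Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the resampling is reproducible given the seed.
#' @return The NJ tree with `node.label` holding support percentages
#'   (`NA` for the root), plus attribute `"replicates"` (replicates used).
#' @export
bootstrapSupport <- function(alignment, n = 1000L, seed = 1L) {
  alignment <- asAlignment(alignment)
  tree <- njTree(poissonDistance(alignment))
  if (n <= 0L) return(tree)
  rows <- do.call(rbind, strsplit(alignment, ""))
  rownames(rows) <- names(alignment)
  L <- ncol(rows)
  orig <- treeBipartitions(tree)
  counts <- stats::setNames(rep(0L, length(orig)), orig)
  used <- 0L
  set.seed(seed)
  for (b in seq_len(n)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- apply(rows[, cols, drop = FALSE], 1L, paste, collapse = "")
    repTree <- tryCatch(
      suppressWarnings(njTree(poissonDistance(rep_aln))),
      error = function(e) NULL
    )
    if (is.null(repTree)) next
    used <- used + 1L
    hits <- treeBipartitions(repTree)
    present <- names(counts) %in% hits
    counts[present] <- counts[present] + 1L
  }
  support <- if (used > 0L) 100 * counts / used else rep(NA_real_, length(counts))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  labels <- rep(NA_character_, nnode)
  nodeIds <- as.integer(names(orig))
  labels[nodeIds - ntip] <- sprintf("%g", support)
  tree$node.label <- labels
  attr(tree, "replicates") <- used
  tree
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param dm Symmetric distance matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDistancePhylip <- function(dm, path) {
  n <- nrow(dm)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste0(formatC(rownames(dm)[i], width = -10),
                      paste(sprintf("%.6f", dm[i, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
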