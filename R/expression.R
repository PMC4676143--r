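#' Log2-transform an RPKM matrix
#'
#' Positive values become `log2(value)`; zeros become missing (they render
#' gray in the usual heatmap convention, and a log of zero has no place on
#' the color scale); already-missing entries stay missing. Order is
#' preserved on the positive part.
#'
#' @param m Numeric RPKM matrix (genes x samples), `NA` = missing.
#' @return Matrix of the same shape on the log2 scale.
#' @examples
#' log2Transform(matrix(c(8, 0, 1, NA), 2, 2))
#' @export
log2Transform <- function(m) {
  if (any(m < 0, na.rm = TRUE)) stop("RPKM values must be non-negative")
  out <- m
  out[!is.na(m) & m == 0] <- NA_real_
  pos <- !is.na(out)
  out[pos] <- log2(out[pos])
  out
}

#' Euclidean distance between gene rows with missing values
#'
#' Distances are computed over mutually present columns and the squared sum
#' is rescaled by (total columns / present columns) before taking the root,
#' so genes with missing entries remain comparable — the convention of the
#' classic gene-expression clustering tools.
#'
#' @param m Numeric matrix (genes x samples) with `NA` for missing.
#' @return Symmetric distance matrix over rows.
#' @export
euclideanMissing <- function(m) {
  n <- nrow(m)
  ids <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  p <- ncol(m)
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      both <- !is.na(m[i, ]) & !is.na(m[j, ])
      np <- sum(both)
      if (np == 0L)
        stop("no mutually present values for genes ", ids[i], " / ", ids[j])
      d[i, j] <- d[j, i] <-
        sqrt(sum((m[i, both] - m[j, both])^2) * p / np)
    }
  }
  d
}

#' Complete-linkage hierarchical clustering of gene rows
#'
#' Agglomerative clustering with Euclidean distance (missing values handled
#' as in [euclideanMissing()]) and complete linkage: the distance between two
#' clusters is the maximum pairwise distance between their members, so merge
#' heights are non-decreasing. All ties are broken by the lexicographically
#' smallest gene id, making the dendrogram fully deterministic. Genes whose
#' rows are entirely missing are excluded with a warning.
#'
#' @param m Numeric matrix (genes x samples), typically [log2Transform()]ed.
#' @param distance Optional precomputed distance matrix over the rows.
#' @return An object of class `hclust` (usable with [stats::cutree()]) with
#'   `merge`, `height`, `order` and `labels`.
#' @export
hclusterGenes <- function(m, distance = NULL) {
  allMissing <- rowSums(!is.na(m)) == 0L
  if (any(allMissing)) {
    warning("excluding all-missing gene(s): ",
            paste(rownames(m)[allMissing], collapse = ", "))
    m <- m[!allMissing, , drop = FALSE]
  }
  n <- nrow(m)
  if (n < 2L) stop("clustering needs at least 2 genes with data")
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("g", seq_len(n))
  D <- if (is.null(distance)) euclideanMissing(m) else
    distance[labels, labels, drop = FALSE]

  # active cluster state
  members <- as.list(seq_len(n))          # observation indices
  nodes <- as.integer(-seq_len(n))        # hclust merge codes
  keys <- labels                           # smallest member id per cluster
  leaves <- as.list(seq_len(n))           # leaf order within cluster
  cd <- D                                  # complete-linkage distances
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m_act <- length(members)
    best <- NULL
    for (i in seq_len(m_act - 1L)) {
      for (j in (i + 1L):m_act) {
        better <- FALSE
        if (is.null(best) || cd[i, j] < best$d - 1e-12) {
          better <- TRUE
        } else if (abs(cd[i, j] - best$d) <= 1e-12) {
          kc <- sort(c(keys[i], keys[j]))
          kb <- sort(c(keys[best$i], keys[best$j]))
          if (kc[1L] < kb[1L] || (kc[1L] == kb[1L] && kc[2L] < kb[2L]))
            better <- TRUE
        }
        if (better) best <- list(i = i, j = j, d = cd[i, j])
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sortMergeCodes(nodes[i], nodes[j])
    height[step] <- best$d
    # child order in the leaf sequence: smaller key first
    ord <- if (keys[i] <= keys[j]) c(i, j) else c(j, i)
    newLeaves <- c(leaves[[ord[1L]]], leaves[[ord[2L]]])
    newMembers <- c(members[[i]], members[[j]])
    newKey <- min(keys[i], keys[j])
    newd <- pmax(cd[i, ], cd[j, ])
    keep <- setdiff(seq_len(m_act), c(i, j))
    cd <- rbind(cbind(cd[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    members <- c(members[keep], list(newMembers))
    leaves <- c(leaves[keep], list(newLeaves))
    keys <- c(keys[keep], newKey)
    nodes <- c(nodes[keep], step)
  }
  structure(
    list(merge = merge, height = height, order = leaves[[1L]],
         labels = labels, method = "complete",
         dist.method = "euclidean (missing-rescaled)",
         call = match.call()),
    class = "hclust"
  )
}

# hclust convention: singletons (negative) before merges, else ascending
sortMergeCodes <- function(a, b) {
  if (a < 0L && b < 0L) c(min(a, b), max(a, b))
  else if (a < 0L) c(a, b)
  else if (b < 0L) c(b, a)
  else c(min(a, b), max(a, b))
}

#' Flat gene groups at a dendrogram cut
#'
#' @param clust An `hclust` object from [hclusterGenes()].
#' @param k Number of groups.
#' @return Named integer vector of group memberships.
#' @export
cutClusters <- function(clust, k) {
  stats::cutree(clust, k = k)
}

#' Count expressed genes per sample
#'
#' A gene counts as expressed in a sample when its RPKM exceeds `threshold`
#' (strictly; the default 0 means any non-zero signal). Missing values never
#' count as expressed.
#'
#' @param m RPKM matrix (genes x samples).
#' @param threshold Strict RPKM threshold (default 0).
#' @return A list with `per_sample` (named counts) and `any_sample` (number
#'   of genes expressed in at least one sample).
#' @export
expressedCounts <- function(m, threshold = 0) {
  expressed <- !is.na(m) & m > threshold
  list(
    per_sample = colSums(expressed),
    any_sample = sum(rowSums(expressed) > 0L)
  )
}

#' Relative expression from qPCR Ct values
#'
#' Replicate Ct values are averaged per gene and sample; the difference to
#' the housekeeping reference gene in the same sample gives
#' `dCt = Ct_gene - Ct_ref` and the relative level `2^-dCt`. With a
#' calibrator sample, `ddCt = dCt - dCt_calibrator` and fold changes
#' `2^-ddCt` are added.
#'
#' @param tab Data.frame with columns `gene`, `sample`, `replicate`, `Ct`
#'   (see [readQpcrTable()]).
#' @param reference Id of the housekeeping reference gene; must be measured
#'   in every sample.
#' @param calibrator Optional calibrator sample label for ddCt.
#' @return Data.frame with `gene`, `sample`, `mean_ct`, `dct`, `relative`
#'   (and `ddct`, `fold` when a calibrator is given); the reference gene's
#'   own rows are dropped.
#' @export
qpcrRelativeExpression <- function(tab, reference, calibrator = NULL) {
  if (!reference %in% tab$gene)
    stop("reference gene ", reference, " not in table")
  agg <- stats::aggregate(Ct ~ gene + sample, data = tab, FUN = mean)
  names(agg)[names(agg) == "Ct"] <- "mean_ct"
  refrows <- agg[agg$gene == reference, ]
  samples <- unique(agg$sample)
  missingRef <- setdiff(samples, refrows$sample)
  if (length(missingRef))
    stop("reference gene missing in sample(s): ",
         paste(missingRef, collapse = ", "))
  refCt <- stats::setNames(refrows$mean_ct, refrows$sample)
  out <- agg[agg$gene != reference, , drop = FALSE]
  out$dct <- out$mean_ct - refCt[out$sample]
  out$relative <- 2^(-out$dct)
  if (!is.null(calibrator)) {
    if (!calibrator %in% samples) stop("calibrator sample not in table")
    cal <- out[out$sample == calibrator, ]
    calDct <- stats::setNames(cal$dct, cal$gene)
    if (anyNA(calDct[unique(out$gene)]))
      stop("calibrator sample lacks some genes")
    out$ddct <- out$dct - calDct[out$gene]
    out$fold <- 2^(-out$ddct)
  }
  rownames(out) <- NULL
  out
}
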