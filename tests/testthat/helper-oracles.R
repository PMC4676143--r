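# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the alignment oracle is a plain forward DP over
# explicit matrices, the linkage oracle recomputes cluster distances by
# exhaustive pairwise maxima at every step, and additive test matrices come
# from path lengths on randomly generated trees.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomProtein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                   collapse = "")

# affine-gap global alignment score by explicit three-matrix recursion
naiveAlignScore <- function(a, b, sub, gapOpen, gapExt) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  go <- gapOpen + gapExt
  for (i in seq_len(n + 1)) {
    for (j in seq_len(m + 1)) {
      if (i > 1 && j > 1)
        M[i, j] <- sub[A[i - 1], B[j - 1]] +
          max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      if (i > 1)
        X[i, j] <- max(M[i - 1, j] - go, X[i - 1, j] - gapExt,
                       Y[i - 1, j] - go)
      if (j > 1)
        Y[i, j] <- max(M[i, j - 1] - go, X[i, j - 1] - go,
                       Y[i, j - 1] - gapExt)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# exhaustive complete-linkage merges: returns heights and the partition
# after every merge, recomputing every cluster-pair maximum from scratch
bruteCompleteLinkage <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (is.null(best) || d < best$d) best <- list(i = i, j = j, d = d)
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
    heights <- c(heights, best$d)
    partitions[[length(partitions) + 1]] <-
      lapply(clusters, identity)
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition (list of index vectors) for comparison
canonicalPartition <- function(p) {
  p <- lapply(p, sort)
  p[order(vapply(p, function(x) x[1], numeric(1)))]
}

# partition of an hclust object into k groups, as a canonical list
hclustPartition <- function(h, k) {
  grp <- stats::cutree(h, k = k)
  canonicalPartition(unname(split(seq_along(grp), grp)))
}

# random unrooted binary tree as an additive distance matrix over n taxa
randomAdditiveMatrix <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.05, 1))
  dm <- ape::cophenetic.phylo(tr)
  ids <- sort(rownames(dm))
  dm[ids, ids]
}

# tiny GRangesList gene-model builder for layout tests:
# df columns gene_id, scaffold, start, strand; exons = single CDS of
# given lengths laid from start
toyModels <- function(df, exon_lengths = NULL) {
  models <- list()
  meta <- list()
  for (k in seq_len(nrow(df))) {
    lens <- if (is.null(exon_lengths)) list(300L)[[1]]
            else exon_lengths[[k]]
    introns <- if (length(lens) > 1) rep(100L, length(lens) - 1) else integer(0)
    starts <- df$start[k] + c(0L, cumsum(lens[-length(lens)] + introns))
    ends <- starts + lens - 1L
    gr <- GenomicRanges::GRanges(df$scaffold[k],
                                 IRanges::IRanges(starts, ends),
                                 strand = df$strand[k])
    if (df$strand[k] == "-") gr <- rev(gr)
    models[[df$gene_id[k]]] <- gr
    meta[[k]] <- data.frame(gene_id = df$gene_id[k],
                            scaffold = df$scaffold[k],
                            gene_strand = df$strand[k],
                            gene_start = min(starts),
                            gene_end = max(ends),
                            stringsAsFactors = FALSE)
  }
  grl <- GenomicRanges::GRangesList(models)
  S4Vectors::mcols(grl) <- S4Vectors::DataFrame(do.call(rbind, meta))
  grl
}

# a protein with an intact (or selectively broken) triad for motif tests
triadToy <- function(his = "TAAHC", asp = "DIAL", ser = "GDSGGP",
                     pre = strrep("A", 20), mid1 = strrep("L", 30),
                     mid2 = strrep("K", 40), post = strrep("A", 10)) {
  paste0(pre, his, mid1, asp, mid2, ser, post)
}

# clip cassette string from spacings (s12, s23, s34, s45, s56), spacer "A"
clipToy <- function(s12, s23, s34, s45, s56 = 0, lead = strrep("A", 5),
                    tail = strrep("A", 10)) {
  paste0(lead,
         "C", strrep("A", s12), "C", strrep("A", s23), "C",
         strrep("A", s34), "C", strrep("A", s45), "C", strrep("A", s56), "C",
         tail)
}
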