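#' Alignment parameters
#'
#' Default scoring for all pairwise and progressive alignments: BLOSUM62
#' exchange matrix with affine gap penalties, gap open 10 and gap extension
#' 0.5 (a gap of length L costs `open + L * ext`). These mirror the defaults
#' of the classical progressive aligners used for protease families and are
#' fully overridable.
#'
#' @param submat Substitution matrix with residue dimnames; default BLOSUM62
#'   as shipped with Biostrings.
#' @param gapOpen,gapExt Affine gap penalties (positive costs).
#' @return A list with `submat`, `gapOpen`, `gapExt`.
#' @export
alignParams <- function(submat = blosum62(), gapOpen = 10, gapExt = 0.5) {
  stopifnot(is.matrix(submat), !is.null(rownames(submat)),
            identical(rownames(submat), colnames(submat)),
            gapOpen >= 0, gapExt >= 0)
  list(submat = submat, gapOpen = gapOpen, gapExt = gapExt)
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch with affine gaps (Gotoh three-state dynamic programme,
#' implemented in C++). Tie-breaking is deterministic: on equal score the
#' traceback prefers a residue-residue column, then a gap in the second
#' sequence, then a gap in the first.
#'
#' @param a,b Protein sequences (character scalars or `AAString`(Set)s).
#' @param params Scoring parameters from [alignParams()].
#' @return A list with `score` and `alignment` (named character vector of the
#'   two gapped rows; names are taken from the inputs when available,
#'   otherwise `"a"`/`"b"`).
#' @examples
#' globalAlign("ACDE", "ACE")$alignment
#' @export
globalAlign <- function(a, b, params = alignParams()) {
  na <- if (!is.null(names(a))) names(a)[1L] else "a"
  nb <- if (!is.null(names(b))) names(b)[1L] else "b"
  a <- asSingleSequence(a)
  b <- asSingleSequence(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  r <- .nw_align_cpp(a, b, params$submat,
                     paste(rownames(params$submat), collapse = ""),
                     params$gapOpen, params$gapExt)
  aln <- c(r$a, r$b)
  names(aln) <- c(na, nb)
  list(score = r$score, alignment = aln)
}

#' Pairwise percent identity or similarity from an alignment
#'
#' For each pair of rows, only columns where neither sequence has a gap are
#' counted (pairwise deletion). Identity is the percentage of those columns
#' with identical residues; similarity additionally counts conservative
#' substitutions within the residue groups `{AVLIM} {FWY} {ST} {KRH} {DENQ}
#' {C} {G} {P}`.
#'
#' @param alignment Named character vector of equal-length gapped rows.
#' @param mode `"identity"` or `"similarity"`.
#' @return A symmetric matrix of percentages with 100 on the diagonal.
#' @export
percentIdentity <- function(alignment, mode = c("identity", "similarity")) {
  mode <- match.arg(mode)
  alignment <- asAlignment(alignment)
  n <- length(alignment)
  rows <- strsplit(alignment, "")
  ids <- names(alignment)
  grp <- similarityGroups()
  out <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ri <- rows[[i]]; rj <- rows[[j]]
      shared <- ri != "-" & rj != "-"
      if (!any(shared))
        stop("no shared ungapped columns for pair ", ids[i], " / ", ids[j])
      same <- ri[shared] == rj[shared]
      if (mode == "similarity") {
        gi <- grp[ri[shared]]; gj <- grp[rj[shared]]
        same <- same | (!is.na(gi) & !is.na(gj) & gi == gj)
      }
      out[i, j] <- out[j, i] <- 100 * sum(same) / sum(shared)
    }
  }
  out
}

# residue -> conservation-group id; residues outside all groups give NA
similarityGroups <- function() {
  groups <- list(c("A", "V", "L", "I", "M"), c("F", "W", "Y"),
                 c("S", "T"), c("K", "R", "H"), c("D", "E", "N", "Q"),
                 "C", "G", "P")
  g <- rep(NA_integer_, 26)
  names(g) <- LETTERS
  for (k in seq_along(groups)) g[groups[[k]]] <- k
  g
}

#' Mean pairwise percentage for a group of aligned sequences
#'
#' Convenience wrapper used for reporting the overall similarity of a gene
#' cluster: mean of the off-diagonal entries of [percentIdentity()].
#'
#' @param alignment Named character vector of gapped rows.
#' @param mode `"identity"` or `"similarity"`.
#' @return A single percentage.
#' @export
meanPairwisePercent <- function(alignment,
                                mode = c("identity", "similarity")) {
  m <- percentIdentity(alignment, mode)
  mean(m[upper.tri(m)])
}

#' Progressive multiple sequence alignment
#'
#' Profile-based progressive alignment: pairwise global alignments give a
#' percent-identity distance matrix, a UPGMA guide tree orders the merges,
#' and profiles (residue-frequency columns) are aligned with the same affine
#' three-state dynamic programme as the pairwise engine. Ties in the guide
#' tree are broken by the lexicographically smallest member id, so the
#' result is deterministic.
#'
#' @param seqs Named character vector or `AAStringSet` of at least two
#'   protein sequences.
#' @param params Scoring parameters from [alignParams()].
#' @return Named character vector of equal-length gapped rows, in input
#'   order.
#' @export
progressiveMsa <- function(seqs, params = alignParams()) {
  seqs <- asSequenceVector(seqs)
  n <- length(seqs)
  if (n < 2L) stop("progressive alignment needs at least 2 sequences")
  ids <- names(seqs)

  # pairwise identity distances for the guide tree
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- globalAlign(seqs[i], seqs[j], params)$alignment
      d[i, j] <- d[j, i] <- 1 - percentIdentity(al)[1L, 2L] / 100
    }
  }

  alpha <- strsplit(AA_ALPHABET_X, "")[[1L]]
  sub21 <- params$submat[alpha, alpha]

  # active clusters: list(members=row names, rows=gapped strings)
  clusters <- lapply(seq_len(n), function(i)
    list(members = ids[i], rows = stats::setNames(seqs[i], ids[i])))
  dd <- d
  sizes <- rep(1L, n)
  keyOf <- function(cl) min(cl$members)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        cand <- c(dd[i, j], i, j)
        if (is.null(best) || cand[1L] < best[1L] - 1e-12) {
          best <- cand
        } else if (abs(cand[1L] - best[1L]) <= 1e-12) {
          kc <- sort(c(keyOf(clusters[[i]]), keyOf(clusters[[j]])))
          kb <- sort(c(keyOf(clusters[[best[2L]]]), keyOf(clusters[[best[3L]]])))
          if (kc[1L] < kb[1L] || (kc[1L] == kb[1L] && kc[2L] < kb[2L]))
            best <- cand
        }
      }
    }
    i <- best[2L]; j <- best[3L]
    merged <- mergeProfiles(clusters[[i]], clusters[[j]], sub21, alpha, params)
    # UPGMA update
    newd <- (dd[i, ] * sizes[i] + dd[j, ] * sizes[j]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(m), c(i, j))
    dd <- rbind(cbind(dd[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    clusters <- c(clusters[keep], list(merged))
  }
  rows <- clusters[[1L]]$rows
  rows[ids]
}

mergeProfiles <- function(ca, cb, sub21, alpha, params) {
  pa <- profileOf(ca$rows, alpha)
  pb <- profileOf(cb$rows, alpha)
  r <- .nw_profile_cpp(pa, pb, sub21, params$gapOpen, params$gapExt)
  rowsA <- vapply(ca$rows, insertGaps, character(1), mask = r$gapA)
  rowsB <- vapply(cb$rows, insertGaps, character(1), mask = r$gapB)
  list(members = c(ca$members, cb$members), rows = c(rowsA, rowsB))
}

# residue-frequency profile: K x L, gaps excluded from counts but kept in
# the normalisation (gappy columns score proportionally less)
profileOf <- function(rows, alpha) {
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  L <- ncol(mat)
  p <- matrix(0, length(alpha), L, dimnames = list(alpha, NULL))
  for (k in seq_along(alpha))
    p[k, ] <- colSums(mat == alpha[k]) / nrow(mat)
  p
}

insertGaps <- function(row, mask) {
  out <- character(length(mask))
  out[mask] <- "-"
  out[!mask] <- strsplit(row, "")[[1L]]
  paste(out, collapse = "")
}

#' Write a gapped alignment to FASTA
#'
#' @param alignment Named character vector of gapped rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAlignmentFasta <- function(alignment, path) {
  writeLines(as.vector(rbind(paste0(">", names(alignment)),
                             unname(alignment))), path)
  invisible(path)
}

asAlignment <- function(alignment) {
  if (is(alignment, "AAStringSet")) {
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  }
  if (!is.character(alignment) || is.null(names(alignment)))
    stop("alignment must be a named character vector of gapped rows")
  if (length(unique(nchar(alignment))) != 1L)
    stop("alignment rows differ in length")
  alignment
}

asSequenceVector <- function(seqs) {
  if (is(seqs, "AAStringSet"))
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  if (!is.character(seqs)) stop("expected sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  seqs
}
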