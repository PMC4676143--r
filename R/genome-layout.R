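#' Tandem-duplication clusters on scaffolds
#'
#' Tandem duplication is called for neighboring homologous genes on a single
#' scaffold with at most `maxIntervening` genes between them. Per scaffold,
#' family members are sorted by start coordinate and consecutive members are
#' linked when the number of annotated genes ranked strictly between them is
#' within the bound (and, in `"identity"` mode, when their pairwise global
#' identity reaches the threshold); clusters are maximal runs of linked
#' pairs, singletons are dropped. Intervening genes are counted by distinct
#' gene id in start-coordinate rank order, so nested or antisense genes
#' count once.
#'
#' @param familyIds Character vector of family gene ids.
#' @param models Gene models for *all* annotated genes (family and not), as
#'   returned by [readGeneModels()] or [makeScaffolds()], so intervening
#'   counts are meaningful.
#' @param maxIntervening Maximum number of intervening genes (default 5).
#' @param homology `"family"` (co-membership suffices, the default) or
#'   `"identity"` (consecutive pair must also reach `identityThreshold`
#'   percent global identity; requires `seqs`).
#' @param seqs Named sequences, needed for `homology = "identity"`.
#' @param identityThreshold Percent identity required in `"identity"` mode.
#' @param params Alignment parameters for `"identity"` mode.
#' @return A list of clusters; each is a list with `scaffold`, `members`
#'   (ids ordered by start) and `intervening` (counts between consecutive
#'   members).
#' @export
tandemClusters <- function(familyIds, models, maxIntervening = 5L,
                           homology = c("family", "identity"), seqs = NULL,
                           identityThreshold = 40, params = alignParams()) {
  homology <- match.arg(homology)
  meta <- as.data.frame(S4Vectors::mcols(models))
  missing <- setdiff(familyIds, meta$gene_id)
  if (length(missing))
    stop("family gene id(s) not in gene models: ",
         paste(missing, collapse = ", "))
  if (homology == "identity" && is.null(seqs))
    stop("homology = 'identity' needs sequences")

  clusters <- list()
  for (sc in unique(meta$scaffold[meta$gene_id %in% familyIds])) {
    sub <- meta[meta$scaffold == sc, , drop = FALSE]
    sub <- sub[order(sub$gene_start, sub$gene_id), , drop = FALSE]
    fam <- which(sub$gene_id %in% familyIds)
    if (length(fam) < 2L) next
    linked <- logical(length(fam) - 1L)
    gaps <- integer(length(fam) - 1L)
    for (k in seq_len(length(fam) - 1L)) {
      gaps[k] <- fam[k + 1L] - fam[k] - 1L
      linked[k] <- gaps[k] <= maxIntervening
      if (linked[k] && homology == "identity") {
        a <- seqs[[sub$gene_id[fam[k]]]]
        b <- seqs[[sub$gene_id[fam[k + 1L]]]]
        al <- globalAlign(a, b, params)$alignment
        linked[k] <- percentIdentity(al)[1L, 2L] >= identityThreshold
      }
    }
    run_start <- 1L
    for (k in seq_len(length(fam))) {
      endRun <- k == length(fam) || !linked[k]
      if (endRun) {
        if (k > run_start) {
          idx <- fam[run_start:k]
          clusters[[length(clusters) + 1L]] <- list(
            scaffold = sc,
            members = sub$gene_id[idx],
            intervening = gaps[run_start:(k - 1L)]
          )
        }
        run_start <- k + 1L
      }
    }
  }
  clusters
}

#' Fraction of family genes sitting in tandem clusters
#'
#' @param clusters Output of [tandemClusters()].
#' @param familyIds The family gene ids the clusters were computed over.
#' @return Percentage of `familyIds` that are members of some cluster.
#' @export
clusteredFraction <- function(clusters, familyIds) {
  inCluster <- unique(unlist(lapply(clusters, `[[`, "members")))
  100 * length(intersect(inCluster, familyIds)) / length(familyIds)
}

#' Intron phases of a gene model
#'
#' The phase of intron *i* is the cumulative CDS length of exons 1..*i*
#' modulo 3 (0 = between codons, 1/2 = inside a codon after its first or
#' second base).
#'
#' @param x Either an integer vector of exon CDS lengths in transcription
#'   order, or a `GRanges` of CDS exons in transcription order (as the
#'   elements of [readGeneModels()]).
#' @return A list with `exon_count` and `phases` (integer vector of length
#'   `exon_count - 1`).
#' @examples
#' intronPhases(c(4, 4, 1, 3))$phases # 1 2 0
#' @export
intronPhases <- function(x) {
  lens <- if (is(x, "GRanges")) GenomicRanges::width(x) else as.integer(x)
  if (any(lens <= 0L)) stop("exon lengths must be positive")
  if (sum(lens) < 3L) stop("total CDS length must be at least 3")
  n <- length(lens)
  list(exon_count = n,
       phases = if (n > 1L) as.integer(cumsum(lens)[-n] %% 3L) else integer(0))
}

#' Structural consistency report for a tandem cluster
#'
#' Checks whether all members of a cluster share transcription orientation,
#' exon count and intron-phase vector, and reports the mean pairwise percent
#' identity and similarity of their protein sequences — the pattern expected
#' of recent tandem duplicates.
#'
#' @param cluster One cluster from [tandemClusters()].
#' @param models Gene models covering the members.
#' @param seqs Optional named protein sequences for the similarity figures.
#' @param params Alignment parameters.
#' @return A list with `same_orientation`, `same_exon_count`, `same_phases`,
#'   `phase_vectors` (per member, as strings), and — when `seqs` is given —
#'   `mean_identity` and `mean_similarity`.
#' @export
clusterConsistency <- function(cluster, models, seqs = NULL,
                               params = alignParams()) {
  meta <- as.data.frame(S4Vectors::mcols(models))
  idx <- match(cluster$members, meta$gene_id)
  if (anyNA(idx)) stop("cluster member missing from gene models")
  strands <- meta$gene_strand[idx]
  structs <- lapply(cluster$members, function(g) intronPhases(models[[g]]))
  phases <- vapply(structs, function(s)
    paste(s$phases, collapse = "-"), character(1))
  exonCounts <- vapply(structs, `[[`, integer(1), "exon_count")
  out <- list(
    same_orientation = length(unique(strands)) == 1L,
    same_exon_count = length(unique(exonCounts)) == 1L,
    same_phases = length(unique(phases)) == 1L,
    phase_vectors = stats::setNames(phases, cluster$members)
  )
  if (!is.null(seqs)) {
    ids <- cluster$members
    n <- length(ids)
    pid <- psim <- matrix(100, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        al <- globalAlign(seqs[[ids[i]]], seqs[[ids[j]]], params)$alignment
        pid[i, j] <- pid[j, i] <- percentIdentity(al)[1L, 2L]
        psim[i, j] <- psim[j, i] <- percentIdentity(al, "similarity")[1L, 2L]
      }
    }
    out$mean_identity <- mean(pid[upper.tri(pid)])
    out$mean_similarity <- mean(psim[upper.tri(psim)])
  }
  out
}

#' Write a TSV report of tandem clusters
#'
#' @param clusters Output of [tandemClusters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeClusterReport <- function(clusters, path) {
  df <- data.frame(
    cluster = seq_along(clusters),
    scaffold = vapply(clusters, `[[`, character(1), "scaffold"),
    size = vapply(clusters, function(cl) length(cl$members), integer(1)),
    members = vapply(clusters, function(cl)
      paste(cl$members, collapse = ","), character(1)),
    intervening = vapply(clusters, function(cl)
      paste(cl$intervening, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
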