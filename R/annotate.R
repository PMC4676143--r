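#' Annotate a serine protease family
#'
#' Runs the full per-protein annotation: catalytic-triad motif scan and
#' SP/SPH classification, clip-domain detection, S1-pocket readout with
#' trypsin/chymotrypsin subtype (SPs only), and activation-site typing. The
#' trypsin-like span reported by [findTriadMotifs()] anchors both the clip
#' search region and the pocket alignment.
#'
#' @param proteins Named `AAStringSet` or named character vector of protein
#'   sequences.
#' @param profiles Triad motif profiles, default [triadProfiles()].
#' @param grammar Clip spacing grammar, default [clipGrammar()].
#' @param params Alignment parameters for the pocket readout.
#' @param reference S1-pocket anchor, default [pocketReference()].
#' @return An [SPAnnotation-class] object.
#' @examples
#' fam <- makeFamily(familySpec(n_sp = 2, n_sph = 1, n_trypsin = 1,
#'                              n_chymotrypsin = 1, n_clip_sp = 0,
#'                              n_clip_sph = 0, n_double_clip = 0,
#'                              dup_groups = integer(0), seed = 42))
#' ann <- annotateFamily(fam$proteins)
#' ann
#' @export
annotateFamily <- function(proteins, profiles = triadProfiles(),
                           grammar = clipGrammar(), params = alignParams(),
                           reference = pocketReference()) {
  if (!length(proteins)) stop("no protein sequences supplied")
  seqs <- asSequenceVector(proteins)
  validateProteinSet(unname(seqs), names(seqs))
  ids <- names(seqs)

  triadsL <- clipsL <- vector("list", length(ids))
  names(triadsL) <- names(clipsL) <- ids
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    s <- seqs[[i]]
    triads <- findTriadMotifs(s, profiles)
    clips <- detectClipDomains(s, triads, grammar)
    cls <- classifySpSph(triads, clips)
    first <- if (nrow(triads)) {
      complete <- which(triads$complete)
      triads[if (length(complete)) complete[1L] else 1L, ]
    } else NULL

    res189 <- res216 <- res226 <- NA_character_
    subtype <- NA_character_
    if (cls$class == "SP" && !is.null(first)) {
      pocket <- readPocket(substr(s, first$span_start, nchar(s)),
                           reference, params)
      res189 <- pocket$res189; res216 <- pocket$res216
      res226 <- pocket$res226; subtype <- pocket$subtype
    }

    act <- if (!is.null(first))
      findActivationSite(s, first$span_start)
    else list(motif = NA_character_, motif_start = NA_integer_,
              p1_residue = NA_character_, cascade_position = "unassigned")

    triadsL[[i]] <- triads
    clipsL[[i]] <- clips
    rows[[i]] <- data.frame(
      gene_id = ids[i], class = cls$class, n_trypsp = cls$n_trypsp,
      his_intact = if (!is.null(first)) first$his_intact else FALSE,
      asp_intact = if (!is.null(first)) first$asp_intact else FALSE,
      ser_intact = if (!is.null(first)) first$ser_intact else FALSE,
      n_clip = cls$n_clip,
      clip_groups = paste(clips$group, collapse = ","),
      subtype = subtype, res189 = res189, res216 = res216, res226 = res226,
      activation_motif = act$motif, p1_residue = act$p1_residue,
      cascade_position = act$cascade_position,
      stringsAsFactors = FALSE
    )
  }
  anno <- S4Vectors::DataFrame(do.call(rbind, rows))
  rownames(anno) <- NULL
  methods::new("SPAnnotation", anno = anno, triads = triadsL, clips = clipsL,
               params = list(profiles = profiles, grammar = grammar,
                             align = params[c("gapOpen", "gapExt")]))
}

#' Per-protein annotation table
#'
#' @param x An [SPAnnotation-class].
#' @return The per-protein `DataFrame` (one row per protein).
#' @export
annotationTable <- function(x) {
  stopifnot(is(x, "SPAnnotation"))
  x@anno
}

#' Per-protein triad and clip detail tables
#'
#' @param x An [SPAnnotation-class].
#' @param gene_id Optional single gene id; otherwise the full named list.
#' @return A data.frame (one gene) or named list of data.frames.
#' @export
triadDetails <- function(x, gene_id = NULL) {
  stopifnot(is(x, "SPAnnotation"))
  if (is.null(gene_id)) x@triads else x@triads[[gene_id]]
}

#' @rdname triadDetails
#' @export
clipDetails <- function(x, gene_id = NULL) {
  stopifnot(is(x, "SPAnnotation"))
  if (is.null(gene_id)) x@clips else x@clips[[gene_id]]
}

#' Family-level summary counts
#'
#' @param x An [SPAnnotation-class].
#' @return A list with `n_sp`, `n_sph`, `n_trypsin`, `n_chymotrypsin`,
#'   `n_clip_genes` and `n_clip_domains`.
#' @export
familySummary <- function(x) {
  stopifnot(is(x, "SPAnnotation"))
  a <- x@anno
  list(
    n_sp = sum(a$class == "SP"),
    n_sph = sum(a$class == "SPH"),
    n_trypsin = sum(a$subtype == "trypsin", na.rm = TRUE),
    n_chymotrypsin = sum(a$subtype == "chymotrypsin", na.rm = TRUE),
    n_clip_genes = sum(a$n_clip > 0L),
    n_clip_domains = sum(a$n_clip)
  )
}

#' Write the annotation table as TSV
#'
#' @param x An [SPAnnotation-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAnnotationTsv <- function(x, path) {
  utils::write.table(as.data.frame(annotationTable(x)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Recompute the headline family statistics from supplementary inputs
#'
#' Applies the annotation rules to a user-supplied copy of the published
#' family data and returns the headline numbers: the SP/SPH split from the
#' triad rule, trypsin/chymotrypsin counts from the pocket rule, clip gene
#' and domain counts with their spacing summaries, tandem-duplicated gene
#' counts from the scaffold rule, and expressed-gene counts per tissue.
#' Expected files in `dir` (plain-text conversions of the published
#' supplementary tables): `s2_proteins.fasta` (protein sequences),
#' `s1_genes.gff3` (gene loci; optional) and `s4_tissue_rpkm.tsv` (tissue
#' RPKM matrix; optional).
#'
#' @param dir Directory holding the converted supplementary files.
#' @return A list of headline counts; components are `NA` when the
#'   corresponding input file is absent.
#' @export
supplementaryRecomputation <- function(dir) {
  fa <- file.path(dir, "s2_proteins.fasta")
  if (!file.exists(fa))
    stop("supplementary protein FASTA not found: ", fa)
  proteins <- readProteinFasta(fa)
  ann <- annotateFamily(proteins)
  s <- familySummary(ann)
  clips <- do.call(rbind, clipDetails(ann))
  out <- list(
    n_total = length(proteins),
    n_sp = s$n_sp, n_sph = s$n_sph,
    n_trypsin = s$n_trypsin, n_chymotrypsin = s$n_chymotrypsin,
    n_clip_genes = s$n_clip_genes, n_clip_domains = s$n_clip_domains,
    clip_s23 = if (!is.null(clips)) unique(clips$s23) else integer(0),
    clip_span_max = if (!is.null(clips)) max(clips$span) else NA_integer_,
    n_tandem_genes = NA_integer_,
    expressed_per_tissue = NULL
  )
  gff <- file.path(dir, "s1_genes.gff3")
  if (file.exists(gff)) {
    models <- readGeneModels(gff)
    fam <- intersect(names(proteins),
                     S4Vectors::mcols(models)$gene_id)
    cl <- tandemClusters(fam, models)
    out$n_tandem_genes <- length(unique(unlist(lapply(cl, `[[`, "members"))))
  }
  rpkm <- file.path(dir, "s4_tissue_rpkm.tsv")
  if (file.exists(rpkm)) {
    m <- readExpressionMatrix(rpkm)
    out$expressed_per_tissue <- expressedCounts(m)$per_sample
  }
  out
}

#' Phylogeny of an annotated subset
#'
#' Aligns the chosen proteins with [progressiveMsa()], computes
#' Poisson-corrected distances under pairwise deletion and builds the
#' neighbor-joining tree, optionally with bootstrap supports.
#'
#' @param proteins Named sequences (`AAStringSet` or character).
#' @param subset Ids to include (default all); at least 3.
#' @param bootstrap Number of bootstrap replicates (0 = none).
#' @param seed Seed for the bootstrap resampling.
#' @param params Alignment parameters.
#' @return A list with `alignment`, `distances` and `tree` (an
#'   [ape::phylo]; `node.label` holds supports when `bootstrap > 0`).
#' @export
phyloAnalysis <- function(proteins, subset = NULL, bootstrap = 0L,
                          seed = 1L, params = alignParams()) {
  seqs <- asSequenceVector(proteins)
  if (!is.null(subset)) {
    missing <- setdiff(subset, names(seqs))
    if (length(missing))
      stop("subset id(s) not found: ", paste(missing, collapse = ", "))
    seqs <- seqs[subset]
  }
  if (length(seqs) < 3L) stop("phylogeny needs at least 3 sequences")
  aln <- progressiveMsa(seqs, params)
  dm <- poissonDistance(aln)
  tree <- if (bootstrap > 0L) bootstrapSupport(aln, bootstrap, seed)
          else njTree(dm)
  list(alignment = aln, distances = dm, tree = tree)
}

#' Clustered expression report
#'
#' Log2-transforms an RPKM matrix, clusters the genes (complete linkage,
#' Euclidean distance with missing-value rescaling) and counts expressed
#' genes per sample.
#'
#' @param m RPKM matrix (genes x samples).
#' @param k Optional number of flat groups to cut the dendrogram into.
#' @param threshold Expressed-gene RPKM threshold (strict, default 0).
#' @return A list with `log2` (transformed matrix), `clustering` (`hclust`,
#'   or `NULL` for single-sample input), `groups` (when `k` given) and
#'   `expressed` (from [expressedCounts()]).
#' @export
expressionReport <- function(m, k = NULL, threshold = 0) {
  lg <- log2Transform(m)
  counts <- expressedCounts(m, threshold)
  if (ncol(m) < 2L) {
    return(list(log2 = lg, clustering = NULL, groups = NULL,
                expressed = counts))
  }
  cl <- withCallingHandlers(
    hclusterGenes(lg),
    warning = function(w) invokeRestart("muffleWarning")
  )
  groups <- if (!is.null(k)) cutClusters(cl, k) else NULL
  list(log2 = lg, clustering = cl, groups = groups, expressed = counts)
}
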