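#' Read a protein FASTA file into a validated AAStringSet
#'
#' Wraps [Biostrings::readAAStringSet()] and enforces the conventions used
#' throughout the package: sequences are uppercased, a single trailing stop
#' character (`*`) is stripped, and only the 20 standard amino-acid letters
#' plus the ambiguity code `X` are accepted. Record ids are the first
#' whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @return An [Biostrings::AAStringSet] named by record id.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKTAAHC", ">p2", "mgdsggp*"), fa)
#' readProteinFasta(fa)
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  validateProteinSet(seqs, ids)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

# Shared invariants for a collection of protein sequences.
validateProteinSet <- function(seqs, ids) {
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate record id(s): ", paste(dup, collapse = ", "))
  }
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence for record(s): ", paste(ids[empty], collapse = ", "))
  bad <- grepl(sprintf("[^%s]", AA_ALPHABET_X), seqs)
  if (any(bad))
    stop("non amino-acid characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  invisible(TRUE)
}

# 20 standard residues + ambiguity code X
AA_ALPHABET_X <- "ACDEFGHIKLMNPQRSTVWYX"

#' Write an AAStringSet to FASTA
#'
#' @param x A named [Biostrings::AAStringSet] (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene` and `CDS` features (CDS grouped to genes via their `Parent`
#' attribute, possibly through an intermediate mRNA feature) and returns one
#' gene model per gene: scaffold, strand, gene span and the CDS segments in
#' transcription order (reversed for minus-strand genes). Coordinates stay
#' 1-based inclusive as in GFF.
#'
#' @param path Path to a GFF3 file.
#' @return A [GenomicRanges::GRangesList], one element per gene holding its
#'   CDS exons in transcription order; `S4Vectors::mcols()` of the list
#'   carries `gene_id`, `scaffold`, `gene_strand`, `gene_start`, `gene_end`.
#' @export
readGeneModels <- function(path) {
  if (!file.exists(path)) stop("GFF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", path)
  gid <- as.character(genes$ID)
  if (anyDuplicated(gid)) stop("duplicate gene ids in ", path)

  # map transcript ids to their gene so CDS can point at mRNA parents
  parent_of <- function(x) {
    p <- x$Parent
    vapply(seq_along(x), function(i) {
      pi <- p[[i]]
      if (length(pi) == 0L) NA_character_ else as.character(pi[1L])
    }, character(1))
  }
  tx <- gr[type %in% c("mRNA", "transcript")]
  tx2gene <- if (length(tx)) {
    stats::setNames(parent_of(tx), as.character(tx$ID))
  } else {
    character()
  }

  cds <- gr[type == "CDS"]
  if (length(cds) == 0L) stop("no CDS features in ", path)
  cparent <- parent_of(cds)
  if (anyNA(cparent)) stop("CDS feature without a Parent attribute in ", path)
  hit <- ifelse(cparent %in% gid, cparent,
                unname(tx2gene[cparent]))
  if (anyNA(hit)) {
    orphan <- unique(cparent[is.na(hit)])
    stop("CDS with unknown parent gene: ", paste(orphan, collapse = ", "))
  }

  out <- vector("list", length(gid))
  names(out) <- gid
  for (k in seq_along(gid)) {
    g <- genes[k]
    ck <- cds[hit == gid[k]]
    if (length(ck) == 0L) stop("gene without CDS: ", gid[k])
    if (length(unique(as.character(GenomicRanges::seqnames(ck)))) > 1L ||
        as.character(GenomicRanges::seqnames(ck)[1L]) !=
          as.character(GenomicRanges::seqnames(g)))
      stop("CDS of gene ", gid[k], " span multiple scaffolds")
    minus <- as.character(GenomicRanges::strand(g)) == "-"
    ord <- order(GenomicRanges::start(ck), decreasing = minus)
    ck <- ck[ord]
    if (length(ck) > 1L) {
      st <- sort(GenomicRanges::start(ck))
      en <- sort(GenomicRanges::end(ck))
      if (any(st[-1L] <= en[-length(en)]))
        stop("overlapping CDS segments in gene ", gid[k])
    }
    out[[k]] <- GenomicRanges::granges(ck)
  }
  grl <- GenomicRanges::GRangesList(out)
  # reserved names (start/end/strand) are not allowed as GRangesList mcols
  S4Vectors::mcols(grl) <- S4Vectors::DataFrame(
    gene_id = gid,
    scaffold = as.character(GenomicRanges::seqnames(genes)),
    gene_strand = as.character(GenomicRanges::strand(genes)),
    gene_start = GenomicRanges::start(genes),
    gene_end = GenomicRanges::end(genes)
  )
  grl
}

#' Write gene models back to GFF3
#'
#' Inverse of [readGeneModels()]: emits one `gene` line and its `CDS` lines
#' per model, 1-based inclusive coordinates, CDS parented directly on the
#' gene. `readGeneModels(writeGeneModels(x))` reproduces `x`.
#'
#' @param models A `GRangesList` as returned by [readGeneModels()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(models, path) {
  meta <- S4Vectors::mcols(models)
  lines <- c("##gff-version 3")
  for (k in seq_along(models)) {
    gid <- meta$gene_id[k]
    lines <- c(lines, paste(
      meta$scaffold[k], "spfam", "gene", meta$gene_start[k],
      meta$gene_end[k], ".", meta$gene_strand[k], ".", paste0("ID=", gid),
      sep = "\t"
    ))
    ex <- models[[k]]
    for (i in seq_along(ex)) {
      lines <- c(lines, paste(
        meta$scaffold[k], "spfam", "CDS",
        GenomicRanges::start(ex)[i], GenomicRanges::end(ex)[i], ".",
        meta$gene_strand[k], ".",
        paste0("ID=", gid, ".cds", i, ";Parent=", gid),
        sep = "\t"
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a genes-by-samples RPKM matrix from TSV
#'
#' First column is the gene id, the header row names the samples. Empty cells
#' and the sentinel string (default `"NA"`) become missing values; zeros are
#' data, not missing.
#'
#' @param path Path to a TSV file.
#' @param na Sentinel string treated as missing (besides empty cells).
#' @return A numeric matrix (genes x samples) with `NA` for missing entries.
#' @export
readExpressionMatrix <- function(path, na = "NA") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression table needs a header and data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_expect <- length(fields[[1L]])
  width <- lengths(fields)
  if (any(width != ncol_expect))
    stop("ragged rows in expression table (line ",
         paste(which(width != ncol_expect), collapse = ", "), ")")
  samples <- fields[[1L]][-1L]
  if (anyDuplicated(samples)) stop("duplicate sample labels")
  body <- fields[-1L]
  genes <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(genes)) stop("duplicate gene ids")
  cells <- t(vapply(body, function(f) f[-1L], character(ncol_expect - 1L)))
  if (ncol_expect == 2L) cells <- matrix(cells, ncol = 1L)
  miss <- cells == "" | cells == na
  vals <- suppressWarnings(as.numeric(cells))
  badnum <- !miss & is.na(vals)
  if (any(badnum)) stop("non-numeric expression value(s), e.g. '",
                        cells[which(badnum)[1L]], "'")
  if (any(vals < 0, na.rm = TRUE)) stop("negative RPKM values are invalid")
  vals[miss] <- NA_real_
  m <- matrix(vals, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  m
}

#' Write an RPKM matrix to TSV
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param na Sentinel written for missing values.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(m, path, na = "NA") {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = na)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Expects TSV columns `gene`, `sample`, `replicate`, `Ct`. Ct values must be
#' strictly positive.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the four columns.
#' @export
readQpcrTable <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "sample", "replicate", "Ct")
  if (!all(need %in% names(t)))
    stop("qPCR table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(t$Ct)) || any(t$Ct <= 0))
    stop("Ct values must be finite and > 0")
  t[, need]
}
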