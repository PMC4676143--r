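#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DFrame
NULL

#' Family-wide serine protease annotation
#'
#' Container for the per-protein results of [annotateFamily()]: SP/SPH class,
#' trypsin/chymotrypsin subtype, catalytic-triad status, clip domains with
#' their cysteine spacings and group, S1-pocket readout and zymogen
#' activation-site call. The per-protein detail tables (one triad table and
#' one clip table per protein) are kept alongside the flat summary so that
#' downstream reports can drill into individual domains.
#'
#' @slot anno A [S4Vectors::DataFrame] with one row per protein. Columns:
#'   `gene_id`, `class` ("SP"/"SPH"), `n_trypsp`, `his_intact`, `asp_intact`,
#'   `ser_intact`, `n_clip`, `clip_groups`, `subtype`, `res189`, `res216`,
#'   `res226`, `activation_motif`, `p1_residue`, `cascade_position`.
#' @slot triads Named list of per-protein triad tables (data.frames as
#'   returned by [findTriadMotifs()]).
#' @slot clips Named list of per-protein clip tables (data.frames as returned
#'   by [detectClipDomains()]).
#' @slot params List of the configuration the annotation was run with
#'   (motif profiles, clip grammar, alignment parameters).
#'
#' @seealso [annotateFamily()], [annotationTable()], [familySummary()]
#' @exportClass SPAnnotation
setClass("SPAnnotation",
  slots = c(
    anno = "DFrame",
    triads = "list",
    clips = "list",
    params = "list"
  )
)

setValidity("SPAnnotation", function(object) {
  msg <- character()
  required <- c(
    "gene_id", "class", "n_trypsp", "his_intact", "asp_intact", "ser_intact",
    "n_clip", "clip_groups", "subtype", "res189", "res216", "res226",
    "activation_motif", "p1_residue", "cascade_position"
  )
  missing <- setdiff(required, colnames(object@anno))
  if (length(missing))
    msg <- c(msg, paste("missing annotation columns:",
                        paste(missing, collapse = ", ")))
  if (anyDuplicated(object@anno$gene_id))
    msg <- c(msg, "duplicated gene ids in annotation table")
  if (!all(object@anno$class %in% c("SP", "SPH")))
    msg <- c(msg, "class must be 'SP' or 'SPH'")
  bad <- object@anno$class == "SP" &
    !(object@anno$his_intact & object@anno$asp_intact & object@anno$ser_intact)
  if (any(bad, na.rm = TRUE))
    msg <- c(msg, "SP rows must carry a complete catalytic triad")
  if (length(msg)) msg else TRUE
})

#' @describeIn SPAnnotation Compact per-class and per-subtype summary.
#' @param object An `SPAnnotation`.
#' @export
setMethod("show", "SPAnnotation", function(object) {
  s <- familySummary(object)
  cat("SPAnnotation with", nrow(object@anno), "proteins\n")
  cat("  SP:", s$n_sp, "  SPH:", s$n_sph, "\n")
  cat("  trypsin:", s$n_trypsin, "  chymotrypsin:", s$n_chymotrypsin,
      "  other SP:", s$n_sp - s$n_trypsin - s$n_chymotrypsin, "\n")
  cat("  clip-bearing proteins:", s$n_clip_genes,
      " (", s$n_clip_domains, "clip domains )\n")
})
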