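#' Load the packaged S1-pocket numbering anchor
#'
#' Bovine chymotrypsinogen A is shipped as the reference for reading the
#' primary substrate-binding (S1) pocket: positions 189, 216 and 226 in
#' chymotrypsinogen numbering determine trypsin vs chymotrypsin specificity.
#' The FASTA sequence and a JSON sidecar with the annotated positions live
#' under `inst/extdata/`.
#'
#' @return A list with `id`, `seq` (character), and integer `positions`
#'   (`res189`, `res216`, `res226`).
#' @export
pocketReference <- function() {
  fa <- system.file("extdata", "chymotrypsinogen_A_bovine.fasta",
                    package = "spfam", mustWork = TRUE)
  js <- system.file("extdata", "chymotrypsinogen_A_positions.json",
                    package = "spfam", mustWork = TRUE)
  aa <- readProteinFasta(fa)
  meta <- jsonlite::read_json(js)
  list(
    id = meta$id,
    seq = as.character(aa[[1L]]),
    positions = c(res189 = meta$pocket$res189,
                  res216 = meta$pocket$res216,
                  res226 = meta$pocket$res226)
  )
}

#' Read the S1-pocket residues of a protease domain
#'
#' Globally aligns the trypsin-like domain of a protein to the packaged
#' chymotrypsinogen A anchor and reports the residues aligned opposite
#' reference positions 189, 216 and 226. A gap opposite a key position reads
#' out as `"-"`. If fewer than half of the reference residues are covered by
#' (aligned to a residue of) the query, the call is returned unassigned with
#' a warning.
#'
#' @param seq Protein sequence (ideally trimmed to the trypsin-like span
#'   plus its zymogen region; see [annotateFamily()]).
#' @param reference Anchor from [pocketReference()].
#' @param params Alignment parameters, default [alignParams()].
#' @return A list with `res189`, `res216`, `res226` (single letters or
#'   `"-"`), `coverage` (fraction of reference residues aligned), and
#'   `subtype` from [callSubtype()] (`"unassigned"` when coverage < 0.5).
#' @export
readPocket <- function(seq, reference = pocketReference(),
                       params = alignParams()) {
  seq <- asSingleSequence(seq)
  al <- globalAlign(seq, reference$seq, params)$alignment
  q <- strsplit(al[[1L]], "")[[1L]]
  r <- strsplit(al[[2L]], "")[[1L]]
  refcols <- which(r != "-")       # alignment column of each reference residue
  coverage <- mean(q[refcols] != "-")
  res <- vapply(reference$positions, function(p) q[refcols[p]], character(1))
  names(res) <- names(reference$positions)
  if (coverage < 0.5) {
    warning("reference coverage ", sprintf("%.2f", coverage),
            " < 0.5; pocket call unassigned")
    return(list(res189 = res[["res189"]], res216 = res[["res216"]],
                res226 = res[["res226"]], coverage = coverage,
                subtype = "unassigned"))
  }
  list(res189 = res[["res189"]], res216 = res[["res216"]],
       res226 = res[["res226"]], coverage = coverage,
       subtype = callSubtype(res[["res189"]], res[["res216"]], res[["res226"]]))
}

#' Trypsin/chymotrypsin call from the S1-pocket residue triple
#'
#' Trypsin requires Asp189, Gly216 and Gly/Ala/Ser at 226. Chymotrypsin is
#' the same pocket with position 189 replaced by Ser/Thr/Gly. Everything
#' else — including a gap at a key position — is `"other"`.
#'
#' @param res189,res216,res226 Single characters (residue or `"-"`).
#' @return `"trypsin"`, `"chymotrypsin"` or `"other"`.
#' @examples
#' callSubtype("D", "G", "G") # trypsin
#' callSubtype("S", "G", "S") # chymotrypsin
#' callSubtype("K", "G", "G") # other
#' @export
callSubtype <- function(res189, res216, res226) {
  if (res216 == "G" && res226 %in% c("G", "A", "S")) {
    if (res189 == "D") return("trypsin")
    if (res189 %in% c("S", "T", "G")) return("chymotrypsin")
  }
  "other"
}

#' Locate the zymogen activation site
#'
#' Scans a window around the start of the trypsin-like span (30 residues
#' upstream through 10 residues in) for the best match to the activation
#' motif family `[IVLF][IVLN][GN]G` (IVGG and the reported variants IIGG and
#' IING fall inside it). Candidate matches are ranked by agreement with the
#' canonical IVGG, then by proximity to the span start, then leftmost. The
#' residue immediately preceding the motif is the P1 cleavage residue:
#' Arg/Lys marks a terminal proteinase of the cascade, Leu/His/Ser a
#' penultimate one, anything else is unassigned.
#'
#' @param seq Protein sequence.
#' @param spanStart 1-based position where the trypsin-like span starts
#'   (e.g. `his_pos` region from [findTriadMotifs()]; the window is taken
#'   relative to this).
#' @param pattern List of allowed residue sets for the 4-mer motif.
#' @return A list with `motif` (matched 4-mer or `NA`), `motif_start`,
#'   `p1_residue` and `cascade_position`
#'   (`"terminal"`/`"penultimate"`/`"unassigned"`).
#' @export
findActivationSite <- function(seq, spanStart,
                               pattern = list(c("I", "V", "L", "F"),
                                              c("I", "V", "L", "N"),
                                              c("G", "N"), "G")) {
  seq <- asSingleSequence(seq)
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  lo <- max(1L, spanStart - 30L)
  hi <- min(n - 3L, spanStart + 10L)
  unassigned <- list(motif = NA_character_, motif_start = NA_integer_,
                     p1_residue = NA_character_,
                     cascade_position = "unassigned")
  if (hi < lo) return(unassigned)
  canonical <- c("I", "V", "G", "G")
  best <- NULL
  for (s in lo:hi) {
    w <- chars[s:(s + 3L)]
    ok <- all(vapply(1:4, function(k) w[k] %in% pattern[[k]], logical(1)))
    if (!ok) next
    score <- sum(w == canonical)
    dist <- abs(s - spanStart)
    if (is.null(best) || score > best$score ||
        (score == best$score && dist < best$dist)) {
      best <- list(s = s, w = w, score = score, dist = dist)
    }
  }
  if (is.null(best)) return(unassigned)
  p1 <- if (best$s > 1L) chars[best$s - 1L] else NA_character_
  cascade <- if (is.na(p1)) "unassigned"
  else if (p1 %in% c("R", "K")) "terminal"
  else if (p1 %in% c("L", "H", "S")) "penultimate"
  else "unassigned"
  list(motif = paste(best$w, collapse = ""), motif_start = best$s,
       p1_residue = p1, cascade_position = cascade)
}
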