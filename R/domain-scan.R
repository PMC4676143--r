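#' Default catalytic-triad motif profiles
#'
#' The His, Asp and Ser of the catalytic triad sit in the conserved motifs
#' TAAHC, DIAL and GDSGGP. Exact-match scanning would miss real family
#' members, so each motif is a short positional profile anchored on the
#' catalytic residue: the non-anchor positions must fall in the allowed set,
#' while the anchor position may hold any standard residue — the motif is
#' *intact* only when the anchor actually carries the catalytic residue.
#' This is what lets a knocked-out triad (e.g. GDSGGP -> GDAGGP) still be
#' located and reported as broken. The ambiguity code `X` matches no profile
#' position.
#'
#' @return A list with components `his`, `asp`, `ser`; each has `positions`
#'   (list of allowed residue sets, `NA` marking the anchor), `anchor`
#'   (1-based offset of the catalytic residue in the motif) and `catalytic`
#'   (the residue required for intactness).
#' @examples
#' str(triadProfiles())
#' @export
triadProfiles <- function() {
  list(
    his = list(
      positions = list(c("S", "T"), c("A", "G"), c("A", "G"), NA, "C"),
      anchor = 4L, catalytic = "H"
    ),
    asp = list(
      positions = list(NA, c("I", "V", "L", "M"), c("A", "G"),
                       c("L", "I", "V", "M")),
      anchor = 1L, catalytic = "D"
    ),
    ser = list(
      positions = list("G", c("D", "N"), NA, "G", c("G", "S"),
                       c("P", "S", "A")),
      anchor = 3L, catalytic = "S"
    )
  )
}

# All windows of `seq` matching one anchored profile.
# Returns data.frame(start, end, anchor_pos, anchor_res, match, intact).
matchProfile <- function(seq, profile) {
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  w <- length(profile$positions)
  empty <- data.frame(start = integer(), end = integer(),
                      anchor_pos = integer(), anchor_res = character(),
                      match = character(), intact = logical(),
                      stringsAsFactors = FALSE)
  if (n < w) return(empty)
  ok <- rep(TRUE, n - w + 1L)
  for (k in seq_len(w)) {
    allowed <- profile$positions[[k]]
    colk <- chars[k:(n - w + k)]
    if (k == profile$anchor) {
      # anchor: any standard residue locates the motif; X never does
      ok <- ok & colk != "X"
    } else {
      ok <- ok & colk %in% allowed
    }
  }
  starts <- which(ok)
  if (!length(starts)) return(empty)
  anchor_pos <- starts + profile$anchor - 1L
  data.frame(
    start = starts,
    end = starts + w - 1L,
    anchor_pos = anchor_pos,
    anchor_res = chars[anchor_pos],
    match = vapply(starts, function(s)
      paste(chars[s:(s + w - 1L)], collapse = ""), character(1)),
    intact = chars[anchor_pos] == profile$catalytic,
    stringsAsFactors = FALSE
  )
}

#' Locate catalytic-triad motifs in a protein
#'
#' Scans for the anchored His/Asp/Ser motif profiles (see [triadProfiles()])
#' and assembles them left to right into trypsin-like protease (Tryp_SPc)
#' spans: a span starts at a His-motif hit, takes the first Asp-motif hit
#' downstream of the His anchor and the first Ser-motif hit downstream of
#' that; the next span is sought after the Ser motif, so multi-domain
#' proteins yield multiple non-overlapping rows. A triad is `complete` only
#' when all three catalytic anchors are intact.
#'
#' @param seq A protein sequence (character scalar, or a single-element
#'   `AAStringSet`/`AAString`).
#' @param profiles Motif profiles, default [triadProfiles()].
#' @return A data.frame with one row per detected span: `his_pos`,
#'   `his_match`, `his_intact`, `asp_pos`, `asp_match`, `asp_intact`,
#'   `ser_pos`, `ser_match`, `ser_intact`, `span_start`, `span_end`,
#'   `complete`. Zero rows when no His motif is found.
#' @examples
#' s <- paste0(strrep("A", 20), "TAAHC", strrep("L", 30), "DIAL",
#'             strrep("K", 40), "GDSGGP", strrep("A", 10))
#' findTriadMotifs(s)
#' @export
findTriadMotifs <- function(seq, profiles = triadProfiles()) {
  seq <- asSingleSequence(seq)
  empty <- data.frame(
    his_pos = integer(), his_match = character(), his_intact = logical(),
    asp_pos = integer(), asp_match = character(), asp_intact = logical(),
    ser_pos = integer(), ser_match = character(), ser_intact = logical(),
    span_start = integer(), span_end = integer(), complete = logical(),
    stringsAsFactors = FALSE
  )
  if (nchar(seq) < 50L) return(empty)
  his <- matchProfile(seq, profiles$his)
  asp <- matchProfile(seq, profiles$asp)
  ser <- matchProfile(seq, profiles$ser)
  rows <- list()
  cursor <- 1L
  repeat {
    h <- his[his$start >= cursor, , drop = FALSE]
    if (!nrow(h)) break
    h <- h[1L, ]
    a <- asp[asp$anchor_pos > h$anchor_pos, , drop = FALSE]
    a <- if (nrow(a)) a[1L, ] else NULL
    s_from <- if (is.null(a)) h$anchor_pos else a$anchor_pos
    s <- ser[ser$anchor_pos > s_from, , drop = FALSE]
    s <- if (nrow(s)) s[1L, ] else NULL
    rows[[length(rows) + 1L]] <- data.frame(
      his_pos = h$anchor_pos, his_match = h$match, his_intact = h$intact,
      asp_pos = if (is.null(a)) NA_integer_ else a$anchor_pos,
      asp_match = if (is.null(a)) NA_character_ else a$match,
      asp_intact = if (is.null(a)) FALSE else a$intact,
      ser_pos = if (is.null(s)) NA_integer_ else s$anchor_pos,
      ser_match = if (is.null(s)) NA_character_ else s$match,
      ser_intact = if (is.null(s)) FALSE else s$intact,
      # the trypsin-like domain starts ~41 residues upstream of the
      # catalytic His (chymotrypsinogen numbering: domain 16, His 57);
      # span_start anchors the clip search region and the pocket alignment
      span_start = max(1L, h$start - 41L),
      span_end = if (is.null(s)) nchar(seq) else s$anchor_pos + 3L,
      stringsAsFactors = FALSE
    )
    cursor <- if (is.null(s)) nchar(seq) + 1L else s$anchor_pos + 4L
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$complete <- out$his_intact & out$asp_intact & out$ser_intact
  out
}

#' Classify a protein as SP or SPH
#'
#' A protein is a serine protease (SP) when at least one of its trypsin-like
#' domains carries a complete His/Asp/Ser catalytic triad; otherwise it is a
#' serine protease homolog (SPH).
#'
#' @param triads Triad table from [findTriadMotifs()].
#' @param clips Optional clip table from [detectClipDomains()]; used only to
#'   fill the clip count.
#' @return A list with `class` ("SP"/"SPH"), `n_trypsp` (number of detected
#'   trypsin-like spans) and `n_clip`.
#' @export
classifySpSph <- function(triads, clips = NULL) {
  list(
    class = if (nrow(triads) && any(triads$complete)) "SP" else "SPH",
    n_trypsp = nrow(triads),
    n_clip = if (is.null(clips)) 0L else nrow(clips)
  )
}

#' Default clip-domain spacing grammar
#'
#' A clip domain is six cysteines with a characteristic spacing: Cys-5 and
#' Cys-6 adjacent, exactly five residues between Cys-2 and Cys-3, and an
#' overall Cys-1..Cys-6 span of 37-55 residues (counted strictly between the
#' two cysteines). The Cys-3..Cys-4 spacing separates group 1 (8-17) from
#' group 2 (22-26). The Cys-4..Cys-5 spacing has no canonical published
#' bound; the default [2,20] is wide enough to admit both groups and is
#' configurable. `span_counting` switches the 37-55 bound between the count
#' strictly between Cys-1 and Cys-6 (`"between"`, default) and the inclusive
#' Cys-1..Cys-6 residue count (`"inclusive"`).
#'
#' @return A list of integer ranges `s12`, `s23`, `s34`, `s45`, `span`,
#'   group ranges `group1`, `group2`, and `span_counting`.
#' @export
clipGrammar <- function() {
  list(
    s12 = c(2L, 10L),
    s23 = c(5L, 5L),
    s34 = c(8L, 26L),
    s45 = c(2L, 20L),
    span = c(37L, 55L),
    group1 = c(8L, 17L),
    group2 = c(22L, 26L),
    span_counting = "between"
  )
}

#' Detect clip domains by the six-cysteine spacing grammar
#'
#' Searches the region N-terminal to the first trypsin-like span (the whole
#' sequence when there is none) for six-cysteine placements satisfying the
#' grammar. Candidates are taken leftmost-first and non-overlapping, so a
#' protein with two cassettes in tandem reports both.
#'
#' @param seq Protein sequence.
#' @param triads Triad table from [findTriadMotifs()]; bounds the search
#'   region so no clip can overlap a catalytic domain.
#' @param grammar Spacing grammar, default [clipGrammar()].
#' @return A data.frame with one row per clip: `c1`..`c6` (cysteine
#'   positions), `s12`, `s23`, `s34`, `s45`, `span`, `group`.
#' @export
detectClipDomains <- function(seq, triads = findTriadMotifs(seq),
                              grammar = clipGrammar()) {
  seq <- asSingleSequence(seq)
  empty <- data.frame(
    c1 = integer(), c2 = integer(), c3 = integer(), c4 = integer(),
    c5 = integer(), c6 = integer(), s12 = integer(), s23 = integer(),
    s34 = integer(), s45 = integer(), span = integer(), group = character(),
    stringsAsFactors = FALSE
  )
  lim <- if (nrow(triads)) min(triads$span_start) - 1L else nchar(seq)
  if (lim < 6L) return(empty)
  chars <- strsplit(substr(seq, 1L, lim), "")[[1L]]
  cys <- which(chars == "C")
  if (length(cys) < 6L) return(empty)

  inR <- function(x, r) x >= r[1L] & x <= r[2L]
  spanOf <- function(c1, c6) {
    if (identical(grammar$span_counting, "inclusive")) c6 - c1 + 1L
    else c6 - c1 - 1L
  }
  cand <- list()
  # adjacent pairs are the rare element: anchor enumeration on Cys-5/Cys-6
  adj <- which(diff(cys) == 1L)
  for (i5 in adj) {
    c5 <- cys[i5]; c6 <- cys[i5 + 1L]
    for (c4 in cys[cys < c5]) {
      if (!inR(c5 - c4 - 1L, grammar$s45)) next
      for (c3 in cys[cys < c4]) {
        if (!inR(c4 - c3 - 1L, grammar$s34)) next
        for (c2 in cys[cys < c3]) {
          if (!inR(c3 - c2 - 1L, grammar$s23)) next
          for (c1 in cys[cys < c2]) {
            if (!inR(c2 - c1 - 1L, grammar$s12)) next
            if (!inR(spanOf(c1, c6), grammar$span)) next
            cand[[length(cand) + 1L]] <- c(c1, c2, c3, c4, c5, c6)
          }
        }
      }
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 1L], cand[, 6L]), , drop = FALSE]
  # leftmost-first, non-overlapping
  chosen <- list()
  busyEnd <- 0L
  for (r in seq_len(nrow(cand))) {
    if (cand[r, 1L] > busyEnd) {
      chosen[[length(chosen) + 1L]] <- cand[r, ]
      busyEnd <- cand[r, 6L]
    }
  }
  chosen <- do.call(rbind, chosen)
  out <- data.frame(
    c1 = chosen[, 1L], c2 = chosen[, 2L], c3 = chosen[, 3L],
    c4 = chosen[, 4L], c5 = chosen[, 5L], c6 = chosen[, 6L],
    stringsAsFactors = FALSE
  )
  out$s12 <- out$c2 - out$c1 - 1L
  out$s23 <- out$c3 - out$c2 - 1L
  out$s34 <- out$c4 - out$c3 - 1L
  out$s45 <- out$c5 - out$c4 - 1L
  out$span <- if (identical(grammar$span_counting, "inclusive"))
    out$c6 - out$c1 + 1L else out$c6 - out$c1 - 1L
  out$group <- vapply(out$s34, assignClipGroup, character(1),
                      grammar = grammar)
  out
}

#' Assign a clip domain to group 1 or group 2
#'
#' Group membership is decided by the Cys-3..Cys-4 spacing: group 1 spans
#' 8-17 residues, group 2 spans 22-26; spacings in the gap between the two
#' ranges are left unassigned.
#'
#' @param s34 Residue count strictly between Cys-3 and Cys-4.
#' @param grammar Grammar with `group1`/`group2` ranges.
#' @return `"1"`, `"2"` or `"unassigned"`.
#' @examples
#' assignClipGroup(17) # "1"
#' assignClipGroup(22) # "2"
#' assignClipGroup(20) # "unassigned"
#' @export
assignClipGroup <- function(s34, grammar = clipGrammar()) {
  if (s34 >= grammar$group1[1L] && s34 <= grammar$group1[2L]) return("1")
  if (s34 >= grammar$group2[1L] && s34 <= grammar$group2[2L]) return("2")
  "unassigned"
}

# Accept character scalar, AAString or 1-element AAStringSet.
asSingleSequence <- function(seq) {
  if (is(seq, "AAStringSet")) {
    if (length(seq) != 1L) stop("expected a single sequence")
    return(as.character(seq[[1L]]))
  }
  if (is(seq, "AAString")) return(as.character(seq))
  if (!is.character(seq) || length(seq) != 1L)
    stop("expected a single protein sequence")
  seq
}
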