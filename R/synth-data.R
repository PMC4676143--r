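#' Specification of a synthetic SP/SPH family
#'
#' Defaults mirror the composition of the diamondback-moth family that
#' motivates the package: 221 genes split into 120 SPs (38 trypsins, 8
#' chymotrypsins, 10 clip-bearing, the rest unclassified pockets) and 101
#' SPHs (3 clip-bearing), with one clip gene carrying two clip domains for a
#' total of 14. Trypsins include five duplicate groups of sizes 5/5/4/4/2
#' (20 genes) destined for tandem clusters on scaffolds.
#'
#' @param n_sp,n_sph Class counts.
#' @param n_trypsin,n_chymotrypsin Pocket subtypes among the SPs.
#' @param n_clip_sp,n_clip_sph Clip-bearing counts per class.
#' @param n_double_clip How many clip-SP genes carry two clip domains.
#' @param dup_groups Integer vector of trypsin duplicate-group sizes.
#' @param mutation_rate Per-residue divergence applied within duplicate
#'   groups and as background variation (never touching planted features).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated list of class `familySpec`.
#' @export
familySpec <- function(n_sp = 120L, n_sph = 101L, n_trypsin = 38L,
                       n_chymotrypsin = 8L, n_clip_sp = 10L,
                       n_clip_sph = 3L, n_double_clip = 1L,
                       dup_groups = c(5L, 5L, 4L, 4L, 2L),
                       mutation_rate = 0.05, seed = 1L) {
  spec <- list(n_sp = as.integer(n_sp), n_sph = as.integer(n_sph),
               n_trypsin = as.integer(n_trypsin),
               n_chymotrypsin = as.integer(n_chymotrypsin),
               n_clip_sp = as.integer(n_clip_sp),
               n_clip_sph = as.integer(n_clip_sph),
               n_double_clip = as.integer(n_double_clip),
               dup_groups = as.integer(dup_groups),
               mutation_rate = mutation_rate, seed = as.integer(seed))
  if (spec$n_trypsin + spec$n_chymotrypsin + spec$n_clip_sp > spec$n_sp)
    stop("trypsin + chymotrypsin + clip-SP counts exceed n_sp")
  if (spec$n_clip_sph > spec$n_sph)
    stop("clip-SPH count exceeds n_sph")
  if (spec$n_double_clip > spec$n_clip_sp)
    stop("double-clip count exceeds clip-SP count")
  if (sum(spec$dup_groups) > spec$n_trypsin)
    stop("duplicate groups exceed trypsin count")
  if (spec$mutation_rate < 0 || spec$mutation_rate > 0.3)
    stop("mutation_rate must be in [0, 0.3]")
  class(spec) <- "familySpec"
  spec
}

# Background amino-acid frequencies (approximate proteome composition,
# fixed so spurious-motif rates are a stable, measurable property).
BG_FREQ <- c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9, E = 6.7,
             G = 7.1, H = 2.3, I = 5.9, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
             P = 4.7, S = 6.6, T = 5.4, W = 1.1, Y = 2.9, V = 6.9)

# sample n background residues, optionally excluding letters; in regions
# N-terminal to the catalytic domain C/S/T are excluded so that no cysteine
# topology and no window of the His motif can arise by chance there
bgSample <- function(n, exclude = character()) {
  f <- BG_FREQ[setdiff(names(BG_FREQ), exclude)]
  sample(names(f), n, replace = TRUE, prob = f / sum(f))
}

# Domain template: bovine chymotrypsinogen A with the single substitution
# T104A so the Asp motif reads DIAL. Planted features are edited in at
# fixed template positions (chymotrypsinogen numbering = template index).
domainTemplate <- function() {
  tpl <- pocketReference()$seq
  chars <- strsplit(tpl, "")[[1L]]
  chars[104L] <- "A"
  chars
}

TPL_POS <- list(p1 = 15L, motif = 16:19, his = 57L, asp = 102L, ser = 195L,
                res189 = 189L, res216 = 216L, res226 = 226L,
                his_window = 54:58, asp_window = 102:105, ser_window = 193:198)

# Build one protein and its truth row.
# knockout: "none" or one of "his"/"asp"/"ser"
buildProtein <- function(pocket, knockout, p1, motif, nClip, clipGroups,
                         mutation_rate) {
  dom <- domainTemplate()
  dom[TPL_POS$res189] <- pocket[1L]
  dom[TPL_POS$res216] <- pocket[2L]
  dom[TPL_POS$res226] <- pocket[3L]
  dom[TPL_POS$p1] <- p1
  dom[TPL_POS$motif] <- strsplit(motif, "")[[1L]]
  koPos <- NA_integer_
  if (knockout != "none") {
    koPos <- TPL_POS[[knockout]]
    target <- c(his = "H", asp = "D", ser = "S")[[knockout]]
    dom[koPos] <- sample(setdiff(c("A", "N", "Q", "V", "E", "K", "G"),
                                 target), 1L)
  }

  clips <- list()
  nterm <- character(0)
  cysOff <- integer(0)   # cassette cysteine offsets within nterm
  if (nClip > 0L) {
    for (k in seq_len(nClip)) {
      cassette <- makeClipCassette(clipGroups[k])
      clips[[k]] <- cassette
      cysOff <- c(cysOff, length(nterm) + cassette$cys)
      nterm <- c(nterm, cassette$chars)
      if (k < nClip)   # >= 56 so no cross-cassette chain can satisfy the span
        nterm <- c(nterm, bgSample(sample(56:80, 1L), c("C", "S", "T")))
    }
    nterm <- c(nterm, bgSample(sample(10:60, 1L), c("C", "S", "T")))
  } else {
    nterm <- bgSample(sample(5L:30L, 1L), c("C", "S", "T"))
  }
  lead <- bgSample(sample(0:8, 1L), c("C", "S", "T"))
  chars <- c(lead, nterm, dom)
  offset_dom <- length(lead) + length(nterm)

  protected <- offset_dom + unlist(TPL_POS[c("p1", "motif", "his_window",
                                             "asp_window", "ser_window",
                                             "res189", "res216", "res226")])
  if (length(cysOff)) protected <- c(protected, length(lead) + cysOff)
  if (!is.na(koPos)) protected <- c(protected, offset_dom + koPos)
  chars <- mutateBackground(chars, offset_dom, protected, mutation_rate)
  chars <- clearActivationDecoys(chars, offset_dom)
  parts <- list(chars = chars, offset_dom = offset_dom,
                protected = protected)

  truth <- list(
    class = if (knockout == "none") "SP" else "SPH",
    subtype = if (knockout == "none")
      callSubtype(pocket[1L], pocket[2L], pocket[3L]) else NA_character_,
    knockout = knockout,
    his_intact = knockout != "his",
    asp_intact = knockout != "asp",
    ser_intact = knockout != "ser",
    n_clip = nClip,
    clip_groups = paste(clipGroups, collapse = ","),
    res189 = pocket[1L], res216 = pocket[2L], res226 = pocket[3L],
    activation_motif = motif, p1_residue = p1,
    cascade_position = if (p1 %in% c("R", "K")) "terminal"
    else if (p1 %in% c("L", "H", "S")) "penultimate" else "unassigned"
  )
  list(seq = paste(chars, collapse = ""), truth = truth, parts = parts)
}

# a duplicate-group member: the founder's sequence with additional light
# within-group divergence (40% of the founder rate), same truth labels
duplicateFrom <- function(founder, mutation_rate) {
  chars <- mutateBackground(founder$parts$chars, founder$parts$offset_dom,
                            founder$parts$protected, mutation_rate * 0.4)
  chars <- clearActivationDecoys(chars, founder$parts$offset_dom)
  list(seq = paste(chars, collapse = ""), truth = founder$truth,
       parts = founder$parts)
}

# Background or mutation can create activation-family 4-mers inside the
# scan window that would outrank the planted site; break each decoy at its
# final position (the obligatory G) so planted truth stays unambiguous.
# The planted motif and P1 residue are never touched: matching windows
# cannot overlap them from the left (the residue sets exclude it), and
# windows whose final position falls inside the planted motif are skipped.
clearActivationDecoys <- function(chars, offset_dom) {
  pat <- list(c("I", "V", "L", "F"), c("I", "V", "L", "N"),
              c("G", "N"), "G")
  spanStart <- offset_dom + 13L
  plant <- offset_dom + 16L
  lo <- max(1L, spanStart - 30L)
  hi <- min(length(chars) - 3L, spanStart + 10L)
  if (hi < lo) return(chars)
  profs <- triadProfiles()
  for (s in lo:hi) {
    if (s == plant) next
    w <- chars[s:(s + 3L)]
    if (!all(vapply(1:4, function(k) w[k] %in% pat[[k]], logical(1)))) next
    pos <- s + 3L
    if (pos >= plant && pos <= plant + 3L) next
    old <- chars[pos]
    chars[pos] <- "Q"
    if (pos > offset_dom && anyProfileMatchAround(chars, pos, profs)) {
      chars[pos] <- "E"
      if (anyProfileMatchAround(chars, pos, profs)) chars[pos] <- old
    }
  }
  chars
}

# One clip cassette: C x^s12 C x^5 C x^s34 C x^s45 C C with the span
# (residues strictly between Cys-1 and Cys-6) drawn from [43, 53] and the
# Cys-3..Cys-4 spacing from the requested group range. Spacer residues
# exclude C (topology stays unambiguous) and S/T (no His-motif window can
# start in the cassette).
makeClipCassette <- function(group) {
  g34 <- if (group == "1") 14:17 else 22:25
  repeat {
    s12 <- sample(2:10, 1L)
    s34 <- sample(g34, 1L)
    span <- sample(43:53, 1L)
    s45 <- span - 4L - s12 - 5L - s34
    if (s45 >= 2L && s45 <= 20L) break
  }
  chars <- c("C", bgSample(s12, c("C", "S", "T")),
             "C", bgSample(5L, c("C", "S", "T")),
             "C", bgSample(s34, c("C", "S", "T")),
             "C", bgSample(s45, c("C", "S", "T")),
             "C", "C")
  cys <- cumsum(c(1L, s12 + 1L, 6L, s34 + 1L, s45 + 1L, 1L))
  list(chars = chars, cys = cys, s34 = s34, span = span, group = group)
}

# Background mutations at `rate`: positions before the domain draw from the
# restricted alphabet; domain positions accept a replacement only when no
# window overlapping it matches any triad profile (so planted truth labels
# stay unambiguous). Planted-feature positions are never touched.
mutateBackground <- function(chars, offset_dom, protected, rate) {
  if (rate <= 0) return(chars)
  n <- length(chars)
  candidates <- setdiff(seq_len(n), protected)
  hit <- candidates[stats::runif(length(candidates)) < rate]
  profs <- triadProfiles()
  for (p in hit) {
    if (p <= offset_dom) {
      chars[p] <- bgSample(1L, c("C", "S", "T"))
    } else {
      for (try in seq_len(10L)) {
        cand <- bgSample(1L)
        old <- chars[p]
        chars[p] <- cand
        if (!anyProfileMatchAround(chars, p, profs)) break
        chars[p] <- old
      }
    }
  }
  chars
}

anyProfileMatchAround <- function(chars, p, profs) {
  n <- length(chars)
  for (pr in profs) {
    w <- length(pr$positions)
    for (s in max(1L, p - w + 1L):min(p, n - w + 1L)) {
      ok <- TRUE
      for (k in seq_len(w)) {
        ch <- chars[s + k - 1L]
        if (k == pr$anchor) {
          if (ch == "X") { ok <- FALSE; break }
        } else if (!(ch %in% pr$positions[[k]])) { ok <- FALSE; break }
      }
      if (ok) return(TRUE)
    }
  }
  FALSE
}

#' Generate a synthetic SP/SPH protein family with ground truth
#'
#' Each protein is assembled from a scaffold: an optional clip cassette (or
#' two) with spacings drawn inside the detection grammar, a linker, and a
#' trypsin-like domain built on the chymotrypsinogen A template with the
#' catalytic-triad motifs, the S1-pocket triple, and the activation
#' site/motif edited in at their canonical positions. SPHs get exactly one
#' catalytic residue randomised; background positions diverge at
#' `mutation_rate` under guards that prevent spurious motif or cysteine
#' topology. The returned manifest is the single source of truth that
#' recovery tests compare annotations against.
#'
#' @param spec A [familySpec()].
#' @return A list with `proteins` (named `AAStringSet`) and `manifest`
#'   (data.frame, one row per gene: class, subtype, triad status, clips,
#'   pocket triple, activation call, duplicate group).
#' @export
makeFamily <- function(spec = familySpec()) {
  stopifnot(inherits(spec, "familySpec"))
  set.seed(spec$seed)
  nTotal <- spec$n_sp + spec$n_sph
  ids <- sprintf("SPX%03d", seq_len(nTotal))

  # role layout: trypsins, chymotrypsins, clip-SPs, other SPs, then SPHs
  roles <- c(rep("trypsin", spec$n_trypsin),
             rep("chymotrypsin", spec$n_chymotrypsin),
             rep("clip_sp", spec$n_clip_sp),
             rep("other_sp", spec$n_sp - spec$n_trypsin -
                   spec$n_chymotrypsin - spec$n_clip_sp),
             rep("sph", spec$n_sph))
  dupGroup <- rep(NA_integer_, nTotal)
  at <- 1L
  for (g in seq_along(spec$dup_groups)) {
    dupGroup[at:(at + spec$dup_groups[g] - 1L)] <- g
    at <- at + spec$dup_groups[g]
  }

  seqs <- character(nTotal)
  rows <- vector("list", nTotal)
  founders <- list()
  nClipSph <- 0L
  for (i in seq_len(nTotal)) {
    role <- roles[i]
    pocket <- switch(role,
      trypsin = c("D", "G", sample(c("G", "A", "S"), 1L)),
      chymotrypsin = c(sample(c("S", "T", "G"), 1L), "G",
                       sample(c("G", "A", "S"), 1L)),
      c(sample(c("N", "Q", "E", "K"), 1L), "G", "G")
    )
    knockout <- if (role == "sph") sample(c("his", "asp", "ser"), 1L)
                else "none"
    nClip <- 0L
    clipGroups <- character(0)
    if (role == "clip_sp") {
      clipIdx <- i - spec$n_trypsin - spec$n_chymotrypsin
      nClip <- if (clipIdx <= spec$n_double_clip) 2L else 1L
      clipGroups <- sample(c("1", "2"), nClip, replace = TRUE)
    } else if (role == "sph" && nClipSph < spec$n_clip_sph) {
      nClipSph <- nClipSph + 1L
      nClip <- 1L
      clipGroups <- sample(c("1", "2"), 1L)
    }
    p1 <- sample(c("R", "R", "R", "K", "K", "L", "H", "S", "Y", "F"), 1L)
    motif <- sample(c("IVGG", "IVGG", "IVGG", "IIGG", "IING"), 1L)
    gKey <- as.character(dupGroup[i])
    built <- if (!is.na(dupGroup[i]) && !is.null(founders[[gKey]])) {
      duplicateFrom(founders[[gKey]], spec$mutation_rate)
    } else {
      buildProtein(pocket, knockout, p1, motif, nClip, clipGroups,
                   spec$mutation_rate)
    }
    if (!is.na(dupGroup[i]) && is.null(founders[[gKey]]))
      founders[[gKey]] <- built
    seqs[i] <- built$seq
    rows[[i]] <- c(list(gene_id = ids[i], role = role,
                        dup_group = dupGroup[i]), built$truth)
  }
  manifest <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  proteins <- Biostrings::AAStringSet(seqs)
  names(proteins) <- ids
  list(proteins = proteins, manifest = manifest)
}

#' Place a synthetic family on scaffolds with planted tandem clusters
#'
#' Duplicate groups from the manifest become tandem clusters: each group is
#' laid out on its own scaffold with 0..`maxIntervening` filler genes between
#' consecutive members. Remaining family genes are placed as scaffold
#' singletons (with flanking fillers), and `n_wide_pairs` scaffolds carry two
#' family genes separated by `maxIntervening + 1` fillers — just over the
#' tandem bound, as negative controls. Cluster members share strand and an
#' exon structure drawn from the classic intron-phase classes 1-2-0 / 0-1-2.
#'
#' @param manifest Manifest from [makeFamily()].
#' @param maxIntervening The tandem rule bound the layout is built around.
#' @param n_wide_pairs Number of just-over-the-bound control pairs.
#' @param seed Integer seed.
#' @return A list with `models` (a `GRangesList` in the layout of
#'   [readGeneModels()], family and filler genes together) and `layout`
#'   (data.frame: gene_id, scaffold, cluster id or NA).
#' @export
makeScaffolds <- function(manifest, maxIntervening = 5L, n_wide_pairs = 2L,
                          seed = 1L) {
  set.seed(seed)
  phaseClasses <- list(c(1L, 2L, 0L), c(0L, 1L, 2L))
  genes <- list()   # each: gene_id, scaffold, strand, exon_lengths
  layout <- list()
  scafN <- 0L
  filler <- 0L
  newFiller <- function() {
    filler <<- filler + 1L
    sprintf("FIL%04d", filler)
  }

  addGene <- function(id, scaffold, strand, phases) {
    genes[[length(genes) + 1L]] <<- list(
      gene_id = id, scaffold = scaffold, strand = strand,
      exon_lengths = exonLengthsFor(phases)
    )
  }

  groups <- split(manifest$gene_id, manifest$dup_group)
  placed <- character(0)
  clusterId <- 0L
  for (g in names(groups)) {
    clusterId <- clusterId + 1L
    scafN <- scafN + 1L
    sc <- sprintf("scaffold%03d", scafN)
    phases <- phaseClasses[[1L + clusterId %% 2L]]
    members <- groups[[g]]
    for (k in seq_along(members)) {
      addGene(members[k], sc, "+", phases)
      layout[[length(layout) + 1L]] <- data.frame(
        gene_id = members[k], scaffold = sc, cluster = clusterId,
        stringsAsFactors = FALSE)
      if (k < length(members)) {
        for (f in seq_len(sample(0:maxIntervening, 1L)))
          addGene(newFiller(), sc, sample(c("+", "-"), 1L),
                  sample(phaseClasses, 1L)[[1L]])
      }
    }
    placed <- c(placed, members)
  }

  rest <- setdiff(manifest$gene_id, placed)
  # just-over-the-bound control pairs
  for (w in seq_len(min(n_wide_pairs, length(rest) %/% 2L))) {
    scafN <- scafN + 1L
    sc <- sprintf("scaffold%03d", scafN)
    pair <- rest[1:2]
    rest <- rest[-(1:2)]
    addGene(pair[1L], sc, "+", phaseClasses[[1L]])
    layout[[length(layout) + 1L]] <- data.frame(
      gene_id = pair[1L], scaffold = sc, cluster = NA_integer_,
      stringsAsFactors = FALSE)
    for (f in seq_len(maxIntervening + 1L))
      addGene(newFiller(), sc, sample(c("+", "-"), 1L),
              sample(phaseClasses, 1L)[[1L]])
    addGene(pair[2L], sc, "-", phaseClasses[[2L]])
    layout[[length(layout) + 1L]] <- data.frame(
      gene_id = pair[2L], scaffold = sc, cluster = NA_integer_,
      stringsAsFactors = FALSE)
  }
  for (id in rest) {
    scafN <- scafN + 1L
    sc <- sprintf("scaffold%03d", scafN)
    if (stats::runif(1L) < 0.5) addGene(newFiller(), sc, "+",
                                        sample(phaseClasses, 1L)[[1L]])
    addGene(id, sc, sample(c("+", "-"), 1L), sample(phaseClasses, 1L)[[1L]])
    layout[[length(layout) + 1L]] <- data.frame(
      gene_id = id, scaffold = sc, cluster = NA_integer_,
      stringsAsFactors = FALSE)
  }

  # coordinates: genes laid left to right, ~2 kb intergenic spacing
  models <- list()
  meta <- list()
  cursorBy <- list()
  for (gn in genes) {
    cur <- if (is.null(cursorBy[[gn$scaffold]])) 1000L
           else cursorBy[[gn$scaffold]]
    introns <- if (length(gn$exon_lengths) > 1L)
      sample(50:500, length(gn$exon_lengths) - 1L, replace = TRUE)
    else integer(0)
    starts <- cur + c(0L, cumsum(gn$exon_lengths[-length(gn$exon_lengths)] +
                                   introns))
    ends <- starts + gn$exon_lengths - 1L
    gr <- GenomicRanges::GRanges(gn$scaffold,
                                 IRanges::IRanges(starts, ends),
                                 strand = gn$strand)
    if (gn$strand == "-") gr <- rev(gr)
    models[[gn$gene_id]] <- gr
    meta[[length(meta) + 1L]] <- data.frame(
      gene_id = gn$gene_id, scaffold = gn$scaffold,
      gene_strand = gn$strand, gene_start = min(starts),
      gene_end = max(ends), stringsAsFactors = FALSE)
    cursorBy[[gn$scaffold]] <- max(ends) + 2000L
  }
  grl <- GenomicRanges::GRangesList(models)
  S4Vectors::mcols(grl) <- S4Vectors::DataFrame(do.call(rbind, meta))
  list(models = grl, layout = do.call(rbind, layout))
}

# exon CDS lengths realising a given intron-phase vector, total length 0 mod 3
exonLengthsFor <- function(phases) {
  k <- length(phases) + 1L
  cum <- integer(k)
  prev <- 0L
  lens <- integer(k)
  for (i in seq_len(k - 1L)) {
    base <- sample(30:120, 1L) * 3L
    lens[i] <- base + (phases[i] - prev) %% 3L
    prev <- phases[i]
  }
  lens[k] <- sample(30:120, 1L) * 3L + (0L - prev) %% 3L
  lens
}

#' Synthetic stage and tissue RPKM matrices with planted structure
#'
#' The stage matrix (samples E, L1-L4, P, AM, AF) carries three expression
#' blocks over the non-silent genes — larva-high, egg+pupa-high and
#' adult-male-specific — with multiplicative lognormal noise and random
#' dropout zeros. The tissue matrix (larval midgut, larval head, adult male
#' and female heads) is built directly from planted expressed-gene sets, so
#' the per-tissue expressed counts of the truth are exact by construction.
#' Silent genes are all-zero everywhere.
#'
#' @param manifest Manifest from [makeFamily()].
#' @param block_sizes Named sizes of the three stage blocks; must sum with
#'   `n_silent` to the family size. The default scales the canonical
#'   70/64/62 (+25 silent) composition of a 221-gene family to the input.
#' @param tissue_sizes Named sizes of the per-tissue expressed sets (drawn
#'   from the non-silent genes). The default scales the canonical
#'   161/148/130/140 sets of a 196-gene non-silent complement.
#' @param n_silent Number of all-zero genes.
#' @param noise_sd Lognormal sigma (natural-log scale) of the stage noise.
#' @param dropout_rate Probability of replacing a stage value by zero.
#' @param seed Integer seed.
#' @return A list with `stage` and `tissue` matrices, `blocks` (named gene
#'   to block assignment) and `expressed_sets` (list of gene-id vectors per
#'   tissue).
#' @export
makeExpression <- function(manifest, block_sizes = NULL, tissue_sizes = NULL,
                           n_silent = NULL, noise_sd = 0.5,
                           dropout_rate = 0.05, seed = 1L) {
  set.seed(seed)
  ids <- manifest$gene_id
  n <- length(ids)
  if (is.null(block_sizes)) {
    frac <- c(larva_high = 70, egg_pupa_high = 64, adult_male = 62,
              silent = 25) / 221
    sizes <- floor(frac * n)
    rem <- n - sum(sizes)
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    block_sizes <- sizes[1:3]
    if (is.null(n_silent)) n_silent <- unname(sizes[["silent"]])
  }
  if (is.null(n_silent)) n_silent <- n - sum(block_sizes)
  if (is.null(tissue_sizes)) {
    nonSilent <- n - n_silent
    frac <- c(midgut_L4 = 161, head_L4 = 148, head_AM = 130,
              head_AF = 140) / 196
    tissue_sizes <- stats::setNames(
      pmin(nonSilent, pmax(ceiling(nonSilent / 4),
                           round(frac * nonSilent))),
      names(frac))
  }
  if (n_silent < 0 || sum(block_sizes) + n_silent != n)
    stop("block sizes plus silent genes must equal the family size")
  if (any(tissue_sizes > n - n_silent))
    stop("tissue expressed sets cannot exceed the non-silent gene count")
  if (any(tissue_sizes < ceiling((n - n_silent) / length(tissue_sizes))))
    stop("tissue expressed sets too small to jointly cover the non-silent genes")

  blocks <- rep(names(block_sizes), block_sizes)
  blocks <- c(blocks, rep("silent", n_silent))
  names(blocks) <- ids

  stages <- c("E", "L1", "L2", "L3", "L4", "P", "AM", "AF")
  pattern <- list(
    larva_high    = c(E = 1,  L1 = 80, L2 = 100, L3 = 120, L4 = 150,
                      P = 1,  AM = 1,  AF = 1),
    egg_pupa_high = c(E = 90, L1 = 1,  L2 = 1,   L3 = 1,   L4 = 1,
                      P = 70, AM = 1,  AF = 1),
    adult_male    = c(E = 0.5, L1 = 0.5, L2 = 0.5, L3 = 0.5, L4 = 0.5,
                      P = 0.5, AM = 180, AF = 2),
    silent        = stats::setNames(rep(0, 8L), stages)
  )
  stage <- t(vapply(ids, function(g) {
    mu <- pattern[[blocks[g]]][stages]
    val <- mu * exp(stats::rnorm(length(stages), 0, noise_sd))
    val[mu == 0] <- 0
    drop <- stats::runif(length(stages)) < dropout_rate
    val[drop] <- 0
    val
  }, numeric(length(stages))))
  dimnames(stage) <- list(ids, stages)

  nonSilent <- ids[blocks != "silent"]
  # every non-silent gene gets a "home" tissue, then each set is filled to
  # size — the four sets jointly cover all non-silent genes, so the
  # expressed-in-at-least-one-tissue truth equals the non-silent count
  homes <- sample(rep(names(tissue_sizes),
                      length.out = length(nonSilent)))
  expressedSets <- lapply(names(tissue_sizes), function(tn) {
    own <- nonSilent[homes == tn]
    extra <- sample(setdiff(nonSilent, own),
                    tissue_sizes[[tn]] - length(own))
    sort(c(own, extra))
  })
  names(expressedSets) <- names(tissue_sizes)
  tissue <- matrix(0, n, length(tissue_sizes),
                   dimnames = list(ids, names(tissue_sizes)))
  for (tn in names(tissue_sizes)) {
    sel <- expressedSets[[tn]]
    tissue[sel, tn] <- exp(stats::rnorm(length(sel), log(30), noise_sd))
  }
  list(stage = stage, tissue = tissue, blocks = blocks,
       expressed_sets = expressedSets)
}

#' Write a complete synthetic fixture set to disk
#'
#' Emits the family FASTA, the scaffold GFF3, stage and tissue RPKM TSVs and
#' the JSON truth manifest into `dir` — everything a full pipeline run needs.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [familySpec()]; its seed drives every stage.
#' @return Invisibly, the list of written paths.
#' @export
makeFixtures <- function(dir, spec = familySpec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fam <- makeFamily(spec)
  sca <- makeScaffolds(fam$manifest, seed = spec$seed)
  expr <- makeExpression(fam$manifest, seed = spec$seed)
  paths <- list(
    fasta = file.path(dir, "family.fasta"),
    gff = file.path(dir, "family.gff3"),
    stage = file.path(dir, "rpkm_stages.tsv"),
    tissue = file.path(dir, "rpkm_tissues.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  writeProteinFasta(fam$proteins, paths$fasta)
  writeGeneModels(sca$models, paths$gff)
  writeExpressionMatrix(expr$stage, paths$stage)
  writeExpressionMatrix(expr$tissue, paths$tissue)
  jsonlite::write_json(
    list(manifest = fam$manifest, layout = sca$layout,
         blocks = as.list(expr$blocks),
         expressed_sets = expr$expressed_sets),
    paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
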