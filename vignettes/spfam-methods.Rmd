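---
title: "Methods: rule-based annotation of serine protease gene families"
author: "spfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based annotation of serine protease gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spfam)
```

## The problem

Insect genomes carry large families of serine proteases (SPs) and serine
protease homologs (SPHs). SPs are trypsin-like enzymes built around a
His/Asp/Ser catalytic triad; SPHs are family members whose triad is mutated,
catalytically dead but often immune-active. Annotating such a family from
predicted proteins means answering, per gene: does it have an intact triad
(SP vs SPH)? Is its S1 substrate pocket trypsin- or chymotrypsin-like? Does
it carry N-terminal clip domains, and of which group? Where is its zymogen
activation site and what does the P1 residue say about its position in a
proteolytic cascade? At the genome level: which members are tandem
duplicates, and what do their expression profiles across stages and tissues
suggest about function?

`spfam` implements each of these questions as an explicit, auditable rule,
plus the comparative machinery around them (alignment, Poisson/NJ
phylogenies, expression clustering) and a synthetic-family generator whose
ground-truth manifest makes the whole pipeline testable end to end.

## Catalytic-triad detection

The triad residues sit in conserved motifs, canonically TAAHC (His), DIAL
(Asp) and GDSGGP (Ser). Exact string matching would misclassify real family
members whose motif context drifted, and it could not locate a *broken*
triad at all — yet locating broken triads is exactly what separates an SPH
from an unrelated protein. Each motif is therefore a short positional
profile anchored on the catalytic residue:

* His: `[ST]-[AG]-[AG]-H-C`, anchored on H
* Asp: `D-[IVLM]-[AG]-[LIVM]`, anchored on D
* Ser: `G-[DN]-S-G-[GS]-[PSA]`, anchored on S

The anchor position is allowed to hold *any* standard residue when locating
the motif; the motif is **intact** only if the anchor carries the catalytic
residue. A sequence whose GDSGGP reads GDAGGP is found, reported, and marked
broken. The ambiguity code `X` matches no position (conservative: an
uncertain residue never supports a call). Profiles mirror the style of the
classical pattern databases while staying small enough to audit; every
position set is configurable.

Motifs are assembled left to right into trypsin-like (Tryp_SPc) spans — His,
then the first Asp hit downstream, then the first Ser hit after that — and
the next span is sought beyond the previous one, so multi-domain proteases
yield multiple spans. A protein is an SP when at least one span has all
three anchors intact; otherwise it is an SPH. The reported span start is
placed 41 residues upstream of the catalytic His, which is where the domain
begins in chymotrypsinogen numbering (domain start 16, His 57); this anchors
both the clip-domain search region and the pocket alignment below.

## Clip-domain grammar

Clip domains are recognised purely from their six-cysteine topology in the
region N-terminal to the first trypsin-like span (a clip can therefore never
overlap a catalytic domain). The default grammar, counting residues strictly
between consecutive cysteines:

| spacing | default | note |
|---|---|---|
| Cys1–Cys2 | 2–10 | observed family range |
| Cys2–Cys3 | exactly 5 | constant in the family this package models; override `[4,6]` available for other taxa |
| Cys3–Cys4 | 8–26 | group 1 = 8–17, group 2 = 22–26, between = unassigned |
| Cys4–Cys5 | 2–20 | no published bound exists; chosen wide enough to admit both groups, configurable |
| Cys5–Cys6 | exactly 0 | the defining adjacent pair |
| Cys1–Cys6 span | 37–55 | counted strictly between; an `inclusive` counting mode is exposed because the literature is ambiguous about endpoints |

All placements satisfying the grammar are enumerated; overlapping candidates
are resolved leftmost-first, so tandem double-clip proteins report both
domains. Widening any interval can only add placements, never remove one
(monotonicity, covered by tests).

## S1-pocket specificity and activation sites

Substrate specificity is read from positions 189, 216 and 226 in
chymotrypsinogen numbering. Bovine chymotrypsinogen A is packaged as the
numbering anchor (`inst/extdata/`), with its annotated positions in a JSON
sidecar; the choice of anchor is the field convention these rules assume.
The query domain (from the estimated span start to the C-terminus) is
globally aligned to the anchor and the residues opposite 189/216/226 are
read off; a gap reads `"-"`. The call is:

* trypsin: Asp189, Gly216, Gly/Ala/Ser226
* chymotrypsin: Ser/Thr/Gly189 with the same 216/226 constraints
* anything else, including gapped positions: other

The published rule enumerates 216/226 explicitly only for trypsin; applying
the same canonical constraints to chymotrypsin is the strictest consistent
reading, and both residue sets are plain arguments of `callSubtype()` if a
user needs a looser one. If less than half of the anchor residues are
covered by the query, the call is returned unassigned with a warning rather
than silently read from a degenerate alignment.

Activation sites are scanned in a window from 30 residues upstream of the
span start to 10 residues into it — zymogen activation cleaves immediately
before the domain. The motif family is `[IVLF]-[IVLN]-[GN]-G`, which admits
the canonical IVGG and the reported variants IIGG and IING plus conservative
neighbors. Candidates are ranked by agreement with IVGG, then proximity to
the span start, then position; the residue immediately preceding the winner
is the P1 cleavage residue. Arg/Lys mark a terminal proteinase, Leu/His/Ser
a penultimate one, anything else (e.g. the Tyr/Phe variants that occur in
real families) is left unassigned.

## Tandem duplication and gene structure

Tandem duplication is called for family genes on one scaffold with at most
five annotated genes between them (the bound is an argument). "Genes
between" is a count of distinct gene ids ranked strictly between the two
members when all genes on the scaffold are sorted by start — a gene-count
rule, not a distance rule, so nested or antisense genes count once.
Homology defaults to family co-membership, since the inputs are already a
curated family; an optional mode additionally requires a pairwise global
identity (default 40%) for mixed inputs. Orientation is deliberately *not*
required for membership — shared orientation is reported as an observation
by `clusterConsistency()`, together with exon counts, intron-phase vectors
and mean pairwise identity/similarity.

Intron phases are the cumulative CDS length of the preceding exons modulo 3.

## Alignment and phylogenetics

All alignments (pairwise, profile and the pocket readout) share one engine:
a three-state affine-gap dynamic programme (Gotoh) in C++, BLOSUM62 scoring,
gap open 10, extension 0.5 — the defaults of the classical progressive
aligners — with a gap of length L costing `open + L * ext`. Tie-breaking is
fixed (residue-residue column preferred, then a gap in the second sequence),
so alignments are deterministic. The multiple aligner builds a UPGMA guide
tree from pairwise identity distances and merges residue-frequency profiles
in guide order; guide-tree ties break on the lexicographically smallest
member id. Shelling out to an external aligner is deliberately avoided:
binary reproduction of any particular tool is a non-goal, and an in-package
engine keeps the score model testable against a brute-force oracle.

Percent identity uses the pairwise-deletion denominator (columns where
neither row is gapped). "Similarity" additionally credits substitutions
within the groups `{AVLIM} {FWY} {ST} {KRH} {DENQ} {C} {G} {P}` — the
standard strong-conservation partition; the underlying measure used for the
published family percentages is not documented anywhere, so both modes are
first-class and reported side by side by `clusterConsistency()`.

Evolutionary distances are Poisson-corrected, `d = -ln(1 - p)`, with `p` the
fraction of differing sites over the pairwise-deletion columns; saturated
pairs (`p >= 1`) are flagged infinite and refuse to enter tree building.
Trees are built by the canonical neighbor-joining agglomeration with the
Q-criterion. Numerical choices: ties in Q break on the lexicographically
smallest pair of cluster ids; negative branch-length estimates (a known NJ
artefact on non-additive matrices) are clamped to zero and the clamped
deficit is recorded in an attribute rather than discarded. On additive
matrices the implementation is exact, which the tests quantify over random
5–8 taxon trees at 1e-9. Bootstrap supports resample alignment columns with
replacement, rebuild distance and tree per replicate, and report the
percentage of replicates containing each original internal bipartition;
replicates that saturate are dropped from the denominator.

## Expression analysis

RPKM matrices are log2-transformed; zeros become missing values (a zero has
no place on a log color scale and is rendered as such in the usual heatmap
convention), and missing stays missing. Gene clustering is agglomerative
complete linkage on Euclidean distances; distances over rows with missing
entries are computed on the mutually present columns and the squared sum is
rescaled by total/present columns — the convention of the classic
gene-expression clustering tools. The agglomerator is implemented in the
package (rather than delegated) so that every tie breaks on the
lexicographically smallest gene id and the merge sequence is reproducible;
it is verified against both a brute-force oracle and `stats::hclust` on
tie-free data. "Expressed" means RPKM strictly above a threshold whose
default is 0 — no published criterion exists, so the threshold is an
explicit argument and is echoed in reports. qPCR tables are reduced to
replicate means, normalised against a housekeeping reference gene per
sample (`dCt`, relative level `2^-dCt`), with optional `ddCt` against a
calibrator sample.

## The synthetic-family generator

`makeFamily()` builds proteins from a fixed scaffold: optional clip
cassette(s) with spacings sampled inside the grammar (span 43–53), a linker,
and a trypsin-like domain derived from the chymotrypsinogen A template with
one substitution (T104A) so its Asp motif reads DIAL. Planted features —
pocket triple, activation P1/motif, the single randomised catalytic residue
that defines an SPH — are edited at their canonical template positions.
Defaults encode the study-scale composition: 221 genes, 120 SP / 101 SPH,
38 trypsins and 8 chymotrypsins, 13 clip-bearing genes carrying 14 clip
domains, and five trypsin duplicate groups of sizes 5/5/4/4/2. Duplicate
groups diverge once from a founder and members add lighter (40% of the
founder rate) within-group divergence, so planted clades are recoverable by
the tree methods.

Unambiguous truth labels are a design requirement, enforced three ways:
background and mutations in the region N-terminal to the domain avoid
cysteine (no chance clip topology) and serine/threonine (no chance start of
a His-motif window); mutations inside the domain are rejected if any window
overlapping them would match a triad profile; and activation-motif decoys
that background or mutation create inside the scan window are broken at
their obligatory final glycine. Background residues otherwise follow a
fixed, documented amino-acid frequency table rather than a uniform draw, so
spurious-match rates are a stable property. Expression matrices plant three
stage blocks (larva-high, egg+pupa-high, adult-male-specific) with
multiplicative lognormal noise (default sigma 0.5 on the natural-log scale)
and dropout zeros; tissue matrices are built directly from planted
expressed-gene sets that jointly cover every non-silent gene, so per-tissue
expressed counts are exact by construction.

What the generator does *not* emulate: insertions/deletions inside domains
(all family members share the template backbone, so alignments are easier
than for real, length-variable proteases), codon-level evolution, accessory
domains (LDLA/FRI/SR), and read-level expression noise. Passing the
recovery tests therefore shows the rules are implemented exactly as stated,
not that they would achieve perfect accuracy on arbitrary real proteomes.

## Problem sizes and reproducibility

The test suite runs the full 221-gene recovery, boundary suites for the
tandem rule and clip grammar, 50-pair alignment-oracle checks, 100 random
additive matrices for NJ exactness, brute-force linkage verification on
matrices of up to 7 genes, and block recovery at the default noise level —
sizes chosen so the whole suite completes in a couple of minutes on one
core. All randomness flows from explicit integer seeds through R's RNG, so
every result in the tests, the acceptance script and the README example is
bit-reproducible.

## Known limitations

* Motif profiles are hand-curated for trypsin-like families; distant clans
  (subtilisins, rhomboids) are out of scope.
* The pocket readout depends on a single global alignment to one anchor;
  heavily diverged or truncated domains fall back to an explicit
  "unassigned" rather than a best-effort guess.
* The progressive aligner is a straightforward profile merger without
  iterative refinement; for publication-grade alignments of very divergent
  sets a dedicated aligner remains preferable, and alignments are accepted
  from any FASTA source.
* Tandem clustering trusts the input gene annotation: unannotated intervening
  genes make neighbors look closer than they are.
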