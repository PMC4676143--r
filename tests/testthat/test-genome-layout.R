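test_that("the tandem rule links pairs at <= 5 intervening genes, not 6", {
  mk <- function(nFiller) {
    df <- data.frame(
      gene_id = c("famA", paste0("f", seq_len(nFiller)), "famB"),
      scaffold = "sc1",
      start = seq(1000, by = 5000, length.out = nFiller + 2),
      strand = "+", stringsAsFactors = FALSE
    )
    toyModels(df)
  }
  cl5 <- tandemClusters(c("famA", "famB"), mk(5))
  expect_length(cl5, 1L)
  expect_equal(cl5[[1]]$members, c("famA", "famB"))
  expect_equal(cl5[[1]]$intervening, 5L)

  expect_length(tandemClusters(c("famA", "famB"), mk(6)), 0L)
  expect_length(tandemClusters(c("famA", "famB"), mk(6),
                               maxIntervening = 6L), 1L)
})

test_that("unknown family ids are a hard error", {
  df <- data.frame(gene_id = "g1", scaffold = "sc1", start = 1,
                   strand = "+", stringsAsFactors = FALSE)
  expect_error(tandemClusters(c("g1", "ghost"), toyModels(df)), "ghost")
})

test_that("a planted 20-of-38 layout yields 5 clusters and 52.6%", {
  fam <- makeFamily(familySpec(seed = 1))
  sca <- makeScaffolds(fam$manifest, seed = 1)
  trypsins <- fam$manifest$gene_id[fam$manifest$role == "trypsin"]
  cl <- tandemClusters(trypsins, sca$models)
  expect_length(cl, 5L)
  expect_setequal(vapply(cl, function(x) length(x$members), integer(1)),
                  c(5L, 5L, 4L, 4L, 2L))
  expect_equal(clusteredFraction(cl, trypsins), 100 * 20 / 38,
               tolerance = 1e-12)
  # membership equals the planted duplicate groups
  planted <- split(fam$manifest$gene_id, fam$manifest$dup_group)
  got <- lapply(cl, `[[`, "members")
  expect_setequal(vapply(got, paste, character(1), collapse = ","),
                  vapply(planted, function(x)
                    paste(sort(x), collapse = ","), character(1)))
})

test_that("cluster membership is invariant to gene input order", {
  fam <- makeFamily(familySpec(n_sp = 12, n_sph = 0, n_trypsin = 12,
                               n_chymotrypsin = 0, n_clip_sp = 0,
                               n_clip_sph = 0, n_double_clip = 0,
                               dup_groups = c(4L, 3L), seed = 8))
  sca <- makeScaffolds(fam$manifest, seed = 8)
  ids <- fam$manifest$gene_id
  perm <- sample(seq_along(sca$models))
  shuffled <- sca$models[perm]
  c1 <- tandemClusters(ids, sca$models)
  c2 <- tandemClusters(sample(ids), shuffled)
  key <- function(cl) sort(vapply(cl, function(x)
    paste(x$members, collapse = ","), character(1)))
  expect_identical(key(c1), key(c2))
})

test_that("cluster members plus singletons partition the family", {
  fam <- makeFamily(familySpec(seed = 2))
  sca <- makeScaffolds(fam$manifest, seed = 2)
  ids <- fam$manifest$gene_id
  cl <- tandemClusters(ids, sca$models)
  members <- unlist(lapply(cl, `[[`, "members"))
  expect_false(anyDuplicated(members) > 0)
  singletons <- setdiff(ids, members)
  expect_equal(length(members) + length(singletons), length(ids))
})

test_that("maxIntervening = 0 reduces to a direct adjacency scan", {
  set.seed(5)
  ids <- paste0("g", 1:12)
  famIds <- sample(ids, 6)
  df <- data.frame(gene_id = ids, scaffold = "sc1",
                   start = seq(1000, by = 4000, length.out = 12),
                   strand = "+", stringsAsFactors = FALSE)
  cl <- tandemClusters(famIds, toyModels(df), maxIntervening = 0L)
  # oracle: runs of family genes adjacent in start order
  ord <- ids[order(df$start)]
  isFam <- ord %in% famIds
  runs <- rle(isFam)
  oracleSizes <- runs$lengths[runs$values & runs$lengths >= 2]
  expect_equal(sort(vapply(cl, function(x) length(x$members), integer(1))),
               sort(oracleSizes))
})

test_that("identity-mode homology can reject dissimilar neighbors", {
  df <- data.frame(gene_id = c("a", "b"), scaffold = "sc1",
                   start = c(1000, 9000), strand = "+",
                   stringsAsFactors = FALSE)
  models <- toyModels(df)
  seqs <- c(a = strrep("ACDEFGHIKL", 10), b = strrep("WYWYWPWYWWY", 9))
  expect_length(tandemClusters(c("a", "b"), models, homology = "identity",
                               seqs = seqs), 0L)
  seqs2 <- c(a = strrep("ACDEFGHIKL", 10), b = strrep("ACDEFGHIKL", 10))
  expect_length(tandemClusters(c("a", "b"), models, homology = "identity",
                               seqs = seqs2), 1L)
})

test_that("intron phases equal cumulative CDS length mod 3", {
  expect_equal(intronPhases(c(3, 6))$phases, 0L)
  expect_equal(intronPhases(c(4, 4, 1, 3))$phases, c(1L, 2L, 0L))
  expect_equal(intronPhases(c(5, 4, 3, 3))$phases, c(2L, 0L, 0L))
  # property: brute-force codon walking on random exon structures
  set.seed(11)
  for (r in 1:25) {
    lens <- sample(1:200, sample(2:6, 1), replace = TRUE)
    if (sum(lens) < 3) next
    walked <- integer(0)
    pos <- 0L
    for (i in seq_len(length(lens) - 1)) {
      pos <- pos + lens[i]
      walked <- c(walked, pos %% 3L)
    }
    expect_equal(intronPhases(lens)$phases, walked)
  }
})

test_that("cluster consistency flags orientation and structure agreement", {
  df <- data.frame(gene_id = c("a", "b", "c"), scaffold = "sc1",
                   start = c(1000, 9000, 17000), strand = "+",
                   stringsAsFactors = FALSE)
  ex <- list(c(4L, 4L, 1L, 3L), c(7L, 7L, 4L, 3L), c(4L, 4L, 4L, 3L))
  # all three have phases 1-2-0
  models <- toyModels(df, ex)
  cl <- list(scaffold = "sc1", members = c("a", "b", "c"),
             intervening = c(0L, 0L))
  cc <- clusterConsistency(cl, models)
  expect_true(cc$same_orientation && cc$same_exon_count && cc$same_phases)
  expect_equal(unname(cc$phase_vectors), rep("1-2-0", 3))

  df$strand[2] <- "-"
  cc2 <- clusterConsistency(cl, toyModels(df, ex))
  expect_false(cc2$same_orientation)
})

test_that("consistency similarity agrees with the alignment module", {
  fam <- makeFamily(familySpec(n_sp = 3, n_sph = 0, n_trypsin = 3,
                               n_chymotrypsin = 0, n_clip_sp = 0,
                               n_clip_sph = 0, n_double_clip = 0,
                               dup_groups = c(3L), mutation_rate = 0.1,
                               seed = 19))
  sca <- makeScaffolds(fam$manifest, seed = 19)
  seqs <- setNames(as.character(fam$proteins), names(fam$proteins))
  ids <- fam$manifest$gene_id
  cl <- list(scaffold = "x", members = ids, intervening = c(0L, 0L))
  cc <- clusterConsistency(cl, sca$models, seqs = seqs)
  # oracle: mean of the three pairwise identities computed directly
  p <- alignParams()
  vals <- combn(ids, 2, function(pr) {
    al <- globalAlign(seqs[[pr[1]]], seqs[[pr[2]]], p)$alignment
    percentIdentity(al)[1, 2]
  })
  expect_equal(cc$mean_identity, mean(vals), tolerance = 1e-12)
})
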