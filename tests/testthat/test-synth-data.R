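test_that("family specifications enforce their invariants", {
  expect_error(familySpec(n_sp = 10, n_trypsin = 8, n_chymotrypsin = 2,
                          n_clip_sp = 1), "exceed n_sp")
  expect_error(familySpec(n_sph = 2, n_clip_sph = 3), "exceeds n_sph")
  expect_error(familySpec(n_clip_sp = 1, n_double_clip = 2), "double-clip")
  expect_error(familySpec(n_trypsin = 5, dup_groups = c(4L, 4L)),
               "duplicate groups")
  expect_error(familySpec(mutation_rate = 0.9), "mutation_rate")
})

test_that("generated proteins satisfy the sequence-type invariants", {
  fam <- makeFamily(familySpec(n_sp = 10, n_sph = 5, n_trypsin = 4,
                               n_chymotrypsin = 2, n_clip_sp = 2,
                               n_clip_sph = 1, n_double_clip = 1,
                               dup_groups = c(2L), seed = 14))
  expect_silent(spfam:::validateProteinSet(as.character(fam$proteins),
                                           names(fam$proteins)))
  expect_equal(nrow(fam$manifest), 15L)
  expect_false(any(grepl("[^ACDEFGHIKLMNPQRSTVWYX]",
                         as.character(fam$proteins))))
})

test_that("the generator is deterministic under a fixed seed", {
  s <- familySpec(n_sp = 8, n_sph = 4, n_trypsin = 3, n_chymotrypsin = 1,
                  n_clip_sp = 1, n_clip_sph = 1, n_double_clip = 0,
                  dup_groups = c(2L), seed = 77)
  f1 <- makeFamily(s)
  f2 <- makeFamily(s)
  expect_identical(as.character(f1$proteins), as.character(f2$proteins))
  expect_identical(f1$manifest, f2$manifest)
  s2 <- s; s2$seed <- 78L
  expect_false(identical(as.character(makeFamily(s2)$proteins),
                         as.character(f1$proteins)))
})

test_that("manifest composition equals the requested specification", {
  spec <- familySpec(seed = 5)
  fam <- makeFamily(spec)
  m <- fam$manifest
  expect_equal(sum(m$class == "SP"), spec$n_sp)
  expect_equal(sum(m$class == "SPH"), spec$n_sph)
  expect_equal(sum(m$subtype == "trypsin", na.rm = TRUE), spec$n_trypsin)
  expect_equal(sum(m$subtype == "chymotrypsin", na.rm = TRUE),
               spec$n_chymotrypsin)
  expect_equal(sum(m$n_clip > 0), spec$n_clip_sp + spec$n_clip_sph)
  expect_equal(sum(m$n_clip), spec$n_clip_sp + spec$n_clip_sph +
                 spec$n_double_clip)
  expect_equal(unname(table(m$dup_group)[as.character(1:5)]),
               as.integer(spec$dup_groups), ignore_attr = TRUE)
  # SPHs have exactly one knocked-out catalytic residue
  sph <- m[m$class == "SPH", ]
  expect_true(all(sph$knockout %in% c("his", "asp", "ser")))
  expect_true(all(rowSums(!sph[, c("his_intact", "asp_intact",
                                   "ser_intact")]) == 1))
})

test_that("the recovery theorem holds with zero mutation load", {
  fam <- makeFamily(familySpec(n_sp = 15, n_sph = 10, n_trypsin = 5,
                               n_chymotrypsin = 3, n_clip_sp = 3,
                               n_clip_sph = 2, n_double_clip = 1,
                               dup_groups = c(3L), mutation_rate = 0,
                               seed = 50))
  ann <- as.data.frame(annotationTable(annotateFamily(fam$proteins)))
  m <- fam$manifest
  for (f in c("gene_id", "class", "his_intact", "asp_intact", "ser_intact",
              "n_clip", "clip_groups", "activation_motif", "p1_residue",
              "cascade_position"))
    expect_identical(ann[[f]], m[[f]], info = f)
  sp <- m$class == "SP"
  expect_identical(ann$subtype[sp], m$subtype[sp])
})

test_that("scaffold layouts respect the tandem-rule boundary by design", {
  fam <- makeFamily(familySpec(n_sp = 10, n_sph = 2, n_trypsin = 6,
                               n_chymotrypsin = 0, n_clip_sp = 0,
                               n_clip_sph = 0, n_double_clip = 0,
                               dup_groups = c(3L, 2L), seed = 60))
  sca <- makeScaffolds(fam$manifest, n_wide_pairs = 2L, seed = 60)
  cl <- tandemClusters(fam$manifest$gene_id, sca$models)
  got <- sort(vapply(cl, function(x) paste(sort(x$members), collapse = ","),
                     character(1)))
  planted <- sort(unname(vapply(
    split(fam$manifest$gene_id, fam$manifest$dup_group),
    function(x) paste(sort(x), collapse = ","), character(1))))
  # exactly the planted duplicate groups cluster; wide pairs never do
  expect_identical(got, planted)
  widePairs <- sca$layout$gene_id[is.na(sca$layout$cluster)]
  expect_false(any(widePairs %in% unlist(lapply(cl, `[[`, "members"))))
})

test_that("cluster members share strand and intron-phase class", {
  fam <- makeFamily(familySpec(n_sp = 8, n_sph = 0, n_trypsin = 8,
                               n_chymotrypsin = 0, n_clip_sp = 0,
                               n_clip_sph = 0, n_double_clip = 0,
                               dup_groups = c(4L, 3L), seed = 61))
  sca <- makeScaffolds(fam$manifest, seed = 61)
  cl <- tandemClusters(fam$manifest$gene_id, sca$models)
  for (c1 in cl) {
    cc <- clusterConsistency(c1, sca$models)
    expect_true(cc$same_orientation)
    expect_true(cc$same_exon_count)
    expect_true(cc$same_phases)
    expect_true(all(cc$phase_vectors %in% c("1-2-0", "0-1-2")))
  }
})

test_that("expression matrices carry the planted truth", {
  fam <- makeFamily(familySpec(seed = 9))
  expr <- makeExpression(fam$manifest, seed = 9)
  counts <- expressedCounts(expr$tissue)
  expect_equal(unname(counts$per_sample),
               c(161L, 148L, 130L, 140L))
  expect_equal(counts$any_sample, 196L)
  # silent genes are all-zero in both matrices
  silent <- names(expr$blocks)[expr$blocks == "silent"]
  expect_true(all(expr$stage[silent, ] == 0))
  expect_true(all(expr$tissue[silent, ] == 0))
  # reproducibility
  expr2 <- makeExpression(fam$manifest, seed = 9)
  expect_identical(expr$stage, expr2$stage)
  expect_identical(expr$tissue, expr2$tissue)
})

test_that("fixture files regenerate the in-memory objects", {
  dir <- withr::local_tempdir()
  spec <- familySpec(n_sp = 6, n_sph = 4, n_trypsin = 3, n_chymotrypsin = 1,
                     n_clip_sp = 1, n_clip_sph = 1, n_double_clip = 0,
                     dup_groups = c(2L), seed = 70)
  paths <- makeFixtures(dir, spec)
  expect_true(all(file.exists(unlist(paths))))
  fam <- makeFamily(spec)
  aa <- readProteinFasta(paths$fasta)
  expect_identical(as.character(aa), as.character(fam$proteins))
  expect_identical(names(aa), names(fam$proteins))
  stage <- readExpressionMatrix(paths$stage)
  expr <- makeExpression(fam$manifest, seed = spec$seed)
  expect_equal(stage, expr$stage, tolerance = 1e-12)
  manifest <- jsonlite::read_json(paths$manifest, simplifyVector = TRUE)
  expect_equal(manifest$manifest$class, fam$manifest$class)
})
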