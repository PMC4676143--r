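test_that("protein FASTA reading normalises and validates records", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "MKTAAHC", ">p2", "mgdsggp*"), fa)
  aa <- readProteinFasta(fa)
  expect_equal(names(aa), c("p1", "p2"))
  expect_equal(as.character(aa[["p1"]]), "MKTAAHC")
  expect_equal(as.character(aa[["p2"]]), "MGDSGGP")  # uppercased, * stripped

  writeLines(c(">d", "MK", ">d", "ML"), fa)
  expect_error(readProteinFasta(fa), "duplicate")
  writeLines(c(">p1", "MK", ">empty", ""), fa)
  expect_error(readProteinFasta(fa), "empty")
  writeLines(c(">p1", "MKBZ"), fa)   # B/Z ambiguity codes are rejected
  expect_error(readProteinFasta(fa), "non amino-acid")
})

test_that("FASTA write/read round-trips a synthetic family exactly", {
  fam <- makeFamily(familySpec(n_sp = 5, n_sph = 3, n_trypsin = 2,
                               n_chymotrypsin = 1, n_clip_sp = 1,
                               n_clip_sph = 1, n_double_clip = 0,
                               dup_groups = c(2L), seed = 3))
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeProteinFasta(fam$proteins, fa)
  back <- readProteinFasta(fa)
  expect_identical(names(back), names(fam$proteins))
  expect_identical(as.character(back), as.character(fam$proteins))
})

test_that("GFF gene models keep transcription order and validate parents", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "sc1\t.\tgene\t100\t500\t.\t-\t.\tID=gm1",
    "sc1\t.\tCDS\t100\t190\t.\t-\t.\tID=gm1.c1;Parent=gm1",
    "sc1\t.\tCDS\t300\t500\t.\t-\t.\tID=gm1.c2;Parent=gm1",
    "sc2\t.\tgene\t10\t40\t.\t+\t.\tID=gm2",
    "sc2\t.\tCDS\t10\t40\t.\t+\t.\tID=gm2.c1;Parent=gm2"
  ), gff)
  models <- readGeneModels(gff)
  # minus strand: highest-coordinate exon first
  expect_equal(GenomicRanges::start(models[["gm1"]]), c(300L, 100L))
  expect_equal(length(models[["gm2"]]), 1L)
  expect_equal(intronPhases(models[["gm2"]])$phases, integer(0))

  writeLines(c(
    "##gff-version 3",
    "sc1\t.\tgene\t1\t50\t.\t+\t.\tID=g1",
    "sc1\t.\tCDS\t1\t50\t.\t+\t.\tID=c1;Parent=nosuch"
  ), gff)
  expect_error(readGeneModels(gff), "unknown parent")

  writeLines(c(
    "##gff-version 3",
    "sc1\t.\tgene\t1\t50\t.\t+\t.\tID=g1",
    "sc1\t.\tCDS\t1\t20\t.\t+\t.\tID=c1;Parent=g1",
    "sc2\t.\tCDS\t30\t50\t.\t+\t.\tID=c2;Parent=g1"
  ), gff)
  expect_error(readGeneModels(gff), "multiple scaffolds")
})

test_that("gene models round-trip through GFF3 with CDS lengths intact", {
  fam <- makeFamily(familySpec(n_sp = 4, n_sph = 2, n_trypsin = 4,
                               n_chymotrypsin = 0, n_clip_sp = 0,
                               n_clip_sph = 0, n_double_clip = 0,
                               dup_groups = c(3L), seed = 9))
  sca <- makeScaffolds(fam$manifest, seed = 9)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeGeneModels(sca$models, gff)
  back <- readGeneModels(gff)
  expect_setequal(names(back), names(sca$models))
  for (g in names(sca$models)) {
    expect_equal(sum(GenomicRanges::width(back[[g]])),
                 sum(GenomicRanges::width(sca$models[[g]])), info = g)
    expect_equal(GenomicRanges::start(back[[g]]),
                 GenomicRanges::start(sca$models[[g]]), info = g)
  }
})

test_that("expression TSV parsing distinguishes zeros from missing", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3",
               "g1\t1.5\tNA\t0",
               "g2\t0\t2\t3",
               "g3\t4\t5\t6"), tsv)
  m <- readExpressionMatrix(tsv)
  expect_equal(dim(m), c(3L, 3L))
  expect_true(is.na(m["g1", "s2"]))
  expect_equal(sum(is.na(m)), 1L)           # zeros are data, not missing
  expect_equal(m["g2", "s1"], 0)

  writeLines(c("gene\ts1\ts2", "g1\t0\t0", "g2\t0\t0"), tsv)
  expect_equal(sum(is.na(readExpressionMatrix(tsv))), 0L)

  writeLines(c("gene\ts1\ts2", "g1\t-1\t0"), tsv)
  expect_error(readExpressionMatrix(tsv), "negative")
  writeLines(c("gene\ts1\ts2", "g1\t1"), tsv)
  expect_error(readExpressionMatrix(tsv), "ragged")
})

test_that("expression matrices round-trip to full precision", {
  fam <- makeFamily(familySpec(n_sp = 3, n_sph = 2, n_trypsin = 0,
                               n_chymotrypsin = 0, n_clip_sp = 0,
                               n_clip_sph = 0, n_double_clip = 0,
                               dup_groups = integer(0), seed = 4))
  expr <- makeExpression(fam$manifest,
                         block_sizes = c(larva_high = 2L,
                                         egg_pupa_high = 1L,
                                         adult_male = 1L),
                         tissue_sizes = c(midgut_L4 = 2L, head_L4 = 2L,
                                          head_AM = 1L, head_AF = 2L),
                         n_silent = 1L, seed = 4)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionMatrix(expr$stage, tsv)
  back <- readExpressionMatrix(tsv)
  expect_equal(back, expr$stage, tolerance = 1e-12)
})

test_that("qPCR tables validate their columns and Ct values", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tsample\treplicate\tCt", "g1\ts1\t1\t20.5"), tsv)
  expect_equal(readQpcrTable(tsv)$Ct, 20.5)
  writeLines(c("gene\tsample\treplicate\tCt", "g1\ts1\t1\t-2"), tsv)
  expect_error(readQpcrTable(tsv), "Ct")
})
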