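test_that("log2 transform maps zeros to missing and keeps order", {
  m <- matrix(c(8, 0, 1, NA, 2, 4), 2, 3,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  lg <- log2Transform(m)
  expect_equal(lg["g1", "s1"], 3)
  expect_true(is.na(lg["g2", "s1"]))   # zero becomes missing
  expect_equal(lg["g1", "s2"], 0)      # log2(1)
  expect_true(is.na(lg["g2", "s2"]))   # missing stays missing
  # order-preserving on positives
  v <- sort(stats::runif(20, 0.01, 100))
  expect_false(is.unsorted(log2Transform(matrix(v, 1))[1, ]))
  expect_error(log2Transform(matrix(-1)), "non-negative")
})

test_that("missing-value Euclidean distance rescales by coverage", {
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(1, 2, NA, 8))
  # shared columns 1,2,4; squared sum 16; rescale by 4/3
  expect_equal(euclideanMissing(m)["g1", "g2"], sqrt(16 * 4 / 3),
               tolerance = 1e-12)
  m2 <- rbind(a = c(1, NA), b = c(NA, 1))
  expect_error(euclideanMissing(m2), "mutually present")
})

test_that("the closest pair of identical rows merges first", {
  m <- rbind(g1 = c(1, 1, 1), g2 = c(1, 1, 1), g3 = c(9, 9, 9))
  h <- hclusterGenes(m)
  expect_equal(sort(h$merge[1, ]), c(-2L, -1L))
  expect_equal(h$height[1], 0)
  expect_false(is.unsorted(h$height))   # complete linkage is monotone
})

test_that("merge heights and partitions equal the brute-force oracle", {
  set.seed(21)
  for (r in 1:20) {
    n <- sample(3:7, 1)
    m <- matrix(stats::rnorm(n * 5), n, 5,
                dimnames = list(paste0("g", seq_len(n)), NULL))
    D <- euclideanMissing(m)
    h <- hclusterGenes(m)
    oracle <- bruteCompleteLinkage(D)
    expect_equal(h$height, oracle$heights, tolerance = 1e-9)
    for (s in seq_len(n - 2)) {
      expect_identical(hclustPartition(h, n - s),
                       canonicalPartition(oracle$partitions[[s]]))
    }
  }
})

test_that("clustering matches stats::hclust on tie-free data", {
  set.seed(33)
  m <- matrix(stats::rnorm(7 * 6), 7, 6,
              dimnames = list(paste0("g", 1:7), NULL))
  mine <- hclusterGenes(m)
  ref <- stats::hclust(stats::dist(m) * sqrt(1), method = "complete")
  expect_equal(mine$height, ref$height, tolerance = 1e-9)
  for (k in 2:6)
    expect_identical(hclustPartition(mine, k), hclustPartition(ref, k))
})

test_that("all-missing genes are excluded with a warning", {
  m <- rbind(g1 = c(1, 2), g2 = c(NA, NA), g3 = c(5, 6))
  expect_warning(h <- hclusterGenes(m), "g2")
  expect_setequal(h$labels, c("g1", "g3"))
})

test_that("planted expression blocks are recovered at k = 3", {
  fam <- makeFamily(familySpec(seed = 3))
  expr <- makeExpression(fam$manifest, noise_sd = 0.5, seed = 3)
  keep <- expr$blocks != "silent"
  rep <- expressionReport(expr$stage[keep, ], k = 3)
  tab <- table(rep$groups, expr$blocks[keep])
  # the recovered partition equals the planted one: each group hits exactly
  # one block and each block exactly one group
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
})

test_that("the noiseless limit recovers blocks perfectly", {
  fam <- makeFamily(familySpec(n_sp = 12, n_sph = 0, n_trypsin = 0,
                               n_chymotrypsin = 0, n_clip_sp = 0,
                               n_clip_sph = 0, n_double_clip = 0,
                               dup_groups = integer(0), seed = 6))
  expr <- makeExpression(fam$manifest,
                         block_sizes = c(larva_high = 4L,
                                         egg_pupa_high = 4L,
                                         adult_male = 4L),
                         tissue_sizes = c(midgut_L4 = 8L, head_L4 = 6L,
                                          head_AM = 5L, head_AF = 6L),
                         n_silent = 0L, noise_sd = 0, dropout_rate = 0,
                         seed = 6)
  rep <- expressionReport(expr$stage, k = 3)
  tab <- table(rep$groups, expr$blocks)
  expect_equal(sum(tab > 0), 3L)
})

test_that("expressed counts honor the strict threshold", {
  z <- matrix(0, 3, 2, dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(expressedCounts(z)$per_sample), c(0L, 0L))
  m <- matrix(c(1, 0, 3, 0.5, NA, 2), 3, 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(expressedCounts(m)$per_sample), c(2L, 2L))
  expect_equal(expressedCounts(m)$any_sample, 2L)  # g2 is (0, NA)
  expect_equal(unname(expressedCounts(m, threshold = max(m, na.rm = TRUE))$
                        per_sample), c(0L, 0L))
  # monotone non-increasing in the threshold
  prev <- Inf
  for (th in c(0, 0.5, 1, 2, 3)) {
    cur <- sum(expressedCounts(m, th)$per_sample)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("qPCR relative levels follow 2^-dCt", {
  tab <- data.frame(
    gene = rep(c("ref", "g1", "g2"), each = 2),
    sample = rep("s1", 6),
    replicate = rep(1:2, 3),
    Ct = c(20, 20, 20, 20, 23, 23)
  )
  out <- qpcrRelativeExpression(tab, reference = "ref")
  expect_equal(out$relative[out$gene == "g1"], 1)
  expect_equal(out$relative[out$gene == "g2"], 0.125)

  # reference measured in s1 but not in s2
  tab2 <- rbind(tab, data.frame(gene = "g1", sample = "s2",
                                replicate = 1, Ct = 21))
  expect_error(qpcrRelativeExpression(tab2, reference = "ref"),
               "missing in sample")
  expect_error(qpcrRelativeExpression(tab, reference = "ghost"),
               "not in table")
})

test_that("known expression ratios are recovered from noisy Ct values", {
  set.seed(12)
  genes <- c("g1", "g2")
  trueRel <- c(g1 = 4, g2 = 0.25)   # relative to the reference gene
  rows <- list()
  for (g in genes) {
    for (rep_ in 1:6) {
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, sample = "s1", replicate = rep_,
        Ct = 20 - log2(trueRel[[g]]) + stats::rnorm(1, 0, 0.1))
    }
  }
  for (rep_ in 1:6)
    rows[[length(rows) + 1]] <- data.frame(gene = "ref", sample = "s1",
                                           replicate = rep_,
                                           Ct = 20 + stats::rnorm(1, 0, 0.1))
  out <- qpcrRelativeExpression(do.call(rbind, rows), reference = "ref")
  for (g in genes) {
    got <- out$relative[out$gene == g]
    expect_lt(abs(log2(got) - log2(trueRel[[g]])), 0.5)
  }
})
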