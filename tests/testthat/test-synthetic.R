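test_that("anchor profiles honor their shape contracts", {
  for (seed in c(1L, 42L, 999L)) {
    up <- generateAnchorProfile("increasing", 11, 10, seed = seed)
    expect_length(up, 11)
    expect_true(all(up >= 0))
    expect_true(all(diff(up) > 0))                       # strictly monotone
    dn <- generateAnchorProfile("decreasing", 11, 10, seed = seed)
    expect_identical(dn, rev(up))                        # exact reversal
    pk <- generateAnchorProfile("peaked", 11, 10, seed = seed)
    expect_true(all(pk >= 0))
    s <- sign(diff(pk))
    expect_identical(sum(s == 1 & c(s[-1], -1) == -1), 1L)  # one local max
    expect_true(s[1] == 1 && s[length(s)] == -1)
  }
  expect_error(generateAnchorProfile("wiggly", 11, 10), "invalid profile kind")
  expect_error(generateAnchorProfile("increasing", 2, 10), ">= 3")
})

test_that("planted genes at |rho| = 1 realize the sign exactly", {
  a <- generateAnchorProfile("increasing", 11, 50, seed = 5)
  yp <- plantCorrelatedGene(a, 1)
  yn <- plantCorrelatedGene(a, -1)
  expect_identical(pearsonCorrelation(a, yp), 1)
  expect_identical(pearsonCorrelation(a, yn), -1)
  expect_true(all(yp >= 0) && all(yn >= 0))
  expect_error(plantCorrelatedGene(rep(3, 11), 0.5), "constant")
  expect_error(plantCorrelatedGene(a, 1.2), "<= 1")
  expect_error(plantCorrelatedGene(a, 0, noiseSd = 0), "degenerate")
})

test_that("planted correlation is unbiased near the target (Monte Carlo)", {
  a <- generateAnchorProfile("increasing", 11, 50, seed = 5)
  rs <- vapply(1:1000, function(s)
    pearsonCorrelation(a, plantCorrelatedGene(a, 0.9, noiseSd = 1, seed = s)),
    numeric(1))
  expect_lt(abs(mean(rs) - 0.9), 0.05)
})

test_that("generateDataset bookkeeping, determinism and substream stability", {
  anchors <- data.frame(anchorId = c("A1", "A2"),
                        kind = c("increasing", "peaked"),
                        amplitude = c(50, 80))
  planted <- data.frame(geneId = paste0("p", 1:4),
                        anchorId = rep(c("A1", "A2"), 2),
                        targetRho = c(0.9, -0.9, 0.8, -0.8),
                        family = "G2-like")
  spec <- syntheticSpec(anchors, planted, nBackground = 10,
                        backgroundFamilies = "MYB", seed = 7)
  ds <- generateDataset(spec)
  expect_identical(dim(ds$matrix), c(16L, 11L))          # 2 + 4 + 10 genes
  expect_identical(length(ds$guides), 2L)
  expect_identical(nrow(plantedTruth(ds$truth)), 4L)

  # same seed -> bit-identical serialized output
  f1 <- tempfile(); f2 <- tempfile()
  writeExpressionMatrix(ds$matrix, f1)
  writeExpressionMatrix(generateDataset(spec)$matrix, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # adding a gene never perturbs the others (per-gene substreams)
  spec2 <- syntheticSpec(anchors,
                         rbind(planted, data.frame(geneId = "extra",
                                                   anchorId = "A1",
                                                   targetRho = 0.5,
                                                   family = "G2-like")),
                         nBackground = 10, backgroundFamilies = "MYB",
                         seed = 7)
  m1 <- SummarizedExperiment::assay(ds$matrix)
  m2 <- SummarizedExperiment::assay(generateDataset(spec2)$matrix)
  expect_identical(m2[rownames(m1), ], m1)

  # duplicate ids rejected at spec construction
  expect_error(syntheticSpec(anchors, rbind(planted, planted[1, ]),
                             seed = 7),
               "duplicate")
})

test_that("recovery scoring handles exact, noisy and degenerate cases", {
  anchors <- data.frame(anchorId = c("A1", "A2"),
                        kind = c("increasing", "decreasing"),
                        amplitude = c(50, 50))
  planted <- data.frame(geneId = c("pp", "pn", "weak"),
                        anchorId = "A1",
                        targetRho = c(1, -1, 0.2),
                        family = "G2-like")
  spec <- syntheticSpec(anchors, planted, nBackground = 30,
                        backgroundFamilies = "G2-like", seed = 3)
  ds <- generateDataset(spec)
  tab <- correlateGuides(ds$matrix, ds$guides)
  net <- buildNetwork(tab, ds$families, spec = thresholdSpec(0.6))
  sc <- scoreRecovery(ds$truth, net, ds$backgroundIds)
  expect_identical(sc$sensitivity, 1)    # both |rho|=1 plants recovered
  expect_identical(sc$signAccuracy, 1)   # with the correct signs
  expect_gt(sc$specificity, 0.5)

  # all-background dataset: sensitivity not applicable, specificity near 1
  spec0 <- syntheticSpec(anchors, planted[0, ], nBackground = 60,
                         backgroundFamilies = "G2-like", seed = 9)
  ds0 <- generateDataset(spec0)
  net0 <- buildNetwork(correlateGuides(ds0$matrix, ds0$guides),
                       ds0$families, spec = thresholdSpec(0.6))
  sc0 <- scoreRecovery(ds0$truth, net0, ds0$backgroundIds)
  expect_true(is.na(sc0$sensitivity))
  expect_gt(sc0$specificity, 0.6)
})

test_that("background false-positive rate matches an independent null simulation", {
  # implementation path: one anchor, many background genes, network at 0.6
  anchors <- data.frame(anchorId = "A1", kind = "increasing", amplitude = 50)
  spec <- syntheticSpec(anchors,
                        data.frame(geneId = character(),
                                   anchorId = character(),
                                   targetRho = numeric(),
                                   family = character()),
                        nBackground = 1000, backgroundFamilies = "F",
                        seed = 21)
  ds <- generateDataset(spec)
  tab <- correlateGuides(ds$matrix, ds$guides)
  hits <- filterByThreshold(tab, thresholdSpec(0.6), "A1")
  phat <- length(hits) / 1000

  # independent brute-force null: iid Gaussian vectors against the very
  # same anchor profile, naive coefficient
  a <- SummarizedExperiment::assay(ds$matrix)["A1", ]
  set.seed(4242)
  nullHits <- mean(replicate(4000, {
    abs(naivePearson(a, rnorm(11))) > 0.6
  }))

  # two-sided binomial check at ~99% confidence on the difference
  se <- sqrt(nullHits * (1 - nullHits) * (1 / 1000 + 1 / 4000))
  expect_lt(abs(phat - nullHits), 2.58 * se + 1e-9)
})

test_that("writeSyntheticDataset emits files the readers accept verbatim", {
  ds <- generateDataset(defaultSyntheticSpec(seed = 11))
  d <- tempfile()
  paths <- writeSyntheticDataset(ds, d)
  m <- readExpressionMatrix(paths[["matrix"]])
  expect_identical(rownames(m), rownames(ds$matrix))
  g <- readGuideList(paths[["guides"]])
  expect_identical(guideIds(g), guideIds(ds$guides))
  a <- readFamilyTable(paths[["families"]])
  expect_identical(familyAssignments(a), familyAssignments(ds$families))
  expect_true(file.exists(paths[["truth"]]))
})
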