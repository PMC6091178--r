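test_that("pearsonCorrelation matches hand-derived values and the undefined contract", {
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(3, 2, 1)), -1)
  # cross-products (-1.5,-0.5,0.5,1.5)x(-1.5,0.5,-0.5,1.5): 4 / sqrt(5*5)
  expect_equal(pearsonCorrelation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(pearsonCorrelation(c(5, 5, 5), c(1, 2, 3))))
  expect_error(pearsonCorrelation(1:4, 1:5), "equal length")
  expect_error(pearsonCorrelation(1:2, 2:1), "at least 3")
})

test_that("pearsonCorrelation is symmetric and affine invariant", {
  for (seed in 1:25) {
    set.seed(seed)
    x <- rnorm(11); y <- rnorm(11)
    expect_identical(pearsonCorrelation(x, y), pearsonCorrelation(y, x))
    a <- rnorm(1)
    if (a == 0) a <- 1
    b <- rnorm(1)
    expect_equal(pearsonCorrelation(a * x + b, y),
                 sign(a) * pearsonCorrelation(x, y), tolerance = 1e-12)
  }
})

test_that("correlateGuides reproduces the 4-gene toy matrix", {
  m <- rbind(gA = c(1, 2, 3, 4), gB = c(1, 3, 2, 4),
             gC = c(4, 3, 2, 1), gD = c(2, 2, 2, 2))
  colnames(m) <- paste0("s", 1:4)
  eg <- ExpressionGradient(m)
  tab <- suppressMessages(correlateGuides(eg, GuideGeneSet("gA", "gA")))
  r <- corValues(tab)
  expect_equal(unname(r[1, c("gA", "gB", "gC")]), c(1, 0.8, -1))
  expect_true(is.na(r[1, "gD"]))  # zero variance -> undefined, not 0
  expect_identical(numSamples(tab), 4L)
})

test_that("correlateGuides errors name a missing guide and self-correlation is 1", {
  eg <- randomGradient(10, 11, seed = 3)
  expect_error(correlateGuides(eg, GuideGeneSet("X", "absent_gene")),
               "absent_gene")
  tab <- correlateGuides(eg, GuideGeneSet(c("a", "b"), c("g002", "g007")))
  expect_equal(corValues(tab)["g002", "g002"], 1, tolerance = 1e-12)
  expect_equal(corValues(tab)["g007", "g007"], 1, tolerance = 1e-12)
})

test_that("correlateGuides matches the naive two-pass oracle elementwise", {
  for (seed in 1:20) {
    eg <- randomGradient(20, 11, seed = seed)
    m <- SummarizedExperiment::assay(eg)
    guides <- GuideGeneSet(rownames(m)[1:3], rownames(m)[1:3])
    r <- corValues(correlateGuides(eg, guides))
    for (g in rownames(r))
      for (t in colnames(r))
        expect_equal(r[g, t], naivePearson(m[g, ], m[t, ]),
                     tolerance = 1e-12)
  }
})

test_that("log2 pre-transform option changes the values it should", {
  eg <- randomGradient(6, 11, seed = 9)
  g <- GuideGeneSet("g001", "g001")
  raw <- corValues(correlateGuides(eg, g))
  lg <- corValues(correlateGuides(eg, g, logTransform = TRUE))
  m <- log2(SummarizedExperiment::assay(eg) + 1)
  expect_equal(lg[1, "g004"], naivePearson(m["g001", ], m["g004", ]),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(raw[1, "g004"], lg[1, "g004"])))
})

test_that("filterByThreshold enumerates the toy outcomes exactly", {
  r <- matrix(c(1, 0.9, 0.7, -0.85, NA), nrow = 1,
              dimnames = list("G", c("G", "g1", "g2", "g3", "g4")))
  tab <- makeCorTable(r)
  expect_identical(filterByThreshold(tab, thresholdSpec(0.8), "G"),
                   c("g1", "g3"))
  expect_identical(filterByThreshold(tab, thresholdSpec(0.8, mode = "negative"), "G"),
                   "g3")
  expect_identical(filterByThreshold(tab, thresholdSpec(0.8, mode = "positive"), "G"),
                   "g1")
  # no |r| can exceed 1 strictly
  expect_identical(filterByThreshold(tab, thresholdSpec(1), "G"), character(0))
  # non-strict at an exact boundary
  expect_identical(filterByThreshold(tab, thresholdSpec(0.9, strict = FALSE), "G"),
                   "g1")
  expect_identical(filterByThreshold(tab, thresholdSpec(0.9, strict = TRUE), "G"),
                   character(0))
  expect_error(filterByThreshold(tab, thresholdSpec(0.8), "nope"),
               "unknown guide")
})

test_that("threshold filtering is monotone in tau and never passes undefined", {
  set.seed(11)
  r <- matrix(runif(40, -1, 1), nrow = 1,
              dimnames = list("G", c("G", sprintf("t%02d", 1:39))))
  r[1, sample(2:40, 5)] <- NA
  tab <- makeCorTable(r)
  taus <- sort(runif(6, 0.05, 0.95))
  for (mode in c("absolute", "positive", "negative")) {
    prev <- NULL
    for (tau in rev(taus)) {  # descending tau -> growing sets
      cur <- filterByThreshold(tab, thresholdSpec(tau, mode = mode), "G")
      expect_false("G" %in% cur)
      expect_false(any(is.na(r[1, cur])))
      if (!is.null(prev)) expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("thresholdSpec validates tau", {
  expect_error(thresholdSpec(0), "tau")
  expect_error(thresholdSpec(1.5), "tau")
  expect_s4_class(thresholdSpec(1), "ThresholdSpec")
})
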