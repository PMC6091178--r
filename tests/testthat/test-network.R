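test_that("buildNetwork enumerates the toy edges exactly", {
  net <- toyNetwork()
  nd <- networkNodes(net)
  expect_setequal(nd$id, c("G1", "G2", "t1", "t2"))  # t3 excluded: |r| < 0.6
  ed <- networkEdges(net)
  expect_identical(nrow(ed), 3L)
  expect_identical(ed$sign[ed$guide == "G1" & ed$tf == "t1"], "positive")
  expect_identical(ed$sign[ed$guide == "G1" & ed$tf == "t2"], "negative")
  expect_identical(ed$sign[ed$guide == "G2" & ed$tf == "t2"], "negative")
})

test_that("buildNetwork respects family restriction and rejects unknown families", {
  r <- matrix(c(0.9, 0.9), nrow = 1,
              dimnames = list("G1", c("t1", "t2")))
  ann <- TFFamilyAnnotation(c(t1 = "G2-like", t2 = "MYB"))
  tab <- makeCorTable(r)
  net <- buildNetwork(tab, ann, family = "G2-like", spec = thresholdSpec(0.6))
  expect_identical(networkEdges(net)$tf, "t1")
  expect_error(buildNetwork(tab, ann, family = "NAC"),
               "unknown family 'NAC'.*G2-like.*MYB")
})

test_that("a threshold above every |r| leaves guide nodes only", {
  net <- toyNetwork(spec = thresholdSpec(0.95))
  expect_identical(nrow(networkEdges(net)), 0L)
  expect_setequal(networkNodes(net)$id, c("G1", "G2"))
})

test_that("network edges match brute-force pair enumeration on random toys", {
  for (seed in 1:10) {
    eg <- randomGradient(50, 11, seed = 100 + seed)
    m <- SummarizedExperiment::assay(eg)
    guides <- rownames(m)[1:5]
    ann <- TFFamilyAnnotation(setNames(rep(c("F1", "F2"), length.out = 45),
                                       rownames(m)[6:50]))
    tab <- correlateGuides(eg, GuideGeneSet(guides, guides))
    tau <- runif(1, 0.2, 0.8)
    net <- buildNetwork(tab, ann, family = "all", spec = thresholdSpec(tau))
    got <- networkEdges(net)
    got <- got[order(got$guide, got$tf, method = "radix"), ]
    want <- bruteForceEdges(m, guides, rownames(m)[6:50], tau)
    expect_identical(got$guide, want$guide)
    expect_identical(got$tf, want$tf)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_identical(got$sign, want$sign)
  }
})

test_that("raising tau never adds edges", {
  eg <- randomGradient(40, 11, seed = 77)
  guides <- rownames(eg)[1:3]
  ann <- TFFamilyAnnotation(setNames(rep("F", 37), rownames(eg)[4:40]))
  tab <- correlateGuides(eg, GuideGeneSet(guides, guides))
  prev <- NULL
  for (tau in c(0.9, 0.7, 0.5, 0.3)) {
    ed <- networkEdges(buildNetwork(tab, ann, spec = thresholdSpec(tau)))
    keys <- paste(ed$guide, ed$tf)
    if (!is.null(prev)) expect_true(all(prev %in% keys))
    prev <- keys
  }
})

test_that("reflecting the TF pool flips every edge sign", {
  # x -> max(x) - x is an affine map with negative slope that stays
  # nonnegative, so it flips each correlation sign exactly
  eg <- randomGradient(30, 11, seed = 55)
  m <- SummarizedExperiment::assay(eg)
  guides <- rownames(m)[1:3]
  pool <- rownames(m)[4:30]
  m2 <- m
  for (t in pool) m2[t, ] <- max(m2[t, ]) - m2[t, ]
  ann <- TFFamilyAnnotation(setNames(rep("F", length(pool)), pool))
  tab1 <- correlateGuides(eg, GuideGeneSet(guides, guides))
  tab2 <- suppressMessages(
    correlateGuides(ExpressionGradient(m2), GuideGeneSet(guides, guides)))
  n1 <- buildNetwork(tab1, ann, spec = thresholdSpec(0.5))
  n2 <- buildNetwork(tab2, ann, spec = thresholdSpec(0.5))
  e1 <- networkEdges(n1); e1 <- e1[order(e1$guide, e1$tf), ]
  e2 <- networkEdges(n2); e2 <- e2[order(e2$guide, e2$tf), ]
  expect_identical(e1$tf, e2$tf)
  expect_identical(e1$sign,
                   ifelse(e2$sign == "positive", "negative", "positive"))
  s1 <- countEdgeSigns(n1); s2 <- countEdgeSigns(n2)
  expect_identical(s1$positive, s2$negative)
  expect_identical(s1$negative, s2$positive)
})

test_that("countEdgeSigns classifies TFs by majority with ties as mixed", {
  signs <- countEdgeSigns(toyNetwork())
  expect_identical(signs$positive, 1L)  # t1
  expect_identical(signs$negative, 1L)  # t2
  expect_identical(signs$mixed, 0L)

  empty <- toyNetwork(spec = thresholdSpec(0.95))
  z <- countEdgeSigns(empty)
  expect_identical(c(z$positive, z$negative, z$mixed), c(0L, 0L, 0L))

  r <- matrix(c(0.8, -0.7), nrow = 2,
              dimnames = list(c("G1", "G2"), "t1"))
  ann <- TFFamilyAnnotation(c(t1 = "F"))
  tied <- buildNetwork(makeCorTable(r), ann, spec = thresholdSpec(0.6))
  expect_identical(suppressMessages(countEdgeSigns(tied))$mixed, 1L)
})

test_that("selectNegativeCandidates applies the partner cutoff and sort order", {
  cands <- selectNegativeCandidates(toyNetwork(), minNegativePartners = 2)
  expect_identical(cands$tf_id, "t2")
  expect_identical(cands$n_negative, 2L)
  expect_identical(cands$negative_partners, "G1;G2")
  expect_identical(cands$positive_partners, "")

  none <- selectNegativeCandidates(toyNetwork(spec = thresholdSpec(0.95)), 1)
  expect_identical(nrow(none), 0L)
})

test_that("SIF export is deterministic and round-trips the edge set", {
  net <- toyNetwork()
  f <- tempfile(fileext = ".sif")
  exportSIF(net, f)
  expect_identical(readLines(f),
                   c("G1\tpos\tt1", "G1\tneg\tt2", "G2\tneg\tt2"))
  f2 <- tempfile()
  exportSIF(net, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))
  back <- readSIF(f)
  ed <- networkEdges(net)
  expect_setequal(paste(back$guide, back$tf, back$sign),
                  paste(ed$guide, ed$tf, ed$sign))

  empty <- tempfile()
  exportSIF(toyNetwork(spec = thresholdSpec(0.95)), empty)
  expect_identical(file.size(empty), 0)
})

test_that("GraphML export has typed nodes, 6-decimal r and deterministic bytes", {
  net <- toyNetwork()
  f <- tempfile(fileext = ".graphml")
  exportGraphML(net, f)
  doc <- xml2::read_xml(f)
  ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
  nodes <- xml2::xml_find_all(doc, ".//g:node", ns)
  edges <- xml2::xml_find_all(doc, ".//g:edge", ns)
  expect_identical(length(nodes), 4L)
  expect_identical(length(edges), 3L)
  rVals <- xml2::xml_text(
    xml2::xml_find_all(doc, ".//g:edge/g:data[@key='d_r']", ns))
  expect_true("0.700000" %in% rVals)
  types <- xml2::xml_text(
    xml2::xml_find_all(doc, ".//g:node/g:data[@key='d_type']", ns))
  expect_identical(sort(unique(types)), c("guide", "tf"))

  f2 <- tempfile(fileext = ".graphml")
  exportGraphML(net, f2)
  expect_identical(readLines(f), readLines(f2))

  fe <- tempfile(fileext = ".graphml")
  exportGraphML(toyNetwork(spec = thresholdSpec(0.95)), fe)
  expect_identical(
    length(xml2::xml_find_all(xml2::read_xml(fe), ".//g:edge", ns)), 0L)
})

test_that("SIF and GraphML agree on the edge multiset", {
  net <- toyNetwork()
  fs <- tempfile(); fg <- tempfile()
  exportSIF(net, fs)
  exportGraphML(net, fg)
  sif <- readSIF(fs)
  doc <- xml2::read_xml(fg)
  ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
  edges <- xml2::xml_find_all(doc, ".//g:edge", ns)
  gml <- paste(xml2::xml_attr(edges, "source"),
               xml2::xml_attr(edges, "target"))
  expect_setequal(paste(sif$guide, sif$tf), gml)
})
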