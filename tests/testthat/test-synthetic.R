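test_that("proteomics generator honours templates and all-zero rows", {
  se <- generateProteomics(c(all_zero = 5), noiseSd = 0, seed = 1)
  expect_identical(unname(SummarizedExperiment::assay(se)),
                   matrix(0, 5, 6))

  se <- generateProteomics(c(sharp_decrease = 3), noiseSd = 0, seed = 1)
  mat <- SummarizedExperiment::assay(se)
  expect_true(all(mat[, "S4"] < mat[, "S3"]))
  expect_true(all(mat >= 0))

  # reproducibility: same seed gives identical output
  a <- generateProteomics(c(sharp_increase = 10, flat = 5), noiseSd = 0.3,
                          seed = 42)
  b <- generateProteomics(c(sharp_increase = 10, flat = 5), noiseSd = 0.3,
                          seed = 42)
  expect_identical(SummarizedExperiment::assay(a),
                   SummarizedExperiment::assay(b))

  expect_error(generateProteomics(c(flat = -1), 0.1, 1), "non-negative")
  expect_error(generateProteomics(c(nope = 3), 0.1, 1), "pattern labels")
})

test_that("interactome generator yields a simple scored graph at the expected density", {
  e <- generateInteractome(2, 1, seed = 1)
  expect_equal(nrow(e), 1L)

  e <- generateInteractome(200, 8, seed = 7)
  expect_true(all(e$a != e$b))
  expect_true(all(e$confidence >= 0 & e$confidence <= 1))
  expect_false(anyDuplicated(paste(pmin(e$a, e$b), pmax(e$a, e$b))) > 0)
  # binomial bound on the edge count: mean n*k/2, sd sqrt(Np(1-p))
  nPairs <- choose(200, 2); p <- 8 / 199
  expect_lt(abs(nrow(e) - nPairs * p), 3 * sqrt(nPairs * p * (1 - p)))
  # every conventional threshold keeps something
  for (t in seq(0.4, 0.9, 0.1))
    expect_gt(nrow(filterByConfidence(e, t)), 0)

  expect_error(generateInteractome(10, 10, seed = 1), "meanDegree")
})

test_that("regulon generator produces distinct arcs from the pool", {
  expect_equal(nrow(generateRegulon(0, 3, letters)), 0L)

  r <- generateRegulon(1, 3, letters, seed = 2)
  expect_equal(nrow(r), 3L)
  expect_equal(length(unique(r$tf)), 1L)

  r <- generateRegulon(10, 5, sprintf("g%02d", 1:60), seed = 3)
  expect_equal(nrow(r), 50L)
  expect_false(anyDuplicated(paste(r$tf, r$target)) > 0)
  expect_true(all(r$tf != r$target))

  expect_error(generateRegulon(3, 2, character()), "empty")
})

test_that("planting motifs on fresh nodes adds at least the requested count", {
  net <- mixedFixture(seed = 5)
  un <- plantMotifs(net, "Co-regulated PPI", 0)
  expect_identical(un$network@ppi, net@ppi)

  before <- triadCensus(net)
  pl <- plantMotifs(net, "Bi-feedforward Loop", 20)
  after <- triadCensus(pl$network)
  b <- before$count[before$name == "Bi-feedforward Loop"]
  a <- after$count[after$name == "Bi-feedforward Loop"]
  expect_gte((if (length(a)) a else 0) - (if (length(b)) b else 0), 20)

  expect_error(plantMotifs(net, "No Such Motif", 5), "unknown triad class")
})

test_that("planting into edge lists survives threshold filtering", {
  edges <- generateInteractome(60, 3, seed = 11)
  arcs <- generateRegulon(8, 3, sprintf("N%04d", 1:60), seed = 12)
  pl <- plantMotifTriples(edges, arcs, sprintf("N%04d", 1:60),
                          "Feedback with a PPI", 10, seed = 13)
  top <- filterByConfidence(pl$edges, 0.9)
  net <- integratedNetwork(ppi = top, reg = pl$arcs)
  cen <- triadCensus(net)
  expect_gte(cen$count[cen$name == "Feedback with a PPI"], 10)
})

test_that("annotation generator plants a maximally enriched term", {
  bg <- sprintf("G%03d", 1:40)
  q <- bg[1:8]
  ann <- generateAnnotations(1, plantedTermSize = 8, plantedOverlap = 8,
                             background = bg, query = q, seed = 1)
  expect_setequal(ann$terms$planted_term, q)

  # a single term covering the whole background is uninformative
  ann <- generateAnnotations(1, plantedTermSize = 40, plantedOverlap = 8,
                             background = bg, query = q, seed = 1)
  res <- hypergeomEnrich(q, ann$terms, bg, maxFrac = 1)
  expect_equal(res$p, 1)

  expect_error(
    generateAnnotations(5, plantedTermSize = 3, plantedOverlap = 9,
                        background = bg, query = q, seed = 1),
    "impossible")
})
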