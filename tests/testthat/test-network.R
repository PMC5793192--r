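test_that("confidence filtering is inclusive and monotone in the threshold", {
  e <- data.frame(a = letters[1:4], b = letters[5:8],
                  confidence = c(0.2, 0.4, 0.8, 1.0))
  expect_equal(nrow(filterByConfidence(e, 0)), 4L)
  expect_equal(filterByConfidence(e, 1)$confidence, 1.0)
  expect_equal(nrow(filterByConfidence(e, 0.4)), 3L)   # >= is inclusive
  expect_error(filterByConfidence(e, 1.2), "\\[0, 1\\]")

  edges <- generateInteractome(150, 6, seed = 21)
  counts <- sapply(seq(0.4, 0.9, 0.1),
                   function(t) nrow(filterByConfidence(edges, t)))
  expect_true(all(diff(counts) <= 0))
  # subset property, not only counts
  keys <- lapply(seq(0.4, 0.9, 0.1), function(t) {
    f <- filterByConfidence(edges, t); paste(f$a, f$b)
  })
  for (i in 2:6) expect_true(all(keys[[i]] %in% keys[[i - 1]]))
})

test_that("active subnetwork induction keeps both-active edges and tracks isolates", {
  k4 <- as.data.frame(t(combn(paste0("p", 1:4), 2)))
  names(k4) <- c("a", "b"); k4$confidence <- 1
  net <- induceActiveSubnetwork(k4, c("p1", "p2", "p5"))
  expect_equal(nrow(net@ppi), 1L)
  expect_setequal(net@nodes, c("p1", "p2"))
  expect_identical(net@isolated, "p5")

  # disjoint active set: everything isolated
  net0 <- induceActiveSubnetwork(k4, c("x", "y"))
  expect_equal(nrow(net0@ppi), 0L)
  expect_setequal(net0@isolated, c("x", "y"))

  # active set covering all endpoints reproduces the background
  netAll <- induceActiveSubnetwork(k4, paste0("p", 1:4))
  expect_equal(nrow(netAll@ppi), 6L)

  # idempotence
  again <- induceActiveSubnetwork(netAll@ppi, paste0("p", 1:4))
  expect_identical(again@ppi, netAll@ppi)
})

test_that("active regulon extraction applies the both-endpoint rule", {
  expect_equal(nrow(extractActiveRegulon(
    data.frame(tf = character(), target = character()), c("a"))), 0L)

  arcs <- data.frame(tf = c("a", "a", "b", "c", "z"),
                     target = c("b", "q", "c", "q", "a"))
  kept <- extractActiveRegulon(arcs, c("a", "b", "c", "z"))
  expect_equal(nrow(kept), 3L)   # a->q and c->q dropped
  expect_true(all(kept$target != "q"))

  either <- extractActiveRegulon(arcs, c("a", "b", "c", "z"),
                                 rule = "either")
  expect_equal(nrow(either), 5L)
})

test_that("integration counts a PPI edge as two arcs and a regulatory arc as one", {
  ppi <- integratedNetwork(ppi = data.frame(a = c("x", "y"), b = c("y", "z"),
                                            confidence = c(0.5, 0.6)))
  net <- integrateNetworks(ppi, data.frame(tf = "w", target = "x"))
  expect_equal(totalArcs(net), 2L * 2L + 1L)
  expect_true("w" %in% net@nodes)

  empty <- integratedNetwork()
  expect_equal(totalArcs(empty), 0L)
})

test_that("network statistics satisfy the arc-accounting identity", {
  # hand-built: 3 PPI edges, 2 arcs, 1 isolated active
  net <- integratedNetwork(
    ppi = data.frame(a = c("p1", "p2", "p3"), b = c("p2", "p3", "p4"),
                     confidence = 1),
    reg = data.frame(tf = c("p1", "p4"), target = c("p3", "p2")),
    isolated = "p9")
  st <- networkStats(net)
  expect_equal(st$nProteinsConnected, 4L)
  expect_equal(st$nProteinsWithIsolates, 5L)
  expect_equal(st$nPPIEdges, 3L)
  expect_equal(st$nRegArcs, 2L)
  expect_equal(st$nArcsTotal, 8L)

  expect_equal(unname(unlist(networkStats(integratedNetwork()))),
               rep(0L, 7))
})

test_that("the thresholded series shrinks monotonically", {
  edges <- generateInteractome(120, 5, seed = 31)
  arcs <- generateRegulon(10, 4, sprintf("N%04d", 1:120), seed = 32)
  active <- sprintf("N%04d", 1:80)
  nets <- buildNetworkSeries(edges, arcs, active)
  st <- do.call(rbind, lapply(nets, networkStats))
  expect_true(all(diff(st$nPPIEdges) <= 0))
  expect_true(all(diff(st$nProteinsConnected) <= 0))
  expect_true(all(diff(st$nRegArcs) <= 0))
  expect_true(all(st$nArcsTotal == 2 * st$nPPIEdges + st$nRegArcs))
})

test_that("malformed networks are rejected by the validity checks", {
  expect_warning(integratedNetwork(
    ppi = data.frame(a = "x", b = "x", confidence = 0.5)), "self")
  expect_warning(integratedNetwork(
    ppi = data.frame(a = c("x", "y"), b = c("y", "x"),
                     confidence = c(0.2, 0.9))), "duplicate")
  expect_error(methods::new("IntegratedNetwork",
    nodes = "x", ppi = data.frame(a = "x", b = "y", confidence = 2),
    reg = data.frame(tf = character(), target = character()),
    isolated = character(), threshold = NA_real_))
})
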