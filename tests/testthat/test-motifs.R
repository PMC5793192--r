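test_that("named triad patterns classify to themselves and are label-invariant", {
  tab <- triadClassNames()
  expect_equal(nrow(tab), 13L)
  expect_false(anyDuplicated(tab$code) > 0)

  # canonical code is invariant under all node relabelings, for every
  # possible pair-state combination
  for (s12 in 0:3) for (s13 in 0:3) for (s23 in 0:3) {
    codes <- apply(rbind(c(1,2,3), c(1,3,2), c(2,1,3),
                         c(2,3,1), c(3,1,2), c(3,2,1)), 1, function(p) {
      st <- matrix(0L, 3, 3)
      flip <- function(s) ifelse(s == 1, 2, ifelse(s == 2, 1, s))
      st[1,2] <- s12; st[2,1] <- flip(s12)
      st[1,3] <- s13; st[3,1] <- flip(s13)
      st[2,3] <- s23; st[3,2] <- flip(s23)
      q <- st[p, p]
      rCanonicalCode(q[1,2], q[1,3], q[2,3])
    })
    expect_equal(length(unique(codes)), 1L)
  }
})

test_that("representative triads get the expected display names", {
  clique <- integratedNetwork(ppi = data.frame(
    a = c("x", "x", "y"), b = c("y", "z", "z"), confidence = 1))
  expect_equal(classifyTriad(clique)$name, "Protein Clique")

  coreg <- integratedNetwork(reg = data.frame(
    tf = c("x", "x"), target = c("y", "z")))
  expect_equal(classifyTriad(coreg)$name, "Co-regulated Proteins")

  coregPPI <- integratedNetwork(
    ppi = data.frame(a = "y", b = "z", confidence = 1),
    reg = data.frame(tf = c("x", "x"), target = c("y", "z")))
  expect_equal(classifyTriad(coregPPI)$name, "Co-regulated PPI")

  disconnected <- integratedNetwork(
    ppi = data.frame(a = "x", b = "y", confidence = 1), nodes = "z")
  expect_error(classifyTriad(disconnected), "disconnected")
})

test_that("census matches closed forms and the all-triples oracle", {
  triangle <- integratedNetwork(ppi = data.frame(
    a = c("x", "x", "y"), b = c("y", "z", "z"), confidence = 1))
  cen <- triadCensus(triangle)
  expect_equal(cen$count[cen$name == "Protein Clique"], 1)
  expect_equal(nrow(cen), 1L)

  star <- integratedNetwork(ppi = data.frame(
    a = "c", b = paste0("l", 1:3), confidence = 1))
  cen <- triadCensus(star)
  expect_equal(cen$count[cen$name == "PPI Path"], choose(3, 2))

  for (s in 1:3) {
    net <- mixedFixture(nNodes = 25, meanDegree = 3, seed = s)
    cen <- triadCensus(net)
    oracle <- bruteCensus(net)
    merged <- merge(cen, oracle, by = "code", all = TRUE)
    expect_false(any(is.na(merged$count.x)) || any(is.na(merged$count.y)))
    expect_equal(merged$count.x, as.numeric(merged$count.y))
  }
})

test_that("switching nulls preserve the per-node degree triples exactly", {
  net <- mixedFixture(nNodes = 40, meanDegree = 4, nTfs = 8, seed = 2)
  m0 <- ShewEETNet:::asMixedIndices(net)
  set.seed(11)
  res <- ShewEETNet:::cpp_rewire_mixed(m0$ea, m0$eb, m0$at, m0$ah, m0$n,
                                       100L * (length(m0$ea) + length(m0$at)))
  expect_identical(tabulate(res$ah, m0$n), tabulate(m0$ah, m0$n))  # single-in
  expect_identical(tabulate(res$at, m0$n), tabulate(m0$at, m0$n))  # single-out
  expect_identical(tabulate(c(res$ea, res$eb), m0$n),
                   tabulate(c(m0$ea, m0$eb), m0$n))                # mutual
  # simplicity and layer separation
  ek <- paste(pmin(res$ea, res$eb), pmax(res$ea, res$eb))
  ak <- paste(pmin(res$at, res$ah), pmax(res$at, res$ah))
  expect_false(anyDuplicated(ek) > 0)
  expect_false(anyDuplicated(paste(res$at, res$ah)) > 0)
  expect_equal(sum(ak %in% ek), 0L)
  expect_false(any(res$ea == res$eb) || any(res$at == res$ah))
})

test_that("a single PPI edge cannot be rewired", {
  net <- integratedNetwork(ppi = data.frame(a = "x", b = "y",
                                            confidence = 1))
  r <- randomizeNetwork(net)
  expect_setequal(paste(r@ppi$a, r@ppi$b), paste("x", "y"))
})

test_that("switching mixes the edge set away from the original", {
  far <- 0
  for (s in 1:20) {
    edges <- generateInteractome(60, 4, seed = 300 + s)
    net <- integratedNetwork(ppi = edges)
    set.seed(s)
    r <- randomizeNetwork(net)
    k0 <- paste(pmin(net@ppi$a, net@ppi$b), pmax(net@ppi$a, net@ppi$b))
    k1 <- paste(pmin(r@ppi$a, r@ppi$b), pmax(r@ppi$a, r@ppi$b))
    jac <- length(intersect(k0, k1)) / length(union(k0, k1))
    far <- far + (jac < 0.5)
  }
  expect_gte(far, 18)
})

test_that("z-scores are zero when the null equals the real network", {
  # two PPI edges sharing no legal swap keep every null identical
  net <- integratedNetwork(ppi = data.frame(
    a = c("x", "y"), b = c("y", "z"), confidence = 1))
  sig <- motifSignificance(net, nRandom = 20, seed = 1)
  expect_true(all(sig$z == 0))
  expect_true(all(sig$pOver == 1))
  # z identity with reported mean/sd
  recomputed <- (sig$realCount - sig$nullMean) / ifelse(sig$nullSd > 0,
                                                        sig$nullSd, 1)
  expect_equal(sig$z, recomputed, tolerance = 1e-9)
})

test_that("motif calls apply the quorum and exclusive-set algebra", {
  sig <- list(
    c("M1", "M2", "M7"), c("M1", "M2"), c("M1", "M2"),
    c("M1", "M2"), c("M1", "M2", "M8"), c("M2", "M8"))
  calls <- callMotifs(sig, conserved = "M1", quorum = 5)
  expect_setequal(calls$active, c("M1", "M2"))
  expect_setequal(calls$exclusive, "M2")
  expect_false("M7" %in% calls$active)      # significant in only one network

  same <- callMotifs(sig, conserved = c("M1", "M2"), quorum = 5)
  expect_length(same$exclusive, 0L)
})

test_that("motif proteins are collected from the planted instances", {
  net <- mixedFixture(nNodes = 40, meanDegree = 2, seed = 9)
  pl <- plantMotifs(net, "Bi-feedforward Loop", 5)
  prot <- motifProteins(pl$network, "Bi-feedforward Loop")
  planted <- grep("^MOT", pl$network@nodes, value = TRUE)
  expect_true(all(planted %in% prot))
})
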