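test_that("zero-expression filter removes exactly the all-zero rows", {
  m <- rbind(p1 = rep(0, 6), p2 = c(0, 0, 0, 0, 0, 1), p3 = 1:6)
  out <- filterUnexpressed(m)
  expect_identical(rownames(out), c("p2", "p3"))

  se <- generateProteomics(c(sharp_decrease = 10, all_zero = 5),
                           noiseSd = 0.1, seed = 3)
  expect_equal(nrow(se) - nrow(filterUnexpressed(se)), 5L)
})

test_that("row standardization yields mean 0 / sd 1 and is idempotent", {
  m <- rbind(a = c(1, 2, 3, 4, 5, 6), b = c(2, 1, 7, 3, 2, 9))
  s <- standardizeProfiles(m)
  expect_lt(max(abs(rowMeans(s))), 1e-9)
  expect_equal(unname(apply(s, 1, sd)), c(1, 1))
  expect_equal(standardizeProfiles(s), s, tolerance = 1e-12)
  expect_warning(standardizeProfiles(rbind(cc = rep(2, 6), m)), "constant")
})

test_that("fuzzy c-means memberships normalize and the objective never increases", {
  se <- generateProteomics(c(sharp_decrease = 40, late_increase = 40),
                           noiseSd = 0.3, seed = 9)
  std <- standardizeProfiles(se)
  fit <- fuzzyCMeans(std, c = 2, m = 1.5, seed = 4)
  expect_lt(max(abs(rowSums(memberships(fit)) - 1)), 1e-9)
  expect_true(all(diff(fit@objective) <= 1e-9))
})

test_that("two far-separated clouds are recovered exactly", {
  set.seed(1)
  cloud1 <- matrix(rnorm(30 * 6, mean = 0, sd = 0.1), ncol = 6)
  cloud2 <- matrix(rnorm(30 * 6, mean = 50, sd = 0.1), ncol = 6)
  mat <- rbind(cloud1, cloud2)
  rownames(mat) <- sprintf("r%02d", 1:60)
  fit <- fuzzyCMeans(mat, c = 2, m = 1.5, seed = 1)
  lab <- hardLabels(fit)
  expect_equal(length(unique(lab[1:30])), 1L)
  expect_equal(length(unique(lab[31:60])), 1L)
  expect_false(lab[[1]] == lab[[60]])
})

test_that("converged solution is a fixed point of the reference implementation", {
  skip_if_not_installed("e1071")
  se <- generateProteomics(c(sharp_decrease = 50, sharp_increase = 50,
                             fast_then_slow_decrease = 50),
                           noiseSd = 0.25, seed = 2)
  std <- standardizeProfiles(se)
  fit <- fuzzyCMeans(std, c = 3, m = 1.5, seed = 2)
  ref <- e1071::cmeans(std, centers = centroids(fit), m = 1.5,
                       iter.max = 200, method = "cmeans")
  # starting the reference optimizer at our solution must not move it
  expect_equal(unname(ref$centers), unname(centroids(fit)), tolerance = 1e-3)
  expect_equal(unname(ref$membership), unname(memberships(fit)),
               tolerance = 1e-3)
})

test_that("noiseless archetypes are recovered perfectly", {
  se <- generateProteomics(c(sharp_decrease = 20, sharp_increase = 20,
                             fast_then_slow_decrease = 20,
                             late_increase = 20), noiseSd = 0, seed = 1)
  std <- standardizeProfiles(se)
  fit <- fuzzyCMeans(std, c = 4, m = 1.5, seed = 1)
  truth <- SummarizedExperiment::rowData(se)$pattern
  tab <- table(truth, hardLabels(fit))
  # every pattern maps to exactly one cluster
  expect_true(all(apply(tab, 1, function(r) sum(r > 0)) == 1))
  expect_true(all(apply(tab, 2, function(r) sum(r > 0)) == 1))
})

test_that("sharp-transition rule selects the S3->S4 step clusters", {
  fit <- methods::new("FuzzyClustering",
    memberships = matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = 2),
                         ncol = 3, byrow = FALSE)[, c(1, 2, 3)],
    centroids = rbind(c(1, 1, 1, -1, -1, -1),
                      c(-1, -1, -1, 1, 1, 1),
                      c(0.5, 0.3, 0.1, -0.1, -0.3, -0.5)),
    hardLabels = stats::setNames(c(1L, 1L, 2L, 2L, 3L, 3L),
                                 paste0("p", 1:6)),
    objective = 1, m = 1.5, converged = TRUE, seed = 1L)
  act <- identifyActiveClusters(fit, sharpRatio = 2)
  expect_setequal(downSet(act), c("p1", "p2"))
  expect_setequal(upSet(act), c("p3", "p4"))
  # p5, p6 sit in the gradual cluster: all steps equal, not sharp
  expect_false(any(c("p5", "p6") %in% activeProteins(act)))
})

test_that("missing sharp clusters raise an informative error", {
  fit <- methods::new("FuzzyClustering",
    memberships = matrix(c(1, 0, 0, 1), 2),
    centroids = rbind(c(0.5, 0.3, 0.1, -0.1, -0.3, -0.5),
                      c(0, 0.1, 0, 0.1, 0, 0.1)),
    hardLabels = stats::setNames(1:2, c("p1", "p2")),
    objective = 1, m = 1.5, converged = TRUE, seed = 1L)
  expect_error(identifyActiveClusters(fit), "sharpRatio")
})
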