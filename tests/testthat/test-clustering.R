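test_that("membership probabilities follow W = 1 - D/rowmax", {
  expect_equal(assignmentProbabilities(rbind(c(1, 2, 4))),
               rbind(c(0.75, 0.5, 0)))
  expect_equal(assignmentProbabilities(rbind(c(0, 3))), rbind(c(1, 0)))
  # degenerate all-zero row: uniform by convention
  expect_equal(assignmentProbabilities(rbind(c(0, 0))), rbind(c(1, 1)))
  expect_error(assignmentProbabilities(rbind(c(-1, 2))), "non-negative")
})

test_that("greedy capacity assignment follows the ordered-pair rule", {
  # hand simulation: (1,0) prob 0.9 first -> point 1 to cluster 0;
  # (2,0) prob 0.8 blocked by capacity -> point 2 to cluster 1
  W <- rbind(c(0.9, 0.0), c(0.8, 0.1))
  expect_equal(initialEqualAssignment(W, c(1, 1)), c(0L, 1L))
  # degenerate capacity: everything to cluster 0
  W2 <- matrix(runif(10), 5, 2)
  expect_equal(initialEqualAssignment(W2, c(5, 0)), rep(0L, 5))
  expect_error(initialEqualAssignment(W2, c(3, 1)), "capacity")
})

test_that("degenerate cluster counts reduce to closed forms", {
  set.seed(53)
  pts <- matrix(rnorm(24), 12, 2)
  one <- fitEqualSizeKmeans(pts, 1, seed = 2)
  expect_equal(inertia(one),
               sum(sweep(pts, 2, colMeans(pts))^2), tolerance = 1e-9)
  all <- fitEqualSizeKmeans(pts, 12, seed = 2)
  expect_equal(inertia(all), 0, tolerance = 1e-12)
  expect_error(fitEqualSizeKmeans(pts, 13, seed = 1), "exceed")
  expect_error(fitEqualSizeKmeans(pts, 0, seed = 1), ">= 1")
})

test_that("well-separated pairs recover the textbook partition", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  cm <- fitEqualSizeKmeans(pts, 2, seed = 11)
  expect_equal(clusterLabels(cm), c(0L, 0L, 1L, 1L))
  expect_equal(unname(table(clusterLabels(cm))), c(2L, 2L),
               ignore_attr = TRUE)
  # relabelling: cluster 0 sits left on axis 0
  expect_lt(centroids(cm)[1, 1], centroids(cm)[2, 1])
})

test_that("training refinement is monotone, balanced and deterministic", {
  set.seed(59)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    C <- sample(2:5, 1)
    pts <- matrix(rnorm(2 * n), n, 2)
    cm <- fitEqualSizeKmeans(pts, C, seed = i)
    sizes <- tabulate(clusterLabels(cm) + 1L, nbins = C)
    expect_lte(diff(range(sizes)), 1)
    expect_true(all(abs(sizes - n / C) < 1))
    if (length(cm@iterInertia) > 1)
      expect_true(all(diff(cm@iterInertia) < 0))
    # centroids equal their cluster means at convergence
    for (c in seq_len(C) - 1L)
      expect_equal(centroids(cm)[c + 1L, ],
                   colMeans(pts[clusterLabels(cm) == c, , drop = FALSE]),
                   tolerance = 1e-8)
  }
  pts <- matrix(rnorm(40), 20, 2)
  expect_identical(fitEqualSizeKmeans(pts, 4, seed = 7),
                   fitEqualSizeKmeans(pts, 4, seed = 7))
})

test_that("equal bipartitions match exhaustive search when well separated", {
  # enumerate all equal bipartitions; compare inertia of the fitted one
  bruteBest <- function(pts) {
    n <- nrow(pts)
    half <- combn(n, n / 2)
    best <- Inf; bestSet <- NULL
    for (j in seq_len(ncol(half))) {
      a <- half[, j]; b <- setdiff(seq_len(n), a)
      ia <- sum(sweep(pts[a, , drop = FALSE], 2,
                      colMeans(pts[a, , drop = FALSE]))^2)
      ib <- sum(sweep(pts[b, , drop = FALSE], 2,
                      colMeans(pts[b, , drop = FALSE]))^2)
      if (ia + ib < best) { best <- ia + ib; bestSet <- a }
    }
    list(inertia = best, set = sort(bestSet))
  }
  set.seed(61)
  for (i in 1:10) {
    n <- sample(c(6, 8, 10, 12), 1)
    centers <- rbind(c(0, 0), c(20, 0))  # 5x the intra-cluster spread
    pts <- centers[rep(1:2, each = n / 2), ] + matrix(rnorm(2 * n, 0, 1), n, 2)
    cm <- fitEqualSizeKmeans(pts, 2, seed = i)
    oracle <- bruteBest(pts)
    expect_equal(inertia(cm), oracle$inertia, tolerance = 1e-8)
    expect_true(identical(sort(which(clusterLabels(cm) == 0L)), oracle$set) ||
                identical(sort(which(clusterLabels(cm) == 1L)), oracle$set))
  }
})

test_that("new points take the nearest centroid without size constraints", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  cm <- fitEqualSizeKmeans(pts, 2, seed = 3)
  # training points recovered
  expect_equal(assignNewPoints(cm, pts), clusterLabels(cm))
  # equidistant point: lower cluster id wins
  mid <- matrix(c(5, 0.5), 1, 2)
  expect_equal(assignNewPoints(cm, mid), 0L)
  expect_equal(assignNewPoints(cm, pts[0, , drop = FALSE]), integer(0))
  # no balance for new data: all near one centroid
  far <- matrix(rep(c(10, 0.5), 5), 5, 2, byrow = TRUE)
  expect_equal(assignNewPoints(cm, far), rep(1L, 5))
  expect_error(assignNewPoints(cm, matrix(0, 1, 3)), "dimensions")
})
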