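# Random low-rank feature clouds: points on an r-dimensional plane in 62-D.
planarFeatures <- function(n, r, seed, sds = NULL) {
  set.seed(seed)
  basis <- qr.Q(qr(matrix(rnorm(62 * r), 62, r)))
  scores <- sweep(matrix(rnorm(n * r), n, r), 2, sds %||% (r:1), "*")
  scores %*% t(basis)
}

test_that("principal-axis rotation is an isometry with correct variances", {
  set.seed(17)
  for (m in 2:3) {
    coords <- matrix(rnorm(60 * m), 60, m) %*% diag(seq(3, 1, length.out = m))
    rot <- rotateToPrincipalAxes(coords)
    # orthogonality
    expect_lt(max(abs(crossprod(rot$rotation) - diag(m))), 1e-8)
    # pairwise distances preserved (brute-force comparison)
    expect_lt(max(abs(dist(coords) - dist(rot$rotated))), 1e-8)
    # decorrelation: rotated covariance diagonal
    cv <- cov(rot$rotated)
    expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
    # explained variance equals the covariance eigendecomposition oracle
    ev <- eigen(cov(coords), symmetric = TRUE)$values
    expect_equal(rot$explainedVariance, ev / sum(ev), tolerance = 1e-8)
    expect_false(is.unsorted(rev(rot$explainedVariance)))
  }
  # perfect collinearity: y = x line
  line <- cbind(1:10, 1:10)
  rotLine <- rotateToPrincipalAxes(line)
  expect_equal(rotLine$explainedVariance, c(1, 0), tolerance = 1e-12)
  expect_equal(abs(rotLine$rotation[, 1]), rep(1 / sqrt(2), 2),
               tolerance = 1e-12)
  expect_error(rotateToPrincipalAxes(matrix(1, 1, 2)), "at least")
})

test_that("the PCA reducer matches the covariance eigendecomposition oracle", {
  x <- planarFeatures(80, 2, seed = 23, sds = c(3, 1))
  model <- fitEmbedding(x, config = ReductionConfig(nNeighbors = 10,
                                                    reducer = "pca"))
  ev <- eigen(cov(x), symmetric = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(explainedVariance(model), ev / sum(ev), tolerance = 1e-8)
  # projecting the training data reproduces the stored coordinates
  expect_equal(projectEmbedding(model, x), model@trainRotated,
               tolerance = 1e-6)
})

test_that("projection respects shape and functional determinism", {
  x <- planarFeatures(60, 3, seed = 29)
  for (red in c("pca", "spectral")) {
    model <- fitEmbedding(x, config = ReductionConfig(nNeighbors = 8,
                                                      reducer = red))
    one <- projectEmbedding(model, x[5, , drop = FALSE])
    expect_equal(dim(one), c(1, 2))
    dup <- projectEmbedding(model, x[c(7, 7, 7), ])
    expect_equal(dup[1, ], dup[2, ])
    expect_equal(dup[2, ], dup[3, ])
    # identical refit: bit-stable coordinates
    model2 <- fitEmbedding(x, config = ReductionConfig(nNeighbors = 8,
                                                       reducer = red))
    expect_identical(model@trainRotated, model2@trainRotated)
  }
  expect_error(projectEmbedding(model, x[, 1:10]), "62")
})

test_that("fit rejects undersized or malformed inputs", {
  x <- planarFeatures(10, 2, seed = 3)
  expect_error(fitEmbedding(x, config = ReductionConfig(nNeighbors = 10)),
               "n_neighbors")
  x[1, 1] <- NA
  expect_error(fitEmbedding(x, config = ReductionConfig(nNeighbors = 3)),
               "missing")
})

test_that("axis correlations follow the textbook Pearson formula", {
  set.seed(41)
  rotated <- matrix(rnorm(200), 100, 2)
  agesV <- rnorm(100, 70, 8)
  feats <- matrix(rnorm(100 * 62), 100, 62)
  res <- axisCorrelations(rotated, agesV, feats)
  hand <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  expect_equal(res$axisAgeR[1], hand(rotated[, 1], agesV), tolerance = 1e-12)
  expect_equal(res$axisRegionR[17, 2], hand(rotated[, 2], feats[, 17]),
               tolerance = 1e-12)
  # exact self/anti correlation
  res2 <- axisCorrelations(cbind(agesV, -agesV), agesV, feats)
  expect_equal(res2$axisAgeR, c(1, -1), tolerance = 1e-12)
  # zero-variance column marked undefined, not an error
  res3 <- axisCorrelations(cbind(rep(1, 100), agesV), agesV, feats)
  expect_true(is.na(res3$axisAgeR[1]))
})

test_that("age dominates axis 0 on the synthetic normative cohort", {
  co <- normativeZscore(
    generateNormativeCohort(normativePreset(nSubjects = 300, seed = 19)),
    generateNormativeCohort(normativePreset(nSubjects = 300, seed = 19)))
  tab <- sweepNNeighbors(co, grid = c(5, 20, 50),
                         config = ReductionConfig(seed = 33))
  expect_equal(nrow(tab), 3)
  expect_true(all(abs(tab$r_axis0_age) >= 0.5))
  expect_true(all(abs(tab$r_axis0_age) > abs(tab$r_axis1_age)))
  # repeated k: identical rows (determinism)
  tab2 <- sweepNNeighbors(co, grid = c(20, 20),
                          config = ReductionConfig(seed = 33))
  expect_equal(tab2[1, ], tab2[2, ], ignore_attr = TRUE)
  # 3-D embedding: variance fractions strictly ordered
  m3 <- fitEmbedding(co, config = ReductionConfig(nNeighbors = 20, dim = 3,
                                                  seed = 33))
  ev <- explainedVariance(m3)
  expect_true(ev[1] > ev[2] && ev[2] > ev[3])
})

test_that("n_neighbors selection maximises the axis-0/axis-1 contrast", {
  tab <- data.frame(k = c(5L, 20L), r_axis0_age = c(0.3, 0.6),
                    r_axis1_age = c(0.2, 0.1))
  expect_equal(selectNNeighbors(tab), 20L)
  tie <- data.frame(k = c(47L, 20L), r_axis0_age = c(0.6, 0.6),
                    r_axis1_age = c(0.1, 0.1))
  expect_equal(selectNNeighbors(tie), 20L)
  expect_equal(selectNNeighbors(tab[1, ]), 5L)
  expect_error(selectNNeighbors(tab[0, ]), "empty")
})
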