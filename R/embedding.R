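## --- reducers ---------------------------------------------------------------
## Both reducers implement the same contract: fit on an N x 62 matrix giving
## N x m coordinates, and project new rows into the same space. Both are
## deterministic, so a fitted pipeline is exactly reproducible.

## kNN-graph Laplacian eigenmaps: build the symmetrized k-nearest-neighbour
## affinity graph with a heat kernel, then embed with the leading non-trivial
## eigenvectors of the symmetric normalized Laplacian. New points are placed
## by Nystrom-style kernel-weighted averaging over their k nearest training
## points.
.fitSpectralReducer <- function(features, k, m) {
  n <- nrow(features)
  d <- as.matrix(stats::dist(features))
  nnIdx <- t(apply(d, 1, function(r) order(r)[2:(k + 1)]))
  nnDist <- t(vapply(seq_len(n), function(i) d[i, nnIdx[i, ]], numeric(k)))
  sigma <- mean(nnDist)
  if (sigma <= 0) sigma <- 1
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, nnIdx[i, ]] <- exp(-(nnDist[i, ] / sigma)^2)
  W <- pmax(A, t(A))
  deg <- rowSums(W)
  deg[deg <= 0] <- 1e-12
  isq <- 1 / sqrt(deg)
  Lsym <- diag(n) - (isq * W) * rep(isq, each = n)
  es <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  ## eigen() returns decreasing eigenvalues; the trivial component sits last.
  ## Scale each eigenvector by 1/sqrt(lambda) (commute-time embedding) so
  ## smoother graph directions carry proportionally more variance — without
  ## this every axis has unit norm and the principal axis is meaningless.
  take <- (n - 1):(n - m)
  U <- es$vectors[, take, drop = FALSE]
  lam <- pmax(es$values[take], 1e-12)
  U <- sweep(U, 2, sqrt(lam), "/")
  coords <- (U * isq) * sqrt(n)
  for (j in seq_len(m)) {
    piv <- which.max(abs(coords[, j]))
    if (coords[piv, j] < 0) coords[, j] <- -coords[, j]
  }
  list(type = "spectral", k = k, m = m, sigma = sigma,
       train = features, coords = coords)
}

.projectSpectral <- function(reducer, features) {
  d2 <- squaredDistances(features, reducer$train)
  k <- reducer$k
  out <- matrix(0, nrow(features), reducer$m)
  for (i in seq_len(nrow(features))) {
    nb <- order(d2[i, ])[seq_len(k)]
    w <- exp(-d2[i, nb] / reducer$sigma^2)
    if (sum(w) <= 0) w <- rep(1, k)
    out[i, ] <- colSums(reducer$coords[nb, , drop = FALSE] * (w / sum(w)))
  }
  out
}

## Deterministic principal-component reducer: the linear fallback that makes
## every downstream contract exactly testable (projection of training data
## reproduces the training embedding to machine precision).
.fitPcaReducer <- function(features, m) {
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE, rank. = m)
  list(type = "pca", m = m, center = pc$center,
       loadings = pc$rotation[, seq_len(m), drop = FALSE],
       coords = pc$x[, seq_len(m), drop = FALSE])
}

.projectPca <- function(reducer, features) {
  sweep(features, 2, reducer$center) %*% reducer$loadings
}

.projectReducer <- function(reducer, features) {
  switch(reducer$type,
         spectral = .projectSpectral(reducer, features),
         pca = .projectPca(reducer, features),
         stop("unknown reducer type: ", reducer$type))
}

## --- rotation ---------------------------------------------------------------

#' Rotate embedding coordinates onto their principal axes
#'
#' Centres the coordinates and applies the orthogonal rotation given by the
#' singular value decomposition, so that axis 0 carries maximal variance.
#' Being a rigid rotation it preserves all pairwise distances. Sign
#' convention: when `ages` is supplied axis 0 is flipped so its Pearson
#' correlation with age is non-negative; remaining axes (and all axes without
#' ages) are flipped so the largest-magnitude rotation loading is positive.
#'
#' @param coords N x m embedding coordinates.
#' @param ages optional N-vector of ages fixing the axis-0 sign.
#' @return List with `rotation` (m x m), `rotated` (N x m), `center`
#'   (m-vector) and `explainedVariance` (fractions, non-increasing, sum 1).
#' @export
rotateToPrincipalAxes <- function(coords, ages = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords); m <- ncol(coords)
  if (n < m) stop("need at least m points to rotate an m-D embedding")
  center <- colMeans(coords)
  xc <- sweep(coords, 2, center)
  sv <- svd(xc, nu = 0, nv = m)
  rotation <- sv$v
  total <- sum(sv$d^2)
  ev <- if (total > 0) sv$d^2 / total else c(1, rep(0, m - 1))
  rotated <- xc %*% rotation
  for (j in seq_len(m)) {
    flip <- FALSE
    if (j == 1L && !is.null(ages) && stats::sd(rotated[, 1]) > 0 &&
        stats::sd(ages) > 0) {
      flip <- stats::cor(rotated[, 1], ages) < 0
    } else {
      piv <- which.max(abs(rotation[, j]))
      flip <- rotation[piv, j] < 0
    }
    if (flip) {
      rotation[, j] <- -rotation[, j]
      rotated[, j] <- -rotated[, j]
    }
  }
  list(rotation = rotation, rotated = rotated, center = center,
       explainedVariance = ev)
}

## --- model fitting ----------------------------------------------------------

#' Fit the low-dimensional embedding of thickness z-scores
#'
#' Reduces N x 62 feature vectors to `config@dim` dimensions with the chosen
#' reducer, then rotates the embedding onto its principal axes and computes
#' axis diagnostics (explained variance, Pearson correlations of each axis
#' with age and with every region).
#'
#' @param features N x 62 matrix of thickness z-scores (or a
#'   [ThicknessCohort-class], whose scans and ages are used directly).
#' @param ages N-vector of ages; ignored when `features` is a cohort.
#' @param config a [ReductionConfig-class].
#' @return An [EmbeddingModel-class].
#' @export
fitEmbedding <- function(features, ages = NULL, config = ReductionConfig()) {
  if (is(features, "ThicknessCohort")) {
    ages <- ages(features)
    features <- thicknessMatrix(features)
  }
  features <- as.matrix(features)
  validObject(config)
  if (anyNA(features)) stop("features contain missing values")
  if (nrow(features) <= config@nNeighbors)
    stop(sprintf("need N > n_neighbors (N = %d, n_neighbors = %d)",
                 nrow(features), config@nNeighbors))
  if (!is.null(ages) && length(ages) != nrow(features))
    stop("ages must have one entry per row of features")
  reducer <- withSeed(config@seed, switch(config@reducer,
    spectral = .fitSpectralReducer(features, config@nNeighbors, config@dim),
    pca = .fitPcaReducer(features, config@dim)))
  rot <- rotateToPrincipalAxes(reducer$coords, ages)
  diag <- axisCorrelations(rot$rotated, ages, features)
  new("EmbeddingModel", reducer = reducer, rotation = rot$rotation,
      center = rot$center, trainRotated = rot$rotated,
      explainedVariance = rot$explainedVariance,
      axisAgeR = diag$axisAgeR, axisRegionR = diag$axisRegionR,
      config = config)
}

#' Project new scans into a fitted, rotated embedding
#'
#' @param model an [EmbeddingModel-class].
#' @param features Q x 62 matrix (or a [ThicknessCohort-class]).
#' @return Q x m matrix of rotated coordinates.
#' @export
projectEmbedding <- function(model, features) {
  stopifnot(is(model, "EmbeddingModel"))
  if (is(features, "ThicknessCohort")) features <- thicknessMatrix(features)
  features <- as.matrix(features)
  if (ncol(features) != 62)
    stop(sprintf("features must have 62 region columns, found %d",
                 ncol(features)))
  if (!nrow(features)) return(matrix(0, 0, ncol(model@rotation)))
  raw <- .projectReducer(model@reducer, features)
  sweep(raw, 2, model@center) %*% model@rotation
}

#' Pearson correlations of embedding axes with age and regions
#'
#' @param rotated N x m rotated coordinates.
#' @param ages N-vector of ages, or `NULL`.
#' @param features N x 62 thickness matrix.
#' @return List with `axisAgeR` (m-vector, `NA` when undefined) and
#'   `axisRegionR` (62 x m matrix). Zero-variance pairs yield `NA` rather
#'   than an error.
#' @export
axisCorrelations <- function(rotated, ages, features) {
  rotated <- as.matrix(rotated)
  m <- ncol(rotated)
  safeCor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  ageR <- if (is.null(ages)) rep(NA_real_, m) else
    vapply(seq_len(m), function(j) safeCor(rotated[, j], ages), 0)
  features <- as.matrix(features)
  regionR <- matrix(NA_real_, ncol(features), m,
                    dimnames = list(colnames(features), NULL))
  for (j in seq_len(m))
    for (r in seq_len(ncol(features)))
      regionR[r, j] <- safeCor(rotated[, j], features[, r])
  list(axisAgeR = ageR, axisRegionR = regionR)
}

## --- hyperparameter sweep ---------------------------------------------------

#' Sweep the neighbourhood size and record axis-age correlations
#'
#' Fits one embedding per `n_neighbors` value at a fixed seed and tabulates
#' the Pearson correlation of the first two rotated axes with age.
#'
#' @param features N x 62 matrix (or [ThicknessCohort-class]).
#' @param ages N-vector of ages; ignored when `features` is a cohort.
#' @param grid integer vector of `n_neighbors` values.
#' @param config base [ReductionConfig-class]; its `nNeighbors` is replaced
#'   by each grid value in turn.
#' @return data.frame with columns `k`, `r_axis0_age`, `r_axis1_age`, rows in
#'   grid order.
#' @export
sweepNNeighbors <- function(features, ages = NULL, grid,
                            config = ReductionConfig()) {
  if (!length(grid)) stop("grid must be non-empty")
  if (is(features, "ThicknessCohort")) {
    ages <- ages(features)
    features <- thicknessMatrix(features)
  }
  rows <- lapply(grid, function(k) {
    cfg <- config; cfg@nNeighbors <- as.integer(k)
    fit <- tryCatch(fitEmbedding(features, ages, cfg),
                    error = function(e)
                      stop(sprintf("n_neighbors = %d: %s", k,
                                   conditionMessage(e)), call. = FALSE))
    data.frame(k = as.integer(k),
               r_axis0_age = fit@axisAgeR[1],
               r_axis1_age = if (length(fit@axisAgeR) > 1)
                 fit@axisAgeR[2] else NA_real_)
  })
  do.call(rbind, rows)
}

#' Choose n_neighbors from a sweep table
#'
#' Selects the value maximising `|r_axis0_age| - |r_axis1_age|` — a strong
#' age axis with a weak second axis. Ties resolve to the smallest k.
#'
#' @param sweep data.frame as returned by [sweepNNeighbors()].
#' @return The selected k (integer).
#' @export
selectNNeighbors <- function(sweep) {
  if (!nrow(sweep)) stop("empty sweep table")
  score <- abs(sweep$r_axis0_age) - abs(sweep$r_axis1_age)
  score[is.na(score)] <- -Inf
  sweep$k[order(-score, sweep$k)][1]
}
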