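#' Cluster-membership probabilities from a distance matrix
#'
#' Converts point-to-centroid distances into membership probabilities via
#' `W[i, j] = 1 - D[i, j] / V[i]`, where `V[i]` is the maximum of row i. Each
#' row therefore lies in `[0, 1]` with an exact zero at the furthest
#' centroid. A degenerate all-zero row (a point at distance 0 from every
#' centroid) becomes uniform 1s by convention.
#'
#' @param distances N x C matrix of non-negative distances.
#' @return N x C probability matrix.
#' @export
assignmentProbabilities <- function(distances) {
  distances <- as.matrix(distances)
  if (any(distances < 0)) stop("distances must be non-negative")
  v <- apply(distances, 1, max)
  W <- 1 - distances / ifelse(v > 0, v, 1)
  W[v == 0, ] <- 1
  W
}

#' Capacity-constrained initial assignment
#'
#' Greedy assignment over all (point, cluster) pairs ordered by decreasing
#' membership probability (ties break to the lower point index, then the
#' lower cluster index): a pair is accepted when the point is unassigned and
#' the cluster below capacity. Every point ends up assigned and capacities
#' are met exactly.
#'
#' @param W N x C probability matrix (see [assignmentProbabilities()]).
#' @param capacity integer C-vector of cluster capacities summing to N.
#' @return Integer N-vector of 0-based cluster labels.
#' @export
initialEqualAssignment <- function(W, capacity) {
  W <- as.matrix(W)
  n <- nrow(W); C <- ncol(W)
  capacity <- as.integer(capacity)
  if (length(capacity) != C || sum(capacity) != n || any(capacity < 0))
    stop("capacity must be C non-negative counts summing to N")
  pt <- rep(seq_len(n), C)
  cl <- rep(seq_len(C), each = n)
  ord <- order(-as.vector(W), pt, cl)
  labels <- rep(NA_integer_, n)
  left <- capacity
  assigned <- 0L
  for (e in ord) {
    i <- pt[e]; j <- cl[e]
    if (is.na(labels[i]) && left[j] > 0L) {
      labels[i] <- j - 1L
      left[j] <- left[j] - 1L
      assigned <- assigned + 1L
      if (assigned == n) break
    }
  }
  labels
}

## k-means++ seeding: first centroid uniform, then each subsequent centroid
## drawn with probability proportional to the squared distance to the
## nearest chosen centroid.
.kmeansppCentroids <- function(points, C) {
  n <- nrow(points)
  idx <- integer(C)
  idx[1] <- sample.int(n, 1)
  if (C > 1) {
    d2 <- squaredDistances(points, points[idx[1], , drop = FALSE])[, 1]
    for (c in 2:C) {
      prob <- d2
      if (sum(prob) <= 0) prob <- rep(1, n)
      idx[c] <- sample.int(n, 1, prob = prob)
      d2 <- pmin(d2, squaredDistances(points,
                                      points[idx[c], , drop = FALSE])[, 1])
    }
  }
  points[idx, , drop = FALSE]
}

.inertiaOf <- function(points, labels, cents) {
  sum((points - cents[labels + 1L, , drop = FALSE])^2)
}

#' Fit equal-size k-means
#'
#' k-means constrained to clusters of (near-)identical size: k-means++
#' seeding, capacity-constrained initial assignment through the probability
#' matrix `W = 1 - D / rowmax(D)`, then iterative refinement by
#' size-preserving label swaps. Each iteration recomputes centroids,
#' evaluates the inertia change of every pairwise label exchange against the
#' current centroids, and greedily applies non-overlapping improving swaps;
#' the loop stops when the best available gain falls below `tol` or
#' `maxIter` is reached. Cluster ids are relabelled so they ascend with the
#' centroid's first (principal-axis) coordinate.
#'
#' Capacities are `floor(N / C)` with the `N mod C` leftovers given to the
#' lowest-numbered clusters, so sizes never differ by more than one.
#'
#' @param points N x m coordinate matrix.
#' @param C number of clusters (1 <= C <= N).
#' @param seed RNG seed for the k-means++ initialisation.
#' @param maxIter maximum refinement iterations.
#' @param tol minimum inertia improvement to accept a swap.
#' @return A [ClusterModel-class], deterministic given `seed`.
#' @export
fitEqualSizeKmeans <- function(points, C, seed = 1, maxIter = 100,
                               tol = 1e-6) {
  points <- as.matrix(points)
  n <- nrow(points)
  C <- as.integer(C)
  if (C < 1L) stop("C must be >= 1")
  if (C > n) stop("C must not exceed the number of points")
  capacity <- rep(n %/% C, C)
  extra <- n %% C
  if (extra > 0) capacity[seq_len(extra)] <- capacity[seq_len(extra)] + 1L

  cents <- withSeed(seed, .kmeansppCentroids(points, C))
  D <- sqrt(squaredDistances(points, cents))
  labels <- initialEqualAssignment(assignmentProbabilities(D), capacity)

  cents <- .recomputeCentroids(points, labels, C)
  iterInertia <- .inertiaOf(points, labels, cents)
  for (iter in seq_len(maxIter)) {
    cents <- .recomputeCentroids(points, labels, C)
    d2 <- squaredDistances(points, cents)
    cur <- d2[cbind(seq_len(n), labels + 1L)]
    ## gain of swapping labels of i and j (centroids frozen):
    ## gain_ij = (cost_i + cost_j) - (cost of i under j's label + vice versa)
    cross <- d2[, labels + 1L, drop = FALSE]  # cross[i, j] = d2(i, label_j)
    gain <- outer(cur, cur, "+") - cross - t(cross)
    gain[labels[row(gain)] == labels[col(gain)]] <- -Inf
    diag(gain) <- -Inf
    cand <- which(gain > tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (!nrow(cand)) break
    cand <- cand[order(-gain[cand]), , drop = FALSE]
    touched <- logical(n)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (touched[i] || touched[j]) next
      li <- labels[i]
      labels[i] <- labels[j]
      labels[j] <- li
      touched[i] <- TRUE; touched[j] <- TRUE
    }
    iterInertia <- c(iterInertia,
                     .inertiaOf(points, labels,
                                .recomputeCentroids(points, labels, C)))
  }
  cents <- .recomputeCentroids(points, labels, C)
  ## relabel by ascending axis-0 centroid coordinate
  ord <- order(cents[, 1])
  relabel <- integer(C)
  relabel[ord] <- seq_len(C) - 1L
  labels <- relabel[labels + 1L]
  cents <- cents[ord, , drop = FALSE]
  new("ClusterModel", centroids = cents, labels = as.integer(labels),
      inertia = .inertiaOf(points, labels, cents),
      iterInertia = iterInertia, seed = as.integer(seed))
}

.recomputeCentroids <- function(points, labels, C) {
  cents <- matrix(0, C, ncol(points))
  for (c in seq_len(C) - 1L) {
    idx <- which(labels == c)
    cents[c + 1L, ] <- colMeans(points[idx, , drop = FALSE])
  }
  cents
}

#' Assign new points to the nearest centroid
#'
#' The equal-size constraint applies to training data only; projected test
#' scans take their nearest centroid (ties to the lower cluster id).
#'
#' @param model a [ClusterModel-class].
#' @param points Q x m matrix.
#' @return Integer Q-vector of 0-based labels.
#' @export
assignNewPoints <- function(model, points) {
  stopifnot(is(model, "ClusterModel"))
  points <- as.matrix(points)
  if (!nrow(points)) return(integer(0))
  if (ncol(points) != ncol(model@centroids))
    stop(sprintf("points have %d dimensions, centroids %d",
                 ncol(points), ncol(model@centroids)))
  d2 <- squaredDistances(points, model@centroids)
  as.integer(apply(d2, 1, which.min) - 1L)  # which.min: ties -> lower id
}
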