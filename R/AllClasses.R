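#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

.cohort_kinds <- c("cross_sectional", "longitudinal")
.diagnosis_levels <- c("CH", "MCI", "AD")
.outcome_levels <- c("stable", "converter")

#' ThicknessCohort: regional cortical-thickness scans with visit metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] specialisation holding one
#' column per scan. The single assay `"thickness"` is a 62 x n matrix of
#' regional thickness z-scores in [dktRegionRoster()] order; `colData`
#' carries `subject_id`, `visit_time` (years since the subject's first
#' retained scan), `age` (years at scan), `diagnosis` (CH/MCI/AD) and, for
#' longitudinal cohorts, the subject-level `outcome` (stable/converter).
#'
#' Columns are always grouped by subject and sorted by `visit_time` within
#' subject; the validity method enforces the cohort invariants (one scan per
#' subject when cross-sectional, defined outcomes and non-decreasing age when
#' longitudinal, no duplicated (subject, visit_time) pairs).
#'
#' @slot kind `"cross_sectional"` or `"longitudinal"`.
#' @export
setClass("ThicknessCohort",
  contains = "SummarizedExperiment",
  slots = c(kind = "character")
)

setValidity("ThicknessCohort", function(object) {
  msg <- character()
  roster <- dktRegionRoster()
  if (!identical(object@kind, "cross_sectional") &&
      !identical(object@kind, "longitudinal"))
    msg <- c(msg, "kind must be 'cross_sectional' or 'longitudinal'")
  if (!"thickness" %in% SummarizedExperiment::assayNames(object))
    return(c(msg, "assay 'thickness' is missing"))
  a <- SummarizedExperiment::assay(object, "thickness")
  if (nrow(a) != length(roster))
    msg <- c(msg, sprintf("assay must have %d region rows, found %d",
                          length(roster), nrow(a)))
  else if (!identical(rownames(a), roster))
    msg <- c(msg, "assay rownames must equal the DKT region roster, in order")
  if (any(!is.finite(a)))
    msg <- c(msg, "thickness z-scores must be finite")
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject_id", "visit_time", "age", "diagnosis")
  missing_cols <- setdiff(need, colnames(cd))
  if (length(missing_cols))
    return(c(msg, paste("colData lacks:", paste(missing_cols, collapse = ", "))))
  if (ncol(object) > 0) {
    if (any(cd$visit_time < 0)) msg <- c(msg, "visit_time must be >= 0")
    if (any(cd$age <= 0)) msg <- c(msg, "age must be > 0")
    if (!all(cd$diagnosis %in% .diagnosis_levels))
      msg <- c(msg, "diagnosis must be one of CH, MCI, AD")
    if (anyDuplicated(paste(cd$subject_id, cd$visit_time)))
      msg <- c(msg, "duplicated (subject, visit_time) pair")
    bysub <- split(seq_len(ncol(object)), cd$subject_id)
    if (object@kind == "cross_sectional") {
      if (any(lengths(bysub) != 1L))
        msg <- c(msg, "cross-sectional cohort must have one scan per subject")
    } else {
      if (!"outcome" %in% colnames(cd))
        msg <- c(msg, "longitudinal cohort needs an 'outcome' column")
      else if (any(is.na(cd$outcome)) || !all(cd$outcome %in% .outcome_levels))
        msg <- c(msg, "outcome must be 'stable' or 'converter' for every scan")
      for (idx in bysub) {
        if (is.unsorted(cd$visit_time[idx], strictly = TRUE)) {
          msg <- c(msg, "visits must be strictly sorted by visit_time within subject")
          break
        }
        if (is.unsorted(cd$age[idx])) {
          msg <- c(msg, "age must be non-decreasing with visit_time within subject")
          break
        }
      }
      if ("outcome" %in% colnames(cd)) {
        oc <- vapply(bysub, function(i) length(unique(cd$outcome[i])), 1L)
        if (any(oc != 1L))
          msg <- c(msg, "outcome must be constant within subject")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ThicknessCohort
#'
#' @param thickness numeric matrix, scans in rows and the 62 roster regions in
#'   columns (column names checked against [dktRegionRoster()] when present).
#' @param subjectId character vector, one entry per scan.
#' @param visitTime numeric vector of years since the subject's baseline.
#' @param age numeric vector of ages at scan, years.
#' @param diagnosis character vector of per-visit diagnoses (CH/MCI/AD).
#' @param kind `"cross_sectional"` or `"longitudinal"`.
#' @param outcome for longitudinal cohorts, per-scan (or subject-constant)
#'   outcome labels, `"stable"` or `"converter"`.
#' @return A validated [ThicknessCohort-class] with scans grouped by subject
#'   and sorted by visit time.
#' @export
ThicknessCohort <- function(thickness, subjectId, visitTime, age, diagnosis,
                            kind = c("longitudinal", "cross_sectional"),
                            outcome = NULL) {
  kind <- match.arg(kind)
  roster <- dktRegionRoster()
  thickness <- as.matrix(thickness)
  if (ncol(thickness) != length(roster))
    stop(sprintf("thickness must have %d region columns, found %d",
                 length(roster), ncol(thickness)))
  if (!is.null(colnames(thickness)) &&
      !identical(colnames(thickness), roster)) {
    bad <- c(setdiff(colnames(thickness), roster), setdiff(roster, colnames(thickness)))
    stop("region columns do not match the DKT roster: ",
         paste(unique(bad), collapse = ", "))
  }
  n <- nrow(thickness)
  subjectId <- as.character(subjectId)
  stopifnot(length(subjectId) == n, length(visitTime) == n,
            length(age) == n, length(diagnosis) == n)
  ord <- order(match(subjectId, unique(subjectId)), visitTime)
  cd <- S4Vectors::DataFrame(
    subject_id = subjectId[ord],
    visit_time = as.numeric(visitTime)[ord],
    age = as.numeric(age)[ord],
    diagnosis = as.character(diagnosis)[ord]
  )
  if (kind == "longitudinal") {
    if (is.null(outcome)) stop("longitudinal cohort needs 'outcome'")
    cd$outcome <- as.character(outcome)[ord]
  } else if (!is.null(outcome) && !all(is.na(outcome))) {
    stop("outcome is only meaningful for longitudinal cohorts")
  }
  a <- t(thickness[ord, , drop = FALSE])
  dimnames(a) <- list(roster, NULL)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(thickness = a), colData = cd)
  new("ThicknessCohort", se, kind = kind)
}

#' @describeIn ThicknessCohort cohort kind, `"cross_sectional"` or
#'   `"longitudinal"`.
#' @param x a `ThicknessCohort`.
#' @export
setMethod("cohortKind", "ThicknessCohort", function(x) x@kind)

#' @describeIn ThicknessCohort per-scan subject identifiers.
#' @export
setMethod("subjectIds", "ThicknessCohort",
          function(x) SummarizedExperiment::colData(x)$subject_id)

#' @describeIn ThicknessCohort per-scan visit times (years since baseline).
#' @export
setMethod("visitTimes", "ThicknessCohort",
          function(x) SummarizedExperiment::colData(x)$visit_time)

#' @describeIn ThicknessCohort per-scan ages in years.
#' @export
setMethod("ages", "ThicknessCohort",
          function(x) SummarizedExperiment::colData(x)$age)

#' @describeIn ThicknessCohort per-scan diagnoses (CH/MCI/AD).
#' @export
setMethod("diagnoses", "ThicknessCohort",
          function(x) SummarizedExperiment::colData(x)$diagnosis)

#' @describeIn ThicknessCohort named subject-level outcome vector
#'   (`"stable"`/`"converter"`); `NULL` for cross-sectional cohorts.
#' @export
setMethod("outcomes", "ThicknessCohort", function(x) {
  if (x@kind != "longitudinal") return(NULL)
  cd <- SummarizedExperiment::colData(x)
  first <- !duplicated(cd$subject_id)
  stats::setNames(cd$outcome[first], cd$subject_id[first])
})

#' @describeIn ThicknessCohort scans-by-regions (n x 62) thickness matrix.
#' @export
setMethod("thicknessMatrix", "ThicknessCohort",
          function(x) t(SummarizedExperiment::assay(x, "thickness")))

#' @describeIn ThicknessCohort number of distinct subjects.
#' @export
setMethod("nSubjects", "ThicknessCohort",
          function(x) length(unique(subjectIds(x))))

setMethod("show", "ThicknessCohort", function(object) {
  cat(sprintf("ThicknessCohort (%s): %d scans, %d subjects, %d regions\n",
              object@kind, ncol(object), nSubjects(object), nrow(object)))
  if (object@kind == "longitudinal" && ncol(object) > 0) {
    oc <- outcomes(object)
    cat(sprintf("  outcomes: %d stable, %d converter\n",
                sum(oc == "stable"), sum(oc == "converter")))
  }
})

#' Parameters of the synthetic cohort generator
#'
#' Bundles every knob of the data-generating model: a linear age-related
#' thinning of each region (z-units per decade), subject-level random offsets,
#' per-visit measurement noise, and — for longitudinal cohorts — visit
#' schedule and the converter-specific extra atrophy confined to the
#' AD-signature regions.
#'
#' @slot nSubjects number of subjects.
#' @slot ageRange min/max age in years (baseline age for longitudinal).
#' @slot visitsPerSubject min/max number of visits (longitudinal).
#' @slot visitIntervalMean mean inter-visit gap, years.
#' @slot visitIntervalJitterSD SD of the gap jitter, years.
#' @slot ageSlope 62-vector of thinning rates, z-units per decade (<= 0).
#' @slot signatureRegions roster indices receiving converter atrophy.
#' @slot converterExtraSlope extra converter atrophy, z-units per year (<= 0).
#' @slot converterFraction proportion of converters in (0, 1).
#' @slot subjectSD between-subject offset SD, z-units.
#' @slot noiseSD per-visit measurement noise SD, z-units.
#' @slot seed RNG seed.
#' @export
setClass("GenerationParams", slots = c(
  nSubjects = "integer", ageRange = "numeric", visitsPerSubject = "integer",
  visitIntervalMean = "numeric", visitIntervalJitterSD = "numeric",
  ageSlope = "numeric", signatureRegions = "integer",
  converterExtraSlope = "numeric", converterFraction = "numeric",
  subjectSD = "numeric", noiseSD = "numeric", seed = "integer"
))

setValidity("GenerationParams", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (length(object@ageRange) != 2L || diff(object@ageRange) <= 0)
    msg <- c(msg, "ageRange must be (min, max) with min < max")
  if (length(object@visitsPerSubject) != 2L ||
      object@visitsPerSubject[1] < 1L ||
      object@visitsPerSubject[1] > object@visitsPerSubject[2])
    msg <- c(msg, "visitsPerSubject must be (min, max) with 1 <= min <= max")
  if (object@visitIntervalMean <= 0) msg <- c(msg, "visitIntervalMean must be > 0")
  if (object@visitIntervalJitterSD < 0) msg <- c(msg, "visitIntervalJitterSD must be >= 0")
  if (length(object@ageSlope) != 62L) msg <- c(msg, "ageSlope must have length 62")
  if (any(object@ageSlope > 0)) msg <- c(msg, "ageSlope entries must be <= 0")
  if (object@converterExtraSlope > 0) msg <- c(msg, "converterExtraSlope must be <= 0")
  if (object@converterFraction <= 0 || object@converterFraction >= 1)
    msg <- c(msg, "converterFraction must be in (0, 1)")
  if (object@subjectSD < 0 || object@noiseSD < 0)
    msg <- c(msg, "subjectSD and noiseSD must be >= 0")
  if (length(object@signatureRegions) &&
      (min(object@signatureRegions) < 1L || max(object@signatureRegions) > 62L))
    msg <- c(msg, "signatureRegions must index the 62-region roster")
  if (length(msg)) msg else TRUE
})

#' Configuration of the manifold reduction
#'
#' @slot nNeighbors neighbourhood size k of the kNN graph (>= 2).
#' @slot minDist minimum spacing parameter; retained for interface parity
#'   with UMAP-family reducers, inert for the reducers shipped here.
#' @slot dim target dimension m, 2 or 3.
#' @slot seed RNG seed.
#' @slot reducer `"spectral"` (kNN-graph Laplacian eigenmaps) or `"pca"`.
#' @export
setClass("ReductionConfig", slots = c(
  nNeighbors = "integer", minDist = "numeric", dim = "integer",
  seed = "integer", reducer = "character"
))

setValidity("ReductionConfig", function(object) {
  msg <- character()
  if (object@nNeighbors < 2L) msg <- c(msg, "nNeighbors must be >= 2")
  if (object@minDist < 0) msg <- c(msg, "minDist must be >= 0")
  if (!object@dim %in% c(2L, 3L)) msg <- c(msg, "dim must be 2 or 3")
  if (!object@reducer %in% c("spectral", "pca"))
    msg <- c(msg, "reducer must be 'spectral' or 'pca'")
  if (length(msg)) msg else TRUE
})

#' @rdname ReductionConfig-class
#' @param nNeighbors,minDist,dim,seed,reducer see slots.
#' @export
ReductionConfig <- function(nNeighbors = 20, minDist = 0, dim = 2,
                            seed = 1, reducer = c("spectral", "pca")) {
  reducer <- match.arg(reducer)
  new("ReductionConfig", nNeighbors = as.integer(nNeighbors),
      minDist = as.numeric(minDist), dim = as.integer(dim),
      seed = as.integer(seed), reducer = reducer)
}

#' Fitted embedding with principal-axis rotation (t-UMAP-style)
#'
#' Couples an out-of-sample-capable reducer with the orthogonal rotation that
#' aligns the embedding with its principal axes, plus the axis diagnostics
#' (explained variance fractions, Pearson correlation of each axis with age
#' and with each of the 62 regions).
#'
#' @slot reducer internal list describing the fitted reducer.
#' @slot rotation m x m orthogonal matrix (sign conventions folded in).
#' @slot center m-vector, mean of the raw training embedding.
#' @slot trainRotated rotated training coordinates, n x m.
#' @slot explainedVariance m-vector of non-increasing fractions summing to 1.
#' @slot axisAgeR Pearson r of each rotated axis with age.
#' @slot axisRegionR 62 x m matrix of Pearson r with each region.
#' @slot config the [ReductionConfig-class] used.
#' @export
setClass("EmbeddingModel", slots = c(
  reducer = "list", rotation = "matrix", center = "numeric",
  trainRotated = "matrix", explainedVariance = "numeric",
  axisAgeR = "numeric", axisRegionR = "matrix", config = "ReductionConfig"
))

setValidity("EmbeddingModel", function(object) {
  msg <- character()
  m <- ncol(object@rotation)
  rtr <- crossprod(object@rotation)
  if (max(abs(rtr - diag(m))) > 1e-8)
    msg <- c(msg, "rotation must be orthogonal")
  ev <- object@explainedVariance
  if (abs(sum(ev) - 1) > 1e-8) msg <- c(msg, "explained variance must sum to 1")
  if (is.unsorted(rev(ev))) msg <- c(msg, "explained variance must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' @describeIn EmbeddingModel per-axis explained variance fractions.
#' @param x an `EmbeddingModel`.
#' @export
setMethod("explainedVariance", "EmbeddingModel",
          function(x) x@explainedVariance)

setMethod("show", "EmbeddingModel", function(object) {
  cat(sprintf("EmbeddingModel: %s reducer, m = %d, n_neighbors = %d\n",
              object@config@reducer, object@config@dim,
              object@config@nNeighbors))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * object@explainedVariance), collapse = " / "),
      "\n")
  cat("  axis-age correlation:",
      paste(sprintf("%.3f", object@axisAgeR), collapse = " / "), "\n")
})

#' Equal-size k-means model
#'
#' @slot centroids C x m centroid matrix, rows ordered by ascending axis-0
#'   coordinate (cluster ids read left-to-right along the principal axis).
#' @slot labels integer training labels in 0..C-1.
#' @slot inertia within-cluster sum of squared point-centroid distances.
#' @slot iterInertia inertia after each refinement iteration (decreasing).
#' @slot seed seed used for k-means++ initialisation.
#' @export
setClass("ClusterModel", slots = c(
  centroids = "matrix", labels = "integer", inertia = "numeric",
  iterInertia = "numeric", seed = "integer"
))

setValidity("ClusterModel", function(object) {
  msg <- character()
  C <- nrow(object@centroids)
  if (length(object@labels) &&
      (min(object@labels) < 0L || max(object@labels) >= C))
    msg <- c(msg, "labels must lie in 0..C-1")
  sizes <- tabulate(object@labels + 1L, nbins = C)
  if (diff(range(sizes)) > 1L)
    msg <- c(msg, "cluster sizes must differ by at most 1")
  if (object@inertia < 0) msg <- c(msg, "inertia must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn ClusterModel centroid matrix (C x m).
#' @param x a `ClusterModel`.
#' @export
setMethod("centroids", "ClusterModel", function(x) x@centroids)

#' @describeIn ClusterModel 0-based training labels.
#' @export
setMethod("clusterLabels", "ClusterModel", function(x) x@labels)

#' @describeIn ClusterModel within-cluster sum of squares at convergence.
#' @export
setMethod("inertia", "ClusterModel", function(x) x@inertia)

setMethod("show", "ClusterModel", function(object) {
  sizes <- tabulate(object@labels + 1L, nbins = nrow(object@centroids))
  cat(sprintf("ClusterModel: C = %d, N = %d, inertia = %.4g\n",
              nrow(object@centroids), length(object@labels), object@inertia))
  cat("  sizes:", paste(sizes, collapse = ", "), "\n")
})

#' Probabilistic atlas of cluster trajectories
#'
#' Maps each observed trajectory (ordered cluster-id sequence of length
#' 1..L, read from a subject's last visits) to its stable/converter counts
#' and empirical conversion probability. Trajectories never observed in
#' training implicitly carry probability 0 with population 0.
#'
#' @slot nClusters number of clusters C.
#' @slot maxLength maximum trajectory length L.
#' @slot entries data.frame with columns `trajectory` (dash-joined ids),
#'   `length`, `n_stable`, `n_converter`, `probability`.
#' @export
setClass("TrajectoryAtlas", slots = c(
  nClusters = "integer", maxLength = "integer", entries = "data.frame"
))

setValidity("TrajectoryAtlas", function(object) {
  msg <- character()
  e <- object@entries
  need <- c("trajectory", "length", "n_stable", "n_converter", "probability")
  if (!all(need %in% colnames(e)))
    return("entries must have trajectory/length/n_stable/n_converter/probability")
  if (nrow(e)) {
    tot <- e$n_stable + e$n_converter
    p <- ifelse(tot > 0, e$n_converter / tot, 0)
    if (max(abs(p - e$probability)) > 1e-12)
      msg <- c(msg, "probability must equal n_converter / population")
    if (any(e$length < 1L | e$length > object@maxLength))
      msg <- c(msg, "entry lengths must lie in 1..L")
    if (anyDuplicated(e$trajectory)) msg <- c(msg, "duplicate trajectory keys")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TrajectoryAtlas the atlas entry table.
#' @param x a `TrajectoryAtlas`.
#' @export
setMethod("atlasEntries", "TrajectoryAtlas", function(x) x@entries)

setMethod("show", "TrajectoryAtlas", function(object) {
  cat(sprintf("TrajectoryAtlas: C = %d, L = %d, %d observed trajectories (of %d possible)\n",
              object@nClusters, object@maxLength, nrow(object@entries),
              trajectorySpaceSize(object@nClusters, object@maxLength)))
})

#' Receiver operating characteristic curve
#'
#' @slot thresholds descending threshold grid (distinct scores plus
#'   sentinels above the maximum and at the minimum).
#' @slot tpr sensitivities at each threshold.
#' @slot fpr 1 - specificity at each threshold.
#' @slot auc trapezoidal area under the curve.
#' @export
setClass("RocCurve", slots = c(
  thresholds = "numeric", tpr = "numeric", fpr = "numeric", auc = "numeric"
))

#' @describeIn RocCurve area under the curve.
#' @param x a `RocCurve`.
#' @export
setMethod("auc", "RocCurve", function(x) x@auc)

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: AUC = %.4f over %d thresholds\n",
              object@auc, length(object@thresholds)))
})
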