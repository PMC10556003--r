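#' Assign visits to annual bins
#'
#' Implements the annual standardisation rule for one subject's visit times:
#' each visit maps to the integer year `k = round(t)` and is retained only if
#' `|t - k| <= tolerance` (default 5/12 years, i.e. one year +/- five
#' months). When several visits fall in the same bin the one closest to the
#' bin centre wins, ties going to the earlier visit.
#'
#' @param times numeric vector of visit times (years), sorted ascending.
#' @param tolerance maximal distance from the bin centre, in (0, 0.5).
#' @return Integer vector of indices into `times` of the retained visits, in
#'   chronological order, with the corresponding bins as the `"bins"`
#'   attribute.
#' @export
annualBinIndices <- function(times, tolerance = 5 / 12) {
  stopifnot(tolerance > 0, tolerance < 0.5)
  if (!length(times)) return(structure(integer(0), bins = integer(0)))
  if (is.unsorted(times)) stop("visit times must be sorted")
  bins <- round(times)
  dist <- abs(times - bins)
  ok <- which(dist <= tolerance)
  keep <- integer(0)
  for (b in unique(bins[ok])) {
    cand <- ok[bins[ok] == b]
    keep <- c(keep, cand[which.min(dist[cand])])  # which.min: ties -> earlier
  }
  keep <- sort(keep)
  structure(keep, bins = bins[keep])
}

#' Bin a longitudinal cohort to annual visits
#'
#' Applies [annualBinIndices()] per subject, optionally discarding flagged
#' baseline scans first, and resets each subject's `visit_time` so the first
#' retained scan is 0 (original spacing is preserved, only shifted).
#'
#' @param cohort longitudinal [ThicknessCohort-class].
#' @param tolerance see [annualBinIndices()].
#' @param excludeFirst logical vector, one entry per scan, marking visits to
#'   drop before binning (e.g. baseline scans acquired under a different
#'   protocol); `NULL` to keep all.
#' @return The binned cohort. Subjects losing all visits are removed.
#' @export
binVisitsAnnual <- function(cohort, tolerance = 5 / 12, excludeFirst = NULL) {
  stopifnot(is(cohort, "ThicknessCohort"),
            cohortKind(cohort) == "longitudinal")
  cd <- SummarizedExperiment::colData(cohort)
  keepGlobal <- integer(0)
  newTime <- numeric(0)
  idxBySub <- split(seq_len(ncol(cohort)), cd$subject_id)
  for (idx in idxBySub) {
    if (!is.null(excludeFirst)) idx <- idx[!excludeFirst[idx]]
    if (!length(idx)) next
    t0 <- cd$visit_time[idx] - cd$visit_time[idx][1]
    keep <- annualBinIndices(t0, tolerance)
    if (!length(keep)) next
    keepGlobal <- c(keepGlobal, idx[keep])
    newTime <- c(newTime, t0[keep] - t0[keep][1])
  }
  out <- cohort[, keepGlobal]
  SummarizedExperiment::colData(out)$visit_time <- newTime
  validObject(out)
  out
}

#' Remove subjects with too few visits
#'
#' @param cohort longitudinal [ThicknessCohort-class].
#' @param minVisits minimum retained visits per subject (default 2: baseline
#'   plus at least one follow-up).
#' @return The filtered cohort.
#' @export
filterMinVisits <- function(cohort, minVisits = 2) {
  stopifnot(is(cohort, "ThicknessCohort"),
            cohortKind(cohort) == "longitudinal")
  if (minVisits < 1) stop("minVisits must be >= 1")
  counts <- table(subjectIds(cohort))
  keepSub <- names(counts)[counts >= minVisits]
  cohort[, subjectIds(cohort) %in% keepSub]
}

#' Z-score a cohort against a normative reference
#'
#' Each region is standardised as `(x - mu_ref) / sd_ref` using the
#' reference cohort's per-region mean and standard deviation. Age is
#' deliberately not part of the normalisation: age-related structure must
#' survive into the embedding.
#'
#' @param cohort cohort to transform.
#' @param reference cross-sectional normative [ThicknessCohort-class].
#' @return The transformed cohort.
#' @export
normativeZscore <- function(cohort, reference) {
  stopifnot(is(cohort, "ThicknessCohort"), is(reference, "ThicknessCohort"))
  if (cohortKind(reference) != "cross_sectional")
    stop("reference must be a cross-sectional cohort")
  ref <- SummarizedExperiment::assay(reference, "thickness")
  mu <- rowMeans(ref)
  sdv <- apply(ref, 1, stats::sd)
  if (any(sdv == 0))
    stop("degenerate reference: zero SD in region(s) ",
         paste(rownames(ref)[sdv == 0], collapse = ", "))
  a <- SummarizedExperiment::assay(cohort, "thickness")
  SummarizedExperiment::assay(cohort, "thickness") <- (a - mu) / sdv
  cohort
}
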