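#' Stratified test / space / cross-validation split
#'
#' Splits subjects (never scans) into three disjoint groups, stratified by
#' outcome so each group preserves the stable/converter balance: 10% test,
#' 40% space (reserved for fitting the longitudinal embedding), 50%
#' cross-validation by default.
#'
#' @param cohort longitudinal [ThicknessCohort-class] with outcomes.
#' @param testFraction,spaceFraction fractions per stratum; the remainder is
#'   the CV pool.
#' @param seed RNG seed.
#' @return List with character vectors `test`, `space`, `cv`.
#' @export
splitSubjects <- function(cohort, testFraction = 0.10, spaceFraction = 0.40,
                          seed = 1) {
  stopifnot(is(cohort, "ThicknessCohort"),
            cohortKind(cohort) == "longitudinal",
            testFraction > 0, spaceFraction > 0,
            testFraction + spaceFraction < 1)
  oc <- outcomes(cohort)
  parts <- list(test = character(0), space = character(0), cv = character(0))
  withSeed(seed, {
    for (lvl in .outcome_levels) {
      ids <- sample(names(oc)[oc == lvl])
      n <- length(ids)
      nTest <- round(testFraction * n)
      nSpace <- round(spaceFraction * n)
      nCv <- n - nTest - nSpace
      if (nTest < 1 || nSpace < 1 || nCv < 1)
        stop(sprintf("stratum '%s' too small (%d subjects) to populate all parts",
                     lvl, n))
      parts$test <- c(parts$test, ids[seq_len(nTest)])
      parts$space <- c(parts$space, ids[nTest + seq_len(nSpace)])
      parts$cv <- c(parts$cv, ids[nTest + nSpace + seq_len(nCv)])
    }
  })
  lapply(parts, sort)
}

#' Repeated stratified k-fold subject splits
#'
#' Each repeat partitions the subjects into k disjoint validation folds with
#' outcome proportions preserved to within one subject per fold; repeats use
#' seeds derived from `(seed, repeat)`.
#'
#' @param ids character vector of subject ids.
#' @param outcomeLabels outcome per id (`"stable"`/`"converter"`), parallel
#'   to `ids` or named by them.
#' @param k folds per repeat (default 10).
#' @param repeats number of repeats (default 10).
#' @param seed base RNG seed.
#' @return List of folds; each element has `train`, `validation`, `rep`,
#'   `fold`.
#' @export
stratifiedKFold <- function(ids, outcomeLabels, k = 10, repeats = 10,
                            seed = 1) {
  if (!is.null(names(outcomeLabels))) outcomeLabels <- outcomeLabels[ids]
  stopifnot(length(outcomeLabels) == length(ids))
  for (lvl in unique(outcomeLabels)) {
    if (sum(outcomeLabels == lvl) < k)
      stop(sprintf("stratum '%s' has fewer subjects (%d) than folds (%d)",
                   lvl, sum(outcomeLabels == lvl), k))
  }
  folds <- list()
  for (r in seq_len(repeats)) {
    foldOf <- stats::setNames(integer(length(ids)), ids)
    withSeed(deriveSeed(seed, r), {
      for (lvl in unique(outcomeLabels)) {
        strat <- sample(ids[outcomeLabels == lvl])
        foldOf[strat] <- ((seq_along(strat) - 1L) %% k) + 1L
      }
    })
    for (f in seq_len(k)) {
      val <- ids[foldOf[ids] == f]
      folds[[length(folds) + 1L]] <- list(
        train = setdiff(ids, val), validation = val, rep = r, fold = f)
    }
  }
  folds
}

#' Threshold-swept ROC curve
#'
#' Sweeps the decision threshold across all distinct scores (equal scores
#' grouped at one threshold), accumulating sensitivity and 1-specificity;
#' the AUC is the trapezoidal area, which equals the Mann-Whitney rank-sum
#' estimator with half credit for ties.
#'
#' @param probabilities numeric scores (higher = more converter-like).
#' @param outcomeLabels `"stable"`/`"converter"` per score (or logical,
#'   `TRUE` = converter).
#' @return A [RocCurve-class]. With a single outcome class the AUC is `NA`
#'   (undefined) and a warning is raised.
#' @export
rocCurve <- function(probabilities, outcomeLabels) {
  if (is.logical(outcomeLabels))
    outcomeLabels <- ifelse(outcomeLabels, "converter", "stable")
  keep <- !is.na(probabilities)
  probabilities <- probabilities[keep]
  outcomeLabels <- outcomeLabels[keep]
  pos <- outcomeLabels == "converter"
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0 || nN == 0) {
    warning("ROC undefined: only one outcome class present")
    return(new("RocCurve", thresholds = numeric(0), tpr = numeric(0),
               fpr = numeric(0), auc = NA_real_))
  }
  u <- sort(unique(probabilities), decreasing = TRUE)
  tp <- vapply(u, function(t) sum(pos & probabilities >= t), 0)
  fp <- vapply(u, function(t) sum(!pos & probabilities >= t), 0)
  tpr <- c(0, tp / nP)
  fpr <- c(0, fp / nN)
  thresholds <- c(Inf, u)
  aucv <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  new("RocCurve", thresholds = thresholds, tpr = tpr, fpr = fpr, auc = aucv)
}

## Per-subject cluster sequences from per-scan labels.
.clusterSequences <- function(scanSubjects, scanLabels, ids) {
  seqs <- split(scanLabels, scanSubjects)[ids]
  names(seqs) <- ids
  seqs
}

## Score one set of subjects against an atlas at length l.
## Subjects with fewer than l visits are excluded (counted).
.scoreSubjects <- function(atlas, seqs, l) {
  vapply(seqs, function(s) {
    if (length(s) < l) NA_real_
    else predictConversionProbability(atlas, s, l)$probability
  }, 0)
}

#' Cross-validate the trajectory classifier over a (C, l) grid
#'
#' For every fold: the equal-size clustering is fitted on the projected
#' scans of the training subjects, training trajectories build the atlas,
#' and validation subjects are scored at each trajectory length; the fold
#' AUC comes from the threshold-swept ROC. AUCs are averaged across all
#' folds and repeats (macro average). Folds whose scored validation subjects
#' collapse to one outcome class are skipped and counted.
#'
#' @param cohort preprocessed longitudinal [ThicknessCohort-class].
#' @param model fitted [EmbeddingModel-class].
#' @param cvIds subject ids of the CV pool.
#' @param clusterGrid values of C to evaluate (default 3:6).
#' @param maxLength maximal trajectory length L (default 3).
#' @param k,repeats fold structure (defaults 10, 10).
#' @param seed base seed; folds and every clustering derive from it.
#' @return data.frame with columns `C`, `l`, `mean_auc`, `sd_auc`,
#'   `n_folds`, `n_skipped`.
#' @export
crossValidate <- function(cohort, model, cvIds, clusterGrid = 3:6,
                          maxLength = 3, k = 10, repeats = 10, seed = 1) {
  stopifnot(is(cohort, "ThicknessCohort"), is(model, "EmbeddingModel"))
  sub <- cohort[, subjectIds(cohort) %in% cvIds]
  coords <- projectEmbedding(model, sub)
  scanSubjects <- subjectIds(sub)
  oc <- outcomes(sub)
  folds <- stratifiedKFold(cvIds, oc, k = k, repeats = repeats, seed = seed)
  aucs <- array(NA_real_, dim = c(length(clusterGrid), maxLength,
                                  length(folds)))
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    stopifnot(!any(fold$train %in% fold$validation))
    trainScan <- scanSubjects %in% fold$train
    for (ci in seq_along(clusterGrid)) {
      C <- clusterGrid[ci]
      cm <- fitEqualSizeKmeans(coords[trainScan, , drop = FALSE], C,
                               seed = deriveSeed(seed, fold$rep, fold$fold, C))
      valLabels <- assignNewPoints(cm, coords[!trainScan, , drop = FALSE])
      trainSeqs <- .clusterSequences(scanSubjects[trainScan],
                                     clusterLabels(cm), fold$train)
      valSeqs <- .clusterSequences(scanSubjects[!trainScan][
        scanSubjects[!trainScan] %in% fold$validation],
        valLabels[scanSubjects[!trainScan] %in% fold$validation],
        fold$validation)
      atlas <- buildAtlas(trainSeqs, oc[fold$train], C, maxLength)
      for (l in seq_len(maxLength)) {
        p <- .scoreSubjects(atlas, valSeqs, l)
        scored <- !is.na(p)
        lab <- oc[fold$validation][scored]
        if (length(unique(lab)) < 2) next  # skipped fold, counted below
        aucs[ci, l, fi] <- auc(rocCurve(p[scored], lab))
      }
    }
  }
  grid <- expand.grid(l = seq_len(maxLength), C = clusterGrid)[, c("C", "l")]
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    ci <- match(grid$C[g], clusterGrid)
    a <- aucs[ci, grid$l[g], ]
    data.frame(C = grid$C[g], l = grid$l[g],
               mean_auc = mean(a, na.rm = TRUE),
               sd_auc = stats::sd(a[!is.na(a)]),
               n_folds = sum(!is.na(a)), n_skipped = sum(is.na(a)))
  }))
  rownames(res) <- NULL
  res
}

#' Select the best (C, l) configuration from a CV table
#'
#' Highest mean AUC; ties resolve to the smaller C, then the smaller l.
#'
#' @param cvTable data.frame as returned by [crossValidate()].
#' @return One-row data.frame with the chosen `C` and `l` (and its CV AUC).
#' @export
selectBestConfig <- function(cvTable) {
  stopifnot(nrow(cvTable) > 0)
  ord <- order(-cvTable$mean_auc, cvTable$C, cvTable$l)
  cvTable[ord[1], , drop = FALSE]
}

#' Final held-out test of the selected configuration
#'
#' Refits the equal-size clustering on the full CV pool, rebuilds the atlas,
#' and scores the test subjects once at the selected trajectory length.
#'
#' @param cohort preprocessed longitudinal [ThicknessCohort-class].
#' @param model fitted [EmbeddingModel-class].
#' @param cvIds,testIds subject id vectors (disjoint).
#' @param C,l selected configuration.
#' @param maxLength atlas depth (default 3).
#' @param seed seed for the refit clustering.
#' @return List with `auc`, `roc`, `atlas`, `clusterModel`, `nScored`,
#'   `nExcluded`.
#' @export
finalTest <- function(cohort, model, cvIds, testIds, C, l, maxLength = 3,
                      seed = 1) {
  stopifnot(!any(cvIds %in% testIds))
  sub <- cohort[, subjectIds(cohort) %in% c(cvIds, testIds)]
  coords <- projectEmbedding(model, sub)
  scanSubjects <- subjectIds(sub)
  oc <- outcomes(sub)
  trainScan <- scanSubjects %in% cvIds
  cm <- fitEqualSizeKmeans(coords[trainScan, , drop = FALSE], C,
                           seed = deriveSeed(seed, 0, 0, C))
  trainSeqs <- .clusterSequences(scanSubjects[trainScan],
                                 clusterLabels(cm), cvIds)
  atlas <- buildAtlas(trainSeqs, oc[cvIds], C, maxLength)
  testScan <- scanSubjects %in% testIds
  testLabels <- assignNewPoints(cm, coords[testScan, , drop = FALSE])
  testSeqs <- .clusterSequences(scanSubjects[testScan], testLabels, testIds)
  p <- .scoreSubjects(atlas, testSeqs, l)
  scored <- !is.na(p)
  roc <- rocCurve(p[scored], oc[testIds][scored])
  list(auc = auc(roc), roc = roc, atlas = atlas, clusterModel = cm,
       nScored = sum(scored), nExcluded = sum(!scored))
}
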