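balancedCohort <- function(nStable, nConverter, seed = 1) {
  n <- nStable + nConverter
  ids <- sprintf("P%03d", seq_len(n))
  visits <- stats::setNames(rep(list(c(0, 1, 2)), n), ids)
  oc <- stats::setNames(rep(c("stable", "converter"), c(nStable, nConverter)),
                        ids)
  makeToyCohort(visits, outcome = oc, seed = seed)
}

test_that("the subject split is stratified, exhaustive and disjoint", {
  co <- balancedCohort(100, 100)
  sp <- splitSubjects(co, seed = 5)
  oc <- outcomes(co)
  for (lvl in c("stable", "converter")) {
    expect_equal(sum(oc[sp$test] == lvl), 10)
    expect_equal(sum(oc[sp$space] == lvl), 40)
    expect_equal(sum(oc[sp$cv] == lvl), 50)
  }
  allIds <- sort(c(sp$test, sp$space, sp$cv))
  expect_equal(allIds, sort(names(oc)))
  # different seeds: same counts, different membership
  sp2 <- splitSubjects(co, seed = 6)
  expect_equal(lengths(sp2), lengths(sp))
  expect_false(identical(sp2$test, sp$test))
  # too-small stratum errors
  tiny <- balancedCohort(3, 3)
  expect_error(splitSubjects(tiny, seed = 1), "too small")
})

test_that("stratified folds preserve outcome balance and partition ids", {
  co <- balancedCohort(20, 20)
  oc <- outcomes(co)
  folds <- stratifiedKFold(names(oc), oc, k = 10, repeats = 2, seed = 3)
  expect_length(folds, 20)
  for (r in 1:2) {
    rep_folds <- Filter(function(f) f$rep == r, folds)
    vals <- unlist(lapply(rep_folds, `[[`, "validation"))
    expect_equal(sort(vals), sort(names(oc)))  # exhaustive, disjoint
    for (f in rep_folds) {
      expect_equal(sum(oc[f$validation] == "stable"), 2)
      expect_equal(sum(oc[f$validation] == "converter"), 2)
      expect_length(intersect(f$train, f$validation), 0)
    }
  }
  # repeats shuffle memberships
  v1 <- Filter(function(f) f$rep == 1 & f$fold == 1, folds)[[1]]$validation
  v2 <- Filter(function(f) f$rep == 2 & f$fold == 1, folds)[[1]]$validation
  expect_false(identical(sort(v1), sort(v2)))
  small <- c(1:20, 21:25)  # only 5 converters: below k
  expect_error(stratifiedKFold(names(oc)[small], oc[small], k = 10, seed = 1),
               "fewer subjects")
})

test_that("threshold-swept AUC equals the rank-sum estimator", {
  # boundary behaviours
  sep <- rocCurve(c(0.9, 0.8, 0.2, 0.1), c("converter", "converter",
                                           "stable", "stable"))
  expect_equal(auc(sep), 1.0)
  flat <- rocCurve(rep(0.3, 6), rep(c("converter", "stable"), 3))
  expect_equal(auc(flat), 0.5)
  # 8-point mixed example with ties
  p <- c(0.1, 0.4, 0.35, 0.8, 0.35, 0.8, 0.5, 0.2)
  y <- c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  expect_equal(auc(rocCurve(p, y)), rankSumAuc(p, y), tolerance = 1e-12)
  # random instances, including heavy ties
  set.seed(83)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    r <- rocCurve(scores, y)
    expect_equal(auc(r), rankSumAuc(scores, y), tolerance = 1e-12)
    expect_false(is.unsorted(r@tpr))
    expect_false(is.unsorted(r@fpr))
  }
  expect_warning(r1 <- rocCurve(c(0.1, 0.9), c("stable", "stable")),
                 "one outcome class")
  expect_true(is.na(auc(r1)))
})

test_that("cross-validation bookkeeping aggregates fold AUCs", {
  co <- balancedCohort(16, 16, seed = 9)
  model <- fitEmbedding(co[, 1:40],
                        config = ReductionConfig(nNeighbors = 5,
                                                 reducer = "pca"))
  ids <- unique(subjectIds(co))
  tab <- crossValidate(co, model, ids, clusterGrid = 3, maxLength = 2,
                       k = 2, repeats = 1, seed = 2)
  expect_equal(nrow(tab), 2)  # one C, two lengths
  expect_equal(tab$C, c(3, 3))
  expect_equal(tab$n_folds + tab$n_skipped, c(2, 2))
  ok <- tab$n_folds > 0
  expect_true(all(tab$mean_auc[ok] >= 0 & tab$mean_auc[ok] <= 1))
})

test_that("the final test is deterministic and leak-guarded", {
  co <- balancedCohort(20, 20, seed = 13)
  model <- fitEmbedding(co[, 1:60],
                        config = ReductionConfig(nNeighbors = 5,
                                                 reducer = "pca"))
  ids <- unique(subjectIds(co))
  cvIds <- ids[c(1:16, 21:36)]
  testIds <- ids[c(17:20, 37:40)]  # both outcome classes represented
  r1 <- finalTest(co, model, cvIds, testIds, C = 3, l = 2, seed = 4)
  r2 <- finalTest(co, model, cvIds, testIds, C = 3, l = 2, seed = 4)
  expect_identical(r1$auc, r2$auc)
  expect_identical(atlasEntries(r1$atlas), atlasEntries(r2$atlas))
  expect_equal(r1$nScored + r1$nExcluded, length(testIds))
  expect_error(finalTest(co, model, cvIds, ids[30:35], C = 3, l = 1),
               "cvIds")
})
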