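# Small deterministic fixtures built in code.

# A longitudinal toy cohort with explicit visit structure.
# visitsPerSubject: named list subject -> numeric visit times.
makeToyCohort <- function(visitsPerSubject,
                          outcome = NULL, seed = 1) {
  subs <- names(visitsPerSubject)
  if (is.null(outcome))
    outcome <- stats::setNames(rep("stable", length(subs)), subs)
  rows <- do.call(rbind, lapply(subs, function(s) {
    t <- visitsPerSubject[[s]]
    data.frame(subject_id = s, visit_time = t, age = 70 + t,
               stringsAsFactors = FALSE)
  }))
  set.seed(seed)
  thick <- matrix(rnorm(nrow(rows) * 62), nrow(rows), 62)
  colnames(thick) <- dktRegionRoster()
  ThicknessCohort(
    thickness = thick, subjectId = rows$subject_id,
    visitTime = rows$visit_time, age = rows$age,
    diagnosis = rep("MCI", nrow(rows)), kind = "longitudinal",
    outcome = outcome[rows$subject_id])
}

# A cross-sectional cohort with prescribed ages and thickness.
makeFlatCohort <- function(thickness, age = NULL) {
  n <- nrow(thickness)
  colnames(thickness) <- dktRegionRoster()
  ThicknessCohort(
    thickness = thickness, subjectId = sprintf("S%03d", seq_len(n)),
    visitTime = rep(0, n), age = age %||% rep(60, n),
    diagnosis = rep("CH", n), kind = "cross_sectional")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mann-Whitney AUC with half credit for ties: the independent rank-sum
# oracle for the threshold-swept ROC.
rankSumAuc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
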