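test_that("the normative mean function evaluates exactly without noise", {
  slope <- rep(-0.2, 62)
  p <- GenerationParams(nSubjects = 50, ageRange = c(50, 70),
                        visitsPerSubject = c(1, 1), ageSlope = slope,
                        subjectSD = 0, noiseSD = 0, seed = 7)
  co <- generateNormativeCohort(p)
  z <- thicknessMatrix(co)
  mu <- ages(co) - 60  # deviation from the reference age (range midpoint)
  for (r in c(1, 30, 62))
    expect_equal(unname(z[, r]), -0.2 * mu / 10, tolerance = 1e-12)
  # at the reference age the mean is exactly zero
  p2 <- GenerationParams(nSubjects = 2, ageRange = c(60, 60 + 1e-9),
                         visitsPerSubject = c(1, 1), ageSlope = slope,
                         subjectSD = 0, noiseSD = 0, seed = 7)
  z2 <- thicknessMatrix(generateNormativeCohort(p2))
  expect_true(max(abs(z2)) < 1e-8)
})

test_that("empirical age slopes match the generating slopes (OLS oracle)", {
  p <- normativePreset(nSubjects = 5000, seed = 11)
  co <- generateNormativeCohort(p)
  z <- thicknessMatrix(co)
  a <- ages(co)
  for (r in c(4, 26, 50)) {  # entorhinal-l, superiorfrontal-l, arbitrary rh
    fit <- summary(lm(z[, r] ~ a))
    est <- fit$coefficients["a", "Estimate"]
    se <- fit$coefficients["a", "Std. Error"]
    expect_lt(abs(est - p@ageSlope[r] / 10), 3 * se)
  }
})

test_that("the generator is deterministic and balances outcomes", {
  p <- strongEffectPreset(nSubjects = 60, seed = 5)
  a <- generateLongitudinalCohort(p)
  b <- generateLongitudinalCohort(p)
  expect_identical(thicknessMatrix(a), thicknessMatrix(b))
  expect_identical(visitTimes(a), visitTimes(b))
  oc <- outcomes(a)
  expect_equal(sum(oc == "converter"), round(0.4 * 60))
  # converters are MCI at baseline and AD only at the last visit
  cd <- SummarizedExperiment::colData(a)
  for (s in names(oc)[oc == "converter"][1:5]) {
    dx <- cd$diagnosis[cd$subject_id == s]
    expect_identical(dx, c(rep("MCI", length(dx) - 1), "AD"))
  }
})

test_that("degenerate jitter gives exactly annual visits", {
  p <- GenerationParams(nSubjects = 20, visitIntervalJitterSD = 0,
                        visitsPerSubject = c(3, 3), seed = 9)
  co <- generateLongitudinalCohort(p)
  gaps <- unlist(tapply(visitTimes(co), subjectIds(co), diff))
  expect_equal(unname(gaps), rep(1, length(gaps)), tolerance = 1e-12)
})

test_that("converter atrophy is injected exactly and only where declared", {
  # noise-free: converter minus stable at equal age/time = slope * t on
  # signature regions, zero elsewhere
  p <- GenerationParams(nSubjects = 40, subjectSD = 0, noiseSD = 0,
                        visitIntervalJitterSD = 0,
                        visitsPerSubject = c(3, 3),
                        converterExtraSlope = -0.3, seed = 2)
  co <- generateLongitudinalCohort(p)
  z <- thicknessMatrix(co)
  oc <- outcomes(co)
  t <- visitTimes(co)
  isConv <- oc[subjectIds(co)] == "converter"
  sig <- signatureRegionIndices()
  # remove the age trend analytically, leaving offset-free residuals
  mu <- outer((ages(co) - mean(p@ageRange)) / 10, p@ageSlope)
  resid <- z - mu
  sel <- isConv & t == 2
  expect_equal(unname(resid[sel, sig[1]]), rep(-0.6, sum(sel)),
               tolerance = 1e-12)
  nonsig <- setdiff(seq_len(62), sig)
  expect_true(max(abs(resid[, nonsig])) < 1e-12)
})

test_that("null effect leaves converter and stable profiles indistinguishable", {
  p <- nullEffectPreset(nSubjects = 300, seed = 13)
  co <- generateLongitudinalCohort(p)
  sigMean <- rowMeans(thicknessMatrix(co)[, signatureRegionIndices()])
  isConv <- outcomes(co)[subjectIds(co)] == "converter"
  tt <- t.test(sigMean[isConv], sigMean[!isConv])
  expect_lt(abs(tt$statistic), 3)
})
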