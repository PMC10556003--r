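## Default thinning rates, z-units per decade: a smooth gradient across the
## roster with stronger decline in the AD-signature parcels, mirroring the
## pattern of age-related cortical thinning that drives the principal axis.
.defaultAgeSlope <- function() {
  base <- sub("^(lh|rh)_", "", dktRegionRoster())
  slope <- -0.10 - 0.15 * (match(base, .dkt_base_regions) - 1) /
    (length(.dkt_base_regions) - 1)
  slope[signatureRegionIndices()] <- -0.35
  slope
}

#' Construct generator parameters
#'
#' Defaults encode the study conditions the pipeline targets: a
#' cross-sectional normative cohort spanning ages 18-100, and a longitudinal
#' MCI cohort with baseline ages 55-92, 2-6 roughly annual visits (gap
#' jitter SD 0.2 y), 40% converters, and converter-specific extra atrophy of
#' the bilateral AD-signature regions.
#'
#' @param nSubjects number of subjects (default 400).
#' @param ageRange age range in years; baseline ages for longitudinal cohorts.
#' @param visitsPerSubject min/max visits per subject.
#' @param visitIntervalMean mean inter-visit gap (years).
#' @param visitIntervalJitterSD gap jitter SD (years).
#' @param ageSlope 62-vector of per-region thinning rates, z per decade
#'   (all <= 0).
#' @param signatureRegions roster indices of converter-atrophy regions.
#' @param converterExtraSlope extra converter atrophy, z per year (<= 0).
#' @param converterFraction proportion of converters in (0, 1).
#' @param subjectSD between-subject offset SD (z-units).
#' @param noiseSD per-visit noise SD (z-units).
#' @param seed RNG seed.
#' @return A validated [GenerationParams-class].
#' @export
GenerationParams <- function(nSubjects = 400,
                             ageRange = c(55, 92),
                             visitsPerSubject = c(2, 6),
                             visitIntervalMean = 1.0,
                             visitIntervalJitterSD = 0.2,
                             ageSlope = .defaultAgeSlope(),
                             signatureRegions = signatureRegionIndices(),
                             converterExtraSlope = -0.7,
                             converterFraction = 0.4,
                             subjectSD = 0.4,
                             noiseSD = 0.2,
                             seed = 20) {
  new("GenerationParams",
      nSubjects = as.integer(nSubjects), ageRange = as.numeric(ageRange),
      visitsPerSubject = as.integer(visitsPerSubject),
      visitIntervalMean = as.numeric(visitIntervalMean),
      visitIntervalJitterSD = as.numeric(visitIntervalJitterSD),
      ageSlope = as.numeric(ageSlope),
      signatureRegions = as.integer(signatureRegions),
      converterExtraSlope = as.numeric(converterExtraSlope),
      converterFraction = as.numeric(converterFraction),
      subjectSD = as.numeric(subjectSD), noiseSD = as.numeric(noiseSD),
      seed = as.integer(seed))
}

#' Preset: normative cross-sectional generator parameters
#'
#' Ages uniform over 18-100, one scan per subject; a desk-scale analogue of
#' a large healthy normative sample.
#' @param nSubjects number of subjects (default 1200).
#' @param seed RNG seed.
#' @export
normativePreset <- function(nSubjects = 1200, seed = 18) {
  GenerationParams(nSubjects = nSubjects, ageRange = c(18, 100),
                   visitsPerSubject = c(1, 1), seed = seed)
}

#' Preset: longitudinal MCI cohort with converter atrophy
#'
#' The default effect size (converter extra slope -0.7 z/year on the twelve
#' signature regions) is the "strong effect" condition under which the
#' trajectory classifier should separate converters from stables well above
#' chance.
#' @param nSubjects number of subjects (default 400).
#' @param seed RNG seed.
#' @export
strongEffectPreset <- function(nSubjects = 400, seed = 20) {
  GenerationParams(nSubjects = nSubjects, seed = seed)
}

#' Preset: null-effect longitudinal cohort
#'
#' Converter labels are assigned but carry no atrophy signal
#' (`converterExtraSlope = 0`); any classifier should perform at chance.
#' @param nSubjects number of subjects (default 400).
#' @param seed RNG seed.
#' @export
nullEffectPreset <- function(nSubjects = 400, seed = 20) {
  GenerationParams(nSubjects = nSubjects, converterExtraSlope = 0, seed = seed)
}

## Mean thickness z for one scan under the generative model.
## age_ref is the midpoint of the age range; converter drift acts on the
## signature regions only, linearly in time since baseline.
.meanThickness <- function(params, age, visitTime, isConverter) {
  ageRef <- mean(params@ageRange)
  mu <- params@ageSlope * (age - ageRef) / 10
  if (isConverter && length(params@signatureRegions))
    mu[params@signatureRegions] <- mu[params@signatureRegions] +
      params@converterExtraSlope * visitTime
  mu
}

#' Generate a cross-sectional normative cohort
#'
#' One scan per subject, ages uniform over `ageRange`. Each region's z-score
#' is `ageSlope * (age - ageRef)/10 + subject offset + noise` with `ageRef`
#' the midpoint of the age range, subject offsets `N(0, subjectSD)` shared
#' across regions of a subject, and iid `N(0, noiseSD)` measurement noise.
#'
#' @param params a [GenerationParams-class].
#' @return A cross-sectional [ThicknessCohort-class], deterministic given
#'   `params@seed`.
#' @export
generateNormativeCohort <- function(params = normativePreset()) {
  stopifnot(is(params, "GenerationParams"))
  validObject(params)
  n <- params@nSubjects
  withSeed(params@seed, {
    age <- runif(n, params@ageRange[1], params@ageRange[2])
    offset <- rnorm(n, 0, params@subjectSD)
    thick <- matrix(0, n, 62)
    for (i in seq_len(n)) {
      thick[i, ] <- .meanThickness(params, age[i], 0, FALSE) + offset[i] +
        rnorm(62, 0, params@noiseSD)
    }
    colnames(thick) <- dktRegionRoster()
    ThicknessCohort(
      thickness = thick,
      subjectId = sprintf("N%04d", seq_len(n)),
      visitTime = rep(0, n), age = age,
      diagnosis = rep("CH", n), kind = "cross_sectional")
  })
}

#' Generate a longitudinal MCI cohort
#'
#' Each subject receives `k ~ Uniform{min..max}` visits with gaps
#' `N(intervalMean, jitterSD)` truncated positive (a deliberately irregular
#' schedule that exercises annual binning). A fixed fraction of subjects are
#' converters: their signature regions accrue `converterExtraSlope * t` extra
#' atrophy, and their diagnosis flips from MCI to AD at the final visit.
#' Stables remain MCI throughout.
#'
#' @param params a [GenerationParams-class].
#' @return A longitudinal [ThicknessCohort-class], deterministic given
#'   `params@seed`.
#' @export
generateLongitudinalCohort <- function(params = strongEffectPreset()) {
  stopifnot(is(params, "GenerationParams"))
  validObject(params)
  n <- params@nSubjects
  nConv <- round(params@converterFraction * n)
  withSeed(params@seed, {
    baselineAge <- runif(n, params@ageRange[1], params@ageRange[2])
    nVisits <- sample(seq(params@visitsPerSubject[1],
                          params@visitsPerSubject[2]), n, replace = TRUE)
    isConverter <- seq_len(n) %in% sample.int(n, nConv)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      k <- nVisits[i]
      gaps <- if (k > 1) {
        g <- rnorm(k - 1, params@visitIntervalMean,
                   params@visitIntervalJitterSD)
        while (any(g <= 0))
          g[g <= 0] <- rnorm(sum(g <= 0), params@visitIntervalMean,
                             params@visitIntervalJitterSD)
        g
      } else numeric(0)
      t <- c(0, cumsum(gaps))
      offset <- rnorm(1, 0, params@subjectSD)
      thick <- t(vapply(seq_len(k), function(j) {
        .meanThickness(params, baselineAge[i] + t[j], t[j], isConverter[i]) +
          offset + rnorm(62, 0, params@noiseSD)
      }, numeric(62)))
      dx <- rep("MCI", k)
      if (isConverter[i]) dx[k] <- "AD"
      rows[[i]] <- list(
        thickness = thick,
        subjectId = rep(sprintf("L%04d", i), k),
        visitTime = t, age = baselineAge[i] + t, diagnosis = dx,
        outcome = rep(if (isConverter[i]) "converter" else "stable", k))
    }
    ThicknessCohort(
      thickness = do.call(rbind, lapply(rows, `[[`, "thickness")),
      subjectId = unlist(lapply(rows, `[[`, "subjectId")),
      visitTime = unlist(lapply(rows, `[[`, "visitTime")),
      age = unlist(lapply(rows, `[[`, "age")),
      diagnosis = unlist(lapply(rows, `[[`, "diagnosis")),
      kind = "longitudinal",
      outcome = unlist(lapply(rows, `[[`, "outcome")))
  })
}
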