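#' Extract a trajectory of given length from a cluster sequence
#'
#' A subject's trajectory of length `l` is the chronologically ordered
#' sequence of the clusters of their last `l` visits. A subject with fewer
#' than `l` visits has no trajectory of that length.
#'
#' @param clusterSequence integer vector of per-visit cluster ids, oldest to
#'   newest.
#' @param l trajectory length (>= 1).
#' @return Integer vector of length `l`, or `NULL` when the subject has
#'   fewer than `l` visits.
#' @export
extractTrajectory <- function(clusterSequence, l) {
  if (l < 1) stop("trajectory length must be >= 1")
  if (length(clusterSequence) < l) return(NULL)
  utils::tail(clusterSequence, l)
}

.trajectoryKey <- function(states) paste(states, collapse = "-")

#' Size of the trajectory space
#'
#' The number of possible trajectories of every length 1..L over C clusters,
#' `T = sum_{l=1}^{L} C^l`. The companion [fixedLengthTrajectoryCount()]
#' gives `C^L`, the count at the maximal length alone; both conventions
#' appear in the disease-progression literature.
#'
#' @param C number of clusters (>= 1).
#' @param L maximum trajectory length (>= 1).
#' @return Numeric count.
#' @export
trajectorySpaceSize <- function(C, L) {
  stopifnot(C >= 1, L >= 1)
  sum(as.numeric(C)^(seq_len(L)))
}

#' @rdname trajectorySpaceSize
#' @export
fixedLengthTrajectoryCount <- function(C, L) {
  stopifnot(C >= 1, L >= 1)
  as.numeric(C)^L
}

#' Build the probabilistic trajectory atlas
#'
#' For every subject and every length `l = 1..L` available to them, the
#' trajectory of their last `l` visits is recorded together with the
#' subject's outcome; each observed trajectory's conversion probability is
#' the fraction of its subjects who converted. Trajectories never observed
#' stay out of the table and implicitly score probability 0 with
#' population 0 — "no evidence" rather than evidence of stability, which is
#' why the population is always reported alongside.
#'
#' @param clusterSequences list of integer vectors (per-visit cluster ids,
#'   oldest to newest), one per subject.
#' @param outcomeLabels character vector, `"stable"` or `"converter"`, one
#'   per subject.
#' @param C number of clusters.
#' @param L maximum trajectory length (default 3).
#' @return A [TrajectoryAtlas-class].
#' @export
buildAtlas <- function(clusterSequences, outcomeLabels, C, L = 3) {
  stopifnot(length(clusterSequences) == length(outcomeLabels),
            all(outcomeLabels %in% .outcome_levels))
  C <- as.integer(C); L <- as.integer(L)
  allStates <- unlist(clusterSequences)
  if (length(allStates) && (min(allStates) < 0 || max(allStates) >= C))
    stop("cluster ids must lie in 0..C-1")
  keys <- character(0); lens <- integer(0); conv <- logical(0)
  for (s in seq_along(clusterSequences)) {
    seqS <- clusterSequences[[s]]
    for (l in seq_len(min(L, length(seqS)))) {
      keys <- c(keys, .trajectoryKey(utils::tail(seqS, l)))
      lens <- c(lens, l)
      conv <- c(conv, outcomeLabels[s] == "converter")
    }
  }
  if (length(keys)) {
    agg <- stats::aggregate(cbind(n_converter = conv, n_stable = !conv),
                            by = list(trajectory = keys, length = lens), sum)
    agg <- agg[order(agg$length, agg$trajectory), ]
    entries <- data.frame(
      trajectory = agg$trajectory, length = as.integer(agg$length),
      n_stable = as.integer(agg$n_stable),
      n_converter = as.integer(agg$n_converter),
      probability = agg$n_converter / (agg$n_stable + agg$n_converter),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    entries <- data.frame(trajectory = character(0), length = integer(0),
                          n_stable = integer(0), n_converter = integer(0),
                          probability = numeric(0))
  }
  new("TrajectoryAtlas", nClusters = C, maxLength = L, entries = entries)
}

#' Look up a subject's conversion probability
#'
#' Extracts the subject's length-`l` trajectory and returns the atlas
#' probability with its supporting population. Unseen trajectories return
#' probability 0 with population 0; a subject with fewer than `l` visits
#' returns `NA` probability (insufficient history — distinguishable from a
#' genuine 0).
#'
#' @param atlas a [TrajectoryAtlas-class].
#' @param clusterSequence the subject's per-visit cluster ids.
#' @param l trajectory length.
#' @return List with `probability` and `population`.
#' @export
predictConversionProbability <- function(atlas, clusterSequence, l) {
  stopifnot(is(atlas, "TrajectoryAtlas"))
  if (l < 1 || l > atlas@maxLength) stop("l must lie in 1..L")
  traj <- extractTrajectory(clusterSequence, l)
  if (is.null(traj))
    return(list(probability = NA_real_, population = 0L))
  key <- .trajectoryKey(traj)
  hit <- which(atlas@entries$trajectory == key & atlas@entries$length == l)
  if (!length(hit)) return(list(probability = 0, population = 0L))
  e <- atlas@entries[hit, ]
  list(probability = e$probability,
       population = e$n_stable + e$n_converter)
}

#' Threshold a conversion probability into an outcome call
#'
#' A subject is called a converter when the probability strictly exceeds the
#' threshold.
#'
#' @param probability conversion probability in `[0, 1]` (vectorised).
#' @param threshold decision threshold in `[0, 1]` (default 0.5).
#' @return Character vector, `"converter"` or `"stable"` (`NA` propagates).
#' @export
classifyOutcome <- function(probability, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  ifelse(is.na(probability), NA_character_,
         ifelse(probability > threshold, "converter", "stable"))
}

#' Write / read a trajectory atlas as CSV
#'
#' The CSV uses dash-joined trajectory keys (e.g. `"1-3-3"`).
#'
#' @param atlas a [TrajectoryAtlas-class].
#' @param path file path.
#' @return `writeAtlas` invisibly returns `path`; `readAtlas` the atlas.
#' @export
writeAtlas <- function(atlas, path) {
  stopifnot(is(atlas, "TrajectoryAtlas"))
  df <- cbind(C = atlas@nClusters, L = atlas@maxLength, atlas@entries)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname writeAtlas
#' @export
readAtlas <- function(path) {
  df <- data.table::fread(path, data.table = FALSE,
                          colClasses = list(character = "trajectory"))
  entries <- df[, c("trajectory", "length", "n_stable", "n_converter",
                    "probability")]
  entries$length <- as.integer(entries$length)
  entries$n_stable <- as.integer(entries$n_stable)
  entries$n_converter <- as.integer(entries$n_converter)
  new("TrajectoryAtlas", nClusters = as.integer(df$C[1]), maxLength = as.integer(df$L[1]),
      entries = entries)
}
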