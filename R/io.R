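#' @importFrom data.table fread fwrite
NULL

.metaColumns <- function(kind) {
  base <- c("subject_id", "visit_time", "age", "diagnosis")
  if (kind == "longitudinal") c(base, "outcome") else base
}

#' Read a visit table into a ThicknessCohort
#'
#' Expects a long-format delimited table, one row per scan, with columns
#' `subject_id`, `visit_time`, `age`, `diagnosis`, (`outcome` for
#' longitudinal cohorts) followed by the 62 region columns in
#' [dktRegionRoster()] order. The delimiter is inferred from the extension
#' (`.tsv` tab, otherwise comma).
#'
#' @param path file path.
#' @param kind `"longitudinal"` or `"cross_sectional"`.
#' @return A validated [ThicknessCohort-class].
#' @export
readCohort <- function(path, kind = c("longitudinal", "cross_sectional")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = list(character = "subject_id"),
                          data.table = FALSE)
  roster <- dktRegionRoster()
  meta <- .metaColumns(kind)
  missing_meta <- setdiff(meta, colnames(dt))
  if (length(missing_meta))
    stop("missing metadata columns: ", paste(missing_meta, collapse = ", "))
  region_cols <- setdiff(colnames(dt), meta)
  missing_r <- setdiff(roster, region_cols)
  extra_r <- setdiff(region_cols, roster)
  if (length(missing_r) || length(extra_r))
    stop("region column mismatch; missing: [",
         paste(missing_r, collapse = ", "), "]; unexpected: [",
         paste(extra_r, collapse = ", "), "]")
  thick <- as.matrix(dt[, roster, drop = FALSE])
  if (!is.numeric(thick)) {
    bad <- which(!vapply(dt[roster], is.numeric, TRUE))
    badrow <- which(is.na(suppressWarnings(as.numeric(as.matrix(dt[, roster[bad[1]]])))))[1]
    stop(sprintf("non-numeric thickness in column '%s' (row %d)",
                 roster[bad[1]], badrow))
  }
  if (anyNA(thick)) {
    idx <- which(is.na(thick), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing thickness in column '%s' (row %d)",
                 roster[idx[2]], idx[1]))
  }
  ThicknessCohort(
    thickness = thick,
    subjectId = dt$subject_id, visitTime = dt$visit_time, age = dt$age,
    diagnosis = dt$diagnosis, kind = kind,
    outcome = if (kind == "longitudinal") dt$outcome else NULL
  )
}

#' Write a ThicknessCohort as a long-format visit table
#'
#' Emits exactly the table [readCohort()] accepts, at full double precision.
#'
#' @param cohort a [ThicknessCohort-class].
#' @param path output path; `.tsv` selects tab separation, anything else CSV.
#' @return Invisibly, `path`.
#' @export
writeCohort <- function(cohort, path) {
  stopifnot(is(cohort, "ThicknessCohort"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(
    subject_id = subjectIds(cohort),
    visit_time = visitTimes(cohort),
    age = ages(cohort),
    diagnosis = diagnoses(cohort),
    stringsAsFactors = FALSE
  )
  if (cohortKind(cohort) == "longitudinal")
    df$outcome <- SummarizedExperiment::colData(cohort)$outcome
  df <- cbind(df, as.data.frame(thicknessMatrix(cohort)))
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}
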