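# Cohort readers/writers with schema and referential-integrity validation.
# Interchange format: RFC-4180 CSV, UTF-8, header row.

.cohort_schemas <- list(
  baseline = list(
    file = "baseline.csv",
    cols = c("patient_id", "study_id", "arm", "sex", "age", "smoking",
             "gold_severity", "fev1_baseline", "fev1_pct_pred",
             "sgrq_baseline", "bdi", "eosinophils", "ics_use",
             "prior_exacerbation")
  ),
  visits = list(
    file = "visits.csv",
    cols = c("patient_id", "visit_week", "visit_day", "fev1", "sgrq")
  ),
  exacerbations = list(
    file = "exacerbations.csv",
    cols = c("patient_id", "onset_day", "severity")
  ),
  followup = list(
    file = "followup.csv",
    cols = c("patient_id", "last_contact_day", "discontinued_early",
             "study_end_day")
  )
)

#' Write a cohort to a directory of CSV files
#'
#' Writes `baseline.csv`, `visits.csv`, `exacerbations.csv` and
#' `followup.csv` with the documented column dictionary. The directory is
#' created (with a notice) if absent.
#'
#' @param cohort a `cid_cohort` (or compatible list of the four tables).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) {
    message("creating output directory: ", dir)
    dir.create(dir, recursive = TRUE)
  }
  for (nm in names(.cohort_schemas)) {
    tab <- cohort[[nm]]
    .assert_cols(tab, .cohort_schemas[[nm]]$cols, nm)
    utils::write.csv(tab[, .cohort_schemas[[nm]]$cols, drop = FALSE],
                     file.path(dir, .cohort_schemas[[nm]]$file),
                     row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  }
  invisible(dir)
}

#' Read and validate a cohort from CSV files
#'
#' Loads the four cohort tables, coerces types, and enforces the schema and
#' cross-table referential integrity: no missing columns, no duplicate
#' patients, no visit/exacerbation/follow-up rows for unknown patients,
#' exactly one follow-up row per patient, visit day = 7 x visit week, and
#' `1 <= last_contact_day <= study_end_day` consistent with the
#' early-discontinuation flag. Violations raise errors listing the
#' offending ids.
#'
#' @param dir directory containing the four CSVs (alternatively pass
#'   explicit `paths`, a named list/vector with entries `baseline`,
#'   `visits`, `exacerbations`, `followup`).
#' @param paths optional explicit file paths overriding `dir`.
#' @return a validated `cid_cohort`.
#' @export
read_cohort <- function(dir = NULL, paths = NULL) {
  if (is.null(paths)) {
    if (is.null(dir)) stop("provide 'dir' or 'paths'")
    paths <- vapply(.cohort_schemas, function(s) file.path(dir, s$file), "")
  }
  paths <- as.list(paths)
  out <- list()
  for (nm in names(.cohort_schemas)) {
    p <- paths[[nm]]
    if (is.null(p) || !file.exists(p)) {
      stop("missing cohort file for table '", nm, "': ", p %||% "<unset>")
    }
    tab <- utils::read.csv(p, stringsAsFactors = FALSE)
    .assert_cols(tab, .cohort_schemas[[nm]]$cols, paste0(nm, " (", p, ")"))
    out[[nm]] <- tab[, .cohort_schemas[[nm]]$cols, drop = FALSE]
  }
  out$baseline$ics_use <- as.logical(out$baseline$ics_use)
  out$baseline$prior_exacerbation <- as.logical(out$baseline$prior_exacerbation)
  out$followup$discontinued_early <- as.logical(out$followup$discontinued_early)
  for (nm in c("visit_week", "visit_day")) {
    out$visits[[nm]] <- as.integer(out$visits[[nm]])
  }
  validate_cohort(out)
}

#' Validate a cohort's schema and cross-table integrity
#'
#' @param cohort list of the four cohort tables.
#' @return the cohort, classed `cid_cohort`, invisibly usable downstream.
#' @export
validate_cohort <- function(cohort) {
  b <- cohort$baseline
  ids <- b$patient_id
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate patient_id in baseline: ",
                        paste(dup, collapse = ", "))
  if (any(!is.na(b$fev1_baseline) & b$fev1_baseline <= 0)) {
    stop("fev1_baseline must be positive")
  }
  if (any(!is.na(b$sgrq_baseline) &
          (b$sgrq_baseline < 0 | b$sgrq_baseline > 100))) {
    stop("sgrq_baseline must lie in [0, 100]")
  }
  for (nm in c("visits", "exacerbations", "followup")) {
    orphan <- setdiff(unique(cohort[[nm]]$patient_id), ids)
    if (length(orphan)) {
      stop(sprintf("%s rows refer to unknown patient_id(s): %s", nm,
                   paste(orphan, collapse = ", ")))
    }
  }
  v <- cohort$visits
  bad_day <- v$patient_id[v$visit_day != 7L * v$visit_week]
  if (length(bad_day)) {
    stop("visit_day must equal 7 x visit_week; offending patient(s): ",
         paste(unique(bad_day), collapse = ", "))
  }
  f <- cohort$followup
  if (anyDuplicated(f$patient_id) || !setequal(f$patient_id, ids)) {
    stop("followup must contain exactly one row per baseline patient")
  }
  bad_f <- f$patient_id[f$last_contact_day < 1 |
                          f$last_contact_day > f$study_end_day |
                          (f$discontinued_early !=
                             (f$last_contact_day < f$study_end_day))]
  if (length(bad_f)) {
    stop("invalid follow-up record(s) for patient(s): ",
         paste(unique(bad_f), collapse = ", "))
  }
  e <- cohort$exacerbations
  if (nrow(e)) {
    lc <- f$last_contact_day[match(e$patient_id, f$patient_id)]
    bad_e <- e$patient_id[e$onset_day < 1 | e$onset_day > lc]
    if (length(bad_e)) {
      stop("exacerbation onset_day outside [1, last_contact_day] for patient(s): ",
           paste(unique(bad_e), collapse = ", "))
    }
  }
  structure(cohort[c("baseline", "visits", "exacerbations", "followup")],
            class = "cid_cohort")
}
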