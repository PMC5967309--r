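# Derivation of first and sustained clinically important deterioration (CID)
# events from longitudinal visit records.

.cid_components <- c("FEV1", "SGRQ", "EXACERBATION")

#' CID component thresholds and sustained-rule settings
#'
#' The composite endpoint flags a post-baseline visit when pre-dose FEV1 has
#' fallen by at least `fev1_drop` litres from baseline, or SGRQ total score
#' has risen by at least `sgrq_rise` units; a moderate-to-severe exacerbation
#' after first dose is the third component. Both measurement boundaries are
#' inclusive. A component deterioration is *sustained* when it is present on
#' `sustained_min_consecutive` consecutive scheduled visits spaced one visit
#' interval apart, or on at least `sustained_fraction` of all available
#' subsequent visits (the triggering visit included; "available" = visits
#' with a non-missing measurement for that component, through last contact).
#'
#' @param fev1_drop FEV1 decrease from baseline that flags, in litres
#'   (default 0.100 L).
#' @param sgrq_rise SGRQ increase from baseline that flags, in units
#'   (default 4).
#' @param sustained_min_consecutive consecutive flagged visits satisfying the
#'   first sustained branch (default 2).
#' @param sustained_fraction fraction of available subsequent visits flagged
#'   that satisfies the second branch (default 0.5).
#' @return an object of class `cid_thresholds`.
#' @export
cid_thresholds <- function(fev1_drop = 0.100, sgrq_rise = 4,
                           sustained_min_consecutive = 2L,
                           sustained_fraction = 0.5) {
  .assert_scalar_num(fev1_drop, "fev1_drop", lower = 1e-12)
  .assert_scalar_num(sgrq_rise, "sgrq_rise", lower = 1e-12)
  .assert_scalar_num(sustained_min_consecutive, "sustained_min_consecutive",
                     lower = 2)
  .assert_scalar_num(sustained_fraction, "sustained_fraction",
                     lower = 1e-12, upper = 1)
  structure(list(fev1_drop = fev1_drop, sgrq_rise = sgrq_rise,
                 sustained_min_consecutive = as.integer(sustained_min_consecutive),
                 sustained_fraction = sustained_fraction),
            class = "cid_thresholds")
}

#' Flag per-visit CID measurement components
#'
#' Computes, for every scheduled visit, whether the FEV1 and SGRQ components
#' of the CID definition are met relative to the patient's baseline. A flag
#' is `NA` (not `FALSE`) when the visit measurement is missing. Patients with
#' a missing baseline value are excluded from that component with a warning.
#' Boundaries are inclusive: a decrease of exactly `fev1_drop` litres, or a
#' rise of exactly `sgrq_rise` units, flags.
#'
#' @param baseline PatientBaseline data frame (`patient_id`, `fev1_baseline`,
#'   `sgrq_baseline`, ...).
#' @param visits VisitObservation data frame (`patient_id`, `visit_week`,
#'   `visit_day`, `fev1`, `sgrq`), sorted by visit week within patient.
#' @param thresholds a [cid_thresholds()] object.
#' @return data frame: `patient_id`, `visit_week`, `visit_day`, `fev1_flag`,
#'   `sgrq_flag` (logical, `NA` when unassessable).
#' @export
flag_components <- function(baseline, visits, thresholds = cid_thresholds()) {
  .assert_cols(baseline, c("patient_id", "fev1_baseline", "sgrq_baseline"),
               "baseline")
  .assert_cols(visits, c("patient_id", "visit_week", "visit_day", "fev1", "sgrq"),
               "visits")
  if (!inherits(thresholds, "cid_thresholds")) {
    stop("'thresholds' must be a cid_thresholds object")
  }
  m <- match(visits$patient_id, baseline$patient_id)
  if (anyNA(m)) {
    stop("visits contain unknown patient_id(s): ",
         paste(unique(visits$patient_id[is.na(m)]), collapse = ", "))
  }
  fb <- baseline$fev1_baseline[m]
  sb <- baseline$sgrq_baseline[m]
  for (comp in c("fev1", "sgrq")) {
    bcol <- paste0(comp, "_baseline")
    bad <- unique(baseline$patient_id[is.na(baseline[[bcol]])])
    bad <- bad[bad %in% visits$patient_id]
    if (length(bad)) {
      warning(sprintf("missing baseline %s for patient(s) %s: excluded from the %s component",
                      toupper(comp), paste(bad, collapse = ", "), toupper(comp)),
              call. = FALSE)
    }
  }
  data.frame(
    patient_id = visits$patient_id,
    visit_week = as.integer(visits$visit_week),
    visit_day = as.integer(visits$visit_day),
    fev1_flag = (fb - visits$fev1) >= thresholds$fev1_drop - .cid_eps,
    sgrq_flag = (visits$sgrq - sb) >= thresholds$sgrq_rise - .cid_eps,
    stringsAsFactors = FALSE
  )
}

#' Censoring day for a patient without an event
#'
#' Patients with no deterioration are censored at the end of the study;
#' early discontinuers are censored at their last contact day.
#'
#' @param followup one FollowUpRecord row (`last_contact_day`,
#'   `discontinued_early`, `study_end_day`).
#' @return list with `day` (integer) and `event` (`FALSE`).
#' @export
censor_day <- function(followup) {
  lc <- followup$last_contact_day
  se <- followup$study_end_day
  if (length(lc) != 1L || length(se) != 1L) stop("'followup' must be one record")
  if (is.na(lc) || is.na(se) || lc < 1 || lc > se) {
    stop("invalid follow-up record: need 1 <= last_contact_day <= study_end_day")
  }
  if (isTRUE(followup$discontinued_early) != (lc < se)) {
    stop("'discontinued_early' inconsistent with last_contact_day vs study_end_day")
  }
  list(day = as.integer(if (isTRUE(followup$discontinued_early)) lc else se),
       event = FALSE)
}

# Earliest sustained week for one component's flag sequence, or NA.
# weeks: ascending scheduled visit weeks present through last contact;
# flags: logical with NA for missing measurements.
.sustained_week <- function(weeks, flags, interval, min_consec, frac) {
  k <- length(weeks)
  if (!k) return(NA_integer_)
  ft <- flags %in% TRUE
  obs <- !is.na(flags)
  # branch (b): flagged at v and at >= frac of available visits at/after v
  avail_after <- rev(cumsum(rev(as.integer(obs))))
  flag_after <- rev(cumsum(rev(as.integer(ft))))
  rule_b <- ft & avail_after > 0L & (flag_after / avail_after >= frac - 1e-12)
  # branch (a): flagged on min_consec visits exactly one interval apart on
  # the nominal schedule (a missing intervening measurement breaks the run)
  rule_a <- ft
  if (min_consec > 1L) {
    for (off in seq_len(min_consec - 1L)) {
      nxt <- match(weeks + off * interval, weeks)
      has <- !is.na(nxt)
      nxt[!has] <- 1L
      rule_a <- rule_a & has & ft[nxt]
    }
  }
  hit <- which(rule_a | rule_b)
  if (length(hit)) weeks[hit[1L]] else NA_integer_
}

# Shared per-patient derivation returning all first/sustained fields.
.derive_patient <- function(flags_p, exac_days, followup, thresholds,
                            visit_interval = 4L) {
  cens <- censor_day(followup)
  ord <- order(flags_p$visit_week)
  weeks <- flags_p$visit_week[ord]
  f_fev1 <- flags_p$fev1_flag[ord]
  f_sgrq <- flags_p$sgrq_flag[ord]

  first_week <- function(fl) {
    w <- weeks[fl %in% TRUE]
    if (length(w)) w[1L] else NA_integer_
  }
  fw_fev1 <- first_week(f_fev1)
  fw_sgrq <- first_week(f_sgrq)
  exac_days <- exac_days[!is.na(exac_days) & exac_days >= 1]
  ex_first <- if (length(exac_days)) min(exac_days) else NA_integer_

  comp_first <- c(FEV1 = if (is.na(fw_fev1)) NA_integer_ else 7L * fw_fev1,
                  SGRQ = if (is.na(fw_sgrq)) NA_integer_ else 7L * fw_sgrq,
                  EXACERBATION = as.integer(ex_first))

  sw_fev1 <- .sustained_week(weeks, f_fev1, visit_interval,
                             thresholds$sustained_min_consecutive,
                             thresholds$sustained_fraction)
  sw_sgrq <- .sustained_week(weeks, f_sgrq, visit_interval,
                             thresholds$sustained_min_consecutive,
                             thresholds$sustained_fraction)
  # a single qualifying exacerbation is sustained by definition
  comp_sust <- c(FEV1 = if (is.na(sw_fev1)) NA_integer_ else 7L * sw_fev1,
                 SGRQ = if (is.na(sw_sgrq)) NA_integer_ else 7L * sw_sgrq,
                 EXACERBATION = as.integer(ex_first))

  overall <- function(ct) {
    if (all(is.na(ct))) {
      list(day = cens$day, event = FALSE, components = "")
    } else {
      d <- min(ct, na.rm = TRUE)
      list(day = as.integer(d), event = TRUE,
           components = paste(names(ct)[!is.na(ct) & ct == d], collapse = "+"))
    }
  }
  ofirst <- overall(comp_first)
  osust <- overall(comp_sust)

  cd <- function(x) ifelse(is.na(x), cens$day, as.integer(x))
  list(first_cid_day = ofirst$day, first_cid_event = ofirst$event,
       first_cid_components = ofirst$components,
       sustained_cid_day = osust$day, sustained_cid_event = osust$event,
       sustained_cid_components = osust$components,
       fev1_first_day = cd(comp_first[["FEV1"]]),
       fev1_first_event = !is.na(comp_first[["FEV1"]]),
       sgrq_first_day = cd(comp_first[["SGRQ"]]),
       sgrq_first_event = !is.na(comp_first[["SGRQ"]]),
       exac_first_day = cd(comp_first[["EXACERBATION"]]),
       exac_first_event = !is.na(comp_first[["EXACERBATION"]]),
       fev1_sustained_day = cd(comp_sust[["FEV1"]]),
       fev1_sustained_event = !is.na(comp_sust[["FEV1"]]),
       sgrq_sustained_day = cd(comp_sust[["SGRQ"]]),
       sgrq_sustained_event = !is.na(comp_sust[["SGRQ"]]),
       exac_sustained_day = cd(comp_sust[["EXACERBATION"]]),
       exac_sustained_event = !is.na(comp_sust[["EXACERBATION"]]),
       censor_day = cens$day)
}

#' First CID for one patient
#'
#' Time to first CID is the time to the first event of any component: the
#' visit day of the first flagged FEV1 or SGRQ visit, or the onset day of the
#' first moderate-to-severe exacerbation after first dose. All components
#' attaining the minimum are recorded (ties kept). Without any component
#' event the patient is censored per [censor_day()].
#'
#' @param flags one patient's [flag_components()] rows.
#' @param exacerbations that patient's exacerbation rows (may be empty);
#'   needs `onset_day`.
#' @param followup that patient's FollowUpRecord row.
#' @param thresholds a [cid_thresholds()] object.
#' @param visit_interval scheduled visit spacing in weeks (default 4).
#' @return list: `first_cid_day`, `first_cid_event`, `first_cid_components`.
#' @export
first_cid <- function(flags, exacerbations, followup,
                      thresholds = cid_thresholds(), visit_interval = 4L) {
  r <- .derive_patient(flags, exacerbations$onset_day %||% integer(), followup,
                       thresholds, visit_interval)
  r[c("first_cid_day", "first_cid_event", "first_cid_components")]
}

#' Sustained CID for one patient
#'
#' A measurement component (FEV1, SGRQ) is sustained at the earliest visit v
#' where it is flagged and either (a) also flagged at the
#' `sustained_min_consecutive - 1` following visits spaced exactly one visit
#' interval apart on the nominal schedule, or (b) flagged at >=
#' `sustained_fraction` of all available subsequent visits (v included;
#' visits with a missing measurement for that component do not count as
#' available). The sustained time is the visit day of v. A qualifying
#' exacerbation is sustained by definition at its onset day.
#'
#' @inheritParams first_cid
#' @return list: `sustained_cid_day`, `sustained_cid_event`,
#'   `sustained_cid_components`.
#' @export
sustained_cid <- function(flags, exacerbations, followup,
                          thresholds = cid_thresholds(), visit_interval = 4L) {
  r <- .derive_patient(flags, exacerbations$onset_day %||% integer(), followup,
                       thresholds, visit_interval)
  r[c("sustained_cid_day", "sustained_cid_event", "sustained_cid_components")]
}

#' Derive first and sustained CID results for a whole cohort
#'
#' Vectorized driver: applies the component flagging, first-CID and
#' sustained-CID rules to every patient, producing one row per patient with
#' overall and per-component event times and indicators, plus the censoring
#' day. Identical to per-patient application of [first_cid()] and
#' [sustained_cid()].
#'
#' @param cohort a `cid_cohort` (or list with `baseline`, `visits`,
#'   `exacerbations`, `followup` data frames).
#' @param thresholds a [cid_thresholds()] object.
#' @return data frame of class `cid_result`, one row per patient.
#' @export
derive_cid <- function(cohort, thresholds = cid_thresholds()) {
  baseline <- cohort$baseline; visits <- cohort$visits
  exac <- cohort$exacerbations; followup <- cohort$followup
  .assert_cols(followup, c("patient_id", "last_contact_day",
                           "discontinued_early", "study_end_day"), "followup")
  ids <- baseline$patient_id
  if (anyDuplicated(ids)) {
    stop("duplicate patient_id in baseline: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (nm in c("visits", "exacerbations", "followup")) {
    tab <- cohort[[nm]]
    orphan <- setdiff(unique(tab$patient_id), ids)
    if (length(orphan)) {
      stop(sprintf("%s rows refer to unknown patient_id(s): %s", nm,
                   paste(orphan, collapse = ", ")))
    }
  }
  if (!setequal(followup$patient_id, ids) || anyDuplicated(followup$patient_id)) {
    stop("followup must contain exactly one row per baseline patient")
  }

  interval <- 4L
  dw <- diff(sort(unique(visits$visit_week)))
  if (length(dw)) interval <- as.integer(min(dw))

  flags <- flag_components(baseline, visits, thresholds)
  fl_by <- split(flags, factor(flags$patient_id, levels = ids))
  ex_by <- split(exac$onset_day, factor(exac$patient_id, levels = ids))
  fu_by <- split(followup, factor(followup$patient_id, levels = ids))

  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows[[i]] <- .derive_patient(fl_by[[i]], ex_by[[i]], fu_by[[i]],
                                 thresholds, interval)
  }
  cols <- names(rows[[1L]])
  out <- lapply(cols, function(cn) unlist(lapply(rows, `[[`, cn),
                                          use.names = FALSE))
  names(out) <- cols
  out <- cbind(data.frame(patient_id = ids, stringsAsFactors = FALSE),
               as.data.frame(out, stringsAsFactors = FALSE))
  class(out) <- c("cid_result", "data.frame")
  out
}
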