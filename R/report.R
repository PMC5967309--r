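# Reporting surfaces: event-count summary, at-event measurement comparison,
# and subgroup forest tables.

#' Shipped subgroup definitions
#'
#' The nine standard subgroup splits used in the pooled forest-plot analysis:
#' sex; age (<65 / >=65 years); smoking (ex / current); prior-year
#' exacerbation (yes/no); ICS use (yes/no); baseline SGRQ (<=25 / >25);
#' BDI (<=7 / >7); COPD severity (moderate / severe); blood eosinophils
#' (<300 / >=300 cells/uL, the boundary value assigned to the high group).
#' A GOLD A+B vs C+D split (high risk = severe airflow limitation or a
#' prior-year exacerbation, using the programme's surrogates) is available
#' but disabled by default because a low exacerbation burden makes the risk
#' classification unrepresentative.
#'
#' @param include_gold_ad include the GOLD A+B vs C+D surrogate split
#'   (default `FALSE`).
#' @return named list of subgroup specs; each has `name`, `levels` and a
#'   `splitter(baseline)` function returning one level per patient.
#' @export
subgroup_specs <- function(include_gold_ad = FALSE) {
  spec <- function(name, levels, splitter) {
    list(name = name, levels = levels, splitter = splitter)
  }
  out <- list(
    sex = spec("Sex", c("male", "female"), function(b) b$sex),
    age = spec("Age", c("<65", ">=65"),
               function(b) ifelse(b$age < 65, "<65", ">=65")),
    smoking = spec("Smoking status", c("ex", "current"), function(b) b$smoking),
    prior_exacerbation = spec("Exacerbation in previous year", c("yes", "no"),
                              function(b) ifelse(b$prior_exacerbation, "yes", "no")),
    ics_use = spec("ICS use", c("yes", "no"),
                   function(b) ifelse(b$ics_use, "yes", "no")),
    sgrq = spec("Baseline SGRQ", c("<=25", ">25"),
                function(b) ifelse(b$sgrq_baseline <= 25, "<=25", ">25")),
    bdi = spec("Baseline BDI", c("<=7", ">7"),
               function(b) ifelse(b$bdi <= 7, "<=7", ">7")),
    severity = spec("COPD severity", c("moderate", "severe"),
                    function(b) b$gold_severity),
    eosinophils = spec("Blood eosinophils", c("<300", ">=300"),
                       function(b) ifelse(b$eosinophils >= 300, ">=300", "<300"))
  )
  if (include_gold_ad) {
    out$gold_ad <- spec("GOLD group", c("A+B", "C+D"), function(b) {
      ifelse(b$gold_severity == "severe" | b$prior_exacerbation, "C+D", "A+B")
    })
  }
  out
}

.endpoint_key <- function(endpoint, component) {
  if (component == "overall") return(endpoint)
  paste(switch(component, FEV1 = "fev1", SGRQ = "sgrq",
               EXACERBATION = "exac"), endpoint, sep = "_")
}

#' Event-count summary by arm and endpoint
#'
#' Tabulates, per arm, the number and percentage of patients with first and
#' sustained CID events, overall and by component (FEV1, SGRQ,
#' exacerbation). Percentages are count/arm-N rounded half-away-from-zero to
#' one decimal. Each endpoint/component row carries two between-arm
#' p-values computed on its time-to-event records: the log-rank p and the
#' treatment Wald p from a study-stratified Cox fit (which of the two a
#' published table reports is generally not identifiable, so both are kept).
#'
#' @param cid a [derive_cid()] result.
#' @param baseline PatientBaseline data frame; every arm must be non-empty.
#' @return object of class `cid_event_summary`: `counts` (long data frame:
#'   `endpoint`, `component`, `arm`, `n`, `events`, `pct`) and `tests`
#'   (`endpoint`, `component`, `p_logrank`, `p_cox`).
#' @export
summarize_events <- function(cid, baseline) {
  .assert_cols(baseline, c("patient_id", "arm"), "baseline")
  arms <- sort(unique(baseline$arm))
  arm_n <- table(factor(baseline$arm, levels = arms))
  if (any(arm_n == 0)) stop("every arm must contain at least one patient")
  m <- match(cid$patient_id, baseline$patient_id)
  if (anyNA(m)) stop("cid results contain patients absent from baseline")
  arm_of <- baseline$arm[m]

  counts <- list(); tests <- list(); k <- 0L
  for (endpoint in c("first", "sustained")) {
    for (component in c("overall", "FEV1", "SGRQ", "EXACERBATION")) {
      key <- .endpoint_key(endpoint, component)
      ev <- cid[[paste0(if (component == "overall") paste0(key, "_cid") else key,
                        "_event")]]
      k <- k + 1L
      ev_by <- tapply(ev, factor(arm_of, levels = arms), sum)
      counts[[k]] <- data.frame(
        endpoint = endpoint, component = component, arm = arms,
        n = as.integer(arm_n), events = as.integer(ev_by),
        pct = event_pct(as.integer(ev_by), as.integer(arm_n)),
        stringsAsFactors = FALSE
      )
      rec <- surv_records(cid, baseline,
                          if (component == "overall") endpoint else key)
      p_lr <- NA_real_; p_cox <- NA_real_
      if (length(arms) >= 2L && sum(rec$event) > 0 &&
          length(unique(rec$group[rec$event])) >= 1L) {
        p_lr <- tryCatch(logrank_test(rec)$p_value, error = function(e) NA_real_)
        p_cox <- tryCatch({
          strata <- if (length(unique(rec$study_id)) > 1L) "study_id" else NULL
          cf <- cox_fit(rec, covariates = "group", strata = strata)
          cf$table$p[grep("^group", cf$table$term)[1L]]
        }, error = function(e) NA_real_)
      }
      tests[[k]] <- data.frame(endpoint = endpoint, component = component,
                               p_logrank = p_lr, p_cox = p_cox,
                               stringsAsFactors = FALSE)
    }
  }
  structure(list(counts = do.call(rbind, counts),
                 tests = do.call(rbind, tests), arms = arms),
            class = "cid_event_summary")
}

#' @export
print.cid_event_summary <- function(x, ...) {
  cat("Patients with first and sustained clinically important deteriorations\n")
  for (endpoint in c("first", "sustained")) {
    cat(sprintf("\n%s CID\n",
                paste0(toupper(substr(endpoint, 1, 1)), substring(endpoint, 2))))
    for (component in c("overall", "FEV1", "SGRQ", "EXACERBATION")) {
      rows <- x$counts[x$counts$endpoint == endpoint &
                         x$counts$component == component, ]
      t_row <- x$tests[x$tests$endpoint == endpoint &
                         x$tests$component == component, ]
      cells <- sprintf("%s %d/%d (%.1f%%)", rows$arm, rows$events, rows$n,
                       rows$pct)
      cat(sprintf("  %-13s %s  [log-rank p %.4f, Cox p %.4f]\n",
                  component, paste(cells, collapse = "  "),
                  t_row$p_logrank, t_row$p_cox))
    }
  }
  invisible(x)
}

.mean_sd <- function(x) {
  n <- sum(!is.na(x))
  if (n == 0L) return(c(n = 0, mean = NA_real_, sd = NA_real_))
  c(n = n, mean = mean(x, na.rm = TRUE),
    sd = if (n == 1L) 0 else stats::sd(x, na.rm = TRUE))
}

#' Measurement values at baseline and at the triggering CID visit
#'
#' For patients whose FEV1 (resp. SGRQ) component triggered a first or
#' sustained CID, reports per arm the mean and SD of that measure at baseline
#' and at the triggering visit, with a Welch t-test between the first two
#' arms. Single-patient cells report SD 0 with `n = 1` (flagged by the `n`
#' column); a cohort without events yields an empty summary. Event times
#' that match no visit row are flagged with a warning and excluded.
#'
#' @param cid a [derive_cid()] result.
#' @param visits VisitObservation data frame.
#' @param baseline PatientBaseline data frame.
#' @return data frame of class `cid_at_event`: `endpoint`, `measure`, `arm`,
#'   `n`, `baseline_mean`, `baseline_sd`, `event_mean`, `event_sd`,
#'   `p_baseline`, `p_event` (between-arm), `n_unmatched`.
#' @export
values_at_event <- function(cid, visits, baseline) {
  .assert_cols(visits, c("patient_id", "visit_day", "fev1", "sgrq"), "visits")
  arms <- sort(unique(baseline$arm))
  out <- list(); k <- 0L
  for (endpoint in c("first", "sustained")) {
    for (measure in c("FEV1", "SGRQ")) {
      pref <- if (measure == "FEV1") "fev1" else "sgrq"
      vcol <- pref
      bcol <- paste0(pref, "_baseline")
      ecol <- paste0(pref, "_", endpoint, "_event")
      dcol <- paste0(pref, "_", endpoint, "_day")
      sub <- cid[cid[[ecol]], c("patient_id", dcol)]
      if (!nrow(sub)) next
      vm <- match(paste(sub$patient_id, sub[[dcol]]),
                  paste(visits$patient_id, visits$visit_day))
      unmatched <- sub$patient_id[is.na(vm) | is.na(visits[[vcol]][vm])]
      if (length(unmatched)) {
        warning(sprintf("%s %s events with no matching visit measurement for patient(s): %s",
                        endpoint, measure, paste(unmatched, collapse = ", ")),
                call. = FALSE)
      }
      ok <- !(sub$patient_id %in% unmatched)
      bm <- match(sub$patient_id, baseline$patient_id)
      df <- data.frame(arm = baseline$arm[bm],
                       base_val = baseline[[bcol]][bm],
                       ev_val = visits[[vcol]][vm],
                       stringsAsFactors = FALSE)[ok, , drop = FALSE]
      welch_p <- function(col) {
        if (length(arms) < 2L) return(NA_real_)
        a <- df[[col]][df$arm == arms[1L]]
        b <- df[[col]][df$arm == arms[2L]]
        if (length(a) < 2L || length(b) < 2L) return(NA_real_)
        stats::t.test(a, b)$p.value
      }
      p_b <- welch_p("base_val"); p_e <- welch_p("ev_val")
      for (a in arms) {
        da <- df[df$arm == a, , drop = FALSE]
        sb <- .mean_sd(da$base_val); se <- .mean_sd(da$ev_val)
        k <- k + 1L
        out[[k]] <- data.frame(
          endpoint = endpoint, measure = measure, arm = a,
          n = as.integer(sb[["n"]]),
          baseline_mean = sb[["mean"]], baseline_sd = sb[["sd"]],
          event_mean = se[["mean"]], event_sd = se[["sd"]],
          p_baseline = p_b, p_event = p_e,
          n_unmatched = sum(!ok & baseline$arm[bm] == a),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- if (k) do.call(rbind, out) else
    data.frame(endpoint = character(), measure = character(), arm = character(),
               n = integer(), baseline_mean = numeric(), baseline_sd = numeric(),
               event_mean = numeric(), event_sd = numeric(),
               p_baseline = numeric(), p_event = numeric(),
               n_unmatched = integer(), stringsAsFactors = FALSE)
  class(res) <- c("cid_at_event", "data.frame")
  res
}

#' Subgroup forest table of treatment hazard ratios
#'
#' For each subgroup level, fits a treatment-only Cox model (stratified by
#' study when several are present) restricted to that level and reports the
#' hazard ratio, 95% CI and p-value, with per-arm sizes and event counts.
#' Levels with zero events in an arm are emitted with diagnostics and a
#' `plot_ok = FALSE` marker rather than dropped. Set `adjust = TRUE` for the
#' covariate-adjusted variant.
#'
#' @param cid a [derive_cid()] result.
#' @param baseline PatientBaseline data frame.
#' @param specs subgroup spec list (default [subgroup_specs()]).
#' @param contrast two arm labels, `c(treatment, comparator)`.
#' @param endpoint `"first"` or `"sustained"`.
#' @param adjust adjust for the standard covariate set within each level
#'   (default `FALSE`, i.e. unadjusted-within-level).
#' @return data frame of class `cid_forest`: `subgroup`, `level`, `n_treat`,
#'   `n_comp`, `events_treat`, `events_comp`, `hr`, `lower`, `upper`, `p`,
#'   `plot_ok`, `note`.
#' @export
subgroup_forest <- function(cid, baseline, specs = subgroup_specs(),
                            contrast = c("GLY", "TIO"), endpoint = "first",
                            adjust = FALSE) {
  rows <- list(); k <- 0L
  for (sp in specs) {
    lv <- sp$splitter(baseline)
    if (anyNA(lv)) stop(sprintf("subgroup '%s' is not total on this cohort", sp$name))
    for (level in sp$levels) {
      ids <- baseline$patient_id[lv == level]
      b_sub <- baseline[baseline$patient_id %in% ids, , drop = FALSE]
      c_sub <- cid[cid$patient_id %in% ids, , drop = FALSE]
      rec <- surv_records(c_sub, b_sub, endpoint)
      rec <- rec[rec$group %in% contrast, , drop = FALSE]
      n_t <- sum(rec$group == contrast[1L]); n_c <- sum(rec$group == contrast[2L])
      e_t <- sum(rec$event[rec$group == contrast[1L]])
      e_c <- sum(rec$event[rec$group == contrast[2L]])
      hr <- lower <- upper <- p <- NA_real_; note <- ""; plot_ok <- FALSE
      if (n_t > 0 && n_c > 0 && e_t + e_c > 0) {
        res <- tryCatch(
          fit_treatment_contrasts(c_sub, b_sub, contrast, endpoint,
                                  adjust = adjust),
          error = function(e) e
        )
        if (inherits(res, "error")) {
          note <- conditionMessage(res)
        } else {
          hr <- res$hr; lower <- res$hr_lower; upper <- res$hr_upper
          p <- res$hr_p
          if (e_t == 0 || e_c == 0) {
            note <- "zero events in one arm; excluded from plotting"
          } else if (length(res$cox$diagnostics)) {
            note <- paste(res$cox$diagnostics, collapse = "; ")
            plot_ok <- TRUE
          } else {
            plot_ok <- TRUE
          }
        }
      } else {
        note <- "insufficient subjects or no events in this level"
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        subgroup = sp$name, level = level,
        n_treat = n_t, n_comp = n_c, events_treat = e_t, events_comp = e_c,
        hr = hr, lower = lower, upper = upper, p = p,
        plot_ok = plot_ok, note = note, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "contrast") <- contrast
  attr(res, "endpoint") <- endpoint
  class(res) <- c("cid_forest", "data.frame")
  res
}
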