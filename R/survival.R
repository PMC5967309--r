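# Time-to-event machinery: Kaplan-Meier, log-rank, Cox proportional hazards.
# Estimation is delegated to the survival package; this module defines the
# record schema, result containers and diagnostics the pipeline relies on.

#' Build survival records from derived CID results
#'
#' Joins a `cid_result` table to patient baselines, yielding one analysis
#' record per patient with the endpoint time (days from first dose), event
#' indicator, arm, study stratum and the standard covariate set: sex, age
#' group (<65 / >=65 years), GOLD severity (moderate/severe), current-smoker
#' status, and eosinophil group (<300 / >=300 cells/uL, boundary assigned to
#' the high group).
#'
#' @param cid a [derive_cid()] result.
#' @param baseline PatientBaseline data frame.
#' @param endpoint `"first"` or `"sustained"` composite CID; or a component
#'   endpoint `"fev1_first"`, `"sgrq_first"`, `"exac_first"`,
#'   `"fev1_sustained"`, `"sgrq_sustained"`, `"exac_sustained"`.
#' @return data frame: `patient_id`, `time`, `event`, `group` (arm), `sex`,
#'   `age_group`, `gold_severity`, `smoking`, `eos_group`, `study_id`.
#' @export
surv_records <- function(cid, baseline, endpoint = "first") {
  cols <- switch(endpoint,
    first = c("first_cid_day", "first_cid_event"),
    sustained = c("sustained_cid_day", "sustained_cid_event"),
    fev1_first = c("fev1_first_day", "fev1_first_event"),
    sgrq_first = c("sgrq_first_day", "sgrq_first_event"),
    exac_first = c("exac_first_day", "exac_first_event"),
    fev1_sustained = c("fev1_sustained_day", "fev1_sustained_event"),
    sgrq_sustained = c("sgrq_sustained_day", "sgrq_sustained_event"),
    exac_sustained = c("exac_sustained_day", "exac_sustained_event"),
    stop("unknown endpoint: ", endpoint)
  )
  .assert_cols(cid, c("patient_id", cols), "cid")
  .assert_cols(baseline, c("patient_id", "arm", "study_id"), "baseline")
  m <- match(cid$patient_id, baseline$patient_id)
  if (anyNA(m)) stop("cid results contain patients absent from baseline")
  b <- baseline[m, , drop = FALSE]
  out <- data.frame(
    patient_id = cid$patient_id,
    time = as.numeric(cid[[cols[1L]]]),
    event = as.logical(cid[[cols[2L]]]),
    group = b$arm,
    study_id = b$study_id,
    stringsAsFactors = FALSE
  )
  if (!is.null(b$sex)) out$sex <- b$sex
  if (!is.null(b$age)) out$age_group <- ifelse(b$age < 65, "<65", ">=65")
  if (!is.null(b$gold_severity)) out$gold_severity <- b$gold_severity
  if (!is.null(b$smoking)) out$smoking <- ifelse(b$smoking == "current", "yes", "no")
  if (!is.null(b$eosinophils)) {
    out$eos_group <- ifelse(b$eosinophils >= 300, ">=300", "<300")
  }
  if (any(out$time <= 0)) stop("survival times must be positive")
  out
}

#' Kaplan-Meier estimate of a survival curve
#'
#' Product-limit estimator with the median time to event, its 95% confidence
#' interval (log-log transformed Greenwood) and the 25%/75% quartiles. With
#' an all-censored sample the curve is identically 1 and the median is
#' undefined (`NA`).
#'
#' @param records data frame with `time` (> 0) and `event` (logical) columns.
#' @param conf_level confidence level for the curve/median CI (default 0.95).
#' @return object of class `km_curve`: data frame `curve` (`time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, `lower`, `upper`), `median` with CI,
#'   and quartiles `q25`/`q75`.
#' @export
km_estimate <- function(records, conf_level = 0.95) {
  .assert_cols(records, c("time", "event"), "records")
  if (!nrow(records)) stop("km_estimate needs at least one record")
  if (any(records$time <= 0)) stop("survival times must be positive")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    data = data.frame(time = records$time, event = as.integer(records$event)),
    conf.type = "log-log", conf.int = conf_level
  )
  q <- stats::quantile(fit, probs = c(0.25, 0.5, 0.75))
  qv <- function(slot, p) unname(q[[slot]][paste0(p)])
  structure(list(
    curve = data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, n_censor = fit$n.censor,
                       survival = fit$surv, lower = fit$lower,
                       upper = fit$upper),
    n = fit$n, n_events = sum(fit$n.event),
    median = qv("quantile", 50),
    median_lower = qv("lower", 50), median_upper = qv("upper", 50),
    q25 = qv("quantile", 25), q75 = qv("quantile", 75),
    conf_level = conf_level
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d\n", x$n, x$n_events))
  cat(sprintf("median time %s days (95%% CI %s-%s); quartiles %s / %s\n",
              format(x$median), format(x$median_lower), format(x$median_upper),
              format(x$q25), format(x$q75)))
  invisible(x)
}

#' Plot a Kaplan-Meier curve
#'
#' @param x a `km_curve`.
#' @param ... passed to [plot()].
#' @export
plot.km_curve <- function(x, ...) {
  with(x$curve, {
    plot(stats::stepfun(time, c(1, survival)), do.points = FALSE,
         xlab = "Days from first dose", ylab = "Event-free proportion",
         ylim = c(0, 1), ...)
  })
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank chi-square on 1 degree of freedom:
#' observed-minus-expected events summed over distinct event times, squared,
#' over the summed hypergeometric variance of the risk sets.
#'
#' @param records data frame with `time`, `event` and a two-level `group`
#'   column (override with `group_col`).
#' @param group_col name of the grouping column (default `"group"`).
#' @return object of class `logrank_test`: `statistic`, `df`, `p_value`,
#'   per-group observed/expected counts.
#' @export
logrank_test <- function(records, group_col = "group") {
  .assert_cols(records, c("time", "event", group_col), "records")
  g <- factor(records[[group_col]])
  if (nlevels(g) < 2L) stop("logrank_test needs two non-empty groups")
  if (any(table(g) == 0L)) stop("each group must contain at least one subject")
  sd <- survival::survdiff(
    survival::Surv(time, event) ~ g,
    data = data.frame(time = records$time, event = as.integer(records$event),
                      g = g)
  )
  df <- length(sd$n) - 1L
  structure(list(statistic = unname(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 observed = sd$obs, expected = sd$exp,
                 groups = levels(g), n = as.vector(sd$n)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Maximizes the (optionally study-stratified) partial likelihood with Efron
#' handling of tied event times, and reports per-covariate hazard ratios with
#' Wald 95% confidence intervals and two-sided p-values. Degenerate inputs
#' (zero events in a stratum, apparent complete separation / non-convergence)
#' are surfaced in `diagnostics` rather than silently dropped.
#'
#' @param records survival record data frame ([surv_records()] schema).
#' @param covariates character vector of covariate column names (default
#'   `"group"`).
#' @param strata optional stratum column name (e.g. `"study_id"`).
#' @param conf_level Wald CI level (default 0.95).
#' @return object of class `cox_fit`: data frame `table` (`term`, `coef`,
#'   `se`, `hr`, `lower`, `upper`, `p`), `loglik`, `n`, `n_events`,
#'   `diagnostics` (character vector, possibly empty).
#' @export
cox_fit <- function(records, covariates = "group", strata = NULL,
                    conf_level = 0.95) {
  .assert_cols(records, c("time", "event", covariates), "records")
  if (!is.null(strata)) .assert_cols(records, strata, "records")
  dat <- records
  diag <- character()
  # drop covariates without variation (cannot enter the model matrix)
  keep <- vapply(covariates, function(cv) {
    length(unique(dat[[cv]][!is.na(dat[[cv]])])) >= 2L
  }, TRUE)
  if (any(!keep)) {
    diag <- c(diag, sprintf("covariate '%s' dropped: fewer than 2 observed levels",
                            covariates[!keep]))
  }
  covariates <- covariates[keep]
  if (!length(covariates)) stop("no usable covariates: all are constant")
  if (!any(dat$event)) stop("cox_fit needs at least one event")
  if (!is.null(strata)) {
    ev_by <- tapply(as.integer(dat$event), dat[[strata]], sum)
    zero <- names(ev_by)[ev_by == 0]
    if (length(zero)) {
      diag <- c(diag, sprintf("stratum '%s' has zero events and contributes no information",
                              zero))
    }
  }
  rhs <- paste(covariates, collapse = " + ")
  if (!is.null(strata)) rhs <- paste0(rhs, " + strata(", strata, ")")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      diag <<- c(diag, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  s <- summary(fit, conf.int = conf_level)
  co <- s$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(
    term = rownames(co),
    coef = unname(co[, "coef"]),
    se = unname(co[, "se(coef)"]),
    hr = unname(exp(co[, "coef"])),
    lower = unname(exp(co[, "coef"] - z * co[, "se(coef)"])),
    upper = unname(exp(co[, "coef"] + z * co[, "se(coef)"])),
    p = unname(co[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE
  )
  big <- abs(tab$coef) > 10 | tab$se > 100
  if (any(big)) {
    diag <- c(diag, sprintf("term '%s' shows extreme estimates (possible complete separation)",
                            tab$term[big]))
  }
  structure(list(table = tab, loglik = unname(fit$loglik[length(fit$loglik)]),
                 n = fit$n, n_events = fit$nevent,
                 conf_level = conf_level, diagnostics = diag),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional-hazards fit: n = %d, events = %d\n",
              x$n, x$n_events))
  tb <- x$table
  tb$hr <- round(tb$hr, digits); tb$lower <- round(tb$lower, digits)
  tb$upper <- round(tb$upper, digits); tb$p <- signif(tb$p, digits)
  print(tb[, c("term", "hr", "lower", "upper", "p")], row.names = FALSE)
  if (length(x$diagnostics)) {
    cat("diagnostics:\n"); cat(paste0("  - ", x$diagnostics, "\n"), sep = "")
  }
  invisible(x)
}

#' Headline treatment contrasts on a derived cohort
#'
#' Produces the treatment comparison of the pooled analysis on any cohort:
#' a Cox model for the chosen contrast (stratified by study by default, with
#' the standard covariate adjustment set of sex, age group, GOLD severity,
#' smoking and eosinophil group), per-arm Kaplan-Meier curves, and the
#' two-group log-rank test.
#'
#' @param cid a [derive_cid()] result.
#' @param baseline PatientBaseline data frame.
#' @param contrast character vector of two arm labels, `c(treatment,
#'   comparator)`; the hazard ratio is treatment vs comparator.
#' @param endpoint endpoint name as in [surv_records()].
#' @param adjust add the standard covariate set to the Cox model (default
#'   `TRUE`; `FALSE` fits treatment only).
#' @param strata_by_study stratify the Cox baseline hazard by `study_id`
#'   (default `TRUE`).
#' @return object of class `cid_contrast`: `cox` ([cox_fit()]), `km` (named
#'   list of [km_estimate()] per arm), `logrank`, `hr`/`hr_lower`/`hr_upper`/
#'   `hr_p` for the treatment term, and the endpoint/contrast labels.
#' @export
fit_treatment_contrasts <- function(cid, baseline, contrast = c("GLY", "TIO"),
                                    endpoint = "first", adjust = TRUE,
                                    strata_by_study = TRUE) {
  if (length(contrast) != 2L) stop("'contrast' must name exactly two arms")
  known <- unique(baseline$arm)
  bad <- setdiff(contrast, known)
  if (length(bad)) {
    stop("unknown arm label(s): ", paste(bad, collapse = ", "),
         " (cohort arms: ", paste(known, collapse = ", "), ")")
  }
  rec <- surv_records(cid, baseline, endpoint)
  rec <- rec[rec$group %in% contrast, , drop = FALSE]
  rec$treatment <- factor(rec$group, levels = c(contrast[2L], contrast[1L]))
  covs <- "treatment"
  if (adjust) {
    covs <- c(covs, intersect(c("sex", "age_group", "gold_severity",
                                "smoking", "eos_group"), names(rec)))
  }
  strata <- if (strata_by_study && length(unique(rec$study_id)) > 1L)
    "study_id" else NULL
  cox <- cox_fit(rec, covariates = covs, strata = strata)
  trt_row <- grep("^treatment", cox$table$term)[1L]
  km <- lapply(stats::setNames(contrast, contrast), function(a) {
    km_estimate(rec[rec$group == a, , drop = FALSE])
  })
  lr <- logrank_test(rec)
  structure(list(cox = cox, km = km, logrank = lr,
                 hr = cox$table$hr[trt_row],
                 hr_lower = cox$table$lower[trt_row],
                 hr_upper = cox$table$upper[trt_row],
                 hr_p = cox$table$p[trt_row],
                 endpoint = endpoint, contrast = contrast),
            class = "cid_contrast")
}

#' @export
print.cid_contrast <- function(x, ...) {
  cat(sprintf("%s CID, %s vs %s: HR %.3f (95%% CI %.3f-%.3f), Cox p = %.4g; log-rank p = %.4g\n",
              x$endpoint, x$contrast[1L], x$contrast[2L], x$hr, x$hr_lower,
              x$hr_upper, x$hr_p, x$logrank$p_value))
  invisible(x)
}
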