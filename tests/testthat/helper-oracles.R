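# Independent oracles and fixture builders shared across the test files.
# Oracles are deliberately written as literal, loop-based transcriptions of
# the definitions, independent of the package's vectorized implementations.

# Literal evaluation of the sustained-deterioration rule for one component:
# earliest flagged visit v that is also flagged at the next `min_consec - 1`
# visits exactly `interval` weeks apart on the nominal schedule, OR flagged
# at >= `frac` of all available subsequent visits (v included; visits with a
# missing measurement are not available). Returns the week, or NA.
oracle_sustained <- function(weeks, flags, interval = 4L, min_consec = 2L,
                             frac = 0.5) {
  for (i in seq_along(weeks)) {
    if (!isTRUE(flags[i])) next
    run_ok <- TRUE
    for (off in seq_len(min_consec - 1L)) {
      j <- which(weeks == weeks[i] + off * interval)
      if (length(j) != 1L || !isTRUE(flags[j])) { run_ok <- FALSE; break }
    }
    if (run_ok) return(weeks[i])
    avail <- which(weeks >= weeks[i] & !is.na(flags))
    if (length(avail) && sum(flags[avail] == TRUE) / length(avail) >= frac) {
      return(weeks[i])
    }
  }
  NA_integer_
}

# Hand product-limit arithmetic: survival after each distinct event time.
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ts <- sort(unique(time[event]))
  surv <- numeric(length(ts)); s <- 1
  for (k in seq_along(ts)) {
    n_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  data.frame(time = ts, survival = surv)
}

# Log-rank arithmetic from first principles: sum over distinct event times of
# (O1 - E1) and the hypergeometric variance.
oracle_logrank <- function(time, event, group) {
  g1 <- group == unique(group)[1L]
  ts <- sort(unique(time[event]))
  oe <- 0; v <- 0
  for (tk in ts) {
    n <- sum(time >= tk); n1 <- sum(time >= tk & g1)
    d <- sum(time == tk & event); d1 <- sum(time == tk & event & g1)
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- oe^2 / v
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

# No-ties Cox partial log-likelihood for a single numeric covariate.
oracle_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Flag-table fixture for one patient: weeks plus logical component flags
# (NA = missing measurement).
make_flags <- function(weeks, fev1 = rep(FALSE, length(weeks)),
                       sgrq = rep(FALSE, length(weeks)),
                       patient_id = "P1") {
  data.frame(patient_id = patient_id, visit_week = as.integer(weeks),
             visit_day = 7L * as.integer(weeks),
             fev1_flag = fev1, sgrq_flag = sgrq, stringsAsFactors = FALSE)
}

make_followup <- function(last_contact_day, study_end_day,
                          patient_id = "P1") {
  data.frame(patient_id = patient_id,
             last_contact_day = as.integer(last_contact_day),
             discontinued_early = last_contact_day < study_end_day,
             study_end_day = as.integer(study_end_day),
             stringsAsFactors = FALSE)
}

no_exac <- data.frame(patient_id = character(), onset_day = integer(),
                      severity = character(), stringsAsFactors = FALSE)

exac_at <- function(days, patient_id = "P1") {
  data.frame(patient_id = patient_id, onset_day = as.integer(days),
             severity = "moderate", stringsAsFactors = FALSE)
}

# Small deterministic pooled cohort for end-to-end checks.
small_cohort <- function(seed = 11, n = c("STUDY-A" = 120, "STUDY-B" = 120,
                                          "STUDY-C" = 80, "STUDY-D" = 80),
                         params = sim_params(seed = seed),
                         include_placebo = FALSE) {
  params$seed <- as.integer(seed)
  simulate_cohort(default_designs(include_placebo), params, n)
}
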