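# Synthetic pooled-trial cohort generator.

# Arm-specific lookup with a 0 default for arms absent from an effect vector.
.arm_value <- function(vec, arm, default = 0) {
  if (!is.null(names(vec)) && arm %in% names(vec)) unname(vec[[arm]]) else default
}

# Lognormal parameters matched to a target mean/SD on the natural scale.
.lnorm_pars <- function(m, s) {
  if (s <= 0) return(list(meanlog = log(m), sdlog = 0))
  v <- s^2
  list(meanlog = log(m^2 / sqrt(m^2 + v)), sdlog = sqrt(log(1 + v / m^2)))
}

#' Simulate a pooled multi-study COPD cohort
#'
#' Generates the four tables the CID pipeline consumes: patient baselines,
#' scheduled visit observations (pre-dose FEV1 and SGRQ), adjudicated
#' moderate-to-severe exacerbation episodes, and follow-up records. Day 1 is
#' the day of first dose; visit day = 7 x visit week. Every scheduled visit
#' up to a patient's last contact day gets a row (measurements may be missing
#' under the configured missingness probability); no observations exist after
#' last contact. Dropout times are drawn from the annual hazard and rounded
#' up to the next scheduled visit. The generator is deterministic for a fixed
#' seed, with per-patient substreams so the cohort does not depend on loop
#' order.
#'
#' @param designs list of [study_design()] objects.
#' @param params a [sim_params()] object.
#' @param n_per_study named integer vector/list: patients per `study_id`.
#' @return a `cid_cohort`: list with data frames `baseline`, `visits`,
#'   `exacerbations`, `followup`.
#' @examples
#' coh <- simulate_cohort(default_designs()[1], sim_params(seed = 7),
#'                        c("STUDY-A" = 50))
#' head(coh$baseline)
#' @export
simulate_cohort <- function(designs, params, n_per_study) {
  if (inherits(designs, "study_design")) designs <- list(designs)
  if (!length(designs) || !all(vapply(designs, inherits, TRUE, "study_design"))) {
    stop("'designs' must be a list of study_design objects")
  }
  if (!inherits(params, "sim_params")) stop("'params' must be a sim_params object")
  n_per_study <- unlist(n_per_study)
  ids <- vapply(designs, `[[`, "", "study_id")
  miss_n <- setdiff(ids, names(n_per_study))
  if (length(miss_n)) {
    stop("n_per_study is missing studies: ", paste(miss_n, collapse = ", "))
  }
  if (any(n_per_study[ids] < 1)) stop("'n_per_study' must be >= 1 for every design")

  lp <- .lnorm_pars(params$fev1_mean, params$fev1_sd)
  eos_shape <- if (params$eos_sd > 0) (params$eos_mean / params$eos_sd)^2 else NA
  eos_scale <- if (params$eos_sd > 0) params$eos_sd^2 / params$eos_mean else NA

  base_l <- list(); vis_l <- list(); exa_l <- list(); fup_l <- list()
  idx <- 0L
  for (d in designs) {
    n <- as.integer(n_per_study[[d$study_id]])
    weeks <- seq(d$visit_interval_weeks, d$duration_weeks,
                 by = d$visit_interval_weeks)
    days <- 7L * weeks
    end_day <- 7L * d$duration_weeks
    for (i in seq_len(n)) {
      idx <- idx + 1L
      set.seed(.patient_seed(params$seed, idx))
      pid <- sprintf("%s-%05d", d$study_id, i)

      arm <- sample(names(d$arms), 1L, prob = d$arms)
      sex <- if (stats::runif(1) < params$pct_male / 100) "male" else "female"
      age <- round(pmax(40, stats::rnorm(1, params$age_mean, params$age_sd)), 1)
      smoking <- if (stats::runif(1) < params$pct_current_smoker / 100)
        "current" else "ex"
      gold <- if (stats::runif(1) < params$pct_gold_severe / 100)
        "severe" else "moderate"
      fev1_b <- round(stats::rlnorm(1, lp$meanlog, lp$sdlog), 3)
      pct_pred <- round(pmin(90, pmax(25, stats::rnorm(1, 48, 13.44))), 1)
      sgrq_b <- round(pmin(100, pmax(0, stats::rnorm(1, params$sgrq_mean,
                                                     params$sgrq_sd))), 2)
      bdi <- as.integer(pmin(12, pmax(0, round(stats::rnorm(1, params$bdi_mean,
                                                            params$bdi_sd)))))
      eos <- if (is.na(eos_shape)) params$eos_mean else
        round(stats::rgamma(1, shape = eos_shape, scale = eos_scale))
      ics <- stats::runif(1) < params$pct_ics / 100
      prior_ex <- stats::runif(1) < params$pct_prior_exac / 100

      # dropout: exponential in years, rounded up to the next scheduled visit
      if (params$dropout_hazard > 0) {
        t_drop <- ceiling(stats::rexp(1, params$dropout_hazard) * 365.25)
      } else {
        t_drop <- Inf
      }
      if (t_drop > end_day) {
        last_day <- end_day; disc <- FALSE
      } else {
        nxt <- which(days >= t_drop)
        # dropout after the last scheduled visit rounds up to study end
        last_day <- if (length(nxt)) days[nxt[1L]] else end_day
        disc <- last_day < end_day
      }

      keep <- days <= last_day
      kw <- weeks[keep]; kd <- days[keep]; nv <- length(kw)
      if (nv) {
        z1 <- stats::rnorm(nv); z2 <- stats::rnorm(nv)
        e1 <- numeric(nv); e2 <- numeric(nv)
        rho <- params$noise_ar1
        e1[1] <- params$fev1_noise_sd * z1[1]
        e2[1] <- params$sgrq_noise_sd * z2[1]
        if (nv > 1) for (k in 2:nv) {
          e1[k] <- rho * e1[k - 1] + sqrt(1 - rho^2) * params$fev1_noise_sd * z1[k]
          e2[k] <- rho * e2[k - 1] + sqrt(1 - rho^2) * params$sgrq_noise_sd * z2[k]
        }
        t_yr <- kd / 365.25
        fev1_v <- round(pmax(0.05, fev1_b + .arm_value(params$fev1_effect, arm) +
                               params$fev1_slope * t_yr + e1), 3)
        sgrq_v <- round(pmin(100, pmax(0, sgrq_b +
                               .arm_value(params$sgrq_effect, arm) + e2)), 2)
        if (params$miss_prob > 0) {
          fev1_v[stats::runif(nv) < params$miss_prob] <- NA_real_
          sgrq_v[stats::runif(nv) < params$miss_prob] <- NA_real_
        }
        vis_l[[idx]] <- list(patient_id = rep(pid, nv), visit_week = kw,
                             visit_day = kd, fev1 = fev1_v, sgrq = sgrq_v)
      }

      # gamma-frailty-mixed Poisson exacerbation process over exposure
      rate <- .arm_value(params$exac_rate, arm)
      frail <- if (params$exac_dispersion > 0) {
        stats::rgamma(1, shape = 1 / params$exac_dispersion,
                      rate = 1 / params$exac_dispersion)
      } else 1
      mu <- rate * frail * last_day / 365.25
      nev <- if (mu > 0) stats::rpois(1, mu) else 0L
      if (nev > 0) {
        onset <- sort(pmax(1L, ceiling(stats::runif(nev) * last_day)))
        sev <- ifelse(stats::runif(nev) < params$p_severe, "severe", "moderate")
        exa_l[[idx]] <- list(patient_id = rep(pid, nev),
                             onset_day = as.integer(onset), severity = sev)
      }

      base_l[[idx]] <- list(patient_id = pid, study_id = d$study_id, arm = arm,
                            sex = sex, age = age, smoking = smoking,
                            gold_severity = gold, fev1_baseline = fev1_b,
                            fev1_pct_pred = pct_pred, sgrq_baseline = sgrq_b,
                            bdi = bdi, eosinophils = eos, ics_use = ics,
                            prior_exacerbation = prior_ex)
      fup_l[[idx]] <- list(patient_id = pid,
                           last_contact_day = as.integer(last_day),
                           discontinued_early = disc,
                           study_end_day = as.integer(end_day))
    }
  }

  bind <- function(lst) {
    lst <- Filter(Negate(is.null), lst)
    if (!length(lst)) return(NULL)
    cols <- names(lst[[1L]])
    out <- lapply(cols, function(cn) unlist(lapply(lst, `[[`, cn),
                                            use.names = FALSE))
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  baseline <- bind(base_l)
  visits <- bind(vis_l)
  exac <- bind(exa_l)
  if (is.null(exac)) {
    exac <- data.frame(patient_id = character(), onset_day = integer(),
                       severity = character(), stringsAsFactors = FALSE)
  }
  if (is.null(visits)) {
    visits <- data.frame(patient_id = character(), visit_week = integer(),
                         visit_day = integer(), fev1 = numeric(),
                         sgrq = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(baseline = baseline, visits = visits,
                 exacerbations = exac, followup = bind(fup_l)),
            class = "cid_cohort")
}

#' @export
print.cid_cohort <- function(x, ...) {
  cat(sprintf("cid_cohort: %d patients, %d studies, %d visit rows, %d exacerbations\n",
              nrow(x$baseline), length(unique(x$baseline$study_id)),
              nrow(x$visits), nrow(x$exacerbations)))
  tab <- table(x$baseline$arm)
  cat("arms:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
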