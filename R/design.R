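# Study designs and simulation parameters for the synthetic pooled cohort.

#' Define a study design
#'
#' A study contributes a visit grid (every `visit_interval_weeks` up to
#' `duration_weeks`) and an arm allocation. Pooled LAMA programmes mix 12-,
#' 26- and 52-week studies with 4-weekly spirometry/health-status capture.
#'
#' @param study_id study label.
#' @param duration_weeks total follow-up in weeks (at least one visit
#'   interval). Scheduled visits fall at every multiple of
#'   `visit_interval_weeks` up to `duration_weeks`; for durations that are
#'   not an exact multiple (a 26-week study on a 4-week grid) the study end
#'   lies after the last scheduled visit and completers are censored at the
#'   end-of-study day, not the last visit day.
#' @param arms named numeric vector of allocation fractions (must sum to 1),
#'   e.g. `c(GLY = 0.6, TIO = 0.4)`.
#' @param visit_interval_weeks weeks between scheduled post-baseline visits
#'   (default 4).
#' @return an object of class `study_design`.
#' @examples
#' study_design("STUDY-12WK", 12, c(GLY = 0.5, TIO = 0.5))
#' @export
study_design <- function(study_id, duration_weeks,
                         arms = c(GLY = 0.633, TIO = 0.367),
                         visit_interval_weeks = 4L) {
  if (!is.character(study_id) || length(study_id) != 1L || !nzchar(study_id)) {
    stop("'study_id' must be a non-empty string")
  }
  .assert_scalar_num(duration_weeks, "duration_weeks", lower = 1)
  .assert_scalar_num(visit_interval_weeks, "visit_interval_weeks", lower = 1)
  if (duration_weeks < visit_interval_weeks) {
    stop("'duration_weeks' must cover at least one visit interval")
  }
  if (is.null(names(arms)) || any(!nzchar(names(arms)))) {
    stop("'arms' must be a named vector of allocation fractions")
  }
  if (any(arms < 0) || abs(sum(arms) - 1) > 1e-8) {
    stop("'arms' allocation fractions must be non-negative and sum to 1")
  }
  structure(
    list(study_id = study_id,
         duration_weeks = as.integer(duration_weeks),
         visit_interval_weeks = as.integer(visit_interval_weeks),
         arms = arms),
    class = "study_design"
  )
}

#' Default pooled-programme study designs
#'
#' Four studies emulating a pooled moderate-to-severe COPD programme: one
#' 12-week, two 26-week and one 52-week study, all on a 4-weekly visit grid.
#' Arm allocation defaults to an active LAMA (`GLY`) vs an active comparator
#' (`TIO`) at roughly the pooled 63:37 split; `include_placebo = TRUE` adds a
#' placebo arm for superiority contrasts.
#'
#' @param include_placebo add a `PBO` arm to every study (default `FALSE`).
#' @return list of [study_design()] objects.
#' @export
default_designs <- function(include_placebo = FALSE) {
  arms <- if (include_placebo) {
    c(GLY = 0.503, TIO = 0.291, PBO = 0.206)
  } else {
    c(GLY = 0.633, TIO = 0.367)
  }
  list(
    study_design("STUDY-A", 26L, arms),
    study_design("STUDY-B", 52L, arms),
    study_design("STUDY-C", 12L, arms),
    study_design("STUDY-D", 26L, arms)
  )
}

#' Simulation parameters for the synthetic cohort generator
#'
#' Bundles the stochastic model that the generator draws from. Baseline
#' moment targets default to the pooled-programme population: pre-dose FEV1
#' mean 1.3 L (SD 0.47), SGRQ total 48.0 (SD 17.66), 74% male, 41% current
#' smokers, 25% with a prior-year exacerbation, 38% severe (GOLD 3) airflow
#' limitation, 55% on ICS, eosinophils gamma with mean 270 SD 184 cells/uL,
#' BDI mean 6.2 (SD 2.17), age mean 63.9 (SD 8.9).
#'
#' Trajectory model per patient: visit FEV1 = baseline + arm effect +
#' slope * t(years) + AR(1) noise; SGRQ analogous, clipped to [0, 100].
#' Exacerbations follow a gamma-frailty-mixed Poisson process; dropout is an
#' exponential hazard rounded up to the next scheduled visit.
#'
#' @param fev1_effect named vector, additive post-baseline FEV1 arm effect (L).
#' @param sgrq_effect named vector, additive SGRQ arm effect (units; negative
#'   improves health status).
#' @param fev1_slope FEV1 decline slope in L/year (negative = decline).
#' @param fev1_noise_sd within-patient FEV1 visit noise SD (L).
#' @param sgrq_noise_sd within-patient SGRQ visit noise SD (units).
#' @param noise_ar1 AR(1) autocorrelation of visit noise, in [0, 1).
#' @param exac_rate named vector, annual moderate-to-severe exacerbation rate
#'   per arm (events/patient-year).
#' @param exac_dispersion gamma frailty variance (0 = plain Poisson).
#' @param p_severe probability an exacerbation is severe (vs moderate).
#' @param dropout_hazard annual early-discontinuation hazard (1/year).
#' @param miss_prob per-visit, per-measure missingness probability.
#' @param fev1_mean,fev1_sd,sgrq_mean,sgrq_sd,pct_male,pct_current_smoker,
#'   pct_prior_exac,pct_gold_severe,pct_ics,eos_mean,eos_sd,age_mean,age_sd,
#'   bdi_mean,bdi_sd baseline moment targets.
#' @param seed integer RNG seed governing every stream.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(fev1_effect = c(GLY = 0.06, TIO = 0.06, PBO = 0),
                       sgrq_effect = c(GLY = -3, TIO = -3, PBO = 0),
                       fev1_slope = -0.03,
                       fev1_noise_sd = 0.11,
                       sgrq_noise_sd = 4.5,
                       noise_ar1 = 0.4,
                       exac_rate = c(GLY = 0.45, TIO = 0.45, PBO = 0.75),
                       exac_dispersion = 0.5,
                       p_severe = 0.2,
                       dropout_hazard = 0.25,
                       miss_prob = 0,
                       fev1_mean = 1.3, fev1_sd = 0.47,
                       sgrq_mean = 48.0, sgrq_sd = 17.66,
                       pct_male = 74, pct_current_smoker = 41,
                       pct_prior_exac = 25, pct_gold_severe = 38,
                       pct_ics = 55,
                       eos_mean = 270, eos_sd = 184,
                       age_mean = 63.9, age_sd = 8.9,
                       bdi_mean = 6.2, bdi_sd = 2.17,
                       seed = 1L) {
  for (nm in c("fev1_noise_sd", "sgrq_noise_sd", "fev1_sd", "sgrq_sd",
               "eos_sd", "age_sd", "bdi_sd", "exac_dispersion",
               "dropout_hazard", "miss_prob")) {
    .assert_scalar_num(get(nm), nm, lower = 0)
  }
  if (any(exac_rate < 0)) stop("'exac_rate' must be >= 0 for every arm")
  for (nm in c("pct_male", "pct_current_smoker", "pct_prior_exac",
               "pct_gold_severe", "pct_ics")) {
    .assert_scalar_num(get(nm), nm, lower = 0, upper = 100)
  }
  .assert_scalar_num(noise_ar1, "noise_ar1", lower = 0, upper = 1 - 1e-9)
  .assert_scalar_num(p_severe, "p_severe", lower = 0, upper = 1)
  .assert_scalar_num(miss_prob, "miss_prob", lower = 0, upper = 1)
  .assert_scalar_num(fev1_mean, "fev1_mean", lower = 1e-6)
  .assert_scalar_num(sgrq_mean, "sgrq_mean", lower = 0, upper = 100)
  .assert_scalar_num(seed, "seed")
  structure(
    list(fev1_effect = fev1_effect, sgrq_effect = sgrq_effect,
         fev1_slope = fev1_slope, fev1_noise_sd = fev1_noise_sd,
         sgrq_noise_sd = sgrq_noise_sd, noise_ar1 = noise_ar1,
         exac_rate = exac_rate, exac_dispersion = exac_dispersion,
         p_severe = p_severe, dropout_hazard = dropout_hazard,
         miss_prob = miss_prob,
         fev1_mean = fev1_mean, fev1_sd = fev1_sd,
         sgrq_mean = sgrq_mean, sgrq_sd = sgrq_sd,
         pct_male = pct_male, pct_current_smoker = pct_current_smoker,
         pct_prior_exac = pct_prior_exac, pct_gold_severe = pct_gold_severe,
         pct_ics = pct_ics, eos_mean = eos_mean, eos_sd = eos_sd,
         age_mean = age_mean, age_sd = age_sd,
         bdi_mean = bdi_mean, bdi_sd = bdi_sd,
         seed = as.integer(seed)),
    class = "sim_params"
  )
}
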