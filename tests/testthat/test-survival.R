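# Survival machinery: Kaplan-Meier, log-rank, Cox proportional hazards.

test_that("KM with all events and no censoring steps down by 1/n", {
  rec <- data.frame(time = 1:5, event = TRUE)
  km <- km_estimate(rec)
  expect_equal(km$curve$survival, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$median, 3)
})

test_that("KM on a single censored record is identically 1 with undefined median", {
  km <- km_estimate(data.frame(time = 10, event = FALSE))
  expect_true(all(km$curve$survival == 1))
  expect_true(is.na(km$median))
  expect_error(km_estimate(data.frame(time = numeric(), event = logical())),
               "at least one")
})

test_that("KM equals hand-computed product-limit arithmetic on a mixed fixture", {
  set.seed(40)
  time <- c(2, 3, 3, 5, 6, 6, 7, 8, 10, 10, 11, 12, 13, 13, 14, 16, 18, 20, 22, 25)
  event <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE,
             TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE)
  km <- km_estimate(data.frame(time = time, event = event))
  hand <- oracle_km(time, event)
  got <- km$curve[km$curve$n_event > 0, c("time", "survival")]
  expect_equal(got$time, hand$time)
  expect_equal(got$survival, hand$survival, tolerance = 1e-12)
  # KM with no censoring equals the empirical survival function
  km2 <- km_estimate(data.frame(time = time, event = TRUE))
  emp <- vapply(km2$curve$time, function(t) mean(time > t), 0)
  expect_equal(km2$curve$survival, emp, tolerance = 1e-12)
})

test_that("log-rank statistic is zero for identical groups and matches hand arithmetic", {
  rec <- data.frame(time = rep(c(3, 5, 8, 12), 2),
                    event = rep(c(TRUE, TRUE, FALSE, TRUE), 2),
                    group = rep(c("A", "B"), each = 4))
  lr <- logrank_test(rec)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)
  # tiny 6-record fixture vs first-principles risk-set arithmetic
  rec2 <- data.frame(time = c(1, 4, 6, 2, 5, 9),
                     event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
                     group = rep(c("A", "B"), each = 3))
  lr2 <- logrank_test(rec2)
  hand <- oracle_logrank(rec2$time, rec2$event, rec2$group)
  expect_equal(lr2$statistic, hand$statistic, tolerance = 1e-9)
  expect_equal(lr2$p_value, hand$p_value, tolerance = 1e-9)
  # invariant to swapping the group labels
  rec3 <- rec2; rec3$group <- ifelse(rec2$group == "A", "B", "A")
  expect_equal(logrank_test(rec3)$statistic, lr2$statistic, tolerance = 1e-12)
  expect_error(logrank_test(rec2[rec2$group == "A", ]), "two non-empty groups")
})

test_that("log-rank holds its nominal type-I error under the null", {
  set.seed(1234)
  n_rep <- 800
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    time <- rexp(100, 0.1)
    cens <- rexp(100, 0.03)
    rec <- data.frame(time = pmin(time, cens), event = time <= cens,
                      group = rep(c("A", "B"), each = 50))
    rej[r] <- logrank_test(rec)$p_value < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("Cox coefficient matches direct maximization of the partial likelihood", {
  set.seed(7)
  n <- 60
  x <- rep(0:1, each = n / 2)
  time <- rexp(n, 0.1 * exp(0.7 * x))
  cens <- rexp(n, 0.02)
  rec <- data.frame(time = round(pmin(time, cens), 6) + seq_len(n) * 1e-9,
                    event = time <= cens, x = x)
  fit <- cox_fit(rec, covariates = "x")
  opt <- optimize(function(b) -oracle_partial_loglik(b, rec$time, rec$event,
                                                     rec$x),
                  c(-5, 5), tol = 1e-10)
  expect_equal(fit$table$coef[1], opt$minimum, tolerance = 1e-5)
  expect_equal(fit$loglik, -opt$objective, tolerance = 1e-8)
})

test_that("Cox recovers a planted hazard ratio and brackets it with the Wald CI", {
  set.seed(99)
  n <- 2000
  x <- rep(0:1, each = n / 2)
  time <- rexp(n, 0.05 * exp(log(0.5) * x))
  rec <- data.frame(time = time, event = TRUE, x = factor(x))
  fit <- cox_fit(rec, covariates = "x")
  expect_lt(abs(fit$table$hr[1] - 0.5), 0.06)
  expect_true(fit$table$lower[1] < 0.5 && fit$table$upper[1] > 0.5)
  # permuted covariate: the CI covers 1
  rec$x <- sample(rec$x)
  fit0 <- cox_fit(rec, covariates = "x")
  expect_true(fit0$table$lower[1] < 1 && fit0$table$upper[1] > 1)
})

test_that("stratified fit with a single stratum equals the unstratified fit", {
  set.seed(15)
  rec <- data.frame(time = rexp(80, 0.1), event = runif(80) < 0.8,
                    group = rep(c("A", "B"), 40), study_id = "S1")
  f1 <- cox_fit(rec, "group")
  f2 <- cox_fit(rec, "group", strata = "study_id")
  expect_equal(f1$table$coef, f2$table$coef, tolerance = 1e-10)
  expect_equal(f1$table$se, f2$table$se, tolerance = 1e-10)
})

test_that("degenerate Cox inputs are surfaced, not silent", {
  rec <- data.frame(time = c(1, 2, 3, 4), event = FALSE,
                    group = c("A", "A", "B", "B"))
  expect_error(cox_fit(rec, "group"), "at least one event")
  rec2 <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                     group = rep(c("A", "B"), each = 3))
  fit <- cox_fit(rec2, "group")
  expect_true(length(fit$diagnostics) > 0)
  expect_error(cox_fit(rec2, covariates = "event_const_cov"), "missing required column")
})

test_that("treatment contrasts behave under null and planted-benefit generators", {
  # identical arm effects: |log HR| small, no significant difference
  coh <- small_cohort(seed = 202, n = c("STUDY-A" = 300, "STUDY-B" = 300,
                                        "STUDY-C" = 200, "STUDY-D" = 200))
  cid <- derive_cid(coh)
  ct <- fit_treatment_contrasts(cid, coh$baseline, c("GLY", "TIO"))
  expect_lt(abs(log(ct$hr)), 0.35)
  expect_gt(ct$hr_p, 0.05)
  # strong active-arm benefit vs placebo: HR < 1, p < 0.05
  p <- sim_params(seed = 203)
  cohp <- simulate_cohort(default_designs(TRUE), p,
                          c("STUDY-A" = 500, "STUDY-B" = 500,
                            "STUDY-C" = 350, "STUDY-D" = 350))
  cidp <- derive_cid(cohp)
  cp <- fit_treatment_contrasts(cidp, cohp$baseline, c("GLY", "PBO"))
  expect_lt(cp$hr, 1)
  expect_lt(cp$hr_p, 0.05)
  expect_lt(cp$logrank$p_value, 0.05)
  expect_error(fit_treatment_contrasts(cid, coh$baseline, c("GLY", "NOPE")),
               "NOPE")
})
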