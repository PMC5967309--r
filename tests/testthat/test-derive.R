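# CID endpoint derivation: component flagging, first-CID timing,
# the sustained rule engine, censoring, and the cohort driver.

test_that("component flags use inclusive boundaries and respect missingness", {
  baseline <- data.frame(patient_id = "P1", fev1_baseline = 1.47,
                         sgrq_baseline = 43.42, stringsAsFactors = FALSE)
  visits <- data.frame(patient_id = "P1", visit_week = c(4L, 8L, 12L, 16L),
                       visit_day = c(28L, 56L, 84L, 112L),
                       fev1 = c(1.29, 1.371, 1.37, NA),
                       sgrq = c(47.42, 47.41, NA, 50),
                       stringsAsFactors = FALSE)
  fl <- flag_components(baseline, visits)
  # 0.18 L drop flags; 0.099 L (1 mL above the boundary) does not;
  # exactly 0.100 L flags
  expect_identical(fl$fev1_flag, c(TRUE, FALSE, TRUE, NA))
  # rise of exactly 4 units flags; 3.99 does not; missing stays NA
  expect_identical(fl$sgrq_flag, c(TRUE, FALSE, NA, TRUE))
})

test_that("a missing baseline excludes the patient from that component with a warning", {
  baseline <- data.frame(patient_id = "P1", fev1_baseline = NA_real_,
                         sgrq_baseline = 40, stringsAsFactors = FALSE)
  visits <- data.frame(patient_id = "P1", visit_week = 4L, visit_day = 28L,
                       fev1 = 1.0, sgrq = 50, stringsAsFactors = FALSE)
  expect_warning(fl <- flag_components(baseline, visits), "P1")
  expect_true(is.na(fl$fev1_flag))
  expect_true(fl$sgrq_flag)
})

test_that("first CID takes the earliest component, keeping ties", {
  fu <- make_followup(182, 182)
  # exacerbation at day 30 beats FEV1 flag at week 12 (day 84)
  fl <- make_flags(c(4, 8, 12), fev1 = c(FALSE, FALSE, TRUE))
  r <- first_cid(fl, exac_at(30), fu)
  expect_identical(r$first_cid_day, 30L)
  expect_true(r$first_cid_event)
  expect_identical(r$first_cid_components, "EXACERBATION")
  # FEV1 and SGRQ both first flagged at week 8 -> tie kept
  fl2 <- make_flags(c(4, 8, 12), fev1 = c(FALSE, TRUE, TRUE),
                    sgrq = c(FALSE, TRUE, FALSE))
  r2 <- first_cid(fl2, no_exac, fu)
  expect_identical(r2$first_cid_day, 56L)
  expect_identical(r2$first_cid_components, "FEV1+SGRQ")
  # nothing triggers in a completed 26-week study -> censored at day 182
  r3 <- first_cid(make_flags(c(4, 8, 12)), no_exac, fu)
  expect_false(r3$first_cid_event)
  expect_identical(r3$first_cid_day, 182L)
  expect_identical(r3$first_cid_components, "")
})

test_that("sustained rule: consecutive pair, >=50% branch, exacerbation identity", {
  fu <- make_followup(182, 182)
  # (false, true, true) over weeks 4/8/12 -> sustained at week 8 by the
  # consecutive-pair branch
  r <- sustained_cid(make_flags(c(4, 8, 12), fev1 = c(FALSE, TRUE, TRUE)),
                     no_exac, fu)
  expect_true(r$sustained_cid_event)
  expect_identical(r$sustained_cid_day, 56L)
  expect_identical(r$sustained_cid_components, "FEV1")
  # flagged at weeks 8/16/24 of a 24-week record, false at 12/20:
  # available subsequent visits at week 8 = {8,12,16,20,24}, flagged 3/5 =
  # 60% >= 50% -> sustained at week 8 by the fraction branch
  fu24 <- make_followup(168, 168)
  fl <- make_flags(seq(4, 24, 4),
                   fev1 = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
  r2 <- sustained_cid(fl, no_exac, fu24)
  expect_true(r2$sustained_cid_event)
  expect_identical(r2$sustained_cid_day, 56L)
  # cross-check against the literal oracle
  expect_equal(oracle_sustained(seq(4L, 24L, 4L),
                                c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)),
               8L)
  # a single exacerbation is sustained by definition at its onset day
  r3 <- sustained_cid(make_flags(c(4, 8, 12)), exac_at(30), fu)
  expect_true(r3$sustained_cid_event)
  expect_identical(r3$sustained_cid_day, 30L)
  expect_identical(r3$sustained_cid_components, "EXACERBATION")
})

test_that("a missing intervening measurement breaks the consecutive branch but not the fraction branch", {
  fu <- make_followup(182, 182)
  # flags TRUE, NA, TRUE over weeks 4/8/12: visits 8 weeks apart do not
  # satisfy the consecutive branch; available subsequent visits at week 4 =
  # {4, 12}, flagged 2/2 -> sustained at week 4 by the fraction branch
  r <- sustained_cid(make_flags(c(4, 8, 12), fev1 = c(TRUE, NA, TRUE)),
                     no_exac, fu)
  expect_identical(r$sustained_cid_day, 28L)
  # flags TRUE, NA, FALSE, FALSE: fraction at week 4 is 1/3 -> not sustained
  r2 <- sustained_cid(make_flags(c(4, 8, 12, 16),
                                 fev1 = c(TRUE, NA, FALSE, FALSE)),
                      no_exac, fu)
  expect_false(r2$sustained_cid_event)
  expect_identical(r2$sustained_cid_day, 182L)
})

test_that("rule engine matches exhaustive oracle over all flag patterns on a 6-visit grid", {
  weeks <- seq(4L, 24L, 4L)
  fu <- make_followup(168, 168)
  for (bits in 0:63) {
    flags <- as.logical(bitwAnd(bits, 2^(0:5)) > 0)
    cases <- list(flags)
    for (mpos in 1:6) {
      fm <- flags; fm[mpos] <- NA
      cases[[length(cases) + 1L]] <- fm
    }
    for (fl in cases) {
      expected_week <- oracle_sustained(weeks, fl)
      got <- sustained_cid(make_flags(weeks, fev1 = fl), no_exac, fu)
      if (is.na(expected_week)) {
        expect_false(got$sustained_cid_event)
      } else {
        expect_true(got$sustained_cid_event)
        expect_identical(got$sustained_cid_day, 7L * expected_week)
      }
    }
  }
})

test_that("censoring day follows study completion vs early discontinuation", {
  expect_identical(censor_day(make_followup(364, 364))$day, 364L)
  expect_identical(censor_day(make_followup(100, 182))$day, 100L)
  expect_error(censor_day(data.frame(last_contact_day = 400,
                                     discontinued_early = FALSE,
                                     study_end_day = 364)),
               "last_contact_day")
  # event on the discontinuation day counts as an event
  r <- first_cid(make_flags(4, fev1 = TRUE), no_exac, make_followup(28, 182))
  expect_true(r$first_cid_event)
  expect_identical(r$first_cid_day, 28L)
})

test_that("cohort driver equals per-patient application and enforces integrity", {
  coh <- small_cohort(seed = 31, n = c("STUDY-A" = 40, "STUDY-B" = 40,
                                       "STUDY-C" = 30, "STUDY-D" = 30))
  cid <- derive_cid(coh)
  expect_identical(nrow(cid), nrow(coh$baseline))
  fl <- flag_components(coh$baseline, coh$visits)
  set.seed(1)
  for (pid in sample(coh$baseline$patient_id, 25)) {
    fl_p <- fl[fl$patient_id == pid, ]
    ex_p <- coh$exacerbations[coh$exacerbations$patient_id == pid, ]
    fu_p <- coh$followup[coh$followup$patient_id == pid, ]
    r1 <- first_cid(fl_p, ex_p, fu_p)
    r2 <- sustained_cid(fl_p, ex_p, fu_p)
    row <- cid[cid$patient_id == pid, ]
    expect_identical(row$first_cid_day, r1$first_cid_day)
    expect_identical(row$first_cid_event, r1$first_cid_event)
    expect_identical(row$first_cid_components, r1$first_cid_components)
    expect_identical(row$sustained_cid_day, r2$sustained_cid_day)
    expect_identical(row$sustained_cid_event, r2$sustained_cid_event)
  }
  # orphan rows are rejected with the offending id
  bad <- coh
  bad$visits <- rbind(bad$visits,
                      data.frame(patient_id = "GHOST-1", visit_week = 4L,
                                 visit_day = 28L, fev1 = 1, sgrq = 40))
  expect_error(derive_cid(bad), "GHOST-1")
})

test_that("sustained implies first with ordered times, and component counts never undercount", {
  coh <- small_cohort(seed = 13)
  cid <- derive_cid(coh)
  expect_true(all(!cid$sustained_cid_event | cid$first_cid_event))
  expect_true(all(cid$first_cid_day <= cid$sustained_cid_day))
  # overall count equals patients with >= 1 component event; component sums
  # can only exceed it
  comp_any <- cid$fev1_first_event | cid$sgrq_first_event | cid$exac_first_event
  expect_identical(sum(cid$first_cid_event), sum(comp_any))
  expect_gte(sum(cid$fev1_first_event) + sum(cid$sgrq_first_event) +
               sum(cid$exac_first_event), sum(cid$first_cid_event))
  # per-component sustained exacerbation count equals its first count
  expect_identical(cid$exac_sustained_event, cid$exac_first_event)
  expect_identical(cid$exac_sustained_day, cid$exac_first_day)
  # component-level event implies overall event
  expect_true(all(!cid$fev1_sustained_event | cid$sustained_cid_event))
  # per-component times are consistent with the overall minimum
  trig <- cid$first_cid_event
  mins <- pmin(ifelse(cid$fev1_first_event, cid$fev1_first_day, Inf),
               ifelse(cid$sgrq_first_event, cid$sgrq_first_day, Inf),
               ifelse(cid$exac_first_event, cid$exac_first_day, Inf))
  expect_equal(cid$first_cid_day[trig], mins[trig])
})

test_that("raising a threshold never increases the corresponding event count", {
  coh <- small_cohort(seed = 17, n = c("STUDY-A" = 80, "STUDY-B" = 80,
                                       "STUDY-C" = 60, "STUDY-D" = 60))
  cid1 <- derive_cid(coh, cid_thresholds())
  cid2 <- derive_cid(coh, cid_thresholds(fev1_drop = 0.2))
  expect_lte(sum(cid2$fev1_first_event), sum(cid1$fev1_first_event))
  expect_lte(sum(cid2$first_cid_event), sum(cid1$first_cid_event))
  cid3 <- derive_cid(coh, cid_thresholds(sgrq_rise = 8))
  expect_lte(sum(cid3$sgrq_first_event), sum(cid1$sgrq_first_event))
})
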