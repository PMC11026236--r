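test_that("count-percentage formatting rounds half away from zero", {
  expect_identical(format_count_pct(56, 72), "56 (77.8)")
  expect_identical(format_count_pct(5, 16), "5 (31.3)")    # 31.25 rounds up
  expect_identical(format_count_pct(1, 16), "1 (6.3)")     # 6.25 rounds up
  expect_identical(format_count_pct(0, 72), "0 (0.0)")
  expect_identical(format_count_pct(42, 56, show_denominator = TRUE),
                   "42/56 (75.0)")
  expect_error(format_count_pct(1, 0), "denominator")
  expect_error(format_count_pct(5, 4), "numerator")
  expect_equal(round_half_away(-31.25), -31.3)
})

test_that("formatting agrees with exact integer arithmetic for d <= 200", {
  for (d in 1:200) {
    n <- 0:d
    got <- format_count_pct(n, d)
    want <- sprintf("%d (%.1f)", n, oracle_pct_1dp(n, d))
    expect_identical(got, want, label = paste("denominator", d))
  }
})

test_that("cohort summary tallies flags with the table's denominators", {
  mk <- function(tf_r, tf_l, punct, tc, ts, da, side = "left") {
    cohort <- base_cohort_row(hd_access_side = side)
    if (!tf_r) cohort$CFA_R_diam_mm <- 5.0
    if (!tf_l) cohort$CFA_L_diam_mm <- 5.0
    if (!punct) cohort$cfa_puncture_calc_anterior_R <-
        cohort$cfa_puncture_calc_anterior_L <- TRUE
    if (!tc) { cohort$CCA_R_diam_mm <- 5.0; cohort$CCA_L_diam_mm <- 5.0 }
    if (!ts) cohort$LSA_diam_mm <- 5.0
    if (!da) cohort$asc_ao_insertion_zone_clear <- FALSE
    cohort
  }
  rows <- rbind(mk(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
                mk(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
                mk(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
                mk(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  rows$patient_id <- sprintf("S%02d", 1:4)
  class(rows) <- c("tavi_cohort", "data.frame")
  s <- summarize_assessments(assess_cohort(rows))
  expect_equal(s$n_total, 4L)
  expect_equal(s$n_tf_suitable, 2L)
  expect_equal(s$n_tf_bilateral, 1L)
  expect_equal(s$n_puncture, 1L)
  expect_equal(s$n_alternative, 2L)                 # n_total - n_tf_suitable
  expect_equal(s$n_ta_only, 1L)
  expect_equal(s$n_avoid_ts, 1L)                    # within alternative group
  expect_identical(unname(s$formatted["Suitable for TF approach"]), "2 (50.0)")
  expect_identical(unname(s$formatted["Bilateral approach"]), "1/2 (50.0)")
  expect_identical(unname(s$formatted["Available for only TA approach"]),
                   "1 (50.0)")
  # both puncture percentages are carried (subgroup and whole-cohort)
  expect_equal(s$pct_puncture_of_tf, 50.0)
  expect_equal(s$pct_puncture_of_cohort, 25.0)

  expect_error(summarize_assessments(assess_cohort(rows)[0, ]), "no assessments")
  mixed <- rbind(assess_cohort(rows), assess_cohort(rows, mode = "expanded"))
  expect_error(summarize_assessments(mixed), "mix")

  # expanded-mode summary reports the reduced row set
  s2 <- summarize_assessments(assess_cohort(rows, mode = "expanded"))
  expect_setequal(names(s2$formatted),
                  c("Suitable for TF approach", "Bilateral approach",
                    "Available for TC approach", "Available for TS approach"))
})

test_that("summary counts respect conservation and mode nesting", {
  cohort <- simulate_cohort(cohort_config(n_patients = 300, seed = 17))
  s_ifu <- summarize_assessments(assess_cohort(cohort))
  s_exp <- summarize_assessments(assess_cohort(cohort, mode = "expanded"))
  expect_equal(s_ifu$n_tf_suitable + s_ifu$n_alternative, s_ifu$n_total)
  expect_lte(s_ifu$n_tf_bilateral, s_ifu$n_tf_suitable)
  expect_lte(s_ifu$n_puncture, s_ifu$n_tf_suitable)
  expect_lte(s_ifu$n_avoid_ts, s_ifu$n_alternative)
  expect_lte(s_ifu$n_ta_only, s_ifu$n_alternative)
  expect_lte(s_exp$n_tf_suitable, s_ifu$n_tf_suitable)
})

test_that("grade distributions count every patient exactly once", {
  four <- do.call(rbind, lapply(1:4, function(i) base_cohort_row(
    patient_id = paste0("G", i), D = c(CIA_R = 4))))
  class(four) <- c("tavi_cohort", "data.frame")
  gd <- grade_distribution(four, "CIA_R", "D")
  expect_equal(as.integer(gd), c(0, 0, 0, 0, 4, 0))
  expect_equal(sum(gd), 4L)

  cohort <- simulate_cohort(cohort_config(n_patients = 500, seed = 23))
  for (v in c("CCA_R", "CIA_L")) {
    for (sc in c("D", "R")) {
      expect_equal(sum(grade_distribution(cohort, v, sc)), 500L)
    }
  }
  # carotid degree-0 fraction near its configured value
  p0 <- cohort_config()$vessel_params$CCA_R$d_probs[1]
  expect_lt(abs(grade_distribution(cohort, "CCA_R", "D")[1] / 500 - p0),
            3 * sqrt(p0 * (1 - p0) / 500))
  expect_error(grade_distribution(cohort, "XXX", "D"), "unknown vessel")
})

test_that("unadjusted odds ratio uses the Haldane correction on zero cells", {
  expect_equal(unadjusted_odds_ratio(1, 1, 1, 1), 1.0)
  expect_equal(unadjusted_odds_ratio(4, 9, 12, 47), (4 * 47) / (9 * 12))
  expect_equal(unadjusted_odds_ratio(0, 5, 5, 5),
               (0.5 * 5.5) / (5.5 * 5.5))
  expect_error(unadjusted_odds_ratio(0, 0, 0, 0), "all cells")
  expect_error(unadjusted_odds_ratio(-1, 2, 3, 4), "nonnegative")

  cohort <- simulate_cohort(cohort_config(n_patients = 400, seed = 29))
  a <- assess_cohort(cohort)
  lt <- lead_tf_odds(a)
  expect_equal(sum(lt$table), 400)
  expect_equal(lt$table[1, 1] + lt$table[1, 2], sum(a$lead))
})

test_that("subgroup summary splits descriptives by TF suitability", {
  cohort <- simulate_cohort(cohort_config(n_patients = 200, seed = 37))
  a <- assess_cohort(cohort)
  sg <- subgroup_summary(cohort, a)
  expect_equal(sum(sg$n), 200)
  expect_equal(sg$n[sg$group == "TF-suitable"], sum(a$tf_suitable))
  expect_equal(sum(sg$n_lead), sum(cohort$lead))
})
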