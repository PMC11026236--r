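test_that("required diameter depends on calcification degree and mode", {
  # IFU: mild calcification (<= D2) needs > 5.5 mm; >= D3 needs the full
  # 7.6 mm expanded diameter; the expanded criterion always needs 7.6 mm
  expect_equal(required_diameter(2, "ifu"), 5.5)
  expect_equal(required_diameter(3, "ifu"), 7.6)
  expect_equal(required_diameter(0, "expanded"), 7.6)
  expect_equal(required_diameter(0:5, "ifu"),
               c(5.5, 5.5, 5.5, 7.6, 7.6, 7.6))
  expect_equal(required_diameter(0:5, "expanded"), rep(7.6, 6))
})

test_that("vessel passage uses a strict diameter inequality", {
  pass <- function(d, g, mode = "ifu") {
    vessel_passes(vessel_measurement("CIA_R", d, g, 0), mode)
  }
  expect_true(pass(8.0, 0))
  expect_false(pass(7.0, 4))
  expect_false(pass(5.5, 1))      # 5.5 is not > 5.5
  expect_true(pass(5.6, 1))
  expect_false(pass(7.6, 3))      # 7.6 is not > 7.6
  expect_false(pass(7.0, 1, "expanded"))
  expect_true(pass(7.7, 5, "expanded"))
  expect_error(
    vessel_passes(vessel_measurement("AscAo", NA, 0), "ifu"),
    "no diameter")
})

test_that("route verdicts identify the first limiting vessel", {
  p <- base_profile()
  v <- route_feasible(p, "TF_R")
  expect_true(v$feasible)
  expect_identical(v$limiting_reason, "none")

  p2 <- base_profile(diam = c(CIA_R = 7.0), D = c(CIA_R = 4))
  v2 <- route_feasible(p2, "TF_R")
  expect_false(v2$feasible)
  expect_identical(v2$limiting_vessel, "CIA_R")
  expect_identical(v2$limiting_reason, "diameter_below_threshold")
  # left side unaffected
  expect_true(route_feasible(p2, "TF_L")$feasible)

  # distal-to-proximal ordering: with two failures, CFA is reported first
  p3 <- base_profile(diam = c(CFA_R = 5.0, CIA_R = 5.0))
  expect_identical(route_feasible(p3, "TF_R")$limiting_vessel, "CFA_R")

  # abdominal aorta is part of the transfemoral chain unless disabled
  p4 <- base_profile(diam = c(AbdAo = 7.0), D = c(AbdAo = 5))
  expect_false(route_feasible(p4, "TF_R")$feasible)
  expect_true(route_feasible(p4, "TF_R", include_abdao = FALSE)$feasible)

  # single-vessel chains
  expect_true(route_feasible(base_profile(diam = c(LSA = 7.7),
                                          D = c(LSA = 3)), "TS")$feasible)
  expect_true(route_feasible(p, "TC_R")$off_ifu)
  expect_false(route_feasible(p, "TF_R")$off_ifu)
  expect_error(route_feasible(p, "DA"), "unknown route")
})

test_that("puncture method needs a feasible TF side with a clean site", {
  p <- base_profile()
  expect_true(puncture_feasible(p, "R", route_feasible(p, "TF_R")))
  p_ant <- base_profile(punct_ant_R = TRUE)
  expect_false(puncture_feasible(p_ant, "R", route_feasible(p_ant, "TF_R")))
  p_lat <- base_profile(punct_lat_R = TRUE)
  expect_false(puncture_feasible(p_lat, "R", route_feasible(p_lat, "TF_R")))
  p_no_tf <- base_profile(diam = c(CFA_R = 5.0))
  expect_false(puncture_feasible(p_no_tf, "R",
                                 route_feasible(p_no_tf, "TF_R")))
  expect_error(puncture_feasible(p, "R", route_feasible(p, "TF_L")),
               "same side")
})

test_that("direct-aortic route needs a strictly clean insertion zone", {
  expect_true(da_feasible(base_profile())$feasible)
  v1 <- da_feasible(base_profile(D = c(AscAo = 1)))
  expect_false(v1$feasible)
  expect_identical(v1$limiting_reason, "insertion_zone_calcified")
  expect_false(da_feasible(base_profile(zone_clear = FALSE))$feasible)
})

test_that("patient assessment derives the route flags and TA fallback", {
  a <- assess_patient(base_profile())
  expect_true(a$tf_suitable && a$tf_bilateral && a$tc_available &&
                a$ts_available && a$da_available)
  expect_false(a$alternative_desirable || a$ta_only)

  # everything narrow/calcified except clean carotids: the TA fallback
  narrow <- rep(5.0, 10)
  names(narrow) <- setdiff(vessel_ids(), "AscAo")
  high <- rep(4, 10)
  names(high) <- names(narrow)
  p_ta <- base_cohort_row(diam = narrow, D = c(high, AscAo = 2),
                          zone_clear = FALSE)
  p_ta$CCA_R_diam_mm <- 9; p_ta$CCA_R_D <- 0L
  p_ta$CCA_L_diam_mm <- 9; p_ta$CCA_L_D <- 0L
  a_ta <- assess_patient(cohort_profiles(p_ta)[[1]])
  expect_true(a_ta$ta_only)
  expect_true(a_ta$tc_available)
  expect_true(a_ta$alternative_desirable)

  # TF infeasible, TS feasible, left-sided dialysis access
  p_ts <- base_profile(diam = c(CFA_R = 5.0, CFA_L = 5.0),
                       hd_access_side = "left")
  a_ts <- assess_patient(p_ts)
  expect_true(a_ts$alternative_desirable && a_ts$avoid_ts_flag)
  expect_false(assess_patient(p_ts, avoid_ts_rule = "off")$avoid_ts_flag)

  # invalid profiles are rejected with the violation list
  p_bad <- base_profile()
  p_bad$vessels <- p_bad$vessels[-2]
  expect_error(assess_patient(p_bad), "invalid profile.*missing vessel")
})

test_that("vectorized cohort assessment agrees with the scalar path", {
  cohort <- random_cohort(200, seed = 11)
  profs <- cohort_profiles(cohort)
  for (mode in c("ifu", "expanded")) {
    a <- assess_cohort(cohort, mode = mode)
    ap <- lapply(profs, assess_patient, mode = mode)
    for (r in route_ids()) {
      expect_identical(
        a[[paste0(r, "_feasible")]],
        vapply(ap, function(x) x$verdicts[[r]]$feasible, logical(1)))
      expect_identical(
        a[[paste0(r, "_limiting_vessel")]],
        vapply(ap, function(x) x$verdicts[[r]]$limiting_vessel, character(1)))
    }
    for (f in c("tf_suitable", "tf_bilateral", "puncture_feasible",
                "tc_available", "ts_available", "da_available",
                "alternative_desirable", "avoid_ts_flag", "ta_only")) {
      expect_identical(a[[f]], vapply(ap, `[[`, logical(1), f))
    }
  }
})
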