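#' Access routes evaluated by the simulation
#'
#' Right/left transfemoral (`TF_R`, `TF_L`), right/left transcervical
#' (carotid; `TC_R`, `TC_L`), trans-subclavian (`TS`, via the left
#' subclavian artery) and direct aorta (`DA`). The transapical (TA) route is
#' not itself simulated; it is the fallback recorded when no other route
#' except (at most) the off-label transcervical one is feasible.
#'
#' @return character vector of route identifiers.
#' @export
route_ids <- function() c("TF_R", "TF_L", "TC_R", "TC_L", "TS", "DA")

# Vessels a route's sheath must traverse, ordered distal to proximal.
route_chain <- function(route, include_abdao = TRUE) {
  ch <- switch(route,
    TF_R = c("CFA_R", "EIA_R", "CIA_R", "AbdAo"),
    TF_L = c("CFA_L", "EIA_L", "CIA_L", "AbdAo"),
    TC_R = "CCA_R",
    TC_L = "CCA_L",
    TS   = "LSA",
    stop(sprintf("unknown route '%s'", route), call. = FALSE))
  if (!include_abdao) ch <- setdiff(ch, "AbdAo")
  ch
}

#' Minimum vessel diameter required for sheath passage
#'
#' Under the instructions-for-use (`"ifu"`) criterion, vessels with mild
#' calcification (degree grade <= 2, i.e. at most half the circumference)
#' must exceed the IFU minimum access-route diameter of 5.5 mm; with
#' moderate or severe calcification (degree >= 3) the vessel is assumed
#' unable to stretch, so it must exceed the sheath's maximum expanded outer
#' diameter (7.6 mm for the 14-F eSheath). Under the `"expanded"` criterion
#' every vessel must exceed the fully expanded diameter regardless of
#' calcification. Feasibility always uses the *strict* inequality
#' `diameter > required_diameter(...)`.
#'
#' @param degree integer vector of degree grades (0..5).
#' @param mode `"ifu"` or `"expanded"`.
#' @param sheath a [sheath_spec()]; default [sheath_14f()].
#' @param ifu_min_mm the IFU minimum access-route diameter, mm (5.5 for the
#'   14-F eSheath).
#' @return numeric vector of required diameters in mm.
#' @export
required_diameter <- function(degree, mode = c("ifu", "expanded"),
                              sheath = sheath_14f(), ifu_min_mm = 5.5) {
  mode <- match.arg(mode)
  degree <- calc_grade(degree)
  if (mode == "expanded") {
    rep(sheath$max_expanded_od_mm, length(degree))
  } else {
    ifelse(degree <= 2L, ifu_min_mm, sheath$max_expanded_od_mm)
  }
}

#' Can the sheath pass one vessel?
#'
#' @param v a [vessel_measurement()] with a non-missing diameter.
#' @inheritParams required_diameter
#' @return `TRUE` iff the vessel's minimum diameter strictly exceeds the
#'   required diameter for its degree grade.
#' @export
vessel_passes <- function(v, mode = c("ifu", "expanded"), sheath = sheath_14f()) {
  mode <- match.arg(mode)
  if (is.null(v$min_diameter_mm) || is.na(v$min_diameter_mm)) {
    stop(sprintf("vessel %s has no diameter measurement", v$vessel_id),
         call. = FALSE)
  }
  v$min_diameter_mm > required_diameter(v$degree, mode, sheath)
}

route_verdict <- function(route, feasible, limiting_vessel = NA_character_,
                          limiting_reason = "none", off_ifu = FALSE) {
  structure(list(route = route, feasible = feasible,
                 limiting_vessel = limiting_vessel,
                 limiting_reason = limiting_reason, off_ifu = off_ifu),
            class = "route_verdict")
}

#' Feasibility of a single diameter-based route
#'
#' Evaluates one of the transfemoral, transcervical or trans-subclavian
#' routes: the route is feasible iff every vessel in its chain passes
#' [vessel_passes()]. The transfemoral chain is CFA, EIA, CIA and (by
#' default) the abdominal aorta; the transcervical chains are the single
#' common carotid arteries and the trans-subclavian chain is the left
#' subclavian artery. The direct-aortic route is calcification-based, not
#' diameter-based: see [da_feasible()].
#'
#' @param profile a valid [patient_profile()].
#' @param route one of `"TF_R"`, `"TF_L"`, `"TC_R"`, `"TC_L"`, `"TS"`.
#' @inheritParams required_diameter
#' @param include_abdao include the abdominal aorta in the transfemoral
#'   chain (default `TRUE`).
#' @return a `route_verdict`: `feasible`, `limiting_vessel` (the first
#'   failing vessel in distal-to-proximal order, or `NA`),
#'   `limiting_reason` (`"diameter_below_threshold"` or `"none"`), and
#'   `off_ifu` (`TRUE` for the transcervical route, which lies outside the
#'   device's instructions for use).
#' @export
route_feasible <- function(profile, route, mode = c("ifu", "expanded"),
                           sheath = sheath_14f(), include_abdao = TRUE) {
  mode <- match.arg(mode)
  chain <- route_chain(route, include_abdao)
  vs <- profile$vessels
  ids <- vapply(vs, `[[`, character(1), "vessel_id")
  off_ifu <- route %in% c("TC_R", "TC_L")
  for (vid in chain) {
    v <- vs[[match(vid, ids)]]
    if (!vessel_passes(v, mode, sheath)) {
      return(route_verdict(route, FALSE, vid, "diameter_below_threshold",
                           off_ifu))
    }
  }
  route_verdict(route, TRUE, off_ifu = off_ifu)
}

#' Is the percutaneous puncture method viable for a transfemoral route?
#'
#' The puncture method requires a feasible transfemoral route on that side
#' *and* absence of calcification on both the anterior and lateral sides of
#' the common femoral artery puncture site.
#'
#' @param profile a [patient_profile()].
#' @param side `"R"` or `"L"`.
#' @param tf_verdict the transfemoral `route_verdict` for the same side.
#' @return logical.
#' @export
puncture_feasible <- function(profile, side = c("R", "L"), tf_verdict) {
  side <- match.arg(side)
  if (!identical(tf_verdict$route, paste0("TF_", side))) {
    stop("tf_verdict must be the transfemoral verdict for the same side",
         call. = FALSE)
  }
  tf_verdict$feasible &&
    !profile[[paste0("cfa_puncture_calc_anterior_", side)]] &&
    !profile[[paste0("cfa_puncture_calc_lateral_", side)]]
}

#' Feasibility of the direct-aortic route
#'
#' The direct-aortic route requires absence of calcification or atheroma in
#' the ascending aorta at the cannulation zone (the outer curvature 5.5--6
#' cm above the annulus): the insertion zone must be clear and the
#' ascending-aorta degree grade at the insertion site must be exactly 0.
#'
#' @param profile a [patient_profile()].
#' @return a `route_verdict` with `limiting_reason`
#'   `"insertion_zone_calcified"` when infeasible.
#' @export
da_feasible <- function(profile) {
  ids <- vapply(profile$vessels, `[[`, character(1), "vessel_id")
  asc <- profile$vessels[[match("AscAo", ids)]]
  ok <- isTRUE(profile$asc_ao_insertion_zone_clear) && asc$degree == 0L
  if (ok) route_verdict("DA", TRUE)
  else route_verdict("DA", FALSE, "AscAo", "insertion_zone_calcified")
}

#' Assess every access route for one patient
#'
#' Runs the full approach-simulation flow for a single patient: evaluates
#' the six route verdicts, then derives the cohort-level flags. The
#' transfemoral route is first-line; when neither side is feasible an
#' alternative approach is desirable. When, additionally, neither the
#' trans-subclavian nor the direct-aortic route is feasible — i.e. no route
#' remains except at most the off-label transcervical one — the patient is
#' marked `ta_only` (transapical fallback).
#'
#' @inheritParams route_feasible
#' @param avoid_ts_rule `"left_access"` flags the trans-subclavian route as
#'   preferable-to-avoid when it is feasible but the hemodialysis access is
#'   on the left (the route would share the access arm's inflow); `"off"`
#'   disables the flag. This rule is an interpretation, not a device
#'   criterion, and is reported as such.
#' @return an object of class `approach_assessment`: the six verdicts plus
#'   logical flags `tf_suitable`, `tf_bilateral`, `puncture_feasible`,
#'   `tc_available`, `ts_available`, `da_available`,
#'   `alternative_desirable`, `avoid_ts_flag`, `ta_only`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_patients = 1, seed = 42))
#' assess_patient(cohort_profiles(cohort)[[1]])
#' @export
assess_patient <- function(profile, mode = c("ifu", "expanded"),
                           sheath = sheath_14f(), include_abdao = TRUE,
                           avoid_ts_rule = c("left_access", "off")) {
  mode <- match.arg(mode)
  avoid_ts_rule <- match.arg(avoid_ts_rule)
  bad <- validate_profile(profile)
  if (length(bad)) {
    stop("invalid profile: ", paste(bad, collapse = "; "), call. = FALSE)
  }
  vd <- lapply(c("TF_R", "TF_L", "TC_R", "TC_L", "TS"), function(r) {
    route_feasible(profile, r, mode, sheath, include_abdao)
  })
  names(vd) <- c("TF_R", "TF_L", "TC_R", "TC_L", "TS")
  vd$DA <- da_feasible(profile)

  tf_suitable <- vd$TF_R$feasible || vd$TF_L$feasible
  punct <- (vd$TF_R$feasible && puncture_feasible(profile, "R", vd$TF_R)) ||
           (vd$TF_L$feasible && puncture_feasible(profile, "L", vd$TF_L))
  ts_av <- vd$TS$feasible
  da_av <- vd$DA$feasible
  structure(
    list(patient_id = profile$patient_id, mode = mode,
         verdicts = vd,
         tf_suitable = tf_suitable,
         tf_bilateral = vd$TF_R$feasible && vd$TF_L$feasible,
         puncture_feasible = punct,
         tc_available = vd$TC_R$feasible || vd$TC_L$feasible,
         ts_available = ts_av,
         da_available = da_av,
         alternative_desirable = !tf_suitable,
         avoid_ts_flag = avoid_ts_rule == "left_access" && ts_av &&
           profile$hd_access_side == "left",
         ta_only = !tf_suitable && !ts_av && !da_av),
    class = "approach_assessment"
  )
}

#' @export
print.approach_assessment <- function(x, ...) {
  cat(sprintf("<approach_assessment> patient %s (criterion: %s)\n",
              x$patient_id, x$mode))
  for (v in x$verdicts) {
    cat(sprintf("  %-4s %s%s%s\n", v$route,
                if (v$feasible) "feasible" else "infeasible",
                if (!is.na(v$limiting_vessel))
                  paste0(" (limited by ", v$limiting_vessel, ")") else "",
                if (v$off_ifu) " [off-IFU]" else ""))
  }
  cat(sprintf("  TF suitable: %s; bilateral: %s; puncture: %s\n",
              x$tf_suitable, x$tf_bilateral, x$puncture_feasible))
  if (x$alternative_desirable) {
    cat(sprintf("  alternative desirable; TA-only: %s%s\n", x$ta_only,
                if (x$avoid_ts_flag) "; prefer to avoid TS (left HD access)"
                else ""))
  }
  invisible(x)
}

#' Assess every patient of a cohort (vectorized)
#'
#' Column-wise implementation of [assess_patient()] for a whole cohort
#' table; the two agree row for row. Returns one row per patient with the
#' per-route verdict columns (`<route>_feasible`, `<route>_limiting_vessel`)
#' and the derived flags, carrying `lead` and `hd_access_side` through for
#' reporting.
#'
#' @param cohort a cohort data frame (see [as_cohort()] /
#'   [read_cohort_csv()]).
#' @inheritParams assess_patient
#' @return a data frame of class `c("tavi_assessments", "data.frame")`.
#' @export
assess_cohort <- function(cohort, mode = c("ifu", "expanded"),
                          sheath = sheath_14f(), include_abdao = TRUE,
                          avoid_ts_rule = c("left_access", "off")) {
  mode <- match.arg(mode)
  avoid_ts_rule <- match.arg(avoid_ts_rule)
  n <- nrow(cohort)
  if (n == 0L) stop("empty cohort", call. = FALSE)

  pass <- function(vid) {
    cohort[[paste0(vid, "_diam_mm")]] >
      required_diameter(cohort[[paste0(vid, "_D")]], mode, sheath)
  }
  eval_route <- function(route) {
    chain <- route_chain(route, include_abdao)
    pm <- !vapply(chain, pass, logical(n))    # n x chain failure matrix
    if (n == 1L) pm <- matrix(pm, nrow = 1L)
    feasible <- rowSums(pm) == 0L
    first_fail <- max.col(pm, ties.method = "first")
    list(feasible = feasible,
         limiting = ifelse(feasible, NA_character_, chain[first_fail]))
  }
  tf_r <- eval_route("TF_R"); tf_l <- eval_route("TF_L")
  tc_r <- eval_route("TC_R"); tc_l <- eval_route("TC_L")
  ts <- eval_route("TS")
  da_ok <- cohort$asc_ao_insertion_zone_clear & cohort$AscAo_D == 0L

  tf_suitable <- tf_r$feasible | tf_l$feasible
  punct <- (tf_r$feasible & !cohort$cfa_puncture_calc_anterior_R &
              !cohort$cfa_puncture_calc_lateral_R) |
           (tf_l$feasible & !cohort$cfa_puncture_calc_anterior_L &
              !cohort$cfa_puncture_calc_lateral_L)
  ts_av <- ts$feasible
  out <- data.frame(
    patient_id = as.character(cohort$patient_id), mode = mode,
    TF_R_feasible = tf_r$feasible, TF_R_limiting_vessel = tf_r$limiting,
    TF_L_feasible = tf_l$feasible, TF_L_limiting_vessel = tf_l$limiting,
    TC_R_feasible = tc_r$feasible, TC_R_limiting_vessel = tc_r$limiting,
    TC_L_feasible = tc_l$feasible, TC_L_limiting_vessel = tc_l$limiting,
    TS_feasible = ts$feasible, TS_limiting_vessel = ts$limiting,
    DA_feasible = da_ok,
    DA_limiting_vessel = ifelse(da_ok, NA_character_, "AscAo"),
    tf_suitable = tf_suitable,
    tf_bilateral = tf_r$feasible & tf_l$feasible,
    puncture_feasible = punct,
    tc_available = tc_r$feasible | tc_l$feasible,
    ts_available = ts_av,
    da_available = da_ok,
    alternative_desirable = !tf_suitable,
    avoid_ts_flag = if (avoid_ts_rule == "left_access")
      ts_av & cohort$hd_access_side == "left" else rep(FALSE, n),
    ta_only = !tf_suitable & !ts_av & !da_ok,
    lead = cohort$lead,
    hd_access_side = as.character(cohort$hd_access_side),
    stringsAsFactors = FALSE)
  class(out) <- c("tavi_assessments", "data.frame")
  out
}

#' @export
summary.tavi_assessments <- function(object, ...) {
  summarize_assessments(object)
}
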