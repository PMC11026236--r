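#' A patient's vascular profile
#'
#' Bundles one patient's eleven vessel measurements with the puncture-site
#' findings, the ascending-aorta insertion-zone status, the hemodialysis
#' access side, and demographics. This is the unit record consumed by the
#' route decision engine.
#'
#' @param patient_id opaque identifier string.
#' @param vessels a list of [vessel_measurement()] objects, exactly one per
#'   vessel in [vessel_ids()].
#' @param cfa_puncture_calc_anterior_R,cfa_puncture_calc_anterior_L logical;
#'   calcification present on the anterior side of the right/left common
#'   femoral artery puncture site.
#' @param cfa_puncture_calc_lateral_R,cfa_puncture_calc_lateral_L logical;
#'   calcification present on the lateral side of the puncture site.
#' @param asc_ao_insertion_zone_clear logical; no calcification or atheroma
#'   in the aortic outer curvature 5.5--6 cm from the annulus (the
#'   direct-aortic cannulation zone).
#' @param hd_access_side side of the hemodialysis vascular access:
#'   `"left"`, `"right"`, `"other"` or `"unknown"`.
#' @param lead logical; lower extremity artery disease.
#' @param age_years,bsa_m2,hd_duration_years demographics: age (years), body
#'   surface area (m^2), years on hemodialysis.
#' @param sex `"male"` or `"female"`.
#' @return a list of class `tavi_profile`.
#' @seealso [validate_profile()], [assess_patient()]
#' @export
patient_profile <- function(patient_id, vessels,
                            cfa_puncture_calc_anterior_R = FALSE,
                            cfa_puncture_calc_anterior_L = FALSE,
                            cfa_puncture_calc_lateral_R = FALSE,
                            cfa_puncture_calc_lateral_L = FALSE,
                            asc_ao_insertion_zone_clear = TRUE,
                            hd_access_side = c("left", "right", "other", "unknown"),
                            lead = FALSE,
                            age_years = NA_real_, sex = NA_character_,
                            bsa_m2 = NA_real_, hd_duration_years = NA_real_) {
  hd_access_side <- match.arg(hd_access_side)
  if (!is.list(vessels)) stop("vessels must be a list", call. = FALSE)
  structure(
    list(patient_id = as.character(patient_id),
         vessels = vessels,
         cfa_puncture_calc_anterior_R = isTRUE(cfa_puncture_calc_anterior_R),
         cfa_puncture_calc_anterior_L = isTRUE(cfa_puncture_calc_anterior_L),
         cfa_puncture_calc_lateral_R = isTRUE(cfa_puncture_calc_lateral_R),
         cfa_puncture_calc_lateral_L = isTRUE(cfa_puncture_calc_lateral_L),
         asc_ao_insertion_zone_clear = isTRUE(asc_ao_insertion_zone_clear),
         hd_access_side = hd_access_side,
         lead = isTRUE(lead),
         age_years = as.numeric(age_years),
         sex = as.character(sex),
         bsa_m2 = as.numeric(bsa_m2),
         hd_duration_years = as.numeric(hd_duration_years)),
    class = "tavi_profile"
  )
}

#' Validate a patient profile
#'
#' Checks a profile against the record invariants and returns all violations
#' found: every vessel present exactly once, strictly positive diameters
#' (the ascending-aorta diameter may be absent, as it is excluded from the
#' minimum-diameter assessment), grades in 0..5, and a known access side.
#'
#' @param profile a [patient_profile()].
#' @return character vector of human-readable violations; `character(0)` iff
#'   the profile is valid.
#' @export
validate_profile <- function(profile) {
  bad <- character(0)
  if (!inherits(profile, "tavi_profile")) {
    return("not a tavi_profile object")
  }
  ids <- vapply(profile$vessels, function(v) {
    if (is.list(v) && is.character(v$vessel_id)) v$vessel_id else NA_character_
  }, character(1))
  for (v in vessel_ids()) {
    k <- sum(ids == v, na.rm = TRUE)
    if (k == 0L) bad <- c(bad, sprintf("missing vessel %s", v))
    if (k > 1L)  bad <- c(bad, sprintf("duplicated vessel %s", v))
  }
  for (vm in profile$vessels) {
    id <- vm$vessel_id
    if (is.null(id) || !(id %in% vessel_ids())) {
      bad <- c(bad, sprintf("unknown vessel id '%s'", as.character(id)))
      next
    }
    d <- vm$min_diameter_mm
    if (is.na(d)) {
      if (id != "AscAo") bad <- c(bad, sprintf("%s: missing diameter", id))
    } else if (!is.numeric(d) || d <= 0) {
      bad <- c(bad, sprintf("%s: diameter must be > 0 mm (got %s)", id, d))
    }
    if (is.na(vm$degree) || !(vm$degree %in% 0:5)) {
      bad <- c(bad, sprintf("%s: degree grade must be in 0..5", id))
    }
    if (!is.na(vm$range) && !(vm$range %in% 0:5)) {
      bad <- c(bad, sprintf("%s: range grade must be in 0..5", id))
    }
    if (id != "AscAo" && is.na(vm$range)) {
      bad <- c(bad, sprintf("%s: missing range grade", id))
    }
  }
  if (!profile$hd_access_side %in% c("left", "right", "other", "unknown")) {
    bad <- c(bad, "hd_access_side must be left/right/other/unknown")
  }
  bad
}

#' @export
print.tavi_profile <- function(x, ...) {
  cat(sprintf("<tavi_profile> patient %s (%s, %s y, LEAD: %s, HD access: %s)\n",
              x$patient_id, x$sex, format(x$age_years),
              if (x$lead) "yes" else "no", x$hd_access_side))
  df <- do.call(rbind, lapply(x$vessels, function(v) {
    data.frame(vessel = v$vessel_id, diam_mm = v$min_diameter_mm,
               D = v$degree, R = if (is.na(v$range)) NA_integer_ else v$range)
  }))
  print(df, row.names = FALSE)
  invisible(x)
}

# Column schema of the cohort interchange table (one row per patient).
cohort_columns <- function() {
  c("patient_id", "age_years", "sex", "bsa_m2", "hd_duration_years",
    "lead", "hd_access_side", "asc_ao_insertion_zone_clear",
    "cfa_puncture_calc_anterior_R", "cfa_puncture_calc_anterior_L",
    "cfa_puncture_calc_lateral_R", "cfa_puncture_calc_lateral_L",
    as.vector(t(outer(vessel_ids(), c("_diam_mm", "_D", "_R"), paste0))))
}

#' Convert between profiles and the cohort table
#'
#' A cohort is a plain data frame with one row per patient and the column
#' schema of the cohort CSV (see [read_cohort_csv()]). These helpers convert
#' a list of [patient_profile()] objects to that table and back.
#'
#' @param profiles list of `tavi_profile` objects.
#' @return `as_cohort()` returns a data frame of class
#'   `c("tavi_cohort", "data.frame")`; `cohort_profiles()` returns a list of
#'   `tavi_profile` objects.
#' @export
as_cohort <- function(profiles) {
  if (inherits(profiles, "tavi_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    row <- list(
      patient_id = p$patient_id, age_years = p$age_years, sex = p$sex,
      bsa_m2 = p$bsa_m2, hd_duration_years = p$hd_duration_years,
      lead = p$lead, hd_access_side = p$hd_access_side,
      asc_ao_insertion_zone_clear = p$asc_ao_insertion_zone_clear,
      cfa_puncture_calc_anterior_R = p$cfa_puncture_calc_anterior_R,
      cfa_puncture_calc_anterior_L = p$cfa_puncture_calc_anterior_L,
      cfa_puncture_calc_lateral_R = p$cfa_puncture_calc_lateral_R,
      cfa_puncture_calc_lateral_L = p$cfa_puncture_calc_lateral_L)
    for (vm in p$vessels) {
      row[[paste0(vm$vessel_id, "_diam_mm")]] <- vm$min_diameter_mm
      row[[paste0(vm$vessel_id, "_D")]] <- as.integer(vm$degree)
      row[[paste0(vm$vessel_id, "_R")]] <-
        if (is.na(vm$range)) NA_integer_ else as.integer(vm$range)
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[, cohort_columns()]
  class(df) <- c("tavi_cohort", "data.frame")
  df
}

#' @rdname as_cohort
#' @param cohort a cohort data frame.
#' @export
cohort_profiles <- function(cohort) {
  lapply(seq_len(nrow(cohort)), function(i) {
    r <- cohort[i, , drop = FALSE]
    # lenient build: invalid cells become reportable violations, not errors
    vs <- lapply(vessel_ids(), function(v) {
      structure(list(vessel_id = v,
                     min_diameter_mm = as.numeric(r[[paste0(v, "_diam_mm")]]),
                     degree = r[[paste0(v, "_D")]],
                     range = r[[paste0(v, "_R")]]),
                class = "vessel_measurement")
    })
    patient_profile(
      patient_id = r$patient_id, vessels = vs,
      cfa_puncture_calc_anterior_R = r$cfa_puncture_calc_anterior_R,
      cfa_puncture_calc_anterior_L = r$cfa_puncture_calc_anterior_L,
      cfa_puncture_calc_lateral_R = r$cfa_puncture_calc_lateral_R,
      cfa_puncture_calc_lateral_L = r$cfa_puncture_calc_lateral_L,
      asc_ao_insertion_zone_clear = r$asc_ao_insertion_zone_clear,
      hd_access_side = r$hd_access_side, lead = r$lead,
      age_years = r$age_years, sex = r$sex, bsa_m2 = r$bsa_m2,
      hd_duration_years = r$hd_duration_years)
  })
}

#' Validate every row of a cohort table
#'
#' @param cohort a cohort data frame.
#' @return data frame with columns `row`, `patient_id`, `message`; zero rows
#'   iff every patient record is valid.
#' @export
validate_cohort <- function(cohort) {
  out <- list()
  for (i in seq_len(nrow(cohort))) {
    msgs <- tryCatch(validate_profile(cohort_profiles(cohort[i, ])[[1L]]),
                     error = function(e) conditionMessage(e))
    if (length(msgs)) {
      out[[length(out) + 1L]] <- data.frame(
        row = i, patient_id = as.character(cohort$patient_id[i]),
        message = msgs, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(row = integer(0), patient_id = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
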