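#' Measured access-route vessels
#'
#' The eleven vessels assessed on preoperative CT: ascending aorta (`AscAo`),
#' bilateral common carotid arteries (`CCA_R`, `CCA_L`), left subclavian
#' artery (`LSA`), abdominal aorta (`AbdAo`), and the bilateral iliofemoral
#' chain: common iliac (`CIA_R`, `CIA_L`), external iliac (`EIA_R`, `EIA_L`)
#' and common femoral (`CFA_R`, `CFA_L`) arteries.
#'
#' @return character vector of the eleven vessel identifiers.
#' @export
vessel_ids <- function() {
  c("AscAo", "CCA_R", "CCA_L", "LSA", "AbdAo",
    "CIA_R", "CIA_L", "EIA_R", "EIA_L", "CFA_R", "CFA_L")
}

#' A single vessel measurement
#'
#' Records the minimum short-axis diameter of one vessel together with its
#' degree (D) and range (R) calcification grades, both scored at the site of
#' minimal diameter (for the ascending aorta, the degree grade is scored at
#' the presumed sheath-insertion site and the diameter is not assessed).
#'
#' @param vessel_id one of [vessel_ids()].
#' @param min_diameter_mm minimum short-axis diameter in millimetres
#'   (strictly positive); may be `NA` for `AscAo` only.
#' @param degree degree-of-calcification grade, integer 0..5.
#' @param range range-of-calcification grade, integer 0..5; may be `NA`
#'   for `AscAo`.
#' @return a list of class `vessel_measurement`.
#' @export
vessel_measurement <- function(vessel_id, min_diameter_mm, degree, range = NA) {
  if (!is.character(vessel_id) || length(vessel_id) != 1L ||
      !(vessel_id %in% vessel_ids())) {
    stop("vessel_id must be one of: ", paste(vessel_ids(), collapse = ", "),
         call. = FALSE)
  }
  if (length(min_diameter_mm) != 1L) {
    stop("min_diameter_mm must be a single value", call. = FALSE)
  }
  if (is.na(min_diameter_mm)) {
    if (vessel_id != "AscAo") {
      stop("min_diameter_mm may be missing only for AscAo", call. = FALSE)
    }
  } else if (!is.numeric(min_diameter_mm) || min_diameter_mm <= 0) {
    stop("min_diameter_mm must be > 0 mm", call. = FALSE)
  }
  degree <- calc_grade(degree)
  if (!is.na(range)) range <- calc_grade(range)
  structure(
    list(vessel_id = vessel_id,
         min_diameter_mm = as.numeric(min_diameter_mm),
         degree = degree, range = range),
    class = "vessel_measurement"
  )
}

#' The expandable introducer sheath
#'
#' Device constants for an expandable sheath ("eSheath"): the nominal outer
#' diameter and the maximum outer diameter it reaches transiently while the
#' valve delivery system passes through it.
#'
#' @param name device label.
#' @param nominal_od_mm nominal outer diameter, mm.
#' @param max_expanded_od_mm maximum (fully expanded) outer diameter, mm.
#' @return a list of class `sheath_spec`.
#' @examples
#' sheath_14f() # the 14-F eSheath: 6.0 mm nominal, 7.6 mm fully expanded
#' @export
sheath_spec <- function(name, nominal_od_mm, max_expanded_od_mm) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(nominal_od_mm), nominal_od_mm > 0,
            is.numeric(max_expanded_od_mm), max_expanded_od_mm > 0)
  if (nominal_od_mm > max_expanded_od_mm) {
    stop("nominal_od_mm must not exceed max_expanded_od_mm", call. = FALSE)
  }
  structure(list(name = name,
                 nominal_od_mm = as.numeric(nominal_od_mm),
                 max_expanded_od_mm = as.numeric(max_expanded_od_mm)),
            class = "sheath_spec")
}

#' @rdname sheath_spec
#' @details `sheath_14f()` is the 14-F eSheath used for the 20/23/26-mm
#'   balloon-expandable valve (6.0 mm nominal, expanding to 7.6 mm).
#'   `sheath_16f()` stores the 16-F constants (6.7 to 8.2 mm) for reference;
#'   no route logic in this package uses it, since the 29-mm valve pathway is
#'   out of scope.
#' @export
sheath_14f <- function() sheath_spec("14F eSheath", 6.0, 7.6)

#' @rdname sheath_spec
#' @export
sheath_16f <- function() sheath_spec("16F eSheath", 6.7, 8.2)
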