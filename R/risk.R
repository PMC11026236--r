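#' Sheath-to-artery ratio metrics
#'
#' Two dimensionless predictors of access-site vascular complications: the
#' sheath outer-to-femoral artery ratio (SFAR, sheath outer diameter divided
#' by the minimal common femoral artery diameter; published major-complication
#' cut-off 1.05) and the sheath outer-to-iliofemoral artery ratio (SIFAR,
#' sheath outer diameter divided by the smallest diameter along the
#' iliofemoral chain CFA/EIA/CIA; cut-off 0.95). Which sheath diameter
#' enters the ratio is caller-specified; the default is the *nominal* outer
#' diameter, since the published cut-offs were derived with non-expandable
#' sheaths.
#'
#' @param profile a [patient_profile()].
#' @param side `"R"` or `"L"`.
#' @param sheath_od_mm sheath outer diameter in mm entering the numerator
#'   (default: nominal 14-F eSheath, 6.0 mm).
#' @return a list of class `ratio_result` with fields `metric`, `side`,
#'   `value`, `cutoff` and `exceeds_cutoff` (`value > cutoff`).
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_patients = 1, seed = 3))
#' p <- cohort_profiles(cohort)[[1]]
#' sfar(p, "R")
#' sifar(p, "R")
#' @export
sfar <- function(profile, side = c("R", "L"),
                 sheath_od_mm = sheath_14f()$nominal_od_mm) {
  side <- match.arg(side)
  d <- .vessel_diam(profile, paste0("CFA_", side))
  .ratio_result("SFAR", side, sheath_od_mm / d, cutoff = 1.05)
}

#' @rdname sfar
#' @export
sifar <- function(profile, side = c("R", "L"),
                  sheath_od_mm = sheath_14f()$nominal_od_mm) {
  side <- match.arg(side)
  d <- min(vapply(paste0(c("CFA_", "EIA_", "CIA_"), side),
                  function(v) .vessel_diam(profile, v), numeric(1)))
  .ratio_result("SIFAR", side, sheath_od_mm / d, cutoff = 0.95)
}

.vessel_diam <- function(profile, vessel_id) {
  ids <- vapply(profile$vessels, `[[`, character(1), "vessel_id")
  i <- match(vessel_id, ids)
  if (is.na(i)) stop(sprintf("vessel %s not present", vessel_id), call. = FALSE)
  d <- profile$vessels[[i]]$min_diameter_mm
  if (is.na(d) || d <= 0) {
    stop(sprintf("vessel %s: diameter must be a positive measurement",
                 vessel_id), call. = FALSE)
  }
  d
}

.ratio_result <- function(metric, side, value, cutoff) {
  structure(list(metric = metric, side = side, value = value,
                 cutoff = cutoff, exceeds_cutoff = value > cutoff),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("%s (%s): %.3f [cut-off %.2f%s]\n", x$metric, x$side, x$value,
              x$cutoff, if (x$exceeds_cutoff) ", exceeded" else ""))
  invisible(x)
}

#' Per-patient ratio table for a cohort
#'
#' @param cohort a cohort data frame.
#' @inheritParams sfar
#' @return data frame with per-side SFAR and SIFAR columns plus
#'   `sifar_best` (the smaller of the two sides, i.e. the ratio on the most
#'   favourable access side).
#' @export
cohort_ratios <- function(cohort, sheath_od_mm = sheath_14f()$nominal_od_mm) {
  stopifnot(nrow(cohort) > 0)
  sifar_side <- function(s) {
    sheath_od_mm / pmin(cohort[[paste0("CFA_", s, "_diam_mm")]],
                        cohort[[paste0("EIA_", s, "_diam_mm")]],
                        cohort[[paste0("CIA_", s, "_diam_mm")]])
  }
  out <- data.frame(
    patient_id = as.character(cohort$patient_id),
    sfar_R = sheath_od_mm / cohort$CFA_R_diam_mm,
    sfar_L = sheath_od_mm / cohort$CFA_L_diam_mm,
    sifar_R = sifar_side("R"),
    sifar_L = sifar_side("L"),
    stringsAsFactors = FALSE)
  out$sifar_best <- pmin(out$sifar_R, out$sifar_L)
  out
}

#' Fraction of a cohort whose best-side SIFAR exceeds the cut-off
#'
#' For each patient takes the access side with the smaller SIFAR (the side
#' an operator would choose) and reports the fraction of patients whose
#' ratio still exceeds the 0.95 vascular-complication cut-off.
#'
#' @inheritParams cohort_ratios
#' @param cutoff cut-off for the exceedance count (default 0.95).
#' @return a single fraction in \[0, 1\].
#' @export
cohort_sifar_exceedance <- function(cohort,
                                    sheath_od_mm = sheath_14f()$nominal_od_mm,
                                    cutoff = 0.95) {
  if (is.null(nrow(cohort)) || nrow(cohort) == 0L) {
    stop("empty cohort", call. = FALSE)
  }
  mean(cohort_ratios(cohort, sheath_od_mm)$sifar_best > cutoff)
}
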