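#' Six-level ordinal calcification grades
#'
#' Vascular calcification on CT is scored on two six-level ordinal scales:
#' the *degree* (D) scale grades the fraction of the vessel circumference
#' that is calcified at the site of minimal diameter (for the ascending
#' aorta, at the presumed sheath-insertion site), and the *range* (R) scale
#' grades the fraction of the vessel length involved. Both scales bin a
#' percentage `p` in \[0, 100\] into grades 0..5 with half-open intervals:
#' grade 0 iff `p == 0`, grade 1 for `0 < p <= 25`, grade 2 for
#' `25 < p <= 50`, grade 3 for `50 < p <= 75`, grade 4 for `75 < p < 100`,
#' and grade 5 iff `p == 100` (complete circumferential or full-length
#' calcification).
#'
#' @param level integer vector of grade levels in `0:5`.
#' @return `calc_grade()` returns its input as an integer vector after
#'   validation.
#' @examples
#' grade_from_percent(c(0, 25, 25.0001, 100))
#' @seealso [grade_from_percent()]
#' @export
calc_grade <- function(level) {
  lv <- suppressWarnings(as.integer(level))
  if (anyNA(lv) || any(lv != level) || any(lv < 0L | lv > 5L)) {
    stop("calcification grade levels must be integers in 0..5", call. = FALSE)
  }
  lv
}

#' Bin a calcification percentage into a grade
#'
#' @param p numeric vector of percentages in \[0, 100\] (not fractions).
#' @param scale `"D"` (degree, circumference) or `"R"` (range, length).
#'   The two scales share identical cut points; the argument records which
#'   scale the result belongs to (as attribute `scale`).
#' @return integer vector of grades in `0:5` with attribute `scale`.
#' @export
grade_from_percent <- function(p, scale = c("D", "R")) {
  scale <- match.arg(scale)
  if (!is.numeric(p) || anyNA(p)) {
    stop("p must be numeric with no missing values", call. = FALSE)
  }
  if (any(p < 0 | p > 100)) {
    stop("calcification percentage must lie in [0, 100]", call. = FALSE)
  }
  g <- 1L + findInterval(p, c(25, 50, 75), left.open = TRUE)
  g[p == 0] <- 0L
  g[p == 100] <- 5L
  structure(g, scale = scale)
}
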