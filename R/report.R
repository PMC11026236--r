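#' Round half away from zero
#'
#' Clinical tables round percentages half *away from zero* (31.25 -> 31.3),
#' unlike [round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Format a count with its percentage, "n (p)"
#'
#' Formats counts the way clinical cohort tables print them: the count
#' followed by the percentage of the denominator to one decimal, rounded
#' half away from zero, e.g. `format_count_pct(56, 72)` is `"56 (77.8)"`.
#' With `show_denominator = TRUE` the count is printed as `n/d`, the
#' convention for rows whose denominator is a subgroup rather than the
#' whole cohort (e.g. `"42/56 (75.0)"`).
#'
#' @param numerator,denominator nonnegative counts,
#'   `numerator <= denominator`, `denominator > 0`.
#' @param show_denominator print the denominator with the count.
#' @return character vector.
#' @export
format_count_pct <- function(numerator, denominator, show_denominator = FALSE) {
  if (any(denominator <= 0)) stop("denominator must be > 0", call. = FALSE)
  if (any(numerator < 0 | numerator > denominator)) {
    stop("numerator must lie in [0, denominator]", call. = FALSE)
  }
  pct <- round_half_away(100 * numerator / denominator, 1)
  if (show_denominator) {
    sprintf("%d/%d (%.1f)", numerator, denominator, pct)
  } else {
    sprintf("%d (%.1f)", numerator, pct)
  }
}

#' Summarize route assessments into a cohort table
#'
#' Tallies the per-patient flags of [assess_cohort()] into the standard
#' approach-simulation summary: TF suitability, bilateral and puncture
#' sub-rows (denominator: the TF-suitable subgroup), TC/TS/DA availability,
#' the desirable-for-alternative group, and within it the
#' preferable-to-avoid-TS and TA-only rows (denominator: the alternative
#' group). Under the fully-expanded criterion only the TF, bilateral, TC
#' and TS rows are reported. Because the printed puncture percentage in
#' this study design is ambiguous, the summary carries the puncture
#' fraction both of the TF-suitable subgroup and of the whole cohort.
#'
#' @param assessments a `tavi_assessments` data frame (all one criterion
#'   mode).
#' @return an object of class `cohort_summary`: the counts, the two
#'   puncture percentages, and `formatted`, a named character vector of
#'   "n (p)" rows.
#' @export
summarize_assessments <- function(assessments) {
  if (is.null(nrow(assessments)) || nrow(assessments) == 0L) {
    stop("no assessments to summarize", call. = FALSE)
  }
  mode <- unique(assessments$mode)
  if (length(mode) != 1L) {
    stop("assessments mix criterion modes; summarize one mode at a time",
         call. = FALSE)
  }
  n <- nrow(assessments)
  cnt <- function(flag) sum(assessments[[flag]])
  s <- list(
    n_total = n, mode = mode,
    n_tf_suitable = cnt("tf_suitable"),
    n_tf_bilateral = cnt("tf_bilateral"),
    n_puncture = cnt("puncture_feasible"),
    n_tc = cnt("tc_available"),
    n_ts = cnt("ts_available"),
    n_da = cnt("da_available"),
    n_alternative = cnt("alternative_desirable"),
    n_avoid_ts = sum(assessments$avoid_ts_flag &
                       assessments$alternative_desirable),
    n_ta_only = cnt("ta_only"))
  s$pct_puncture_of_tf <- if (s$n_tf_suitable > 0)
    round_half_away(100 * s$n_puncture / s$n_tf_suitable, 1) else NA_real_
  s$pct_puncture_of_cohort <- round_half_away(100 * s$n_puncture / n, 1)

  sub <- function(num, den) {
    if (den > 0) format_count_pct(num, den, show_denominator = TRUE)
    else NA_character_
  }
  fmt <- c(
    "Suitable for TF approach" = format_count_pct(s$n_tf_suitable, n),
    "Bilateral approach" = sub(s$n_tf_bilateral, s$n_tf_suitable))
  if (mode == "ifu") {
    fmt <- c(fmt,
      "Puncture approach" = sub(s$n_puncture, s$n_tf_suitable),
      "Available for TC approach" = format_count_pct(s$n_tc, n),
      "Available for TS approach" = format_count_pct(s$n_ts, n),
      "Available for DA approach" = format_count_pct(s$n_da, n),
      "Desirable for alternative approach" = format_count_pct(s$n_alternative, n),
      "Preferable to avoid TS approach" = if (s$n_alternative > 0)
        format_count_pct(s$n_avoid_ts, s$n_alternative) else NA_character_,
      "Available for only TA approach" = if (s$n_alternative > 0)
        format_count_pct(s$n_ta_only, s$n_alternative) else NA_character_)
  } else {
    fmt <- c(fmt,
      "Available for TC approach" = format_count_pct(s$n_tc, n),
      "Available for TS approach" = format_count_pct(s$n_ts, n))
  }
  s$formatted <- fmt
  structure(s, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("TAVI approach simulation (criterion: %s), N = %d\n",
              x$mode, x$n_total))
  w <- max(nchar(names(x$formatted)))
  for (i in seq_along(x$formatted)) {
    cat(sprintf("  %-*s n (%%)  %s\n", w, names(x$formatted)[i],
                x$formatted[i]))
  }
  invisible(x)
}

#' Calcification grade distribution of one vessel across a cohort
#'
#' @param cohort a cohort data frame.
#' @param vessel_id one of [vessel_ids()].
#' @param scale `"D"` (degree) or `"R"` (range).
#' @return an object of class `grade_distribution`: integer counts for
#'   grades 0..5 (summing to the cohort size), with the vessel and scale as
#'   attributes.
#' @export
grade_distribution <- function(cohort, vessel_id, scale = c("D", "R")) {
  scale <- match.arg(scale)
  if (is.null(nrow(cohort)) || nrow(cohort) == 0L) {
    stop("empty cohort", call. = FALSE)
  }
  if (!vessel_id %in% vessel_ids()) {
    stop(sprintf("unknown vessel '%s'", vessel_id), call. = FALSE)
  }
  g <- cohort[[paste0(vessel_id, "_", scale)]]
  counts <- vapply(0:5, function(k) sum(g == k, na.rm = TRUE), integer(1))
  structure(counts, names = paste0(scale, 0:5), vessel_id = vessel_id,
            scale = scale, n = nrow(cohort), class = "grade_distribution")
}

#' @export
print.grade_distribution <- function(x, ...) {
  cat(sprintf("%s %s-grade distribution (n = %d)\n", attr(x, "vessel_id"),
              attr(x, "scale"), attr(x, "n")))
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' @export
plot.grade_distribution <- function(x, ...) {
  graphics::barplot(as.integer(x) / attr(x, "n") * 100, names.arg = names(x),
                    ylab = "patients (%)",
                    main = sprintf("%s calcification (%s scale)",
                                   attr(x, "vessel_id"), attr(x, "scale")),
                    ...)
  invisible(x)
}

#' Unadjusted odds ratio of a 2x2 table
#'
#' Cross-product odds ratio `(a d) / (b c)` with the Haldane--Anscombe
#' correction (0.5 added to every cell) applied whenever any cell is zero.
#' Orientation used for the LEAD analysis: rows are exposure (LEAD yes/no),
#' columns are outcome (TF-unsuitable yes/no), so `a` = LEAD and
#' TF-unsuitable.
#'
#' @param a,b,c,d nonnegative cell counts.
#' @return positive odds ratio.
#' @export
unadjusted_odds_ratio <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be nonnegative", call. = FALSE)
  if (all(cells == 0)) stop("all cells are zero", call. = FALSE)
  if (any(cells == 0)) cells <- cells + 0.5
  (cells[1] * cells[4]) / (cells[2] * cells[3])
}

#' LEAD vs transfemoral-unsuitability 2x2 table and odds ratio
#'
#' @param assessments a `tavi_assessments` data frame (carries the `lead`
#'   flag through from the cohort).
#' @return list with the 2x2 `table` (rows LEAD yes/no, columns
#'   TF-unsuitable yes/no) and the unadjusted `odds_ratio`.
#' @export
lead_tf_odds <- function(assessments) {
  unsuit <- !assessments$tf_suitable
  lead <- assessments$lead
  tab <- matrix(c(sum(lead & unsuit), sum(lead & !unsuit),
                  sum(!lead & unsuit), sum(!lead & !unsuit)),
                nrow = 2, byrow = TRUE,
                dimnames = list(LEAD = c("yes", "no"),
                                TF_unsuitable = c("yes", "no")))
  list(table = tab,
       odds_ratio = unadjusted_odds_ratio(tab[1, 1], tab[1, 2],
                                          tab[2, 1], tab[2, 2]))
}

#' Descriptive subgroup comparison by transfemoral suitability
#'
#' Group means (age, body surface area) and medians (hemodialysis
#' duration) plus LEAD counts for the TF-suitable and TF-unsuitable
#' subgroups. Descriptive only: no hypothesis tests.
#'
#' @param cohort a cohort data frame.
#' @param assessments the matching `tavi_assessments` (same patient order).
#' @return data frame, one row per subgroup.
#' @export
subgroup_summary <- function(cohort, assessments) {
  stopifnot(nrow(cohort) == nrow(assessments),
            all(cohort$patient_id == assessments$patient_id))
  grp <- ifelse(assessments$tf_suitable, "TF-suitable", "TF-unsuitable")
  one <- function(g) {
    i <- grp == g
    data.frame(group = g, n = sum(i),
               mean_age_years = mean(cohort$age_years[i]),
               mean_bsa_m2 = mean(cohort$bsa_m2[i]),
               median_hd_duration_years =
                 stats::median(cohort$hd_duration_years[i]),
               n_lead = sum(cohort$lead[i]),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(unique(c("TF-suitable", "TF-unsuitable")), one))
}
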