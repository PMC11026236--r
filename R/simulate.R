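#' Configuration for the synthetic hemodialysis cohort generator
#'
#' Returns a generator configuration whose marginal targets encode the
#' vascular-calcification structure observed in elderly hemodialysis
#' patients with aortic stenosis: heavily calcified common iliac arteries
#' and abdominal aorta, nearly calcification-free common carotids, mildly
#' calcified common femoral arteries (about 70% at degree <= 1), about 20%
#' of left subclavian arteries at degree >= 3, an ascending aorta with no
#' or minor insertion-site calcification in about 88% of patients, and
#' external iliacs strictly less calcified than the common iliacs. Common
#' iliac mean minimal diameters default to 7.3 mm (right) and 7.0 mm
#' (left).
#'
#' @param n_patients cohort size (default 72).
#' @param seed integer seed; all randomness in [simulate_cohort()] flows
#'   from it.
#' @param lead_prevalence prevalence of lower extremity artery disease
#'   (default 0.181).
#' @param lead_calc_shift nonnegative integer grade shift added to the
#'   iliofemoral (CIA/EIA/CFA) degree grades of LEAD patients, capped at 5
#'   (default 1).
#' @param diameter_calc_correlation correlation in \[-1, 0\] between the
#'   latent diameter and latent calcification variables of each vessel
#'   (Gaussian-copula coupling; default -0.4, i.e. more calcified vessels
#'   tend to be narrower).
#' @param insertion_zone_clear_prob probability that the ascending-aorta
#'   cannulation zone is free of calcification and atheroma (default 0.88).
#' @param puncture_calc_prob length-6 vector: probability of calcification
#'   on the anterior (and, independently, the lateral) side of the femoral
#'   puncture site given the common femoral degree grade 0..5.
#' @param access_side_probs named probabilities of the hemodialysis access
#'   side; defaults to predominantly left-sided access.
#' @param vessel_params named list (one entry per vessel) of
#'   `diam_mean`/`diam_sd` (mm; `NA` for the ascending aorta, excluded from
#'   the diameter assessment) and length-6 `d_probs`/`r_probs` categorical
#'   grade probabilities. Defaults encode the marginals described above.
#' @param demographics list of demographic parameters: age is normal
#'   (mean 72.2, SD 7.3) truncated to \[40, 95\] years, male fraction
#'   0.597, body surface area normal (1.4, 0.2) truncated to
#'   \[0.9, 2.2\] m^2, hemodialysis duration log-normal fitted at
#'   construction time to median 9 and quartiles \[4, 16\] years.
#' @param diam_floor_mm truncation floor for sampled diameters (0.5 mm).
#' @return a list of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_patients = 72L, seed = 1L,
                          lead_prevalence = 0.181,
                          lead_calc_shift = 1L,
                          diameter_calc_correlation = -0.4,
                          insertion_zone_clear_prob = 0.88,
                          puncture_calc_prob = c(0.02, 0.10, 0.30, 0.55, 0.75, 0.90),
                          access_side_probs = c(left = 0.90, right = 0.08, other = 0.02),
                          vessel_params = default_vessel_params(),
                          demographics = list(
                            age_mean = 72.2, age_sd = 7.3,
                            age_range = c(40, 95),
                            male_prob = 0.597,
                            bsa_mean = 1.4, bsa_sd = 0.2,
                            bsa_range = c(0.9, 2.2),
                            hd_quartiles = c(4, 9, 16)),
                          diam_floor_mm = 0.5) {
  stopifnot(n_patients >= 1, length(seed) == 1L,
            lead_prevalence >= 0, lead_prevalence <= 1,
            lead_calc_shift >= 0, lead_calc_shift == as.integer(lead_calc_shift),
            diameter_calc_correlation >= -1, diameter_calc_correlation <= 0,
            insertion_zone_clear_prob >= 0, insertion_zone_clear_prob <= 1,
            length(puncture_calc_prob) == 6L,
            all(puncture_calc_prob >= 0 & puncture_calc_prob <= 1))
  .check_probs(access_side_probs, "access_side_probs")
  if (!setequal(names(vessel_params), vessel_ids())) {
    stop("vessel_params must have one entry per vessel", call. = FALSE)
  }
  for (v in names(vessel_params)) {
    .check_probs(vessel_params[[v]]$d_probs, paste0(v, " d_probs"), 6L)
    .check_probs(vessel_params[[v]]$r_probs, paste0(v, " r_probs"), 6L)
  }
  hd <- demographics$hd_quartiles
  lnorm <- .fit_lognormal_quartiles(hd[1], hd[2], hd[3])
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         lead_prevalence = lead_prevalence,
         lead_calc_shift = as.integer(lead_calc_shift),
         diameter_calc_correlation = diameter_calc_correlation,
         insertion_zone_clear_prob = insertion_zone_clear_prob,
         puncture_calc_prob = puncture_calc_prob,
         access_side_probs = access_side_probs,
         vessel_params = vessel_params,
         demographics = demographics,
         hd_lognormal = lnorm,
         diam_floor_mm = diam_floor_mm),
    class = "cohort_config"
  )
}

.check_probs <- function(p, what, len = NULL) {
  if (!is.numeric(p) || (!is.null(len) && length(p) != len) || any(p < 0)) {
    stop(what, " must be a nonnegative probability vector", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop(what, " must sum to 1 (within 1e-9)", call. = FALSE)
  }
}

# Least-squares fit of log-normal meanlog/sdlog to three quartiles
# (q25, q50, q75) on the log scale.
.fit_lognormal_quartiles <- function(q1, med, q3) {
  stopifnot(q1 > 0, med > q1, q3 > med)
  z <- stats::qnorm(0.75)
  list(meanlog = mean(log(c(q1, med, q3))),
       sdlog = (log(q3) - log(q1)) / (2 * z))
}

#' @rdname cohort_config
#' @details `default_vessel_params()` returns the per-vessel diameter and
#'   grade-probability defaults. The right/left common iliac diameter means
#'   are 7.3 and 7.0 mm; degree probabilities give P(degree >= 3) = 0.5 for
#'   the common iliacs, P(degree in \{4,5\}) = 0.5 for the abdominal aorta,
#'   P(degree = 0) = 0.95 for the carotids, P(degree >= 3) = 0.2 for the
#'   left subclavian, P(degree <= 1) = 0.7 for the common femorals and
#'   P(degree <= 1) = 0.88 for the ascending aorta; range probabilities give
#'   P(range >= 4) = 0.6 for the common iliacs and abdominal aorta and
#'   P(range >= 3) = 0.5 for the common femorals. The external iliac grade
#'   distributions are strictly stochastically smaller than the common
#'   iliac ones.
#' @export
default_vessel_params <- function() {
  vp <- function(mean, sd, d, r) {
    list(diam_mean = mean, diam_sd = sd, d_probs = d, r_probs = r)
  }
  cia_d <- c(0.10, 0.20, 0.20, 0.25, 0.15, 0.10)
  cia_r <- c(0.05, 0.10, 0.10, 0.15, 0.30, 0.30)
  eia_d <- c(0.30, 0.25, 0.20, 0.12, 0.08, 0.05)
  eia_r <- c(0.20, 0.25, 0.20, 0.15, 0.12, 0.08)
  cfa_d <- c(0.35, 0.35, 0.15, 0.08, 0.05, 0.02)
  cfa_r <- c(0.15, 0.20, 0.15, 0.25, 0.15, 0.10)
  cca_d <- c(0.95, 0.03, 0.01, 0.005, 0.003, 0.002)
  asc_d <- c(0.55, 0.33, 0.06, 0.03, 0.02, 0.01)
  list(
    AscAo = vp(NA, NA, asc_d, asc_d),
    CCA_R = vp(6.8, 0.9, cca_d, cca_d),
    CCA_L = vp(6.7, 0.9, cca_d, cca_d),
    LSA   = vp(8.6, 1.3, c(0.35, 0.25, 0.20, 0.10, 0.06, 0.04),
                          c(0.40, 0.25, 0.15, 0.10, 0.06, 0.04)),
    AbdAo = vp(14.0, 2.5, c(0.05, 0.15, 0.15, 0.15, 0.30, 0.20),
                          c(0.05, 0.10, 0.10, 0.15, 0.35, 0.25)),
    CIA_R = vp(7.3, 1.5, cia_d, cia_r),
    CIA_L = vp(7.0, 1.5, cia_d, cia_r),
    EIA_R = vp(6.9, 1.1, eia_d, eia_r),
    EIA_L = vp(6.7, 1.1, eia_d, eia_r),
    CFA_R = vp(7.2, 1.2, cfa_d, cfa_r),
    CFA_L = vp(7.1, 1.2, cfa_d, cfa_r)
  )
}

# inverse-CDF draw from a length-6 categorical given uniforms in (0,1)
.cat_from_u <- function(u, probs) {
  cum <- cumsum(probs)
  cum[length(cum)] <- 1
  pmin(findInterval(u, cum, left.open = TRUE), 5L)
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic hemodialysis cohort
#'
#' Draws a cohort of patient vascular profiles from the configured marginal
#' distributions. Within each vessel, the minimum diameter and the
#' calcification grades are coupled through a shared standard-normal latent
#' pair with the configured (negative) correlation: the degree and range
#' grades are read off their categorical inverse CDFs at the same latent
#' quantile, so marginal grade probabilities are preserved exactly while
#' narrower vessels tend to be more calcified. LEAD patients then receive
#' the configured upward shift of their iliofemoral degree grades (capped
#' at grade 5), and femoral puncture-site calcification is drawn
#' conditionally on the resulting common femoral degree grade.
#'
#' @param config a [cohort_config()].
#' @param seed optional override of `config$seed`.
#' @return a cohort data frame of class `c("tavi_cohort", "data.frame")`,
#'   one row per patient, in the cohort CSV schema; every row passes
#'   [validate_profile()]. Deterministic given `(config, seed)`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_patients = 10, seed = 7))
#' summary(assess_cohort(cohort))
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  if (!inherits(config, "cohort_config")) {
    stop("config must be a cohort_config", call. = FALSE)
  }
  n <- config$n_patients
  dem <- config$demographics
  set.seed(seed)

  df <- data.frame(
    patient_id = sprintf("HD%04d", seq_len(n)),
    age_years = round(.rtruncnorm(n, dem$age_mean, dem$age_sd,
                                  dem$age_range[1], dem$age_range[2]), 1),
    sex = ifelse(stats::runif(n) < dem$male_prob, "male", "female"),
    bsa_m2 = round(.rtruncnorm(n, dem$bsa_mean, dem$bsa_sd,
                               dem$bsa_range[1], dem$bsa_range[2]), 2),
    hd_duration_years = round(stats::rlnorm(n, config$hd_lognormal$meanlog,
                                            config$hd_lognormal$sdlog), 1),
    lead = stats::runif(n) < config$lead_prevalence,
    hd_access_side = sample(names(config$access_side_probs), n,
                            replace = TRUE, prob = config$access_side_probs),
    asc_ao_insertion_zone_clear =
      stats::runif(n) < config$insertion_zone_clear_prob,
    stringsAsFactors = FALSE)

  rho <- config$diameter_calc_correlation
  for (v in vessel_ids()) {
    pars <- config$vessel_params[[v]]
    z_diam <- stats::rnorm(n)
    z_ind <- stats::rnorm(n)
    z_calc <- rho * z_diam + sqrt(1 - rho^2) * z_ind
    u_calc <- stats::pnorm(z_calc)
    df[[paste0(v, "_diam_mm")]] <- if (is.na(pars$diam_mean)) NA_real_ else
      round(pmax(config$diam_floor_mm,
                 pars$diam_mean + pars$diam_sd * z_diam), 1)
    df[[paste0(v, "_D")]] <- .cat_from_u(u_calc, pars$d_probs)
    df[[paste0(v, "_R")]] <- .cat_from_u(u_calc, pars$r_probs)
  }

  # LEAD: extra iliofemoral degree burden
  if (config$lead_calc_shift > 0L && any(df$lead)) {
    for (v in c("CIA_R", "CIA_L", "EIA_R", "EIA_L", "CFA_R", "CFA_L")) {
      col <- paste0(v, "_D")
      df[[col]][df$lead] <- pmin(5L, df[[col]][df$lead] + config$lead_calc_shift)
    }
  }

  for (s in c("R", "L")) {
    p <- config$puncture_calc_prob[df[[paste0("CFA_", s, "_D")]] + 1L]
    df[[paste0("cfa_puncture_calc_anterior_", s)]] <- stats::runif(n) < p
    df[[paste0("cfa_puncture_calc_lateral_", s)]] <- stats::runif(n) < p
  }

  df <- df[, cohort_columns()]
  class(df) <- c("tavi_cohort", "data.frame")
  df
}
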