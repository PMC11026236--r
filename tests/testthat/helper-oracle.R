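# Independent brute-force oracles and fixture builders.
# These deliberately re-derive the rules in plain scalar if/else form,
# sharing no code with the package internals they check.

# -- scalar rule oracle -------------------------------------------------

oracle_required <- function(grade, mode) {
  if (mode == "expanded") {
    7.6
  } else if (grade == 0 || grade == 1 || grade == 2) {
    5.5
  } else {
    7.6
  }
}

oracle_vessel_passes <- function(diam, grade, mode) {
  diam > oracle_required(grade, mode)
}

# chain: list of c(diam, grade) pairs in distal-to-proximal order
oracle_chain_feasible <- function(chain, mode) {
  for (v in chain) {
    if (!oracle_vessel_passes(v[1], v[2], mode)) return(FALSE)
  }
  TRUE
}

oracle_chain_limiting <- function(chain, names, mode) {
  for (i in seq_along(chain)) {
    if (!oracle_vessel_passes(chain[[i]][1], chain[[i]][2], mode)) {
      return(names[i])
    }
  }
  NA_character_
}

oracle_da <- function(zone_clear, asc_degree) {
  isTRUE(zone_clear) && asc_degree == 0
}

# -- exact decimal formatting oracle ------------------------------------

# percentage of n/d to one decimal, half away from zero, in pure integer
# arithmetic: floor((2000 n + d) / (2 d)) / 10
oracle_pct_1dp <- function(n, d) {
  ((2000 * n + d) %/% (2 * d)) / 10
}

# -- fixture builders ---------------------------------------------------

# one-row cohort data frame; every vessel wide (9 mm) and clean (grade 0)
# unless overridden. diam/D/R are named vectors of per-vessel overrides.
base_cohort_row <- function(patient_id = "T01", diam = NULL, D = NULL,
                            R = NULL, zone_clear = TRUE,
                            punct_ant_R = FALSE, punct_ant_L = FALSE,
                            punct_lat_R = FALSE, punct_lat_L = FALSE,
                            hd_access_side = "left", lead = FALSE) {
  df <- data.frame(
    patient_id = patient_id, age_years = 72, sex = "male", bsa_m2 = 1.5,
    hd_duration_years = 9, lead = lead, hd_access_side = hd_access_side,
    asc_ao_insertion_zone_clear = zone_clear,
    cfa_puncture_calc_anterior_R = punct_ant_R,
    cfa_puncture_calc_anterior_L = punct_ant_L,
    cfa_puncture_calc_lateral_R = punct_lat_R,
    cfa_puncture_calc_lateral_L = punct_lat_L,
    stringsAsFactors = FALSE)
  for (v in vessel_ids()) {
    df[[paste0(v, "_diam_mm")]] <- if (v == "AscAo") NA_real_ else 9.0
    df[[paste0(v, "_D")]] <- 0L
    df[[paste0(v, "_R")]] <- 0L
  }
  for (v in names(diam)) df[[paste0(v, "_diam_mm")]] <- diam[[v]]
  for (v in names(D)) df[[paste0(v, "_D")]] <- as.integer(D[[v]])
  for (v in names(R)) df[[paste0(v, "_R")]] <- as.integer(R[[v]])
  class(df) <- c("tavi_cohort", "data.frame")
  df
}

base_profile <- function(...) cohort_profiles(base_cohort_row(...))[[1]]

# random cohorts for property tests (independent of simulate_cohort)
random_cohort <- function(n, seed) {
  set.seed(seed)
  df <- data.frame(
    patient_id = sprintf("R%05d", seq_len(n)),
    age_years = 72, sex = "male", bsa_m2 = 1.5, hd_duration_years = 9,
    lead = runif(n) < 0.2,
    hd_access_side = sample(c("left", "right", "other"), n, TRUE),
    asc_ao_insertion_zone_clear = runif(n) < 0.6,
    cfa_puncture_calc_anterior_R = runif(n) < 0.3,
    cfa_puncture_calc_anterior_L = runif(n) < 0.3,
    cfa_puncture_calc_lateral_R = runif(n) < 0.3,
    cfa_puncture_calc_lateral_L = runif(n) < 0.3,
    stringsAsFactors = FALSE)
  for (v in vessel_ids()) {
    df[[paste0(v, "_diam_mm")]] <- if (v == "AscAo") NA_real_ else
      round(runif(n, 4, 10), 2)
    df[[paste0(v, "_D")]] <- sample(0:5, n, TRUE)
    df[[paste0(v, "_R")]] <- sample(0:5, n, TRUE)
  }
  class(df) <- c("tavi_cohort", "data.frame")
  df
}
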