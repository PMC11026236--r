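#' Read and write cohort CSV files
#'
#' The cohort interchange format is a UTF-8 CSV with one row per patient and
#' columns `patient_id, age_years, sex, bsa_m2, hd_duration_years, lead,
#' hd_access_side, asc_ao_insertion_zone_clear`, the four femoral
#' puncture-site booleans, and `<vessel>_diam_mm, <vessel>_D, <vessel>_R`
#' for each of the eleven vessels. A missing ascending-aorta diameter is
#' encoded as an empty field. `read_cohort_csv()` validates the schema
#' (missing columns are named), parses cells (unparsable cells are reported
#' with their file line), and validates every patient record.
#'
#' @param path file path.
#' @return `read_cohort_csv()` returns a `tavi_cohort` data frame;
#'   `write_cohort_csv()` invisibly returns `path`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""), colClasses = "character")
  missing <- setdiff(cohort_columns(), names(df))
  if (length(missing)) {
    stop("cohort CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, cohort_columns()]
  if (nrow(df) == 0L) {
    warning("cohort CSV has a header but no rows", call. = FALSE)
    class(df) <- c("tavi_cohort", "data.frame")
    return(df)
  }
  num_cols <- c("age_years", "bsa_m2", "hd_duration_years",
                paste0(vessel_ids(), "_diam_mm"))
  int_cols <- as.vector(outer(vessel_ids(), c("_D", "_R"), paste0))
  lgl_cols <- c("lead", "asc_ao_insertion_zone_clear",
                "cfa_puncture_calc_anterior_R", "cfa_puncture_calc_anterior_L",
                "cfa_puncture_calc_lateral_R", "cfa_puncture_calc_lateral_L")
  parse_col <- function(col, fn, what) {
    raw <- df[[col]]
    val <- fn(raw)
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad)) {
      stop(sprintf("cannot parse %s value '%s' in column %s (file line %d)",
                   what, raw[bad[1]], col, bad[1] + 1L), call. = FALSE)
    }
    val
  }
  for (col in num_cols) {
    df[[col]] <- parse_col(col, function(x) suppressWarnings(as.numeric(x)),
                           "numeric")
  }
  for (col in int_cols) {
    df[[col]] <- parse_col(col, function(x) suppressWarnings(as.integer(x)),
                           "integer")
  }
  for (col in lgl_cols) {
    df[[col]] <- parse_col(col, function(x) as.logical(x), "logical")
  }
  class(df) <- c("tavi_cohort", "data.frame")
  viol <- validate_cohort(df)
  if (nrow(viol)) {
    msgs <- sprintf("line %d (%s): %s", viol$row + 1L, viol$patient_id,
                    viol$message)
    stop("invalid patient record(s):\n  ", paste(msgs, collapse = "\n  "),
         call. = FALSE)
  }
  df
}

#' @rdname read_cohort_csv
#' @param cohort a cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[, cohort_columns()], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

.config_hash <- function(config) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(unclass(config)), f)
  unname(tools::md5sum(f))
}

#' Write and read route assessments
#'
#' CSV preserves the flat assessment table; JSON additionally carries a
#' provenance block (package version, seed, and a hash plus echo of the
#' generator or run configuration when supplied). Output is deterministic:
#' identical inputs yield byte-identical files.
#'
#' @param assessments a `tavi_assessments` data frame.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @param seed optional seed to record in the JSON provenance.
#' @param config optional configuration object echoed into the provenance.
#' @return invisibly, `path`.
#' @export
write_assessments <- function(assessments, path, format = c("csv", "json"),
                              seed = NULL, config = NULL) {
  format <- match.arg(format)
  if (is.null(nrow(assessments)) || nrow(assessments) == 0L) {
    stop("no assessments to write", call. = FALSE)
  }
  if (format == "csv") {
    utils::write.csv(as.data.frame(assessments), path, row.names = FALSE,
                     na = "")
  } else {
    payload <- list(
      provenance = list(
        package = "tavisim",
        version = as.character(utils::packageVersion("tavisim")),
        seed = seed,
        config_hash = if (!is.null(config)) .config_hash(config) else NULL,
        config = if (!is.null(config)) unclass(config) else NULL),
      assessments = as.data.frame(assessments))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_assessments
#' @export
read_assessments <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  } else {
    df <- as.data.frame(jsonlite::read_json(path,
                                            simplifyVector = TRUE)$assessments)
  }
  df$patient_id <- as.character(df$patient_id)
  for (col in grep("_limiting_vessel$", names(df), value = TRUE)) {
    df[[col]] <- as.character(df[[col]])
  }
  for (col in c(grep("_feasible$", names(df), value = TRUE),
                intersect(c("tf_suitable", "tf_bilateral", "tc_available",
                            "ts_available", "da_available",
                            "alternative_desirable", "avoid_ts_flag",
                            "ta_only", "lead"), names(df)))) {
    df[[col]] <- as.logical(df[[col]])
  }
  class(df) <- c("tavi_assessments", "data.frame")
  df
}

#' Pipeline run configuration
#'
#' A small serializable record of everything a classification run depends
#' on: the criterion mode, the sheath, the transfemoral-chain and avoid-TS
#' options, input/output paths, the seed, and the log level. Round-trips
#' losslessly through YAML.
#'
#' @param mode `"ifu"` or `"expanded"`.
#' @param sheath `"14F"` or `"16F"` (named device; resolved with
#'   [sheath_14f()] / [sheath_16f()]).
#' @param include_abdao include the abdominal aorta in the transfemoral
#'   chain.
#' @param avoid_ts_rule `"left_access"` or `"off"`.
#' @param input,output file paths (may be `NA`).
#' @param seed integer seed or `NA`.
#' @param log_level one of `"quiet"`, `"info"`, `"debug"`.
#' @return a list of class `run_config`.
#' @export
run_config <- function(mode = c("ifu", "expanded"), sheath = c("14F", "16F"),
                       include_abdao = TRUE,
                       avoid_ts_rule = c("left_access", "off"),
                       input = NA_character_, output = NA_character_,
                       seed = NA_integer_,
                       log_level = c("info", "quiet", "debug")) {
  structure(list(mode = match.arg(mode), sheath = match.arg(sheath),
                 include_abdao = isTRUE(include_abdao),
                 avoid_ts_rule = match.arg(avoid_ts_rule),
                 input = as.character(input), output = as.character(output),
                 seed = if (is.na(seed)) NA_integer_ else as.integer(seed),
                 log_level = match.arg(log_level)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  writeLines(yaml::as.yaml(unclass(config)), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(mode = x$mode, sheath = x$sheath,
             include_abdao = x$include_abdao,
             avoid_ts_rule = x$avoid_ts_rule,
             input = if (is.null(x$input)) NA_character_ else x$input,
             output = if (is.null(x$output)) NA_character_ else x$output,
             seed = if (is.null(x$seed) || is.na(x$seed)) NA_integer_
                    else x$seed,
             log_level = x$log_level)
}

#' Resolve a sheath name from a run configuration
#' @param name `"14F"` or `"16F"`.
#' @return a [sheath_spec()].
#' @export
resolve_sheath <- function(name) {
  switch(name, "14F" = sheath_14f(), "16F" = sheath_16f(),
         stop("unknown sheath '", name, "'", call. = FALSE))
}
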