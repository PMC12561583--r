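#' Construct and validate a joint-angle trial
#'
#' An `angle_trial` is one sampled movement cycle: a strictly increasing,
#' uniformly spaced time base and one angle series per named joint (sagittal
#' plane, degrees, relative to the joint's neutral position — the package
#' imposes no anatomical sign convention).
#'
#' @param time Time stamps in seconds, strictly increasing, uniform spacing
#'   (relative tolerance 1e-6), length >= 8.
#' @param angles Named list of numeric angle series (degrees), one per joint,
#'   each the same length as `time`, no missing values.
#' @param subject_id Opaque subject label.
#' @param group One of `"control"`, `"test"`, `"target"`.
#' @param stage One of `"pre"`, `"post"`, `"single"`.
#' @param trial_index Positive integer.
#' @return An `angle_trial` object (list with the fields above plus
#'   `sample_rate` in Hz).
#' @export
angle_trial <- function(time, angles, subject_id = "s1", group = "control",
                        stage = "pre", trial_index = 1L) {
  group <- match.arg(group, c("control", "test", "target"))
  stage <- match.arg(stage, c("pre", "post", "single"))
  stopifnot(is.numeric(time), is.list(angles), length(angles) >= 1L,
            !is.null(names(angles)))
  if (length(time) < 8L) {
    stop("trial must have at least 8 samples, got ", length(time), call. = FALSE)
  }
  if (anyNA(time) || any(diff(time) <= 0)) {
    stop("time must be strictly increasing with no missing values", call. = FALSE)
  }
  dts <- diff(time)
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > 1e-6 * dt) {
    stop("time samples are not uniformly spaced (relative tolerance 1e-6)",
         call. = FALSE)
  }
  for (j in names(angles)) {
    a <- angles[[j]]
    if (length(a) != length(time)) {
      stop("angle series '", j, "' has length ", length(a),
           " but time has length ", length(time), call. = FALSE)
    }
    bad <- which(!is.finite(a))
    if (length(bad) > 0L) {
      stop("angle series '", j, "' has missing/non-finite values at rows ",
           paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
    }
  }
  trial_index <- as.integer(trial_index)
  stopifnot(!is.na(trial_index), trial_index >= 1L)
  structure(
    list(
      subject_id = as.character(subject_id), group = group, stage = stage,
      trial_index = trial_index, sample_rate = 1 / dt,
      time = as.numeric(time), angles = lapply(angles, as.numeric)
    ),
    class = "angle_trial"
  )
}

#' @export
print.angle_trial <- function(x, ...) {
  cat(sprintf(
    "<angle_trial> subject %s | %s/%s | trial %d | %d samples @ %.6g Hz | joints: %s\n",
    x$subject_id, x$group, x$stage, x$trial_index, length(x$time),
    x$sample_rate, paste(names(x$angles), collapse = ", ")
  ))
  invisible(x)
}

#' Read a trial table from CSV
#'
#' The on-disk dialect is comma-delimited UTF-8 with a header row: a `time_s`
#' column (seconds) plus one column per joint, named by the joint label, in
#' degrees.
#'
#' @param path CSV file path.
#' @param subject_id,group,stage,trial_index Trial metadata (the file carries
#'   only the series).
#' @param required_joints Joints that must be present (default ankle, knee,
#'   pelvis); a missing column is a schema error naming the column.
#' @return An [angle_trial()].
#' @export
read_trial_table <- function(path, subject_id = "s1", group = "control",
                             stage = "pre", trial_index = 1L,
                             required_joints = c("ankle", "knee", "pelvis")) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"time_s" %in% names(df)) {
    stop("schema error in ", path, ": missing required column 'time_s'",
         call. = FALSE)
  }
  joints <- setdiff(names(df), "time_s")
  missing_joints <- setdiff(required_joints, joints)
  if (length(missing_joints) > 0L) {
    stop("schema error in ", path, ": missing required joint column(s): ",
         paste(missing_joints, collapse = ", "), call. = FALSE)
  }
  na_rows <- which(rowSums(is.na(df)) > 0)
  if (length(na_rows) > 0L) {
    stop("validation error in ", path, ": NaN/missing cells at rows ",
         paste(utils::head(na_rows, 10L), collapse = ", "), call. = FALSE)
  }
  angle_trial(
    time = df$time_s,
    angles = as.list(df[joints]),
    subject_id = subject_id, group = group, stage = stage,
    trial_index = trial_index
  )
}

#' Write a trial table to CSV
#'
#' Inverse of [read_trial_table()]: full double precision is preserved, so a
#' write/read round trip reproduces the numeric payload to at least 12
#' significant digits.
#'
#' @param trial An [angle_trial()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trial, path) {
  stopifnot(inherits(trial, "angle_trial"))
  df <- tibble::as_tibble(c(list(time_s = trial$time), trial$angles))
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' Manifest columns: `subject_id`, `group`, `stage`, `trial_path`, `age_y`,
#' `height_m`, `weight_kg` (one row per trial file). BMI (kg/m^2) is computed
#' on load. Target-group records must have stage `"single"`; duplicate
#' (subject, stage, trial_path) rows are rejected.
#'
#' @param path Manifest CSV path.
#' @return A `cohort_manifest`: tibble of records with a `bmi` column and a
#'   `group_counts` attribute (distinct subjects per group).
#' @export
read_manifest <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "group", "stage", "trial_path",
                "age_y", "height_m", "weight_kg")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop("schema error in ", path, ": missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  validate_manifest(df)
}

#' Validate a manifest table (adds BMI and group counts)
#'
#' @param df Data frame with the manifest columns.
#' @return A `cohort_manifest` tibble.
#' @export
validate_manifest <- function(df) {
  df <- tibble::as_tibble(df)
  bad_group <- setdiff(unique(df$group), c("control", "test", "target"))
  if (length(bad_group) > 0L) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  bad_stage <- setdiff(unique(df$stage), c("pre", "post", "single"))
  if (length(bad_stage) > 0L) {
    stop("unknown stage label(s): ", paste(bad_stage, collapse = ", "),
         call. = FALSE)
  }
  offender <- df$group == "target" & df$stage != "single"
  if (any(offender)) {
    stop("validation error: target-group records must have stage 'single' (rows ",
         paste(which(offender), collapse = ", "), ")", call. = FALSE)
  }
  key <- paste(df$subject_id, df$stage, df$trial_path, sep = "\r")
  if (anyDuplicated(key)) {
    stop("validation error: duplicate (subject, stage, trial) records",
         call. = FALSE)
  }
  df$bmi <- compute_bmi(df$weight_kg, df$height_m)
  counts <- vapply(
    split(df$subject_id, df$group),
    function(s) length(unique(s)), integer(1)
  )
  structure(df, class = c("cohort_manifest", class(df)), group_counts = counts)
}

#' Body mass index
#'
#' @param weight_kg Weight in kilograms.
#' @param height_m Height in metres (> 0).
#' @return BMI in kg/m^2, `weight_kg / height_m^2`.
#' @export
compute_bmi <- function(weight_kg, height_m) {
  stopifnot(all(height_m > 0))
  weight_kg / height_m^2
}

#' Write the group-level coordination metrics table
#'
#' Summarises per-subject metrics into one row per (group, stage, coupling)
#' with the group mean and between-subject sample SD of MARP and DP, in plain
#' numeric columns (no "mean (SD)" strings), sorted deterministically by
#' (group, stage, coupling). The SD columns are empty where a cell has a
#' single subject.
#'
#' @param metrics Tibble of per-subject metrics from [cohort_metrics()]
#'   (non-empty).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(metrics, path) {
  if (is.null(metrics) || nrow(metrics) == 0L) {
    stop("empty metrics collection", call. = FALSE)
  }
  out <- dplyr::arrange(group_summary(metrics), .data$group, .data$stage,
                        .data$coupling)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Analysis configuration
#'
#' @param couplings List of `c(distal, proximal)` character pairs; default the
#'   ankle-knee and knee-pelvis couplings of the lower limb.
#' @param n_cycle_points Cycle grid size N (>= 11), default 101.
#' @param angle_unit_out `"degrees"` (default) or `"radians"` for reported
#'   MARP/DP.
#' @param alpha Significance threshold in (0, 1), default 0.05.
#' @param posthoc_correction `"none"` (default, matches unadjusted pairwise
#'   t-tests) or `"bonferroni"`.
#' @param variance_policy `"pooled"` (default), `"welch"`, or `"auto_levene"`
#'   (Welch when Levene rejects at `alpha`).
#' @param seed Optional integer seed recorded with the run.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(couplings = list(c("ankle", "knee"), c("knee", "pelvis")),
                            n_cycle_points = 101L,
                            angle_unit_out = c("degrees", "radians"),
                            alpha = 0.05,
                            posthoc_correction = c("none", "bonferroni"),
                            variance_policy = c("pooled", "welch", "auto_levene"),
                            seed = NULL) {
  angle_unit_out <- match.arg(angle_unit_out)
  posthoc_correction <- match.arg(posthoc_correction)
  variance_policy <- match.arg(variance_policy)
  if (length(couplings) == 0L) stop("couplings must be non-empty", call. = FALSE)
  stopifnot(all(vapply(couplings, length, integer(1)) == 2L))
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1)) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  n_cycle_points <- as.integer(n_cycle_points)
  if (is.na(n_cycle_points) || n_cycle_points < 11L) {
    stop("n_cycle_points must be an integer >= 11", call. = FALSE)
  }
  structure(
    list(
      couplings = couplings, n_cycle_points = n_cycle_points,
      angle_unit_out = angle_unit_out, alpha = alpha,
      posthoc_correction = posthoc_correction,
      variance_policy = variance_policy, seed = seed
    ),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from YAML
#'
#' Fields mirror [analysis_config()]; absent fields take their defaults.
#' `couplings` is a list of two-element `[distal, proximal]` entries.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$couplings)) {
    args$couplings <- lapply(raw$couplings, function(p) as.character(unlist(p)))
  }
  for (f in c("n_cycle_points", "angle_unit_out", "alpha",
              "posthoc_correction", "variance_policy", "seed")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  do.call(analysis_config, args)
}
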