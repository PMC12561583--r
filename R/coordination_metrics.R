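#' Mean absolute relative phase (MARP) of one CRP curve
#'
#' Mean over the N cycle grid points of |theta_i|. MARP is a relative index:
#' lower values mean the two joints move more in phase, higher values more out
#' of phase. The absolute value makes the index invariant to which joint leads
#' (MARP(theta) = MARP(-theta)); `absolute = FALSE` gives the plain signed
#' mean, kept for auditing formulations that omit the absolute value.
#'
#' @param theta A `crp_curve` or a numeric relative-phase series (degrees).
#' @param absolute Apply |.| per point (default TRUE).
#' @return Non-negative scalar (same angular unit as `theta`).
#' @export
marp <- function(theta, absolute = TRUE) {
  if (inherits(theta, "crp_curve")) theta <- theta$theta
  stopifnot(is.numeric(theta))
  if (length(theta) == 0L) stop("empty relative-phase curve", call. = FALSE)
  if (anyNA(theta)) stop("relative-phase curve has missing values", call. = FALSE)
  if (absolute) mean(abs(theta)) else mean(theta)
}

theta_matrix <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  get_theta <- function(cv) if (inherits(cv, "crp_curve")) cv$theta else as.numeric(cv)
  mats <- lapply(curves, get_theta)
  n <- unique(lengths(mats))
  if (length(n) != 1L) {
    stop("curves are not on a common grid (lengths ",
         paste(unique(lengths(mats)), collapse = ", "), ")", call. = FALSE)
  }
  do.call(cbind, mats)
}

#' Deviation phase (DP) across replicate CRP curves
#'
#' Per cycle grid point i, the sample standard deviation (n - 1 denominator)
#' of theta_i across the curves; DP is the average of those SDs over the N
#' points. DP quantifies coordination variability: lower values indicate a
#' more stable (less variable) neuromuscular organisation.
#'
#' @param curves List of >= 2 `crp_curve`s (or numeric series) on a common
#'   grid, same coupling.
#' @return Non-negative scalar, same angular unit as the curves.
#' @export
deviation_phase <- function(curves) {
  m <- theta_matrix(curves)
  if (ncol(m) < 2L) {
    stop("deviation phase needs at least 2 replicate curves, got ", ncol(m),
         call. = FALSE)
  }
  mean(apply(m, 1L, stats::sd))
}

#' Pointwise ensemble mean and SD of replicate CRP curves
#'
#' @param curves List of >= 2 curves on a common 0-100% grid.
#' @return An `ensemble_curve`: tibble with `cycle_pct`, `mean_theta`,
#'   `sd_theta`, and attribute `n` (number of curves).
#' @export
ensemble_curve <- function(curves) {
  m <- theta_matrix(curves)
  if (ncol(m) < 2L) {
    stop("ensemble curve needs at least 2 curves, got ", ncol(m), call. = FALSE)
  }
  grid <- if (inherits(curves[[1L]], "crp_curve")) {
    curves[[1L]]$cycle_fraction
  } else {
    seq(0, 100, length.out = nrow(m))
  }
  out <- tibble::tibble(
    cycle_pct = grid,
    mean_theta = rowMeans(m),
    sd_theta = apply(m, 1L, stats::sd),
    n = ncol(m)
  )
  structure(out, class = c("ensemble_curve", class(out)))
}

#' Per-subject coordination metrics for one coupling and stage
#'
#' Aggregation used for inference: each subject contributes one MARP (the mean
#' of the per-trial MARPs) and one DP (the pointwise SD across that subject's
#' trial CRP curves, averaged over the cycle). DP is NA when the subject has a
#' single trial — one cycle carries no variability information, and reporting
#' zero would fake perfect stability.
#'
#' @param trials List of `angle_trial`s from one subject and stage.
#' @param coupling `c(distal, proximal)` joint pair.
#' @param n_points Cycle grid size (default 101).
#' @return One-row tibble: subject_id, group, stage, coupling, marp, dp,
#'   n_cycles.
#' @export
subject_coupling_metrics <- function(trials, coupling, n_points = 101L) {
  if (length(trials) == 0L) stop("no trials supplied", call. = FALSE)
  curves <- lapply(trials, crp_curve, coupling = coupling, n_points = n_points)
  marps <- vapply(curves, marp, numeric(1))
  dp <- if (length(curves) >= 2L) deviation_phase(curves) else NA_real_
  t1 <- trials[[1L]]
  tibble::tibble(
    subject_id = t1$subject_id, group = t1$group, stage = t1$stage,
    coupling = paste(coupling, collapse = "-"),
    marp = mean(marps), dp = dp, n_cycles = length(curves)
  )
}

#' Per-subject metrics for a whole cohort
#'
#' Runs [subject_coupling_metrics()] for every (subject, stage, coupling) in a
#' cohort of trials.
#'
#' @param trials List of `angle_trial`s.
#' @param couplings List of `c(distal, proximal)` pairs.
#' @param n_points Cycle grid size.
#' @return Tibble, one row per subject x stage x coupling.
#' @export
cohort_metrics <- function(trials,
                           couplings = list(c("ankle", "knee"), c("knee", "pelvis")),
                           n_points = 101L) {
  keys <- vapply(trials, function(tr) paste(tr$subject_id, tr$stage, sep = "\r"),
                 character(1))
  by_subject_stage <- split(trials, keys)
  rows <- lapply(by_subject_stage, function(trs) {
    dplyr::bind_rows(lapply(couplings, function(cp) {
      subject_coupling_metrics(trs, cp, n_points)
    }))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$group, .data$stage,
                 .data$coupling, .data$subject_id)
}

#' Group-level summary of per-subject metrics
#'
#' Mean and sample SD of the per-subject MARP and DP within each
#' (group, stage, coupling) cell — the layout of a study summary table.
#'
#' @param metrics Tibble from [cohort_metrics()].
#' @return Tibble with marp_mean, marp_sd, dp_mean, dp_sd, n per cell.
#' @export
group_summary <- function(metrics) {
  stopifnot(nrow(metrics) > 0L)
  dplyr::summarise(
    dplyr::group_by(metrics, .data$group, .data$stage, .data$coupling),
    marp_mean = mean(.data$marp),
    marp_sd = stats::sd(.data$marp),
    dp_mean = mean(.data$dp, na.rm = TRUE),
    dp_sd = stats::sd(.data$dp, na.rm = TRUE),
    n = dplyr::n(),
    .groups = "drop"
  )
}
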