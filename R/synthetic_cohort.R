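#' Simulation parameters for a synthetic coordination cohort
#'
#' Describes a three-group (control / test novices, target professionals),
#' two-stage (pre / post for novices, single for the target group) training
#' study. Per (group, stage, coupling) cell the generator needs a mean
#' inter-joint phase offset Delta (degrees), a between-subject SD of Delta,
#' and a within-subject trial-to-trial phase jitter SD; optionally an additive
#' per-sample angle noise SD.
#'
#' @param offsets Named list `group -> stage -> coupling -> degrees` of mean
#'   phase offsets Delta, each in (-180, 180).
#' @param sd_between Same shape: between-subject SD of Delta (degrees, >= 0).
#' @param sd_jitter `group -> stage -> degrees`: within-subject cycle-to-cycle
#'   jitter SD, applied as a constant phase shift per trial and coupling.
#' @param sd_noise Additive per-sample angle noise SD in degrees (default 0;
#'   nonzero noise also perturbs the phase and is not captured by the
#'   closed-form DP ground truth).
#' @param n_subjects Named integer vector, subjects per group (>= 2 each).
#' @param trials_per_subject Trials per subject and stage (default 10).
#' @param samples_per_cycle Samples in one movement cycle (default 200,
#'   >= 16).
#' @param cycle_duration_s Duration of one cycle in seconds (default 0.6).
#' @param amplitude,baseline Sinusoid amplitude and offset in degrees
#'   (defaults 30 and 10).
#' @return A `sim_params` list.
#' @export
sim_params <- function(offsets, sd_between, sd_jitter, sd_noise = 0,
                       n_subjects = c(control = 7L, test = 7L, target = 14L),
                       trials_per_subject = 10L, samples_per_cycle = 200L,
                       cycle_duration_s = 0.6, amplitude = 30, baseline = 10) {
  stopifnot(is.list(offsets), is.list(sd_between), is.list(sd_jitter))
  if (any(n_subjects < 2L)) stop("each group needs >= 2 subjects", call. = FALSE)
  if (samples_per_cycle < 16L) {
    stop("samples_per_cycle must be >= 16 (undersampled phase)", call. = FALSE)
  }
  flat <- unlist(offsets)
  if (any(abs(flat) >= 180)) {
    stop("phase offsets must lie in (-180, 180) degrees", call. = FALSE)
  }
  if (any(unlist(sd_between) < 0) || any(unlist(sd_jitter) < 0) || sd_noise < 0) {
    stop("all SDs must be >= 0", call. = FALSE)
  }
  structure(
    list(
      offsets = offsets, sd_between = sd_between, sd_jitter = sd_jitter,
      sd_noise = sd_noise, n_subjects = n_subjects,
      trials_per_subject = as.integer(trials_per_subject),
      samples_per_cycle = as.integer(samples_per_cycle),
      cycle_duration_s = cycle_duration_s,
      amplitude = amplitude, baseline = baseline
    ),
    class = "sim_params"
  )
}

#' Study-design preset
#'
#' Three groups of 7/7/14 male handball players; both novice groups share one
#' true pre-training offset (groups are randomized, so equal coordination at
#' baseline is the design assumption), professionals sit far more out of
#' phase, and training shifts the novice offsets toward the professional
#' value. Between-subject SDs and within-subject jitter SDs follow the
#' relative magnitudes typical of such studies (MARP SD around a third of the
#' mean; DP around a hundredth of MARP). All values in degrees.
#'
#' @param ... Overrides forwarded to [sim_params()].
#' @return A `sim_params`.
#' @export
study_preset <- function(...) {
  ak <- "ankle-knee"; kp <- "knee-pelvis"
  offsets <- list(
    control = list(pre = stats::setNames(c(17, 24), c(ak, kp)),
                   post = stats::setNames(c(32, 28), c(ak, kp))),
    test = list(pre = stats::setNames(c(17, 24), c(ak, kp)),
                post = stats::setNames(c(32, 28), c(ak, kp))),
    target = list(single = stats::setNames(c(38, 34), c(ak, kp)))
  )
  sd_between <- list(
    control = list(pre = stats::setNames(c(5, 12.5), c(ak, kp)),
                   post = stats::setNames(c(7, 15), c(ak, kp))),
    test = list(pre = stats::setNames(c(5, 12.5), c(ak, kp)),
                post = stats::setNames(c(7, 15), c(ak, kp))),
    target = list(single = stats::setNames(c(12, 21), c(ak, kp)))
  )
  sd_jitter <- list(
    control = list(pre = 0.2, post = 0.2),
    test = list(pre = 0.2, post = 0.15),
    target = list(single = 0.3)
  )
  args <- utils::modifyList(
    list(offsets = offsets, sd_between = sd_between, sd_jitter = sd_jitter),
    list(...)
  )
  do.call(sim_params, args)
}

#' Simulate one movement cycle of ankle/knee/pelvis angles
#'
#' Single-harmonic model of the sagittal joint-angle curves over one cycle:
#' the pelvis follows `A sin(2 pi t / T) + baseline` and each more distal
#' joint lags its proximal neighbour by the coupling's phase offset plus any
#' per-trial jitter, so the continuous relative phase of each coupling equals
#' that offset by construction. Optional iid angle noise is added per sample.
#'
#' @param offset_deg Named offsets `c("ankle-knee" = ..., "knee-pelvis" = ...)`
#'   in degrees for this trial (jitter already included if desired).
#' @param n_samples Samples in the cycle (>= 16).
#' @param cycle_duration_s Cycle duration (s).
#' @param amplitude,baseline Waveform amplitude/offset (degrees).
#' @param sd_noise Additive per-sample angle noise SD (degrees).
#' @param subject_id,group,stage,trial_index Trial provenance.
#' @return An [angle_trial()] with joints pelvis, knee, ankle.
#' @export
simulate_joint_cycle <- function(offset_deg, n_samples = 200L,
                                 cycle_duration_s = 0.6, amplitude = 30,
                                 baseline = 10, sd_noise = 0,
                                 subject_id = "s1", group = "control",
                                 stage = "pre", trial_index = 1L) {
  if (n_samples < 16L) {
    stop("n_samples must be >= 16 (undersampled phase)", call. = FALSE)
  }
  stopifnot(all(c("ankle-knee", "knee-pelvis") %in% names(offset_deg)))
  tt <- seq(0, cycle_duration_s, length.out = n_samples)
  w <- 2 * pi / cycle_duration_s
  d_kp <- offset_deg[["knee-pelvis"]] * pi / 180
  d_ak <- offset_deg[["ankle-knee"]] * pi / 180
  wave <- function(delay) {
    a <- amplitude * sin(w * tt - delay) + baseline
    if (sd_noise > 0) a <- a + stats::rnorm(n_samples, 0, sd_noise)
    a
  }
  # phase angle of A*sin(wt - d) on the portrait is 90 - (wt - d) degrees,
  # so CRP(distal, proximal) = d_distal - d_proximal; chain the delays so each
  # coupling's CRP equals its named offset
  angle_trial(
    time = tt,
    angles = list(
      pelvis = wave(0),
      knee = wave(d_kp),
      ankle = wave(d_kp + d_ak)
    ),
    subject_id = subject_id, group = group, stage = stage,
    trial_index = trial_index
  )
}

stages_for_group <- function(group) {
  if (group == "target") "single" else c("pre", "post")
}

#' Simulate a full cohort with known coordination ground truth
#'
#' Per (group, stage): subject-level coupling offsets are drawn as
#' `Normal(Delta_group_stage, sd_between)` independently per stage (the
#' training response is modeled as a stage-dependent shift, not as a dynamic
#' process), then each trial perturbs every coupling offset by a constant
#' phase jitter `Normal(0, sd_jitter)`. Control and test groups get pre and
#' post stages, the target group a single stage.
#'
#' Randomness is drawn from R's global RNG; call `set.seed()` first for a
#' reproducible cohort.
#'
#' @param params A [sim_params()] (e.g. [study_preset()]).
#' @return A `cohort_dataset`: list with `trials` (list of `angle_trial`s),
#'   `manifest` (tibble), and `ground_truth` (from [ground_truth()]).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  trials <- list()
  man <- list()
  demo <- list(control = c(21, 1.70, 75), test = c(22, 1.75, 73),
               target = c(21, 1.72, 74))
  for (group in names(params$n_subjects)) {
    n_sub <- params$n_subjects[[group]]
    for (s in seq_len(n_sub)) {
      sid <- sprintf("%s_%02d", group, s)
      for (stage in stages_for_group(group)) {
        mu <- params$offsets[[group]][[stage]]
        sb <- params$sd_between[[group]][[stage]]
        sj <- params$sd_jitter[[group]][[stage]]
        subj_offset <- mu + stats::rnorm(length(mu), 0, sb)
        names(subj_offset) <- names(mu)
        for (k in seq_len(params$trials_per_subject)) {
          jit <- stats::rnorm(length(subj_offset), 0, sj)
          trial <- simulate_joint_cycle(
            offset_deg = subj_offset + stats::setNames(jit, names(subj_offset)),
            n_samples = params$samples_per_cycle,
            cycle_duration_s = params$cycle_duration_s,
            amplitude = params$amplitude, baseline = params$baseline,
            sd_noise = params$sd_noise,
            subject_id = sid, group = group, stage = stage, trial_index = k
          )
          trials[[length(trials) + 1L]] <- trial
          man[[length(man) + 1L]] <- tibble::tibble(
            subject_id = sid, group = group, stage = stage,
            trial_path = sprintf("%s_%s_t%02d.csv", sid, stage, k),
            age_y = demo[[group]][1L], height_m = demo[[group]][2L],
            weight_kg = demo[[group]][3L]
          )
        }
      }
    }
  }
  structure(
    list(
      trials = trials,
      manifest = validate_manifest(dplyr::bind_rows(man)),
      ground_truth = ground_truth(params),
      params = params
    ),
    class = "cohort_dataset"
  )
}

# E[sample SD] / sigma for a normal sample of size n
c4_correction <- function(n) {
  stopifnot(n >= 2L)
  sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
}

folded_normal_mean <- function(mu, sigma) {
  if (sigma == 0) return(abs(mu))
  sigma * sqrt(2 / pi) * exp(-mu^2 / (2 * sigma^2)) +
    mu * (1 - 2 * stats::pnorm(-mu / sigma))
}

#' Closed-form expectations implied by simulation parameters
#'
#' For each (group, stage, coupling): the expected per-subject MARP is the
#' folded-normal mean of the subject offset draw `|Normal(Delta, sd_between)|`
#' (which reduces to `|Delta|` when `sd_between` is 0 or `|Delta|` is large
#' relative to it), and the expected DP is the c4-corrected expectation of the
#' pointwise sample SD induced by per-trial constant phase jitter,
#' `c4(n_trials) * sd_jitter`. Both use the constant-phase-shift
#' approximation: additive per-sample angle noise is not included.
#'
#' @param params A [sim_params()].
#' @return Tibble: group, stage, coupling, expected_marp, expected_dp.
#' @export
ground_truth <- function(params) {
  rows <- list()
  for (group in names(params$n_subjects)) {
    for (stage in stages_for_group(group)) {
      mu <- params$offsets[[group]][[stage]]
      sb <- params$sd_between[[group]][[stage]]
      sj <- params$sd_jitter[[group]][[stage]]
      for (cp in names(mu)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          group = group, stage = stage, coupling = cp,
          expected_marp = folded_normal_mean(mu[[cp]], sb[[cp]]),
          expected_dp = if (params$trials_per_subject < 2L) {
            NA_real_  # DP needs >= 2 cycles
          } else if (sj > 0) {
            c4_correction(params$trials_per_subject) * sj
          } else 0
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a simulated cohort to disk in the trial/manifest CSV formats
#'
#' @param cohort A `cohort_dataset` from [simulate_cohort()].
#' @param dir Output directory (created if absent); trials are written under
#'   `dir/trials/`, the manifest to `dir/manifest.csv`, and the ground truth
#'   to `dir/ground_truth.json`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  trial_dir <- file.path(dir, "trials")
  dir.create(trial_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$trials)) {
    write_trial_table(cohort$trials[[i]],
                      file.path(trial_dir, cohort$manifest$trial_path[i]))
  }
  man <- cohort$manifest
  man$trial_path <- file.path("trials", man$trial_path)
  readr::write_csv(tibble::as_tibble(man), file.path(dir, "manifest.csv"))
  jsonlite::write_json(cohort$ground_truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
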