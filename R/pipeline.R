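metric_sample <- function(metrics, grp, stg, cpl, index) {
  x <- metrics[metrics$group == grp & metrics$stage == stg &
                 metrics$coupling == cpl, ][[index]]
  x[is.finite(x)]
}

#' Run the full coordination analysis on a cohort
#'
#' simulate/load -> CRP -> per-subject MARP/DP -> group summaries -> gated
#' inference. For every coupling and index (MARP, DP) the report contains:
#' the pre-training independent t-test between the two novice groups; the
#' pre-training three-group one-way ANOVA (novice pre vs the professional
#' reference) with pairwise post hoc tests; the pre/post paired t-test within
#' each novice group; the post-training novice t-test; and the post-training
#' three-group ANOVA with post hoc tests — all with effect sizes. Assumption
#' checks (Shapiro-Wilk, Levene) are run per comparison cell; a failed gate is
#' recorded as a warning in the report and the parametric analysis continues.
#'
#' @param trials List of `angle_trial`s (e.g. `simulate_cohort(...)$trials`
#'   or [load_cohort()]).
#' @param config An [analysis_config()].
#' @return A `report_bundle`: list with `metrics`, `summaries`, `assumptions`,
#'   `tests`, `ensembles`, and `metadata`.
#' @export
run_analysis <- function(trials, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  metrics <- cohort_metrics(trials, config$couplings, config$n_cycle_points)
  if (config$angle_unit_out == "radians") {
    metrics$marp <- metrics$marp * pi / 180
    metrics$dp <- metrics$dp * pi / 180
  }
  summaries <- group_summary(metrics)
  couplings <- unique(metrics$coupling)
  have_novice_pre <- all(c("control", "test") %in% metrics$group) &&
    "pre" %in% metrics$stage
  have_post <- "post" %in% metrics$stage
  have_target <- "target" %in% metrics$group

  tests <- list()
  assumptions <- list()
  add_test <- function(comparison, coupling, index, row) {
    tests[[length(tests) + 1L]] <<- dplyr::bind_cols(
      tibble::tibble(comparison = comparison, coupling = coupling, index = index),
      row
    )
  }
  gate <- function(comparison, coupling, index, groups) {
    groups <- groups[lengths(groups) >= 3L]
    if (length(groups) < 1L) return(invisible(NULL))
    g <- assumption_gate(groups, config$alpha)
    assumptions[[length(assumptions) + 1L]] <<- dplyr::bind_cols(
      tibble::tibble(comparison = comparison, coupling = coupling, index = index),
      tidyr::pivot_wider(g$shapiro[, c("group", "p")], names_from = "group",
                         values_from = "p", names_prefix = "shapiro_p_"),
      tibble::tibble(levene_p = g$levene$p,
                     all_pass = all(g$shapiro$pass) && !isFALSE(g$levene$pass))
    )
    if (!all(g$shapiro$pass, na.rm = TRUE) || isFALSE(g$levene$pass)) {
      warning("assumption gate flagged ", comparison, " / ", coupling, " / ",
              index, "; parametric analysis continues", call. = FALSE)
    }
    invisible(NULL)
  }

  for (cpl in couplings) {
    for (index in c("marp", "dp")) {
      ctrl_pre <- metric_sample(metrics, "control", "pre", cpl, index)
      test_pre <- metric_sample(metrics, "test", "pre", cpl, index)
      target <- metric_sample(metrics, "target", "single", cpl, index)
      ctrl_post <- metric_sample(metrics, "control", "post", cpl, index)
      test_post <- metric_sample(metrics, "test", "post", cpl, index)

      if (have_novice_pre && length(ctrl_pre) >= 2L && length(test_pre) >= 2L) {
        gate("pre_novice_t", cpl, index, list(control = ctrl_pre, test = test_pre))
        add_test("pre_novice_t", cpl, index,
                 independent_t(ctrl_pre, test_pre, config$variance_policy,
                               config$alpha))
      }
      if (have_novice_pre && have_target && length(target) >= 2L) {
        pre3 <- list(control = ctrl_pre, test = test_pre, target = target)
        gate("pre_anova", cpl, index, pre3)
        add_test("pre_anova", cpl, index, one_way_anova(pre3))
        ph <- posthoc_pairwise(pre3, config$posthoc_correction)
        for (i in seq_len(nrow(ph))) {
          add_test(sprintf("pre_posthoc_%s_vs_%s", ph$group1[i], ph$group2[i]),
                   cpl, index, ph[i, setdiff(names(ph), c("group1", "group2"))])
        }
      }
      if (have_post) {
        for (grp in c("control", "test")) {
          pre_m <- metrics[metrics$group == grp & metrics$stage == "pre" &
                             metrics$coupling == cpl, c("subject_id", index)]
          post_m <- metrics[metrics$group == grp & metrics$stage == "post" &
                              metrics$coupling == cpl, c("subject_id", index)]
          paired <- dplyr::inner_join(pre_m, post_m, by = "subject_id",
                                      suffix = c("_pre", "_post"))
          paired <- paired[stats::complete.cases(paired), ]
          if (nrow(paired) >= 2L) {
            add_test(sprintf("paired_%s_pre_post", grp), cpl, index,
                     paired_t(paired[[paste0(index, "_pre")]],
                              paired[[paste0(index, "_post")]]))
          }
        }
        if (length(ctrl_post) >= 2L && length(test_post) >= 2L) {
          gate("post_novice_t", cpl, index,
               list(control = ctrl_post, test = test_post))
          add_test("post_novice_t", cpl, index,
                   independent_t(ctrl_post, test_post, config$variance_policy,
                                 config$alpha))
        }
        if (have_target && length(ctrl_post) >= 2L && length(test_post) >= 2L &&
            length(target) >= 2L) {
          post3 <- list(control = ctrl_post, test = test_post, target = target)
          gate("post_anova", cpl, index, post3)
          add_test("post_anova", cpl, index, one_way_anova(post3))
          ph <- posthoc_pairwise(post3, config$posthoc_correction)
          for (i in seq_len(nrow(ph))) {
            add_test(sprintf("post_posthoc_%s_vs_%s", ph$group1[i], ph$group2[i]),
                     cpl, index, ph[i, setdiff(names(ph), c("group1", "group2"))])
          }
        }
      }
    }
  }

  ensembles <- ensemble_by_cell(trials, config)
  structure(
    list(
      metrics = metrics,
      summaries = summaries,
      assumptions = if (length(assumptions)) dplyr::bind_rows(assumptions) else NULL,
      tests = dplyr::bind_rows(tests),
      ensembles = ensembles,
      metadata = list(
        config = unclass(config),
        config_hash = rlang::hash(unclass(config)),
        seed = config$seed,
        n_trials = length(trials),
        package_version = as.character(utils::packageVersion("crpcoord")),
        timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "report_bundle"
  )
}

# group/stage/coupling ensemble mean +/- SD curves across all trial CRP curves
ensemble_by_cell <- function(trials, config) {
  cells <- list()
  for (cpl in config$couplings) {
    cpl_name <- paste(cpl, collapse = "-")
    curves <- lapply(trials, crp_curve, coupling = cpl,
                     n_points = config$n_cycle_points)
    key <- vapply(curves, function(cv) paste(cv$group, cv$stage, sep = "\r"),
                  character(1))
    for (k in unique(key)) {
      sub <- curves[key == k]
      if (length(sub) < 2L) next
      parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
      ens <- ensemble_curve(sub)
      ens$group <- parts[1L]
      ens$stage <- parts[2L]
      ens$coupling <- cpl_name
      cells[[length(cells) + 1L]] <- ens
    }
  }
  if (length(cells)) dplyr::bind_rows(cells) else NULL
}

#' Load a cohort written by [write_cohort()] (or hand-assembled in the same
#' layout) from disk
#'
#' @param dir Directory containing `manifest.csv` and the trial CSVs it
#'   points to.
#' @return List with `trials` and `manifest`.
#' @export
load_cohort <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  trial_counter <- new.env(parent = emptyenv())
  trials <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- file.path(dir, manifest$trial_path[i])
    if (!file.exists(p)) stop("unreadable trial file: ", p, call. = FALSE)
    key <- paste(manifest$subject_id[i], manifest$stage[i])
    idx <- (get0(key, trial_counter, ifnotfound = 0L)) + 1L
    assign(key, idx, trial_counter)
    read_trial_table(p, subject_id = manifest$subject_id[i],
                     group = manifest$group[i], stage = manifest$stage[i],
                     trial_index = idx)
  })
  list(trials = trials, manifest = manifest)
}

#' Write a report bundle to a directory as CSV/JSON
#'
#' Emits `metrics.csv`, `group_summary.csv`, `assumptions.csv`, `tests.csv`,
#' `ensembles.csv`, and `run_metadata.json`. Every statistic in `tests.csv`
#' is recomputable from `metrics.csv` alone.
#'
#' @param bundle A `report_bundle` from [run_analysis()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$metrics, file.path(dir, "metrics.csv"), na = "")
  readr::write_csv(bundle$summaries, file.path(dir, "group_summary.csv"), na = "")
  if (!is.null(bundle$assumptions)) {
    readr::write_csv(bundle$assumptions, file.path(dir, "assumptions.csv"), na = "")
  }
  readr::write_csv(bundle$tests, file.path(dir, "tests.csv"), na = "")
  if (!is.null(bundle$ensembles)) {
    readr::write_csv(bundle$ensembles, file.path(dir, "ensembles.csv"), na = "")
  }
  jsonlite::write_json(bundle$metadata, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
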