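#' Bar chart of group-level MARP or DP with SD error bars
#'
#' One panel per coupling; bars are group x stage cells, error bars are the
#' between-subject standard deviations (a zero SD renders as a zero-length
#' bar).
#'
#' @param summaries Tibble from [group_summary()] (non-empty).
#' @param index `"marp"` or `"dp"`.
#' @return A ggplot object.
#' @export
plot_metric_bars <- function(summaries, index = c("marp", "dp")) {
  index <- match.arg(index)
  if (is.null(summaries) || nrow(summaries) == 0L) {
    stop("empty metrics summary", call. = FALSE)
  }
  mean_col <- paste0(index, "_mean")
  sd_col <- paste0(index, "_sd")
  df <- summaries
  df$cell <- paste(df$group, df$stage, sep = "\n")
  df$lo <- df[[mean_col]] - dplyr::coalesce(df[[sd_col]], 0)
  df$hi <- df[[mean_col]] + dplyr::coalesce(df[[sd_col]], 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data[[mean_col]],
                                   fill = .data$group)) +
    ggplot2::geom_col(width = 0.7, show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.25) +
    ggplot2::facet_wrap(~coupling) +
    ggplot2::labs(x = NULL, y = paste(toupper(index), "(deg)"),
                  title = paste(toupper(index), "by group and stage")) +
    ggplot2::theme_minimal()
}

#' Ensemble relative-phase curve: mean line with +/- SD envelope
#'
#' Solid line is the pointwise mean CRP over the 0-100% cycle; dashed lines
#' bound the pointwise +/- 1 SD envelope across curves.
#'
#' @param ensemble An [ensemble_curve()] (or a filtered row set of the
#'   pipeline's `ensembles` table for one cell).
#' @return A ggplot object.
#' @export
plot_ensemble <- function(ensemble) {
  stopifnot(all(c("cycle_pct", "mean_theta", "sd_theta") %in% names(ensemble)))
  df <- tibble::as_tibble(ensemble)
  df$lo <- df$mean_theta - df$sd_theta
  df$hi <- df$mean_theta + df$sd_theta
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle_pct)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_theta), linewidth = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lo), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$hi), linetype = "dashed") +
    ggplot2::labs(x = "movement cycle (%)", y = "relative phase (deg)",
                  title = "Ensemble continuous relative phase (mean +/- SD)") +
    ggplot2::theme_minimal()
}

#' Save the standard report figures
#'
#' Writes `marp_bars.png`, `dp_bars.png`, and one
#' `ensemble_<group>_<stage>_<coupling>.png` per cell with deterministic file
#' names.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory.
#' @return Character vector of files written, invisibly.
#' @export
save_report_figures <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (index in c("marp", "dp")) {
    f <- file.path(dir, paste0(index, "_bars.png"))
    ggplot2::ggsave(f, plot_metric_bars(bundle$summaries, index),
                    width = 7, height = 4.5, dpi = 150)
    written <- c(written, f)
  }
  if (!is.null(bundle$ensembles)) {
    cells <- unique(bundle$ensembles[, c("group", "stage", "coupling")])
    for (i in seq_len(nrow(cells))) {
      sub <- dplyr::semi_join(bundle$ensembles, cells[i, ],
                              by = c("group", "stage", "coupling"))
      f <- file.path(dir, sprintf("ensemble_%s_%s_%s.png", cells$group[i],
                                  cells$stage[i], cells$coupling[i]))
      ggplot2::ggsave(f, plot_ensemble(sub), width = 7, height = 4.5, dpi = 150)
      written <- c(written, f)
    }
  }
  invisible(written)
}
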