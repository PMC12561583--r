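stats_row <- function(method, statistic, df1, df2 = NA_real_, p_value,
                      effect, effect_type, n1, n2 = NA_integer_,
                      note = NA_character_) {
  tibble::tibble(
    method = method, statistic = statistic, df1 = df1, df2 = df2,
    p_value = p_value, effect = effect, effect_type = effect_type,
    n1 = as.integer(n1), n2 = as.integer(n2), note = note
  )
}

#' Normality and homogeneity-of-variance checks
#'
#' Shapiro-Wilk per group and Levene's test (centered on the mean) across
#' groups, each flagged at `alpha`. A degenerate group (e.g. constant sample)
#' is surfaced as an assumption failure with the error noted rather than
#' aborting the analysis.
#'
#' @param groups Named list of numeric samples, each n >= 3.
#' @param alpha Significance threshold (default 0.05).
#' @return List with `shapiro` (tibble: group, W, p, pass, note), `levene`
#'   (one-row tibble: statistic, df1, df2, p, pass; NA when fewer than 2
#'   groups), and `alpha`.
#' @export
assumption_gate <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  small <- names(groups)[vapply(groups, length, integer(1)) < 3L]
  if (length(small) > 0L) {
    stop("assumption checks need n >= 3 per group; too small: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  shapiro <- dplyr::bind_rows(lapply(names(groups), function(g) {
    res <- tryCatch(stats::shapiro.test(groups[[g]]), error = function(e) e)
    if (inherits(res, "error")) {
      tibble::tibble(group = g, W = NA_real_, p = NA_real_, pass = FALSE,
                     note = conditionMessage(res))
    } else {
      tibble::tibble(group = g, W = unname(res$statistic), p = res$p.value,
                     pass = res$p.value > alpha, note = NA_character_)
    }
  }))
  levene <- if (length(groups) >= 2L) {
    y <- unlist(groups, use.names = FALSE)
    f <- factor(rep(names(groups), lengths(groups)))
    lv <- car::leveneTest(y ~ f, center = mean)
    tibble::tibble(statistic = lv[1L, "F value"], df1 = lv[1L, "Df"],
                   df2 = lv[2L, "Df"], p = lv[1L, "Pr(>F)"],
                   pass = lv[1L, "Pr(>F)"] > alpha)
  } else {
    tibble::tibble(statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                   p = NA_real_, pass = NA)
  }
  list(shapiro = shapiro, levene = levene, alpha = alpha)
}

#' Independent two-sample t-test with Cohen's d
#'
#' Default is the pooled-variance (Student) test with df = n1 + n2 - 2;
#' `variance_policy = "welch"` uses the Welch-Satterthwaite test, and
#' `"auto_levene"` switches to Welch when Levene's test rejects equal
#' variances at `alpha`. Cohen's d always uses the pooled SD. Two-sided
#' p-values throughout. When both groups have zero variance, t is 0 for equal
#' means and flagged infinite for unequal means.
#'
#' @param g1,g2 Numeric samples, each n >= 2.
#' @param variance_policy `"pooled"` (default), `"welch"`, `"auto_levene"`.
#' @param alpha Threshold for the auto_levene gate.
#' @return One-row tibble (method, statistic, df1, p_value, effect = Cohen's
#'   d, n1, n2, note).
#' @export
independent_t <- function(g1, g2, variance_policy = c("pooled", "welch", "auto_levene"),
                          alpha = 0.05) {
  variance_policy <- match.arg(variance_policy)
  stopifnot(length(g1) >= 2L, length(g2) >= 2L)
  if (variance_policy == "auto_levene") {
    lv <- assumption_gate(list(a = g1, b = g2), alpha)$levene
    variance_policy <- if (isFALSE(lv$pass)) "welch" else "pooled"
  }
  if (variance_policy == "welch") {
    tt <- stats::t.test(g1, g2, var.equal = FALSE)
    sp <- pooled_sd(stats::sd(g1), length(g1), stats::sd(g2), length(g2))
    d <- if (sp > 0) (mean(g1) - mean(g2)) / sp else
      ifelse(mean(g1) == mean(g2), 0, Inf * sign(mean(g1) - mean(g2)))
    return(stats_row("welch_t", unname(tt$statistic), unname(tt$parameter),
                     p_value = tt$p.value, effect = d, effect_type = "cohen_d",
                     n1 = length(g1), n2 = length(g2)))
  }
  summary_stat_t(mean(g1), stats::sd(g1), length(g1),
                 mean(g2), stats::sd(g2), length(g2))
}

pooled_sd <- function(sd1, n1, sd2, n2) {
  sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
}

#' Pooled-variance t-test from summary statistics
#'
#' Audit tool: reproduces a published independent t-test from the printed
#' group means, SDs, and sizes alone. Identical to [independent_t()] with the
#' pooled policy when given a raw sample's own summaries.
#'
#' @param mean1,sd1,n1 First group's mean, SD (>= 0), and size (>= 2).
#' @param mean2,sd2,n2 Second group's.
#' @return One-row tibble as in [independent_t()].
#' @export
summary_stat_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2L, n2 >= 2L)
  df <- n1 + n2 - 2
  sp <- pooled_sd(sd1, n1, sd2, n2)
  se <- sp * sqrt(1 / n1 + 1 / n2)
  note <- NA_character_
  if (se == 0) {
    if (mean1 == mean2) {
      t <- 0
      p <- 1
      d <- 0
    } else {
      t <- Inf * sign(mean1 - mean2)
      p <- 0
      d <- t
      note <- "zero pooled variance with unequal means: statistic infinite"
    }
  } else {
    t <- (mean1 - mean2) / se
    p <- 2 * stats::pt(-abs(t), df)
    d <- (mean1 - mean2) / sp
  }
  stats_row("student_t", t, df, p_value = p, effect = d,
            effect_type = "cohen_d", n1 = n1, n2 = n2, note = note)
}

#' Paired t-test with Cohen's d_z
#'
#' t on the within-subject differences with df = n - 1; the effect size is
#' d_z = mean(diff) / sd(diff).
#'
#' @param pre,post Numeric vectors matched by subject, equal length n >= 2.
#' @return One-row tibble.
#' @export
paired_t <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 2L)
  d <- post - pre
  n <- length(d)
  sdd <- stats::sd(d)
  note <- NA_character_
  if (sdd == 0) {
    if (mean(d) == 0) {
      t <- 0; p <- 1; dz <- 0
    } else {
      t <- Inf * sign(mean(d)); p <- 0; dz <- t
      note <- "zero-variance differences with nonzero mean: statistic infinite"
    }
  } else {
    t <- mean(d) / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(t), n - 1)
    dz <- mean(d) / sdd
  }
  stats_row("paired_t", t, n - 1, p_value = p, effect = dz,
            effect_type = "cohen_dz", n1 = n, n2 = n, note = note)
}

#' One-way ANOVA with eta squared
#'
#' F on k groups with df (k - 1, N - k); the effect size is
#' eta^2 = SS_between / SS_total. For k = 2, F equals the square of the
#' pooled-variance t statistic.
#'
#' @param groups Named list of >= 2 numeric samples, each n >= 2.
#' @return One-row tibble (df1 = k - 1, df2 = N - k, effect = eta squared).
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  stopifnot(all(vapply(groups, length, integer(1)) >= 2L))
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  grand <- mean(unlist(groups, use.names = FALSE))
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  ss_total <- ss_between + ss_within
  df1 <- k - 1
  df2 <- N - k
  if (ss_within == 0) {
    if (ss_between == 0) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- 0
    }
  } else {
    f <- (ss_between / df1) / (ss_within / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  eta2 <- if (ss_total > 0) ss_between / ss_total else 0
  stats_row("one_way_anova", f, df1, df2, p_value = p, effect = eta2,
            effect_type = "eta_squared", n1 = N)
}

#' Pairwise post hoc t-tests after a one-way ANOVA
#'
#' Unadjusted pooled-variance t per unordered pair, each with its own
#' df = n_i + n_j - 2 (so groups of 7, 7, 14 give the df pattern 12, 19, 19);
#' `correction = "bonferroni"` multiplies each p by the number of pairs,
#' capped at 1. The table lists both orderings of every pair; statistic sign
#' follows (group1 - group2), p-values and |t| are symmetric.
#'
#' @param groups Named list of >= 2 numeric samples.
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @return Tibble with columns group1, group2 plus the [independent_t()]
#'   columns and `p_adjusted`.
#' @export
posthoc_pairwise <- function(groups, correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  gn <- names(groups)
  pairs <- utils::combn(gn, 2L, simplify = FALSE)
  n_pairs <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    res <- independent_t(groups[[pr[1L]]], groups[[pr[2L]]], "pooled")
    adj <- if (correction == "bonferroni") min(1, res$p_value * n_pairs) else res$p_value
    fwd <- dplyr::bind_cols(tibble::tibble(group1 = pr[1L], group2 = pr[2L]),
                            res, tibble::tibble(p_adjusted = adj))
    rev <- fwd
    rev$group1 <- pr[2L]
    rev$group2 <- pr[1L]
    rev$statistic <- -rev$statistic
    rev$effect <- -rev$effect
    rev$n1 <- fwd$n2
    rev$n2 <- fwd$n1
    dplyr::bind_rows(fwd, rev)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$group1, .data$group2)
}
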