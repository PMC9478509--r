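#' Unpaired two-tailed Student's t-test from summary statistics
#'
#' Pooled-variance Student's t from group means, standard errors of the mean
#' and sizes: `s_i = sem_i * sqrt(n_i)`, pooled variance
#' `((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`, `df = n1 + n2 - 2`. This
#' summary-statistic entry point makes published group values directly
#' testable without subject-level data; for balanced designs it coincides
#' with `stats::t.test(var.equal = TRUE)` on the raw samples.
#'
#' @param mean1,mean2 Group means.
#' @param sem1,sem2 Standard errors of the mean, `>= 0`.
#' @param n1,n2 Group sizes, `>= 2`.
#' @return A one-row tibble with `t`, `df`, `p` (two-tailed), and
#'   `degenerate` (`TRUE` when both dispersions are zero but the means
#'   differ, in which case `p = 0` is returned with a warning).
#' @export
#' @examples
#' students_t(56, 3.0, 6, 83, 1.0, 6) # ventricular volumes, p ~ 6e-6
students_t <- function(mean1, sem1, n1, mean2, sem2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sem1 >= 0, sem2 >= 0)
  s1sq <- (sem1 * sqrt(n1))^2
  s2sq <- (sem2 * sqrt(n2))^2
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1sq + (n2 - 1) * s2sq) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  degenerate <- FALSE
  if (se == 0) {
    if (mean1 == mean2) {
      t_stat <- 0
      p <- 1
    } else {
      warn("zero pooled variance with unequal means; p reported as 0.")
      t_stat <- sign(mean1 - mean2) * Inf
      p <- 0
      degenerate <- TRUE
    }
  } else {
    t_stat <- (mean1 - mean2) / se
    p <- 2 * pt(-abs(t_stat), df)
  }
  tibble::tibble(t = t_stat, df = df, p = p, degenerate = degenerate)
}

#' Percent change relative to a reference mean
#'
#' `100 * (reference - other) / reference`: positive values are reductions
#' relative to the reference group.
#'
#' @param reference_mean Reference (e.g. normotensive control) mean, nonzero.
#' @param other_mean Comparison mean.
#' @return Percent change.
#' @export
#' @examples
#' percent_change(14.4, 9.22) # ~36% reduction in delivery
percent_change <- function(reference_mean, other_mean) {
  if (any(reference_mean == 0)) abort("`reference_mean` must be nonzero.")
  100 * (reference_mean - other_mean) / reference_mean
}

#' Fold change relative to a reference mean
#'
#' `other / reference`; e.g. the ~1.5-fold ventriculomegaly of hypertensive
#' animals relative to controls.
#'
#' @param other_mean Comparison mean.
#' @param reference_mean Reference mean, `> 0`.
#' @return Dimensionless fold change.
#' @export
#' @examples
#' fold_change(83, 56) # ~1.48
fold_change <- function(other_mean, reference_mean) {
  if (any(reference_mean <= 0)) abort("`reference_mean` must be positive.")
  other_mean / reference_mean
}

#' Two-group comparison table from subject-level data
#'
#' Computes, for each metric column, group means, SEMs, the pooled-variance
#' Student's t-test, the percent change relative to the reference group and
#' the fold change of the other group over the reference.
#'
#' @param data Data frame with one row per subject.
#' @param group Name of the grouping column (two levels).
#' @param metrics Character vector of numeric metric columns; defaults to
#'   all numeric columns.
#' @param reference Reference group label; defaults to the first level (or
#'   first value encountered).
#' @return A tibble of class `group_comparison`, one row per metric, with
#'   columns `metric`, `reference`, `mean_ref`, `sem_ref`, `n_ref`, `other`,
#'   `mean_other`, `sem_other`, `n_other`, `t`, `df`, `p`,
#'   `percent_change`, `fold_change`.
#' @export
compare_groups <- function(data, group = "group", metrics = NULL,
                           reference = NULL) {
  stopifnot(is.data.frame(data), group %in% names(data))
  g <- data[[group]]
  levels <- if (is.factor(g)) levels(g) else unique(as.character(g))
  if (length(levels) != 2L) abort("`group` must have exactly two levels.")
  reference <- reference %||% levels[1]
  if (!reference %in% levels) abort("`reference` is not a group level.")
  other <- setdiff(levels, reference)
  if (is.null(metrics)) {
    metrics <- names(data)[vapply(data, is.numeric, logical(1))]
    metrics <- setdiff(metrics, group)
  }
  if (length(metrics) == 0L) abort("no numeric metric columns found.")
  gchr <- as.character(g)
  if (sum(gchr == reference) < 2L || sum(gchr == other) < 2L) {
    abort("need at least 2 subjects per group.")
  }
  rows <- purrr::map_dfr(metrics, function(m) {
    x_ref <- data[[m]][gchr == reference]
    x_oth <- data[[m]][gchr == other]
    summ <- function(x) {
      x <- x[!is.na(x)]
      list(mean = mean(x), sem = sd(x) / sqrt(length(x)), n = length(x))
    }
    sr <- summ(x_ref); so <- summ(x_oth)
    tt <- students_t(sr$mean, sr$sem, sr$n, so$mean, so$sem, so$n)
    tibble::tibble(
      metric = m,
      reference = reference, mean_ref = sr$mean, sem_ref = sr$sem,
      n_ref = sr$n,
      other = other, mean_other = so$mean, sem_other = so$sem,
      n_other = so$n,
      t = tt$t, df = tt$df, p = tt$p,
      percent_change = percent_change(sr$mean, so$mean),
      fold_change = fold_change(so$mean, sr$mean)
    )
  })
  class(rows) <- c("group_comparison", class(rows))
  rows
}

#' Two-group comparison table from published summary statistics
#'
#' Same output as [compare_groups()], but starting from a tidy table of
#' group summaries (columns `metric`, `group`, `mean`, `sem`, `n`), so that
#' printed results can be analysed without subject-level data. See
#' [reported_group_summaries()].
#'
#' @param summaries Data frame with columns `metric`, `group`, `mean`,
#'   `sem`, `n`.
#' @param reference Reference group label; defaults to the first group.
#' @return A `group_comparison` tibble (see [compare_groups()]).
#' @export
compare_groups_summary <- function(summaries, reference = NULL) {
  stopifnot(is.data.frame(summaries),
            all(c("metric", "group", "mean", "sem", "n") %in%
                  names(summaries)))
  levels <- unique(as.character(summaries$group))
  if (length(levels) != 2L) abort("`group` must have exactly two levels.")
  reference <- reference %||% levels[1]
  other <- setdiff(levels, reference)
  rows <- purrr::map_dfr(unique(summaries$metric), function(m) {
    sub <- summaries[summaries$metric == m, ]
    sr <- sub[sub$group == reference, ]
    so <- sub[sub$group == other, ]
    if (nrow(sr) != 1L || nrow(so) != 1L) {
      abort(sprintf("metric '%s' needs exactly one row per group.", m))
    }
    tt <- students_t(sr$mean, sr$sem, sr$n, so$mean, so$sem, so$n)
    tibble::tibble(
      metric = m,
      reference = reference, mean_ref = sr$mean, sem_ref = sr$sem,
      n_ref = sr$n,
      other = other, mean_other = so$mean, sem_other = so$sem,
      n_other = so$n,
      t = tt$t, df = tt$df, p = tt$p,
      percent_change = percent_change(sr$mean, so$mean),
      fold_change = fold_change(so$mean, sr$mean)
    )
  })
  class(rows) <- c("group_comparison", class(rows))
  rows
}

#' Published WKY/SHR group summaries
#'
#' Reference group-level summary statistics (mean, SEM, n per strain) for
#' the five imaging metrics in the WKY (normotensive control) versus SHR
#' (spontaneously hypertensive) comparison that this package's simulator
#' presets emulate: total BCSFB-mediated water delivery (ul/min), cortical
#' CBF (ml/min/100 g), `T1_CSF` (s), cortical `T1` (s) and lateral
#' ventricular volume (mm^3). These are summary-level reference values, not
#' subject-level data; analyse them with [compare_groups_summary()].
#'
#' @return A tibble with columns `metric`, `unit`, `group`, `mean`, `sem`,
#'   `n`.
#' @export
reported_group_summaries <- function() {
  path <- system.file("extdata", "reported_group_summaries.csv",
                      package = "bcsfbasl", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Published WKY/SHR blood-pressure summaries
#'
#' Reference invasive arterial blood-pressure summaries (femoral-artery
#' catheter, n = 4 per strain) confirming the hypertensive state of the SHR
#' group: systolic, diastolic and mean pressure plus the pulse pressure
#' (systolic minus diastolic range), in mmHg.
#'
#' @return A tibble with columns `metric`, `unit`, `group`, `mean`, `sem`,
#'   `n`.
#' @export
blood_pressure_summaries <- function() {
  path <- system.file("extdata", "blood_pressure_summaries.csv",
                      package = "bcsfbasl", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
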