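# The statistical stage: exact p arithmetic for correlation coefficients,
# the change-change correlation battery, paired tests, trajectory subgroup
# comparisons, and rounded proportion reporting. Raw (unadjusted) p values
# throughout; no multiple-testing correction is applied anywhere.

#' Two-sided p value for a correlation coefficient
#'
#' The exact t transform: `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to
#' the t distribution with `n - 2` df. The same transform is applied to
#' Spearman's rho (the usual large-sample approximation).
#'
#' @param r correlation coefficient, |r| <= 1.
#' @param n number of pairs, >= 3.
#' @param method `"pearson"` or `"spearman"` (same arithmetic; recorded for
#'   provenance).
#' @return Two-sided p value; at |r| = 1 the limit 0 is returned with a
#'   warning flag.
#' @export
correlation_p_from_r <- function(r, n, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (n < 3) stop("need n >= 3")
  if (abs(r) > 1) stop("|r| must be <= 1")
  if (abs(r) == 1) {
    warning("|r| = 1: returning the p = 0 limit")
    return(0)
  }
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * pt(-abs(t_stat), df = n - 2)
}

#' Correlation battery of covariate changes against liver-volume change
#'
#' For each covariate, the early-to-late change is correlated with the
#' early-to-late liver-volume change over complete cases (so per-variable n
#' varies with missingness). Spearman is used where the method map says so
#' (by default for IHL and EGP, mirroring the table footnote), Pearson
#' elsewhere.
#'
#' @param cohort a `cohort_table` (long format, `early`/`late` rows).
#' @param variables covariate columns to test (default: all change-target
#'   covariates present).
#' @param method_map named character vector variable -> method; variables
#'   not named use `"pearson"`.
#' @return Data frame with `variable`, `method`, `n`, `r`, `p`, one row per
#'   variable; zero-variance or undersized variables are skipped with a
#'   warning.
#' @export
correlation_battery <- function(cohort,
                                variables = NULL,
                                method_map = c(ihl = "spearman",
                                               egp = "spearman")) {
  stopifnot(inherits(cohort, "data.frame"))
  early <- cohort[cohort$stage == "early", ]
  late <- cohort[cohort$stage == "late", ]
  late <- late[match(early$id, late$id), ]
  if (is.null(variables)) {
    candidates <- COHORT_CHANGE_VARS$variable
    variables <- candidates[candidates %in% names(cohort)]
  }
  d_liver <- late$liver_volume - early$liver_volume
  rows <- list()
  for (v in variables) {
    method <- if (v %in% names(method_map)) unname(method_map[[v]]) else "pearson"
    d_v <- late[[v]] - early[[v]]
    ok <- is.finite(d_v) & is.finite(d_liver)
    n <- sum(ok)
    if (n < 3) {
      warning("variable ", v, " skipped: fewer than 3 complete pairs")
      next
    }
    if (sd(d_v[ok]) == 0 || sd(d_liver[ok]) == 0) {
      warning("variable ", v, " skipped: zero variance")
      next
    }
    r <- cor(d_liver[ok], d_v[ok],
             method = if (method == "spearman") "spearman" else "pearson")
    p <- if (abs(r) == 1) {
      0
    } else correlation_p_from_r(r, n, method)
    rows[[v]] <- data.frame(variable = v, method = method, n = n, r = r,
                            p = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired t test on before/after measurements
#'
#' @param before,after paired numeric vectors, n >= 2, with nonzero
#'   difference variance.
#' @return List with `mean_diff`, `sd_diff`, `n`, `t`, `p` (two-sided).
#' @export
paired_test <- function(before, after) {
  if (length(before) != length(after)) stop("unpaired input")
  ok <- is.finite(before) & is.finite(after)
  d <- after[ok] - before[ok]
  n <- length(d)
  if (n < 2) stop("need at least 2 pairs")
  s <- sd(d)
  if (s == 0) stop("degenerate: zero variance of differences")
  t_stat <- mean(d) / (s / sqrt(n))
  list(mean_diff = mean(d), sd_diff = s, n = n, t = t_stat,
       p = 2 * pt(-abs(t_stat), df = n - 1))
}

#' Derive per-participant trajectory patterns from a cohort table
#'
#' Applies [classify_pattern()] to each participant's early/late/postwean
#' liver volumes.
#'
#' @param cohort a `cohort_table`.
#' @param tolerance_pct measurement-error band, percent.
#' @return Data frame with one row per participant: `id`,
#'   `pregnancy_change`, `postwean_change`, `pattern`, `subtype`,
#'   `complete`.
#' @export
cohort_patterns <- function(cohort, tolerance_pct = 7) {
  ids <- unique(cohort$id)
  get_vol <- function(id, stage) {
    v <- cohort$liver_volume[cohort$id == id & cohort$stage == stage]
    if (length(v)) v[1] else NA_real_
  }
  rows <- lapply(ids, function(id) {
    cp <- classify_pattern(get_vol(id, "early"), get_vol(id, "late"),
                           get_vol(id, "postwean"), tolerance_pct)
    data.frame(id = id, pregnancy_change = cp$pregnancy_change,
               postwean_change = cp$postwean_change, pattern = cp$pattern,
               subtype = cp$subtype, complete = cp$complete)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare a metric between the gain-loss and not-gain-loss groups
#'
#' Continuous metrics (late-pregnancy EGP or Rd) are compared with a
#' two-sided Welch two-sample t test; the hypertension flag with an exact
#' count comparison (Fisher).
#'
#' @param cohort a `cohort_table`.
#' @param patterns a [cohort_patterns()] table (or NULL to derive it).
#' @param metric `"egp"`, `"rd"` or `"hypertension"`.
#' @param stage visit at which continuous metrics are compared (default
#'   `"late"`, where the group effects live).
#' @return List with per-group summaries, the difference
#'   (gain-loss minus not-gain-loss), test statistic and two-sided `p`,
#'   and `direction`.
#' @export
subgroup_comparison <- function(cohort, patterns = NULL,
                                metric = c("egp", "rd", "hypertension"),
                                stage = "late") {
  metric <- match.arg(metric)
  if (is.null(patterns)) patterns <- cohort_patterns(cohort)
  patterns <- patterns[patterns$complete, ]
  groups <- split(patterns$id, patterns$pattern == "gain-loss")
  gl <- groups[["TRUE"]]; ngl <- groups[["FALSE"]]
  if (is.null(gl) || !length(gl)) stop("empty group: gain-loss")
  if (is.null(ngl) || !length(ngl)) stop("empty group: not gain-loss")
  if (metric == "hypertension") {
    sub <- cohort[cohort$stage == "early", ]
    h_gl <- sub$hypertension[match(gl, sub$id)]
    h_ngl <- sub$hypertension[match(ngl, sub$id)]
    tab <- matrix(c(sum(h_gl), sum(!h_gl), sum(h_ngl), sum(!h_ngl)), 2,
                  dimnames = list(c("htn", "no_htn"),
                                  c("gain-loss", "not gain-loss")))
    ft <- stats::fisher.test(tab)
    return(list(metric = metric, counts = tab,
                prevalence = c(`gain-loss` = mean(h_gl),
                               `not gain-loss` = mean(h_ngl)),
                p = ft$p.value,
                direction = if (mean(h_gl) < mean(h_ngl))
                  "lower in gain-loss" else "higher in gain-loss"))
  }
  sub <- cohort[cohort$stage == stage, ]
  x <- sub[[metric]][match(gl, sub$id)]
  y <- sub[[metric]][match(ngl, sub$id)]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(metric = metric, stage = stage,
       mean_gain_loss = mean(x), mean_not_gain_loss = mean(y),
       n = c(`gain-loss` = length(x), `not gain-loss` = length(y)),
       difference = mean(x) - mean(y), t = unname(tt$statistic),
       p = tt$p.value,
       direction = if (mean(x) > mean(y)) "higher in gain-loss"
                   else "lower in gain-loss")
}

#' Rounded percentage report
#'
#' Percentages rounded half-up to integers, the convention used for the
#' printed subgroup proportions (34/47 -> 72%).
#'
#' @param counts nonnegative counts, each <= `total`.
#' @param total denominator, > 0.
#' @return Integer percentages.
#' @export
proportion_report <- function(counts, total) {
  if (total <= 0) stop("total must be positive")
  if (any(counts > total) || any(counts < 0))
    stop("counts must lie in [0, total]")
  as.integer(floor(100 * counts / total + 0.5))
}

#' Full cohort analysis
#'
#' Runs the complete statistics stage on a cohort table: the paired
#' early-vs-late liver-volume test, the headline percent change (ratio of
#' mean change to mean early volume, plus the mean of per-participant
#' percent changes), the correlation battery, subgroup proportions, the
#' trajectory patterns, and the gain-loss group comparisons.
#'
#' @param cohort a `cohort_table`.
#' @param tolerance_pct measurement-error band, percent.
#' @return List of class `cohort_analysis`.
#' @export
analyze_cohort <- function(cohort, tolerance_pct = 7) {
  early <- cohort[cohort$stage == "early", ]
  late <- cohort[cohort$stage == "late", ]
  late <- late[match(early$id, late$id), ]
  paired <- paired_test(early$liver_volume, late$liver_volume)
  headline_pct <- percent_change(mean(early$liver_volume),
                                 mean(late$liver_volume))
  per_participant_pct <- mean(percent_change(early$liver_volume,
                                             late$liver_volume))
  patterns <- cohort_patterns(cohort, tolerance_pct)
  n <- nrow(patterns)
  preg_counts <- table(factor(patterns$pregnancy_change,
                              levels = c("gain", "no-change", "loss")))
  completers <- sum(patterns$complete)
  res <- list(
    n = n,
    paired = paired,
    headline_pct = headline_pct,
    per_participant_pct = per_participant_pct,
    mean_early = mean(early$liver_volume),
    mean_late = mean(late$liver_volume),
    battery = correlation_battery(cohort),
    pregnancy_counts = as.integer(preg_counts),
    pregnancy_pct = proportion_report(as.integer(preg_counts), n),
    completers = completers,
    completers_pct = proportion_report(completers, n),
    patterns = patterns)
  if (completers > 0 &&
      any(patterns$pattern == "gain-loss", na.rm = TRUE) &&
      any(patterns$pattern == "not gain-loss", na.rm = TRUE)) {
    gl <- sum(patterns$pattern == "gain-loss", na.rm = TRUE)
    res$gain_loss_pct <- proportion_report(gl, completers)
    res$subgroups <- list(
      egp = subgroup_comparison(cohort, patterns, "egp"),
      rd = subgroup_comparison(cohort, patterns, "rd"),
      hypertension = subgroup_comparison(cohort, patterns, "hypertension"))
  }
  class(res) <- "cohort_analysis"
  res
}

#' Write a cohort analysis report
#'
#' Emits the regenerated correlation table and subgroup summary as CSV plus
#' a Markdown report carrying raw p values only.
#'
#' @param analysis an [analyze_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "cohort_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(analysis$battery, file.path(dir, "correlation_table.csv"),
            row.names = FALSE)
  write.csv(analysis$patterns, file.path(dir, "patterns.csv"),
            row.names = FALSE)
  md <- c(
    "# Cohort liver-volume report", "",
    sprintf("- n = %d participants; %d (%d%%) completed the postwean visit",
            analysis$n, analysis$completers, analysis$completers_pct),
    sprintf("- Mean liver volume: early %.0f cm^3, late %.0f cm^3 (change %.0f cm^3, %.0f%%)",
            analysis$mean_early, analysis$mean_late,
            analysis$paired$mean_diff, round(analysis$headline_pct)),
    sprintf("- Paired t test early vs late: t = %.2f, p = %.3g",
            analysis$paired$t, analysis$paired$p),
    sprintf("- Pregnancy change: gain %d%%, no-change %d%%, loss %d%%",
            analysis$pregnancy_pct[1], analysis$pregnancy_pct[2],
            analysis$pregnancy_pct[3]),
    "", "## Correlation battery (raw p, no adjustment)", "",
    "| variable | method | n | r | p |", "|---|---|---|---|---|",
    sprintf("| %s | %s | %d | %.3f | %.3f |", analysis$battery$variable,
            analysis$battery$method, analysis$battery$n,
            analysis$battery$r, analysis$battery$p))
  if (!is.null(analysis$subgroups)) {
    md <- c(md, "", "## Gain-loss subgroup", "",
      sprintf("- gain-loss pattern: %d%% of completers", analysis$gain_loss_pct),
      sprintf("- late EGP: %s (diff %.2f, p = %.3f)",
              analysis$subgroups$egp$direction,
              analysis$subgroups$egp$difference, analysis$subgroups$egp$p),
      sprintf("- late Rd: %s (diff %.2f, p = %.3f)",
              analysis$subgroups$rd$direction,
              analysis$subgroups$rd$difference, analysis$subgroups$rd$p),
      sprintf("- hypertension prevalence: gain-loss %.0f%%, not gain-loss %.0f%% (p = %.3f)",
              100 * analysis$subgroups$hypertension$prevalence[1],
              100 * analysis$subgroups$hypertension$prevalence[2],
              analysis$subgroups$hypertension$p))
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
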