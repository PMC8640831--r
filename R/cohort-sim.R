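# Synthetic cohort with the study's printed statistical structure: stage
# means/SDs for liver volume, the change-change correlation battery, the
# pregnancy gain/no-change/loss proportions, the postwean completion
# fraction and trajectory patterns, hypertension confined to the
# not-gain-loss group, and late-pregnancy EGP/Rd group shifts.

# Table-1 correlation targets between each covariate's pregnancy change and
# the liver-volume change, plus the scales on which those changes live.
COHORT_CHANGE_VARS <- data.frame(
  variable = c("weight", "bmi", "fat_mass", "ffm", "sat", "vat", "ihl",
               "m_value", "egp", "rd", "insulin", "cholesterol",
               "triglycerides", "ldl", "hdl", "vldl"),
  r_target = c(0.260, 0.213, 0.077, 0.335, 0.123, 0.245, -0.035,
               -0.015, -0.047, 0.053, 0.095, 0.062, 0.176, -0.119, 0.103,
               -0.103),
  base_mean = c(70, 26, 22, 48, 4500, 1100, 0.02,
                6, 2.0, 7, 8, 180, 110, 100, 60, 22),
  base_sd = c(12, 3.5, 6, 5, 1400, 550, 0.015,
              2, 0.35, 2, 3, 30, 40, 25, 12, 8),
  change_mean = c(11, 4, 2.5, 8, 250, 180, 0,
                  -1.5, 0.25, -1.5, 6, 45, 90, 30, 6, 12),
  change_sd = c(4, 1.5, 2.5, 3, 900, 450, 0.01,
                1.5, 0.3, 1.8, 4, 25, 45, 20, 8, 9),
  stringsAsFactors = FALSE)

#' Specification of the synthetic cohort
#'
#' Defaults encode the printed cohort structure: early liver volume
#' 1,239 +- 220.8 cm^3, early-to-late change 182 +- 197 cm^3 (early volume
#' and change drawn independently, which reproduces the printed late SD of
#' 298.6 to within 1%), pregnancy change subgroups 34/10/3 of 47, postwean
#' completion 17/47 with 9 of 17 in the gain-loss pattern, hypertension
#' only in the not-gain-loss group (50% there), and positive late-pregnancy
#' EGP/Rd shifts for the gain-loss group.
#'
#' @param n number of participants.
#' @param early_mean,early_sd early-pregnancy liver volume, cm^3.
#' @param change_mean,change_sd early-to-late liver volume change, cm^3.
#' @param tolerance_pct measurement-error band for the change classifier.
#' @param prop_gain,prop_nochange,prop_loss pregnancy-change subgroup
#'   proportions (must sum to 1).
#' @param completion_fraction fraction returning for the postwean visit.
#' @param pattern_counts_17 postwean trajectory quota for 17 completers,
#'   scaled proportionally for other cohort sizes: gain-loss, loss-gain,
#'   no-change, continuous-gain, gain-then-no-change.
#' @param htn_not_gain_loss hypertension prevalence in the not-gain-loss
#'   completers (zero in gain-loss by construction).
#' @param egp_shift_sd,rd_shift_sd late-pregnancy group effect for
#'   gain-loss completers, in within-cohort SD units.
#' @param weight_liver_r correlation of early-visit weight with early liver
#'   volume (the baseline "hepatostat").
#' @param change_vars data frame of covariate change targets/scales; see
#'   `COHORT_CHANGE_VARS`.
#' @param quota enforce subgroup counts exactly by stratified sampling
#'   (default); when `FALSE` subgroup membership is emergent from the draws
#'   and correlations are exactly those of the latent factor model.
#' @param seed RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = 47,
                        early_mean = 1239, early_sd = 220.8,
                        change_mean = 182, change_sd = 197,
                        tolerance_pct = 7,
                        prop_gain = 34 / 47, prop_nochange = 10 / 47,
                        prop_loss = 3 / 47,
                        completion_fraction = 17 / 47,
                        pattern_counts_17 = c(`gain-loss` = 9,
                                              `loss-gain` = 3,
                                              `no-change` = 3,
                                              `continuous-gain` = 1,
                                              `gain-no-change` = 1),
                        htn_not_gain_loss = 0.5,
                        egp_shift_sd = 1, rd_shift_sd = 1,
                        weight_liver_r = 0.5,
                        change_vars = COHORT_CHANGE_VARS,
                        quota = TRUE, seed = 1L) {
  props <- c(prop_gain, prop_nochange, prop_loss)
  if (any(props < 0) || abs(sum(props) - 1) > 1e-8)
    stop("subgroup proportions must be nonnegative and sum to 1")
  if (completion_fraction < 0 || completion_fraction > 1)
    stop("completion fraction must be in [0, 1]")
  if (any(abs(change_vars$r_target) >= 1))
    stop("infeasible correlation targets (|r| >= 1): ",
         paste(change_vars$variable[abs(change_vars$r_target) >= 1],
               collapse = ", "))
  if (early_sd < 0 || change_sd < 0) stop("SDs must be >= 0")
  structure(list(n = as.integer(n), early_mean = early_mean,
                 early_sd = early_sd, change_mean = change_mean,
                 change_sd = change_sd, tolerance_pct = tolerance_pct,
                 props = props, completion_fraction = completion_fraction,
                 pattern_counts_17 = pattern_counts_17,
                 htn_not_gain_loss = htn_not_gain_loss,
                 egp_shift_sd = egp_shift_sd, rd_shift_sd = rd_shift_sd,
                 weight_liver_r = weight_liver_r, change_vars = change_vars,
                 quota = isTRUE(quota), seed = as.integer(seed)),
            class = "cohort_spec")
}

# Largest-remainder apportionment of `n` among `props`.
apportion <- function(n, props) {
  raw <- n * props / sum(props)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Draw one batch of latent participants: early volume, liver change, and
# all covariate baselines/changes tied to the liver change by a one-factor
# Gaussian copula (the factor is the standardised liver change, so each
# covariate change hits its target correlation and the matrix is PSD by
# construction).
draw_latent <- function(m, spec) {
  cv <- spec$change_vars
  early <- rnorm(m, spec$early_mean, spec$early_sd)
  z <- rnorm(m)
  change <- spec$change_mean + spec$change_sd * z
  ok <- early > 0 & early + change > 0
  out <- data.frame(early = early, change = change, z = z)
  for (i in seq_len(nrow(cv))) {
    r <- cv$r_target[i]
    e <- rnorm(m)
    out[[paste0("d_", cv$variable[i])]] <-
      cv$change_mean[i] + cv$change_sd[i] * (r * z + sqrt(1 - r^2) * e)
  }
  # baseline weight tied to early liver volume (the "hepatostat")
  z_early <- if (spec$early_sd > 0) (early - spec$early_mean) / spec$early_sd
             else rep(0, m)
  rw <- spec$weight_liver_r
  wrow <- match("weight", cv$variable)
  out$b_weight <- cv$base_mean[wrow] + cv$base_sd[wrow] *
    (rw * z_early + sqrt(1 - rw^2) * rnorm(m))
  for (i in seq_len(nrow(cv))) {
    v <- cv$variable[i]
    if (v == "weight") next
    out[[paste0("b_", v)]] <- rnorm(m, cv$base_mean[i], cv$base_sd[i])
  }
  out[ok, , drop = FALSE]
}

pregnancy_class <- function(latent, tolerance_pct) {
  classify_change(latent$early, latent$early + latent$change, tolerance_pct)
}

#' Simulate a cohort table
#'
#' Draws the participant-level latent variables, assigns pregnancy-change
#' subgroups (by exact stratified quotas by default, or emergent when
#' `spec$quota` is FALSE), selects postwean completers and their trajectory
#' patterns, places hypertension only in not-gain-loss completers, injects
#' the late-pregnancy EGP/Rd shifts for the gain-loss group, and emits a
#' tidy table with one row per participant-visit. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return A data frame of class `cohort_table`; every participant has
#'   `early` and `late` rows, completers also a `postwean` row.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  tol <- spec$tolerance_pct

  if (spec$quota) {
    want <- apportion(n, spec$props)          # gain, no-change, loss
    names(want) <- c("gain", "no-change", "loss")
    pool <- draw_latent(max(50L, 25L * n), spec)
    cls <- pregnancy_class(pool, tol)
    picked <- list()
    for (g in names(want)) {
      idx <- which(cls == g)
      guard <- 0L
      while (length(idx) < want[[g]] && guard < 200L) {
        extra <- draw_latent(max(50L, 25L * n), spec)
        pool <- rbind(pool, extra)
        cls <- c(cls, pregnancy_class(extra, tol))
        idx <- which(cls == g)
        guard <- guard + 1L
      }
      if (length(idx) < want[[g]])
        stop("could not fill subgroup quota for ", g,
             " (degenerate spec for this tolerance)")
      picked[[g]] <- idx[seq_len(want[[g]])]
    }
    latent <- pool[unlist(picked), , drop = FALSE]
    preg <- rep(names(want), times = want)
  } else {
    latent <- draw_latent(ceiling(n * 1.2) + 20L, spec)
    guard <- 0L
    while (nrow(latent) < n && guard < 200L) {
      latent <- rbind(latent, draw_latent(n, spec))
      guard <- guard + 1L
    }
    latent <- latent[seq_len(n), , drop = FALSE]
    preg <- pregnancy_class(latent, tol)
  }
  rownames(latent) <- NULL
  early_vol <- latent$early
  late_vol <- latent$early + latent$change

  # --- postwean completers and trajectory patterns ---------------------
  n_complete <- apportion(n, c(spec$completion_fraction,
                               1 - spec$completion_fraction))[1]
  pattern <- rep(NA_character_, n)
  post_vol <- rep(NA_real_, n)
  if (n_complete > 0) {
    pq <- apportion(n_complete, spec$pattern_counts_17)
    names(pq) <- names(spec$pattern_counts_17)
    # each pattern draws its completers from a compatible pregnancy stratum
    needs <- c(`gain-loss` = "gain", `loss-gain` = "loss",
               `no-change` = "no-change", `continuous-gain` = "gain",
               `gain-no-change` = "gain")
    avail <- split(seq_len(n), preg)
    for (p in names(pq)) {
      k <- pq[[p]]
      if (k == 0) next
      stratum <- needs[[p]]
      cand <- setdiff(avail[[stratum]], which(!is.na(pattern)))
      k <- min(k, length(cand))
      if (k == 0) next
      sel <- if (length(cand) == 1L) cand else sample(cand, k)
      pattern[sel] <- p
    }
    # top up to n_complete if quotas were infeasible for these strata
    short <- n_complete - sum(!is.na(pattern))
    if (short > 0) {
      cand <- which(is.na(pattern))
      sel <- if (length(cand) == 1L) cand else sample(cand, min(short, length(cand)))
      pattern[sel] <- ifelse(preg[sel] == "gain", "gain-loss",
                             ifelse(preg[sel] == "loss", "loss-gain",
                                    "no-change"))
    }
    # postwean percent change (relative to late volume) per pattern
    draw_pct <- function(m, lo, hi, mean, sd) {
      x <- rnorm(m, mean, sd)
      bad <- x <= lo | x >= hi
      guard <- 0L
      while (any(bad) && guard < 1000L) {
        x[bad] <- rnorm(sum(bad), mean, sd)
        bad <- x <= lo | x >= hi
        guard <- guard + 1L
      }
      pmin(pmax(x, lo + 0.1), hi - 0.1)
    }
    for (p in names(pq)) {
      idx <- which(pattern == p)
      if (!length(idx)) next
      pct <- switch(p,
        `gain-loss` = draw_pct(length(idx), -25, -7.5, -13, 4),
        `loss-gain` = draw_pct(length(idx), 7.5, 25, 13, 4),
        `no-change` = ,
        `gain-no-change` = draw_pct(length(idx), -6.5, 6.5, 0, 3),
        `continuous-gain` = draw_pct(length(idx), 7.5, 25, 12, 3))
      post_vol[idx] <- late_vol[idx] * (1 + pct / 100)
    }
  }
  complete <- !is.na(pattern)
  gain_loss <- !is.na(pattern) & pattern == "gain-loss"

  # --- hypertension: confined to the not-gain-loss completers ----------
  htn <- rep(FALSE, n)
  ngl <- which(complete & !gain_loss)
  if (length(ngl)) {
    k <- apportion(length(ngl), c(spec$htn_not_gain_loss,
                                  1 - spec$htn_not_gain_loss))[1]
    if (k > 0) {
      sel <- if (length(ngl) == 1L) ngl else sample(ngl, k)
      htn[sel] <- TRUE
    }
  }

  # --- assemble the tidy table -----------------------------------------
  cv <- spec$change_vars
  base <- as.data.frame(lapply(cv$variable, function(v) latent[[paste0("b_", v)]]))
  delta <- as.data.frame(lapply(cv$variable, function(v) latent[[paste0("d_", v)]]))
  names(base) <- names(delta) <- cv$variable

  # late-pregnancy EGP/Rd group shift for gain-loss participants
  late_cov <- base + delta
  egp_sd <- sd(late_cov$egp)
  rd_sd <- sd(late_cov$rd)
  late_cov$egp[gain_loss] <- late_cov$egp[gain_loss] + spec$egp_shift_sd * egp_sd
  late_cov$rd[gain_loss] <- late_cov$rd[gain_loss] + spec$rd_shift_sd * rd_sd

  # newborn anthropometrics, independent of pattern group (the cohort's
  # null finding)
  nb_weight <- rnorm(n, 3400, 450)
  nb_length <- rnorm(n, 50, 2.5)
  ponderal <- 100 * nb_weight / nb_length^3

  mk_rows <- function(stage, vols, covs, keep) {
    d <- data.frame(id = seq_len(n), stage = stage, liver_volume = vols,
                    covs, pregnancy_class = preg, pattern = pattern,
                    hypertension = htn, newborn_weight = nb_weight,
                    newborn_length = nb_length, ponderal_index = ponderal)
    d[keep, , drop = FALSE]
  }
  postwean_cov <- base  # covariates revert toward baseline after weaning
  tab <- rbind(mk_rows("early", early_vol, base, rep(TRUE, n)),
               mk_rows("late", late_vol, late_cov, rep(TRUE, n)),
               mk_rows("postwean", post_vol, postwean_cov, complete))
  tab <- tab[order(tab$id, match(tab$stage, c("early", "late", "postwean"))), ]
  rownames(tab) <- NULL
  attr(tab, "spec") <- spec
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Attach synthetic slice stacks to a cohort
#'
#' Gives every participant-visit one or more liver slice stacks whose
#' slice-summation volume reproduces the tabulated volume (exactly when
#' `operator_noise_sd = 0`, or with a multiplicative per-replicate operator
#' error otherwise), so the volumetric pipeline can run end to end.
#'
#' @param cohort a [simulate_cohort()] table.
#' @param n_slices,interval_cm stack geometry (defaults: 40 slices at 0.6 cm).
#' @param replicates stacks per visit (2 emulates the two-operator
#'   measurement-error exercise).
#' @param operator_noise_sd SD of the multiplicative operator error
#'   (fraction; 0 = exact).
#' @param seed RNG seed.
#' @return Named list, one element per `"<id>_<stage>"`, each a list of
#'   [slice_roi_series()] replicates.
#' @export
attach_imaging <- function(cohort, n_slices = 40, interval_cm = 0.6,
                           replicates = 1, operator_noise_sd = 0,
                           seed = 1L) {
  stopifnot(inherits(cohort, "cohort_table"))
  set.seed(seed)
  out <- vector("list", nrow(cohort))
  names(out) <- paste0(cohort$id, "_", cohort$stage)
  for (i in seq_len(nrow(cohort))) {
    v <- cohort$liver_volume[i]
    reps <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      target <- v * (1 + if (operator_noise_sd > 0)
        rnorm(1, sd = operator_noise_sd) else 0)
      reps[[r]] <- make_liver_slice_stack(
        target, n_slices = n_slices, interval_cm = interval_cm,
        stage = cohort$stage[i],
        seed = sample.int(.Machine$integer.max, 1))
    }
    out[[i]] <- reps
  }
  out
}
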