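#' Ordered per-slice liver ROI areas
#'
#' The input to slice-summation volumetry: one freehand ROI area per axial
#' slice, with a fixed inter-slice interval.
#'
#' @param areas_cm2 nonnegative per-slice areas, cm^2; at least one slice.
#' @param interval_cm inter-slice spacing, cm; > 0.
#' @param stage optional visit tag: `"early"`, `"late"` or `"postwean"`.
#' @return A `slice_roi_series` object.
#' @export
slice_roi_series <- function(areas_cm2, interval_cm, stage = NA_character_) {
  areas_cm2 <- as.numeric(areas_cm2)
  if (length(areas_cm2) < 1L) stop("need at least one slice")
  if (any(!is.finite(areas_cm2)) || any(areas_cm2 < 0))
    stop("areas must be finite and nonnegative")
  if (!is.numeric(interval_cm) || length(interval_cm) != 1L || interval_cm <= 0)
    stop("interval must be a single positive number (cm)")
  if (!is.na(stage) && !stage %in% c("early", "late", "postwean"))
    stop("stage must be early, late or postwean")
  structure(list(areas_cm2 = areas_cm2, interval_cm = interval_cm,
                 stage = stage),
            class = "slice_roi_series")
}

#' @export
print.slice_roi_series <- function(x, ...) {
  cat("<slice_roi_series> ", length(x$areas_cm2), " slices x ",
      x$interval_cm, " cm",
      if (!is.na(x$stage)) paste0(" [", x$stage, "]"), "; volume ",
      round(compute_liver_volume(x), 1), " cm^3\n", sep = "")
  invisible(x)
}

#' Liver volume by slice summation
#'
#' The slice-summation estimator: each slice's ROI area times the
#' inter-slice interval, summed over all slices containing liver.
#'
#' @param series a [slice_roi_series()].
#' @return Volume in cm^3.
#' @export
compute_liver_volume <- function(series) {
  stopifnot(inherits(series, "slice_roi_series"))
  sum(series$areas_cm2) * series$interval_cm
}

#' Percent change between two volumes
#'
#' @param v_ref reference volume (> 0), the denominator.
#' @param v_new comparison volume.
#' @return `100 * (v_new - v_ref) / v_ref`.
#' @export
percent_change <- function(v_ref, v_new) {
  if (any(v_ref <= 0)) stop("reference volume must be positive")
  100 * (v_new - v_ref) / v_ref
}

#' Interoperator variability of paired volume measurements
#'
#' Per-case percent difference between two blinded operators, using the pair
#' mean as denominator (symmetric in the operators), and the symmetric range
#' `max |difference|` used to benchmark the measurement-error band (the
#' cohort's two-operator exercise yielded +-7%).
#'
#' @param op_a,op_b paired volumes per case, same length and case order.
#' @return List with `percent_diff` (per case) and `range` (max absolute
#'   percent difference).
#' @export
interoperator_variability <- function(op_a, op_b) {
  if (length(op_a) != length(op_b))
    stop("operators must report the same cases (unpaired input)")
  if (length(op_a) < 1L) stop("need at least one case")
  m <- (op_a + op_b) / 2
  if (any(m <= 0)) stop("volumes must be positive")
  pd <- 100 * (op_a - op_b) / m
  list(percent_diff = pd, range = max(abs(pd)))
}

#' Classify a volume change against the measurement-error band
#'
#' A change counts as real only when it exceeds the interoperator
#' measurement-error band: gain if the percent change is above `+tolerance`,
#' loss if below `-tolerance`, otherwise no-change.
#'
#' @param v_before baseline volume (> 0), the percent-change denominator.
#' @param v_after follow-up volume.
#' @param tolerance_pct half-width of the no-change band, percent; default 7
#'   (the observed two-operator range).
#' @return `"gain"`, `"no-change"` or `"loss"` (vectorised).
#' @export
classify_change <- function(v_before, v_after, tolerance_pct = 7) {
  pc <- percent_change(v_before, v_after)
  ifelse(pc > tolerance_pct, "gain",
         ifelse(pc < -tolerance_pct, "loss", "no-change"))
}

#' Classify a three-visit liver trajectory
#'
#' Combines the pregnancy change (early -> late, early volume as denominator)
#' and the postwean change (late -> postwean, late volume as denominator)
#' into the trajectory pattern: `"gain-loss"` iff pregnancy gain AND postwean
#' loss, else `"not gain-loss"` with a subtype (`loss-gain`, `no-change`,
#' `continuous-gain`, `continuous-loss`, or `other`).
#'
#' @param early,late,postwean visit volumes, all > 0; `postwean = NA` flags
#'   a non-completer (pattern undefined).
#' @param tolerance_pct see [classify_change()].
#' @return List with `pregnancy_change`, `postwean_change`, `pattern`,
#'   `subtype`, `complete`.
#' @export
classify_pattern <- function(early, late, postwean, tolerance_pct = 7) {
  preg <- classify_change(early, late, tolerance_pct)
  if (is.na(postwean)) {
    return(list(pregnancy_change = preg, postwean_change = NA_character_,
                pattern = NA_character_, subtype = NA_character_,
                complete = FALSE))
  }
  post <- classify_change(late, postwean, tolerance_pct)
  gain_loss <- preg == "gain" && post == "loss"
  subtype <- if (gain_loss) "gain-loss"
    else if (preg == "loss" && post == "gain") "loss-gain"
    else if (preg == "no-change" && post == "no-change") "no-change"
    else if (preg == "gain" && post == "gain") "continuous-gain"
    else if (preg == "loss" && post == "loss") "continuous-loss"
    else "other"
  list(pregnancy_change = preg, postwean_change = post,
       pattern = if (gain_loss) "gain-loss" else "not gain-loss",
       subtype = subtype, complete = TRUE)
}

#' Merge two overlapping scan stations
#'
#' Multi-station abdominal acquisitions overlap by a few slices; the merged
#' series keeps the overlapping slices from the upper (liver-centred)
#' station and drops the duplicates from the lower one.
#'
#' @param stack_upper,stack_lower [slice_roi_series()] with equal intervals;
#'   the upper station ends where the lower station begins, overlapping by
#'   `overlap_slices`.
#' @param overlap_slices number of duplicated slices; must be smaller than
#'   each stack.
#' @return Merged [slice_roi_series()] of length
#'   `len(upper) + len(lower) - overlap`.
#' @export
eliminate_station_overlap <- function(stack_upper, stack_lower, overlap_slices) {
  stopifnot(inherits(stack_upper, "slice_roi_series"),
            inherits(stack_lower, "slice_roi_series"))
  if (!isTRUE(all.equal(stack_upper$interval_cm, stack_lower$interval_cm)))
    stop("stations must share the slice interval")
  n_up <- length(stack_upper$areas_cm2)
  n_lo <- length(stack_lower$areas_cm2)
  if (overlap_slices < 0 || overlap_slices >= n_up || overlap_slices >= n_lo)
    stop("overlap must be nonnegative and smaller than each stack")
  keep_lower <- if (overlap_slices == 0) stack_lower$areas_cm2
                else stack_lower$areas_cm2[-seq_len(overlap_slices)]
  slice_roi_series(c(stack_upper$areas_cm2, keep_lower),
                   stack_upper$interval_cm, stage = stack_upper$stage)
}
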