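#' Tracer/insulin clamp record for one participant-visit
#'
#' Steady-state quantities from a hyperinsulinemic-euglycemic clamp with a
#' primed constant stable-isotope glucose infusion: the basal period (last
#' 30 min of the 2-h tracer infusion) gives basal endogenous glucose
#' production (EGP) by tracer dilution; the insulin clamp period (final 30
#' min) gives suppressed EGP and glucose disposal.
#'
#' @param tracer_rate_F tracer infusion rate, umol/kg/min; >= 0.
#' @param enrich_infusate infusate enrichment, mole percent excess (MPE),
#'   0-100.
#' @param enrich_basal basal plasma enrichment, MPE; 0 < value <= infusate.
#' @param enrich_clamp clamp-period plasma enrichment, MPE (NA if the clamp
#'   period is absent).
#' @param gir glucose infusion rate at clamp steady state, mg/kg/min.
#' @param insulin steady-state insulin, mU/L.
#' @param ffm fat-free mass, kg; > 0.
#' @param glucose plasma glucose, mg/dL (held near 90 during the clamp).
#' @return A `clamp_record` list.
#' @export
clamp_record <- function(tracer_rate_F, enrich_infusate, enrich_basal,
                         enrich_clamp = NA_real_, gir = NA_real_,
                         insulin = NA_real_, ffm = NA_real_, glucose = 90) {
  if (tracer_rate_F < 0) stop("tracer rate must be >= 0")
  if (enrich_infusate <= 0 || enrich_infusate > 100)
    stop("infusate enrichment must be in (0, 100] MPE")
  if (enrich_basal <= 0) stop("basal plasma enrichment must be positive (no dilution measurable at 0)")
  if (enrich_basal > enrich_infusate)
    stop("plasma enrichment cannot exceed infusate enrichment")
  if (!is.na(enrich_clamp) && (enrich_clamp <= 0 || enrich_clamp > enrich_infusate))
    stop("clamp plasma enrichment must be in (0, infusate]")
  if (!is.na(ffm) && ffm <= 0) stop("fat-free mass must be positive")
  structure(list(tracer_rate_F = tracer_rate_F,
                 enrich_infusate = enrich_infusate,
                 enrich_basal = enrich_basal, enrich_clamp = enrich_clamp,
                 gir = gir, insulin = insulin, ffm = ffm, glucose = glucose),
            class = "clamp_record")
}

#' Basal endogenous glucose production (Steele steady state)
#'
#' At isotopic steady state the tracer infusion F is diluted by endogenous
#' glucose appearance, so `EGP = F * (E_inf / E_plasma - 1)`.
#'
#' @param rec a [clamp_record()].
#' @return Basal EGP in the tracer-rate units (per kg per min).
#' @export
basal_egp_steele <- function(rec) {
  stopifnot(inherits(rec, "clamp_record"))
  rec$tracer_rate_F * (rec$enrich_infusate / rec$enrich_basal - 1)
}

#' Insulin-suppressed EGP during the clamp
#'
#' Total glucose appearance during the clamp is measured by the same tracer
#' dilution applied to the clamp-period enrichment; EGP is what remains
#' after subtracting the exogenous glucose infusion, floored at zero
#' (tracer noise can push the difference slightly negative). Suppression is
#' expressed relative to basal EGP. The appearance formula is pluggable via
#' `ra_fn` because published restatements of the suppression method differ
#' in their non-steady-state correction terms; the default is the
#' steady-state dilution.
#'
#' @param rec a [clamp_record()] with clamp enrichment and `gir` present.
#' @param ra_fn function(rec) giving total glucose appearance during the
#'   clamp, same units as `gir`.
#' @return List with `egp_clamp`, `egp_basal` and `suppression_pct`
#'   (`NA` with a warning when basal EGP is zero).
#' @export
clamp_egp_suppressed <- function(rec, ra_fn = NULL) {
  stopifnot(inherits(rec, "clamp_record"))
  if (is.na(rec$enrich_clamp)) stop("clamp-period enrichment missing")
  if (is.na(rec$gir)) stop("glucose infusion rate missing")
  if (rec$gir < 0) stop("glucose infusion rate must be >= 0")
  egp_basal <- basal_egp_steele(rec)
  ra <- if (is.null(ra_fn))
    rec$tracer_rate_F * (rec$enrich_infusate / rec$enrich_clamp - 1)
  else ra_fn(rec)
  egp_clamp <- max(0, ra - rec$gir)
  suppression <- if (egp_basal <= 0) {
    warning("basal EGP is zero; suppression undefined")
    NA_real_
  } else 100 * (1 - egp_clamp / egp_basal)
  list(egp_clamp = egp_clamp, egp_basal = egp_basal,
       suppression_pct = suppression)
}

#' Glucose disposal rate at clamp steady state
#'
#' With plasma glucose clamped, appearance equals disposal, so
#' `Rd = GIR + EGP_clamp`.
#'
#' @param rec a [clamp_record()].
#' @param ra_fn see [clamp_egp_suppressed()].
#' @return Rd in the GIR units (mg/kg/min).
#' @export
rd_clamp <- function(rec, ra_fn = NULL) {
  if (is.na(rec$gir) || rec$gir < 0) stop("valid glucose infusion rate required")
  sup <- clamp_egp_suppressed(rec, ra_fn)
  rec$gir + sup$egp_clamp
}

#' Adjust a clamp metric for insulin level and fat-free mass
#'
#' Whole-body rates are expressed per kg fat-free mass and per unit
#' steady-state insulin: `value / (insulin * ffm)`.
#'
#' @param value whole-body metric (EGP, Rd or M value).
#' @param insulin_mU_L steady-state insulin, mU/L; > 0.
#' @param ffm_kg fat-free mass, kg; > 0.
#' @return Adjusted value.
#' @export
adjust_metric <- function(value, insulin_mU_L, ffm_kg) {
  if (any(insulin_mU_L <= 0) || any(ffm_kg <= 0))
    stop("insulin and fat-free mass must be positive")
  value / (insulin_mU_L * ffm_kg)
}

#' Two-compartment body composition from body density
#'
#' Air-displacement plethysmography yields body density `Db = mass/volume`;
#' the two-compartment model gives the fat fraction
#' `(1/Db - 1/d_ffm) / (1/d_fat - 1/d_ffm)`. During pregnancy the fat-free
#' compartment hydrates and its density falls, so `d_ffm` is supplied per
#' gestational stage (van Raaij-style pregnancy adjustment). The default
#' stage table is a placeholder with the standard nonpregnant value and
#' modest late-pregnancy reduction; supply assay-specific coefficients for
#' real analyses.
#'
#' @param mass_kg body mass, kg; > 0.
#' @param volume_L body volume, L; > 0.
#' @param stage gestational stage, a name of `d_ffm_table`.
#' @param d_fat fat density, g/cm^3 (default 0.9007).
#' @param d_ffm_table named vector of stage-dependent fat-free-mass
#'   densities, g/cm^3.
#' @return List with `fat_fraction` (clamped to \[0, 1\] with a warning when
#'   density falls outside the model range), `fat_pct`, `fat_mass_kg`,
#'   `ffm_kg`, `density`.
#' @export
body_composition <- function(mass_kg, volume_L, stage = "early",
                             d_fat = 0.9007,
                             d_ffm_table = c(nonpregnant = 1.100,
                                             early = 1.099,
                                             late = 1.087,
                                             postwean = 1.100)) {
  if (mass_kg <= 0 || volume_L <= 0) stop("mass and volume must be positive")
  d_ffm <- d_ffm_table[[stage]]
  if (is.null(d_ffm)) stop("unknown stage: ", stage)
  if (d_fat >= d_ffm) stop("fat density must be below fat-free density")
  db <- mass_kg / volume_L  # kg/L == g/cm^3
  frac <- (1 / db - 1 / d_ffm) / (1 / d_fat - 1 / d_ffm)
  if (frac < 0 || frac > 1) {
    warning("body density outside the (d_fat, d_ffm) range; fat fraction clamped")
    frac <- min(1, max(0, frac))
  }
  fat <- frac * mass_kg
  list(fat_fraction = frac, fat_pct = 100 * frac, fat_mass_kg = fat,
       ffm_kg = mass_kg - fat, density = db)
}

#' Intrahepatic lipid fraction from MRS peak areas
#'
#' IHL is the ratio of the primary lipid peak area to the water peak area;
#' repeated acquisitions are averaged as per-series ratios.
#'
#' @param lipid_peak_area,water_peak_area peak areas, one value per
#'   acquisition series; water areas must be positive.
#' @return Mean of the per-series lipid/water ratios.
#' @export
ihl_fraction <- function(lipid_peak_area, water_peak_area) {
  if (length(lipid_peak_area) != length(water_peak_area))
    stop("peak-area vectors must be paired")
  if (any(water_peak_area <= 0)) stop("water peak area must be positive")
  if (any(lipid_peak_area < 0)) stop("lipid peak area must be nonnegative")
  mean(lipid_peak_area / water_peak_area)
}

#' Fit a weighted linear calibration curve
#'
#' LC-MS/MS quantification fits analyte/internal-standard peak-area ratio
#' against standard concentration with a linear model under 1/x weighting
#' (weights inverse to concentration, stabilising the relative error that
#' dominates mass-spectrometric response).
#'
#' @param concentration standard concentrations; > 0 under 1/x weighting;
#'   at least 3 distinct standards.
#' @param ratio peak-area ratios, paired with `concentration`.
#' @param weighting `"1/x"` (default) or `"none"`.
#' @return A `calibration_curve` with `slope`, `intercept`, `weighting`,
#'   `range` (min/max standard concentration).
#' @export
fit_calibration <- function(concentration, ratio, weighting = c("1/x", "none")) {
  weighting <- match.arg(weighting)
  if (length(concentration) != length(ratio)) stop("unpaired standards")
  if (length(concentration) < 3L) stop("need at least 3 standards")
  if (length(unique(concentration)) < 2L) stop("standards must span a range")
  if (weighting == "1/x" && any(concentration <= 0))
    stop("1/x weighting requires positive concentrations")
  w <- if (weighting == "1/x") 1 / concentration else rep(1, length(concentration))
  # weighted least squares in closed form
  sw <- sum(w)
  xb <- sum(w * concentration) / sw
  yb <- sum(w * ratio) / sw
  slope <- sum(w * (concentration - xb) * (ratio - yb)) /
    sum(w * (concentration - xb)^2)
  intercept <- yb - slope * xb
  if (slope == 0) stop("degenerate fit: zero slope")
  structure(list(slope = slope, intercept = intercept, weighting = weighting,
                 range = range(concentration)),
            class = "calibration_curve")
}

#' Back-calculate a concentration from a calibration curve
#'
#' @param curve a [fit_calibration()] result.
#' @param peak_ratio observed analyte/internal-standard peak-area ratio
#'   (vectorised).
#' @return Data frame with `concentration` and `out_of_range` (TRUE when the
#'   back-calculated value falls outside the calibration range).
#' @export
quantify <- function(curve, peak_ratio) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("degenerate curve: zero slope")
  conc <- (peak_ratio - curve$intercept) / curve$slope
  data.frame(concentration = conc,
             out_of_range = conc < curve$range[1] | conc > curve$range[2])
}
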