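#' Specification of a synthetic abdominal phantom
#'
#' Describes a 2.5D abdominal phantom: an elliptical body cross-section with
#' a bright subcutaneous fat (SAT) ring, a muscle wall, an organ interior
#' with scattered visceral fat (VAT) blobs, optional bright "uterus" and
#' "liver" regions (the two structures that are notorious false positives
#' for adipose classification and therefore carry exclusion masks), a smooth
#' multiplicative bias field, and additive Gaussian noise. Axial slices lie
#' along the third array axis and share topology, with slow axial variation,
#' mimicking thick-slice (6 mm) abdominal T1 acquisitions.
#'
#' @param shape grid dimensions (x, y, slices).
#' @param spacing voxel size mm; default (1.25, 1.25, 6) matches a typical
#'   abdominal T1 protocol.
#' @param body_radii_mm in-plane semi-axes of the body ellipse.
#' @param sat_thickness_mm thickness of the subcutaneous fat ring.
#' @param muscle_thickness_mm thickness of the abdominal-wall muscle shell
#'   just inside the SAT ring.
#' @param n_vat_blobs number of scattered visceral fat blobs.
#' @param vat_radius_mm_range in-plane blob radius range, mm.
#' @param vat_margin_mm minimum clearance kept between VAT blobs and the
#'   inner muscle boundary, so SAT and VAT stay morphologically separable.
#' @param include_uterus,include_liver add an adipose-bright lower-slab
#'   "uterus" region / an upper-slab "liver" region, each with a matching
#'   exclusion mask.
#' @param class_means mean intensity per class, named
#'   `background/sat/vat/muscle/organ/uterus/liver`. The adipose classes
#'   must be brightest (T1 fat hyperintensity), then organ, then muscle,
#'   then background, so that thresholding is well posed.
#' @param noise_sd additive Gaussian noise SD (0 = noise free). The adipose
#'   mean divided by this SD is the phantom's nominal SNR.
#' @param bias_amplitude peak log-amplitude of the multiplicative bias field
#'   (0.3 means roughly +-30%); 0 disables it.
#' @param bias_sigma_mm smoothness (Gaussian correlation length) of the bias
#'   field.
#' @param axial_taper fractional shrinkage of the body ellipse from the
#'   central slice towards the stack ends (slow axial variation).
#' @param seed RNG seed; fixed seed gives a bit-identical phantom.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(160, 160, 30),
                         spacing = c(1.25, 1.25, 6),
                         body_radii_mm = c(85, 65),
                         sat_thickness_mm = 15,
                         muscle_thickness_mm = 9,
                         n_vat_blobs = 25,
                         vat_radius_mm_range = c(4, 11),
                         vat_margin_mm = 6,
                         include_uterus = TRUE,
                         include_liver = TRUE,
                         class_means = c(background = 40, sat = 1000,
                                         vat = 1000, muscle = 300,
                                         organ = 550, uterus = 950,
                                         liver = 520),
                         noise_sd = 0,
                         bias_amplitude = 0,
                         bias_sigma_mm = 60,
                         axial_taper = 0.06,
                         seed = 1L) {
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               body_radii_mm = body_radii_mm,
               sat_thickness_mm = sat_thickness_mm,
               muscle_thickness_mm = muscle_thickness_mm,
               n_vat_blobs = as.integer(n_vat_blobs),
               vat_radius_mm_range = vat_radius_mm_range,
               vat_margin_mm = vat_margin_mm,
               include_uterus = isTRUE(include_uterus),
               include_liver = isTRUE(include_liver),
               class_means = class_means, noise_sd = noise_sd,
               bias_amplitude = bias_amplitude, bias_sigma_mm = bias_sigma_mm,
               axial_taper = axial_taper, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (any(shape < 1L)) stop("grid dimensions must be >= 1")
    if (any(spacing <= 0)) stop("spacing must be positive")
    if (sat_thickness_mm <= 0 || muscle_thickness_mm <= 0)
      stop("shell thicknesses must be positive")
    if (sat_thickness_mm + muscle_thickness_mm >= min(body_radii_mm))
      stop("degenerate spec: SAT ring plus muscle wall thicker than the body radius")
    if (noise_sd < 0 || bias_amplitude < 0) stop("noise/bias must be >= 0")
    cm <- class_means
    if (!(min(cm[c("sat", "vat")]) > cm[["organ"]] &&
          cm[["organ"]] > cm[["muscle"]] && cm[["muscle"]] > cm[["background"]]))
      stop("class means must be ordered adipose > organ > muscle > background")
  })
  invisible(spec)
}

# Per-slice taper factor: ellipse largest at the central slice, shrinking
# smoothly (cosine) towards the ends.
axial_scale <- function(nz, taper) {
  if (nz == 1L) return(1)
  z <- seq(0, 1, length.out = nz)
  1 - taper * (1 - cos(2 * pi * (z - 0.5))) / 2
}

# Physical in-plane coordinates (mm) centred on the grid.
plane_coords <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - (shape[1] + 1) / 2) * spacing[1],
       y = (seq_len(shape[2]) - (shape[2] + 1) / 2) * spacing[2])
}

inside_ellipse <- function(x, y, radii) {
  outer(x^2 / radii[1]^2, y^2 / radii[2]^2, `+`) <= 1
}

#' Generate an abdominal phantom with ground truth
#'
#' Renders the geometry described by a [phantom_spec()] into an intensity
#' volume (class-mean map times a smooth multiplicative bias field, plus
#' additive Gaussian noise), the ground-truth five-class label volume, the
#' bias field itself, and binary uterus/liver exclusion masks (disjoint from
#' SAT ground truth).
#'
#' @param spec a [phantom_spec()].
#' @return List with elements `image` ([image_volume()]), `labels`
#'   ([label_volume()]), `bias` (numeric array, the multiplicative field),
#'   `exclusion` (list of logical arrays `uterus`, `liver`), and `geometry`
#'   (the sampled blob table and shell radii, for independent re-rasterisation).
#' @export
make_abdomen_phantom <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  dm <- spec$shape
  sp <- spec$spacing
  pc <- plane_coords(dm, sp)
  taper <- axial_scale(dm[3], spec$axial_taper)

  labels <- array(CLASS_UNLABELED, dm)
  body <- array(FALSE, dm)
  interior <- array(FALSE, dm)   # inside the muscle wall
  vat_region <- array(FALSE, dm) # interior eroded by the VAT margin

  r_body <- spec$body_radii_mm
  r_inner_sat <- r_body - spec$sat_thickness_mm
  r_inner_musc <- r_inner_sat - spec$muscle_thickness_mm
  r_vat_lim <- r_inner_musc - spec$vat_margin_mm
  if (any(r_vat_lim <= 0)) stop("degenerate spec: no room for VAT inside the muscle wall")

  for (z in seq_len(dm[3])) {
    s <- taper[z]
    in_body <- inside_ellipse(pc$x, pc$y, r_body * s)
    in_sat <- in_body & !inside_ellipse(pc$x, pc$y, r_inner_sat * s)
    in_musc <- inside_ellipse(pc$x, pc$y, r_inner_sat * s) &
      !inside_ellipse(pc$x, pc$y, r_inner_musc * s)
    in_int <- inside_ellipse(pc$x, pc$y, r_inner_musc * s)
    sl <- labels[, , z]
    sl[in_int] <- CLASS_ORGAN
    sl[in_musc] <- CLASS_MUSCLE
    sl[in_sat] <- CLASS_SAT
    labels[, , z] <- sl
    body[, , z] <- in_body
    interior[, , z] <- in_int
    vat_region[, , z] <- inside_ellipse(pc$x, pc$y, r_vat_lim * s)
  }

  # VAT blobs: axially elongated ellipsoids with centres kept inside the
  # margin-eroded interior so the blobs never touch the muscle wall.
  zc_mm <- (seq_len(dm[3]) - (dm[3] + 1) / 2) * sp[3]
  blobs <- data.frame(cx = numeric(0), cy = numeric(0), cz = numeric(0),
                      rx = numeric(0), ry = numeric(0), rz = numeric(0))
  if (spec$n_vat_blobs > 0) {
    n <- spec$n_vat_blobs
    rr <- spec$vat_radius_mm_range
    k <- 0L
    while (k < n) {
      cx <- runif(1, -r_vat_lim[1], r_vat_lim[1])
      cy <- runif(1, -r_vat_lim[2], r_vat_lim[2])
      if ((cx / r_vat_lim[1])^2 + (cy / r_vat_lim[2])^2 > 0.95) next
      cz <- runif(1, min(zc_mm), max(zc_mm))
      rx <- runif(1, rr[1], rr[2])
      ry <- runif(1, rr[1], rr[2])
      rz <- runif(1, 1.2, 2.5) * sp[3]  # span a few thick slices
      k <- k + 1L
      blobs[k, ] <- c(cx, cy, cz, rx, ry, rz)
    }
    for (b in seq_len(nrow(blobs))) {
      zr <- which(abs(zc_mm - blobs$cz[b]) <= blobs$rz[b])
      for (z in zr) {
        # ellipsoid cross-section at this slice
        f <- 1 - ((zc_mm[z] - blobs$cz[b]) / blobs$rz[b])^2
        if (f <= 0) next
        in_blob <- outer((pc$x - blobs$cx[b])^2 / (blobs$rx[b]^2 * f),
                         (pc$y - blobs$cy[b])^2 / (blobs$ry[b]^2 * f), `+`) <= 1
        sl <- labels[, , z]
        put <- in_blob & vat_region[, , z] & sl == CLASS_ORGAN
        sl[put] <- CLASS_VAT
        labels[, , z] <- sl
      }
    }
  }

  # "Uterus": bright (adipose-like) organ slab in the lower slices;
  # "liver": large organ-class slab in the upper slices. Both carry
  # exclusion masks; both live inside the VAT-margin region and displace
  # any VAT blobs there so ground-truth classes stay disjoint.
  uterus <- array(FALSE, dm)
  liver <- array(FALSE, dm)
  carve_slab <- function(mask, z_range, radii_scale, centre_mm) {
    for (z in z_range) {
      s <- taper[z]
      in_sl <- outer((pc$x - centre_mm[1])^2 / (r_vat_lim[1] * radii_scale[1] * s)^2,
                     (pc$y - centre_mm[2])^2 / (r_vat_lim[2] * radii_scale[2] * s)^2,
                     `+`) <= 1
      mask[, , z] <- in_sl & vat_region[, , z]
    }
    mask
  }
  nz <- dm[3]
  if (spec$include_uterus && nz >= 4) {
    uterus <- carve_slab(uterus, seq_len(max(2L, nz %/% 4)),
                         radii_scale = c(0.55, 0.55), centre_mm = c(0, -8))
    labels[uterus] <- CLASS_ORGAN  # truth class is organ, intensity adipose-like
  }
  if (spec$include_liver && nz >= 4) {
    liver <- carve_slab(liver, (nz - max(2L, nz %/% 4) + 1L):nz,
                        radii_scale = c(0.7, 0.6), centre_mm = c(12, 6))
    labels[liver] <- CLASS_ORGAN
  }

  # Intensity map from class means.
  cm <- spec$class_means
  lut <- c(cm[["background"]], cm[["sat"]], cm[["vat"]], cm[["muscle"]],
           cm[["organ"]])
  intens <- array(lut[labels + 1L], dm)
  intens[uterus] <- cm[["uterus"]]
  intens[liver] <- cm[["liver"]]

  bias <- make_bias_field(dm, sp, spec$bias_amplitude, spec$bias_sigma_mm)
  img <- intens * bias
  if (spec$noise_sd > 0)
    img <- img + array(rnorm(prod(dm), sd = spec$noise_sd), dm)

  list(image = image_volume(img, spacing = sp),
       labels = label_volume(labels, spacing = sp),
       bias = bias,
       exclusion = list(uterus = uterus, liver = liver),
       geometry = list(blobs = blobs, body_radii_mm = r_body,
                       r_inner_sat = r_inner_sat, r_inner_musc = r_inner_musc,
                       r_vat_lim = r_vat_lim, taper = taper))
}

# Smooth multiplicative bias: Gaussian-blurred white noise in the log domain,
# rescaled so the maximum |log field| equals `amplitude`, then exponentiated.
make_bias_field <- function(dm, spacing, amplitude, sigma_mm) {
  if (amplitude <= 0) return(array(1, dm))
  raw <- array(rnorm(prod(dm)), dm)
  sm <- gaussian_smooth(raw, sigma_mm / spacing)
  sm <- sm - mean(sm)
  sm <- sm / max(abs(sm))
  exp(amplitude * sm)
}

#' Synthesize a per-slice liver ROI series with a known total volume
#'
#' Emulates the freehand slice-by-slice liver areas that slice-summation
#' volumetry consumes: a smooth axial area profile scaled so the
#' slice-summation volume hits the target exactly (to well within 0.1%).
#'
#' @param target_volume_cm3 desired slice-summation volume, cm^3; > 0.
#' @param n_slices number of slices containing liver, >= 1.
#' @param interval_cm inter-slice interval, cm; > 0.
#' @param shape_profile `"dome"` (parabolic-arch area profile typical of a
#'   liver stack) or `"uniform"`.
#' @param noise_sd multiplicative per-slice jitter SD (fraction) applied
#'   before the exact rescaling, emulating freehand outlining variation.
#' @param stage optional stage tag (`"early"`, `"late"`, `"postwean"`).
#' @param seed RNG seed for the jitter.
#' @return A [slice_roi_series()].
#' @export
make_liver_slice_stack <- function(target_volume_cm3, n_slices = 40,
                                   interval_cm = 0.6,
                                   shape_profile = c("dome", "uniform"),
                                   noise_sd = 0.02, stage = NA_character_,
                                   seed = 1L) {
  if (target_volume_cm3 <= 0) stop("target volume must be positive")
  if (n_slices < 1L) stop("need at least one slice")
  if (interval_cm <= 0) stop("interval must be positive")
  shape_profile <- match.arg(shape_profile)
  set.seed(seed)
  base <- switch(shape_profile,
    uniform = rep(1, n_slices),
    dome = {
      u <- seq(0, 1, length.out = n_slices + 2L)[2:(n_slices + 1L)]
      0.15 + sin(pi * u)  # smooth arch, nonzero at the caps
    })
  if (noise_sd > 0 && n_slices > 1L)
    base <- base * pmax(0.05, 1 + rnorm(n_slices, sd = noise_sd))
  areas <- base * target_volume_cm3 / (sum(base) * interval_cm)
  slice_roi_series(areas, interval_cm, stage = stage)
}
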