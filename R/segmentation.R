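# The five-class abdominal segmentation stages. Masks are plain logical 3D
# arrays on the image grid; the stages compose into segment_abdomen() and
# are individually testable against phantom ground truth.

#' Extract the body mask
#'
#' Separates air background from body tissue by hierarchical Otsu: a first
#' split isolates the bright tissue, a second split of the remaining dark
#' half then falls into the air-to-darkest-tissue gap (a single Otsu lands
#' between tissue classes instead, because air dominates the histogram).
#' Small components are removed and interior holes filled in-plane.
#'
#' @param vol an [image_volume()].
#' @param min_voxels smallest retained component.
#' @return Logical array.
#' @export
body_mask <- function(vol, min_voxels = 64) {
  a <- vol$data
  if (diff(range(a)) == 0) return(array(TRUE, dim(a)))
  thr1 <- otsu_threshold(a)
  lower <- a[a < thr1]
  thr <- if (length(lower) > 1 && diff(range(lower)) > 0)
    otsu_threshold(lower) else thr1
  fill_holes(remove_small_components(a > thr, min_voxels))
}

#' Threshold total adipose tissue
#'
#' Bright-voxel thresholding inside the body mask (fat is hyperintense on
#' T1), with small-component cleanup. The default rule is Otsu computed
#' within the body mask, overridable by an absolute value.
#'
#' @param vol an [image_volume()] (bias-corrected).
#' @param body logical body mask; must be nonempty.
#' @param cfg a [segmentation_config()].
#' @return Logical total-adipose mask, a subset of `body`.
#' @export
threshold_adipose <- function(vol, body, cfg = segmentation_config()) {
  if (!any(body)) stop("body mask is empty")
  thr <- if (identical(cfg$adipose_threshold, "otsu"))
    otsu_threshold(vol$data[body]) else cfg$adipose_threshold
  mask <- vol$data > thr & body
  if (!any(mask)) {
    warning("adipose threshold excludes all voxels; returning empty mask")
    return(mask)
  }
  remove_small_components(mask, cfg$min_component_voxels)
}

#' Muscle segmentation by seeded compact watershed
#'
#' Grows the sparse manual muscle seed map (the cohort protocol seeded 11 of
#' 30 slices) through the non-adipose body with a compact watershed on the
#' gradient magnitude: flooding prefers flat-intensity terrain but pays an
#' additive penalty per mm travelled from its seed, which keeps regions
#' compact across unseeded slices.
#'
#' @param vol bias-corrected [image_volume()].
#' @param seed_labels a [label_volume()] carrying at least one muscle-coded
#'   voxel (code 3); other class codes act as competing seeds.
#' @param body logical body mask.
#' @param adipose logical total-adipose mask; excluded from the muscle
#'   terrain so the result is disjoint from fat.
#' @param cfg a [segmentation_config()].
#' @return Logical muscle mask containing all muscle seeds.
#' @export
segment_muscle <- function(vol, seed_labels, body, adipose,
                           cfg = segmentation_config()) {
  stopifnot(inherits(seed_labels, "label_volume"))
  seeds <- seed_labels$labels
  if (!any(seeds == CLASS_MUSCLE)) stop("no muscle seeds supplied")
  terrain <- body & !adipose
  smoothed <- image_volume(gaussian_smooth(vol$data, c(1, 1, 0)),
                           spacing = vol$spacing, origin = vol$origin)
  grad <- gradient_magnitude(smoothed)
  markers <- array(0L, dim(seeds))
  markers[seeds == CLASS_MUSCLE & terrain] <- 1L
  markers[seeds %in% c(CLASS_ORGAN, CLASS_SAT, CLASS_VAT) & terrain] <- 2L
  ws <- .compact_watershed(as.numeric(grad), markers, terrain, dim(seeds),
                           vol$spacing, cfg$watershed_compactness)
  muscle <- ws == 1L
  muscle | (seeds == CLASS_MUSCLE & terrain)
}

#' Subcutaneous fat as the peripheral adipose shell
#'
#' Morphological inward evolution of a contour initialised at the body
#' boundary: the adipose mask is opened (erosion radius `morph_radius`) to
#' cut thin bridges into internal fat, the opened mask is propagated
#' geodesically from the boundary-adjacent fat inward (capped at
#' `contour_iterations` steps), re-dilated inside the adipose mask, and
#' morphologically closed. The result is the connected subcutaneous shell;
#' internal (visceral) fat is left behind.
#'
#' @param total_adipose logical total-adipose mask.
#' @param body logical body mask; `total_adipose` must be inside it.
#' @param cfg a [segmentation_config()].
#' @return Logical SAT mask, a subset of `total_adipose`.
#' @export
segment_sat <- function(total_adipose, body, cfg = segmentation_config()) {
  if (any(total_adipose & !body)) stop("total_adipose must lie inside body")
  if (!any(total_adipose)) return(total_adipose)
  r <- c(cfg$morph_radius, cfg$morph_radius, 0)  # in-plane: thick slices
  core <- erode_mask(total_adipose, r)
  boundary <- body & !erode_mask(body, r)
  front <- dilate_mask(boundary, r) & core
  if (!any(front)) front <- boundary & total_adipose
  # geodesic propagation of the boundary front through the opened adipose
  grown <- front
  for (i in seq_len(cfg$contour_iterations)) {
    nxt <- dilate_mask(grown, c(1, 1, 0)) & core
    if (identical(nxt, grown)) break
    grown <- nxt
  }
  claim <- dilate_mask(grown, r) & total_adipose
  # assign whole adipose components by majority claim: the peripheral shell
  # is the component(s) the boundary front swept; internal fat is untouched
  comp <- label_components(total_adipose, 6)
  n_comp <- max(comp)
  if (n_comp == 0L) return(total_adipose)
  sizes <- tabulate(comp, n_comp)
  claimed <- tabulate(comp[claim], n_comp)
  keep <- which(claimed / sizes >= 0.5)
  array(comp %in% keep, dim(total_adipose))
}

#' Visceral fat by subtraction
#'
#' @param total_adipose logical total-adipose mask.
#' @param sat logical SAT mask; must be a subset of `total_adipose`.
#' @return Logical VAT mask: `total_adipose & !sat` (so SAT and VAT
#'   partition the adipose mask exactly).
#' @export
vat_by_subtraction <- function(total_adipose, sat) {
  if (any(sat & !total_adipose))
    stop("contract violation: sat must be a subset of total_adipose")
  total_adipose & !sat
}

#' Remove uterus/liver false positives from an adipose mask
#'
#' The uterus/placenta and the liver classify as fat at high rates; manually
#' outlined exclusion masks are subtracted from adipose (or VAT) masks.
#'
#' @param mask logical adipose or VAT mask.
#' @param uterus_mask,liver_mask logical exclusion masks on the same grid.
#' @return `mask & !(uterus | liver)`.
#' @export
apply_exclusion_masks <- function(mask, uterus_mask, liver_mask) {
  if (!identical(dim(mask), dim(uterus_mask)) ||
      !identical(dim(mask), dim(liver_mask)))
    stop("exclusion masks must share the mask's grid")
  mask & !(uterus_mask | liver_mask)
}

#' Crop grids to the axial analysis region
#'
#' Abdominal fat volumes are reported between the top of the liver (upper
#' bound) and the L4/5 intervertebral disk (lower bound). Bounds are 0-based
#' slice indices, half-open `[lower, upper)`.
#'
#' @param vols named list of 3D arrays (images, labels or masks) on a
#'   common grid.
#' @param l45_index lower bound (0-based, inclusive).
#' @param top_of_liver_index upper bound (0-based, exclusive).
#' @return The list with every array cropped along the slice axis.
#' @export
bound_analysis_region <- function(vols, l45_index, top_of_liver_index) {
  nz <- dim(vols[[1]])[3]
  if (l45_index >= top_of_liver_index)
    stop("reversed bounds: lower index must be below the upper index")
  if (l45_index < 0 || top_of_liver_index > nz)
    stop("bounds outside the axial range")
  keep <- (l45_index + 1L):top_of_liver_index
  lapply(vols, function(a) a[, , keep, drop = FALSE])
}

#' Run the full five-class segmentation pipeline
#'
#' Bias correction, body extraction, adipose thresholding, compact-watershed
#' muscle segmentation, subcutaneous-shell extraction, visceral fat by
#' subtraction, and uterus/liver exclusion, emitting the five-class label
#' volume plus the intermediate masks.
#'
#' @param vol an [image_volume()].
#' @param seed_labels [label_volume()] of sparse manual seeds (muscle
#'   required; other classes used as competing watershed seeds).
#' @param exclusion optional list with logical `uterus` / `liver` masks.
#' @param cfg a [segmentation_config()].
#' @return List with `labels` ([label_volume()]), masks `body`, `adipose`,
#'   `sat`, `vat`, `muscle`, and the estimated `bias_field`.
#' @export
segment_abdomen <- function(vol, seed_labels, exclusion = NULL,
                            cfg = segmentation_config()) {
  bc <- correct_bias_field(vol, cfg)
  corrected <- bc$corrected
  body <- body_mask(corrected)
  adipose <- threshold_adipose(corrected, body, cfg)
  if (!is.null(exclusion))
    adipose <- apply_exclusion_masks(adipose, exclusion$uterus, exclusion$liver)
  sat <- segment_sat(adipose, body, cfg)
  vat <- vat_by_subtraction(adipose, sat)  # exact SAT/VAT partition of adipose
  muscle <- segment_muscle(corrected, seed_labels, body, adipose, cfg)
  labs <- array(CLASS_UNLABELED, dim(vol$data))
  labs[body] <- CLASS_ORGAN
  labs[muscle] <- CLASS_MUSCLE
  labs[sat] <- CLASS_SAT
  labs[vat] <- CLASS_VAT
  list(labels = label_volume(labs, spacing = vol$spacing, origin = vol$origin),
       body = body, adipose = adipose, sat = sat, vat = vat, muscle = muscle,
       bias_field = bc$field)
}
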