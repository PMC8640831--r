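#' 3D image volume on a physical voxel grid
#'
#' A minimal container for a 3D scalar image with anisotropic voxel spacing,
#' the in-memory analogue of a single-station abdominal T1-weighted
#' acquisition (axial slices along the third array axis).
#'
#' @param data 3D numeric array of intensities (arbitrary units). All values
#'   must be finite.
#' @param spacing numeric length-3, per-axis voxel size in mm; all > 0.
#'   Default `c(1.25, 1.25, 6)` mirrors a typical abdominal T1 protocol
#'   ((1.25 mm)^2 in plane, 6 mm slices).
#' @param origin numeric length-3 physical offset in mm.
#' @return An object of class `image_volume` with elements `data`, `spacing`,
#'   `origin`.
#' @export
image_volume <- function(data, spacing = c(1.25, 1.25, 6), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!all(is.finite(data)))
    stop("intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  if (any(dim(data) < 1L))
    stop("grid dimensions must be >= 1 in each axis")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "image_volume")
}

#' Integer tissue-label volume paired to an image grid
#'
#' Holds the five-class abdominal tissue segmentation: 0 unlabeled, 1 SAT
#' (subcutaneous adipose), 2 VAT (visceral adipose), 3 muscle, 4 organ.
#'
#' @param labels 3D integer array restricted to codes 0:4.
#' @param spacing,origin as in [image_volume()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing = c(1.25, 1.25, 6), origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:4))
    stop("labels restricted to codes 0 (unlabeled), 1 (SAT), 2 (VAT), 3 (muscle), 4 (organ)")
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "label_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, range [", signif(min(x$data), 5), ", ", signif(max(x$data), 5),
      "]\n", sep = "")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:4,
                      labels = c("unlabeled", "SAT", "VAT", "muscle", "organ")))
  cat("<label_volume> ", paste(dim(x$labels), collapse = " x "), " voxels\n", sep = "")
  print(tab)
  invisible(x)
}

# Tissue class codes used throughout the five-class segmentation.
CLASS_UNLABELED <- 0L
CLASS_SAT <- 1L
CLASS_VAT <- 2L
CLASS_MUSCLE <- 3L
CLASS_ORGAN <- 4L

#' Physical volume of a binary mask
#'
#' @param mask logical 3D array.
#' @param spacing per-axis voxel size, mm.
#' @return Volume in cm^3 (voxel count times voxel volume).
#' @export
mask_volume_cm3 <- function(mask, spacing) {
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  sum(mask) * prod(spacing) / 1000
}

#' Dice overlap coefficient
#'
#' `2|A intersect B| / (|A| + |B|)`, the standard agreement score between a
#' predicted segmentation mask and ground truth. Returns 1 when both masks
#' are empty.
#'
#' @param a,b logical arrays of identical shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
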