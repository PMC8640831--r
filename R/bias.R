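#' Segmentation pipeline configuration
#'
#' Tunables for the five-class abdominal pipeline. Defaults are chosen for
#' thick-slice abdominal T1 volumes and are exercised by the phantom
#' acceptance gate.
#'
#' @param bias_sigma_mm smoothness (Gaussian scale, mm) of the estimated
#'   log bias field; fields with structure finer than this are treated as
#'   anatomy, not bias.
#' @param bias_iterations alternating class-fit / field-fit iterations.
#' @param bias_classes number of intensity classes used by the piecewise-
#'   constant tissue model during field estimation.
#' @param adipose_threshold `"otsu"` (within the body mask) or an absolute
#'   intensity value.
#' @param morph_radius in-plane voxel radius for the dilation/erosion steps
#'   that separate the subcutaneous shell from internal fat.
#' @param watershed_compactness additive spatial penalty (intensity units
#'   per mm) of the compact watershed.
#' @param contour_iterations maximum inward-evolution steps of the
#'   subcutaneous-shell contour (capped geodesic propagation).
#' @param min_component_voxels smallest connected component retained.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(bias_sigma_mm = 40, bias_iterations = 4,
                                bias_classes = 4,
                                adipose_threshold = "otsu",
                                morph_radius = 2,
                                watershed_compactness = 0.5,
                                contour_iterations = 200,
                                min_component_voxels = 27) {
  stopifnot(bias_sigma_mm > 0, bias_iterations >= 1, bias_classes >= 2,
            morph_radius >= 0, watershed_compactness >= 0,
            contour_iterations >= 1, min_component_voxels >= 0)
  if (!(identical(adipose_threshold, "otsu") ||
        (is.numeric(adipose_threshold) && length(adipose_threshold) == 1L)))
    stop("adipose_threshold must be \"otsu\" or a single number")
  structure(list(bias_sigma_mm = bias_sigma_mm,
                 bias_iterations = bias_iterations,
                 bias_classes = bias_classes,
                 adipose_threshold = adipose_threshold,
                 morph_radius = morph_radius,
                 watershed_compactness = watershed_compactness,
                 contour_iterations = contour_iterations,
                 min_component_voxels = min_component_voxels),
            class = "segmentation_config")
}

# Block-mean downsampling / nearest-neighbour upsampling, used to estimate
# the (smooth) bias field on a coarse grid.
block_downsample <- function(a, f) {
  for (axis in 1:3) {
    if (f[axis] == 1L) next
    perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    a <- aperm(a, perm)
    dm <- dim(a)
    n_blocks <- ceiling(dm[1] / f[axis])
    pad <- n_blocks * f[axis] - dm[1]
    if (pad > 0) {
      top <- a[rep(dm[1], pad), , , drop = FALSE]
      a <- array(c(aperm(a, c(2, 3, 1)), aperm(top, c(2, 3, 1))),
                 c(dm[2], dm[3], dm[1] + pad))
      a <- aperm(a, c(3, 1, 2))
      dm <- dim(a)
    }
    a <- array(colMeans(array(a, c(f[axis], dm[1] / f[axis], dm[2], dm[3]))),
               c(dm[1] / f[axis], dm[2], dm[3]))
    a <- aperm(a, order(perm))
  }
  a
}

block_upsample <- function(a, f, target_dim) {
  idx <- lapply(1:3, function(axis)
    pmin(ceiling(seq_len(target_dim[axis]) / f[axis]), dim(a)[axis]))
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Estimate and remove a smooth multiplicative bias field
#'
#' Retrospective bias correction in the spirit of N4: the log image is
#' modelled as a piecewise-constant tissue term plus a smooth field, and
#' the two are estimated alternately — intensity classes by quantile-
#' initialised k-means in the log domain, the field by masked Gaussian
#' smoothing of the class residuals (computed on a coarse grid, since the
#' field is smooth by definition). The estimated field is normalised to
#' unit geometric mean over the body so overall intensity scale is
#' preserved.
#'
#' @param vol an [image_volume()]; nonpositive intensities are shifted up
#'   before the log transform.
#' @param cfg a [segmentation_config()].
#' @param body optional logical array restricting the fit (default: the
#'   [body_mask()] of the volume).
#' @return List with `corrected` ([image_volume()]) and `field` (numeric
#'   array; the input equals `corrected * field` up to the positivity
#'   shift).
#' @export
correct_bias_field <- function(vol, cfg = segmentation_config(),
                               body = NULL) {
  stopifnot(inherits(vol, "image_volume"))
  a <- vol$data
  dm <- dim(a)
  if (diff(range(a)) == 0) {
    return(list(corrected = vol, field = array(1, dm)))
  }
  shift <- 0
  mn <- min(a)
  if (mn <= 0) shift <- -mn + 1e-3 * diff(range(a))
  if (is.null(body)) body <- body_mask(vol)
  if (!any(body)) stop("empty body mask")
  u <- log(a + shift)

  # coarse grid: ~5 mm in plane is ample for a smooth field
  f <- pmax(1L, floor(5 / vol$spacing))
  coarse_dim <- dim(block_downsample(array(0, dm), f))
  body_num <- array(as.numeric(body), dm)
  w_coarse <- block_downsample(body_num, f)
  sigma_coarse <- cfg$bias_sigma_mm / (vol$spacing * f)
  sm_w <- gaussian_smooth(w_coarse, sigma_coarse)

  idx_body <- which(body)
  sub <- if (length(idx_body) > 50000L)
    idx_body[unique(round(seq(1L, length(idx_body), length.out = 50000L)))]
  else idx_body
  f_log <- array(0, dm)
  for (it in seq_len(cfg$bias_iterations)) {
    corr <- u - f_log
    k <- cfg$bias_classes
    centers <- unique(quantile(corr[sub], probs = (2 * seq_len(k) - 1) / (2 * k),
                               names = FALSE))
    km <- suppressWarnings(kmeans(corr[sub], centers = centers, iter.max = 30))
    cs <- sort(km$centers[, 1])
    # nearest-centre class assignment over the whole body
    mids <- (cs[-1] + cs[-length(cs)]) / 2
    cls <- findInterval(corr, c(-Inf, mids))
    resid <- (corr - cs[cls]) * body_num
    num <- gaussian_smooth(block_downsample(resid, f), sigma_coarse)
    delta_coarse <- ifelse(sm_w > 1e-6, num / pmax(sm_w, 1e-6), 0)
    f_log <- f_log + block_upsample(delta_coarse, f, dm)
  }
  # soften the block structure of the coarse-grid estimate
  f_log <- gaussian_smooth(f_log, pmax(1, 2 / vol$spacing))
  f_log <- f_log - mean(f_log[idx_body])  # unit geometric mean over the body
  field <- array(exp(f_log), dm)
  corrected <- (a + shift) / field - shift
  list(corrected = image_volume(corrected, spacing = vol$spacing,
                                origin = vol$origin),
       field = field)
}
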