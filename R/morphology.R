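# Binary morphology and smoothing on 3D grids, implemented with vectorised
# array shifts. Radii are given in voxels per axis (length 1 or 3); a radius
# of 0 along the slice axis keeps an operation in-plane, which is the natural
# choice for thick-slice axial data.

ball_offsets <- function(radius) {
  r <- rep_len(as.integer(round(radius)), 3L)
  stopifnot(all(r >= 0))
  grid <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  rr <- pmax(r, 1L)  # avoid 0/0 on collapsed axes
  keep <- (grid$dx / rr[1])^2 + (grid$dy / rr[2])^2 + (grid$dz / rr[3])^2 <= 1 + 1e-9
  keep[grid$dx != 0 & r[1] == 0] <- FALSE
  keep[grid$dy != 0 & r[2] == 0] <- FALSE
  keep[grid$dz != 0 & r[3] == 0] <- FALSE
  as.matrix(grid[keep, , drop = FALSE])
}

shift_mask <- function(mask, d, fill = FALSE) {
  if (all(d == 0)) return(mask)
  dm <- dim(mask)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    if (d[k] >= 0) {
      if (d[k] >= dm[k]) return(out)
      src[[k]] <- 1:(dm[k] - d[k]); dst[[k]] <- (1 + d[k]):dm[k]
    } else {
      if (-d[k] >= dm[k]) return(out)
      src[[k]] <- (1 - d[k]):dm[k]; dst[[k]] <- 1:(dm[k] + d[k])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

#' Binary dilation / erosion on a 3D mask
#'
#' @param mask logical 3D array.
#' @param radius voxel radius per axis (length 1 or 3); the structuring
#'   element is the discrete ellipsoid of those radii. Radius 0 along an axis
#'   restricts the operation to the remaining axes.
#' @return Logical array of the same shape.
#' @export
dilate_mask <- function(mask, radius = 1) {
  offs <- ball_offsets(radius)
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(offs)))
    out <- out | shift_mask(mask, offs[i, ], fill = FALSE)
  out
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, radius = 1) {
  offs <- ball_offsets(radius)
  out <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(offs)))
    out <- out & shift_mask(mask, offs[i, ], fill = FALSE)
  out
}

#' @rdname dilate_mask
#' @export
open_mask <- function(mask, radius = 1) dilate_mask(erode_mask(mask, radius), radius)

#' @rdname dilate_mask
#' @export
close_mask <- function(mask, radius = 1) erode_mask(dilate_mask(mask, radius), radius)

#' Connected-component labelling
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return Integer array of component ids (0 = background).
#' @export
label_components <- function(mask, connectivity = 6) {
  stopifnot(connectivity %in% c(6, 26))
  .cc_label(as.logical(mask), dim(mask), as.integer(connectivity))
}

#' Drop connected components smaller than a voxel count
#'
#' @param mask logical 3D array.
#' @param min_voxels smallest component retained.
#' @param connectivity see [label_components()].
#' @return Cleaned logical array.
#' @export
remove_small_components <- function(mask, min_voxels = 27, connectivity = 6) {
  if (min_voxels <= 1 || !any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_voxels)
  array(lab %in% keep, dim(mask))
}

#' Fill interior holes of a binary mask
#'
#' Background components of the complement that do not reach the exterior
#' are interior holes and are filled. With `per_slice = TRUE` (the default)
#' each axial slice is filled independently in-plane, which is the right
#' notion of "interior" for a slice stack whose structures run through the
#' first and last slices; `per_slice = FALSE` fills in full 3D.
#'
#' @param mask logical 3D array.
#' @param per_slice fill in-plane per axial slice (default) or in 3D.
#' @return Logical array with holes filled.
#' @export
fill_holes <- function(mask, per_slice = TRUE) {
  dm <- dim(mask)
  if (per_slice) {
    for (z in seq_len(dm[3])) {
      sl <- array(mask[, , z], c(dm[1], dm[2], 1L))
      comp <- label_components(!sl, connectivity = 6)
      border <- unique(c(comp[c(1, dm[1]), , 1], comp[, c(1, dm[2]), 1]))
      border <- border[border > 0]
      holes <- comp > 0 & !(comp %in% border)
      mask[, , z] <- sl | holes
    }
    return(mask)
  }
  comp <- label_components(!mask, connectivity = 6)
  border <- unique(c(
    comp[c(1, dm[1]), , ], comp[, c(1, dm[2]), ], comp[, , c(1, dm[3])]))
  border <- border[border > 0]
  holes <- comp > 0 & !(comp %in% border)
  mask | holes
}

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-half:half, sd = sigma)
  k / sum(k)
}

convolve_axis <- function(arr, k, axis) {
  if (length(k) == 1L) return(arr)
  half <- (length(k) - 1L) / 2L
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  a <- aperm(arr, perm)
  dm <- dim(a)
  m <- matrix(a, nrow = dm[1])
  # replicate-pad so class plateaus stay flat at the boundary
  padded <- rbind(m[rep(1L, half), , drop = FALSE], m,
                  m[rep(nrow(m), half), , drop = FALSE])
  out <- matrix(0, nrow = dm[1], ncol = ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * padded[j:(j + dm[1] - 1L), , drop = FALSE]
  aperm(array(out, dm), order(perm))
}

#' Separable Gaussian smoothing of a 3D array
#'
#' @param arr numeric 3D array.
#' @param sigma_vox standard deviation in voxels, per axis (length 1 or 3).
#' @return Smoothed array.
#' @export
gaussian_smooth <- function(arr, sigma_vox) {
  s <- rep_len(sigma_vox, 3L)
  for (axis in 1:3) arr <- convolve_axis(arr, gauss_kernel(s[axis]), axis)
  arr
}

#' Gradient magnitude of a 3D image in physical units
#'
#' Central differences divided by voxel spacing, so thick slices contribute
#' proportionally weaker axial gradients.
#'
#' @param vol an [image_volume()].
#' @return Numeric array of |grad| in intensity per mm.
#' @export
gradient_magnitude <- function(vol) {
  a <- vol$data; sp <- vol$spacing
  g2 <- array(0, dim(a))
  for (axis in 1:3) {
    d <- c(0L, 0L, 0L)
    d[axis] <- 1L
    fwd <- shift_array_num(a, -d)
    bwd <- shift_array_num(a, d)
    g <- (fwd - bwd) / (2 * sp[axis])
    g2 <- g2 + g^2
  }
  sqrt(g2)
}

shift_array_num <- function(a, d) {
  # shift with replicate padding (numeric)
  dm <- dim(a)
  idx <- vector("list", 3L)
  for (k in 1:3) {
    i <- seq_len(dm[k]) - d[k]
    idx[[k]] <- pmin(pmax(i, 1L), dm[k])
  }
  a[idx[[1]], idx[[2]], idx[[3]]]
}

#' Otsu threshold of intensities
#'
#' Maximises between-class variance over a 256-bin histogram; the standard
#' parameter-free split for bimodal intensity distributions.
#'
#' @param x numeric vector of intensities.
#' @param n_bins histogram resolution.
#' @return Threshold value; voxels strictly above it form the bright class.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu_t <- mu1[n_bins]
  between <- (mu_t * w1 - mu1)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}
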