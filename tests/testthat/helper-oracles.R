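# Independent oracles and shared fixtures for the test suite.

# --- one-compartment mass-balance ODE oracle for the tracer clamp --------
# Forward-Euler integration of a single glucose pool with endogenous
# appearance Ra, tracer infusion F at infusate enrichment E_inf, optional
# exogenous glucose infusion `gir`, and first-order clearance. Run to
# steady state; returns the plasma enrichment (MPE) the tracer equations
# consume. Independent of the package's algebra.
ode_clamp_oracle <- function(F, Ra, E_inf = 99, gir = 0, k = 0.1,
                             dt = 0.02, t_end = 2000) {
  Q <- (F + Ra + gir) / k   # start near steady state to converge fast
  Qt <- 0
  n <- ceiling(t_end / dt)
  for (i in seq_len(n)) {
    out <- k * Q
    Q <- Q + dt * (F + Ra + gir - out)
    Qt <- Qt + dt * (F * E_inf / 100 - out * Qt / Q)
  }
  100 * Qt / Q
}

# --- brute-force rasterisation oracle for phantom VAT ground truth -------
# Recomputes VAT membership voxel-by-voxel from the sampled blob geometry
# using the full 3D ellipsoid inequality (the generator rasterises
# slice-wise cross-sections), intersected with the margin-eroded interior
# and minus the uterus/liver slabs.
rasterize_vat_oracle <- function(ph, spec) {
  dm <- spec$shape
  sp <- spec$spacing
  x <- (seq_len(dm[1]) - (dm[1] + 1) / 2) * sp[1]
  y <- (seq_len(dm[2]) - (dm[2] + 1) / 2) * sp[2]
  z <- (seq_len(dm[3]) - (dm[3] + 1) / 2) * sp[3]
  g <- ph$geometry
  vat <- array(FALSE, dm)
  for (zi in seq_len(dm[3])) {
    s <- g$taper[zi]
    in_region <- outer(x^2 / (g$r_vat_lim[1] * s)^2,
                       y^2 / (g$r_vat_lim[2] * s)^2, `+`) <= 1
    in_any <- array(FALSE, dm[1:2])
    for (b in seq_len(nrow(g$blobs))) {
      bl <- g$blobs[b, ]
      dz2 <- ((z[zi] - bl$cz) / bl$rz)^2
      if (dz2 >= 1) next
      in_any <- in_any |
        (outer((x - bl$cx)^2 / bl$rx^2, (y - bl$cy)^2 / bl$ry^2, `+`) +
           dz2) <= 1
    }
    vat[, , zi] <- in_any & in_region &
      !ph$exclusion$uterus[, , zi] & !ph$exclusion$liver[, , zi]
  }
  vat
}

# --- shared noisy-phantom fixture (SNR 10, 30% bias) ---------------------
# Built once per test run; several test files and the acceptance gate use
# the same end-to-end segmentation.
.phantom_cache <- new.env(parent = emptyenv())
noisy_phantom_fixture <- function() {
  if (is.null(.phantom_cache$fx)) {
    spec <- phantom_spec(noise_sd = 100, bias_amplitude = 0.3, seed = 17)
    ph <- make_abdomen_phantom(spec)
    truth <- ph$labels$labels
    seeds <- array(0L, dim(truth))
    sl <- round(seq(1, dim(truth)[3], length.out = 11))
    seeds[, , sl] <- truth[, , sl]
    seg <- segment_abdomen(ph$image,
                           label_volume(seeds, spacing = spec$spacing),
                           exclusion = ph$exclusion)
    .phantom_cache$fx <- list(spec = spec, ph = ph, truth = truth,
                              seed_slices = sl, seg = seg)
  }
  .phantom_cache$fx
}
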