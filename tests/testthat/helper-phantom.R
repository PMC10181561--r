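# Shared fixture builders: tiny phantoms and single-component variants.

zero_fractions <- function() {
  lapply(default_noise_fractions(), function(f) f * 0)
}

# All injected variance in one component (plus thermal remainder), same in
# every tissue class.
pure_fractions <- function(component, f = 1, thermal_rest = TRUE) {
  base <- c(bold = 0, physio = 0, motion = 0, drift = 0, thermal = 0)
  base[component] <- f
  if (thermal_rest && component != "thermal") base["thermal"] <- 1 - f
  list(gm = base, wm = base, csf = base)
}

# Spatially uniform phantom: one T2*/S0 everywhere, no jitter, no dropout.
flat_truth <- function(t2 = 40, s0 = 1000, shape = c(10, 10, 8),
                       fractions = zero_fractions(), seed = 1, cv = 0.02) {
  generate_phantom(shape = shape, n_networks = 1, seed = seed,
                   noise_fractions = fractions,
                   t2star_ms = c(gm = t2, wm = t2, csf = t2),
                   s0 = c(gm = s0, wm = s0, csf = s0),
                   t2star_jitter_ms = 0, s0_jitter = 0,
                   dropout_radius_vox = 0, cv = cv)
}

small_truth <- function(shape = c(12, 12, 10), seed = 1, ...) {
  generate_phantom(shape = shape, n_networks = 2, seed = seed, ...)
}

# Hand-built 3-echo series from per-echo 4D arrays.
manual_series <- function(data_list, echo_times, tr = 940,
                          mask = NULL) {
  d <- dim(data_list[[1]])
  structure(list(
    data = data_list, echo_times = echo_times, tr = tr,
    frame_times = (seq_len(d[4]) - 1) * tr / 1000,
    mask = mask %||% array(TRUE, dim = d[1:3]),
    voxel_mm = c(2.38, 2.38, 2.7)
  ), class = "me_series")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Masked voxels-by-frames view of a 4D array (test-local, independent of
# the package internals).
vox_mat_test <- function(a, mask) {
  d <- dim(a)
  m <- matrix(a, prod(d[1:3]), d[4])
  m[as.vector(mask), , drop = FALSE]
}
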