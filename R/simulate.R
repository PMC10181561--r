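#' Simulate a multi-echo BOLD time series from a phantom
#'
#' Realises the signal model at every voxel `v` inside the head and frame
#' `t`: for echo `e`, `S(v, e, t) = S0(v) * exp(-TE_e / T2*(v, t))` plus
#' additive structured noise shared across echoes and thermal noise drawn
#' independently per echo. BOLD fluctuation enters multiplicatively through
#' T2*: `T2*(v, t)` varies about its baseline in proportion to the planted
#' network time courses weighted by the voxel's network-map membership, so
#' later echoes carry a larger fractional BOLD change while the structured
#' and thermal noise do not scale with TE. This is the mechanism by which
#' T2*-weighted echo combination can average down thermal noise while
#' preserving BOLD.
#'
#' Additive components (amplitudes calibrated so that each contributes its
#' configured fraction of total temporal variance at the middle echo, per
#' voxel):
#' \itemize{
#'   \item physiological: quasi-periodic cardiac (~1 Hz) and respiratory
#'     (~0.3 Hz) intensity modulation built from first- and second-order
#'     Fourier terms of the generated phase traces, with random per-voxel
#'     coefficients;
#'   \item motion-coupled: per-voxel random linear combination of the six
#'     generated rigid-body motion parameters;
#'   \item drift: low-order Legendre polynomial with random per-voxel
#'     coefficients;
#'   \item thermal: zero-mean Gaussian, independent across echoes, voxels
#'     and frames, equal SD per echo at each voxel.
#' }
#' Motion parameter traces are random walks with a per-TR step norm of
#' about 0.03 mm (the scale seen in still, healthy volunteers); optional
#' spikes exercise frame censoring. Voxels outside the head carry pure
#' thermal noise so a background-air region is available for noise-SD
#' estimation.
#'
#' @param truth a [generate_phantom()] object.
#' @param protocol a [protocol_spec()]; supplies TR and echo times.
#' @param n_frames number of frames (>= 2).
#' @param seed integer RNG seed.
#' @param keep_components if `TRUE`, the generated mid-echo component time
#'   series (bold, physio, motion, drift, thermal) are returned for
#'   variance accounting; memory scales with voxels x frames.
#' @param motion_spikes number of injected motion spikes (step changes
#'   larger than the censoring threshold).
#' @param spike_mm translation jump per injected spike (mm).
#' @return an object of class `me_sim`: list with
#'   \describe{
#'     \item{series}{`me_series`: per-echo 4D arrays, echo times, TR,
#'       frame times, head mask, voxel size.}
#'     \item{physio}{`physio_trace`: cardiac/respiratory phase in
#'       \[0, 2pi) and an RVT proxy, sampled at frame times.}
#'     \item{motion}{`n_frames` x 6 matrix (3 translations mm,
#'       3 rotations deg).}
#'     \item{components}{saved mid-echo component matrices (voxels inside
#'       head x frames) and their calibrated target SDs, or `NULL`.}
#'     \item{truth}{the input truth with `network_timecourses` filled.}
#'   }
#' @export
#' @examples
#' truth <- generate_phantom(shape = c(12, 12, 10), n_networks = 2, seed = 1)
#' sim <- simulate_multiecho(truth, reference_protocol("multi"),
#'                           n_frames = 40, seed = 2)
#' dim(sim$series$data[[2]])
simulate_multiecho <- function(truth, protocol, n_frames, seed = 1,
                               keep_components = TRUE, motion_spikes = 0,
                               spike_mm = 0.5) {
  stopifnot(inherits(truth, "phantom_truth"),
            inherits(protocol, "protocol_spec"), n_frames >= 2)
  te <- protocol$echo_times_ms
  if (any(te >= 3 * max(truth$t2star_map))) {
    warning("echo time(s) beyond 3x the longest T2*; late echoes will be ",
            "essentially noise")
  }
  set.seed(as.integer(seed))
  tr_s <- protocol$tr_ms / 1000
  tt <- as.integer(n_frames)
  ft <- (seq_len(tt) - 1L) * tr_s
  ne <- length(te)
  e_mid <- ceiling(ne / 2)
  shape <- truth$shape
  head <- phantom_mask(truth, "head")
  nv <- sum(head)
  tis <- truth$tissue[head]                      # 1 GM, 2 WM, 3 CSF
  s0 <- truth$s0_map[head]
  t2_0 <- truth$t2star_map[head]

  frac <- function(comp) {
    f <- numeric(nv)
    f[tis == 1L] <- truth$noise_fractions$gm[[comp]]
    f[tis == 2L] <- truth$noise_fractions$wm[[comp]]
    f[tis == 3L] <- truth$noise_fractions$csf[[comp]]
    f
  }

  base <- lapply(te, function(x) s0 * exp(-x / t2_0))   # per echo, length nv
  sig_tot <- truth$cv * base[[e_mid]]

  ## ---- network time courses (low-frequency, unit variance) ----
  nk <- length(truth$network_maps)
  z <- matrix(0, nk, tt)
  for (k in seq_len(nk)) {
    z[k, ] <- lowfreq_series(tt, tr_s, band = c(0.01, 0.08))
  }
  truth$network_timecourses <- z

  ## ---- BOLD through T2* fluctuation ----
  mmat <- vapply(truth$network_maps, function(m) m[head], numeric(nv))
  g <- mmat %*% z                                 # nv x tt
  sd_g <- row_sd(g)
  f_bold <- frac("bold")
  idx_b <- which(sd_g > 1e-8 & f_bold > 0)
  t2_t <- NULL
  if (length(idx_b)) {
    amp <- sqrt(f_bold[idx_b]) * truth$cv * t2_0[idx_b]^2 /
      (te[e_mid] * sd_g[idx_b])
    t2_t <- pmax(t2_0[idx_b] + amp * g[idx_b, , drop = FALSE], 2)
  }

  ## ---- physiological traces and component ----
  f_card <- rnorm(1, 1.05, 0.05)
  f_resp <- rnorm(1, 0.30, 0.02)
  jit_c <- cumsum(rnorm(tt, 0, 0.01))
  jit_r <- cumsum(rnorm(tt, 0, 0.01))
  ph_c <- (2 * pi * (f_card * ft + jit_c)) %% (2 * pi)
  ph_r <- (2 * pi * (f_resp * ft + jit_r)) %% (2 * pi)
  rvt <- lowfreq_series(tt, tr_s, band = c(0.0, 0.05))
  physio <- structure(list(cardiac_phase = ph_c, respiratory_phase = ph_r,
                           rvt = rvt, frame_times = ft),
                      class = "physio_trace")
  pbasis <- cbind(sin(ph_c), cos(ph_c), sin(2 * ph_c), cos(2 * ph_c),
                  sin(ph_r), cos(ph_r), sin(2 * ph_r), cos(2 * ph_r))
  physio_comp <- scaled_mix(nv, pbasis, sqrt(frac("physio")) * sig_tot)

  ## ---- motion parameters and motion-coupled component ----
  step_sd <- 0.028 / 2.35        # per-TR L2 norm of 6 iid steps ~ 0.028 mm
  mot <- apply(matrix(rnorm(tt * 6, 0, step_sd), tt, 6), 2, cumsum)
  if (motion_spikes > 0) {
    at <- sample(2:tt, motion_spikes)
    for (a in at) mot[a:tt, 1] <- mot[a:tt, 1] + spike_mm
  }
  colnames(mot) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
  motion_comp <- scaled_mix(nv, std_cols(mot), sqrt(frac("motion")) * sig_tot)

  ## ---- polynomial drift component ----
  dbasis <- legendre_basis(tt, 3)[, -1, drop = FALSE]
  drift_comp <- scaled_mix(nv, dbasis, sqrt(frac("drift")) * sig_tot)

  shared <- physio_comp + motion_comp + drift_comp

  ## ---- thermal noise and assembly ----
  sd_th <- sqrt(frac("thermal")) * sig_tot
  gm_sd <- sd_th[tis == 1L]
  sd_air <- if (length(gm_sd)) median(gm_sd) else median(sd_th)
  n_air <- prod(shape) - nv

  data <- vector("list", ne)
  thermal_mid <- NULL
  for (e in seq_len(ne)) {
    th <- matrix(rnorm(nv * tt), nv, tt) * sd_th
    y <- matrix(base[[e]], nv, tt) + shared + th
    if (length(idx_b)) {
      y[idx_b, ] <- s0[idx_b] * exp(-te[e] / t2_t) +
        shared[idx_b, , drop = FALSE] + th[idx_b, , drop = FALSE]
    }
    if (e == e_mid && keep_components) thermal_mid <- th
    vol <- array(0, dim = c(shape, tt))
    full <- matrix(0, prod(shape), tt)
    full[as.vector(head), ] <- y
    if (n_air > 0) {
      full[!as.vector(head), ] <- rnorm(n_air * tt, 0, sd_air)
    }
    vol[] <- full
    data[[e]] <- vol
  }

  components <- NULL
  if (keep_components) {
    bold_mid <- matrix(0, nv, tt)
    if (length(idx_b)) {
      bold_mid[idx_b, ] <- s0[idx_b] * exp(-te[e_mid] / t2_t) - base[[e_mid]][idx_b]
    }
    components <- list(
      mask = head,
      matrices = list(bold = bold_mid, physio = physio_comp,
                      motion = motion_comp, drift = drift_comp,
                      thermal = thermal_mid),
      target_sd = list(bold = sqrt(f_bold) * sig_tot * (sd_g > 1e-8),
                       physio = sqrt(frac("physio")) * sig_tot,
                       motion = sqrt(frac("motion")) * sig_tot,
                       drift = sqrt(frac("drift")) * sig_tot,
                       thermal = sd_th),
      total_sd = sig_tot
    )
  }

  series <- structure(list(
    data = data, echo_times = te, tr = protocol$tr_ms, frame_times = ft,
    mask = head, voxel_mm = truth$voxel_mm
  ), class = "me_series")

  structure(list(series = series, physio = physio, motion = mot,
                 components = components, truth = truth,
                 seed = as.integer(seed), mid_echo = e_mid),
            class = "me_sim")
}

#' @export
print.me_series <- function(x, ...) {
  d <- dim(x$data[[1]])
  cat("<me_series>", length(x$echo_times), "echo(es), grid",
      paste(d[1:3], collapse = "x"), ",", d[4], "frames, TR", x$tr, "ms\n")
  cat("  TE (ms):", paste(x$echo_times, collapse = ", "), "\n")
  invisible(x)
}

# Unit-variance low-frequency series: white noise restricted to `band` (Hz)
# in the frequency domain, rescaled to sample SD 1.
lowfreq_series <- function(n, tr_s, band = c(0.01, 0.08)) {
  x <- rnorm(n)
  xf <- fft(x)
  fr <- seq(0, n - 1) / (n * tr_s)
  fr <- pmin(fr, 1 / tr_s - fr)                  # two-sided frequency
  keep <- fr >= band[1] & fr <= band[2]
  keep[1] <- FALSE
  xf[!keep] <- 0
  y <- Re(fft(xf, inverse = TRUE)) / n
  s <- sd(y)
  if (s < 1e-12) return(rep(0, n))
  (y - mean(y)) / s
}

# nv voxels x frames: random per-voxel mixtures of the columns of `basis`
# (frames x p), each row standardised to unit temporal SD then scaled by
# `amp` (length nv). Zero rows where amp is 0.
scaled_mix <- function(nv, basis, amp) {
  tt <- nrow(basis)
  p <- ncol(basis)
  cf <- matrix(rnorm(nv * p), nv, p)
  q <- cf %*% t(basis)
  s <- row_sd(q)
  s[s < 1e-12] <- 1
  q * (amp / s)
}

#' Extract one echo of a multi-echo series as a 4D array
#'
#' @param series an `me_series`.
#' @param echo echo index; defaults to the middle echo.
#' @return 4D array.
#' @export
echo_data <- function(series, echo = ceiling(length(series$echo_times) / 2)) {
  stopifnot(inherits(series, "me_series"))
  series$data[[echo]]
}
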