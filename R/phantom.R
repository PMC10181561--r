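#' Default injected-variance fractions per tissue class
#'
#' Fraction of total temporal variance at the middle echo contributed by
#' each component, per tissue class. Fractions are nonnegative and sum to
#' at most 1 within each tissue; the defaults sum to exactly 1 so the
#' total temporal coefficient of variation of the simulated series equals
#' the phantom's `cv` parameter. BOLD applies only at voxels belonging to a
#' planted network map.
#'
#' @return named list with elements `gm`, `wm`, `csf`, each a named numeric
#'   vector over components `bold`, `physio`, `motion`, `drift`, `thermal`.
#' @export
default_noise_fractions <- function() {
  list(
    gm  = c(bold = 0.03, physio = 0.10, motion = 0.04, drift = 0.08,
            thermal = 0.75),
    wm  = c(bold = 0.00, physio = 0.04, motion = 0.04, drift = 0.08,
            thermal = 0.84),
    csf = c(bold = 0.00, physio = 0.25, motion = 0.05, drift = 0.10,
            thermal = 0.60)
  )
}

component_names <- c("bold", "physio", "motion", "drift", "thermal")

validate_noise_fractions <- function(noise_fractions) {
  stopifnot(is.list(noise_fractions))
  for (tis in c("gm", "wm", "csf")) {
    f <- noise_fractions[[tis]]
    if (is.null(f)) stop("noise_fractions is missing tissue class '", tis, "'")
    if (!all(component_names %in% names(f))) {
      stop("noise_fractions$", tis, " must name components ",
           paste(component_names, collapse = ", "))
    }
    f <- f[component_names]
    if (any(f < 0)) {
      stop("noise_fractions must be nonnegative in tissue '", tis, "'")
    }
    if (sum(f) > 1 + 1e-12) {
      stop("noise_fractions sum to ", signif(sum(f), 4), " > 1 in tissue '",
           tis, "'")
    }
    noise_fractions[[tis]] <- f
  }
  noise_fractions
}

#' Generate a synthetic head phantom with known ground truth
#'
#' Builds concentric tissue compartments on a 3D grid -- a grey-matter (GM)
#' shell, a white-matter (WM) interior and a small central CSF (ventricle)
#' compartment inside an ellipsoidal head mask -- together with per-voxel
#' equilibrium signal S0 and effective transverse relaxation time T2*, and
#' `n_networks` smooth network spatial maps planted inside GM. Baseline T2*
#' is 66 ms in GM (typical cortical value at 3 T), 53 ms in WM and 100 ms
#' in CSF, with small Gaussian spatial jitter. A designated inferior GM
#' subregion receives a short T2* (default 10 ms) to emulate
#' susceptibility-induced signal dropout; its size and severity are chosen
#' so that dropout voxels fall below a conventional intensity-mask clip at
#' the middle echo while combined-echo images retain them.
#'
#' The object records, per tissue class, the fraction of total temporal
#' variance each noise component should contribute at the middle echo; the
#' amplitudes themselves are realised by [simulate_multiecho()].
#'
#' @param shape integer length-3 grid size, each entry >= 8.
#' @param n_networks number of planted network maps (>= 1).
#' @param seed integer RNG seed; generation is deterministic given `seed`.
#' @param noise_fractions per-tissue component variance fractions, as
#'   [default_noise_fractions()]; values must be nonnegative and sum to
#'   <= 1 per tissue.
#' @param voxel_mm voxel dimensions in mm.
#' @param t2star_ms named baseline T2* per tissue (ms).
#' @param s0 named equilibrium signal per tissue (arbitrary units).
#' @param t2star_jitter_ms SD of Gaussian spatial jitter on T2* (ms).
#' @param s0_jitter relative SD of Gaussian spatial jitter on S0.
#' @param dropout_t2star_ms T2* assigned to the high-susceptibility GM
#'   subregion (ms).
#' @param dropout_radius_vox radius (voxels) of the dropout ball; 0 disables
#'   it.
#' @param cv total temporal coefficient of variation at the middle echo
#'   (SD of the simulated series divided by its baseline, per voxel) when
#'   the component fractions sum to 1.
#' @param network_radius_vox Gaussian radius of planted network maps
#'   (voxels).
#' @return an object of class `phantom_truth`: a list with `tissue`
#'   (3D integer array: 0 background, 1 GM, 2 WM, 3 CSF), `s0_map`,
#'   `t2star_map`, `network_maps` (list of 3D weight maps in \[0, 1\]),
#'   `network_timecourses` (filled by [simulate_multiecho()]),
#'   `noise_fractions`, `cv`, `voxel_mm`, `dropout_mask`, `seed`.
#' @export
#' @examples
#' truth <- generate_phantom(shape = c(12, 12, 10), n_networks = 2, seed = 1)
#' table(truth$tissue)
generate_phantom <- function(shape = c(24, 24, 16), n_networks = 3, seed = 1,
                             noise_fractions = default_noise_fractions(),
                             voxel_mm = c(2.38, 2.38, 2.7),
                             t2star_ms = c(gm = 66, wm = 53, csf = 100),
                             s0 = c(gm = 1000, wm = 950, csf = 1200),
                             t2star_jitter_ms = 2, s0_jitter = 0.01,
                             dropout_t2star_ms = 10,
                             dropout_radius_vox = max(2, round(shape[1] / 8)),
                             cv = 0.02,
                             network_radius_vox = max(2, shape[1] / 8)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L), n_networks >= 1)
  noise_fractions <- validate_noise_fractions(noise_fractions)
  set.seed(as.integer(seed))

  ctr <- (shape + 1) / 2
  rad <- (shape - 2) / 2
  ax <- (seq_len(shape[1]) - ctr[1]) / rad[1]
  ay <- (seq_len(shape[2]) - ctr[2]) / rad[2]
  az <- (seq_len(shape[3]) - ctr[3]) / rad[3]
  re <- sqrt(outer(outer(ax^2, ay^2, "+"), az^2, "+"))
  head <- re <= 1

  # ventricle-like CSF core, elongated in y
  rv <- sqrt(outer(outer((ax / 0.22)^2, (ay / 0.40)^2, "+"),
                   (az / 0.25)^2, "+"))
  csf <- head & rv <= 1
  gm <- head & re > 0.80
  wm <- head & !gm & !csf
  tissue <- array(0L, dim = shape)
  tissue[gm] <- 1L
  tissue[wm] <- 2L
  tissue[csf] <- 3L

  t2 <- array(0, dim = shape)
  t2[gm] <- t2star_ms[["gm"]]
  t2[wm] <- t2star_ms[["wm"]]
  t2[csf] <- t2star_ms[["csf"]]
  jit <- array(rnorm(prod(shape), 0, t2star_jitter_ms), dim = shape)
  t2[head] <- pmax(t2[head] + jit[head], 2)

  s0_map <- array(0, dim = shape)
  s0_map[gm] <- s0[["gm"]]
  s0_map[wm] <- s0[["wm"]]
  s0_map[csf] <- s0[["csf"]]
  if (s0_jitter > 0) {
    s0_map[head] <- s0_map[head] * (1 + rnorm(sum(head), 0, s0_jitter))
  }

  # high-susceptibility dropout ball on the inferior GM shell
  dropout <- array(FALSE, dim = shape)
  if (dropout_radius_vox > 0) {
    dctr <- c(ctr[1], ctr[2], ctr[3] - 0.85 * rad[3])
    co <- mask_coords(gm)
    dd <- sqrt((co[, 1] - dctr[1])^2 + (co[, 2] - dctr[2])^2 +
                 (co[, 3] - dctr[3])^2)
    sel <- which(gm)[dd <= dropout_radius_vox]
    dropout[sel] <- TRUE
    t2[dropout] <- pmax(dropout_t2star_ms + rnorm(sum(dropout), 0, 0.5), 2)
  }

  # planted networks: Gaussian blobs on GM, compact support, away from the
  # dropout region so detection truth is independent of signal loss
  eligible <- gm & !dropout
  co_g <- mask_coords(eligible)
  maps <- vector("list", n_networks)
  centers <- co_g[sample.int(nrow(co_g), n_networks), , drop = FALSE]
  co_all <- mask_coords(eligible)
  for (k in seq_len(n_networks)) {
    d2 <- (co_all[, 1] - centers[k, 1])^2 + (co_all[, 2] - centers[k, 2])^2 +
      (co_all[, 3] - centers[k, 3])^2
    w <- exp(-d2 / (2 * network_radius_vox^2))
    w[w < 0.25] <- 0
    m <- array(0, dim = shape)
    m[eligible] <- w
    maps[[k]] <- m
  }
  names(maps) <- paste0("network", seq_len(n_networks))

  structure(list(
    tissue = tissue, s0_map = s0_map, t2star_map = t2,
    network_maps = maps, network_timecourses = NULL,
    noise_fractions = noise_fractions, cv = cv, voxel_mm = voxel_mm,
    dropout_mask = dropout, shape = shape, seed = as.integer(seed)
  ), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth> grid", paste(x$shape, collapse = "x"),
      " seed", x$seed, "\n")
  cat("  voxels: GM", sum(x$tissue == 1L), " WM", sum(x$tissue == 2L),
      " CSF", sum(x$tissue == 3L),
      " dropout", sum(x$dropout_mask), "\n")
  cat("  networks:", length(x$network_maps), "\n")
  invisible(x)
}

#' Tissue masks of a phantom
#'
#' @param truth a [generate_phantom()] object.
#' @param which one of `"head"`, `"gm"`, `"wm"`, `"csf"`, `"air"`,
#'   `"dropout"`.
#' @return 3D logical array.
#' @export
phantom_mask <- function(truth,
                         which = c("head", "gm", "wm", "csf", "air",
                                   "dropout")) {
  which <- match.arg(which)
  switch(which,
         head = truth$tissue > 0L,
         gm = truth$tissue == 1L,
         wm = truth$tissue == 2L,
         csf = truth$tissue == 3L,
         air = truth$tissue == 0L,
         dropout = truth$dropout_mask)
}
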