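#' Fit a voxelwise T2* map from a multi-echo series
#'
#' Ordinary least squares of `log(mean signal)` on echo time at each voxel:
#' the temporal mean over uncensored frames is computed per echo, and the
#' mono-exponential decay `S(TE) = S0 * exp(-TE/T2*)` is fitted log-linearly,
#' giving `T2* = -1/slope`. Estimates are clamped to \[2, 300\] ms. Voxels
#' with a nonpositive mean at any echo or a nonnegative slope are marked
#' invalid and assigned a fallback T2* equal to the middle echo time, which
#' keeps downstream combination weights well defined.
#'
#' @param series an `me_series` with at least two echoes.
#' @param mask optional 3D logical analysis mask; defaults to the series
#'   head mask.
#' @param censor optional logical frame-retention vector (`TRUE` = keep).
#' @return object of class `t2star_map`: list with 3D arrays `t2star_ms`,
#'   `s0`, `fit_r2`, logical `valid_mask`, and the `echo_times` used.
#' @export
fit_t2star <- function(series, mask = NULL, censor = NULL) {
  stopifnot(inherits(series, "me_series"))
  te <- series$echo_times
  if (length(te) < 2) stop("T2* fitting requires at least two echoes")
  mask <- mask %||% series$mask
  keep <- censor %||% rep(TRUE, length(series$frame_times))
  mu <- vapply(series$data, function(a) {
    rowMeans(vox_mat(a, mask)[, keep, drop = FALSE])
  }, numeric(sum(mask)))                         # voxels x echoes
  valid <- rowSums(mu <= 0) == 0
  lnmu <- log(pmax(mu, .Machine$double.eps))
  te_c <- te - mean(te)
  slope <- as.vector(lnmu %*% te_c) / sum(te_c^2)
  valid <- valid & slope < 0
  t2 <- rep(te[ceiling(length(te) / 2)], length(slope))  # fallback: mid TE
  t2[valid] <- pmin(pmax(-1 / slope[valid], 2), 300)
  icpt <- rowMeans(lnmu) - slope * mean(te)
  s0 <- exp(icpt)
  fitted <- outer(slope, te) + icpt
  ss_res <- rowSums((lnmu - fitted)^2)
  ss_tot <- rowSums((lnmu - rowMeans(lnmu))^2)
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, 0)
  dim3 <- dim(series$data[[1]])[1:3]
  structure(list(
    t2star_ms = unvox(t2, dim3, mask, fill = NA_real_),
    s0 = unvox(s0, dim3, mask, fill = NA_real_),
    fit_r2 = unvox(r2, dim3, mask, fill = NA_real_),
    valid_mask = unvox(valid, dim3, mask, fill = 0) > 0,
    echo_times = te, mask = mask
  ), class = "t2star_map")
}

#' T2*-weighted optimal combination weights
#'
#' The matched-filter weights for combining echo images acquired at echo
#' times `TE_e` given a voxel's T2*: `w_e` proportional to
#' `TE_e * exp(-TE_e / T2*)`, normalised to sum to one. This weighting
#' maximises BOLD contrast-to-noise for a multiplicative T2* signal model
#' under equal per-echo thermal noise. Voxels with an invalid T2* fit get
#' uniform weights `1/E`.
#'
#' @param t2star a `t2star_map` from [fit_t2star()], or a numeric vector /
#'   3D array of T2* values in ms (all treated as valid).
#' @param echo_times_ms echo times (ms); taken from the `t2star_map` when
#'   omitted.
#' @return matrix (voxels x echoes) when `t2star` is a vector, otherwise a
#'   4D array (x, y, z, echo). Weights are nonnegative and each voxel's
#'   weights sum to 1.
#' @export
#' @examples
#' oc_weights(40, c(11.9, 29.8, 47.8))   # 0.236 0.378 0.386
oc_weights <- function(t2star, echo_times_ms = NULL) {
  if (inherits(t2star, "t2star_map")) {
    te <- echo_times_ms %||% t2star$echo_times
    mask <- t2star$mask
    t2v <- t2star$t2star_ms[mask]
    validv <- t2star$valid_mask[mask]
    w <- oc_weight_matrix(t2v, te, validv)
    dim3 <- dim(t2star$t2star_ms)
    out <- array(0, dim = c(dim3, length(te)))
    for (e in seq_along(te)) {
      out[, , , e] <- unvox(w[, e], dim3, mask, fill = 1 / length(te))
    }
    return(out)
  }
  te <- echo_times_ms
  if (is.null(te)) stop("echo_times_ms required when t2star is numeric")
  w <- oc_weight_matrix(as.vector(t2star), te, rep(TRUE, length(t2star)))
  if (length(t2star) == 1L) drop(w) else w
}

oc_weight_matrix <- function(t2v, te, valid) {
  raw <- outer(t2v, te, function(t2, x) x * exp(-x / t2))
  s <- rowSums(raw)
  bad <- !valid | s <= 0 | !is.finite(s)
  w <- raw / s
  if (any(bad)) w[bad, ] <- 1 / length(te)
  w
}

#' Combine echoes with fixed per-voxel weights
#'
#' Framewise weighted sum across echoes. Weights are computed once from
#' temporal means (see [oc_weights()]) and held fixed over time, keeping
#' the combination linear in the data.
#'
#' @param series an `me_series`.
#' @param weights 4D array (x, y, z, echo) of per-voxel weights conforming
#'   to the series grid and echo count.
#' @return object of class `combined_series`: list with 4D `data`, the
#'   `weights` and `source_echo_times`.
#' @export
combine_echoes <- function(series, weights) {
  stopifnot(inherits(series, "me_series"))
  d <- dim(series$data[[1]])
  ne <- length(series$data)
  if (!identical(dim(weights), as.integer(c(d[1:3], ne)))) {
    stop("weights must have dimensions ", paste(d[1:3], collapse = "x"),
         "x", ne)
  }
  out <- array(0, dim = d)
  for (e in seq_len(ne)) {
    wv <- as.vector(weights[, , , e])
    out <- out + array(sweep(matrix(series$data[[e]], prod(d[1:3]), d[4]),
                             1L, wv, "*"), dim = d)
  }
  structure(list(data = out, weights = weights,
                 source_echo_times = series$echo_times,
                 tr = series$tr, frame_times = series$frame_times,
                 mask = series$mask, voxel_mm = series$voxel_mm),
            class = "combined_series")
}

#' SNR and temporal SNR summaries per tissue
#'
#' Three voxelwise quantities, summarised as mean and SD over each tissue
#' mask:
#' \itemize{
#'   \item SNR: temporal mean divided by the thermal-noise SD estimated
#'     from a background-air region (SD of the air voxel time series);
#'   \item TSNR0: temporal mean divided by temporal SD of the raw series;
#'   \item TSNR: temporal mean divided by temporal SD of the
#'     nuisance-regressed residual, when a design is supplied.
#' }
#' The numerator is always the temporal mean of the pre-residualisation
#' series.
#'
#' @param data 4D array (or `combined_series`).
#' @param tissue_masks named list of 3D logical masks (e.g. gm, wm).
#' @param design optional [build_nuisance_design()]; enables the TSNR
#'   column.
#' @param air_mask optional 3D logical mask of background air used for the
#'   thermal-noise SD; without it the SNR column is `NA`.
#' @param min_frames minimum frames required.
#' @return tibble with one row per tissue: mean and SD of snr, tsnr0, tsnr,
#'   and the thermal SD estimate used.
#' @export
snr_tsnr <- function(data, tissue_masks, design = NULL, air_mask = NULL,
                     min_frames = 10) {
  if (inherits(data, "combined_series")) data <- data$data
  stopifnot(length(dim(data)) == 4L)
  if (dim(data)[4] < min_frames) stop("need at least ", min_frames, " frames")
  if (!length(tissue_masks) || any(!vapply(tissue_masks, any, logical(1)))) {
    stop("empty tissue mask")
  }
  noise_sd <- NA_real_
  if (!is.null(air_mask) && any(air_mask)) {
    airm <- vox_mat(data, air_mask)
    noise_sd <- sqrt(mean(row_sd(airm)^2))
  }
  res <- NULL
  if (!is.null(design)) {
    allmask <- Reduce(`|`, tissue_masks)
    fit <- fit_nuisance_glm(data, design, mask = allmask)
    res <- list(mask = allmask, resid = fit$residuals)
  }
  rows <- lapply(names(tissue_masks), function(nm) {
    m <- tissue_masks[[nm]]
    y <- vox_mat(data, m)
    mu <- rowMeans(y)
    tsnr0 <- mu / row_sd(y)
    snr <- if (is.na(noise_sd)) rep(NA_real_, length(mu)) else mu / noise_sd
    tsnr <- rep(NA_real_, length(mu))
    if (!is.null(res)) {
      sel <- as.vector(m)[as.vector(res$mask)]
      rsd <- row_sd(res$resid[sel, , drop = FALSE])
      tsnr <- mu / rsd
    }
    tibble::tibble(
      tissue = nm, n_voxels = length(mu),
      snr_mean = mean(snr), snr_sd = sd(snr),
      tsnr0_mean = mean(tsnr0), tsnr0_sd = sd(tsnr0),
      tsnr_mean = mean(tsnr), tsnr_sd = sd(tsnr),
      noise_sd = noise_sd
    )
  })
  do.call(rbind, rows)
}
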