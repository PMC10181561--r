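#' Censor frames by per-TR motion displacement
#'
#' The Euclidean norm of the backward first differences of the six
#' rigid-body motion parameters (rotations in degrees treated as
#' mm-equivalent, the AFNI enorm convention) is computed per frame; frames
#' whose norm exceeds the threshold are flagged for exclusion. The first
#' frame has no predecessor and is never flagged.
#'
#' @param motion_params frames x 6 matrix (3 translations mm, 3 rotations
#'   deg).
#' @param threshold_mm censoring threshold on the per-TR displacement norm.
#' @return list with `keep` (logical, `TRUE` = retained), `enorm` (per-TR
#'   displacement norm) and `n_censored`.
#' @export
censor_frames <- function(motion_params, threshold_mm = 0.2) {
  motion_params <- as.matrix(motion_params)
  if (nrow(motion_params) < 2) stop("need at least 2 frames to censor")
  if (ncol(motion_params) != 6) stop("motion_params must have 6 columns")
  d <- diff(motion_params)
  enorm <- c(0, sqrt(rowSums(d^2)))
  keep <- enorm <= threshold_mm
  list(keep = keep, enorm = enorm, n_censored = sum(!keep))
}

#' RETROICOR-style physiological regressors
#'
#' Fourier expansion of the cardiac and respiratory phase traces up to the
#' given order (sin and cos at each order for each trace) plus lagged
#' copies of the respiration-volume-per-time (RVT) series. With the
#' defaults (order 2, 5 RVT lags) this yields the conventional 13 columns:
#' 8 Fourier terms and RVT at lags 0-4 frames.
#'
#' @param trace a `physio_trace` (see [simulate_multiecho()]) or a list
#'   with `cardiac_phase`, `respiratory_phase` and `rvt`.
#' @param order Fourier expansion order per trace.
#' @param n_rvt_lags number of lagged RVT columns (lag 0 upward).
#' @return frames x (4*order + n_rvt_lags) matrix with named columns.
#' @export
build_physio_regressors <- function(trace, order = 2, n_rvt_lags = 5) {
  pc <- trace$cardiac_phase
  pr <- trace$respiratory_phase
  stopifnot(length(pc) == length(pr))
  cols <- list()
  for (o in seq_len(order)) {
    cols[[paste0("card_sin", o)]] <- sin(o * pc)
    cols[[paste0("card_cos", o)]] <- cos(o * pc)
    cols[[paste0("resp_sin", o)]] <- sin(o * pr)
    cols[[paste0("resp_cos", o)]] <- cos(o * pr)
  }
  if (n_rvt_lags > 0) {
    rvt <- trace$rvt
    stopifnot(length(rvt) == length(pc))
    for (l in seq_len(n_rvt_lags) - 1L) {
      cols[[paste0("rvt_lag", l)]] <-
        c(rep(rvt[1], l), head(rvt, length(rvt) - l))
    }
  }
  x <- do.call(cbind, cols)
  const <- apply(x, 2, function(v) sd(v) < 1e-10)
  if (any(const)) {
    warning("collinear (constant) physiological regressor column(s): ",
            paste(colnames(x)[const], collapse = ", "))
  }
  x
}

#' Rigid-body motion regressors
#'
#' The six motion parameters plus their backward first differences
#' (first-frame derivative set to 0): 12 columns.
#'
#' @param motion_params frames x 6 matrix.
#' @return frames x 12 matrix with named columns.
#' @export
build_motion_regressors <- function(motion_params) {
  motion_params <- as.matrix(motion_params)
  if (ncol(motion_params) != 6) stop("motion_params must have 6 columns")
  d <- rbind(0, diff(motion_params))
  nm <- colnames(motion_params) %||% paste0("mot", 1:6)
  x <- cbind(motion_params, d)
  colnames(x) <- c(nm, paste0("d_", nm))
  x
}

#' Principal-component CSF regressors
#'
#' Top temporal principal components of the (demeaned) CSF voxel time
#' series, scaled to unit variance -- the conventional global-CSF nuisance
#' set uses the first three components of the lateral ventricles.
#'
#' @param data 4D array.
#' @param csf_mask 3D logical mask of CSF voxels.
#' @param k number of components (default 3).
#' @return frames x k matrix (fewer columns, with a warning, if the CSF
#'   series has lower rank).
#' @export
build_csf_regressors <- function(data, csf_mask, k = 3) {
  if (sum(csf_mask) < k) {
    warning("fewer CSF voxels (", sum(csf_mask), ") than requested ",
            "components; returning ", sum(csf_mask))
  }
  y <- t(vox_mat(data, csf_mask))                # frames x voxels
  y <- sweep(y, 2L, colMeans(y), "-")
  pc <- prcomp(y, center = FALSE, scale. = FALSE)
  pos <- pc$sdev > max(pc$sdev) * 1e-8
  kk <- min(k, sum(pos))
  if (kk < k) warning("CSF series rank ", kk, " < ", k, " components")
  s <- pc$x[, seq_len(kk), drop = FALSE]
  s <- sweep(s, 2L, apply(s, 2L, sd), "/")
  colnames(s) <- paste0("csf_pc", seq_len(kk))
  s
}

#' Per-voxel local white-matter (ANATICOR-style) regressors
#'
#' For each target voxel, the mean time series of eroded white-matter
#' voxels within a spherical neighbourhood (default radius 15 mm). Targets
#' whose neighbourhood contains no eroded-WM voxel fall back to the global
#' eroded-WM mean.
#'
#' @param data 4D array.
#' @param wm_mask 3D logical white-matter mask (eroded internally by one
#'   voxel; if erosion empties it the full mask is used with a warning).
#' @param target_mask 3D logical mask of voxels needing a regressor.
#' @param radius_mm neighbourhood radius in mm.
#' @param voxel_mm voxel dimensions in mm.
#' @return matrix (targets x frames), rows in mask order of `target_mask`;
#'   attribute `fallback` flags rows using the global-WM fallback.
#' @export
build_local_wm_regressor <- function(data, wm_mask, target_mask,
                                     radius_mm = 15,
                                     voxel_mm = c(2.38, 2.38, 2.7)) {
  if (!any(wm_mask)) stop("white-matter mask is empty")
  wme <- erode_mask(wm_mask)
  if (!any(wme)) {
    warning("eroded WM mask is empty; using the uneroded mask")
    wme <- wm_mask
  }
  wmdat <- vox_mat(data, wme)                    # wm voxels x frames
  co_t <- sweep(mask_coords(target_mask), 2L, voxel_mm, "*")
  co_w <- sweep(mask_coords(wme), 2L, voxel_mm, "*")
  d2 <- outer(rowSums(co_t^2), rep(1, nrow(co_w))) +
    outer(rep(1, nrow(co_t)), rowSums(co_w^2)) - 2 * co_t %*% t(co_w)
  w <- (d2 <= radius_mm^2) * 1
  nn <- rowSums(w)
  fallback <- nn == 0
  out <- matrix(0, nrow(w), ncol(wmdat))
  if (any(!fallback)) {
    out[!fallback, ] <- (w[!fallback, , drop = FALSE] %*% wmdat) /
      nn[!fallback]
  }
  if (any(fallback)) {
    out[fallback, ] <- matrix(colMeans(wmdat), sum(fallback), ncol(wmdat),
                              byrow = TRUE)
  }
  attr(out, "fallback") <- fallback
  out
}

#' Assemble a nuisance design
#'
#' Collects named regressor groups into one design matrix: Legendre drift
#' columns (`polort`; default order `1 + floor(duration/150 s)`), and any
#' of `physio` (13 columns), `motion` (12), `csf` (3). A per-voxel local
#' white-matter regressor is carried separately (it is a different column
#' at every voxel) and is included in fits by [fit_nuisance_glm()].
#'
#' @param n_frames number of frames.
#' @param tr_ms repetition time (ms).
#' @param physio,motion,csf optional regressor matrices from the
#'   `build_*_regressors` helpers.
#' @param local_wm optional per-voxel regressor matrix from
#'   [build_local_wm_regressor()] (targets x frames, rows in the voxel
#'   order of `local_wm_mask`).
#' @param local_wm_mask 3D logical mask giving the voxel order of
#'   `local_wm` rows; fits over a subset mask select the matching rows.
#' @param censor optional logical frame-retention vector, e.g.
#'   `censor_frames()$keep`.
#' @param polort drift order; `NULL` for the duration-based default.
#' @return object of class `nuisance_design`: list with `X` (frames x
#'   columns), `groups` (named list of column indices), `local_wm`,
#'   `keep`, `tr_ms`, `frame_times`.
#' @export
build_nuisance_design <- function(n_frames, tr_ms, physio = NULL,
                                  motion = NULL, csf = NULL, local_wm = NULL,
                                  local_wm_mask = NULL, censor = NULL,
                                  polort = NULL) {
  tt <- as.integer(n_frames)
  duration_s <- tt * tr_ms / 1000
  p <- polort %||% default_polort(duration_s)
  X <- legendre_basis(tt, p)
  groups <- list(polort = seq_len(ncol(X)))
  add <- function(X, groups, mat, nm) {
    if (is.null(mat)) return(list(X, groups))
    mat <- as.matrix(mat)
    stopifnot(nrow(mat) == tt)
    groups[[nm]] <- ncol(X) + seq_len(ncol(mat))
    list(cbind(X, mat), groups)
  }
  r <- add(X, groups, physio, "physio"); X <- r[[1]]; groups <- r[[2]]
  r <- add(X, groups, motion, "motion"); X <- r[[1]]; groups <- r[[2]]
  r <- add(X, groups, csf, "csf");       X <- r[[1]]; groups <- r[[2]]
  keep <- censor %||% rep(TRUE, tt)
  stopifnot(length(keep) == tt)
  if (!is.null(local_wm)) stopifnot(ncol(local_wm) == tt)
  structure(list(X = X, groups = groups, local_wm = local_wm,
                 local_wm_mask = local_wm_mask, keep = keep,
                 tr_ms = tr_ms,
                 frame_times = (seq_len(tt) - 1L) * tr_ms / 1000),
            class = "nuisance_design")
}

# Drop collinear columns of a (censored) design matrix, warning once.
prune_design <- function(Xk) {
  q <- qr(Xk)
  if (q$rank < ncol(Xk)) {
    drop_idx <- q$pivot[(q$rank + 1L):ncol(Xk)]
    warning("dropping ", length(drop_idx), " collinear design column(s): ",
            paste(colnames(Xk)[drop_idx], collapse = ", "))
    kept <- setdiff(seq_len(ncol(Xk)), drop_idx)
    return(list(X = Xk[, kept, drop = FALSE], kept = kept))
  }
  list(X = Xk, kept = seq_len(ncol(Xk)))
}

# Rows of design$local_wm corresponding to the voxels of `mask`; NULL when
# the rows already match.
lw_rows_for <- function(design, mask) {
  if (is.null(design$local_wm) || is.null(design$local_wm_mask)) return(NULL)
  lwm <- as.vector(design$local_wm_mask)
  mv <- as.vector(mask)
  if (any(mv & !lwm)) {
    stop("analysis mask extends outside the local-WM regressor's ",
         "target mask")
  }
  which(mv[lwm])
}

# Residuals and RSS of Y (voxels x kept frames) against censored design
# columns `cols` of the design, with optional per-voxel local-WM column.
# Returns list(resid, rss).
project_out <- function(Ymat, design, cols, use_local_wm, lw_rows = NULL) {
  keep <- design$keep
  Xk <- design$X[keep, cols, drop = FALSE]
  Xk <- prune_design(Xk)$X
  Yk <- Ymat[, keep, drop = FALSE]
  q <- qr(Xk)
  # residual of each voxel series against Xk
  E <- Yk - t(qr.fitted(q, t(Yk)))
  if (use_local_wm && !is.null(design$local_wm)) {
    W <- design$local_wm[, keep, drop = FALSE]
    if (!is.null(lw_rows)) W <- W[lw_rows, , drop = FALSE]
    stopifnot(nrow(W) == nrow(Yk))
    EW <- W - t(qr.fitted(q, t(W)))
    num <- rowSums(E * EW)
    den <- rowSums(EW^2)
    b <- ifelse(den > 1e-12, num / den, 0)
    E <- E - EW * b
  }
  list(resid = E, rss = rowSums(E^2))
}

#' Fit the nuisance GLM per voxel
#'
#' Ordinary least squares of each voxel's time series on the full design
#' (all groups plus the per-voxel local-WM column when present), restricted
#' to uncensored frames. Residuals retain the voxel temporal mean so that
#' TSNR remains defined. Rank-deficient designs have collinear columns
#' dropped with a warning.
#'
#' @param data 4D array or `combined_series`.
#' @param design a [build_nuisance_design()].
#' @param mask 3D logical analysis mask. If the design carries a local-WM
#'   regressor its rows must correspond to this mask's voxel order.
#' @return object of class `nuisance_fit`: list with `residuals` (voxels
#'   in mask x kept frames, mean restored), `rss` (per voxel, of the
#'   mean-removed residual), `mask`, `keep`.
#' @export
fit_nuisance_glm <- function(data, design, mask) {
  if (inherits(data, "combined_series")) data <- data$data
  stopifnot(inherits(design, "nuisance_design"))
  n_par <- ncol(design$X) + as.integer(!is.null(design$local_wm))
  if (n_par >= sum(design$keep)) {
    stop("design has ", n_par, " columns but only ", sum(design$keep),
         " uncensored frames")
  }
  Y <- vox_mat(data, mask)
  pr <- project_out(Y, design, seq_len(ncol(design$X)),
                    use_local_wm = TRUE, lw_rows = lw_rows_for(design, mask))
  mu <- rowMeans(Y[, design$keep, drop = FALSE])
  structure(list(residuals = pr$resid + mu, rss = pr$rss, mask = mask,
                 keep = design$keep), class = "nuisance_fit")
}

#' Marginal explained variance of one preprocessing step
#'
#' The leave-one-step-out statistic `R2_step = 1 - SS_total / SS_step`,
#' where `SS_total` is the per-voxel residual sum of squares with every
#' step applied and `SS_step` the residual sum of squares with the named
#' step omitted. For regressor steps (`"physio"`, `"motion"`, `"csf"`,
#' `"local_wm"`, `"polort"`) the designs are nested, so `R2` lies in
#' \[0, 1\]. For `step = "combine"`, `SS_total` is the full-design RSS of
#' the echo-combined series and `SS_step` that of the mid-echo-only series
#' (`reference`) after the identical regression, treating the combination
#' itself as a variance-reducing step. No time-course scaling is applied
#' before partitioning.
#'
#' @param data 4D array (the series with all steps available; for
#'   `step = "combine"` this is the combined series).
#' @param design a [build_nuisance_design()].
#' @param step one of the design's group names, `"local_wm"`, or
#'   `"combine"`.
#' @param mask 3D logical analysis mask.
#' @param tissue_masks optional named list of 3D masks for the summary
#'   (e.g. gm, wm).
#' @param reference mid-echo 4D array, required for `step = "combine"`.
#' @return object of class `variance_partition`: list with 3D `r2`,
#'   per-voxel `ss_total`, `ss_step`, the `step` name and a
#'   `tissue_summary` tibble (mean R2 per tissue).
#' @export
marginal_r2 <- function(data, design, step, mask, tissue_masks = NULL,
                        reference = NULL) {
  if (inherits(data, "combined_series")) data <- data$data
  all_cols <- seq_len(ncol(design$X))
  lwr <- lw_rows_for(design, mask)
  if (step == "combine") {
    if (is.null(reference)) stop("step='combine' requires the mid-echo ",
                                 "series as 'reference'")
    Yc <- vox_mat(data, mask)
    Ym <- vox_mat(reference, mask)
    ss_total <- project_out(Yc, design, all_cols, TRUE, lwr)$rss
    ss_step <- project_out(Ym, design, all_cols, TRUE, lwr)$rss
  } else if (step == "local_wm") {
    if (is.null(design$local_wm)) stop("design has no local_wm regressor")
    Y <- vox_mat(data, mask)
    ss_total <- project_out(Y, design, all_cols, TRUE, lwr)$rss
    ss_step <- project_out(Y, design, all_cols, FALSE)$rss
  } else {
    if (!step %in% names(design$groups)) {
      stop("unknown step '", step, "'; design has: ",
           paste(c(names(design$groups),
                   if (!is.null(design$local_wm)) "local_wm", "combine"),
                 collapse = ", "))
    }
    Y <- vox_mat(data, mask)
    ss_total <- project_out(Y, design, all_cols, TRUE, lwr)$rss
    omit <- setdiff(all_cols, design$groups[[step]])
    ss_step <- project_out(Y, design, omit, TRUE, lwr)$rss
  }
  r2 <- ifelse(ss_step > 0, 1 - ss_total / ss_step, 0)
  dim3 <- dim(data)[1:3]
  summary <- NULL
  if (!is.null(tissue_masks)) {
    summary <- do.call(rbind, lapply(names(tissue_masks), function(nm) {
      sel <- as.vector(tissue_masks[[nm]])[as.vector(mask)]
      tibble::tibble(tissue = nm, step = step,
                     r2_mean = mean(r2[sel]), r2_sd = sd(r2[sel]))
    }))
  }
  structure(list(r2 = unvox(r2, dim3, mask, fill = NA_real_),
                 ss_total = ss_total, ss_step = ss_step, step = step,
                 mask = mask, tissue_summary = summary),
            class = "variance_partition")
}

# Index pairs (rows of the mask-order voxel list) of 6-neighbour adjacent
# voxels inside `mask`.
adjacent_pairs <- function(mask) {
  d <- dim(mask)
  lin <- array(0L, dim = d)
  lin[mask] <- seq_len(sum(mask))
  pairs <- list()
  for (ax in 1:3) {
    idx_a <- lapply(d, seq_len)
    idx_b <- idx_a
    idx_a[[ax]] <- seq_len(d[ax] - 1L)
    idx_b[[ax]] <- seq_len(d[ax] - 1L) + 1L
    a <- lin[idx_a[[1]], idx_a[[2]], idx_a[[3]]]
    b <- lin[idx_b[[1]], idx_b[[2]], idx_b[[3]]]
    ok <- a > 0L & b > 0L
    pairs[[ax]] <- cbind(a[ok], b[ok])
  }
  do.call(rbind, pairs)
}

# Row-by-row Pearson correlation of two conformable matrices.
rowwise_cor <- function(a, b) {
  a <- a - rowMeans(a)
  b <- b - rowMeans(b)
  den <- sqrt(rowSums(a^2) * rowSums(b^2))
  out <- rowSums(a * b) / den
  out[!is.finite(out)] <- 0
  out
}

#' Dependence of combination-removed noise on nuisance regressors
#'
#' The noise removed by echo combination is estimated as the difference
#' between the echo-combined and mid-echo-only time courses (both
#' demeaned). Pearson correlations of this removed series are computed
#' against every design column and, voxelwise, between 6-neighbour
#' adjacent voxels; when the design carries a local-WM regressor the
#' adjacent-voxel correlation of that regressor is reported alongside for
#' contrast. Correlations are summarised as root-mean-square over voxels,
#' columns and pairs.
#'
#' @param series the `me_series` (supplies the mid echo).
#' @param combined a [combine_echoes()] result.
#' @param design a [build_nuisance_design()].
#' @param mask 3D logical analysis mask (e.g. grey matter).
#' @return tibble with columns `quantity` and `rms_r`: rows
#'   `removed_vs_<group>` per design group, `removed_adjacent`, and
#'   `local_wm_adjacent` when available.
#' @export
removed_noise_correlations <- function(series, combined, design, mask) {
  mid <- echo_data(series)
  keep <- design$keep
  rem <- (vox_mat(combined$data, mask) - vox_mat(mid, mask))[, keep,
                                                             drop = FALSE]
  rem <- rem - rowMeans(rem)
  rows <- list()
  for (g in names(design$groups)) {
    Xg <- design$X[keep, design$groups[[g]], drop = FALSE]
    Xg <- Xg[, apply(Xg, 2, sd) > 1e-12, drop = FALSE]
    if (!ncol(Xg)) next
    r <- suppressWarnings(cor(t(rem), Xg))
    r[!is.finite(r)] <- 0
    rows[[paste0("removed_vs_", g)]] <- sqrt(mean(r^2))
  }
  ap <- adjacent_pairs(mask)
  if (nrow(ap)) {
    ra <- rowwise_cor(rem[ap[, 1], , drop = FALSE],
                      rem[ap[, 2], , drop = FALSE])
    rows[["removed_adjacent"]] <- sqrt(mean(ra^2))
    if (!is.null(design$local_wm)) {
      lw <- design$local_wm[, keep, drop = FALSE]
      rl <- rowwise_cor(lw[ap[, 1], , drop = FALSE],
                        lw[ap[, 2], , drop = FALSE])
      rows[["local_wm_adjacent"]] <- sqrt(mean(rl^2))
    }
  }
  tibble::tibble(quantity = names(rows), rms_r = unlist(rows, use.names = FALSE))
}
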