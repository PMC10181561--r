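#' Temporal bandpass filter and spatial Gaussian smoothing
#'
#' Frequency-domain projection with hard band edges (bins whose two-sided
#' frequency falls outside the band are zeroed; the DC component is kept so
#' the series retains its mean), followed by spatial smoothing with a
#' Gaussian kernel of the given full width at half maximum. The
#' resting-state defaults pass 0.009-0.1 Hz and smooth at 4 mm FWHM.
#'
#' @param data 4D array or `combined_series` (typically nuisance
#'   residuals).
#' @param tr_s repetition time in seconds.
#' @param band passband in Hz, `c(low, high)`; `high` must be below the
#'   Nyquist frequency `1/(2 TR)`.
#' @param fwhm_mm smoothing kernel FWHM in mm (0 disables smoothing).
#' @param voxel_mm voxel dimensions in mm.
#' @return filtered and smoothed 4D array.
#' @export
bandpass_and_smooth <- function(data, tr_s, band = c(0.009, 0.1),
                                fwhm_mm = 4, voxel_mm = c(2.38, 2.38, 2.7)) {
  if (inherits(data, "combined_series")) {
    voxel_mm <- data$voxel_mm %||% voxel_mm
    tr_s <- data$tr / 1000
    data <- data$data
  }
  d <- dim(data)
  stopifnot(length(d) == 4L)
  nyq <- 1 / (2 * tr_s)
  if (band[2] > nyq + 1e-12) {
    stop("band upper edge ", band[2], " Hz exceeds Nyquist ",
         signif(nyq, 4), " Hz")
  }
  tt <- d[4]
  m <- t(matrix(data, prod(d[1:3]), tt))         # frames x voxels
  fr <- seq(0, tt - 1) / (tt * tr_s)
  fr <- pmin(fr, 1 / tr_s - fr)
  keepbin <- (fr >= band[1] & fr <= band[2])
  keepbin[1] <- TRUE                             # retain DC / voxel mean
  mf <- mvfft(m)
  mf[!keepbin, ] <- 0
  out <- Re(mvfft(mf, inverse = TRUE)) / tt
  out <- array(t(out), dim = d)
  if (fwhm_mm > 0) out <- gauss_smooth(out, fwhm_mm, voxel_mm)
  out
}

#' Concatenate runs after per-run z-score normalisation
#'
#' Each run is z-scored per voxel over time (mean 0, SD 1; constant voxels
#' become 0) and the runs are stacked along the time axis, the standard
#' recipe for pooling repeated acquisitions into one long series.
#'
#' @param runs list of 4D arrays on the same grid.
#' @param mode only `"zscore"` is implemented.
#' @return 4D array with `sum(frames)` frames.
#' @export
concat_runs <- function(runs, mode = "zscore") {
  mode <- match.arg(mode, "zscore")
  stopifnot(length(runs) >= 1)
  runs <- lapply(runs, function(r) {
    if (inherits(r, "combined_series")) r$data else r
  })
  d3 <- dim(runs[[1]])[1:3]
  zs <- lapply(runs, function(r) {
    if (!identical(dim(r)[1:3], d3)) stop("runs must share one grid")
    m <- matrix(r, prod(d3), dim(r)[4])
    mu <- rowMeans(m)
    s <- row_sd(m)
    s[s < 1e-12] <- 1
    array((m - mu) / s, dim = dim(r))
  })
  tt <- vapply(zs, function(r) dim(r)[4], integer(1))
  out <- array(0, dim = c(d3, sum(tt)))
  at <- 0L
  for (r in zs) {
    out[, , , at + seq_len(dim(r)[4])] <- r
    at <- at + dim(r)[4]
  }
  out
}

#' Inter-ROI functional connectivity matrix
#'
#' Pearson correlation between the mean time courses of every pair of
#' parcels, Fisher z-transformed. The diagonal is set to zero by
#' convention; correlations are clipped to plus/minus (1 - 1e-7) before
#' `atanh` so the matrix stays finite (clipped entries are flagged).
#'
#' @param data 4D array.
#' @param parcels 3D integer label volume (0 = unlabelled).
#' @return object of class `fc_matrix`: list with `z` (symmetric matrix),
#'   `labels`, `n_frames`, and `clipped`/`constant` flags.
#' @export
roi_fc_matrix <- function(data, parcels) {
  labs <- sort(setdiff(unique(as.vector(parcels)), 0))
  if (length(labs) < 2) stop("need at least 2 parcels")
  tt <- dim(data)[4]
  if (tt < 3) stop("need at least 3 frames")
  tc <- vapply(labs, function(l) colMeans(vox_mat(data, parcels == l)),
               numeric(tt))
  const <- apply(tc, 2, sd) < 1e-12
  if (any(const)) {
    warning("constant parcel time course(s): ",
            paste(labs[const], collapse = ", "), "; z set missing")
  }
  r <- suppressWarnings(cor(tc))
  clipped <- abs(r) >= 1 - 1e-7
  diag(clipped) <- FALSE
  z <- fisher_z(r)
  z[const, ] <- NA_real_
  z[, const] <- NA_real_
  diag(z) <- 0
  labels <- paste0("roi", labs)
  dimnames(z) <- list(labels, labels)
  structure(list(z = z, labels = labels, n_frames = tt, clipped = clipped,
                 constant = const), class = "fc_matrix")
}

#' Paired group comparison of FC matrices with edge screening
#'
#' Edgewise paired t-tests between two matched sets of Fisher-z FC
#' matrices. An edge survives when the paired difference is significant
#' (`p < p_thresh`, uncorrected) AND the connection is meaningful in at
#' least one group (`max(|mean z_a|, |mean z_b|) > z_thresh`). Edges whose
#' paired differences have zero variance (e.g. identical groups) get
#' `p = 1`.
#'
#' @param matrices_a,matrices_b lists of `fc_matrix` (or plain matrices),
#'   paired by position, `n >= 3`.
#' @param p_thresh uncorrected p-value threshold (default 0.01).
#' @param z_thresh Fisher-z magnitude threshold (default 0.3).
#' @return list with `edges` (logical matrix of surviving edges),
#'   `p`, `mean_a`, `mean_b`, and `per_roi` (tibble of surviving-edge
#'   counts per ROI).
#' @export
compare_fc_groups <- function(matrices_a, matrices_b, p_thresh = 0.01,
                              z_thresh = 0.3) {
  za <- lapply(matrices_a, function(m) if (inherits(m, "fc_matrix")) m$z else m)
  zb <- lapply(matrices_b, function(m) if (inherits(m, "fc_matrix")) m$z else m)
  n <- length(za)
  if (n != length(zb)) stop("groups must be paired (equal length)")
  if (n < 3) stop("need n >= 3 pairs")
  arr_a <- simplify2array(za)
  arr_b <- simplify2array(zb)
  dif <- arr_a - arr_b
  mu_d <- apply(dif, c(1, 2), mean)
  sd_d <- apply(dif, c(1, 2), sd)
  se <- sd_d / sqrt(n)
  tstat <- ifelse(se > 1e-12, mu_d / se, 0)
  p <- 2 * pt(-abs(tstat), df = n - 1)
  p[se <= 1e-12] <- 1
  mean_a <- apply(arr_a, c(1, 2), mean)
  mean_b <- apply(arr_b, c(1, 2), mean)
  meaningful <- pmax(abs(mean_a), abs(mean_b)) > z_thresh
  edges <- (p < p_thresh) & meaningful
  diag(edges) <- FALSE
  labels <- rownames(mean_a) %||% paste0("roi", seq_len(nrow(mean_a)))
  per_roi <- tibble::tibble(roi = labels, n_edges = rowSums(edges))
  list(edges = edges, p = p, mean_a = mean_a, mean_b = mean_b,
       per_roi = per_roi)
}

#' Seed-based functional connectivity map
#'
#' Pearson correlation between each voxel's time course and the mean time
#' course of the seed region, Fisher z-transformed.
#'
#' @param data 4D array.
#' @param seed_mask 3D logical seed mask (nonempty).
#' @param mask optional 3D analysis mask (defaults to all voxels).
#' @return 3D array of Fisher z values (`NA` outside `mask`).
#' @export
seed_fc_map <- function(data, seed_mask, mask = NULL) {
  if (!any(seed_mask)) stop("empty seed")
  d3 <- dim(data)[1:3]
  mask <- mask %||% array(TRUE, dim = d3)
  seed_tc <- colMeans(vox_mat(data, seed_mask))
  y <- vox_mat(data, mask)
  r <- suppressWarnings(as.vector(cor(t(y), seed_tc)))
  r[!is.finite(r)] <- 0
  unvox(fisher_z(r), d3, mask, fill = NA_real_)
}

#' Global correlation (GCOR) of a masked series
#'
#' The average of all pairwise voxel-time-series Pearson correlations
#' (including the unit diagonal), computed in O(voxels x frames) as the
#' squared norm of the mean unit-norm time series rather than by forming
#' the voxel-pair matrix.
#'
#' @param data 4D array.
#' @param mask 3D logical mask with >= 2 voxels.
#' @return scalar GCOR in \[0, 1\].
#' @export
gcor <- function(data, mask) {
  y <- vox_mat(data, mask)
  if (nrow(y) < 2) stop("need at least 2 voxels")
  y <- y - rowMeans(y)
  nrm <- sqrt(rowSums(y^2))
  ok <- nrm > 1e-12
  z <- y[ok, , drop = FALSE] / nrm[ok]
  g <- colMeans(z)
  sum(g^2) * nrow(z)^2 / nrow(y)^2
}

#' Group-level seed-FC map with a GCOR covariate
#'
#' Voxelwise one-sample inference on subject Fisher-z seed maps adjusting
#' for each subject's global correlation: per voxel, `z_i` is regressed on
#' an intercept and the centred GCOR covariate, the intercept is tested
#' (two-sided t), p-values are corrected by Benjamini-Hochberg FDR at
#' level `q`, and surviving voxels are additionally required to exceed the
#' Fisher-z magnitude threshold.
#'
#' @param maps list of subject 3D Fisher-z maps.
#' @param gcor_covariate numeric vector of subject GCOR values.
#' @param mask 3D analysis mask.
#' @param q FDR level (default 0.001).
#' @param z_thresh group-mean Fisher-z magnitude threshold (default 0.3).
#' @return list with `survived` (3D logical), `extent` (voxel count),
#'   `mean_z` (3D), `p` and `p_fdr` (vectors over mask voxels).
#' @export
group_seed_fc <- function(maps, gcor_covariate, mask, q = 0.001,
                          z_thresh = 0.3) {
  n <- length(maps)
  stopifnot(n >= 3, length(gcor_covariate) == n)
  Y <- vapply(maps, function(m) m[mask], numeric(sum(mask)))  # vox x subj
  gc <- gcor_covariate - mean(gcor_covariate)
  X <- cbind(1, gc)
  fit <- ols_rows(Y, X)
  p <- 2 * pt(-abs(fit$t1), df = n - ncol(X))
  p_fdr <- p.adjust(p, "BH")
  surv <- p_fdr < q & abs(fit$b1) > z_thresh
  d3 <- dim(mask)
  list(survived = unvox(surv, d3, mask, fill = 0) > 0,
       extent = sum(surv),
       mean_z = unvox(fit$b1, d3, mask, fill = NA_real_),
       p = p, p_fdr = p_fdr)
}

# Row-wise OLS of Y (units x n) on X (n x p); returns intercept estimate
# and its t statistic.
ols_rows <- function(Y, X) {
  n <- ncol(Y)
  xtx_inv <- solve(crossprod(X))
  B <- Y %*% X %*% xtx_inv                      # units x p
  fitted <- B %*% t(X)
  rss <- rowSums((Y - fitted)^2)
  df <- n - ncol(X)
  sigma2 <- rss / df
  se1 <- sqrt(pmax(sigma2 * xtx_inv[1, 1], 0))
  t1 <- ifelse(se1 > 1e-12, B[, 1] / se1,
               ifelse(abs(B[, 1]) > 1e-12, sign(B[, 1]) * Inf, 0))
  list(b1 = B[, 1], t1 = t1, se1 = se1, df = df)
}
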