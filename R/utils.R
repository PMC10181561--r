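# Internal array/series helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Flatten a 4D array to a voxels-by-frames matrix
#'
#' @param x 4D array (x, y, z, t) or a matrix already in voxel-by-frame form.
#' @param mask optional 3D logical array; only voxels inside it are kept
#'   (in column-major order).
#' @return numeric matrix, one row per voxel, one column per frame.
#' @keywords internal
#' @noRd
vox_mat <- function(x, mask = NULL) {
  if (is.matrix(x)) return(x)
  stopifnot(length(dim(x)) == 4L)
  d <- dim(x)
  m <- matrix(x, nrow = prod(d[1:3]), ncol = d[4])
  if (!is.null(mask)) m <- m[as.vector(mask), , drop = FALSE]
  m
}

# Inverse of vox_mat: place a voxel-by-frame matrix (or voxel vector) back
# onto the grid. Voxels outside `mask` are filled with `fill`.
unvox <- function(m, dim3, mask = NULL, fill = 0) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 1L)
  tt <- ncol(m)
  out <- array(fill, dim = c(dim3, tt))
  full <- matrix(fill, nrow = prod(dim3), ncol = tt)
  if (is.null(mask)) full[] <- m else full[as.vector(mask), ] <- m
  out[] <- full
  if (tt == 1L) array(out, dim = dim3) else out
}

# Voxel coordinates (in voxel index units) for TRUE entries of a 3D mask.
mask_coords <- function(mask) {
  d <- dim(mask)
  idx <- which(as.vector(mask))
  i <- (idx - 1L) %% d[1] + 1L
  j <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  k <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  cbind(i, j, k)
}

# Legendre polynomial basis P_0..P_order evaluated on n points mapped to
# [-1, 1]; columns are the standard (unnormalised) Legendre polynomials.
legendre_basis <- function(n, order) {
  x <- if (n == 1L) 0 else seq(-1, 1, length.out = n)
  out <- matrix(0, n, order + 1L)
  out[, 1L] <- 1
  if (order >= 1L) out[, 2L] <- x
  if (order >= 2L) {
    for (k in 2:order) {
      out[, k + 1L] <- ((2 * k - 1) * x * out[, k] - (k - 1) * out[, k - 1L]) / k
    }
  }
  colnames(out) <- paste0("polort", 0:order)
  out
}

# AFNI-style default Legendre detrending order for a run of given duration.
default_polort <- function(duration_s) 1L + floor(duration_s / 150)

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# 1D Gaussian smoothing matrix (n x n) with edge renormalisation, sigma in
# voxel units. Returns identity when sigma is negligible.
gauss_smooth_matrix <- function(n, sigma_vox) {
  if (sigma_vox < 1e-6) return(diag(n))
  half <- max(1L, ceiling(3 * sigma_vox))
  offs <- (-half):half
  kern <- exp(-offs^2 / (2 * sigma_vox^2))
  s <- matrix(0, n, n)
  for (o in seq_along(offs)) {
    idx <- seq_len(n) + offs[o]
    ok <- idx >= 1L & idx <= n
    s[cbind(which(ok), idx[ok])] <- s[cbind(which(ok), idx[ok])] + kern[o]
  }
  s / rowSums(s)
}

# Separable 3D Gaussian smoothing of a 3D or 4D array; fwhm in mm, voxel_mm
# a length-3 vector of voxel dimensions.
gauss_smooth <- function(x, fwhm_mm, voxel_mm) {
  d <- dim(x)
  dim3 <- d[1:3]
  tt <- if (length(d) == 4L) d[4] else 1L
  sig <- fwhm_to_sigma(fwhm_mm) / voxel_mm
  sx <- gauss_smooth_matrix(dim3[1], sig[1])
  sy <- gauss_smooth_matrix(dim3[2], sig[2])
  sz <- gauss_smooth_matrix(dim3[3], sig[3])
  a <- array(x, dim = c(dim3, tt))
  # contract each spatial dimension in turn
  m <- matrix(a, nrow = dim3[1])                       # x by (y z t)
  m <- sx %*% m
  a <- array(m, dim = c(dim3, tt))
  a <- aperm(a, c(2, 1, 3, 4))
  m <- sy %*% matrix(a, nrow = dim3[2])
  a <- aperm(array(m, dim = c(dim3[2], dim3[1], dim3[3], tt)), c(2, 1, 3, 4))
  a <- aperm(a, c(3, 1, 2, 4))
  m <- sz %*% matrix(a, nrow = dim3[3])
  a <- aperm(array(m, dim = c(dim3[3], dim3[1], dim3[2], tt)), c(2, 3, 1, 4))
  if (length(d) == 3L) array(a, dim = dim3) else a
}

#' Fisher z-transform of correlation coefficients
#'
#' Applies `atanh` after clipping `r` to plus/minus (1 - 1e-7) so the
#' transform stays finite at numerically perfect correlations.
#'
#' @param r numeric vector/matrix of Pearson correlations.
#' @param clip clipping bound applied to `|r|` before `atanh`.
#' @return object of the same shape as `r` on the Fisher z scale.
#' @export
#' @examples
#' fisher_z(0.3)  # 0.3095...
fisher_z <- function(r, clip = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clip), clip))
}

# Erode a 3D logical mask by one voxel (6-connectivity).
erode_mask <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, ax, by) {
    r <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by > 0) {
      idx_dst[[ax]] <- seq_len(d[ax] - by) + by
      idx_src[[ax]] <- seq_len(d[ax] - by)
    } else {
      idx_dst[[ax]] <- seq_len(d[ax] + by)
      idx_src[[ax]] <- seq_len(d[ax] + by) - by
    }
    r[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    r
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) out <- out & shift(mask, ax, by)
  out
}

# Column-standardise a matrix (mean 0, sd 1); constant columns become 0.
std_cols <- function(x) {
  x <- sweep(x, 2L, colMeans(x), "-")
  s <- apply(x, 2L, stats::sd)
  s[s < .Machine$double.eps] <- 1
  sweep(x, 2L, s, "/")
}

# Row-wise temporal sd of a voxel-by-frame matrix.
row_sd <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(pmax(rowSums((m - mu)^2) / (n - 1), 0))
}

stamp_hash <- function(x) rlang::hash(x)
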