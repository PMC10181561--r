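#' Dual regression of group network maps against a subject series
#'
#' Stage 1 (spatial regression): each frame's image is regressed on the K
#' group spatial maps (plus an intercept), giving one subject-specific
#' time course per network. Stage 2 (temporal regression): each voxel's
#' time series is regressed on the K stage-1 time courses (plus an
#' intercept), giving one subject-specific beta map per network. On a
#' noiseless mixture `series = maps x timecourses` both stages are exact
#' inverses.
#'
#' @param group_maps list of K 3D spatial maps (weights; linearly
#'   independent on the mask).
#' @param data 4D array.
#' @param mask 3D logical analysis mask.
#' @return list with `timecourses` (K x frames) and `subject_maps`
#'   (list of K 3D beta maps).
#' @export
dual_regression <- function(group_maps, data, mask) {
  k <- length(group_maps)
  stopifnot(k >= 1)
  A <- vapply(group_maps, function(m) m[mask], numeric(sum(mask)))  # vox x K
  cc <- suppressWarnings(cor(A))
  cc[!is.finite(cc)] <- 0
  off <- abs(cc - diag(k))
  if (qr(cbind(1, A))$rank < k + 1) {
    worst <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop("collinear group maps: ", worst[1], " and ", worst[2])
  }
  Y <- vox_mat(data, mask)                        # vox x frames
  X1 <- cbind(1, A)
  tc <- solve(crossprod(X1), crossprod(X1, Y))[-1, , drop = FALSE]  # K x T
  X2 <- cbind(1, t(tc))                           # frames x (K+1)
  B <- t(solve(crossprod(X2), crossprod(X2, t(Y))))[, -1, drop = FALSE]
  d3 <- dim(mask)
  maps <- lapply(seq_len(k), function(j) unvox(B[, j], d3, mask, fill = 0))
  names(maps) <- names(group_maps)
  rownames(tc) <- names(group_maps)
  list(timecourses = tc, subject_maps = maps)
}

#' One-sample group threshold of subject network maps
#'
#' Voxelwise one-sample t-test across subjects on dual-regression beta
#' maps, Benjamini-Hochberg FDR correction at level `q`, and a positive
#' group-mean requirement; the surviving voxels form the detected network
#' mask.
#'
#' @param subject_maps list of subject 3D beta maps for one network.
#' @param mask 3D analysis mask.
#' @param q FDR level (default 0.001).
#' @return 3D logical detection mask.
#' @export
group_network_mask <- function(subject_maps, mask, q = 0.001) {
  n <- length(subject_maps)
  stopifnot(n >= 3)
  Y <- vapply(subject_maps, function(m) m[mask], numeric(sum(mask)))
  mu <- rowMeans(Y)
  se <- row_sd(Y) / sqrt(n)
  tstat <- ifelse(se > 1e-12, mu / se,
                  ifelse(abs(mu) > 1e-12, sign(mu) * Inf, 0))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  surv <- p.adjust(p, "BH") < q & mu > 0
  unvox(surv, dim(mask), mask, fill = 0) > 0
}

#' Voxel-count detection metrics against a ground-truth mask
#'
#' Counts true/false positives/negatives of a detected mask against the
#' truth inside the analysis mask and evaluates sensitivity
#' `TP/(TP+FN)`, false positive rate `1 - TN/(TN+FP)` and accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`.
#'
#' @param truth_mask 3D logical ground-truth network mask (nonempty).
#' @param test_mask 3D logical detected mask on the same grid.
#' @param mask 3D analysis mask over which voxels are counted.
#' @return object of class `detection_metrics`: tibble with tp, tn, fp,
#'   fn, sensitivity, fpr, accuracy.
#' @export
detection_metrics <- function(truth_mask, test_mask, mask = NULL) {
  stopifnot(identical(dim(truth_mask), dim(test_mask)))
  mask <- mask %||% array(TRUE, dim = dim(truth_mask))
  tr <- truth_mask[mask]
  te <- test_mask[mask]
  if (!any(tr)) stop("empty truth mask")
  tp <- sum(tr & te); fn <- sum(tr & !te)
  fp <- sum(!tr & te); tn <- sum(!tr & !te)
  out <- tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sensitivity = tp / (tp + fn),
    fpr = 1 - tn / (tn + fp),
    accuracy = (tp + tn) / (tp + tn + fp + fn)
  )
  class(out) <- c("detection_metrics", class(out))
  out
}

#' Network-detection metrics as a function of scan length
#'
#' For each requested scan length, every subject's series is truncated to
#' the frame count covering that duration, dual regression against the
#' group maps yields subject beta maps, the one-sample FDR-thresholded
#' group mask is formed per network, and [detection_metrics()] is
#' evaluated against each network's ground-truth mask.
#'
#' @param subject_data list of subject 4D arrays (all at least as long as
#'   the longest requested length).
#' @param group_maps list of K network weight maps (regression inputs).
#' @param truth_masks list of K 3D logical ground-truth masks.
#' @param tr_ms repetition time (ms).
#' @param mask 3D analysis mask.
#' @param lengths_min scan lengths in minutes (default 2 to 9).
#' @param q FDR level for the group threshold.
#' @return tibble with columns `length_min`, `network`, `n_frames`,
#'   `sensitivity`, `fpr`, `accuracy`.
#' @export
scan_length_curve <- function(subject_data, group_maps, truth_masks, tr_ms,
                              mask, lengths_min = 2:9, q = 0.001) {
  stopifnot(length(group_maps) == length(truth_masks))
  if (any(lengths_min <= 0)) stop("scan lengths must be positive")
  tt_avail <- min(vapply(subject_data, function(d) dim(d)[4], integer(1)))
  rows <- list()
  for (len in lengths_min) {
    nf <- frames_in_duration(len * 60, tr_ms)
    if (nf > tt_avail) stop("length ", len, " min needs ", nf,
                            " frames but only ", tt_avail, " available")
    subj_maps <- lapply(subject_data, function(d) {
      dual_regression(group_maps, d[, , , seq_len(nf), drop = FALSE],
                      mask)$subject_maps
    })
    for (k in seq_along(group_maps)) {
      det <- group_network_mask(lapply(subj_maps, `[[`, k), mask, q = q)
      m <- detection_metrics(truth_masks[[k]], det, mask)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        length_min = len,
        network = names(group_maps)[k] %||% paste0("network", k),
        n_frames = nf, sensitivity = m$sensitivity, fpr = m$fpr,
        accuracy = m$accuracy)
    }
  }
  do.call(rbind, rows)
}

#' Intensity-based EPI coverage mask
#'
#' A voxel is covered when its temporal-mean intensity exceeds
#' `clip_frac` times the robust (median) temporal-mean intensity of the
#' reference region -- the phantom analogue of automatic EPI brain
#' masking, which loses voxels in signal-dropout regions.
#'
#' @param data 4D array or `combined_series`.
#' @param ref_mask 3D mask defining the reference intensity region
#'   (e.g. the head mask); defaults to voxels with positive temporal mean.
#' @param clip_frac clip fraction of the reference median (default 0.1).
#' @return 3D logical coverage mask.
#' @export
epi_mask <- function(data, ref_mask = NULL, clip_frac = 0.1) {
  if (inherits(data, "combined_series")) data <- data$data
  d3 <- dim(data)[1:3]
  tmean <- array(rowMeans(matrix(data, prod(d3), dim(data)[4])), dim = d3)
  if (is.null(ref_mask)) ref_mask <- tmean > 0
  med <- median(tmean[ref_mask])
  tmean > clip_frac * med
}

#' Cortical coverage ratio of EPI masks against grey matter
#'
#' Voxelwise mean of per-subject EPI coverage masks restricted to the
#' grey-matter mask, and its grand mean: the fraction of subjects covering
#' each GM voxel and the overall GM coverage ratio.
#'
#' @param epi_masks list of per-subject 3D logical masks.
#' @param gm_mask 3D logical grey-matter mask (nonempty).
#' @return list with `map` (3D fraction map, `NA` outside GM) and `ratio`
#'   (scalar mean over GM).
#' @export
coverage_ratio <- function(epi_masks, gm_mask) {
  if (!any(gm_mask)) stop("empty grey-matter mask")
  stopifnot(length(epi_masks) >= 1)
  frac <- Reduce(`+`, lapply(epi_masks, function(m) m[gm_mask] * 1)) /
    length(epi_masks)
  list(map = unvox(frac, dim(gm_mask), gm_mask, fill = NA_real_),
       ratio = mean(frac))
}
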