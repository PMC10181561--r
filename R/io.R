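# NIfTI/TSV/JSON round-trip for simulated datasets.

nifti_with_geometry <- function(arr, voxel_mm, tr_s = NULL) {
  img <- RNifti::asNifti(arr)
  pd <- RNifti::pixdim(img)
  pd[1:3] <- voxel_mm
  if (!is.null(tr_s) && length(pd) >= 4) pd[4] <- tr_s
  RNifti::pixdim(img) <- pd
  img
}

#' Write a simulated dataset to disk
#'
#' Writes one NIfTI file per echo (RAS+ affine, mm units, double
#' precision), the motion parameters and physiological traces as TSV with
#' header rows, ground-truth maps (tissue labels, S0, T2*, network maps)
#' as NIfTI, and a JSON manifest carrying echo times (ms), TR (ms), seed
#' and file names. The dataset round-trips losslessly through
#' [read_dataset()] at stored precision.
#'
#' @param sim an [simulate_multiecho()] result.
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly (a named list).
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "me_sim"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("cannot create output directory: ", dir)
  series <- sim$series
  tr_s <- series$tr / 1000
  vx <- series$voxel_mm
  echo_files <- sprintf("echo-%d_bold.nii.gz", seq_along(series$echo_times))
  for (e in seq_along(series$echo_times)) {
    path <- file.path(dir, echo_files[e])
    r <- try(RNifti::writeNifti(
      nifti_with_geometry(series$data[[e]], vx, tr_s), path,
      datatype = "double"), silent = TRUE)
    if (inherits(r, "try-error")) stop("failed to write ", path)
  }
  truth <- sim$truth
  truth_files <- c(tissue = "truth_tissue.nii.gz", s0 = "truth_s0.nii.gz",
                   t2star = "truth_t2star.nii.gz")
  RNifti::writeNifti(nifti_with_geometry(truth$tissue + 0, vx),
                     file.path(dir, truth_files[["tissue"]]),
                     datatype = "double")
  RNifti::writeNifti(nifti_with_geometry(truth$s0_map, vx),
                     file.path(dir, truth_files[["s0"]]), datatype = "double")
  RNifti::writeNifti(nifti_with_geometry(truth$t2star_map, vx),
                     file.path(dir, truth_files[["t2star"]]),
                     datatype = "double")
  net_files <- sprintf("truth_network-%d.nii.gz",
                       seq_along(truth$network_maps))
  for (k in seq_along(truth$network_maps)) {
    RNifti::writeNifti(nifti_with_geometry(truth$network_maps[[k]], vx),
                       file.path(dir, net_files[k]), datatype = "double")
  }
  mot <- as.data.frame(sim$motion)
  write.table(mot, file.path(dir, "motion.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  phys <- data.frame(frame_time_s = sim$physio$frame_times,
                     cardiac_phase = sim$physio$cardiac_phase,
                     respiratory_phase = sim$physio$respiratory_phase,
                     rvt = sim$physio$rvt)
  write.table(phys, file.path(dir, "physio.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  manifest <- list(
    echo_times_ms = series$echo_times, tr_ms = series$tr,
    n_frames = length(series$frame_times), voxel_mm = vx,
    seed = sim$seed, echo_files = echo_files,
    truth_files = as.list(truth_files), network_files = net_files,
    motion_file = "motion.tsv", physio_file = "physio.tsv"
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' Also accepts externally produced directories following the same layout
#' (one 4D NIfTI per echo plus TSV motion/physio traces and a JSON
#' manifest).
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return list with `series` (an `me_series`), `motion`, `physio`,
#'   `truth_maps` (tissue/s0/t2star arrays and network maps, when present)
#'   and the `manifest`.
#' @export
read_dataset <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  data <- lapply(file.path(dir, mf$echo_files), function(p) {
    arr <- as.array(RNifti::readNifti(p))
    if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
    arr
  })
  tissue <- NULL
  truth_maps <- NULL
  if (!is.null(mf$truth_files)) {
    rd <- function(f) as.array(RNifti::readNifti(file.path(dir, f)))
    tissue <- rd(mf$truth_files$tissue)
    truth_maps <- list(
      tissue = tissue, s0 = rd(mf$truth_files$s0),
      t2star = rd(mf$truth_files$t2star),
      network_maps = lapply(mf$network_files, rd)
    )
  }
  mask <- if (!is.null(tissue)) tissue > 0 else data[[1]][, , , 1] != 0
  tr_s <- mf$tr_ms / 1000
  series <- structure(list(
    data = data, echo_times = mf$echo_times_ms, tr = mf$tr_ms,
    frame_times = (seq_len(mf$n_frames) - 1L) * tr_s,
    mask = mask, voxel_mm = mf$voxel_mm
  ), class = "me_series")
  mot <- as.matrix(utils::read.delim(file.path(dir, mf$motion_file)))
  phys_df <- utils::read.delim(file.path(dir, mf$physio_file))
  physio <- structure(list(cardiac_phase = phys_df$cardiac_phase,
                           respiratory_phase = phys_df$respiratory_phase,
                           rvt = phys_df$rvt,
                           frame_times = phys_df$frame_time_s),
                      class = "physio_trace")
  list(series = series, motion = mot, physio = physio,
       truth_maps = truth_maps, manifest = mf)
}
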