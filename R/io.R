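#' Read rigid-body motion parameters from a text file
#'
#' Expects whitespace- or tab-separated text with one row per volume and
#' six columns: translations in mm, then rotations (degrees by default).
#'
#' @param path file path.
#' @param tr repetition time in seconds.
#' @param degrees logical; rotation unit of the file.
#' @param col_order integer permutation mapping file columns to
#'   \code{tx, ty, tz, rx, ry, rz}.
#' @return a \code{\link{motion_trace}}.
#' @export
read_motion_params <- function(path, tr, degrees = TRUE,
                               col_order = 1:6) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L) stop("expected 6 columns in ", path)
  motion_trace(m[, col_order, drop = FALSE], tr = tr, degrees = degrees)
}

#' Write a motion trace as TSV
#'
#' @param trace a \code{\link{motion_trace}}.
#' @param path output path.
#' @export
write_motion_params <- function(trace, path) {
  utils::write.table(trace$params, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write a parcel time-series TSV
#'
#' The TSV layout is one row per region: a \code{region_id} column followed
#' by one column per timepoint. Centroids, when present, are a companion
#' TSV with columns \code{region_id, x, y, z}.
#'
#' @param path time-series TSV path.
#' @param tr repetition time in seconds.
#' @param centroid_path optional centroid TSV path.
#' @return a \code{\link{parcel_ts}}.
#' @export
read_parcel_ts <- function(path, tr, centroid_path = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  cen <- NULL
  if (!is.null(centroid_path)) {
    cd <- utils::read.table(centroid_path, header = TRUE, sep = "\t")
    cen <- as.matrix(cd[match(ids, as.character(cd$region_id)),
                        c("x", "y", "z")])
  }
  parcel_ts(m, region_ids = ids, centroids = cen, tr = tr)
}

#' @rdname read_parcel_ts
#' @param ts a \code{\link{parcel_ts}} object.
#' @export
write_parcel_ts <- function(ts, path, centroid_path = NULL) {
  d <- data.frame(region_id = ts$region_ids, ts$data, check.names = FALSE)
  colnames(d) <- c("region_id", paste0("t", seq_len(ncol(ts$data))))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(centroid_path) && !is.null(ts$centroids)) {
    cd <- data.frame(region_id = ts$region_ids, x = ts$centroids[, 1],
                     y = ts$centroids[, 2], z = ts$centroids[, 3])
    utils::write.table(cd, centroid_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write a subject QC report (edge table TSV + summary JSON)
#'
#' @param report an \code{\link{assess_subject}} result.
#' @param edge_path TSV path for the edge-level table.
#' @param summary_path optional JSON path for the subject summary
#'   (fractions, medians, settings, per-region counts).
#' @export
write_subject_qc <- function(report, edge_path, summary_path = NULL) {
  utils::write.table(report$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(summary_path)) {
    s <- list(frac_corrupted = report$frac_corrupted,
              median_abs_r = report$median_abs_r,
              distance_dependence = report$distance_dependence,
              alpha = report$alpha, correction = report$correction,
              null_mode = report$null_mode, n_windows = report$n_windows,
              n_edges = report$n_edges,
              fd_degenerate = report$fd_degenerate,
              excluded_regions = report$excluded_regions,
              region_counts = as.list(report$region_counts))
    jsonlite::write_json(s, summary_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(edge_path)
}

# voxel (0-based ijk) -> world mm coordinates under a 4x4 affine
.vox_to_world <- function(ijk, affine) {
  p <- cbind(ijk, 1) %*% t(affine)
  p[, 1:3, drop = FALSE]
}

#' Extract region-mean time series from a 4D image and a label image
#'
#' Region signals are the per-volume mean over that region's voxels;
#' centroids are the mean voxel position mapped to world mm through the
#' image affine (voxel indices are 0-based).
#'
#' @param bold 4D BOLD image: an \code{RNifti} image, a path to a NIfTI
#'   file, or a plain 4D array.
#' @param labels 3D integer label image (same grid as \code{bold});
#'   background is 0.
#' @param tr repetition time in seconds; taken from the NIfTI header when
#'   available.
#' @return a \code{\link{parcel_ts}} (empty regions are dropped with a
#'   warning).
#' @export
extract_parcel_timeseries <- function(bold, labels, tr = NULL) {
  if (is.character(bold)) bold <- RNifti::readNifti(bold)
  if (is.character(labels)) labels <- RNifti::readNifti(labels)
  if (is.null(tr)) {
    pd <- attr(bold, "pixdim")
    tr <- if (!is.null(pd) && length(pd) >= 4) pd[4] else 1
  }
  affine <- tryCatch(unclass(RNifti::xform(labels)),
                     error = function(e) diag(4))
  d <- dim(bold)
  if (length(d) != 4L) stop("bold must be 4-dimensional")
  if (!all(dim(labels) == d[1:3]))
    stop("label image grid does not match the BOLD grid")
  lab_v <- as.vector(labels)
  ids <- sort(unique(lab_v[lab_v > 0]))
  vox <- matrix(as.vector(bold), nrow = prod(d[1:3]))
  data <- matrix(0, length(ids), d[4])
  cen <- matrix(0, length(ids), 3)
  keep <- logical(length(ids))
  for (i in seq_along(ids)) {
    sel <- lab_v == ids[i]
    if (!any(sel)) next
    keep[i] <- TRUE
    data[i, ] <- colMeans(vox[sel, , drop = FALSE])
    ijk <- which(array(sel, d[1:3]), arr.ind = TRUE) - 1
    cen[i, ] <- colMeans(.vox_to_world(ijk, affine))
  }
  if (!all(keep)) {
    warning("dropping empty regions: ", paste(ids[!keep], collapse = ", "))
  }
  parcel_ts(data[keep, , drop = FALSE], region_ids = as.character(ids[keep]),
            centroids = cen[keep, , drop = FALSE], tr = tr)
}

#' Generate a synthetic fixture subject on disk
#'
#' Builds a small, fully synthetic stand-in for one preprocessed fetal
#' fMRI subject: a 4D BOLD NIfTI whose region signals come from the
#' generative simulator, a parcellation label image, brain/WM/CSF masks, a
#' rigid-motion parameter file whose framewise displacement reproduces the
#' simulated ground-truth displacement proxy, and a JSON ground-truth
#' sidecar recording which regions carry the shared motion-related noise.
#' Edges between two contaminated regions are the planted corrupted set.
#'
#' The default contamination level emulates a heavily moving fetus (the
#' regime the subject-level QC is designed for); regions without planted
#' contamination receive only thermal noise.
#'
#' @param dir output directory (created if needed).
#' @param n_regions number of parcel regions.
#' @param vol_dim 3D grid size of the synthetic volume.
#' @param params a \code{\link{sim_params}}; the default uses
#'   high-contamination noise ratios.
#' @param frac_corrupt fraction of regions receiving the shared noise.
#' @param voxel_noise_sd iid voxel-level noise added on top of region
#'   signals.
#' @param voxel_size voxel edge length in mm (sets the affine and hence
#'   centroid distances).
#' @param seed RNG seed; outputs are byte-identical for a fixed seed.
#' @return invisible list with file paths, the ground-truth corrupted
#'   regions/edges, \code{fd_true}, and the \code{\link{parcel_ts}} used to
#'   paint the volume.
#' @export
make_fixture_subject <- function(dir, n_regions = 12L, vol_dim = c(18L, 18L, 12L),
                                 params = sim_params(n_obs = 192, snr_phys = 0.5,
                                                     snr_scan = 3,
                                                     env_model = "burst"),
                                 frac_corrupt = 0.5, voxel_noise_sd = 0.1,
                                 voxel_size = 4, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  p <- params
  p$seed <- NULL
  kernel <- hrf_kernel(hrf_params(), dt = 1 / p$nu_g)
  nt <- p$n_obs
  n_corrupt <- max(1L, round(frac_corrupt * n_regions))
  corrupt_regions <- seq_len(n_corrupt)  # planted set

  # shared episodic physiological noise drives both the contaminated
  # regions and the ground-truth displacement proxy
  pn <- phys_noise(p$n_latent, p) / p$snr_phys
  fd_true <- abs(.block_downsample(pn, p$d, p$downsample))
  sig <- matrix(0, n_regions, nt)
  for (i in seq_len(n_regions)) {
    ev <- generate_neural_events(p)
    b <- .convolve_events(ev, kernel)
    b <- (b - mean(b)) / max(stats::sd(b), 1e-12)
    lat <- if (i %in% corrupt_regions) b + pn else b
    x <- .block_downsample(lat, p$d, p$downsample)
    x <- x + stats::rnorm(nt, sd = .rms(x) / p$snr_scan)
    sig[i, ] <- (x - mean(x)) / stats::sd(x)
  }

  # geometry: slab 1 = WM, slab 2 = CSF, remaining x-slabs cycle regions
  nx <- vol_dim[1]; ny <- vol_dim[2]; nz <- vol_dim[3]
  lab <- array(0L, vol_dim)
  wm <- array(FALSE, vol_dim); csf <- array(FALSE, vol_dim)
  wm[1, , ] <- TRUE
  csf[2, , ] <- TRUE
  region_slabs <- rep(seq_len(n_regions), length.out = nx - 2L)
  for (x in 3:nx) lab[x, , ] <- region_slabs[x - 2L]
  brain <- array(TRUE, vol_dim)

  bold <- array(0, c(vol_dim, nt))
  wm_sig <- 0.5 * colMeans(sig[corrupt_regions, , drop = FALSE])
  csf_sig <- stats::rnorm(nt, sd = 0.5)
  vox_lin <- function(mask3d) which(mask3d)
  nvx <- prod(vol_dim)
  bold_m <- matrix(0, nvx, nt)
  for (i in seq_len(n_regions)) {
    sel <- vox_lin(lab == i)
    bold_m[sel, ] <- matrix(sig[i, ], length(sel), nt, byrow = TRUE) +
      matrix(stats::rnorm(length(sel) * nt, sd = voxel_noise_sd),
             length(sel), nt)
  }
  for (nm in c("wm", "csf")) {
    msk <- if (nm == "wm") wm else csf
    base <- if (nm == "wm") wm_sig else csf_sig
    sel <- vox_lin(msk)
    bold_m[sel, ] <- matrix(base, length(sel), nt, byrow = TRUE) +
      matrix(stats::rnorm(length(sel) * nt, sd = voxel_noise_sd),
             length(sel), nt)
  }
  bold <- array(bold_m, c(vol_dim, nt))

  # motion: x-translations whose increments reproduce fd_true (t >= 2)
  tx <- cumsum(c(0, fd_true[-1]))
  mot <- cbind(tx, 0, 0, 0, 0, 0)
  fd_gt <- c(0, fd_true[-1])

  pix <- c(rep(voxel_size, 3), 1 / p$nu_o)
  img4 <- RNifti::asNifti(bold, reference = NULL)
  RNifti::pixdim(img4) <- pix
  paths <- list(bold = file.path(dir, "bold.nii"),
                labels = file.path(dir, "parcellation.nii"),
                brain_mask = file.path(dir, "mask_brain.nii"),
                wm_mask = file.path(dir, "mask_wm.nii"),
                csf_mask = file.path(dir, "mask_csf.nii"),
                motion = file.path(dir, "motion.tsv"),
                truth = file.path(dir, "ground_truth.json"))
  RNifti::writeNifti(img4, paths$bold)
  wr3 <- function(arr, path) {
    im <- RNifti::asNifti(arr * 1)
    RNifti::pixdim(im) <- rep(voxel_size, 3)
    RNifti::writeNifti(im, path)
  }
  wr3(lab, paths$labels)
  wr3(brain, paths$brain_mask)
  wr3(wm, paths$wm_mask)
  wr3(csf, paths$csf_mask)
  utils::write.table(mot, paths$motion, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  pairs <- utils::combn(n_regions, 2)
  planted <- pairs[, pairs[1, ] %in% corrupt_regions &
                     pairs[2, ] %in% corrupt_regions, drop = FALSE]
  truth <- list(corrupt_regions = corrupt_regions,
                planted_edges = apply(planted, 2, paste, collapse = "-"),
                fd_true = fd_gt, seed = seed,
                snr_phys = p$snr_phys, snr_scan = p$snr_scan,
                tr = 1 / p$nu_o, n_obs = nt)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, corrupt_regions = corrupt_regions,
                 planted_edges = planted, fd_true = fd_gt,
                 ts = parcel_ts(sig, tr = 1 / p$nu_o)))
}
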