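#' Rigid-body motion trace
#'
#' Container for per-volume rigid realignment parameters: three translations
#' in millimeters and three rotations (about the x, y and z axes).
#'
#' @param params \code{T x 6} numeric matrix, columns
#'   \code{tx, ty, tz, rx, ry, rz}.
#' @param tr repetition time in seconds.
#' @param degrees logical; \code{TRUE} if rotations are in degrees (the
#'   default convention), \code{FALSE} for radians.
#' @return an object of class \code{fetalqc_motion}.
#' @export
motion_trace <- function(params, tr, degrees = TRUE) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("motion parameters must have 6 columns")
  if (nrow(params) < 2L) stop("need at least 2 volumes")
  if (anyNA(params)) stop("motion parameters contain NA")
  if (!(tr > 0)) stop("tr must be positive")
  colnames(params) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  structure(list(params = params, tr = tr, degrees = degrees),
            class = "fetalqc_motion")
}

#' Least-squares sphere fit
#'
#' Fits a sphere to a point cloud by the algebraic (linear) least-squares
#' method: expanding \eqn{|p - c|^2 = r^2} gives a linear system in the
#' center and in \eqn{r^2 - |c|^2}. Exact on noiseless spherical data. Used
#' to estimate the fetal head radius per subject, since brain size changes
#' substantially over gestation and cannot be assumed fixed.
#'
#' @param points \code{n x 3} matrix of coordinates in mm, \code{n >= 4},
#'   not coplanar.
#' @return an object of class \code{fetalqc_sphere} with \code{center}
#'   (mm), \code{radius} (mm) and \code{rms_residual} (mm).
#' @export
fit_sphere <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be n x 3")
  if (nrow(points) < 4L) stop("need at least 4 points to determine a sphere")
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  qrA <- qr(A)
  if (qrA$rank < 4L)
    stop("degenerate point configuration (coplanar or coincident points)")
  beta <- qr.coef(qrA, b)
  center <- beta[1:3]
  r2 <- beta[4] + sum(center^2)
  if (r2 <= 0) stop("degenerate fit: nonpositive squared radius")
  radius <- sqrt(r2)
  dists <- sqrt(rowSums(sweep(points, 2, center)^2))
  structure(list(center = unname(center), radius = unname(radius),
                 rms_residual = .rms(dists - radius)),
            class = "fetalqc_sphere")
}

#' @export
print.fetalqc_sphere <- function(x, ...) {
  cat(sprintf("sphere: center (%.2f, %.2f, %.2f) mm, radius %.2f mm, rms residual %.3g mm\n",
              x$center[1], x$center[2], x$center[3], x$radius, x$rms_residual))
  invisible(x)
}

# rotation matrix for extrinsic x-y-z Euler angles (radians): R = Rz Ry Rx
.euler_xyz <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Deterministic quasi-uniform points on a sphere surface
#'
#' Fibonacci lattice on the sphere of the given center and radius; used as
#' the evaluation points for surface-mode framewise displacement.
#'
#' @param sphere a \code{\link{fit_sphere}} result (or a list with
#'   \code{center} and \code{radius}).
#' @param n number of surface points.
#' @return \code{n x 3} matrix of coordinates in mm.
#' @export
sphere_surface_points <- function(sphere, n = 256L) {
  i <- seq_len(n) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n
  rad <- sqrt(pmax(0, 1 - z^2))
  theta <- golden * (seq_len(n) - 1)
  p <- cbind(rad * cos(theta), rad * sin(theta), z) * sphere$radius
  sweep(p, 2, sphere$center, "+")
}

#' Framewise displacement from rigid-body realignment parameters
#'
#' For each consecutive volume pair the two rigid transforms are applied to
#' a set of reference points and the root-mean-square displacement between
#' the two mapped positions is returned (equivalently, the relative
#' transform between the volumes applied to the points). Reference points
#' are either the surface of a fitted head sphere (default, matching the
#' per-subject sphere-fit convention) or explicit brain-voxel coordinates.
#' Rotations are applied about \code{center} (the sphere center when a
#' sphere is supplied).
#'
#' A Power-style summary (\code{mode = "power"}) is also available:
#' the L1 norm of the translation increments plus \code{radius} times the
#' L1 norm of the rotation increments in radians.
#'
#' @param trace a \code{\link{motion_trace}}.
#' @param sphere optional \code{\link{fit_sphere}} result; used to generate
#'   surface points when \code{coords} is not supplied.
#' @param coords optional \code{n x 3} matrix of brain-voxel coordinates in
#'   mm; overrides the sphere surface.
#' @param center rotation center (3-vector, mm); defaults to the sphere
#'   center if available, else the centroid of \code{coords}.
#' @param n_surface number of sphere-surface evaluation points.
#' @param mode \code{"rms"} (default) or \code{"power"}.
#' @param radius radius for \code{mode = "power"}; defaults to the sphere
#'   radius.
#' @return numeric vector of length \code{T} (a leading 0 is prepended so
#'   the series aligns with volumes), in mm.
#' @examples
#' tr <- motion_trace(cbind(c(0, 1), 0, 0, 0, 0, 0), tr = 3)
#' fd_series(tr, sphere = list(center = c(0, 0, 0), radius = 50))  # 0, 1
#' @export
fd_series <- function(trace, sphere = NULL, coords = NULL, center = NULL,
                      n_surface = 256L, mode = c("rms", "power"),
                      radius = NULL) {
  stopifnot(inherits(trace, "fetalqc_motion"))
  mode <- match.arg(mode)
  m <- trace$params
  rot <- m[, 4:6, drop = FALSE]
  if (trace$degrees) {
    if (any(abs(rot) > 180))
      warning("rotations exceed 180 degrees; check units")
    rot <- rot * pi / 180
  } else if (any(abs(rot) > pi)) {
    warning("rotations exceed pi radians; check units")
  }
  n_vol <- nrow(m)
  if (mode == "power") {
    if (is.null(radius)) {
      if (is.null(sphere)) stop("mode 'power' needs a radius or a sphere")
      radius <- sphere$radius
    }
    dfd <- rowSums(abs(diff(m[, 1:3, drop = FALSE]))) +
      radius * rowSums(abs(diff(rot)))
    return(c(0, dfd))
  }
  if (is.null(coords)) {
    if (is.null(sphere))
      stop("supply either voxel coordinates or a fitted sphere")
    coords <- sphere_surface_points(sphere, n_surface)
  }
  coords <- as.matrix(coords)
  if (is.null(center)) {
    center <- if (!is.null(sphere)) sphere$center else colMeans(coords)
  }
  pc <- sweep(coords, 2, center)  # points relative to rotation center
  pos <- function(t) {
    R <- .euler_xyz(rot[t, 1], rot[t, 2], rot[t, 3])
    sweep(pc %*% t(R), 2, center + m[t, 1:3], "+")
  }
  prev <- pos(1)
  fd <- numeric(n_vol)
  for (t in 2:n_vol) {
    cur <- pos(t)
    fd[t] <- sqrt(mean(rowSums((cur - prev)^2)))
    prev <- cur
  }
  fd
}

#' Censoring mask
#'
#' @param keep logical vector, one element per volume.
#' @param reason character vector of per-volume tags (\code{"none"},
#'   \code{"fd"}, \code{"intensity"}, or combinations).
#' @return an object of class \code{fetalqc_censor}.
#' @export
censor_mask <- function(keep, reason = NULL) {
  keep <- as.logical(keep)
  if (is.null(reason)) reason <- ifelse(keep, "none", "flagged")
  if (length(reason) != length(keep))
    stop("keep and reason must have equal length")
  structure(list(keep = keep, reason = reason), class = "fetalqc_censor")
}

#' @export
print.fetalqc_censor <- function(x, ...) {
  cat(sprintf("censor mask: %d/%d volumes kept\n", sum(x$keep), length(x$keep)))
  invisible(x)
}

#' Intensity-outlier volume censoring
#'
#' Within each volume, a voxel is flagged when its intensity deviates from
#' the bulk of the other in-mask voxels by more than \code{sd_thresh}
#' standard deviations. The center and spread are estimated robustly
#' (median and normalized MAD) so that the outliers themselves cannot mask
#' the detection when contamination is substantial. A volume is censored
#' when more than \code{frac_thresh} of in-mask voxels are flagged.
#'
#' @param bold 4D numeric array (x, y, z, time).
#' @param brain_mask 3D logical (or 0/1) array.
#' @param sd_thresh flagging threshold in standard deviations.
#' @param frac_thresh volume-censoring threshold on the flagged fraction.
#' @return a \code{\link{censor_mask}}.
#' @export
intensity_outlier_flags <- function(bold, brain_mask, sd_thresh = 3,
                                    frac_thresh = 0.05) {
  d <- dim(bold)
  if (length(d) != 4L) stop("bold must be a 4D array")
  mask <- as.logical(brain_mask)
  if (!any(mask)) stop("brain mask is empty")
  nt <- d[4]
  if (sum(mask) < 3L) stop("brain mask must contain at least 3 voxels")
  vox <- matrix(bold, nrow = prod(d[1:3]))[mask, , drop = FALSE]
  keep <- logical(nt)
  for (t in seq_len(nt)) {
    v <- vox[, t]
    ctr <- stats::median(v)
    spread <- stats::mad(v)  # 1.4826 * MAD, consistent for a normal bulk
    flagged <- spread > 0 & abs(v - ctr) > sd_thresh * spread
    keep[t] <- mean(flagged) <= frac_thresh
  }
  censor_mask(keep, ifelse(keep, "none", "intensity"))
}

#' FD-threshold volume censoring
#'
#' @param fd framewise displacement series (mm), one value per volume.
#' @param threshold censoring threshold in mm. The appropriate value is
#'   dataset dependent; 0.5 mm is the package default and is recorded in
#'   outputs.
#' @return a \code{\link{censor_mask}}.
#' @export
fd_censor_flags <- function(fd, threshold = 0.5) {
  if (!(threshold > 0)) stop("threshold must be positive")
  keep <- fd <= threshold
  censor_mask(keep, ifelse(keep, "none", "fd"))
}

#' Combine censoring masks by logical OR of their exclusions
#'
#' @param ... \code{\link{censor_mask}} objects of equal length.
#' @return a \code{\link{censor_mask}}.
#' @export
combine_censor <- function(...) {
  masks <- list(...)
  stopifnot(length(masks) >= 1L)
  keep <- Reduce(`&`, lapply(masks, `[[`, "keep"))
  reason <- rep("none", length(keep))
  for (m in masks) {
    bad <- !m$keep
    reason[bad] <- ifelse(reason[bad] == "none", m$reason[bad],
                          paste(reason[bad], m$reason[bad], sep = "+"))
  }
  censor_mask(keep, reason)
}
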