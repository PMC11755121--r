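# ---- strategy registry -----------------------------------------------------

# Each strategy is declared as a list of component tags; users can register
# additional combinations at run time, so any published strategy table can
# be declared without code changes.
.strategy_registry <- new.env(parent = emptyenv())

.default_strategies <- list(
  "none"               = character(0),
  "6HMP"               = "hmp6",
  "24HMP"              = "hmp24",
  "2Phys"              = "phys2",
  "8Phys"              = "phys8",
  "GSR"                = "gsr1",
  "2GSR"               = "gsr2",
  "4GSR"               = "gsr4",
  "aCompCor"           = "acompcor",
  "aCompCor+6HMP"      = c("acompcor", "hmp6"),
  "tCompCor"           = "tcompcor",
  "localWM"            = "localwm",
  "4GSR+8Phys+24HMP"   = c("gsr4", "phys8", "hmp24")
)

.init_registry <- function() {
  if (length(ls(.strategy_registry)) == 0L)
    for (nm in names(.default_strategies))
      assign(nm, .default_strategies[[nm]], envir = .strategy_registry)
}

#' List or extend the nuisance-strategy registry
#'
#' \code{list_strategies} returns the registered strategy names.
#' \code{register_strategy} declares a new strategy as a combination of the
#' component tags \code{hmp6, hmp24, phys2, phys8, gsr1, gsr2, gsr4,
#' acompcor, tcompcor, localwm}.
#'
#' @return \code{list_strategies}: character vector of names.
#' @export
list_strategies <- function() {
  .init_registry()
  sort(ls(.strategy_registry))
}

#' @rdname list_strategies
#' @param name strategy name.
#' @param components character vector of component tags.
#' @export
register_strategy <- function(name, components) {
  .init_registry()
  known <- c("hmp6", "hmp24", "phys2", "phys8", "gsr1", "gsr2", "gsr4",
             "acompcor", "tcompcor", "localwm")
  bad <- setdiff(components, known)
  if (length(bad))
    stop("unknown components: ", paste(bad, collapse = ", "))
  assign(name, components, envir = .strategy_registry)
  invisible(name)
}

# backward difference with leading 0, column-wise
.bdiff <- function(m) {
  m <- as.matrix(m)
  rbind(0, diff(m))
}

# voxel time series matrix (voxels x T) for a 3D logical mask
.mask_ts <- function(bold, mask) {
  d <- dim(bold)
  matrix(bold, nrow = prod(d[1:3]))[as.logical(mask), , drop = FALSE]
}

# top-k principal component time courses of a voxels x T matrix
.pc_timecourses <- function(vox, k) {
  X <- t(vox)                      # T x voxels
  X <- scale(X, center = TRUE, scale = FALSE)
  X[is.nan(X)] <- 0
  sv <- svd(X, nu = min(k, nrow(X) - 1L), nv = 0)
  k <- min(k, ncol(sv$u))
  sv$u[, seq_len(k), drop = FALSE]
}

#' Build a nuisance design matrix
#'
#' Constructs the regressor matrix for a registered denoising strategy.
#' Component definitions: \code{6HMP} = the six realignment parameters;
#' \code{24HMP} = the six parameters, their backward-difference temporal
#' derivatives, and the squares of both; \code{2Phys}/\code{8Phys} = WM and
#' CSF mean signals (plus derivatives and squares for \code{8Phys});
#' \code{GSR}/\code{2GSR}/\code{4GSR} = mean in-brain signal and its
#' expansions (derivative, square, squared derivative); \code{aCompCor} =
#' top principal components of the WM+CSF voxel time series;
#' \code{tCompCor} = top principal components of the highest-temporal-
#' variance in-brain voxels; \code{localWM} = per-region mean of
#' white-matter voxels within a given radius of the region centroid
#' (region-specific; stored separately and combined per region by
#' \code{\link{regress_out}}).
#'
#' @param strategy a registered strategy name (see
#'   \code{\link{list_strategies}}).
#' @param motion a \code{\link{motion_trace}} (required for HMP
#'   components).
#' @param bold 4D array (required for tissue, GSR and CompCor components).
#' @param masks named list with logical 3D arrays \code{brain}, \code{wm},
#'   \code{csf} as needed.
#' @param n_compcor number of aCompCor/tCompCor components.
#' @param tcompcor_frac fraction of highest-temporal-variance voxels used
#'   by tCompCor.
#' @param parcellation 3D integer label array (localWM only).
#' @param affine 4x4 voxel-to-world affine in mm (localWM only); defaults
#'   to identity spacing.
#' @param localwm_radius radius in mm around each region centroid within
#'   which white-matter voxels are averaged (localWM only).
#' @return an object of class \code{fetalqc_design}: list with
#'   \code{regressors} (\code{T x k}), \code{names}, \code{strategy}, and
#'   optionally \code{per_region} (\code{T x n_regions} localWM matrix).
#' @export
build_design <- function(strategy, motion = NULL, bold = NULL,
                         masks = list(), n_compcor = 5, tcompcor_frac = 0.02,
                         parcellation = NULL, affine = NULL,
                         localwm_radius = 25) {
  .init_registry()
  if (!exists(strategy, envir = .strategy_registry))
    stop("unknown strategy '", strategy, "'; registered strategies: ",
         paste(list_strategies(), collapse = ", "))
  comps <- get(strategy, envir = .strategy_registry)
  nt <- NULL
  if (!is.null(motion)) nt <- nrow(motion$params)
  if (!is.null(bold)) nt <- dim(bold)[4]
  cols <- list()
  per_region <- NULL
  need_mask <- function(nm) {
    m <- masks[[nm]]
    if (is.null(m) || !any(m > 0))
      stop("strategy '", strategy, "' needs a nonempty '", nm, "' mask")
    storage.mode(m) <- "logical"  # keep array dims
    m
  }
  for (comp in comps) {
    switch(comp,
      hmp6 = {
        if (is.null(motion)) stop("strategy needs motion parameters")
        cols[[length(cols) + 1L]] <- motion$params
      },
      hmp24 = {
        if (is.null(motion)) stop("strategy needs motion parameters")
        m <- motion$params
        dm <- .bdiff(m)
        x <- cbind(m, dm, m^2, dm^2)
        colnames(x) <- c(colnames(m), paste0("d_", colnames(m)),
                         paste0(colnames(m), "_sq"),
                         paste0("d_", colnames(m), "_sq"))
        cols[[length(cols) + 1L]] <- x
      },
      phys2 = {
        wm <- colMeans(.mask_ts(bold, need_mask("wm")))
        csf <- colMeans(.mask_ts(bold, need_mask("csf")))
        x <- cbind(wm = wm, csf = csf)
        cols[[length(cols) + 1L]] <- x
      },
      phys8 = {
        wm <- colMeans(.mask_ts(bold, need_mask("wm")))
        csf <- colMeans(.mask_ts(bold, need_mask("csf")))
        base <- cbind(wm = wm, csf = csf)
        d <- .bdiff(base)
        x <- cbind(base, d, base^2, d^2)
        colnames(x) <- c("wm", "csf", "d_wm", "d_csf", "wm_sq", "csf_sq",
                         "d_wm_sq", "d_csf_sq")
        cols[[length(cols) + 1L]] <- x
      },
      gsr1 = ,
      gsr2 = ,
      gsr4 = {
        gs <- colMeans(.mask_ts(bold, need_mask("brain")))
        dgs <- .bdiff(matrix(gs))[, 1]
        x <- switch(comp,
          gsr1 = cbind(gs = gs),
          gsr2 = cbind(gs = gs, d_gs = dgs),
          gsr4 = cbind(gs = gs, d_gs = dgs, gs_sq = gs^2, d_gs_sq = dgs^2))
        cols[[length(cols) + 1L]] <- x
      },
      acompcor = {
        vox <- rbind(.mask_ts(bold, need_mask("wm")),
                     .mask_ts(bold, need_mask("csf")))
        x <- .pc_timecourses(vox, n_compcor)
        colnames(x) <- paste0("acompcor", seq_len(ncol(x)))
        cols[[length(cols) + 1L]] <- x
      },
      tcompcor = {
        vox <- .mask_ts(bold, need_mask("brain"))
        v <- apply(vox, 1, stats::sd)
        cut <- stats::quantile(v, 1 - tcompcor_frac)
        sel <- vox[v >= cut, , drop = FALSE]
        x <- .pc_timecourses(sel, n_compcor)
        colnames(x) <- paste0("tcompcor", seq_len(ncol(x)))
        cols[[length(cols) + 1L]] <- x
      },
      localwm = {
        if (is.null(parcellation)) stop("localWM needs a parcellation")
        per_region <- .localwm_matrix(bold, need_mask("wm"), parcellation,
                                      affine, localwm_radius)
      })
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = if (is.null(nt)) 0L else nt, ncol = 0L)
  if (ncol(X) > 0) {
    const0 <- apply(X, 2, function(v) all(v == 0))
    if (any(const0)) X <- X[, !const0, drop = FALSE]
  }
  structure(list(regressors = X,
                 names = colnames(X),
                 strategy = strategy,
                 rank = if (ncol(X)) qr(X)$rank else 0L,
                 per_region = per_region),
            class = "fetalqc_design")
}

# T x n_regions matrix of local eroded-WM mean signals
.localwm_matrix <- function(bold, wm, parcellation, affine, radius) {
  d <- dim(bold)
  if (is.null(affine)) affine <- diag(4)
  idx <- which(wm, arr.ind = TRUE) - 1  # 0-based voxel indices
  wm_mm <- cbind(idx, 1) %*% t(affine)
  wm_mm <- wm_mm[, 1:3, drop = FALSE]
  vox <- .mask_ts(bold, wm)
  labs <- sort(unique(as.vector(parcellation[parcellation > 0])))
  out <- matrix(0, d[4], length(labs))
  colnames(out) <- paste0("localwm_", labs)
  for (i in seq_along(labs)) {
    ridx <- which(parcellation == labs[i], arr.ind = TRUE) - 1
    cen <- colMeans(cbind(ridx, 1) %*% t(affine))[1:3]
    near <- sqrt(colSums((t(wm_mm) - cen)^2)) <= radius
    if (!any(near)) next
    out[, i] <- colMeans(vox[near, , drop = FALSE])
  }
  out
}

#' @export
print.fetalqc_design <- function(x, ...) {
  cat(sprintf("fetalqc design '%s': %d regressors (rank %d)%s\n", x$strategy,
              ncol(x$regressors), x$rank,
              if (!is.null(x$per_region)) sprintf(" + %d region-specific localWM columns",
                                                  ncol(x$per_region)) else ""))
  invisible(x)
}

#' Remove nuisance regressors by ordinary least squares
#'
#' Projects each time series onto the orthogonal complement of the design
#' columns (plus an intercept), fitting on retained frames only when a
#' censor mask is supplied. When the design carries region-specific localWM
#' columns, each region's series additionally gets its own local regressor.
#'
#' @param ts numeric vector, \code{regions x T} matrix, or
#'   \code{\link{parcel_ts}} object.
#' @param design a \code{\link{build_design}} result (or plain matrix).
#' @param censor optional \code{\link{censor_mask}}; censored frames are
#'   excluded from the fit and dropped from the output.
#' @return residual series with the same organization as the input (minus
#'   censored frames when censoring is active); the retained frame indices
#'   are attached as attribute \code{"frames"}.
#' @export
regress_out <- function(ts, design, censor = NULL) {
  is_pts <- inherits(ts, "fetalqc_parcel_ts")
  X0 <- if (inherits(design, "fetalqc_design")) design$regressors else as.matrix(design)
  per_region <- if (inherits(design, "fetalqc_design")) design$per_region else NULL
  m <- if (is_pts) ts$data else if (is.matrix(ts)) ts else matrix(ts, nrow = 1)
  nt <- ncol(m)
  if (nrow(X0) == 0L && ncol(X0) == 0L) X0 <- matrix(numeric(0), nt, 0)
  if (nrow(X0) != nt) stop("design rows must match the number of timepoints")
  keep <- if (is.null(censor)) rep(TRUE, nt) else censor$keep
  if (length(keep) != nt) stop("censor mask length must match timepoints")
  nkeep <- sum(keep)
  fit_resid <- function(y, X) {
    if (ncol(X) > 0) {
      # constant columns are redundant with the intercept
      const <- apply(X, 2, function(v) stats::sd(v) == 0)
      X <- X[, !const, drop = FALSE]
    }
    X <- cbind(1, X)
    if (ncol(X) >= nkeep)
      stop(sprintf("more regressors (%d) than retained frames (%d)",
                   ncol(X) - 1L, nkeep))
    qrX <- qr(X[keep, , drop = FALSE])
    if (qrX$rank < ncol(X)) {
      warning("rank-deficient design; fitting via pseudoinverse")
      Xk <- X[keep, , drop = FALSE]
      beta <- .pinv(Xk) %*% y[keep]
    } else {
      beta <- qr.coef(qrX, y[keep])
      beta[is.na(beta)] <- 0
    }
    y[keep] - as.vector(X[keep, , drop = FALSE] %*% beta)
  }
  out <- matrix(0, nrow(m), nkeep)
  for (i in seq_len(nrow(m))) {
    Xi <- X0
    if (!is.null(per_region) && i <= ncol(per_region))
      Xi <- cbind(X0, per_region[, i])
    out[i, ] <- fit_resid(m[i, ], Xi)
  }
  rownames(out) <- rownames(m)
  attr(out, "frames") <- which(keep)
  if (is_pts) {
    res <- ts
    res$data <- out
    attr(res, "frames") <- which(keep)
    return(res)
  }
  if (is.matrix(ts)) out else structure(out[1, ], frames = which(keep))
}

.pinv <- function(X, tol = 1e-10) {
  sv <- svd(X)
  pos <- sv$d > tol * sv$d[1]
  sv$v[, pos, drop = FALSE] %*% ((1 / sv$d[pos]) * t(sv$u[, pos, drop = FALSE]))
}

#' Temporal high-pass filter
#'
#' Demeans, removes a linear trend, and projects out a discrete-cosine
#' basis spanning frequencies below \code{cutoff}. Deterministic and
#' identical for any series of the same length.
#'
#' @param ts numeric vector or \code{regions x T} matrix.
#' @param cutoff high-pass cutoff frequency in Hz.
#' @param tr repetition time in seconds.
#' @return filtered series with the same shape.
#' @export
highpass <- function(ts, cutoff = 0.008, tr) {
  m <- if (is.matrix(ts)) ts else matrix(ts, nrow = 1)
  nt <- ncol(m)
  if (nt < 3L) stop("series must have at least 3 samples")
  if (!(cutoff < 1 / (2 * tr))) stop("cutoff must be below the Nyquist frequency")
  tt <- seq_len(nt)
  K <- floor(2 * nt * tr * cutoff)
  basis <- cbind(1, tt)
  if (K >= 1) {
    dct <- sapply(seq_len(K), function(k) cos(pi * (2 * (tt - 1) + 1) * k / (2 * nt)))
    basis <- cbind(basis, dct)
  }
  Q <- qr.Q(qr(basis))
  res <- m - (m %*% Q) %*% t(Q)
  if (is.matrix(ts)) res else res[1, ]
}
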