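#' Sliding-window specification
#'
#' @param width_tr window length in TRs (volumes); the package default of 46
#'   TR corresponds to 138 s at a 3-s TR.
#' @param stride window step in TRs.
#' @return an object of class \code{fetalqc_window}.
#' @export
window_spec <- function(width_tr = 46L, stride = 1L) {
  if (!.is_count(width_tr) || width_tr < 3L)
    stop("width_tr must be an integer >= 3")
  if (!.is_count(stride)) stop("stride must be a positive integer")
  structure(list(width_tr = as.integer(width_tr), stride = as.integer(stride)),
            class = "fetalqc_window")
}

.window_starts <- function(n, win) {
  if (win$width_tr > n) stop("window is longer than the series")
  seq.int(1L, n - win$width_tr + 1L, by = win$stride)
}

#' Number of window positions for a series length
#'
#' @param n series length in TRs.
#' @param win a \code{\link{window_spec}}.
#' @return integer window count L.
#' @export
n_windows <- function(n, win = window_spec()) length(.window_starts(n, win))

#' Sliding-window correlation (time-varying functional connectivity)
#'
#' Pearson correlation of two series restricted to each window position,
#' computed from running sums. Windows with zero variance in either series
#' yield \code{NA} (counted in attribute \code{"n_undefined"}).
#'
#' @param x,y numeric series of equal length T.
#' @param win a \code{\link{window_spec}}.
#' @return numeric vector of length \code{L = floor((T - width)/stride) + 1}.
#' @export
sliding_fc <- function(x, y, win = window_spec()) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  starts <- .window_starts(n, win)
  w <- win$width_tr
  # centring globally improves conditioning and leaves windowed r unchanged
  x <- x - mean(x); y <- y - mean(y)
  cx <- c(0, cumsum(x));  cy <- c(0, cumsum(y))
  cxx <- c(0, cumsum(x^2)); cyy <- c(0, cumsum(y^2)); cxy <- c(0, cumsum(x * y))
  e <- starts + w - 1L
  sx <- cx[e + 1L] - cx[starts];   sy <- cy[e + 1L] - cy[starts]
  sxx <- cxx[e + 1L] - cxx[starts]; syy <- cyy[e + 1L] - cyy[starts]
  sxy <- cxy[e + 1L] - cxy[starts]
  vx <- sxx - sx^2 / w
  vy <- syy - sy^2 / w
  cov <- sxy - sx * sy / w
  cc <- rep(NA_real_, length(starts))
  ok <- vx > 0 & vy > 0
  cc[ok] <- cov[ok] / sqrt(vx[ok] * vy[ok])
  cc[ok] <- pmin(1, pmax(-1, cc[ok]))
  attr(cc, "n_undefined") <- sum(!ok)
  cc
}

#' Sliding-window mean (time-varying framewise displacement)
#'
#' Window means of an FD series over the same windows as
#' \code{\link{sliding_fc}}.
#'
#' @param fd numeric series of length T.
#' @param win a \code{\link{window_spec}}.
#' @return numeric vector of length L.
#' @export
sliding_fd <- function(fd, win = window_spec()) {
  starts <- .window_starts(length(fd), win)
  w <- win$width_tr
  cf <- c(0, cumsum(fd))
  (cf[starts + w] - cf[starts]) / w
}

#' Parametric test of the time-varying FC-FD association
#'
#' Pearson correlation r between the windowed FC series and the
#' window-averaged FD series, with the Student-t statistic
#' \eqn{t = r \sqrt{df} / \sqrt{1 - r^2}}, \eqn{df = L - 2} where L is the
#' number of complete window pairs, and a two-sided p-value. The t
#' reference distribution assumes serially independent samples; with
#' overlapping windows the windowed series are strongly autocorrelated and
#' this test is anticonservative, so the surrogate null
#' (\code{\link{surrogate_null}}) is preferred for real data.
#'
#' @param cc_series windowed FC series.
#' @param fd_series_w window-averaged FD series of equal length.
#' @return list with \code{r}, \code{t_stat}, \code{df}, \code{p_param},
#'   and \code{n_used} (complete pairs entering the correlation).
#' @export
fcfd_test <- function(cc_series, fd_series_w) {
  if (length(cc_series) != length(fd_series_w))
    stop("series must have equal length")
  ok <- is.finite(cc_series) & is.finite(fd_series_w)
  L <- sum(ok)
  if (L < 4L) stop("need at least 4 complete window pairs")
  r <- .safe_cor(cc_series[ok], fd_series_w[ok])
  df <- L - 2L
  if (is.na(r))
    return(list(r = NA_real_, t_stat = NA_real_, df = df, p_param = NA_real_,
                n_used = L))
  if (abs(r) >= 1 - 1e-12) {
    r <- sign(r)
    return(list(r = r, t_stat = sign(r) * Inf, df = df, p_param = 0,
                n_used = L))
  }
  t_stat <- r * sqrt(df) / sqrt(1 - r^2)
  list(r = r, t_stat = t_stat, df = df,
       p_param = 2 * stats::pt(-abs(t_stat), df), n_used = L)
}

# matrix of phase-randomized surrogates preserving the amplitude spectrum;
# columns are surrogates, Hermitian-symmetric phases give real output
.phase_surrogates <- function(x, n_surr) {
  n <- length(x)
  A <- Mod(stats::fft(x))
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  ph <- matrix(0, n, n_surr)
  if (half >= 1) {
    ph[2:(half + 1), ] <- matrix(stats::runif(half * n_surr, 0, 2 * pi),
                                 half, n_surr)
    ph[n:(n - half + 1), ] <- -ph[2:(half + 1), , drop = FALSE]
  }
  Re(stats::mvfft(A * exp(1i * ph), inverse = TRUE)) / n
}

# window means of every column of a matrix
.sliding_fd_mat <- function(m, win) {
  starts <- .window_starts(nrow(m), win)
  w <- win$width_tr
  cf <- rbind(0, apply(m, 2, cumsum))
  (cf[starts + w, , drop = FALSE] - cf[starts, , drop = FALSE]) / w
}

#' Surrogate null distribution of the FC-FD correlation
#'
#' Generates phase-randomization surrogates of the FD series: the amplitude
#' spectrum of the discrete Fourier transform is kept exactly and the
#' phases are drawn uniformly (Hermitian-symmetric, so surrogates are
#' real). Each surrogate FD is pushed through the same pipeline -- window
#' averaging, then correlation with the observed windowed-FC series -- so
#' the null inherits the serial dependence of the windowed statistics. The
#' two-sided empirical p-value uses the add-one correction
#' \eqn{p = (1 + \#\{|r_0| \ge |r|\}) / (n_{surr} + 1)}.
#'
#' @param fd raw FD series (length T).
#' @param cc_source observed windowed-FC series (length L).
#' @param win a \code{\link{window_spec}}.
#' @param n_surrogates number of surrogates; fewer than 100 triggers a
#'   warning (unstable tail).
#' @param seed optional RNG seed.
#' @param randomize \code{"fd"} (default: condition on the observed FC) or
#'   \code{"both"} (also phase-randomize the FC series).
#' @return list with \code{r_obs}, \code{r_null} (length
#'   \code{n_surrogates}), and \code{p_surr}.
#' @export
surrogate_null <- function(fd, cc_source, win = window_spec(),
                           n_surrogates = 1000L, seed = NULL,
                           randomize = c("fd", "both")) {
  randomize <- match.arg(randomize)
  if (n_surrogates < 100L)
    warning("fewer than 100 surrogates gives an unstable null tail")
  if (!is.null(seed)) set.seed(seed)
  ok <- is.finite(cc_source)
  fdw_obs <- sliding_fd(fd, win)
  r_obs <- .safe_cor(cc_source[ok], fdw_obs[ok])
  S <- .phase_surrogates(fd, n_surrogates)
  Sw <- .sliding_fd_mat(S, win)
  if (randomize == "both") {
    C <- .phase_surrogates(cc_source[ok], n_surrogates)
    r_null <- vapply(seq_len(n_surrogates),
                     function(s) .safe_cor(C[, s], Sw[ok, s]),
                     numeric(1))
  } else {
    r_null <- suppressWarnings(
      as.vector(stats::cor(cc_source[ok], Sw[ok, , drop = FALSE])))
  }
  p <- (1 + sum(abs(r_null) >= abs(r_obs), na.rm = TRUE)) / (n_surrogates + 1)
  list(r_obs = r_obs, r_null = r_null, p_surr = p)
}

#' Parcel time-series container
#'
#' @param data \code{n_regions x T} numeric matrix of region-mean BOLD
#'   signals.
#' @param region_ids region labels.
#' @param centroids \code{n_regions x 3} region centroids in mm (same space
#'   as the FD computation).
#' @param tr repetition time in seconds.
#' @return an object of class \code{fetalqc_parcel_ts}.
#' @export
parcel_ts <- function(data, region_ids = NULL, centroids = NULL, tr = 3) {
  data <- as.matrix(data)
  if (is.null(region_ids)) region_ids <- rownames(data)
  if (is.null(region_ids)) region_ids <- as.character(seq_len(nrow(data)))
  if (!is.null(centroids)) {
    centroids <- as.matrix(centroids)
    if (nrow(centroids) != nrow(data) || ncol(centroids) != 3L)
      stop("centroids must be n_regions x 3")
  }
  structure(list(data = data, region_ids = as.character(region_ids),
                 centroids = centroids, tr = tr),
            class = "fetalqc_parcel_ts")
}

#' @export
print.fetalqc_parcel_ts <- function(x, ...) {
  cat(sprintf("fetalqc parcel time series: %d regions x %d timepoints (TR %g s)%s\n",
              nrow(x$data), ncol(x$data), x$tr,
              if (is.null(x$centroids)) ", no centroids" else ""))
  invisible(x)
}

#' Subject-level QC: flag motion-corrupted connections
#'
#' For every region pair, computes the time-varying FC over sliding
#' windows, the window-averaged FD, and their correlation r, then tests r
#' against the chosen null. An edge is corrupted when its (optionally
#' FDR-adjusted) p-value is below \code{alpha}. The report includes the
#' fraction of corrupted edges, the median |r|, per-region counts of
#' significant incident edges (the uncertainty map), and the Spearman
#' correlation between r and inter-centroid Euclidean distance.
#'
#' All edges share one set of FD surrogates (FD randomization does not
#' depend on the edge), which makes the surrogate mode tractable for
#' thousands of edges.
#'
#' @param ts a \code{\link{parcel_ts}} object.
#' @param fd framewise displacement series, one value per volume.
#' @param win a \code{\link{window_spec}}.
#' @param alpha significance level.
#' @param null_mode \code{"surrogate"} (default; calibrated under the
#'   serial dependence of windowed series) or \code{"parametric"} (Student
#'   t, appropriate for serially independent inputs).
#' @param correction \code{"none"} (default) or \code{"fdr"}
#'   (Benjamini-Hochberg).
#' @param n_surrogates surrogates for the null (surrogate mode).
#' @param seed optional RNG seed for the surrogates.
#' @return an object of class \code{fetalqc_subject_qc}: list with
#'   \code{edges} (data frame: region_i, region_j, distance_mm, r, t_stat,
#'   p, corrupted), \code{frac_corrupted}, \code{median_abs_r},
#'   \code{region_counts}, \code{distance_dependence} (Spearman rho and p),
#'   \code{excluded_regions}, \code{fd_degenerate}, plus the analysis
#'   settings.
#' @export
assess_subject <- function(ts, fd, win = window_spec(), alpha = 0.05,
                           null_mode = c("surrogate", "parametric"),
                           correction = c("none", "fdr"),
                           n_surrogates = 1000L, seed = NULL) {
  null_mode <- match.arg(null_mode)
  correction <- match.arg(correction)
  stopifnot(inherits(ts, "fetalqc_parcel_ts"))
  nt <- ncol(ts$data)
  if (length(fd) != nt)
    stop("fd length must equal the number of timepoints")
  sds <- apply(ts$data, 1, stats::sd)
  excluded <- ts$region_ids[sds == 0 | !is.finite(sds)]
  use <- which(sds > 0 & is.finite(sds))
  ids <- ts$region_ids[use]
  nr <- length(use)
  if (nr < 2L) stop("fewer than 2 usable regions")
  pairs <- utils::combn(nr, 2)
  ne <- ncol(pairs)
  fd_degenerate <- stats::sd(fd) == 0
  starts_n <- n_windows(nt, win)

  dist_mm <- rep(NA_real_, ne)
  if (!is.null(ts$centroids)) {
    cen <- ts$centroids[use, , drop = FALSE]
    dist_mm <- sqrt(colSums((t(cen[pairs[1, ], ]) - t(cen[pairs[2, ], ]))^2))
  }

  r <- t_stat <- p <- rep(NA_real_, ne)
  if (!fd_degenerate) {
    fdw <- sliding_fd(fd, win)
    cc_mat <- matrix(NA_real_, starts_n, ne)
    for (e in seq_len(ne)) {
      cc_mat[, e] <- sliding_fc(ts$data[use[pairs[1, e]], ],
                                ts$data[use[pairs[2, e]], ], win)
    }
    for (e in seq_len(ne)) {
      ok <- is.finite(cc_mat[, e])
      if (sum(ok) >= 4L) {
        ft <- fcfd_test(cc_mat[ok, e], fdw[ok])
        r[e] <- ft$r; t_stat[e] <- ft$t_stat
        if (null_mode == "parametric") p[e] <- ft$p_param
      }
    }
    if (null_mode == "surrogate") {
      if (!is.null(seed)) set.seed(seed)
      S <- .phase_surrogates(fd, n_surrogates)
      Sw <- .sliding_fd_mat(S, win)
      ok_rows <- rowSums(!is.finite(cc_mat)) == 0
      # complete-window case: one big correlation; rows edges, cols surrogates
      Rn <- suppressWarnings(stats::cor(cc_mat[ok_rows, , drop = FALSE],
                                        Sw[ok_rows, , drop = FALSE]))
      exceed <- rowSums(abs(Rn) >= abs(r), na.rm = TRUE)
      p <- (1 + exceed) / (n_surrogates + 1)
      p[is.na(r)] <- NA_real_
    }
  }
  p_adj <- if (correction == "fdr") stats::p.adjust(p, "BH") else p
  corrupted <- !is.na(p_adj) & p_adj < alpha
  edges <- data.frame(region_i = ids[pairs[1, ]], region_j = ids[pairs[2, ]],
                      distance_mm = dist_mm, r = r, t_stat = t_stat, p = p,
                      p_adj = p_adj, corrupted = corrupted,
                      stringsAsFactors = FALSE)
  counts <- stats::setNames(numeric(nr), ids)
  if (any(corrupted)) {
    tab <- table(c(edges$region_i[corrupted], edges$region_j[corrupted]))
    counts[names(tab)] <- as.numeric(tab)
  }
  dd <- list(rho = NA_real_, p = NA_real_)
  okd <- is.finite(edges$r) & is.finite(edges$distance_mm)
  if (sum(okd) >= 4L && stats::sd(edges$distance_mm[okd]) > 0) {
    ct <- suppressWarnings(stats::cor.test(edges$r[okd], edges$distance_mm[okd],
                                           method = "spearman", exact = FALSE))
    dd <- list(rho = unname(ct$estimate), p = ct$p.value)
  }
  structure(list(
    edges = edges,
    frac_corrupted = if (fd_degenerate) NA_real_ else mean(corrupted[!is.na(p_adj)]),
    median_abs_r = stats::median(abs(edges$r), na.rm = TRUE),
    region_counts = counts,
    distance_dependence = dd,
    excluded_regions = excluded,
    fd_degenerate = fd_degenerate,
    alpha = alpha, correction = correction, null_mode = null_mode,
    n_windows = starts_n, n_edges = ne
  ), class = "fetalqc_subject_qc")
}

#' @export
print.fetalqc_subject_qc <- function(x, ...) {
  cat("fetalqc subject QC report\n")
  cat(sprintf("  %d edges over %d windows; null: %s, alpha = %g (%s)\n",
              x$n_edges, x$n_windows, x$null_mode, x$alpha, x$correction))
  if (x$fd_degenerate) {
    cat("  FD series is constant: FC-FD correlations undefined\n")
  } else {
    cat(sprintf("  corrupted fraction: %.1f%%; median |r| = %.3f\n",
                100 * x$frac_corrupted, x$median_abs_r))
    if (is.finite(x$distance_dependence$rho))
      cat(sprintf("  distance dependence (Spearman rho): %.4f (p = %.3g)\n",
                  x$distance_dependence$rho, x$distance_dependence$p))
  }
  if (length(x$excluded_regions))
    cat("  excluded zero-variance regions:",
        paste(x$excluded_regions, collapse = ", "), "\n")
  invisible(x)
}
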