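#' Group table for QC-FC benchmarking
#'
#' @param fc \code{n_subjects x n_edges} matrix of per-edge FC values with
#'   consistent edge ordering across subjects.
#' @param mean_fd per-subject mean framewise displacement (mm).
#' @param subject_ids optional subject labels.
#' @param edge_distances optional per-edge distances (mm); a matrix
#'   (\code{n_subjects x n_edges}) when distances are subject-specific, or
#'   a vector when common.
#' @return an object of class \code{fetalqc_group}.
#' @export
group_table <- function(fc, mean_fd, subject_ids = NULL,
                        edge_distances = NULL) {
  fc <- as.matrix(fc)
  if (nrow(fc) < 3L) stop("QC-FC needs at least 3 subjects")
  if (length(mean_fd) != nrow(fc))
    stop("mean_fd must have one value per subject")
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(nrow(fc)))
  structure(list(fc = fc, mean_fd = as.numeric(mean_fd),
                 subject_ids = subject_ids, edge_distances = edge_distances),
            class = "fetalqc_group")
}

#' Classical group-level QC-FC metric
#'
#' For each edge, the correlation across subjects between the edge's FC
#' value and the subjects' mean FD. Edges whose correlation is significant
#' at \code{alpha} (uncorrected, two-sided) are flagged as motion-corrupted
#' for the group.
#'
#' @param group a \code{\link{group_table}}.
#' @param alpha significance level.
#' @param method \code{"pearson"} (classical definition) or
#'   \code{"spearman"}.
#' @return list with \code{edges} (data frame: r_qcfc, p, significant),
#'   \code{n_significant}, and \code{frac_significant}.
#' @export
qcfc <- function(group, alpha = 0.05, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(group, "fetalqc_group"))
  mfd <- group$mean_fd
  if (stats::sd(mfd) == 0) stop("mean FD has zero variance across subjects")
  n <- length(mfd)
  fc <- group$fc
  if (method == "spearman") {
    fc <- apply(fc, 2, rank)
    mfd <- rank(mfd)
  }
  mfd_c <- mfd - mean(mfd)
  fc_c <- sweep(fc, 2, colMeans(fc))
  sx <- sqrt(colSums(fc_c^2))
  sy <- sqrt(sum(mfd_c^2))
  r <- as.vector(crossprod(fc_c, mfd_c)) / (sx * sy)
  r[sx == 0] <- NA_real_
  df <- n - 2L
  tt <- r * sqrt(df) / sqrt(pmax(1e-300, 1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df)
  sig <- !is.na(p) & p < alpha
  list(edges = data.frame(r_qcfc = r, p = p, significant = sig),
       n_significant = sum(sig),
       frac_significant = mean(sig[!is.na(p)]))
}

#' Cross-subject summary of the subject-level QC metric
#'
#' Summarizes per-subject corrupted-edge fractions for each denoising
#' strategy: median and interquartile range, with an explicit exclusion
#' rule for saturated subjects (all edges corrupted, as happens when
#' censoring leaves too short a series).
#'
#' @param frac_corrupted data frame with columns \code{subject},
#'   \code{strategy} and \code{frac_corrupted} (one row per subject and
#'   strategy), or a named list of per-strategy numeric vectors.
#' @param exclude_saturated logical; when \code{TRUE}, subjects with all
#'   edges corrupted are excluded from the summary (they are always
#'   reported).
#' @return data frame with one row per strategy: \code{median}, \code{iqr},
#'   \code{n_subjects}, \code{n_saturated}.
#' @export
group_summary <- function(frac_corrupted, exclude_saturated = TRUE) {
  if (is.list(frac_corrupted) && !is.data.frame(frac_corrupted)) {
    frac_corrupted <- do.call(rbind, lapply(names(frac_corrupted), function(s) {
      v <- frac_corrupted[[s]]
      data.frame(subject = seq_along(v), strategy = s, frac_corrupted = v,
                 stringsAsFactors = FALSE)
    }))
  }
  stopifnot(all(c("subject", "strategy", "frac_corrupted") %in%
                  names(frac_corrupted)))
  out <- lapply(split(frac_corrupted, frac_corrupted$strategy), function(d) {
    v <- d$frac_corrupted
    sat <- !is.na(v) & v >= 1
    use <- if (exclude_saturated) v[!sat & !is.na(v)] else v[!is.na(v)]
    data.frame(strategy = d$strategy[1],
               median = stats::median(use),
               iqr = stats::IQR(use),
               n_subjects = length(use),
               n_saturated = sum(sat),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pooled distance dependence of the FC-FD correlations
#'
#' Pools each subject's per-edge FC-FD correlations together with the
#' subject-specific inter-regional distances (brain size changes over
#' gestation, so distances are computed per subject) and returns the
#' Spearman rank correlation over the pooled pairs.
#'
#' @param reports list of \code{\link{assess_subject}} reports (each with
#'   edge distances), or a data frame with columns \code{r} and
#'   \code{distance_mm}.
#' @return list with \code{rho}, \code{p}, and \code{n_pairs}.
#' @export
pooled_distance_dependence <- function(reports) {
  if (is.data.frame(reports)) {
    d <- reports
  } else {
    d <- do.call(rbind, lapply(reports, function(r)
      r$edges[, c("r", "distance_mm")]))
  }
  ok <- is.finite(d$r) & is.finite(d$distance_mm)
  if (sum(ok) < 4L) stop("need at least 4 complete (r, distance) pairs")
  ct <- suppressWarnings(stats::cor.test(d$r[ok], d$distance_mm[ok],
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n_pairs = sum(ok))
}
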