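#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style FD: per volume, the sum of absolute volume-to-volume
#' changes in the 3 translations (mm) plus the 3 rotations (radians)
#' converted to arc length on a sphere of `head_radius` mm. The first
#' volume has FD 0 by convention; `mean_fd` averages volumes 2..T.
#'
#' @param trace numeric T x 6 matrix (tx ty tz rx ry rz), T >= 2.
#' @param head_radius rotation-to-mm conversion radius (mm), default 50.
#' @return list of class `fd_series`: `fd` (length T), `mean_fd`,
#'   `max_fd`, `n_volumes`.
#' @examples
#' tr <- matrix(0, 5, 6); tr[2:5, 1] <- 0.1
#' framewise_displacement(tr)$fd
#' @export
framewise_displacement <- function(trace, head_radius = 50) {
  trace <- as.matrix(trace)
  if (nrow(trace) < 2L || ncol(trace) != 6L) {
    stop_invalid("motion trace must be a T x 6 matrix with T >= 2")
  }
  check_finite(trace, "motion trace")
  d <- abs(diff(trace))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius * rowSums(d[, 4:6, drop = FALSE]))
  out <- list(fd = fd, mean_fd = mean(fd[-1L]), max_fd = max(fd),
              n_volumes = nrow(trace))
  class(out) <- "fd_series"
  out
}

#' Scan exclusion by head-motion thresholds
#'
#' Drops a scan when its mean FD exceeds `mean_thresh` (default 0.3 mm)
#' or its maximum FD exceeds `max_thresh` (default 1.3 mm).
#'
#' @param fd an `fd_series` from [framewise_displacement()], or a list
#'   with `mean_fd` and `max_fd`.
#' @param mean_thresh,max_thresh thresholds in mm.
#' @return list: `keep` (logical) and `reason` ("ok", "mean_fd",
#'   "max_fd", or "mean_fd;max_fd").
#' @export
scan_exclusion <- function(fd, mean_thresh = 0.3, max_thresh = 1.3) {
  if (is.null(fd$mean_fd) || is.null(fd$max_fd)) {
    stop_invalid("fd must carry mean_fd and max_fd")
  }
  reasons <- c(if (fd$mean_fd > mean_thresh) "mean_fd",
               if (fd$max_fd > max_thresh) "max_fd")
  list(keep = length(reasons) == 0L,
       reason = if (length(reasons)) paste(reasons, collapse = ";") else "ok")
}

#' Exclude regions with low mean signal intensity
#'
#' Within each scan, regional mean intensities are z-scored across
#' regions; a region is excluded if its z falls below `z_thresh`
#' (default -1.96) in at least one scan.
#'
#' @param mean_intensities scans x regions matrix of regional mean
#'   signal intensities (>= 3 regions).
#' @param z_thresh exclusion threshold on the within-scan z-score.
#' @return integer vector of excluded region indices (possibly empty).
#' @export
low_signal_region_filter <- function(mean_intensities, z_thresh = -1.96) {
  m <- as.matrix(mean_intensities)
  if (ncol(m) < 3L) stop_invalid("need >= 3 regions")
  check_finite(m, "mean_intensities")
  excluded <- logical(ncol(m))
  for (s in seq_len(nrow(m))) {
    sdv <- stats::sd(m[s, ])
    # equal intensities across regions: no region is unusually low
    if (sdv == 0) next
    z <- (m[s, ] - mean(m[s, ])) / sdv
    excluded <- excluded | (z < z_thresh)
  }
  which(excluded)
}

#' Earliest low-motion window of a scan
#'
#' Finds the first run of `window` consecutive volumes all with
#' FD below `thresh`; scans possessing such a window qualify for a
#' low-motion sensitivity subset.
#'
#' @param fd an `fd_series`.
#' @param thresh FD threshold in mm (default 0.2).
#' @param window run length in volumes (default 100).
#' @return 1-based start index of the first qualifying window, or `NA`
#'   if none exists (including when `window` exceeds the scan length).
#' @export
low_motion_subset <- function(fd, thresh = 0.2, window = 100L) {
  x <- fd$fd < thresh
  n <- length(x)
  if (window > n) return(NA_integer_)
  run <- 0L
  for (t in seq_len(n)) {
    run <- if (x[t]) run + 1L else 0L
    if (run >= window) return(t - window + 1L)
  }
  NA_integer_
}

#' QC-FC motion-contamination diagnostics
#'
#' Per edge, the Pearson correlation across scans between FC and scan
#' mean FD (QC-FC); the distance-dependence statistic is the Spearman
#' correlation, across edges, of QC-FC with inter-centroid distance.
#'
#' @param dataset an `fc_dataset` (edge x scan FC plus metadata).
#' @param mean_fd per-scan mean FD; defaults to `dataset$meta$mean_fd`.
#' @param distances per-edge distances (mm); needed for the
#'   distance-dependence statistic.
#' @param stage label recorded in the report ("pre" or "post" correction).
#' @return list of class `qcfc_report`: `qcfc` per edge,
#'   `median_qcfc`, `median_abs_qcfc`, `distance_dependence`, `stage`.
#'   When every per-edge QC-FC is zero to numerical precision (below
#'   1e-8 in absolute value, as after in-sample FD regression), the
#'   ranks of the remaining floating-point dust carry no information and
#'   the distance-dependence statistic is reported as exactly 0.
#' @export
qcfc <- function(dataset, mean_fd = NULL, distances = NULL, stage = "pre") {
  fc <- dataset$fc
  if (is.null(mean_fd)) mean_fd <- dataset$meta$mean_fd
  if (ncol(fc) < 3L) stop_invalid("need >= 3 scans for QC-FC")
  if (stats::sd(mean_fd) == 0) {
    stop_invalid("degenerate input: mean FD is constant across scans")
  }
  q <- as.numeric(stats::cor(t(fc), mean_fd))
  dd <- if (is.null(distances)) {
    NA_real_
  } else if (max(abs(q)) < 1e-8) {
    # all QC-FC are zero to numerical precision (e.g. after in-sample FD
    # regression): ranking the rounding dust would manufacture a spurious
    # statistic, so there is no distance dependence by construction
    0
  } else {
    spearman_rho_pairwise(q, distances)
  }
  out <- list(qcfc = q, median_qcfc = stats::median(q),
              median_abs_qcfc = stats::median(abs(q)),
              distance_dependence = dd, stage = stage)
  class(out) <- "qcfc_report"
  out
}

#' Correct FC for head motion by FD regression
#'
#' Per edge, ordinary least squares of FC on scan mean FD pooled over
#' all scans; corrected FC is the residual plus the fitted intercept,
#' preserving each edge's level so baseline connectivity remains
#' interpretable. By construction the post-correction QC-FC on the same
#' scans is zero (up to numerical error), and the operation is
#' idempotent.
#'
#' @param dataset an `fc_dataset`.
#' @param mean_fd per-scan mean FD; defaults to `dataset$meta$mean_fd`.
#' @return a corrected `fc_dataset`.
#' @export
fd_regress <- function(dataset, mean_fd = NULL) {
  if (is.null(mean_fd)) mean_fd <- dataset$meta$mean_fd
  fc <- dataset$fc
  if (ncol(fc) < 3L) stop_invalid("need >= 3 scans for FD regression")
  if (stats::var(mean_fd) == 0) {
    stop_invalid("degenerate input: mean FD is constant across scans")
  }
  fd_c <- mean_fd - mean(mean_fd)
  beta <- as.numeric(fc %*% fd_c) / sum(fd_c^2)    # per-edge OLS slope
  # residual + fitted intercept = fc - beta * fd  (intercept a cancels:
  # a + (fc - a - beta*fd) = fc - beta*fd)
  corrected <- fc - beta %*% t(mean_fd)
  out <- dataset
  out$fc <- corrected
  out
}

#' Global signal regression
#'
#' Removes the across-region mean series from every regional series by
#' per-region OLS (with intercept); an aggressive motion-correction
#' alternative to FD regression.
#'
#' @param ts a `regional_timeseries` (see [regional_timeseries()]).
#' @return a `regional_timeseries` of residuals.
#' @export
global_signal_regress <- function(ts) {
  x <- ts$data
  if (ncol(x) < 2L) stop_invalid("need >= 2 regions")
  g <- rowMeans(x)
  if (stats::sd(g) == 0) {
    stop_invalid("degenerate input: global signal is constant")
  }
  gc <- g - mean(g)
  beta <- crossprod(gc, x) / sum(gc^2)
  res <- x - outer(gc, as.numeric(beta)) -
    matrix(colMeans(x), nrow(x), ncol(x), byrow = TRUE)
  out <- ts
  out$data <- res
  out
}
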