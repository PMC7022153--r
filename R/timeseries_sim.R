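#' Nearest positive-semidefinite correlation repair
#'
#' Projects a symmetric unit-diagonal target onto a valid correlation
#' matrix by clipping negative eigenvalues to a small floor and rescaling
#' back to unit diagonal. A target that is already positive semidefinite
#' is returned unchanged.
#'
#' @param target symmetric matrix with unit diagonal.
#' @param eig_floor smallest retained eigenvalue.
#' @return a positive-semidefinite correlation matrix.
#' @export
nearest_psd_correlation <- function(target, eig_floor = 1e-8) {
  if (!isSymmetric(unname(target), tol = 1e-10)) {
    stop_invalid("target correlation matrix must be symmetric")
  }
  if (any(abs(diag(target) - 1) > 1e-10)) {
    stop_invalid("target correlation matrix must have unit diagonal")
  }
  es <- eigen(target, symmetric = TRUE)
  if (min(es$values) >= 0) return(target)
  vals <- pmax(es$values, eig_floor)
  m <- es$vectors %*% (vals * t(es$vectors))
  stats::cov2cor(m)
}

#' Simulate a regional BOLD scan with injected motion artifacts
#'
#' Samples Gaussian time series whose population correlation is the
#' PSD-repaired `target_fc`, then adds a shared motion transient: a
#' sparse per-volume event amplitude loads (with region-specific
#' weights) onto every regional series, and a consistent 6-parameter
#' rigid-body motion trace (3 translations in mm, 3 rotations in
#' radians) is emitted whose steps coincide with the events. Sample
#' Pearson FC of the clean component converges to the repaired target
#' as `n_volumes` grows.
#'
#' @param target_fc symmetric region-by-region correlation target with
#'   unit diagonal.
#' @param n_volumes number of volumes (>= 2).
#' @param tr_seconds repetition time (seconds).
#' @param seed integer seed.
#' @param motion_event_rate probability a volume carries a motion event.
#' @param motion_amplitude typical artifact amplitude (signal units) and
#'   motion step scale (mm / rad x 0.01).
#' @return list with `ts` (an object as from [regional_timeseries()]),
#'   `motion` (n_volumes x 6 matrix: tx ty tz rx ry rz), and
#'   `target_repaired` (the PSD-projected correlation actually used).
#' @export
simulate_scan_timeseries <- function(target_fc, n_volumes, tr_seconds = 2.42,
                                     seed = 1L, motion_event_rate = 0.03,
                                     motion_amplitude = 1) {
  n_volumes <- as.integer(n_volumes)
  if (n_volumes < 2L) stop_invalid("n_volumes must be >= 2")
  target <- nearest_psd_correlation(target_fc)
  r <- nrow(target)
  with_seed(seed, {
    l <- chol_psd(target)
    x <- matrix(stats::rnorm(n_volumes * r), n_volumes, r) %*% l
    events <- stats::rbinom(n_volumes, 1L, motion_event_rate) *
      abs(stats::rnorm(n_volumes, 0, motion_amplitude))
    load <- stats::runif(r, 0.5, 1.5)
    x <- x + outer(events, load)
    # rigid-body trace: cumulative drift plus steps at the event volumes
    drift <- matrix(stats::rnorm(n_volumes * 6L, 0, 0.002), n_volumes, 6L)
    steps <- outer(events, c(1, 1, 1, 0.01, 0.01, 0.01) * 0.05)
    motion <- apply(drift + steps, 2L, cumsum)
    colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    ts <- regional_timeseries(x, tr_seconds = tr_seconds,
                              scan_id = "sim_scan")
    list(ts = ts, motion = motion, target_repaired = target)
  })
}

# Cholesky-like factor that tolerates PSD (rank-deficient) inputs.
chol_psd <- function(m) {
  es <- eigen(m, symmetric = TRUE)
  vals <- pmax(es$values, 0)
  t(es$vectors %*% (sqrt(vals) * t(es$vectors)))
}
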