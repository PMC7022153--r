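#' Configuration for a synthetic accelerated-longitudinal cohort
#'
#' Collects every parameter of the generative model in one validated
#' list. The generator emulates an adolescent neurodevelopment study:
#' subjects aged `age_min`-`age_max` years scanned 1-3 times, per-edge
#' linear age trajectories with subject random intercepts, a planted
#' per-region coupling between edgewise baseline and slope (the true
#' Maturational Index), an optional distance-dependent head-motion
#' confound of FC, and annotation maps with controlled spatial
#' correlation to the true MI map.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param age_min,age_max age range in years (default 14-26).
#' @param scans_per_subject_probs probability vector over 1, 2, 3 scans
#'   per subject; must sum to 1.
#' @param n_cortical,n_subcortical region counts (`n_cortical` even, >= 8).
#' @param subject_sd random-intercept SD (FC units).
#' @param noise_sd scan-level residual SD (FC units).
#' @param motion_gamma0 motion confound: FC units per mm of mean FD.
#' @param motion_gamma_slope change of the confound per mm of
#'   inter-region distance (FC units per mm FD per mm distance).
#' @param mi_targets per-region target baseline/slope coupling in
#'   \[-1, 1\]; recycled to the region count; default alternates +0.6/-0.6.
#' @param map_coupling target Spearman coupling of each generated
#'   continuous annotation map with the true MI map, each in \[-1, 1\].
#' @param smoothness_mm spatial autocorrelation length of surrogate maps.
#' @param edge_baseline_mean,edge_baseline_sd distribution of edge
#'   baselines B_e (positive mean: edge correlations are generally
#'   positive in resting-state data).
#' @param slope_scale annual-slope scale (FC units/year) multiplying the
#'   coupled component of each edge slope.
#' @param slope_noise_sd SD of the uncoupled slope noise (FC units/year).
#' @param beta_sex,beta_site fixed covariate effects (FC units).
#' @param fd_shape,fd_scale Gamma parameters of the per-scan mean FD
#'   distribution (mm); right-skewed, independent of age by default.
#' @param fd_age_slope optional mm/year trend of mean FD with age
#'   (default 0: no age-related change in head motion).
#' @param followup_min,followup_max inter-scan interval window (years).
#' @param seed integer master seed.
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(n_subjects = 150L,
                              age_min = 14, age_max = 26,
                              scans_per_subject_probs = c(0.4, 0.4, 0.2),
                              n_cortical = 36L, n_subcortical = 4L,
                              subject_sd = 0.06, noise_sd = 0.04,
                              motion_gamma0 = 0, motion_gamma_slope = 0,
                              mi_targets = NULL,
                              map_coupling = numeric(0),
                              smoothness_mm = 20,
                              edge_baseline_mean = 0.25,
                              edge_baseline_sd = 0.12,
                              slope_scale = 0.005,
                              slope_noise_sd = 0.0015,
                              beta_sex = 0.01, beta_site = 0.01,
                              fd_shape = 2, fd_scale = 0.05,
                              fd_age_slope = 0,
                              followup_min = 0.5, followup_max = 2.5,
                              seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2L) {
    stop_invalid("n_subjects must be >= 2")
  }
  if (!(age_min < age_max)) stop_invalid("age_min must be < age_max")
  p <- scans_per_subject_probs
  if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop_invalid("scans_per_subject_probs must be 3 nonnegative values summing to 1")
  }
  n_cortical <- as.integer(n_cortical)
  if (n_cortical < 8L || n_cortical %% 2L != 0L) {
    stop_invalid("n_cortical must be even and >= 8")
  }
  n_regions <- n_cortical + as.integer(n_subcortical)
  if (is.null(mi_targets)) {
    mi_targets <- rep_len(c(0.6, -0.6), n_regions)
  }
  mi_targets <- rep_len(mi_targets, n_regions)
  if (any(abs(mi_targets) > 1)) stop_invalid("mi_targets must lie in [-1, 1]")
  if (length(map_coupling) && any(abs(map_coupling) > 1)) {
    stop_invalid("map_coupling must lie in [-1, 1]")
  }
  if (smoothness_mm <= 0) stop_invalid("smoothness_mm must be > 0")
  if (followup_min <= 0 || followup_max < followup_min) {
    stop_invalid("follow-up window must satisfy 0 < min <= max")
  }
  cfg <- list(
    n_subjects = n_subjects, age_min = age_min, age_max = age_max,
    scans_per_subject_probs = p,
    n_cortical = n_cortical, n_subcortical = as.integer(n_subcortical),
    subject_sd = subject_sd, noise_sd = noise_sd,
    motion_gamma0 = motion_gamma0, motion_gamma_slope = motion_gamma_slope,
    mi_targets = mi_targets, map_coupling = map_coupling,
    smoothness_mm = smoothness_mm,
    edge_baseline_mean = edge_baseline_mean,
    edge_baseline_sd = edge_baseline_sd,
    slope_scale = slope_scale, slope_noise_sd = slope_noise_sd,
    beta_sex = beta_sex, beta_site = beta_site,
    fd_shape = fd_shape, fd_scale = fd_scale, fd_age_slope = fd_age_slope,
    followup_min = followup_min, followup_max = followup_max,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Sample an accelerated-longitudinal scan schedule
#'
#' One row per scan. Baseline ages are stratified-uniform over
#' `n_subjects` equal strata spanning \[age_min, age_max\] (so the age
#' range is covered evenly, as in an accelerated longitudinal design);
#' each follow-up adds a uniform `followup_min`-`followup_max` year
#' interval, capped at `age_max`. Sex is balanced Bernoulli(0.5) and two
#' scanner sites are assigned with equal probability.
#'
#' @param config a [simulation_config()].
#' @return data.frame with columns `scan_id`, `subject_id`, `age` (years),
#'   `sex` (0/1), `site` (factor "site1"/"site2").
#' @export
sample_cohort_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 101L, {
    n <- config$n_subjects
    strata <- seq(config$age_min, config$age_max, length.out = n + 1L)
    base_age <- stats::runif(n, strata[-(n + 1L)], strata[-1L])
    base_age <- sample(base_age)                      # decouple id and stratum
    n_scans <- sample(1:3, n, replace = TRUE,
                      prob = config$scans_per_subject_probs)
    sex <- stats::rbinom(n, 1L, 0.5)
    site <- sample(c("site1", "site2"), n, replace = TRUE)
    rows <- lapply(seq_len(n), function(s) {
      ages <- base_age[s]
      if (n_scans[s] > 1L) {
        gaps <- stats::runif(n_scans[s] - 1L, config$followup_min,
                             config$followup_max)
        ages <- pmin(base_age[s] + cumsum(c(0, gaps)), config$age_max)
      }
      data.frame(subject_id = sprintf("sub%04d", s), age = ages,
                 sex = sex[s], site = site[s], stringsAsFactors = FALSE)
    })
    meta <- do.call(rbind, rows)
    meta$scan_id <- sprintf("scan%05d", seq_len(nrow(meta)))
    meta$site <- factor(meta$site, levels = c("site1", "site2"))
    meta[, c("scan_id", "subject_id", "age", "sex", "site")]
  })
}

#' Plant per-edge growth parameters with a known Maturational Index
#'
#' Draws edge baselines B_e from a positive-mean normal distribution and
#' couples slopes to baselines region-wise:
#' `S_e = slope_scale * 0.5 * (a_i + a_j) * z(B_e) + eta_e`,
#' where `a_i` is region i's MI target, `z()` standardizes across edges
#' and `eta_e` is independent slope noise. The recorded ground truth MI
#' is the *realized* Spearman correlation of (B_e, S_e) over each
#' region's incident edges, recomputed exactly from the stored values.
#'
#' @param parc parcellation from [make_parcellation()].
#' @param config a [simulation_config()]; `mi_targets` must have one
#'   entry per region.
#' @return list of class `ground_truth`: `edge_baseline`, `edge_slope`
#'   (per edge in [edge_index()] order), `edges` (the index),
#'   `mi_targets`, `true_mi` (per region), `n_regions`.
#' @export
plant_edge_trajectories <- function(parc, config) {
  stopifnot(inherits(config, "sim_config"))
  n_regions <- nrow(parc)
  targets <- rep_len(config$mi_targets, n_regions)
  if (any(abs(targets) > 1)) stop_invalid("mi_targets must lie in [-1, 1]")
  ei <- edge_index(n_regions)
  with_seed(config$seed + 202L, {
    b <- stats::rnorm(nrow(ei), config$edge_baseline_mean,
                      config$edge_baseline_sd)
    zb <- as.numeric(scale(b))
    a_edge <- 0.5 * (targets[ei$i] + targets[ei$j])
    s <- config$slope_scale * a_edge * zb +
      stats::rnorm(nrow(ei), 0, config$slope_noise_sd)
    truth <- list(
      edge_baseline = b, edge_slope = s, edges = ei,
      mi_targets = targets,
      true_mi = realized_mi(b, s, ei, n_regions),
      n_regions = n_regions
    )
    class(truth) <- "ground_truth"
    truth
  })
}

# Spearman coupling of (baseline, slope) over each region's incident edges.
realized_mi <- function(b, s, ei, n_regions) {
  vapply(seq_len(n_regions), function(r) {
    inc <- which(ei$i == r | ei$j == r)
    if (length(inc) < 3L) return(NA_real_)
    spearman_rho_pairwise(b[inc], s[inc])
  }, numeric(1))
}

#' Simulate scan-level edge FC from planted trajectories
#'
#' Generates, for every scan and edge,
#' `FC = B_e + S_e (age - age_min) + beta_sex sex + beta_site site +
#'  u_subj + gamma_e meanFD + eps`,
#' with subject random intercepts `u_subj ~ N(0, subject_sd^2)`, residual
#' noise `eps ~ N(0, noise_sd^2)` and a distance-dependent motion
#' confound `gamma_e = motion_gamma0 + motion_gamma_slope * d_e`. Mean
#' FD per scan is Gamma-distributed (right-skewed) and independent of
#' age unless `fd_age_slope` is nonzero. Values are clipped to
#' (-0.999, 0.999) so simulated correlations remain valid.
#'
#' @param truth output of [plant_edge_trajectories()].
#' @param meta scan metadata from [sample_cohort_design()].
#' @param config the [simulation_config()].
#' @param parc the parcellation (for edge distances).
#' @return list of class `fc_dataset`: `fc` (edges x scans matrix),
#'   `edges`, `meta` (with `mean_fd` column appended), and
#'   `subject_intercepts`.
#' @export
simulate_edge_fc <- function(truth, meta, config, parc) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  if (truth$n_regions != nrow(parc)) {
    stop_invalid("truth and parcellation disagree on region count")
  }
  subjects <- unique(meta$subject_id)
  with_seed(config$seed + 303L, {
    u <- stats::rnorm(length(subjects), 0, config$subject_sd)
    names(u) <- subjects
    fd <- stats::rgamma(nrow(meta), shape = config$fd_shape,
                        scale = config$fd_scale) +
      config$fd_age_slope * (meta$age - config$age_min)
    fd <- pmax(fd, 1e-4)
    d <- edge_distance(parc)
    gamma_e <- config$motion_gamma0 + config$motion_gamma_slope * d
    site_code <- as.integer(meta$site) - 1L
    n_edges <- nrow(truth$edges)
    fixed <- config$beta_sex * meta$sex + config$beta_site * site_code +
      u[meta$subject_id]
    age_c <- meta$age - config$age_min
    fc <- outer(truth$edge_baseline, rep(1, nrow(meta))) +
      outer(truth$edge_slope, age_c) +
      matrix(fixed, n_edges, nrow(meta), byrow = TRUE) +
      outer(gamma_e, fd)
    if (config$noise_sd > 0) {
      fc <- fc + matrix(stats::rnorm(length(fc), 0, config$noise_sd),
                        n_edges, nrow(meta))
    }
    fc <- pmin(pmax(fc, -0.999), 0.999)
    colnames(fc) <- meta$scan_id
    meta$mean_fd <- fd
    out <- list(fc = fc, edges = truth$edges, meta = meta,
                subject_intercepts = u)
    class(out) <- "fc_dataset"
    out
  })
}

#' Spatially autocorrelated surrogate map over cortical regions
#'
#' A draw from a stationary isotropic Gaussian process at the cortical
#' centroids with squared-exponential covariance
#' `C(d) = exp(-d^2 / (2 smoothness_mm^2))` within each hemisphere and
#' zero covariance across hemispheres, standardized to zero mean and
#' unit variance. Both choices protect the exchangeability the spin
#' test relies on: a stationary process is invariant under the
#' within-hemisphere rotations the spin applies (a surrogate whose local
#' variance tracked centroid density would not be), and the cortical
#' sheet is not spatially continuous across hemispheres, so
#' cross-hemisphere covariance - which hemisphere-wise rotations do not
#' preserve - is anatomically absent rather than zeroed ad hoc.
#' Independent of any MI map; used to calibrate the spin test and to
#' build annotation maps of controlled coupling.
#'
#' @param parc parcellation with >= 8 cortical regions.
#' @param smoothness_mm Gaussian-process length scale (mm), > 0.
#' @param seed integer seed.
#' @param n_maps number of independent maps to draw; the covariance is
#'   factorized once, so drawing many maps together is much cheaper than
#'   repeated single draws.
#' @param nugget fraction of variance in \[0, 1) contributed by
#'   uncorrelated region-level noise (the geostatistical nugget effect);
#'   empirical annotation maps always carry such a measurement-noise
#'   floor on top of their smooth spatial signal.
#' @return for `n_maps = 1` (default) a numeric vector over all regions
#'   with NA subcortical entries; otherwise a regions x `n_maps` matrix
#'   of independent draws.
#' @export
generate_null_map <- function(parc, smoothness_mm = 20, seed = 1L,
                              n_maps = 1L, nugget = 0) {
  if (smoothness_mm <= 0) stop_invalid("smoothness_mm must be > 0")
  if (n_maps < 1L) stop_invalid("n_maps must be >= 1")
  if (nugget < 0 || nugget >= 1) stop_invalid("nugget must lie in [0, 1)")
  ctx <- which(parc$class == "cortical")
  if (length(ctx) < 8L) stop_invalid("need >= 8 cortical regions")
  with_seed(seed, {
    xyz <- as.matrix(parc[ctx, c("x", "y", "z")])
    d <- as.matrix(stats::dist(xyz))
    cmat <- (1 - nugget) * exp(-d^2 / (2 * smoothness_mm^2)) +
      nugget * diag(length(ctx))
    hemi <- parc$hemisphere[ctx]
    cmat[outer(hemi, hemi, "!=")] <- 0
    l <- chol_psd(cmat)
    v <- l %*% matrix(stats::rnorm(length(ctx) * n_maps), length(ctx))
    out <- matrix(NA_real_, nrow(parc), n_maps)
    out[ctx, ] <- apply(v, 2L, function(col) as.numeric(scale(col)))
    if (n_maps == 1L) out[, 1L] else out
  })
}

#' Generate annotation maps with controlled coupling to the true MI
#'
#' Continuous maps are built as
#' `coupling * z(true_mi) + sqrt(1 - coupling^2) * surrogate`
#' over cortical regions, where the surrogate is a spatially
#' autocorrelated null map ([generate_null_map()]); the realized Spearman
#' correlation with the true MI is therefore `coupling` in expectation.
#' One categorical map (`k_classes` clusters of the cortical centroids,
#' a stand-in for cytoarchitectonic classes or functional networks) is
#' appended.
#'
#' @param truth output of [plant_edge_trajectories()].
#' @param parc the parcellation.
#' @param config the [simulation_config()]; `map_coupling` gives one
#'   coupling per requested continuous map.
#' @param k_classes number of classes in the categorical map.
#' @return named list of maps. Continuous maps are numeric vectors over
#'   all regions (NA on subcortex), named `map01`, `map02`, ...; the
#'   categorical map is a factor vector named `classes`.
#' @export
make_annotation_maps <- function(truth, parc, config, k_classes = 4L) {
  stopifnot(inherits(config, "sim_config"))
  coupling <- config$map_coupling
  if (length(coupling) && any(abs(coupling) > 1)) {
    stop_invalid("map_coupling must lie in [-1, 1]")
  }
  ctx <- which(parc$class == "cortical")
  z_mi <- rep(NA_real_, nrow(parc))
  z_mi[ctx] <- as.numeric(scale(truth$true_mi[ctx]))
  maps <- list()
  for (m in seq_along(coupling)) {
    surr <- generate_null_map(parc, config$smoothness_mm,
                              seed = config$seed + 404L + m)
    mp <- coupling[m] * z_mi + sqrt(1 - coupling[m]^2) * surr
    maps[[sprintf("map%02d", m)]] <- mp
  }
  maps$classes <- with_seed(config$seed + 505L, {
    km <- stats::kmeans(as.matrix(parc[ctx, c("x", "y", "z")]),
                        centers = min(k_classes, length(ctx) %/% 2L),
                        nstart = 5L)
    cls <- rep(NA_character_, nrow(parc))
    cls[ctx] <- paste0("class", km$cluster)
    cls[parc$class == "subcortical"] <- "subcortical"
    factor(cls)
  })
  maps
}
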