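# Independent oracles used across tests. These deliberately recompute
# quantities by brute force / dense linear algebra, never through the
# package's own code paths.

# Dense GLS fixed effects at a fixed variance ratio lambda:
# V = I + lambda * Z Z' with Z the subject-intercept indicator matrix.
gls_oracle <- function(y, X, subject, lambda) {
  z <- stats::model.matrix(~ 0 + factor(subject))
  v <- diag(length(y)) + lambda * tcrossprod(z)
  vi <- solve(v)
  solve(t(X) %*% vi %*% X, t(X) %*% vi %*% y)
}

# Brute-force Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Midrank Spearman via explicit rank-then-Pearson.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Small synthetic cohort shared by several tests.
make_small_cohort <- function(seed = 1, n_subjects = 60, n_cortical = 20,
                              n_subcortical = 4, ...) {
  cfg <- simulation_config(n_subjects = n_subjects, n_cortical = n_cortical,
                           n_subcortical = n_subcortical, seed = seed, ...)
  parc <- make_parcellation(cfg$n_cortical, cfg$n_subcortical, seed = cfg$seed)
  meta <- sample_cohort_design(cfg)
  truth <- plant_edge_trajectories(parc, cfg)
  dataset <- simulate_edge_fc(truth, meta, cfg, parc)
  list(cfg = cfg, parc = parc, meta = meta, truth = truth, dataset = dataset)
}

# Random longitudinal design for growth-model tests.
random_design <- function(seed, n_subjects = 8, max_scans = 4) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    k <- sample(seq_len(max_scans), 1)
    data.frame(subject_id = sprintf("s%02d", s),
               age = sort(runif(k, 14, 26)),
               sex = rbinom(1, 1, 0.5),
               site = sample(c("site1", "site2"), 1))
  }))
  rows$scan_id <- sprintf("scan%03d", seq_len(nrow(rows)))
  rows$site <- factor(rows$site, levels = c("site1", "site2"))
  rows
}
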