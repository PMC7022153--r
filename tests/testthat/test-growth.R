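test_that("noise-free cross-sectional data are recovered exactly with OLS flag", {
  meta <- data.frame(scan_id = sprintf("s%02d", 1:20),
                     subject_id = sprintf("p%02d", 1:20),
                     age = seq(14, 26, length.out = 20),
                     sex = 0, site = "site1")
  y <- 0.2 + 0.01 * (meta$age - 14)
  fit <- fit_growth(y, meta)
  expect_equal(fit$fc14, 0.2, tolerance = 1e-10)
  expect_equal(fit$slope, 0.01, tolerance = 1e-10)
  expect_equal(fit$delta_14_26, 0.12, tolerance = 1e-10)
  expect_identical(fit$delta_14_26, 12 * fit$slope)
  expect_lt(fit$sigma_e2, 1e-20)
  expect_equal(fit$method, "OLS-fallback")
})

test_that("single-scan designs reduce exactly to ordinary least squares", {
  meta <- random_design(31, n_subjects = 25, max_scans = 1)
  set.seed(32)
  y <- 0.1 + 0.02 * (meta$age - 14) + 0.05 * meta$sex + rnorm(nrow(meta), 0, 0.1)
  fit <- fit_growth(y, meta)
  expect_equal(fit$method, "OLS-fallback")
  ols <- lm(y ~ I(meta$age - 14) + meta$sex + meta$site)
  expect_equal(unname(fit$beta),
               unname(coef(ols)[c(1, 2, 3, 4)]), tolerance = 1e-8)
})

test_that("REML fixed effects match a dense GLS oracle at the same lambda", {
  for (s in 1:25) {
    meta <- random_design(1000 + s, n_subjects = sample(5:9, 1))
    if (nrow(meta) > 30 || length(unique(meta$age)) < 2) next
    set.seed(2000 + s)
    y <- 0.2 + 0.01 * (meta$age - 14) + rnorm(nrow(meta), 0, 0.05) +
      rnorm(length(unique(meta$subject_id)), 0, 0.08)[
        as.integer(factor(meta$subject_id))]
    X <- cbind(1, meta$age - 14,
               if (length(unique(meta$sex)) > 1) meta$sex,
               if (length(unique(meta$site)) > 1)
                 as.integer(meta$site == "site2"))
    if (qr(X)$rank < ncol(X)) next   # collinear draw: model undefined
    fit <- fit_growth(y, meta)
    oracle <- gls_oracle(y, X, meta$subject_id, fit$lambda)
    expect_lt(max(abs(unname(fit$beta) - as.numeric(oracle))), 1e-6)
  }
})

test_that("REML matches lme4 on balanced longitudinal data", {
  skip_if_not_installed("lme4")
  meta <- do.call(rbind, lapply(1:40, function(s) {
    data.frame(scan_id = sprintf("s%02d_%d", s, 1:2),
               subject_id = sprintf("p%02d", s),
               age = 14 + (s %% 12) + c(0, 1.5),
               sex = s %% 2, site = c("site1", "site2")[1 + (s %/% 2) %% 2])
  }))
  meta$site <- factor(meta$site)
  set.seed(41)
  u <- rnorm(40, 0, 0.1)
  y <- 0.2 + 0.01 * (meta$age - 14) + 0.03 * meta$sex +
    u[as.integer(factor(meta$subject_id))] + rnorm(80, 0, 0.05)
  fit <- fit_growth(y, meta)
  d <- data.frame(y = y, age_c = meta$age - 14, sex = meta$sex,
                  site = meta$site, subj = factor(meta$subject_id))
  lmm <- lme4::lmer(y ~ age_c + sex + site + (1 | subj), data = d,
                    REML = TRUE)
  expect_equal(unname(fit$beta), unname(lme4::fixef(lmm)), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(lmm))
  expect_equal(fit$sigma_u2, vc$vcov[1], tolerance = 1e-3)
  expect_equal(fit$sigma_e2, vc$vcov[2], tolerance = 1e-3)
  expect_equal(fit$method, "REML")
})

test_that("the slope estimator is unbiased on balanced two-scan cohorts", {
  slopes <- vapply(1:60, function(rep) {
    set.seed(5000 + rep)
    n <- 100
    meta <- do.call(rbind, lapply(1:n, function(s) {
      a0 <- runif(1, 14, 24.5)
      data.frame(scan_id = sprintf("r%03d_%d", s, 1:2),
                 subject_id = sprintf("p%03d", s), age = c(a0, a0 + 1.5),
                 sex = rbinom(1, 1, 0.5), site = "site1")
    }))
    u <- rnorm(n, 0, 0.1)
    y <- 0.2 + 0.01 * (meta$age - 14) +
      u[as.integer(factor(meta$subject_id))] + rnorm(2 * n, 0, 0.05)
    fit_growth(y, meta)$slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.01), 3 * se)
})

test_that("zero planted subject variance drives the REML estimate to zero", {
  devs <- vapply(1:20, function(rep) {
    set.seed(6000 + rep)
    meta <- random_design(6000 + rep, n_subjects = 30)
    y <- 0.2 + 0.01 * (meta$age - 14) + rnorm(nrow(meta), 0, 0.05)
    fit <- fit_growth(y, meta)
    X <- cbind(1, meta$age - 14,
               if (length(unique(meta$sex)) > 1) meta$sex,
               if (length(unique(meta$site)) > 1)
                 as.integer(meta$site == "site2"))
    ols <- qr.solve(X, y)
    c(fit$sigma_u2, max(abs(unname(fit$beta) - ols)))
  }, numeric(2))
  expect_lt(median(devs[1, ]), 1e-4)
  expect_lt(median(devs[2, ]), 1e-6)
})

test_that("per-edge fitting recovers planted slopes and ignores edge order", {
  co <- make_small_cohort(seed = 51, n_subjects = 120, n_cortical = 14,
                          n_subcortical = 0)
  fits <- fit_all_edges(co$dataset)
  expect_equal(nrow(fits), nrow(co$truth$edges))
  expect_true(all(fits$ok))
  expect_gt(cor(fits$slope, co$truth$edge_slope), 0.9)
  expect_gt(cor(fits$fc14, co$truth$edge_baseline), 0.9)
  # edge order does not matter: permute rows of the value matrix
  perm <- sample(nrow(co$dataset$fc))
  ds2 <- co$dataset
  ds2$fc <- co$dataset$fc[perm, ]
  ds2$edges <- co$dataset$edges[perm, ]
  fits2 <- fit_all_edges(ds2)
  expect_equal(fits2$slope, fits$slope[perm], tolerance = 1e-10)
})

test_that("fit_growth rejects degenerate inputs", {
  meta <- data.frame(scan_id = c("a", "b"), subject_id = c("p", "q"),
                     age = c(15, 16), sex = 0, site = "site1")
  expect_error(fit_growth(c(0.1, 0.2), meta), ">= 3 scans")
  meta3 <- data.frame(scan_id = c("a", "b", "c"),
                      subject_id = c("p", "q", "r"), age = 15, sex = 0,
                      site = "site1")
  expect_error(fit_growth(c(0.1, 0.2, 0.3), meta3), "constant")
  meta3$age <- c(14, 15, 16)
  expect_error(fit_growth(c(0.1, NA, 0.3), meta3), "non-finite")
})

test_that("node-strength growth controls FDR and detects planted age effects", {
  co <- make_small_cohort(seed = 52, n_subjects = 200, n_cortical = 16,
                          n_subcortical = 4)
  # plant a strong positive age effect on every edge: strength must grow
  tr <- co$truth
  tr$edge_slope <- rep(0.02, length(tr$edge_slope))
  ds <- simulate_edge_fc(tr, co$meta, co$cfg, co$parc)
  ns <- fit_node_strengths(ds, co$parc, blocks = c("all", "cc"))
  expect_true(all(ns$q >= ns$p - 1e-12))
  expect_true(all(c("all", "cc") %in% ns$block))
  # planted positive mean slope on strength: high detection power
  all_blk <- ns[ns$block == "all", ]
  expect_gte(mean(all_blk$q < 0.05), 0.8)

  # a null cohort yields strength slopes near zero
  co0 <- make_small_cohort(seed = 53, n_subjects = 100, n_cortical = 12,
                           n_subcortical = 0, slope_scale = 0,
                           slope_noise_sd = 0)
  ns0 <- fit_node_strengths(co0$dataset, co0$parc)
  expect_true(all(abs(ns0$slope) < 3 * ns0$slope_se + 1e-12))
})

test_that("global mean trend equals fitting the manually averaged series", {
  co <- make_small_cohort(seed = 54, n_subjects = 60, n_cortical = 10,
                          n_subcortical = 0)
  g <- global_mean_trend(co$dataset)
  manual <- fit_growth(colMeans(co$dataset$fc), co$dataset$meta)
  expect_identical(g$slope, manual$slope)
  expect_identical(g$fc14, manual$fc14)
})

test_that("a planted global drift is detected with high power", {
  detected <- vapply(1:20, function(rep) {
    co <- make_small_cohort(seed = 7000 + rep, n_subjects = 150,
                            n_cortical = 10, n_subcortical = 0,
                            mi_targets = 0, slope_noise_sd = 0)
    tr <- co$truth
    tr$edge_slope <- rep(0.005, length(tr$edge_slope))
    ds <- simulate_edge_fc(tr, co$meta, co$cfg, co$parc)
    global_mean_trend(ds)$p < 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.8)

  null_ok <- vapply(1:10, function(rep) {
    co <- make_small_cohort(seed = 7100 + rep, n_subjects = 100,
                            n_cortical = 10, n_subcortical = 0,
                            mi_targets = 0, slope_scale = 0,
                            slope_noise_sd = 0)
    fit <- global_mean_trend(co$dataset)
    abs(fit$slope) < 3 * fit$slope_se
  }, logical(1))
  expect_gte(mean(null_ok), 0.9)
})
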