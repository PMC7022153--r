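test_that("spearman_rho uses midranks and matches a manual oracle", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, -(1:10)), -1)
  expect_equal(spearman_rho(c(1, 2, 2, 3), c(1, 2, 3, 4)), 0.9487,
               tolerance = 1e-4)
  set.seed(1)
  for (k in 1:20) {
    x <- sample(1:6, 15, replace = TRUE)   # plenty of ties
    y <- rnorm(15)
    expect_equal(spearman_rho(x, y), spearman_oracle(x, y), tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:4, 1:5), "length")
})

test_that("bh_fdr reproduces the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(2)
  for (k in 1:200) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-14)
  }
  expect_true(all(bh_fdr(runif(50)) >= runif(0)))  # q >= p elementwise
  p <- runif(30)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

make_edge_table <- function(parc, fc14, delta) {
  ei <- edge_index(nrow(parc))
  data.frame(i = ei$i, j = ei$j, fc14 = fc14, delta_14_26 = delta,
             ok = TRUE)
}

test_that("maturational index hits +/-1 on perfectly coupled edges", {
  parc <- make_parcellation(12, 0, seed = 1)
  ei <- edge_index(12)
  set.seed(3)
  fc14 <- rnorm(nrow(ei), 0.3, 0.1)
  cons <- make_edge_table(parc, fc14, 2 * fc14)
  mi_c <- maturational_index(cons, parc, min_edges = 3)
  expect_true(all(mi_c$mi == 1))
  expect_true(all(mi_c$mode == "conservative"))
  disr <- make_edge_table(parc, fc14, 0.3 - fc14)
  mi_d <- maturational_index(disr, parc, min_edges = 3)
  expect_true(all(mi_d$mi == -1))
  expect_true(all(mi_d$mode == "disruptive"))
  expect_equal(unique(mi_c$n_edges), 11)
  # too few incident edges: indeterminate, never fatal
  mi_small <- maturational_index(cons, parc, min_edges = 50)
  expect_true(all(is.na(mi_small$mi)))
  expect_true(all(mi_small$mode == "indeterminate"))
})

test_that("MI is invariant to monotone transforms and to slope rescaling", {
  parc <- make_parcellation(10, 0, seed = 2)
  ei <- edge_index(10)
  set.seed(4)
  tab <- make_edge_table(parc, rnorm(nrow(ei), 0.3, 0.1),
                         rnorm(nrow(ei), 0, 0.05))
  base <- maturational_index(tab, parc, min_edges = 3)$mi
  warped <- tab
  warped$fc14 <- exp(tab$fc14)           # strictly increasing transform
  warped$delta_14_26 <- tab$delta_14_26 / 12  # annual slope instead of delta
  expect_equal(maturational_index(warped, parc, min_edges = 3)$mi, base,
               tolerance = 1e-12)
})

test_that("edge subsets restrict the MI to the requested block", {
  parc <- make_parcellation(10, 4, seed = 3)
  ei <- edge_index(14)
  set.seed(5)
  tab <- make_edge_table(parc, rnorm(nrow(ei), 0.3, 0.1),
                         rnorm(nrow(ei), 0, 0.05))
  mi_cc <- maturational_index(tab, parc, subset = "cc", min_edges = 3)
  expect_true(all(is.na(mi_cc$mi[parc$class == "subcortical"])))
  expect_equal(unique(mi_cc$n_edges[parc$class == "cortical"]), 9)
  mi_ss <- maturational_index(tab, parc, subset = "ss", min_edges = 3)
  expect_true(all(is.na(mi_ss$mi[parc$class == "cortical"])))
  expect_equal(unique(mi_ss$n_edges[parc$class == "subcortical"]), 3)
})

test_that("spin banks are bijective, hemisphere-preserving and reproducible", {
  parc <- make_parcellation(40, 4, seed = 4)
  spins <- generate_spins(parc, 100, seed = 7)
  expect_equal(dim(spins$perms), c(100, 40))
  left <- which(parc$hemisphere[spins$cortical] == "L")
  right <- which(parc$hemisphere[spins$cortical] == "R")
  for (s in 1:100) {
    expect_identical(sort(spins$perms[s, ]), 1:40)
    expect_true(all(spins$perms[s, left] %in% left))
    expect_true(all(spins$perms[s, right] %in% right))
  }
  expect_identical(spins$perms, generate_spins(parc, 100, seed = 7)$perms)
  parc_bad <- parc; parc_bad$sph_x[1] <- NA
  expect_error(generate_spins(parc_bad, 5), "spherical")
})

test_that("identity rotation yields the identity permutation", {
  parc <- make_parcellation(20, 0, seed = 5)
  sph <- as.matrix(parc[, c("sph_x", "sph_y", "sph_z")])
  left <- which(parc$hemisphere == "L")
  perm <- devfc:::greedy_assign(sph[left, ], sph[left, ])
  expect_identical(perm, seq_along(left))
})

test_that("spin map correlation attains the minimal p on self-comparison", {
  parc <- make_parcellation(30, 0, seed = 6)
  spins <- generate_spins(parc, 999, seed = 8)
  m <- generate_null_map(parc, 20, seed = 9)
  st <- spin_test_map_correlation(m, m, spins)
  expect_equal(st$rho, 1)
  # at coarse resolution a small-angle rotation can reproduce the
  # identity permutation, which ties the observed statistic; the
  # empirical p must count those ties and nothing else
  ties <- sum(abs(st$null) >= 1 - 1e-12)
  expect_equal(st$p_spin, (1 + ties) / 1000)
  expect_gte(st$p_spin, 1 / 1000)
  # at finer resolution the identity basin is negligible: exact floor
  parc2 <- make_parcellation(120, 0, seed = 6)
  spins2 <- generate_spins(parc2, 199, seed = 8)
  m2 <- generate_null_map(parc2, 20, seed = 9)
  st2 <- spin_test_map_correlation(m2, m2, spins2)
  expect_equal(st2$p_spin, 1 / 200)
  # p is never below 1/(n_spins+1)
  m2 <- generate_null_map(parc, 20, seed = 10)
  st2 <- spin_test_map_correlation(m, m2, spins)
  expect_gte(st2$p_spin, 1 / 1000)
  expect_error(spin_test_map_correlation(rep(1, 30), m, spins), "constant")
})

test_that("the spin null equals brute-force map shuffling with the same permutations", {
  parc <- make_parcellation(8, 0, seed = 7)
  spins <- generate_spins(parc, 50, seed = 11)
  a <- generate_null_map(parc, 15, seed = 12)
  b <- generate_null_map(parc, 15, seed = 13)
  st <- spin_test_map_correlation(a, b, spins)
  manual <- vapply(1:50, function(s) {
    shuffled <- a[spins$cortical][spins$perms[s, ]]
    cor(shuffled, b[spins$cortical], method = "spearman")
  }, numeric(1))
  expect_identical(st$null, manual)
})

test_that("per-region MI spin test calibrates under the null and detects strong coupling", {
  parc <- make_parcellation(24, 0, seed = 8)
  ei <- edge_index(24)
  spins <- generate_spins(parc, 199, seed = 14)
  set.seed(15)
  # strong coupling at every region: high power
  fc14 <- rnorm(nrow(ei), 0.3, 0.1)
  strong <- make_edge_table(parc, fc14,
                            2 * fc14 + rnorm(nrow(ei), 0, 0.02))
  hits <- vapply(1:10, function(r) {
    spin_test_mi(strong, parc, r, spins, min_edges = 5)$p_spin < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # null coupling: rejection stays near the nominal level (one region per
  # independent draw; 3-sigma binomial band)
  rej <- vapply(1:60, function(k) {
    set.seed(100 + k)
    tabn <- make_edge_table(parc, rnorm(nrow(ei), 0.3, 0.1),
                            rnorm(nrow(ei), 0, 0.05))
    spin_test_mi(tabn, parc, 1 + (k %% 24), spins, min_edges = 5)$p_spin <= 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
  # subcortical regions are not spinnable
  parc2 <- make_parcellation(8, 2, seed = 9)
  ei2 <- edge_index(10)
  tab2 <- make_edge_table(parc2, rnorm(nrow(ei2), 0.3, 0.1),
                          rnorm(nrow(ei2), 0, 0.05))
  expect_error(spin_test_mi(tab2, parc2, 9, generate_spins(parc2, 5),
                            min_edges = 3), "subcortical")
})

test_that("mode classification flags significance from spin q-values", {
  co <- make_small_cohort(seed = 61, n_subjects = 100, n_cortical = 16,
                          n_subcortical = 2)
  fits <- fit_all_edges(co$dataset)
  spins <- generate_spins(co$parc, 99, seed = 16)
  mi <- maturational_index(fits, co$parc, min_edges = 5)
  mi <- classify_modes(mi, fits, co$parc, spins, min_edges = 5)
  p_use <- ifelse(is.na(mi$p_spin), mi$p_param, mi$p_spin)
  ok <- !is.na(mi$q)
  expect_true(all(mi$q[ok] >= p_use[ok] - 1e-12))
  expect_true(all(mi$mode[mi$mi > 0] == "conservative", na.rm = TRUE))
  expect_true(all(mi$mode[mi$mi < 0] == "disruptive", na.rm = TRUE))
  expect_true(all(!mi$significant[is.na(mi$q)]))
  # subcortical rows keep a parametric q only
  expect_true(all(is.na(mi$p_spin[mi$class == "subcortical"])))
})

test_that("half-split stability is high for strongly coupled cohorts", {
  co <- make_small_cohort(seed = 62, n_subjects = 200, n_cortical = 16,
                          n_subcortical = 0,
                          mi_targets = rep_len(c(0.8, -0.8), 16))
  r <- half_split_stability(co$dataset, co$parc, n_splits = 5, seed = 17,
                            min_edges = 5)
  expect_length(r, 5)
  expect_gte(median(r), 0.6)
  expect_error(half_split_stability(co$dataset, co$parc, 0), "n_splits")
  small <- co$dataset
  keep <- small$meta$subject_id %in% unique(small$meta$subject_id)[1:4]
  small$fc <- small$fc[, keep]; small$meta <- small$meta[keep, ]
  expect_error(half_split_stability(small, co$parc, 2), "8 subjects")
})

test_that("half splits are subject-disjoint and exhaustive", {
  co <- make_small_cohort(seed = 63, n_subjects = 20, n_cortical = 10,
                          n_subcortical = 0)
  subjects <- unique(co$dataset$meta$subject_id)
  r <- half_split_stability(co$dataset, co$parc, n_splits = 3, seed = 99,
                            min_edges = 3)
  for (half in attr(r, "halves")) {
    other <- setdiff(subjects, half)
    expect_length(intersect(half, other), 0)
    expect_setequal(c(half, other), subjects)
    expect_equal(length(half), 10)
  }
})
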