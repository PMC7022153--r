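# Accelerated-longitudinal growth models.
#
# Each outcome (edge FC or node strength) is modeled as
#   y = b0 + b_age (age - baseline_age) + b_sex sex + b_site site
#       + u_subject + e,   u ~ N(0, s_u^2), e ~ N(0, s_e^2)
# i.e. a linear mixed model with a subject random intercept. The model
# is estimated by REML, profiling out the residual variance and
# searching the variance ratio lambda = s_u^2 / s_e^2 by golden
# section. With a single random intercept the marginal covariance is
# block diagonal (V_i = I + lambda J per subject) so all REML
# quantities reduce to per-subject sums; one evaluation costs O(p^2)
# per subject, which makes fitting tens of thousands of edges feasible.

# Design matrix and reference row for a scan metadata table.
growth_design <- function(meta, baseline_age = 14, use_sex = TRUE,
                          use_site = TRUE) {
  n <- nrow(meta)
  X <- cbind(intercept = rep(1, n), age = meta$age - baseline_age)
  if (use_sex && length(unique(meta$sex)) > 1L) {
    X <- cbind(X, sex = as.numeric(meta$sex))
  }
  if (use_site) {
    site <- droplevels(factor(meta$site))
    if (nlevels(site) > 1L) {
      dum <- stats::model.matrix(~site)[, -1L, drop = FALSE]
      colnames(dum) <- paste0("site_", levels(site)[-1L])
      X <- cbind(X, dum)
    }
  }
  # reference row: age = baseline, covariates at sample-frequency means,
  # so the fitted baseline is a population-average quantity
  ref <- colMeans(X)
  ref["age"] <- 0
  list(X = X, ref = ref,
       subj = match(meta$subject_id, unique(meta$subject_id)),
       n_subjects = length(unique(meta$subject_id)))
}

# Shared sufficient statistics for one design (reused across edges).
growth_precompute <- function(des) {
  X <- des$X
  subj <- des$subj
  list(X = X, subj = subj, ref = des$ref,
       XtX = crossprod(X),
       Sx = rowsum(X, subj),
       n_i = as.numeric(table(subj)),
       N = nrow(X), p = ncol(X),
       n_subjects = des$n_subjects,
       has_repeats = any(table(subj) > 1L))
}

# REML criterion pieces at a given variance ratio.
reml_eval <- function(lambda, pc, Xty, yty, Sy) {
  ci <- lambda / (1 + pc$n_i * lambda)
  A <- pc$XtX - crossprod(pc$Sx, ci * pc$Sx)
  b <- Xty - crossprod(pc$Sx, ci * Sy)
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) return(list(crit = Inf))
  yvy <- yty - sum(ci * Sy^2)
  rss <- max(yvy - sum(beta * b), 1e-300)
  crit <- (pc$N - pc$p) * log(rss) + sum(log1p(pc$n_i * lambda)) +
    determinant(A, logarithm = TRUE)$modulus[1L]
  list(crit = crit, beta = as.numeric(beta), A = A, rss = rss)
}

golden_section <- function(f, lower, upper, tol = 1e-8) {
  phi <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    }
  }
  (a + b) / 2
}

# Core fit for one outcome vector given precomputed design structures.
# Xty/yty/Sy may be supplied when batched over many outcomes.
fit_growth_core <- function(y, pc, lambda_max = 1e3, boundary_tol = 1e-6,
                            Xty = NULL, yty = NULL, Sy = NULL) {
  if (is.null(Xty)) Xty <- as.numeric(crossprod(pc$X, y))
  if (is.null(yty)) yty <- sum(y^2)
  if (is.null(Sy)) Sy <- as.numeric(rowsum(y, pc$subj))
  lambda_hat <- 0
  method <- "OLS-fallback"
  if (pc$has_repeats) {
    f <- function(l) reml_eval(l, pc, Xty, yty, Sy)$crit
    lambda_hat <- golden_section(f, 0, lambda_max)
    # boundary: golden section converging onto 0 means no subject variance
    if (!is.finite(f(lambda_hat)) || lambda_hat <= boundary_tol ||
        f(lambda_hat) >= f(0)) {
      lambda_hat <- 0
    } else {
      method <- "REML"
    }
  }
  ev <- reml_eval(lambda_hat, pc, Xty, yty, Sy)
  if (!is.finite(ev$crit)) stop_invalid("singular design: fit failed")
  sigma_e2 <- ev$rss / (pc$N - pc$p)
  cov_beta <- sigma_e2 * solve(ev$A)
  beta <- ev$beta
  names(beta) <- colnames(pc$X)
  slope <- beta[["age"]]
  slope_se <- sqrt(cov_beta[2L, 2L])
  ref <- pc$ref
  fc14 <- sum(ref * beta)
  fc14_se <- sqrt(drop(t(ref) %*% cov_beta %*% ref))
  z <- if (slope_se > 0) slope / slope_se else sign(slope) * Inf
  fit <- list(
    fc14 = fc14, fc14_se = fc14_se,
    slope = slope, slope_se = slope_se,
    delta_14_26 = 12 * slope,
    p = max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin),
    beta = beta,
    sigma_u2 = lambda_hat * sigma_e2, sigma_e2 = sigma_e2,
    lambda = lambda_hat,
    n_scans = pc$N, n_subjects = pc$n_subjects,
    method = method
  )
  class(fit) <- "growth_fit"
  fit
}

#' Fit the accelerated-longitudinal growth model to one outcome
#'
#' Random-intercept linear mixed model of an outcome on age (centred at
#' `baseline_age`), sex and scanner site, estimated by REML with the
#' variance ratio profiled by golden-section search. Reports the
#' model-predicted baseline value at `baseline_age` (covariates at their
#' sample-frequency-weighted means), the annual slope, and the total
#' change over the 14-26 y window (`delta_14_26 = 12 * slope`). When the
#' random-intercept variance estimate hits the zero boundary, or no
#' subject has repeated scans, the fit reduces exactly to ordinary least
#' squares and the `method` flag records the fallback. Slope inference
#' uses the normal approximation z = slope / SE.
#'
#' @param values per-scan outcome vector, aligned with `meta`.
#' @param meta scan metadata (`subject_id`, `age`, `sex`, `site`).
#' @param baseline_age age (years) at which the baseline is evaluated.
#' @param use_sex,use_site include the covariates (dropped automatically
#'   when constant).
#' @return list of class `growth_fit`; see fields in the source.
#' @export
fit_growth <- function(values, meta, baseline_age = 14, use_sex = TRUE,
                       use_site = TRUE) {
  if (length(values) != nrow(meta)) stop_invalid("values/meta length mismatch")
  if (length(values) < 3L) stop_invalid("need >= 3 scans")
  check_finite(values, "values")
  if (length(unique(meta$age)) < 2L) stop_invalid("age is constant")
  des <- growth_design(meta, baseline_age, use_sex, use_site)
  pc <- growth_precompute(des)
  fit_growth_core(values, pc)
}

#' Fit the growth model independently to every edge
#'
#' Applies [fit_growth()] per edge with shared design structures; edges
#' whose fit fails are recorded (`ok = FALSE`) rather than fatal and are
#' excluded downstream.
#'
#' @param dataset an `fc_dataset`.
#' @inheritParams fit_growth
#' @return data.frame of class `edge_growth`: `i`, `j`, `fc14`, `slope`,
#'   `delta_14_26`, `slope_se`, `p`, `method`, `ok`.
#' @export
fit_all_edges <- function(dataset, baseline_age = 14, use_sex = TRUE,
                          use_site = TRUE) {
  meta <- dataset$meta
  des <- growth_design(meta, baseline_age, use_sex, use_site)
  pc <- growth_precompute(des)
  n_edges <- nrow(dataset$edges)
  res <- data.frame(
    i = dataset$edges$i, j = dataset$edges$j,
    fc14 = NA_real_, slope = NA_real_, delta_14_26 = NA_real_,
    slope_se = NA_real_, p = NA_real_, method = NA_character_,
    ok = FALSE, stringsAsFactors = FALSE
  )
  XtY <- crossprod(pc$X, t(dataset$fc))          # p x edges
  SY <- rowsum(t(dataset$fc), pc$subj)           # subjects x edges
  ytY <- rowSums(dataset$fc^2)
  for (e in seq_len(n_edges)) {
    fit <- tryCatch(
      fit_growth_core(dataset$fc[e, ], pc, Xty = XtY[, e], yty = ytY[e],
                      Sy = SY[, e]),
      error = function(err) NULL)
    if (!is.null(fit)) {
      res$fc14[e] <- fit$fc14
      res$slope[e] <- fit$slope
      res$delta_14_26[e] <- fit$delta_14_26
      res$slope_se[e] <- fit$slope_se
      res$p[e] <- fit$p
      res$method[e] <- fit$method
      res$ok[e] <- TRUE
    }
  }
  if (!any(res$ok)) stop_invalid("all edge fits failed")
  class(res) <- c("edge_growth", "data.frame")
  res
}

#' Growth of node strength per region and connectivity block
#'
#' Computes per-scan weighted degree for each requested block
#' ([node_strength()]), fits the growth model per region, and applies
#' Benjamini-Hochberg FDR across regions within each block.
#'
#' @param dataset an `fc_dataset`.
#' @param parc the parcellation aligned to the dataset's regions.
#' @param blocks character vector of blocks ("all", "cc", "cs", "sc", "ss").
#' @inheritParams fit_growth
#' @return data.frame: `region`, `label`, `block`, `fc14`, `slope`,
#'   `delta_14_26`, `slope_se`, `p`, `q`, `method`.
#' @export
fit_node_strengths <- function(dataset, parc, blocks = "all",
                               baseline_age = 14, use_sex = TRUE,
                               use_site = TRUE) {
  mats <- unstack_dataset(dataset)
  des <- growth_design(dataset$meta, baseline_age, use_sex, use_site)
  pc <- growth_precompute(des)
  out <- list()
  for (blk in blocks) {
    strength <- vapply(mats, node_strength, numeric(nrow(parc)),
                       parc = parc, block = blk)
    rows <- which(!is.na(strength[, 1L]))
    fits <- lapply(rows, function(r) fit_growth_core(strength[r, ], pc))
    df <- data.frame(
      region = parc$region[rows], label = parc$label[rows], block = blk,
      fc14 = vapply(fits, `[[`, numeric(1), "fc14"),
      slope = vapply(fits, `[[`, numeric(1), "slope"),
      delta_14_26 = vapply(fits, `[[`, numeric(1), "delta_14_26"),
      slope_se = vapply(fits, `[[`, numeric(1), "slope_se"),
      p = vapply(fits, `[[`, numeric(1), "p"),
      method = vapply(fits, `[[`, character(1), "method"),
      stringsAsFactors = FALSE
    )
    df$q <- bh_fdr(df$p)
    out[[blk]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Growth of the global mean connectivity
#'
#' Fits the growth model to the per-scan mean over all edges.
#'
#' @param dataset an `fc_dataset`.
#' @inheritParams fit_growth
#' @return a `growth_fit`.
#' @export
global_mean_trend <- function(dataset, baseline_age = 14, use_sex = TRUE,
                              use_site = TRUE) {
  fit_growth(colMeans(dataset$fc), dataset$meta, baseline_age,
             use_sex, use_site)
}
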