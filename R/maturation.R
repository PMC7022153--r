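#' Per-region Maturational Index
#'
#' For each region, the MI is the Spearman correlation, over the edges
#' incident to it, between edgewise baseline connectivity (FC14) and
#' edgewise change (delta FC 14-26). A positive MI marks a
#' "conservative" mode (edges strong at 14 strengthen further); a
#' negative MI marks a "disruptive" mode (weak edges strengthen, strong
#' edges weaken). The index is a rank statistic and is invariant to any
#' strictly increasing transform of either input, in particular to using
#' the annual slope instead of the 12-year change.
#'
#' @param edges an `edge_growth` table from [fit_all_edges()].
#' @param parc the parcellation.
#' @param subset which edges enter: all, cortico-cortical only ("cc"),
#'   or subcortico-subcortical only ("ss").
#' @param min_edges minimum incident edges for a defined MI; regions
#'   below it are marked indeterminate.
#' @return data.frame of class `mi_result`: `region`, `label`, `class`,
#'   `mi`, `n_edges`, `p_param`, `mode` ("conservative", "disruptive",
#'   "indeterminate"), `subset`. Spin p-values and q-values are appended
#'   by [spin_test_mi()] / [classify_modes()].
#' @export
maturational_index <- function(edges, parc, subset = c("all", "cc", "ss"),
                               min_edges = 10L) {
  subset <- match.arg(subset)
  ok <- edges$ok & is.finite(edges$fc14) & is.finite(edges$delta_14_26)
  if (!all(edges$ok)) {
    warning(sprintf("%d edge fits failed and are excluded from MI",
                    sum(!edges$ok)))
  }
  is_ctx <- parc$class == "cortical"
  keep <- switch(subset,
    all = ok,
    cc = ok & is_ctx[edges$i] & is_ctx[edges$j],
    ss = ok & !is_ctx[edges$i] & !is_ctx[edges$j]
  )
  n_regions <- nrow(parc)
  mi <- rep(NA_real_, n_regions)
  n_inc <- integer(n_regions)
  p_param <- rep(NA_real_, n_regions)
  for (r in seq_len(n_regions)) {
    inc <- which(keep & (edges$i == r | edges$j == r))
    n_inc[r] <- length(inc)
    if (length(inc) < max(min_edges, 3L)) next
    rho <- spearman_rho_pairwise(edges$fc14[inc], edges$delta_14_26[inc])
    mi[r] <- rho
    p_param[r] <- spearman_p_param(rho, length(inc))
  }
  mode <- ifelse(is.na(mi) | mi == 0, "indeterminate",
                 ifelse(mi > 0, "conservative", "disruptive"))
  res <- data.frame(
    region = parc$region, label = parc$label, class = parc$class,
    mi = mi, n_edges = n_inc, p_param = p_param, mode = mode,
    subset = subset, stringsAsFactors = FALSE
  )
  class(res) <- c("mi_result", "data.frame")
  res
}

#' Spin-permutation significance of one region's Maturational Index
#'
#' Null MI values are obtained by spin-permuting the region's map of
#' edgewise change over its cortical partner regions while the FC14
#' values stay fixed; each permutation yields one null Spearman
#' correlation and the two-sided empirical p-value uses the +1
#' correction. Partners whose permuted source is the index region
#' itself (whose change value toward itself is undefined) are dropped
#' pairwise for that spin. Only cortical regions can be spun;
#' subcortical regions keep a parametric p only.
#'
#' @param edges `edge_growth` table.
#' @param parc the parcellation.
#' @param region region id (must be cortical).
#' @param spins a `spin_null`.
#' @param min_edges as in [maturational_index()].
#' @return list: `mi`, `p_spin`, `n_edges`, `null`.
#' @export
spin_test_mi <- function(edges, parc, region, spins, min_edges = 10L) {
  if (parc$class[region] != "cortical") {
    stop_invalid("region %d is subcortical: spin test unsupported, use the parametric p", region)
  }
  ok <- edges$ok & is.finite(edges$fc14) & is.finite(edges$delta_14_26)
  inc <- which(ok & (edges$i == region | edges$j == region))
  partners <- ifelse(edges$i[inc] == region, edges$j[inc], edges$i[inc])
  ctx_only <- parc$class[partners] == "cortical"
  inc <- inc[ctx_only]; partners <- partners[ctx_only]
  if (length(inc) < max(min_edges, 3L)) {
    return(list(mi = NA_real_, p_spin = NA_real_, n_edges = length(inc),
                null = numeric(0)))
  }
  fc14 <- edges$fc14[inc]
  delta <- edges$delta_14_26[inc]
  if (stats::sd(delta) == 0 || stats::sd(fc14) == 0) {
    return(list(mi = NA_real_, p_spin = NA_real_, n_edges = length(inc),
                null = numeric(0)))
  }
  obs <- stats::cor(fc14, delta, method = "spearman")
  # delta as a cortical map over partner regions (NA at the region itself
  # and at non-partners)
  ctx <- spins$cortical
  dmap <- rep(NA_real_, nrow(parc))
  dmap[partners] <- delta
  dmap_ctx <- dmap[ctx]
  pos <- match(partners, ctx)
  null <- vapply(seq_len(spins$n_spins), function(s) {
    spun <- dmap_ctx[spins$perms[s, ]]
    spearman_rho_pairwise(fc14, spun[pos])
  }, numeric(1))
  null_ok <- null[is.finite(null)]
  p <- (1 + sum(abs(null_ok) >= abs(obs))) / (length(null_ok) + 1)
  list(mi = obs, p_spin = p, n_edges = length(inc), null = null)
}

#' Classify conservative and disruptive maturational modes
#'
#' Attaches spin p-values for all cortical regions, Benjamini-Hochberg
#' q-values across regions (over whichever p is available: spin p for
#' cortex, parametric p for subcortex), and a significance flag at
#' `alpha`.
#'
#' @param mi an `mi_result` from [maturational_index()].
#' @param edges the `edge_growth` table the MI came from.
#' @param parc the parcellation.
#' @param spins optional `spin_null`; when NULL only parametric p is used.
#' @param alpha significance level on the q-value.
#' @param min_edges as in [maturational_index()].
#' @return the `mi_result` with columns `p_spin`, `q`, `significant`.
#' @export
classify_modes <- function(mi, edges, parc, spins = NULL, alpha = 0.05,
                           min_edges = 10L) {
  p_spin <- rep(NA_real_, nrow(mi))
  if (!is.null(spins)) {
    for (r in which(mi$class == "cortical" & !is.na(mi$mi))) {
      p_spin[r] <- spin_test_mi(edges, parc, mi$region[r], spins,
                                min_edges = min_edges)$p_spin
    }
  }
  mi$p_spin <- p_spin
  p_use <- ifelse(is.na(p_spin), mi$p_param, p_spin)
  q <- rep(NA_real_, nrow(mi))
  def <- which(is.finite(p_use))
  if (length(def)) q[def] <- bh_fdr(p_use[def])
  mi$q <- q
  mi$significant <- !is.na(q) & q < alpha & mi$mode != "indeterminate"
  mi
}

#' Split-half stability of the Maturational Index map
#'
#' Repeatedly splits the *subjects* (never scans) into two disjoint
#' halves, reruns edge fitting and MI estimation independently in each
#' half, and records the Spearman correlation between the two MI maps.
#'
#' @param dataset an `fc_dataset`.
#' @param parc the parcellation.
#' @param n_splits number of random half-splits (>= 1).
#' @param seed integer seed.
#' @param min_edges as in [maturational_index()].
#' @return numeric vector of between-half MI correlations, length
#'   `n_splits`; attribute `halves` records the first-half subject set of
#'   each split.
#' @export
half_split_stability <- function(dataset, parc, n_splits, seed = 1L,
                                 min_edges = 10L) {
  if (n_splits < 1L) stop_invalid("n_splits must be >= 1")
  subjects <- unique(dataset$meta$subject_id)
  if (length(subjects) < 8L) stop_invalid("need >= 8 subjects")
  with_seed(seed, {
    halves <- vector("list", n_splits)
    rhos <- vapply(seq_len(n_splits), function(k) {
      half <- sample(subjects, length(subjects) %/% 2L)
      halves[[k]] <<- half
      in_a <- dataset$meta$subject_id %in% half
      mi_ab <- lapply(list(in_a, !in_a), function(sel) {
        sub <- dataset
        sub$fc <- dataset$fc[, sel, drop = FALSE]
        sub$meta <- dataset$meta[sel, , drop = FALSE]
        fits <- fit_all_edges(sub)
        maturational_index(fits, parc, min_edges = min_edges)$mi
      })
      spearman_rho_pairwise(mi_ab[[1L]], mi_ab[[2L]])
    }, numeric(1))
    attr(rhos, "halves") <- halves
    rhos
  })
}
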