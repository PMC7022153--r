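# Spin-permutation spatial null model.
#
# The spin test builds a null distribution for spatial statistics on a
# cortical map by rotating the spherical coordinates of the cortical
# regions and reassigning values by nearest rotated neighbour. The same
# random rotation is applied to the left hemisphere and its sagittal
# mirror image to the right hemisphere, so the null preserves both the
# spatial autocorrelation of the map and its hemispheric symmetry.
# Subcortical regions have no spherical coordinates and are never spun.

# Uniform random 3D rotation via QR of a Gaussian matrix, sign-fixed
# and reflection-corrected so the distribution is Haar over SO(3).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  d[d == 0] <- 1
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# Greedy bijective nearest-neighbour assignment: pairs sorted by
# ascending distance, each original region and each rotated centroid
# used once. Returns perm with perm[k] = source region whose value
# region k receives. Processed in chunks of the sorted pair list so the
# interpreted loop only visits pairs whose row and column are still
# free; the result is identical to walking the full sorted list.
greedy_assign <- function(orig, rotated) {
  n <- nrow(orig)
  d2 <- outer(rowSums(orig^2), rowSums(rotated^2), "+") -
    2 * tcrossprod(orig, rotated)
  ord <- order(d2)
  perm <- integer(n)
  row_free <- rep(TRUE, n)
  col_free <- rep(TRUE, n)
  filled <- 0L
  chunk <- max(4L * n, 256L)
  for (start in seq(1L, length(ord), by = chunk)) {
    idx <- ord[start:min(start + chunk - 1L, length(ord))]
    r_all <- ((idx - 1L) %% n) + 1L
    c_all <- ((idx - 1L) %/% n) + 1L
    live <- row_free[r_all] & col_free[c_all]
    r_all <- r_all[live]
    c_all <- c_all[live]
    for (k in seq_along(r_all)) {
      r <- r_all[k]
      cc <- c_all[k]
      if (row_free[r] && col_free[cc]) {
        perm[r] <- cc
        row_free[r] <- FALSE
        col_free[cc] <- FALSE
        filled <- filled + 1L
      }
    }
    if (filled == n) break
  }
  perm
}

#' Generate a bank of spin permutations
#'
#' Draws `n_spins` uniform random rotations; each rotation is applied to
#' the left-hemisphere spherical coordinates and its mirror image (about
#' the sagittal plane) to the right hemisphere, and every cortical
#' region is reassigned the value of the nearest rotated centroid within
#' its own hemisphere. Duplicate nearest-neighbour assignments are
#' resolved greedily by ascending distance so every row is a bijection
#' of the cortical indices. Left regions therefore map only to left
#' regions, and right to right.
#'
#' @param parc parcellation with cortical spherical coordinates.
#' @param n_spins number of permutations (>= 1).
#' @param seed integer seed.
#' @return list of class `spin_null`: `perms` (n_spins x n_cortical
#'   integer matrix of permutations of the cortical *positions within
#'   the cortical set*), `cortical` (region indices the columns refer
#'   to), `seed`, `n_spins`.
#' @export
generate_spins <- function(parc, n_spins, seed = 1L) {
  if (n_spins < 1L) stop_invalid("n_spins must be >= 1")
  ctx <- which(parc$class == "cortical")
  sph <- as.matrix(parc[ctx, c("sph_x", "sph_y", "sph_z")])
  if (any(!is.finite(sph))) {
    stop_invalid("cortical regions must have spherical coordinates")
  }
  left <- which(parc$hemisphere[ctx] == "L")
  right <- which(parc$hemisphere[ctx] == "R")
  mirror <- diag(c(-1, 1, 1))
  with_seed(seed, {
    perms <- matrix(0L, n_spins, length(ctx))
    for (s in seq_len(n_spins)) {
      rot <- random_rotation()
      rot_r <- mirror %*% rot %*% mirror
      perm <- integer(length(ctx))
      perm[left] <- left[greedy_assign(sph[left, , drop = FALSE],
                                       sph[left, , drop = FALSE] %*% t(rot))]
      perm[right] <- right[greedy_assign(sph[right, , drop = FALSE],
                                         sph[right, , drop = FALSE] %*% t(rot_r))]
      perms[s, ] <- perm
    }
    out <- list(perms = perms, cortical = ctx, seed = as.integer(seed),
                n_spins = as.integer(n_spins))
    class(out) <- "spin_null"
    out
  })
}

#' Spin test for the spatial correlation of two cortical maps
#'
#' Observed statistic: Spearman correlation of the two maps over the
#' cortical regions where both are defined. Null distribution: the
#' first map is spun by each permutation in the bank while the second
#' stays fixed; pairs where a spun value is undefined are dropped.
#' The two-sided empirical p-value is
#' `(1 + #\{|null| >= |observed|\}) / (n_spins + 1)`, so the minimal
#' attainable p is `1 / (n_spins + 1)`.
#'
#' @param map_a,map_b numeric vectors over all regions (NA outside
#'   coverage); `map_a` is the map that gets spun.
#' @param spins a `spin_null` from [generate_spins()].
#' @return list: `rho`, `p_spin`, `p_param` (large-sample parametric p),
#'   `n` (regions used), `null` (the null correlations).
#' @export
spin_test_map_correlation <- function(map_a, map_b, spins) {
  ctx <- spins$cortical
  a <- map_a[ctx]
  b <- map_b[ctx]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L) stop_invalid("fewer than 3 shared cortical regions")
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
    stop_invalid("degenerate input: constant map")
  }
  obs <- stats::cor(a[ok], b[ok], method = "spearman")
  null <- vapply(seq_len(spins$n_spins), function(s) {
    spearman_rho_pairwise(a[spins$perms[s, ]], b)
  }, numeric(1))
  null_ok <- null[is.finite(null)]
  p <- (1 + sum(abs(null_ok) >= abs(obs))) / (length(null_ok) + 1)
  list(rho = obs, p_spin = p, p_param = spearman_p_param(obs, sum(ok)),
       n = sum(ok), null = null)
}
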