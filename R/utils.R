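#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_finite <- function(x, name) {
  if (!all(is.finite(x))) stop_invalid("'%s' contains non-finite values", name)
  invisible(x)
}

#' Unordered edge index for a set of regions
#'
#' Enumerates all unordered region pairs (i < j) in a fixed, documented
#' order: j ascends fastest, i.e. (1,2), (1,3), ..., (1,R), (2,3), ...
#' This ordering is used everywhere an edge-by-scan matrix is laid out.
#'
#' @param n_regions number of regions (>= 2).
#' @return data.frame with integer columns `i` and `j` (`i < j`),
#'   one row per edge, `n_regions * (n_regions - 1) / 2` rows.
#' @examples
#' edge_index(4)
#' @export
edge_index <- function(n_regions) {
  n_regions <- as.integer(n_regions)
  if (is.na(n_regions) || n_regions < 2L) {
    stop_invalid("edge_index() needs at least 2 regions")
  }
  i <- rep.int(seq_len(n_regions - 1L), times = (n_regions - 1L):1L)
  j <- unlist(lapply(seq_len(n_regions - 1L), function(k) (k + 1L):n_regions),
              use.names = FALSE)
  data.frame(i = i, j = j)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity (`q >= p`
#' elementwise). Inputs are validated to lie in (0, 1]; the adjustment
#' itself is the standard one from [stats::p.adjust()].
#'
#' @param p vector of p-values in (0, 1].
#' @return vector of q-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.5))
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop_invalid("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Spearman rank correlation with midranks
#'
#' Pearson correlation of average-ranked values; ties receive midranks.
#'
#' @param x,y numeric vectors of equal length >= 3, each non-constant.
#' @return the rank correlation in \[-1, 1\].
#' @examples
#' spearman_rho(c(1, 2, 2, 3), c(1, 2, 3, 4))
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  if (length(x) < 3L) stop_invalid("need at least 3 observations")
  check_finite(x, "x"); check_finite(y, "y")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_invalid("degenerate input: constant vector has no rank correlation")
  }
  stats::cor(x, y, method = "spearman")
}

# Pairwise-complete Spearman over a mask; returns NA if fewer than 3
# complete pairs or a constant side. Internal: used by the spin machinery
# where permuted values can land outside a map's coverage.
spearman_rho_pairwise <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

# Large-sample (t approximation) two-sided p-value for a Spearman rho on n
# pairs. Clamps |rho| slightly below 1 to avoid infinite t.
spearman_p_param <- function(rho, n) {
  if (!is.finite(rho) || n < 3L) return(NA_real_)
  r <- max(min(rho, 1 - 1e-12), -1 + 1e-12)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}
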