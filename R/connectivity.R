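#' Regional time-series container
#'
#' @param data volumes x regions numeric matrix, finite, >= 2 volumes.
#' @param tr_seconds repetition time (seconds).
#' @param scan_id scan identifier.
#' @param region_labels optional column labels.
#' @return list of class `regional_timeseries`.
#' @export
regional_timeseries <- function(data, tr_seconds, scan_id = "scan",
                                region_labels = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop_invalid("need >= 2 volumes")
  check_finite(data, "time series")
  if (!is.null(region_labels)) colnames(data) <- region_labels
  out <- list(data = data, tr_seconds = tr_seconds, scan_id = scan_id)
  class(out) <- "regional_timeseries"
  out
}

#' Pearson functional-connectivity matrix of one scan
#'
#' @param ts a `regional_timeseries`; every region must be non-constant.
#' @return symmetric regions x regions correlation matrix with unit
#'   diagonal (the diagonal carries no information and is excluded from
#'   all downstream summaries).
#' @export
fc_matrix <- function(ts) {
  x <- ts$data
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop_invalid("degenerate input: constant time series in region(s) %s",
                 paste(bad, collapse = ", "))
  }
  stats::cor(x)
}

#' Stack per-scan FC matrices into an edge-by-scan dataset
#'
#' Lays out the upper triangles of the per-scan matrices in the stable
#' [edge_index()] order (unordered pairs, i < j). The round trip through
#' [unstack_dataset()] is lossless.
#'
#' @param fcs list of symmetric FC matrices with identical dimension.
#' @param meta scan metadata (one row per matrix, with `scan_id`,
#'   `subject_id`, `age`, `sex`, `site`; `mean_fd` optional).
#' @return an `fc_dataset`: `fc` (edges x scans), `edges`, `meta`.
#' @export
stack_dataset <- function(fcs, meta) {
  if (length(fcs) != nrow(meta)) {
    stop_invalid("number of FC matrices (%d) and metadata rows (%d) differ",
                 length(fcs), nrow(meta))
  }
  dims <- vapply(fcs, nrow, integer(1))
  if (length(unique(dims)) != 1L) stop_invalid("FC matrices differ in region count")
  r <- dims[1L]
  ei <- edge_index(r)
  idx <- cbind(ei$i, ei$j)
  fc <- vapply(fcs, function(m) m[idx], numeric(nrow(ei)))
  colnames(fc) <- meta$scan_id
  out <- list(fc = fc, edges = ei, meta = meta)
  class(out) <- "fc_dataset"
  out
}

#' Recover per-scan FC matrices from an edge dataset
#'
#' @param dataset an `fc_dataset`.
#' @return list of symmetric matrices (unit diagonal), one per scan.
#' @export
unstack_dataset <- function(dataset) {
  ei <- dataset$edges
  r <- max(ei$j)
  lapply(seq_len(ncol(dataset$fc)), function(s) {
    m <- diag(r)
    m[cbind(ei$i, ei$j)] <- dataset$fc[, s]
    m[cbind(ei$j, ei$i)] <- dataset$fc[, s]
    m
  })
}

#' Weighted degree (connectivity strength) per region
#'
#' Mean off-diagonal correlation from each region to a partner set:
#' all other regions (`"all"`), or the block-restricted sets
#' cortico-cortical (`"cc"`), cortico-subcortical (`"cs"`),
#' subcortico-cortical (`"sc"`) and subcortico-subcortical (`"ss"`).
#' Block strengths are defined for source regions of the matching class
#' and are `NA` elsewhere; raw correlations are averaged (no Fisher
#' transform). The diagonal never contributes.
#'
#' @param fc symmetric regions x regions FC matrix.
#' @param parc parcellation with a `class` column aligned to `fc`.
#' @param block one of "all", "cc", "cs", "sc", "ss".
#' @return numeric vector of per-region strengths.
#' @export
node_strength <- function(fc, parc, block = c("all", "cc", "cs", "sc", "ss")) {
  block <- match.arg(block)
  r <- nrow(fc)
  if (nrow(parc) != r) stop_invalid("parcellation and FC matrix disagree")
  is_ctx <- parc$class == "cortical"
  src <- switch(block, all = rep(TRUE, r), cc = is_ctx, cs = is_ctx,
                sc = !is_ctx, ss = !is_ctx)
  tgt <- switch(block, all = rep(TRUE, r), cc = is_ctx, cs = !is_ctx,
                sc = is_ctx, ss = !is_ctx)
  out <- rep(NA_real_, r)
  for (k in which(src)) {
    partners <- which(tgt)
    partners <- partners[partners != k]
    if (!length(partners)) {
      stop_invalid("empty partner set for region %d in block '%s'", k, block)
    }
    out[k] <- mean(fc[k, partners])
  }
  names(out) <- parc$label
  out
}

#' Cortical connectivity profile of a bilateral subcortical nucleus
#'
#' Mean FC between each cortical region and the (up to two) regions of
#' one bilateral subcortical pair.
#'
#' @param fc symmetric FC matrix.
#' @param parc parcellation with `nucleus` labels for subcortical rows.
#' @param nucleus nucleus name (as in `parc$nucleus`).
#' @return named numeric vector, one value per cortical region.
#' @export
cortex_to_nucleus_profile <- function(fc, parc, nucleus) {
  rows <- which(!is.na(parc$nucleus) & parc$nucleus == nucleus)
  if (!length(rows)) stop_invalid("unknown nucleus '%s'", nucleus)
  ctx <- which(parc$class == "cortical")
  prof <- colMeans(fc[rows, ctx, drop = FALSE])
  names(prof) <- parc$label[ctx]
  prof
}
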