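#' Maturational Index profile by categorical class
#'
#' Descriptive per-class summaries of MI over a categorical annotation
#' map (cytoarchitectonic classes, functional networks, ...); classes
#' are ordered by decreasing mean MI. When the parcellation includes
#' subcortical regions carrying a class label (e.g. "subcortical"), they
#' appear as an additional class.
#'
#' @param mi an `mi_result`.
#' @param classes factor or character vector of class labels per region
#'   (NA = region not covered).
#' @return data.frame: `class`, `n`, `mean_mi`, `median_mi`, `q25`,
#'   `q75`, ordered by decreasing mean; classes with < 2 regions with
#'   defined MI are dropped with a warning.
#' @export
class_profile <- function(mi, classes) {
  if (length(classes) != nrow(mi)) stop_invalid("classes/mi length mismatch")
  ok <- !is.na(mi$mi) & !is.na(classes)
  cls <- unique(as.character(classes[ok]))
  if (length(cls) < 2L) stop_invalid("need >= 2 classes with defined MI")
  rows <- lapply(cls, function(cl) {
    v <- mi$mi[ok & as.character(classes) == cl]
    if (length(v) < 2L) return(NULL)
    data.frame(class = cl, n = length(v), mean_mi = mean(v),
               median_mi = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  })
  dropped <- cls[vapply(rows, is.null, logical(1))]
  if (length(dropped)) {
    warning(sprintf("dropping class(es) with < 2 members: %s",
                    paste(dropped, collapse = ", ")))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_mi), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Colocate the MI map with a battery of annotation maps
#'
#' For each continuous annotation map, the Spearman correlation with the
#' MI map over their shared cortical coverage, a spin p-value
#' ([spin_test_map_correlation()]; the MI map is spun, the annotation
#' map stays fixed), a parametric p, and Benjamini-Hochberg q-values
#' over the whole battery. Maps sharing fewer than `min_overlap` regions
#' with the MI mask are skipped with a warning and the battery size
#' recorded accordingly.
#'
#' @param mi an `mi_result`.
#' @param maps named list of numeric per-region vectors.
#' @param spins a `spin_null`.
#' @param min_overlap minimum shared regions per comparison.
#' @return data.frame of class `colocation_table`: `map`, `n`, `rho`,
#'   `p_param`, `p_spin`, `q`; attribute `battery_size` gives the number
#'   of comparisons the FDR was computed over.
#' @export
colocate_battery <- function(mi, maps, spins, min_overlap = 10L) {
  mi_map <- rep(NA_real_, nrow(mi))
  mi_map[mi$class == "cortical"] <- mi$mi[mi$class == "cortical"]
  rows <- list()
  for (nm in names(maps)) {
    m <- maps[[nm]]
    if (!is.numeric(m)) next                      # categorical maps skipped
    shared <- sum(is.finite(mi_map) & is.finite(m))
    if (shared < min_overlap) {
      warning(sprintf("map '%s' shares only %d regions with MI: skipped",
                      nm, shared))
      next
    }
    st <- spin_test_map_correlation(mi_map, m, spins)
    rows[[nm]] <- data.frame(map = nm, n = st$n, rho = st$rho,
                             p_param = st$p_param, p_spin = st$p_spin,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop_invalid("no map had sufficient overlap with MI")
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p_spin)
  rownames(out) <- NULL
  attr(out, "battery_size") <- nrow(out)
  class(out) <- c("colocation_table", "data.frame")
  out
}
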