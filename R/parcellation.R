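#' Construct a synthetic bilateral parcellation
#'
#' Builds a cortical parcellation of `n_cortical` regions, plus
#' `n_subcortical` deep-brain regions with volumetric coordinates only.
#' Each hemisphere carries its own *full* unit sphere of spherical
#' coordinates (the surface-inflation convention the spin test needs: a
#' random rotation maps a hemisphere sphere onto itself, so rotated
#' points always have nearby match candidates); centroids form a
#' quasi-uniform Fibonacci lattice, randomly rotated as a whole by the
#' seed, and the right hemisphere is the sagittal mirror image of the
#' left. Volumetric centroids scale
#' each hemisphere sphere to 45 mm and offset it +/-50 mm laterally, so
#' left regions have x < 0 and right regions x > 0; subcortical
#' centroids sit within 30 mm of the origin, between the hemispheres.
#' When `n_subcortical` is even, subcortical
#' regions form bilateral nucleus pairs (labels `sub<k>_L/R` sharing a
#' `nucleus` name); an odd count leaves one unilateral midline nucleus.
#'
#' @param n_cortical even number of cortical regions, >= 8.
#' @param n_subcortical number of subcortical regions, >= 0.
#' @param seed integer seed; the same seed reproduces the geometry.
#' @return data.frame of class `parcellation` with one row per region:
#'   `region` (1-based id), `label`, `hemisphere` ("L"/"R"/"none"),
#'   `class` ("cortical"/"subcortical"), `nucleus` (shared name of a
#'   bilateral subcortical pair, NA for cortex), volumetric centroid
#'   `x`,`y`,`z` (mm) and unit-sphere coordinates `sph_x`,`sph_y`,`sph_z`
#'   (NA for subcortical regions).
#' @examples
#' parc <- make_parcellation(8, 2, seed = 1)
#' table(parc$class, parc$hemisphere)
#' @export
make_parcellation <- function(n_cortical, n_subcortical, seed = 1L) {
  n_cortical <- as.integer(n_cortical)
  n_subcortical <- as.integer(n_subcortical)
  if (is.na(n_cortical) || n_cortical < 8L || n_cortical %% 2L != 0L) {
    stop_invalid("n_cortical must be an even integer >= 8 (got %s)", n_cortical)
  }
  if (is.na(n_subcortical) || n_subcortical < 0L) {
    stop_invalid("n_subcortical must be >= 0")
  }
  with_seed(seed, {
    n_half <- n_cortical %/% 2L
    # left-hemisphere inflation: quasi-uniform Fibonacci lattice on the
    # full unit sphere, randomly rotated as a whole by the seed. Parcel
    # centroids tile the cortex at near-constant density; clustered
    # random points would instead give the spin test's bijective
    # nearest-neighbour reassignment a heavy error tail wherever density
    # fluctuates, degrading its calibration.
    idx <- seq_len(n_half) - 0.5
    phi <- acos(1 - 2 * idx / n_half)
    theta <- pi * (1 + sqrt(5)) * idx
    pts <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
    left <- pts %*% t(random_rotation())
    right <- left
    right[, 1L] <- -right[, 1L]
    sph <- rbind(left, right)
    hemi <- rep(c("L", "R"), each = n_half)
    vol <- sph * 45
    vol[, 1L] <- vol[, 1L] + ifelse(hemi == "L", -50, 50)
    lab <- c(sprintf("ctx%03d_L", seq_len(n_half)),
             sprintf("ctx%03d_R", seq_len(n_half)))

    if (n_subcortical > 0L) {
      n_pair <- n_subcortical %/% 2L
      n_mid <- n_subcortical %% 2L
      nuclei <- sprintf("sub%02d", seq_len(n_pair + n_mid))
      sc_left <- matrix(stats::runif(3L * (n_pair + n_mid), -1, 1), ncol = 3L)
      sc_left <- sc_left / pmax(sqrt(rowSums(sc_left^2)), 1e-9) *
        stats::runif(n_pair + n_mid, 8, 30)
      sc_left[, 1L] <- -abs(sc_left[, 1L])
      sc_vol <- NULL; sc_hemi <- character(0); sc_lab <- character(0)
      sc_nuc <- character(0)
      if (n_pair > 0L) {
        l <- sc_left[seq_len(n_pair), , drop = FALSE]
        r <- l; r[, 1L] <- -r[, 1L]
        sc_vol <- rbind(l, r)
        sc_hemi <- rep(c("L", "R"), each = n_pair)
        sc_lab <- c(paste0(nuclei[seq_len(n_pair)], "_L"),
                    paste0(nuclei[seq_len(n_pair)], "_R"))
        sc_nuc <- rep(nuclei[seq_len(n_pair)], 2L)
      }
      if (n_mid == 1L) {
        m <- sc_left[n_pair + 1L, , drop = FALSE]
        m[, 1L] <- 0
        sc_vol <- rbind(sc_vol, m)
        sc_hemi <- c(sc_hemi, "none")
        sc_lab <- c(sc_lab, nuclei[n_pair + 1L])
        sc_nuc <- c(sc_nuc, nuclei[n_pair + 1L])
      }
      vol <- rbind(vol, sc_vol)
      sph <- rbind(sph, matrix(NA_real_, n_subcortical, 3L))
      hemi <- c(hemi, sc_hemi)
      lab <- c(lab, sc_lab)
      nucleus <- c(rep(NA_character_, n_cortical), sc_nuc)
    } else {
      nucleus <- rep(NA_character_, n_cortical)
    }

    parc <- data.frame(
      region = seq_len(n_cortical + n_subcortical),
      label = lab,
      hemisphere = hemi,
      class = rep(c("cortical", "subcortical"), c(n_cortical, n_subcortical)),
      nucleus = nucleus,
      x = vol[, 1L], y = vol[, 2L], z = vol[, 3L],
      sph_x = sph[, 1L], sph_y = sph[, 2L], sph_z = sph[, 3L],
      stringsAsFactors = FALSE
    )
    class(parc) <- c("parcellation", "data.frame")
    parc
  })
}

#' Euclidean inter-centroid distance per edge
#'
#' @param parc parcellation from [make_parcellation()] (or any data.frame
#'   with volumetric `x`,`y`,`z` columns).
#' @return numeric vector of distances (mm), one per unordered edge in
#'   [edge_index()] order.
#' @export
edge_distance <- function(parc) {
  if (any(!is.finite(parc$x)) || any(!is.finite(parc$y)) ||
      any(!is.finite(parc$z))) {
    stop_invalid("missing volumetric centroid coordinates")
  }
  xyz <- as.matrix(parc[, c("x", "y", "z")])
  ei <- edge_index(nrow(parc))
  sqrt(rowSums((xyz[ei$i, , drop = FALSE] - xyz[ei$j, , drop = FALSE])^2))
}
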