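# Thresholding regimes and the hemispheric split.
#
# Two regimes are supported, mirroring the two analysis arms:
#   * strength: an absolute weight cutoff shared across subjects (preserves
#     absolute network organization; subjects may differ in density);
#   * density: keep the top fraction of edges by weight and (optionally)
#     rescale surviving weights to overall mean 1, so all subjects share the
#     same density and overall strength (relative organization).
# Negative functional correlations are zeroed before either procedure:
# weighted path-length metrics are undefined for negative weights.

#' Threshold scheme
#'
#' @param mode "strength" (absolute weight cutoff) or "density" (fixed edge
#'   fraction grid with overall-strength normalization).
#' @param strength_threshold absolute cutoff; `NULL` uses the modality
#'   default at apply time (functional r > 0.2; structural count > 2.5,
#'   i.e. streamline counts of 3 or more). Comparison is strictly greater.
#' @param density_grid increasing densities in (0, 1]; default 0.08-0.15 in
#'   steps of 0.01. The grid minimum must satisfy [check_min_density()] for
#'   45-node hemispheric networks.
#' @param normalize_overall_mean rescale surviving weights to mean 1
#'   (density mode; default TRUE).
#' @return a list of class `threshold_scheme`.
#' @export
threshold_scheme <- function(mode = c("strength", "density"),
                             strength_threshold = NULL,
                             density_grid = seq(0.08, 0.15, by = 0.01),
                             normalize_overall_mean = TRUE) {
  mode <- match.arg(mode)
  if (mode == "density") {
    if (any(density_grid <= 0 | density_grid > 1)) {
      stop("densities must lie in (0, 1]")
    }
    if (is.unsorted(density_grid, strictly = TRUE)) {
      stop("density grid must be strictly increasing")
    }
    check_min_density(45, grid = density_grid)
  }
  structure(list(mode = mode, strength_threshold = strength_threshold,
                 density_grid = density_grid,
                 normalize_overall_mean = normalize_overall_mean),
            class = "threshold_scheme")
}

#' Default absolute strength threshold per modality
#'
#' There is no standardized absolute cutoff in the literature; these
#' defaults (r > 0.2 for correlations, more than 2.5 i.e. at least 3
#' streamlines for counts) are declared assumptions, configurable in
#' [threshold_scheme()].
#'
#' @param modality "functional" or "structural".
#' @return numeric threshold.
#' @export
default_strength_threshold <- function(modality = c("functional", "structural")) {
  modality <- match.arg(modality)
  if (modality == "functional") 0.2 else 2.5
}

#' Absolute-strength thresholding
#'
#' Zeroes negative functional correlations, then retains entries strictly
#' greater than the threshold with their original weights.
#'
#' @param m a `wholebrain_matrix` (or plain matrix plus `modality`).
#' @param threshold absolute cutoff; `NULL` uses the modality default.
#' @param modality used only when `m` is a plain matrix.
#' @return thresholded object of the same kind as `m`.
#' @export
threshold_strength <- function(m, threshold = NULL, modality = NULL) {
  is_wb <- inherits(m, "wholebrain_matrix")
  if (is_wb) modality <- m$modality
  if (is.null(modality)) stop("modality required for plain matrices")
  if (is.null(threshold)) threshold <- default_strength_threshold(modality)
  if (modality == "structural" && threshold < 0) {
    stop("structural threshold must be non-negative")
  }
  if (modality == "functional" && threshold >= 1) {
    stop("functional threshold must be below 1 (r units)")
  }
  w <- if (is_wb) m$weights else m
  if (modality == "functional") w[w < 0] <- 0
  w[w <= threshold] <- 0
  if (is_wb) {
    m$weights <- w
    m
  } else w
}

#' Fixed-density thresholding with overall-strength normalization
#'
#' Retains the top `floor(density * E_max)` edges by weight (`E_max` =
#' `n(n-1)/2`), zeroing the rest; negative functional entries are removed
#' first. Ties at the cutoff are broken deterministically by
#' (weight descending, row index, column index). With `normalize = TRUE` the
#' surviving weights are divided by their mean, so the overall mean
#' connectivity strength is exactly 1.
#'
#' @param m a `wholebrain_matrix` or plain matrix.
#' @param density target edge fraction in (0, 1].
#' @param normalize rescale surviving weights to mean 1 (default TRUE).
#' @param modality used only when `m` is a plain matrix (for the negative-
#'   correlation rule); `NULL` on a plain matrix skips that rule for
#'   non-negative input.
#' @return thresholded object of the same kind as `m`; attribute
#'   `realized_density` gives the achieved edge fraction.
#' @export
threshold_density <- function(m, density, normalize = TRUE, modality = NULL) {
  if (density <= 0 || density > 1) stop("density must lie in (0, 1]")
  is_wb <- inherits(m, "wholebrain_matrix")
  if (is_wb) modality <- m$modality
  w <- if (is_wb) m$weights else m
  if (identical(modality, "functional")) w[w < 0] <- 0
  if (any(w < 0)) stop("negative weights present; specify modality = 'functional'")
  n <- nrow(w)
  ut <- .ut(n)
  e_max <- n * (n - 1) / 2
  k <- floor(density * e_max)
  idx <- which(ut, arr.ind = TRUE)
  wv <- w[ut]
  pos <- which(wv > 0)
  ord <- pos[order(-wv[pos], idx[pos, 1], idx[pos, 2])]
  keep <- ord[seq_len(min(k, length(ord)))]
  out <- matrix(0, n, n)
  sel <- cbind(idx[keep, 1, drop = FALSE], idx[keep, 2, drop = FALSE])
  out[sel] <- wv[keep]
  if (normalize && length(keep) > 0) {
    out[sel] <- out[sel] / mean(out[sel])
  }
  out <- out + t(out)
  attr(out, "realized_density") <- length(keep) / e_max
  if (is_wb) {
    rd <- attr(out, "realized_density")
    attr(out, "realized_density") <- NULL
    m$weights <- out
    attr(m, "realized_density") <- rd
    m
  } else out
}

#' Minimum admissible density under the mean-degree rule
#'
#' A density `d` is admissible for an `n`-node network when the implied mean
#' degree `d * (n - 1)` exceeds `2 * log10(n)`. Returns the smallest
#' admissible density on the grid (or on the multiples of `step` when no
#' grid is given); errors when the supplied grid starts below the admissible
#' minimum.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param grid optional density grid to validate.
#' @param step grid step used when `grid` is `NULL` (default 0.01).
#' @return smallest admissible density.
#' @export
check_min_density <- function(n_nodes, grid = NULL, step = 0.01) {
  if (n_nodes < 2) stop("n_nodes must be >= 2")
  lim <- 2 * log10(n_nodes) / (n_nodes - 1)
  if (is.null(grid)) {
    k <- ceiling(lim / step)
    d <- k * step
    if (d * (n_nodes - 1) <= 2 * log10(n_nodes)) d <- d + step
    return(d)
  }
  ok <- grid * (n_nodes - 1) > 2 * log10(n_nodes)
  if (!ok[1]) {
    stop("density grid starts at ", grid[1],
         " but the mean-degree rule requires more than ", format(lim),
         " for ", n_nodes, " nodes")
  }
  min(grid[ok])
}

#' Split a whole-brain matrix into hemispheric networks
#'
#' Extracts the two within-hemisphere blocks as 45x45 (generally m x m)
#' hemispheric networks and the cross block as an inter-hemispheric field
#' indexed (left region, right region). No weight is lost or duplicated:
#' counting each undirected edge once, the three parts partition the
#' whole-brain weight sum.
#'
#' @param m a (thresholded) `wholebrain_matrix` or plain matrix.
#' @param atlas an `atlas_table` matching the matrix dimension.
#' @return list with elements `L`, `R` (class `hemispheric_network`: fields
#'   subject_id, modality, hemisphere, region_ids, weights, density) and
#'   `inter` (class `inter_field`: weights plus left/right region ids and
#'   the homotopic column index per left row).
#' @export
split_hemispheres <- function(m, atlas) {
  is_wb <- inherits(m, "wholebrain_matrix")
  w <- if (is_wb) m$weights else m
  subject_id <- if (is_wb) m$subject_id else NA_character_
  modality <- if (is_wb) m$modality else NA_character_
  if (nrow(w) != nrow(atlas)) {
    stop("matrix dimension (", nrow(w), ") does not match atlas (",
         nrow(atlas), ")")
  }
  lid <- atlas_hemi_ids(atlas, "L")
  rid <- atlas_hemi_ids(atlas, "R")
  partner <- atlas_partner(atlas)
  mk_net <- function(ids, hemi) {
    hw <- w[ids, ids, drop = FALSE]
    nh <- length(ids)
    structure(list(subject_id = subject_id, modality = modality,
                   hemisphere = hemi, region_ids = ids, weights = hw,
                   density = sum(hw[.ut(nh)] > 0) / (nh * (nh - 1) / 2)),
              class = "hemispheric_network")
  }
  inter_w <- w[lid, rid, drop = FALSE]
  # column (right region) paired with each left row
  homo_col <- match(partner[lid], rid)
  inter <- structure(list(subject_id = subject_id, modality = modality,
                          left_ids = lid, right_ids = rid,
                          weights = inter_w, homotopic_col = homo_col),
                     class = "inter_field")
  list(L = mk_net(lid, "L"), R = mk_net(rid, "R"), inter = inter)
}
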