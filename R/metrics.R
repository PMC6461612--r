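# Weighted network metrics.
#
# Conventions (the Rubinov-Sporns / GRETNA lineage): weights are first
# divided by the network's maximum weight, shortest-path edge lengths are
# the reciprocal 1/w of the normalized weights, efficiency is the mean
# inverse shortest-path distance (disconnected pairs contribute 0), and
# local efficiency averages the global efficiency of each node's neighbor
# subgraph with the original (normalized) weights. Under these conventions
# both efficiencies lie in [0, 1] and are invariant to a global rescaling
# of the weights.

.as_weights <- function(net) {
  if (inherits(net, "hemispheric_network")) return(net$weights)
  if (inherits(net, "wholebrain_matrix")) return(net$weights)
  if (is.matrix(net)) return(net)
  stop("expected a network object or a weight matrix")
}

# all-pairs shortest-path distances for edge lengths 1/w, by vectorized
# Floyd-Warshall (dense networks of <= 90 nodes: faster than building a
# graph object per call)
.sp_dist <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  pos <- w > 0
  d[pos] <- 1 / w[pos]
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- d[, k]
    if (all(is.infinite(dk[-k]))) next
    d <- pmin(d, dk + rep(d[k, ], each = n))
  }
  d
}

# efficiency of a weight matrix whose weights are already on the final
# scale (no re-normalization); lengths = 1/w
.eff_core <- function(w) {
  n <- nrow(w)
  if (n < 2) return(0)
  if (all(w == 0)) return(0)
  d <- .sp_dist(w)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted global efficiency
#'
#' Mean inverse shortest-path distance over all node pairs, with weights
#' normalized by the network maximum and edge lengths 1/w. Empty networks
#' return 0; disconnected pairs contribute 0.
#'
#' @param net a `hemispheric_network`, `wholebrain_matrix` or non-negative
#'   weight matrix.
#' @param normalize_max divide weights by their maximum first (default TRUE).
#' @return efficiency in \[0, 1\] (when `normalize_max` is on).
#' @export
global_efficiency <- function(net, normalize_max = TRUE) {
  w <- .as_weights(net)
  if (any(w < 0)) stop("weights must be non-negative")
  mx <- max(w)
  if (mx == 0) return(0)
  if (normalize_max) w <- w / mx
  .eff_core(w)
}

#' Weighted local efficiency
#'
#' Mean over nodes of the global efficiency of the node's neighbor subgraph,
#' computed on the original (max-normalized) weights. Nodes with fewer than
#' two neighbors contribute 0.
#'
#' @inheritParams global_efficiency
#' @return local efficiency in \[0, 1\] (when `normalize_max` is on).
#' @export
local_efficiency <- function(net, normalize_max = TRUE) {
  w <- .as_weights(net)
  if (any(w < 0)) stop("weights must be non-negative")
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(0)
  if (normalize_max) w <- w / mx
  eff <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) next
    eff[i] <- .eff_core(w[nb, nb, drop = FALSE])
  }
  mean(eff)
}

# one degree-preserving null: Maslov-Sneppen rewiring of the binary
# topology, original weight multiset reassigned to the rewired edges at
# random. Complete (or otherwise unrewirable) graphs keep their topology and
# only shuffle weights.
.null_network <- function(w, n_swaps_factor = 10) {
  n <- nrow(w)
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected",
                                           diag = FALSE)
  ne <- igraph::ecount(g)
  if (ne >= 2 && ne < n * (n - 1) / 2) {
    g <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                  niter = n_swaps_factor * ne))
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  wv <- w[.ut(n)]
  wv <- wv[wv > 0]
  wv <- sample(wv)
  out <- matrix(0, n, n)
  out[el] <- wv
  out[el[, c(2, 1), drop = FALSE]] <- wv
  out
}

#' Random-network-normalized efficiencies
#'
#' Ratios of the network's global and local efficiency to the mean over
#' degree-preserving random nulls (Maslov-Sneppen edge swaps, 10x edge count
#' successful swaps, weight multiset shuffled onto the rewired topology).
#' Small-world organization shows as `e_loc_norm > 1` with
#' `e_glob_norm` near 1. Complete graphs cannot be rewired; their nulls are
#' weight shuffles only (a warning is raised).
#'
#' @param net network or weight matrix.
#' @param n_nulls number of null networks (default 100).
#' @param seed optional seed for the null ensemble (restores the caller's
#'   RNG state afterwards).
#' @return list with `e_glob_norm`, `e_loc_norm`, `e_glob`, `e_loc`,
#'   `n_nulls`.
#' @export
normalized_efficiencies <- function(net, n_nulls = 100, seed = NULL) {
  w <- .as_weights(net)
  if (any(w < 0)) stop("weights must be non-negative")
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) {
    return(list(e_glob_norm = NA_real_, e_loc_norm = NA_real_,
                e_glob = 0, e_loc = 0, n_nulls = n_nulls))
  }
  wn <- w / mx
  ne <- sum(wn[.ut(n)] > 0)
  if (ne == n * (n - 1) / 2) {
    warning("complete graph cannot be rewired; nulls shuffle weights only")
  }
  eg <- .eff_core(wn)
  el <- local_efficiency(wn, normalize_max = FALSE)
  sims <- with_seed(seed, {
    vapply(seq_len(n_nulls), function(b) {
      nw <- .null_network(wn)
      c(.eff_core(nw), local_efficiency(nw, normalize_max = FALSE))
    }, numeric(2))
  })
  list(e_glob_norm = eg / mean(sims[1, ]),
       e_loc_norm = el / mean(sims[2, ]),
       e_glob = eg, e_loc = el, n_nulls = n_nulls)
}

#' Connection-class summary for one subject and modality
#'
#' Sums of surviving weights by connection class: left and right
#' intra-hemispheric, homotopic (atlas-partner pairs) and heterotopic
#' inter-hemispheric; each undirected edge counted once. With
#' `mode = "mean"` sums are divided by the pair count of each class.
#'
#' @param L,R `hemispheric_network`s from [split_hemispheres()].
#' @param inter the matching `inter_field`.
#' @param mode "sum" (default) or "mean".
#' @return one-row data.frame: subject_id, modality, intra_left,
#'   intra_right, homotopic, heterotopic.
#' @export
classify_connections <- function(L, R, inter, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  nh <- nrow(L$weights)
  ut <- .ut(nh)
  homo_idx <- cbind(seq_len(nh), inter$homotopic_col)
  homo <- sum(inter$weights[homo_idx])
  total_inter <- sum(inter$weights)
  res <- data.frame(subject_id = L$subject_id, modality = L$modality,
                    intra_left = sum(L$weights[ut]),
                    intra_right = sum(R$weights[ut]),
                    homotopic = homo,
                    heterotopic = total_inter - homo,
                    stringsAsFactors = FALSE)
  if (mode == "mean") {
    np <- nh * (nh - 1) / 2
    res$intra_left <- res$intra_left / np
    res$intra_right <- res$intra_right / np
    res$homotopic <- res$homotopic / nh
    res$heterotopic <- res$heterotopic / (nh * nh - nh)
  }
  res
}

#' Intra- and inter-hemispheric nodal degree
#'
#' Weighted degree (strength) of each region within its own hemisphere and
#' towards the opposite hemisphere. With `binary = TRUE`, edge counts are
#' returned instead.
#'
#' @param L,R `hemispheric_network`s.
#' @param inter matching `inter_field`.
#' @param atlas the atlas (for region labels).
#' @param binary count edges instead of summing weights.
#' @return data.frame: subject_id, modality, hemisphere, region_id, region,
#'   intra_degree, inter_degree.
#' @export
nodal_degrees <- function(L, R, inter, atlas, binary = FALSE) {
  wl <- L$weights; wr <- R$weights; wi <- inter$weights
  if (binary) {
    wl <- (wl > 0) + 0; wr <- (wr > 0) + 0; wi <- (wi > 0) + 0
  }
  mk <- function(ids, hemi, intra, inter_deg) {
    data.frame(subject_id = L$subject_id, modality = L$modality,
               hemisphere = hemi, region_id = ids,
               region = atlas$abbreviation[ids],
               intra_degree = intra, inter_degree = inter_deg,
               stringsAsFactors = FALSE)
  }
  rbind(mk(L$region_ids, "L", rowSums(wl), rowSums(wi)),
        mk(R$region_ids, "R", rowSums(wr), colSums(wi)))
}

#' Area under a metric-versus-density curve
#'
#' Trapezoidal integral of per-density metric values over the density grid,
#' the summary fed to statistics in the density-thresholding arm.
#'
#' @param values metric values, one per grid density.
#' @param grid density grid.
#' @return the integral.
#' @export
auc_over_densities <- function(values, grid) {
  if (length(values) != length(grid)) {
    stop("need exactly one value per grid density")
  }
  .trapz(grid, values)
}
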