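# Functional-structural coupling: the number of region pairs connected in
# both modalities (amount) and the correlation between transformed weights
# on those pairs (degree). Functional weights enter as Fisher z values;
# structural weights are resampled into a normal distribution by the
# rank-based inverse-normal (Blom) transform, which makes the degree
# invariant to any strictly monotone rescaling of streamline counts.

# extract comparable weight containers; returns list(weights, pairs_mask)
.coupling_weights <- function(net) {
  if (inherits(net, "hemispheric_network")) {
    w <- net$weights
    list(w = w, mask = .ut(nrow(w)))
  } else if (inherits(net, "inter_field")) {
    w <- net$weights
    list(w = w, mask = matrix(TRUE, nrow(w), ncol(w)))
  } else if (is.matrix(net)) {
    if (nrow(net) == ncol(net)) list(w = net, mask = .ut(nrow(net)))
    else list(w = net, mask = matrix(TRUE, nrow(net), ncol(net)))
  } else stop("expected a network, inter_field, or matrix")
}

#' Coupling amount
#'
#' Number of region pairs with nonzero weight in both the functional and the
#' structural network of the same scope (both thresholded under the study
#' scheme). For square/hemispheric inputs pairs are unordered (upper
#' triangle); for inter-hemispheric fields all left-by-right entries count.
#'
#' @param f_net functional network (`hemispheric_network`, `inter_field`, or
#'   matrix).
#' @param s_net structural network of the same scope and dimension.
#' @return integer count of simultaneously connected pairs.
#' @export
coupling_amount <- function(f_net, s_net) {
  f <- .coupling_weights(f_net)
  s <- .coupling_weights(s_net)
  if (!identical(dim(f$w), dim(s$w))) {
    stop("functional and structural networks have different node sets")
  }
  sum(f$w > 0 & s$w > 0 & f$mask)
}

#' Coupling degree
#'
#' Pearson correlation, over the simultaneously connected pairs, between
#' Fisher-z-transformed functional weights and rank-normal (Blom) scores of
#' the structural weights. Undefined (NA) when fewer than `min_overlap`
#' pairs overlap or when either transformed vector has zero variance.
#'
#' @inheritParams coupling_amount
#' @param min_overlap smallest overlap for which a correlation is reported
#'   (default 3).
#' @return correlation in \[-1, 1\], or NA with attribute
#'   `undefined = TRUE`.
#' @export
coupling_degree <- function(f_net, s_net, min_overlap = 3) {
  f <- .coupling_weights(f_net)
  s <- .coupling_weights(s_net)
  if (!identical(dim(f$w), dim(s$w))) {
    stop("functional and structural networks have different node sets")
  }
  ov <- f$w > 0 & s$w > 0 & f$mask
  if (sum(ov) < min_overlap) {
    return(structure(NA_real_, undefined = TRUE))
  }
  fz <- fisher_z(f$w[ov])
  sz <- rank_normal(s$w[ov])
  if (stats::sd(fz) == 0 || stats::sd(sz) == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  stats::cor(fz, sz)
}

#' Per-subject coupling results for all scopes
#'
#' Computes coupling amount and degree for the left and right
#' intra-hemispheric networks and the inter-hemispheric field of one
#' subject.
#'
#' @param f_split,s_split outputs of [split_hemispheres()] for the
#'   thresholded functional and structural matrices of one subject.
#' @return data.frame: subject_id, scope (intra_L/intra_R/inter), amount,
#'   degree, n_overlap.
#' @export
coupling_results <- function(f_split, s_split) {
  one <- function(f, s, scope) {
    amt <- coupling_amount(f, s)
    deg <- coupling_degree(f, s)
    data.frame(subject_id = f_split$L$subject_id, scope = scope,
               amount = amt, degree = as.numeric(deg), n_overlap = amt,
               stringsAsFactors = FALSE)
  }
  rbind(one(f_split$L, s_split$L, "intra_L"),
        one(f_split$R, s_split$R, "intra_R"),
        one(f_split$inter, s_split$inter, "inter"))
}
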