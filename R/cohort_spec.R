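# Specification object for the synthetic cohort generator.

#' Synthetic cohort specification
#'
#' Parameters of the generative model for paired functional/structural
#' cohorts. Defaults emulate the study conditions downstream modules are
#' designed for: two groups of 35 subjects, 90 regions, a depression-related
#' multiplicative reduction of functional (but not structural) connectivity,
#' a mild rightward connectivity advantage in both modalities, strongly
#' enhanced homotopic connections, and a controllable cross-modal coupling.
#'
#' @param n_per_group subjects per group (default 35).
#' @param n_regions even region count (default 90; interleaved hemisphere
#'   convention: odd left, even right).
#' @param t_points functional time-series length used to sample the Pearson
#'   correlation matrix (default 200).
#' @param base_fc mean within-hemisphere population correlation (default 0.2).
#' @param inter_base_factor heterotopic inter-hemispheric correlations equal
#'   `base_fc * inter_base_factor` (default 0.75).
#' @param homotopic_boost additive correlation for homotopic pairs on top of
#'   the heterotopic level (default 0.45).
#' @param asym_factor multiplicative right-over-left scaling (>= 1) of
#'   intra-hemispheric connectivity in both modalities (default 1.08).
#' @param mdd_fc_effect multiplicative reduction of functional correlations in
#'   the MDD group (default 0.85; 1 = null).
#' @param mdd_struct_effect multiplicative structural effect in MDD (default
#'   1 = structurally intact).
#' @param coupling_rho target cross-modal correlation, i.e. the expected
#'   measured coupling degree (Fisher-z functional vs rank-normal structural
#'   weights on shared edges) at the given `t_points` (default 0.3).
#' @param struct_density expected structural edge density (default 0.25).
#' @param homotopic_density_boost additive edge-existence probability for
#'   homotopic structural connections (default 0.5).
#' @param homotopic_fiber_factor multiplicative streamline-count enhancement
#'   on homotopic structural edges (default 8).
#' @param fiber_scale mean streamline count on existing heterotopic/intra
#'   edges (default 50).
#' @param fiber_dispersion negative-binomial size parameter of streamline
#'   counts (default 5; `Inf` gives deterministic counts `round(mu)`, the
#'   noise-free limit).
#' @param noise_sd SD of the subject-level shift of functional correlations
#'   (default 0.02). A single standard-normal latent per subject drives both
#'   this shift and (via `hamd_slope`) the HAMD score, planting a recoverable
#'   positive brain-clinical association.
#' @param hamd_slope HAMD points per SD of the subject latent, MDD group only
#'   (default 2; 0 disables the planted brain-clinical correlation).
#' @param seed integer RNG seed.
#' @return a validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 35, n_regions = 90, t_points = 200,
                        base_fc = 0.2, inter_base_factor = 0.75,
                        homotopic_boost = 0.45, asym_factor = 1.08,
                        mdd_fc_effect = 0.85, mdd_struct_effect = 1,
                        coupling_rho = 0.3, struct_density = 0.25,
                        homotopic_density_boost = 0.5,
                        homotopic_fiber_factor = 8,
                        fiber_scale = 50, fiber_dispersion = 5,
                        noise_sd = 0.02, hamd_slope = 2, seed = 1L) {
  spec <- list(n_per_group = n_per_group, n_regions = n_regions,
               t_points = t_points, base_fc = base_fc,
               inter_base_factor = inter_base_factor,
               homotopic_boost = homotopic_boost, asym_factor = asym_factor,
               mdd_fc_effect = mdd_fc_effect,
               mdd_struct_effect = mdd_struct_effect,
               coupling_rho = coupling_rho, struct_density = struct_density,
               homotopic_density_boost = homotopic_density_boost,
               homotopic_fiber_factor = homotopic_fiber_factor,
               fiber_scale = fiber_scale,
               fiber_dispersion = fiber_dispersion,
               noise_sd = noise_sd, hamd_slope = hamd_slope,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
}

#' Validate a cohort specification
#' @param spec list of generator parameters.
#' @return the validated spec, classed `cohort_spec`.
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(spec$n_per_group >= 1,
            spec$n_regions >= 4, spec$n_regions %% 2 == 0,
            spec$t_points >= 10,
            spec$base_fc > 0, spec$base_fc < 1,
            spec$inter_base_factor > 0, spec$inter_base_factor <= 1,
            spec$homotopic_boost >= 0, spec$homotopic_boost < 1,
            spec$asym_factor >= 1,
            spec$mdd_fc_effect > 0, spec$mdd_fc_effect <= 1,
            spec$mdd_struct_effect > 0,
            spec$coupling_rho >= 0, spec$coupling_rho < 1,
            spec$struct_density > 0, spec$struct_density <= 1,
            spec$homotopic_density_boost >= 0,
            spec$homotopic_fiber_factor >= 1,
            spec$fiber_scale > 0,
            spec$fiber_dispersion > 0,
            spec$noise_sd >= 0, is.finite(spec$noise_sd))
  if (spec$base_fc * spec$asym_factor + spec$homotopic_boost >= 0.995) {
    stop("base_fc/homotopic_boost/asym_factor imply correlations >= 1")
  }
  class(spec) <- "cohort_spec"
  spec
}
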