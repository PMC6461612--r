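# Synthetic paired functional/structural cohorts with planted effects.
#
# The generative model, in brief:
#   * structural: edges exist independently with probability struct_density
#     (boosted for homotopic pairs); streamline counts are negative-binomial
#     around fiber_scale (overdispersed, integer-valued); the right
#     intra-hemispheric block is scaled by asym_factor and MDD subjects by
#     mdd_struct_effect.
#   * functional: a population correlation matrix is assembled from base_fc
#     (within hemisphere; right block times asym_factor), a reduced
#     heterotopic level, an additive homotopic boost, an MDD scaling, a
#     subject-level shift, and a structural->functional coupling term added
#     in Fisher-z space on structurally connected pairs; after
#     positive-definite repair, t_points Gaussian samples are drawn and the
#     SAMPLE Pearson correlation matrix is returned, so correlation noise has
#     its genuine sampling distribution.

# hemisphere/partner masks for the generator, from an atlas
.block_masks <- function(atlas) {
  n <- nrow(atlas)
  isL <- atlas$hemisphere == "L"
  partner <- atlas_partner(atlas)
  intraL <- outer(isL, isL, "&")
  intraR <- outer(!isL, !isL, "&")
  inter <- !(intraL | intraR)
  homo <- matrix(FALSE, n, n)
  homo[cbind(seq_len(n), partner)] <- TRUE
  diag(intraL) <- diag(intraR) <- FALSE
  list(intraL = intraL, intraR = intraR, inter = inter, homotopic = homo)
}

#' Generate one synthetic structural connectivity matrix
#'
#' Draws using the current RNG stream (seed it, or use [generate_cohort()]
#' which seeds everything from the spec).
#'
#' @param spec a [cohort_spec()].
#' @param group "HC" or "MDD".
#' @param subject_id id to attach.
#' @param atlas atlas defining hemispheres/partners; default interleaved.
#' @param subject_factor optional subject-level lognormal scale on expected
#'   counts; drawn as `exp(rnorm(1, 0, noise_sd))` when `NULL`.
#' @return a structural `wholebrain_matrix` of integer streamline counts.
#' @export
generate_structural <- function(spec, group = c("HC", "MDD"),
                                subject_id = "subject", atlas = NULL,
                                subject_factor = NULL) {
  group <- match.arg(group)
  n <- spec$n_regions
  if (is.null(atlas)) atlas <- make_interleaved_atlas(n)
  bm <- .block_masks(atlas)
  ut <- .ut(n)

  p <- matrix(spec$struct_density, n, n)
  p[bm$homotopic] <- min(1, spec$struct_density + spec$homotopic_density_boost)
  mu <- matrix(spec$fiber_scale, n, n)
  mu[bm$homotopic] <- mu[bm$homotopic] * spec$homotopic_fiber_factor
  mu[bm$intraR] <- mu[bm$intraR] * spec$asym_factor
  if (group == "MDD") mu <- mu * spec$mdd_struct_effect
  if (is.null(subject_factor)) {
    subject_factor <- exp(stats::rnorm(1, 0, spec$noise_sd))
  }
  mu <- mu * subject_factor

  ne <- sum(ut)
  exist <- stats::runif(ne) < p[ut]
  counts <- numeric(ne)
  if (is.finite(spec$fiber_dispersion)) {
    counts[exist] <- stats::rnbinom(sum(exist), size = spec$fiber_dispersion,
                                    mu = mu[ut][exist])
  } else {
    counts[exist] <- round(mu[ut][exist])
  }
  w <- matrix(0, n, n)
  w[ut] <- counts
  w <- w + t(w)
  wholebrain_matrix(w, subject_id = subject_id, modality = "structural")
}

# eigenvalue-clipping projection to a positive-definite correlation matrix
.pd_repair <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  v <- pmax(e$values, 1e-6)
  stats::cov2cor(e$vectors %*% (v * t(e$vectors)))
}

# Population correlation construction. Returns list(construct, pd):
# `construct` is the assembled matrix before positive-definite repair (the
# infinite-time construction identity used in tests); `pd` is the matrix
# actually sampled from.
#
# The coupling coefficient is tuned so the MEASURED coupling degree (noisy
# Fisher-z functional weights vs rank-normal structural weights) targets
# coupling_rho: the Fisher z of a sample correlation at t_points carries
# noise variance ~ 1/(t_points - 3) on top of the planted signal, and the
# PD repair can additionally shrink the planted component, so after a
# repair the realized coefficient is re-estimated by regressing the
# repaired z-weights on the planted scores and the coupling term is
# rescaled (up to 4 refinement passes).
.population_correlation <- function(spec, group, structural, fc_shift, bm, n) {
  base <- matrix(0, n, n)
  base[bm$intraL] <- spec$base_fc
  base[bm$intraR] <- spec$base_fc * spec$asym_factor
  base[bm$inter] <- spec$base_fc * spec$inter_base_factor
  base[bm$homotopic] <- spec$base_fc * spec$inter_base_factor +
    spec$homotopic_boost
  if (group == "MDD") base <- base * spec$mdd_fc_effect
  base <- base + fc_shift
  diag(base) <- 0
  base <- pmin(pmax(base, -0.95), 0.95)

  sw <- NULL
  if (spec$coupling_rho > 0 && !is.null(structural)) {
    sw <- if (inherits(structural, "wholebrain_matrix")) structural$weights
          else structural
  }
  ut <- .ut(n)
  support <- if (is.null(sw)) matrix(FALSE, n, n) else (ut & sw > 0)

  assemble <- function(beta) {
    rho <- base
    if (beta > 0) {
      g <- rank_normal(sw[support])
      z <- fisher_z(rho[support]) + beta * g
      rho[support] <- tanh(z)
      rho <- pmin(pmax(rho, -0.95), 0.95)
    }
    rho[t(ut)] <- 0
    rho <- rho + t(rho)
    diag(rho) <- 1
    rho
  }

  if (!any(support) || sum(support) < 3) {
    rho <- assemble(0)
    pd <- if (is.null(tryCatch(chol(rho), error = function(e) NULL))) {
      .pd_repair(rho)
    } else rho
    return(list(construct = rho, pd = pd))
  }

  sigma_n <- sqrt(1 / (spec$t_points - 3))
  beta_target <- spec$coupling_rho * sigma_n / sqrt(1 - spec$coupling_rho^2)
  g <- rank_normal(sw[support])
  z0 <- fisher_z(base[support])
  # calibration is anchored on the intra-hemispheric edges, the scope whose
  # coupling degree the analysis models as the two-level within-subject
  # measure
  in_scope <- (bm$intraL | bm$intraR)[support]
  if (!any(in_scope)) in_scope <- rep(TRUE, length(g))
  gs <- g[in_scope] - mean(g[in_scope])
  beta_use <- beta_target
  rho <- assemble(beta_use)
  pd <- rho
  for (pass in seq_len(4)) {
    if (!is.null(tryCatch(chol(pd), error = function(e) NULL))) break
    pd <- .pd_repair(rho)
    # realized in-scope coupling coefficient after repair
    dev <- (fisher_z(pd[support]) - z0)[in_scope]
    b_hat <- sum(dev * gs) / sum(gs^2)
    if (!is.finite(b_hat) || b_hat <= 0 ||
        abs(b_hat - beta_target) < 0.02 * beta_target || pass == 4) break
    beta_use <- beta_use * beta_target / b_hat
    rho <- assemble(beta_use)
    pd <- rho
  }
  list(construct = assemble(beta_target), pd = pd)
}

#' Generate one synthetic functional connectivity matrix
#'
#' Simulates `t_points` multivariate Gaussian time samples under the
#' population correlation built from the spec (and, when supplied, the
#' subject's structural matrix, which adds the cross-modal coupling term) and
#' returns the sample Pearson correlation matrix. The population matrix is
#' projected to the nearest positive-definite correlation matrix (eigenvalue
#' clipping at 1e-6 plus rescaling) before sampling when needed.
#'
#' @param spec a [cohort_spec()].
#' @param group "HC" or "MDD".
#' @param structural the subject's structural `wholebrain_matrix` (or plain
#'   matrix); `NULL` drops the coupling term.
#' @param subject_id id to attach.
#' @param atlas atlas defining hemispheres/partners; default interleaved.
#' @param fc_shift subject-level additive correlation shift; drawn as
#'   `rnorm(1, 0, noise_sd)` when `NULL`.
#' @param population if `TRUE`, return the constructed population matrix
#'   itself (zero diagonal, before positive-definite repair) instead of a
#'   sampled matrix -- the infinite-time limit used in construction tests.
#' @return a functional `wholebrain_matrix`.
#' @export
generate_functional <- function(spec, group = c("HC", "MDD"),
                                structural = NULL, subject_id = "subject",
                                atlas = NULL, fc_shift = NULL,
                                population = FALSE) {
  group <- match.arg(group)
  n <- spec$n_regions
  if (is.null(atlas)) atlas <- make_interleaved_atlas(n)
  bm <- .block_masks(atlas)
  if (is.null(fc_shift)) fc_shift <- stats::rnorm(1, 0, spec$noise_sd)

  pc <- .population_correlation(spec, group, structural, fc_shift, bm, n)
  if (population) {
    pop <- pc$construct
    diag(pop) <- 0
    return(wholebrain_matrix(pop, subject_id = subject_id,
                             modality = "functional"))
  }
  ch <- tryCatch(chol(pc$pd), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(.pd_repair(pc$pd)), error = function(e) NULL)
    if (is.null(ch)) {
      stop("positive-definite repair failed (base_fc = ", spec$base_fc,
           ", homotopic_boost = ", spec$homotopic_boost, ")")
    }
  }
  x <- matrix(stats::rnorm(spec$t_points * n), spec$t_points, n) %*% ch
  s <- stats::cor(x)
  diag(s) <- 0
  s[abs(s) < .Machine$double.eps] <- 0
  wholebrain_matrix(s, subject_id = subject_id, modality = "functional")
}

#' Generate a full synthetic cohort
#'
#' Generates `n_per_group` MDD and HC subjects: covariates (age, gender,
#' education, head motion), clinical scores (HAMD >= 18 for MDD, with an
#' optional planted dependence on the subject latent that also raises
#' functional connectivity, so the brain-clinical correlation is
#' recoverable), and paired structural + functional matrices per subject.
#' Fully seeded from `spec$seed`; the caller's RNG state is untouched.
#'
#' @param spec a [cohort_spec()].
#' @param atlas atlas to use (default: bundled 90-region atlas when
#'   `n_regions == 90`, interleaved toy atlas otherwise).
#' @return a `connectome_cohort`: list with `subjects` (subject_table),
#'   `matrices` (per subject: functional, structural), `truth` (ground-truth
#'   latents and the spec) and `atlas`.
#' @export
generate_cohort <- function(spec, atlas = NULL) {
  if (is.null(atlas)) {
    atlas <- if (spec$n_regions == 90) default_atlas()
             else make_interleaved_atlas(spec$n_regions)
  }
  with_seed(spec$seed, {
    n_tot <- 2L * spec$n_per_group
    group <- rep(c("MDD", "HC"), each = spec$n_per_group)
    ids <- sprintf("%s%03d", group, c(seq_len(spec$n_per_group),
                                      seq_len(spec$n_per_group)))
    u <- stats::rnorm(n_tot)           # subject latent: drives fc and HAMD
    age <- round(pmin(pmax(stats::rnorm(n_tot, 40, 10), 18), 65))
    gender <- sample(c("F", "M"), n_tot, replace = TRUE)
    education <- round(pmin(pmax(stats::rnorm(n_tot, 12, 3), 6), 22))
    mean_fd <- exp(stats::rnorm(n_tot, log(0.12), 0.3))
    hamd <- integer(n_tot)
    mdd <- group == "MDD"
    hamd[mdd] <- pmax(18L, 18L + stats::rpois(sum(mdd), 4) +
                        as.integer(round(spec$hamd_slope * u[mdd] - 2)))
    hamd[!mdd] <- stats::rpois(sum(!mdd), 2)
    duration <- numeric(n_tot)
    duration[mdd] <- round(exp(stats::rnorm(sum(mdd), log(24), 0.6)))

    subjects <- validate_subjects(data.frame(
      subject_id = ids, group = group, age = age, gender = gender,
      education = education, mean_fd = mean_fd, hamd = hamd,
      duration = duration, stringsAsFactors = FALSE))

    matrices <- vector("list", n_tot)
    names(matrices) <- ids
    for (i in seq_len(n_tot)) {
      s <- generate_structural(spec, group[i], subject_id = ids[i],
                               atlas = atlas)
      f <- generate_functional(spec, group[i], structural = s,
                               subject_id = ids[i], atlas = atlas,
                               fc_shift = spec$noise_sd * u[i])
      matrices[[i]] <- list(functional = f, structural = s)
    }
    truth <- list(spec = unclass(spec),
                  subjects = data.frame(subject_id = ids, group = group,
                                        latent = u,
                                        fc_shift = spec$noise_sd * u,
                                        stringsAsFactors = FALSE))
    structure(list(subjects = subjects, matrices = matrices, truth = truth,
                   atlas = atlas),
              class = "connectome_cohort")
  })
}
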