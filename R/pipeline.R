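# End-to-end orchestration: cohort -> thresholded hemispheric networks ->
# metrics -> statistics, under the absolute-strength scheme (primary
# analysis) and the density-grid/AUC scheme plus regional-size checks
# (validation analysis).

.functional_covariates <- c("age", "gender", "education", "mean_fd")
.structural_covariates <- c("age", "gender", "education")

#' Per-subject network metrics under the strength scheme
#'
#' Thresholds both modalities of every subject, splits hemispheres, and
#' returns tidy tables of connection-class sums, global efficiencies
#' (optionally random-network normalized), nodal degrees, and
#' functional-structural coupling.
#'
#' @param cohort a `connectome_cohort`.
#' @param atlas atlas (defaults to the cohort's).
#' @param scheme a strength-mode [threshold_scheme()].
#' @param n_nulls null networks per hemisphere for normalized efficiencies
#'   (0 skips them).
#' @param null_seed base seed for the null ensembles (one derived seed per
#'   network, so results do not depend on subject order).
#' @return list of data.frames: classes, globals, nodal, coupling.
#' @export
compute_subject_metrics <- function(cohort, atlas = NULL,
                                    scheme = threshold_scheme("strength"),
                                    n_nulls = 100, null_seed = 1L) {
  if (is.null(atlas)) atlas <- cohort$atlas
  if (is.null(atlas)) atlas <- default_atlas()
  stopifnot(scheme$mode == "strength")
  classes <- list(); globals <- list(); nodal <- list(); coup <- list()
  idx <- 0L
  for (id in cohort$subjects$subject_id) {
    splits <- list()
    for (mod in c("functional", "structural")) {
      idx <- idx + 1L
      m <- threshold_strength(cohort$matrices[[id]][[mod]],
                              threshold = scheme$strength_threshold)
      sp <- split_hemispheres(m, atlas)
      splits[[mod]] <- sp
      classes[[idx]] <- classify_connections(sp$L, sp$R, sp$inter)
      g <- lapply(list(L = sp$L, R = sp$R), function(net) {
        if (n_nulls > 0) {
          ne <- normalized_efficiencies(net, n_nulls = n_nulls,
                                        seed = null_seed + idx * 7L +
                                          (net$hemisphere == "R"))
          data.frame(subject_id = id, modality = mod,
                     hemisphere = net$hemisphere,
                     e_glob = ne$e_glob, e_loc = ne$e_loc,
                     e_glob_norm = ne$e_glob_norm,
                     e_loc_norm = ne$e_loc_norm,
                     stringsAsFactors = FALSE)
        } else {
          data.frame(subject_id = id, modality = mod,
                     hemisphere = net$hemisphere,
                     e_glob = global_efficiency(net),
                     e_loc = local_efficiency(net),
                     e_glob_norm = NA_real_, e_loc_norm = NA_real_,
                     stringsAsFactors = FALSE)
        }
      })
      globals[[idx]] <- rbind(g$L, g$R)
      nodal[[idx]] <- nodal_degrees(sp$L, sp$R, sp$inter, atlas)
    }
    coup[[id]] <- coupling_results(splits$functional, splits$structural)
  }
  list(classes = do.call(rbind, classes),
       globals = do.call(rbind, globals),
       nodal = do.call(rbind, nodal),
       coupling = do.call(rbind, c(coup, list(make.row.names = FALSE))))
}

# (L, R) value matrix for a subject-by-hemisphere long table
.lr_matrix <- function(df, subjects, value, hemi_col = "hemisphere") {
  out <- matrix(NA_real_, nrow(subjects), 2,
                dimnames = list(NULL, c("L", "R")))
  for (h in c("L", "R")) {
    sub <- df[df[[hemi_col]] == h, ]
    out[, h] <- sub[[value]][match(subjects$subject_id, sub$subject_id)]
  }
  out
}

# run the full mixed-ANCOVA + post hoc battery for one two-level measure
.anova_with_posthoc <- function(vals, subjects, covariates, measure,
                                alpha = 0.05) {
  ok <- stats::complete.cases(vals)   # e.g. undefined coupling degrees
  if (!all(ok)) {
    vals <- vals[ok, , drop = FALSE]
    subjects <- subjects[ok, , drop = FALSE]
  }
  an <- mixed_anova(vals, subjects, covariates, measure = measure)
  post <- list()
  if (an$p_hemi < alpha) {
    post$hemisphere <- posthoc_tests(vals, subjects, covariates, "hemisphere")
  }
  if (an$p_group < alpha) {
    post$group <- posthoc_tests(vals, subjects, covariates, "group")
  }
  list(anova = an, posthoc = post)
}

#' Primary analysis: strength-thresholded hemispheric networks
#'
#' Runs the whole study design on a cohort (loaded or generated):
#' demographics tests; mixed group x hemisphere ANCOVA on intra-hemispheric
#' connectivity, the four global efficiency measures, and intra-hemispheric
#' coupling (amount and degree); covariate-adjusted group tests on homotopic
#' and heterotopic connectivity and inter-hemispheric coupling;
#' Bonferroni-corrected region-wise nodal-degree tests; and partial
#' correlations of MDD-related measures with HAMD and illness duration
#' within the patient group. Head motion is an additional covariate for all
#' functional comparisons.
#'
#' @param cohort a `connectome_cohort`, or `NULL` to generate one.
#' @param spec a [cohort_spec()] used when `cohort` is `NULL`.
#' @param atlas atlas (defaults to the cohort's).
#' @param scheme strength-mode [threshold_scheme()].
#' @param n_nulls nulls for normalized efficiencies (0 skips those two
#'   measures).
#' @param null_seed seed for null ensembles.
#' @param alpha significance level gating post hoc tests.
#' @param output_dir optional directory for TSV/JSON reports and the run
#'   manifest.
#' @return list of class `effect_report`: demographics, connectivity and
#'   coupling ANOVAs/tests, region tables, brain-clinical correlations,
#'   metric tables and the manifest.
#' @export
run_primary_analysis <- function(cohort = NULL, spec = NULL, atlas = NULL,
                                 scheme = threshold_scheme("strength"),
                                 n_nulls = 100, null_seed = 1L,
                                 alpha = 0.05, output_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (is.null(cohort)) {
    if (is.null(spec)) stop("either a cohort or a cohort_spec is required")
    cohort <- generate_cohort(spec)
  }
  if (is.null(atlas)) atlas <- cohort$atlas
  if (is.null(atlas)) atlas <- default_atlas()
  subjects <- cohort$subjects
  metrics <- compute_subject_metrics(cohort, atlas, scheme,
                                     n_nulls = n_nulls,
                                     null_seed = null_seed)
  report <- list(demographics = demographics_tests(subjects))

  anovas <- list(); group_tests <- list(); regions <- list()
  for (mod in c("functional", "structural")) {
    covs <- if (mod == "functional") .functional_covariates
            else .structural_covariates
    cl <- metrics$classes[metrics$classes$modality == mod, ]
    iv <- cbind(L = cl$intra_left[match(subjects$subject_id, cl$subject_id)],
                R = cl$intra_right[match(subjects$subject_id, cl$subject_id)])
    anovas[[paste0(mod, "_intra_connectivity")]] <-
      .anova_with_posthoc(iv, subjects, covs,
                          paste(mod, "intra-hemispheric connectivity"), alpha)
    for (cls in c("homotopic", "heterotopic")) {
      y <- cl[[cls]][match(subjects$subject_id, cl$subject_id)]
      group_tests[[paste0(mod, "_", cls)]] <-
        group_ttest(y, subjects, covs, paste(mod, cls, "connectivity"))
    }
    gl <- metrics$globals[metrics$globals$modality == mod, ]
    eff_measures <- c("e_glob", "e_loc")
    if (n_nulls > 0) eff_measures <- c(eff_measures, "e_glob_norm",
                                       "e_loc_norm")
    for (em in eff_measures) {
      vals <- .lr_matrix(gl, subjects, em)
      anovas[[paste0(mod, "_", em)]] <-
        .anova_with_posthoc(vals, subjects, covs, paste(mod, em), alpha)
    }
    nd <- metrics$nodal[metrics$nodal$modality == mod, ]
    for (ms in c("intra_degree", "inter_degree")) {
      regions[[paste0(mod, "_", ms)]] <-
        regionwise_tests(nd, atlas, subjects, covs, measure = ms,
                         alpha = alpha)
    }
  }

  cp <- metrics$coupling
  for (what in c("amount", "degree")) {
    vals <- cbind(
      L = cp[[what]][cp$scope == "intra_L"][
        match(subjects$subject_id, cp$subject_id[cp$scope == "intra_L"])],
      R = cp[[what]][cp$scope == "intra_R"][
        match(subjects$subject_id, cp$subject_id[cp$scope == "intra_R"])])
    anovas[[paste0("coupling_intra_", what)]] <-
      .anova_with_posthoc(vals, subjects, .functional_covariates,
                          paste("intra-hemispheric coupling", what), alpha)
    yin <- cp[[what]][cp$scope == "inter"][
      match(subjects$subject_id, cp$subject_id[cp$scope == "inter"])]
    group_tests[[paste0("coupling_inter_", what)]] <-
      group_ttest(yin, subjects, .functional_covariates,
                  paste("inter-hemispheric coupling", what))
  }

  # brain-clinical partial correlations within the patient group
  mdd <- subjects[subjects$group == "MDD", ]
  covs <- cbind(age = mdd$age,
                gender = as.numeric(factor(mdd$gender,
                                           levels = sort(unique(subjects$gender)))) - 1,
                education = mdd$education)
  clinical <- list()
  for (scope in c("intra_L", "intra_R")) {
    amt <- cp$amount[cp$scope == scope][
      match(mdd$subject_id, cp$subject_id[cp$scope == scope])]
    for (cv in c("hamd", "duration")) {
      pc <- if (nrow(mdd) > ncol(covs) + 2) {
        partial_correlation(amt, mdd[[cv]], covs)
      } else {
        list(r = NA_real_, p = NA_real_, n = nrow(mdd),
             df = NA_integer_)    # too few patients to control covariates
      }
      clinical[[paste0("coupling_amount_", scope, "_vs_", cv)]] <-
        data.frame(x = paste0("coupling_amount_", scope), y = cv,
                   r = as.numeric(pc$r), p = pc$p, n = pc$n, df = pc$df,
                   stringsAsFactors = FALSE)
    }
  }
  clinical <- do.call(rbind, c(clinical, list(make.row.names = FALSE)))

  manifest <- list(
    scheme = unclass(scheme), n_nulls = n_nulls, null_seed = null_seed,
    alpha = alpha, n_subjects = nrow(subjects),
    n_regions = nrow(atlas),
    package_version = as.character(utils::packageVersion("hemiconn")),
    rows = list(classes = nrow(metrics$classes),
                globals = nrow(metrics$globals),
                nodal = nrow(metrics$nodal),
                coupling = nrow(metrics$coupling)),
    elapsed_s = proc.time()[["elapsed"]] - t0)
  report <- c(report, list(anovas = anovas, group_tests = group_tests,
                           regions = regions, clinical = clinical,
                           metrics = metrics, manifest = manifest))
  class(report) <- "effect_report"
  if (!is.null(output_dir)) .write_report(report, output_dir)
  report
}

#' Validation analysis: density grid, AUC statistics and regional size
#'
#' Re-analyzes a cohort under fixed network densities (default grid
#' 0.08-0.15, step 0.01) with surviving weights normalized to overall mean
#' 1: computes global efficiencies and nodal degrees per density, integrates
#' them over the grid (area under the curve), and runs the mixed-ANCOVA
#' battery on the AUC values. Also runs the regional-size validation on the
#' strength-scheme nodal degrees.
#'
#' @param cohort a `connectome_cohort`.
#' @param atlas atlas (defaults to the cohort's).
#' @param scheme density-mode [threshold_scheme()].
#' @param n_nulls nulls per network per density for normalized efficiencies
#'   (default 0: efficiency AUCs only, which keeps the validation arm
#'   affordable).
#' @param null_seed seed for null ensembles.
#' @param alpha significance level.
#' @param strength_metrics optional precomputed [compute_subject_metrics()]
#'   output for the regional-size validation; computed if `NULL`.
#' @param output_dir optional output directory.
#' @return list of class `effect_report`: AUC ANOVAs, AUC region tables,
#'   size validation, per-density metric table, manifest.
#' @export
run_validation_analysis <- function(cohort, atlas = NULL,
                                    scheme = threshold_scheme("density"),
                                    n_nulls = 0, null_seed = 1L,
                                    alpha = 0.05, strength_metrics = NULL,
                                    output_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (is.null(atlas)) atlas <- cohort$atlas
  if (is.null(atlas)) atlas <- default_atlas()
  stopifnot(scheme$mode == "density")
  subjects <- cohort$subjects
  grid <- scheme$density_grid
  check_min_density(sum(atlas$hemisphere == "L"), grid = grid)

  globals <- list(); nodal <- list(); idx <- 0L
  for (id in subjects$subject_id) {
    for (mod in c("functional", "structural")) {
      for (d in grid) {
        idx <- idx + 1L
        m <- threshold_density(cohort$matrices[[id]][[mod]], d,
                               normalize = scheme$normalize_overall_mean)
        sp <- split_hemispheres(m, atlas)
        for (net in list(sp$L, sp$R)) {
          row <- data.frame(subject_id = id, modality = mod,
                            hemisphere = net$hemisphere, density = d,
                            e_glob = global_efficiency(net),
                            e_loc = local_efficiency(net),
                            e_glob_norm = NA_real_, e_loc_norm = NA_real_,
                            stringsAsFactors = FALSE)
          if (n_nulls > 0) {
            ne <- normalized_efficiencies(net, n_nulls = n_nulls,
                                          seed = null_seed + idx)
            row$e_glob_norm <- ne$e_glob_norm
            row$e_loc_norm <- ne$e_loc_norm
          }
          globals[[length(globals) + 1L]] <- row
        }
        nd <- nodal_degrees(sp$L, sp$R, sp$inter, atlas)
        nd$density <- d
        nodal[[length(nodal) + 1L]] <- nd
      }
    }
  }
  globals <- do.call(rbind, globals)
  nodal <- do.call(rbind, nodal)

  auc_of <- function(df, value) {
    split_keys <- interaction(df$subject_id, df$modality, df$hemisphere,
                              drop = TRUE)
    agg <- lapply(split(df, split_keys), function(s) {
      s <- s[order(s$density), ]
      data.frame(subject_id = s$subject_id[1], modality = s$modality[1],
                 hemisphere = s$hemisphere[1],
                 auc = auc_over_densities(s[[value]], grid),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(agg, list(make.row.names = FALSE)))
  }

  anovas <- list(); regions <- list()
  eff_measures <- c("e_glob", "e_loc")
  if (n_nulls > 0) eff_measures <- c(eff_measures, "e_glob_norm",
                                     "e_loc_norm")
  for (mod in c("functional", "structural")) {
    covs <- if (mod == "functional") .functional_covariates
            else .structural_covariates
    for (em in eff_measures) {
      ac <- auc_of(globals[globals$modality == mod, ], em)
      vals <- .lr_matrix(ac, subjects, "auc")
      anovas[[paste0(mod, "_", em, "_auc")]] <-
        .anova_with_posthoc(vals, subjects, covs,
                            paste(mod, em, "AUC"), alpha)
    }
    nd <- nodal[nodal$modality == mod, ]
    for (ms in c("intra_degree", "inter_degree")) {
      keys <- interaction(nd$subject_id, nd$region_id, drop = TRUE)
      agg <- lapply(split(nd, keys), function(s) {
        s <- s[order(s$density), ]
        out <- s[1, c("subject_id", "modality", "hemisphere", "region_id",
                      "region")]
        out[[ms]] <- auc_over_densities(s[[ms]], grid)
        out
      })
      nd_auc <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
      regions[[paste0(mod, "_", ms, "_auc")]] <-
        regionwise_tests(nd_auc, atlas, subjects, covs, measure = ms,
                         alpha = alpha)
    }
  }

  if (is.null(strength_metrics)) {
    strength_metrics <- compute_subject_metrics(
      cohort, atlas, threshold_scheme("strength"), n_nulls = 0)
  }
  size_validation <- list()
  for (mod in c("functional", "structural")) {
    covs <- if (mod == "functional") .functional_covariates
            else .structural_covariates
    size_validation[[mod]] <- regional_size_validation(
      strength_metrics$nodal[strength_metrics$nodal$modality == mod, ],
      atlas, subjects, covs, modality = mod, alpha = alpha)
  }

  manifest <- list(scheme = unclass(scheme), n_nulls = n_nulls,
                   null_seed = null_seed, alpha = alpha,
                   n_subjects = nrow(subjects),
                   package_version =
                     as.character(utils::packageVersion("hemiconn")),
                   rows = list(globals = nrow(globals), nodal = nrow(nodal)),
                   elapsed_s = proc.time()[["elapsed"]] - t0)
  report <- list(anovas = anovas, regions = regions,
                 size_validation = size_validation,
                 density_globals = globals, manifest = manifest)
  class(report) <- "effect_report"
  if (!is.null(output_dir)) .write_report(report, output_dir)
  report
}

# flatten an effect report into TSV files + a JSON bundle
.write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$demographics)) {
    write_table(report$demographics, file.path(dir, "demographics.tsv"))
  }
  if (!is.null(report$anovas)) {
    an <- do.call(rbind, lapply(names(report$anovas), function(nm) {
      a <- report$anovas[[nm]]$anova
      data.frame(measure = a$measure, n = a$n, df2 = a$df[2],
                 F_group = a$F_group, p_group = a$p_group,
                 direction_group = a$direction_group,
                 F_hemi = a$F_hemi, p_hemi = a$p_hemi,
                 direction_hemi = a$direction_hemi,
                 F_interaction = a$F_interaction,
                 p_interaction = a$p_interaction,
                 stringsAsFactors = FALSE)
    }))
    write_table(an, file.path(dir, "anovas.tsv"))
  }
  if (!is.null(report$group_tests)) {
    write_table(do.call(rbind, c(report$group_tests,
                                 list(make.row.names = FALSE))),
                file.path(dir, "group_tests.tsv"))
  }
  if (!is.null(report$regions)) {
    for (nm in names(report$regions)) {
      write_table(report$regions[[nm]],
                  file.path(dir, paste0("regions_", nm, ".tsv")))
    }
  }
  if (!is.null(report$clinical)) {
    write_table(report$clinical, file.path(dir, "clinical.tsv"))
  }
  if (!is.null(report$metrics)) {
    for (nm in names(report$metrics)) {
      write_table(report$metrics[[nm]],
                  file.path(dir, paste0("metrics_", nm, ".tsv")))
    }
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
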