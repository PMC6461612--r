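test_that("demographics tests match closed forms", {
  subj <- toy_subjects(10)
  # identical distributions by construction: copy MDD values into HC rows
  same <- subj
  same[same$group == "HC", c("age", "education", "mean_fd")] <-
    same[same$group == "MDD", c("age", "education", "mean_fd")]
  res <- demographics_tests(same)
  expect_equal(res$statistic[res$variable == "age"], 0)
  expect_equal(res$p[res$variable == "age"], 1)

  # chi-squared equals sum((O-E)^2/E) on a 20/15 vs 18/17 gender table
  gsub <- data.frame(subject_id = as.character(1:70),
                     group = rep(c("MDD", "HC"), each = 35),
                     age = 40, gender = c(rep("F", 20), rep("M", 15),
                                          rep("F", 18), rep("M", 17)),
                     education = 12, mean_fd = 0.1, hamd = 20, duration = 1,
                     stringsAsFactors = FALSE)
  res <- demographics_tests(gsub)
  O <- matrix(c(18, 17, 20, 15), 2, byrow = TRUE)  # rows HC, MDD
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$statistic[res$variable == "gender"],
               sum((O - E)^2 / E))
})

test_that("split-regression mixed ANCOVA equals the GLM oracle", {
  set.seed(400)
  for (i in 1:25) {
    n1 <- sample(6:10, 1); n2 <- sample(6:10, 1); n <- n1 + n2
    subj <- data.frame(subject_id = as.character(seq_len(n)),
                       group = rep(c("MDD", "HC"), c(n1, n2)),
                       z1 = rnorm(n), z2 = rnorm(n),
                       stringsAsFactors = FALSE)
    L <- rnorm(n) + 0.4 * subj$z1
    R <- rnorm(n) + 0.3 * (subj$group == "MDD")
    mine <- mixed_anova(cbind(L, R), subj, covariates = c("z1", "z2"))
    oracle <- car_anova_oracle(L, R, subj, c("z1", "z2"))
    expect_equal(mine$F_group, unname(oracle["group"]), tolerance = 1e-8)
    expect_equal(mine$F_hemi, unname(oracle["hemi"]), tolerance = 1e-8)
    expect_equal(mine$F_interaction, unname(oracle["interaction"]),
                 tolerance = 1e-8)
  }
})

test_that("mixed ANCOVA degrees of freedom and directions are coherent", {
  subj <- toy_subjects(20, seed = 5)
  set.seed(401)
  L <- rnorm(40) - 0.8 * (subj$group == "MDD")
  R <- L + 0.5 + rnorm(40, sd = 0.2)
  res <- mixed_anova(cbind(L, R), subj)
  expect_equal(res$df, c(1, 40 - 2 - 3))
  expect_equal(res$direction_group, "MDD < HCs")
  expect_equal(res$direction_hemi, "RH > LH")
  expect_error(mixed_anova(cbind(L, R), subj, covariates = "nope"),
               "missing covariate")
})

test_that("post hoc tests reduce to their defining t tests", {
  subj <- toy_subjects(12, seed = 6)
  set.seed(402)
  L <- rnorm(24); R <- L + 0.3 + rnorm(24, sd = 0.5)
  ph <- posthoc_tests(cbind(L, R), subj, which = "hemisphere")
  ref <- stats::t.test(R - L)       # identical to paired t.test(R, L)
  expect_equal(ph$T, unname(ref$statistic))
  expect_equal(ph$p, ref$p.value)
  # L = R exactly
  ph0 <- posthoc_tests(cbind(L, L), subj, which = "hemisphere")
  expect_equal(ph0$T, 0)
  expect_equal(ph0$p, 1)
  # group post hoc recovers a planted deficit
  L2 <- rnorm(24) - 1.5 * (subj$group == "MDD")
  ph2 <- posthoc_tests(cbind(L2, L2 + rnorm(24, sd = .1)), subj,
                       which = "group")
  expect_equal(ph2$direction, "MDD < HCs")
  expect_lt(ph2$p, 0.01)
  expect_equal(ph2$df, 48 - 2 - 3)
})

test_that("partial correlation reduces to Pearson and recovers a known partial rho", {
  set.seed(403)
  x <- rnorm(60); y <- 0.4 * x + rnorm(60)
  pc <- partial_correlation(x, y)
  ct <- stats::cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate))
  expect_equal(pc$p, ct$p.value)
  # construction with exact partial correlation 0.4 given z
  n <- 5000
  z <- rnorm(n)
  e <- matrix(rnorm(2 * n), n)
  e[, 2] <- 0.4 * e[, 1] + sqrt(1 - 0.16) * e[, 2]
  x <- 2 * z + e[, 1]; y <- -1.5 * z + e[, 2]
  pc <- partial_correlation(x, y, cbind(z))
  expect_lt(abs(pc$r - 0.4), 0.05)
  expect_equal(pc$df, n - 3)
  # y identical to a covariate -> zero residual, undefined flag
  pc0 <- partial_correlation(x, z, cbind(z))
  expect_true(is.na(pc0$r))
  expect_true(attr(pc0$r, "undefined"))
})

test_that("region-wise tests flag a planted asymmetry and nothing else", {
  atlas <- default_atlas()
  subj <- toy_subjects(35, seed = 7)
  n <- nrow(subj)
  set.seed(404)
  # null degrees everywhere except one region pair with rightward asymmetry
  target <- 12  # pair index (left region ids are odd: region 23 / partner 24)
  lid <- atlas_hemi_ids(atlas, "L")
  nodal <- do.call(rbind, lapply(seq_len(n), function(i) {
    v <- rnorm(90, mean = 10)
    v[lid[target] + 1] <- v[lid[target]] + 3 + rnorm(1, sd = 0.5)
    data.frame(subject_id = subj$subject_id[i], modality = "functional",
               hemisphere = atlas$hemisphere, region_id = atlas$region_id,
               region = atlas$abbreviation, intra_degree = v,
               inter_degree = 0, stringsAsFactors = FALSE)
  }))
  rt <- regionwise_tests(nodal, atlas, subj, measure = "intra_degree")
  expect_equal(nrow(rt), 45)
  expect_true(rt$sig_hemi[target])
  expect_equal(rt$dir_hemi[target], "RH > LH")
  expect_equal(sum(rt$sig_hemi), 1)
  expect_equal(sum(rt$sig_group), 0)
  # all-zero degrees: no flags, no errors
  nodal0 <- nodal
  nodal0$intra_degree <- 0
  rt0 <- regionwise_tests(nodal0, atlas, subj, measure = "intra_degree")
  expect_false(any(rt0$sig_group | rt0$sig_hemi | rt0$sig_interaction))
})

test_that("Bonferroni flags are monotone in the family size", {
  atlas <- default_atlas()
  subj <- toy_subjects(20, seed = 8)
  set.seed(405)
  nodal <- do.call(rbind, lapply(seq_len(nrow(subj)), function(i) {
    data.frame(subject_id = subj$subject_id[i], modality = "functional",
               hemisphere = atlas$hemisphere, region_id = atlas$region_id,
               region = atlas$abbreviation,
               intra_degree = rnorm(90, 10) +
                 0.8 * (atlas$hemisphere == "R"),
               inter_degree = 0, stringsAsFactors = FALSE)
  }))
  strict <- regionwise_tests(nodal, atlas, subj, measure = "intra_degree",
                             alpha = 0.05)
  lax <- regionwise_tests(nodal, atlas, subj, measure = "intra_degree",
                          alpha = 0.20)
  expect_true(all(strict$sig_hemi <= lax$sig_hemi))
})

test_that("regional-size validation triggers only on size-degree dependence", {
  atlas <- default_atlas()
  subj <- toy_subjects(20, seed = 9)
  n <- nrow(subj)
  set.seed(406)
  # size-degree correlation much tighter in the right hemisphere: the
  # hemisphere effect on the Fisher-z correlations must trigger the
  # size-normalized re-analysis
  nodal <- do.call(rbind, lapply(seq_len(n), function(i) {
    noise_sd <- ifelse(atlas$hemisphere == "R", 0.1, 0.9)
    data.frame(subject_id = subj$subject_id[i], modality = "functional",
               hemisphere = atlas$hemisphere, region_id = atlas$region_id,
               region = atlas$abbreviation,
               intra_degree = atlas$size_volume * exp(rnorm(90, sd = noise_sd)),
               inter_degree = rnorm(90, 50, 1),
               stringsAsFactors = FALSE)
  }))
  rv <- regional_size_validation(nodal, atlas, subj, modality = "functional")
  expect_lt(rv$size_anova$intra_degree$p_hemi, 0.05)
  expect_false(is.null(rv$normalized_regions))
  # size-independent degrees: correlations hover near zero, nothing triggers
  nodal$intra_degree <- rnorm(nrow(nodal), 100, 5)
  nodal$inter_degree <- rnorm(nrow(nodal), 100, 5)
  rv0 <- regional_size_validation(nodal, atlas, subj,
                                  modality = "functional")
  ps <- unlist(lapply(rv0$size_anova, function(a) {
    c(a$p_group, a$p_hemi, a$p_interaction)
  }))
  expect_gt(min(ps), 1e-4)   # no systematic size effect manufactured
})
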