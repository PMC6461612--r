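test_that("cohort generation is deterministic and respects the design", {
  spec <- cohort_spec(n_per_group = 3, n_regions = 20, t_points = 60,
                      seed = 42)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1$subjects, co2$subjects)
  for (id in co1$subjects$subject_id) {
    expect_identical(co1$matrices[[id]]$functional$weights,
                     co2$matrices[[id]]$functional$weights)
    expect_identical(co1$matrices[[id]]$structural$weights,
                     co2$matrices[[id]]$structural$weights)
  }
  expect_equal(nrow(co1$subjects), 6)
  expect_equal(length(co1$matrices) * 2, 12)      # two modalities each
  expect_true(all(co1$subjects$hamd[co1$subjects$group == "MDD"] >= 18))
  # caller's RNG stream is not disturbed
  set.seed(7); before <- rnorm(3)
  set.seed(7); invisible(generate_cohort(spec)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("default cohort matches the study dimensions", {
  spec <- cohort_spec(seed = 1)
  expect_equal(spec$n_per_group, 35)
  expect_equal(spec$n_regions, 90)
  co <- generate_cohort(cohort_spec(n_per_group = 2, seed = 1))
  expect_equal(dim(co$matrices[[1]]$functional$weights), c(90, 90))
  expect_true(all(co$matrices[[1]]$structural$weights ==
                    round(co$matrices[[1]]$structural$weights)))
})

test_that("noise-free structural limit is a complete graph with the planted asymmetry", {
  spec <- cohort_spec(struct_density = 1, homotopic_density_boost = 0,
                      homotopic_fiber_factor = 1, fiber_dispersion = Inf,
                      noise_sd = 0, fiber_scale = 50, asym_factor = 1.08,
                      n_regions = 10, seed = 1)
  atlas <- make_interleaved_atlas(10)
  set.seed(1)
  s <- generate_structural(spec, "HC", atlas = atlas)
  w <- s$weights
  ut <- upper.tri(w)
  expect_true(all(w[ut] > 0))                     # complete graph
  isR <- atlas$hemisphere == "R"
  rr <- outer(isR, isR, "&") & ut
  expect_true(all(w[rr] == 54))                   # round(50 * 1.08)
  ll <- outer(!isR, !isR, "&") & ut
  expect_true(all(w[ll] == 50))
})

test_that("structural right/left weight-sum ratio recovers asym_factor", {
  spec <- cohort_spec(seed = 1)
  atlas <- default_atlas()
  isR <- atlas$hemisphere == "R"
  rr <- outer(isR, isR, "&") & upper.tri(diag(90))
  ll <- outer(!isR, !isR, "&") & upper.tri(diag(90))
  set.seed(21)
  sums <- vapply(seq_len(400), function(i) {
    w <- generate_structural(spec, "HC", atlas = atlas)$weights
    c(sum(w[rr]), sum(w[ll]))
  }, numeric(2))
  expect_lt(abs(mean(sums[1, ]) / mean(sums[2, ]) / spec$asym_factor - 1),
            0.01)
})

test_that("functional population construction carries the planted block structure", {
  spec <- cohort_spec(seed = 1)
  atlas <- default_atlas()
  hc <- generate_functional(spec, "HC", atlas = atlas,
                            fc_shift = 0, population = TRUE)$weights
  mdd <- generate_functional(spec, "MDD", atlas = atlas,
                             fc_shift = 0, population = TRUE)$weights
  isR <- atlas$hemisphere == "R"
  p <- atlas_partner(atlas)
  homo <- matrix(FALSE, 90, 90); homo[cbind(1:90, p)] <- TRUE
  inter <- outer(isR, isR, FUN = xor)
  hetero <- inter & !homo
  # homotopic entries exceed heterotopic entries by exactly the boost
  expect_equal(unique(round(hc[homo] - mean(hc[hetero]), 10)),
               round(spec$homotopic_boost, 10))
  # rightward intra asymmetry
  rr <- outer(isR, isR, "&") & upper.tri(hc)
  ll <- outer(!isR, !isR, "&") & upper.tri(hc)
  expect_equal(mean(hc[rr]) / mean(hc[ll]), spec$asym_factor,
               tolerance = 1e-10)
  # MDD scaling applies multiplicatively
  expect_equal(mdd[ll], spec$mdd_fc_effect * hc[ll], tolerance = 1e-10)
})

test_that("group means recover the planted functional reduction", {
  spec <- cohort_spec(n_regions = 40, seed = 1)
  atlas <- make_interleaved_atlas(40)
  intra <- with(list(isR = atlas$hemisphere == "R"), {
    outer(isR, isR, "&") | outer(!isR, !isR, "&")
  }) & upper.tri(diag(40))
  mean_intra <- function(group, m) {
    vapply(seq_len(m), function(i) {
      mean(generate_functional(spec, group, atlas = atlas)$weights[intra])
    }, numeric(1))
  }
  set.seed(31)
  hc <- mean_intra("HC", 150)
  mdd <- mean_intra("MDD", 150)
  expect_lt(abs(mean(mdd) / mean(hc) - spec$mdd_fc_effect), 0.02)
})

test_that("zero coupling_rho yields no cross-modal association", {
  spec <- cohort_spec(coupling_rho = 0, base_fc = 0.4, struct_density = 0.5,
                      seed = 1)
  atlas <- default_atlas()
  set.seed(41)
  degs <- unlist(lapply(seq_len(40), function(i) {
    s <- generate_structural(spec, "HC", atlas = atlas)
    f <- generate_functional(spec, "HC", structural = s, atlas = atlas)
    fs <- split_hemispheres(threshold_strength(f), atlas)
    ss <- split_hemispheres(threshold_strength(s), atlas)
    coupling_results(fs, ss)$degree[1:2]
  }))
  tt <- stats::t.test(degs)
  expect_gt(tt$p.value, 0.001)
  expect_lt(abs(mean(degs)), 0.02)
})

test_that("weakening mdd_fc_effect strictly widens the recovered group gap", {
  atlas <- make_interleaved_atlas(30)
  intra <- with(list(isR = atlas$hemisphere == "R"), {
    outer(isR, isR, "&") | outer(!isR, !isR, "&")
  }) & upper.tri(diag(30))
  gap <- function(effect) {
    spec <- cohort_spec(n_per_group = 25, n_regions = 30,
                        mdd_fc_effect = effect, coupling_rho = 0, seed = 77)
    co <- generate_cohort(spec, atlas = atlas)
    sums <- vapply(co$subjects$subject_id, function(id) {
      w <- threshold_strength(co$matrices[[id]]$functional)$weights
      sum(w[intra])
    }, numeric(1))
    mean(sums[co$subjects$group == "HC"]) -
      mean(sums[co$subjects$group == "MDD"])
  }
  gaps <- vapply(c(1, 0.85, 0.7), gap, numeric(1))
  expect_true(all(diff(gaps) > 0))
  expect_lt(abs(gaps[1]), gaps[2] / 2)   # null effect gap is comparatively tiny
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(asym_factor = 0.9))
  expect_error(cohort_spec(mdd_fc_effect = 0))
  expect_error(cohort_spec(mdd_fc_effect = 1.2))
  expect_error(cohort_spec(struct_density = 0))
  expect_error(cohort_spec(base_fc = 0.6, homotopic_boost = 0.5))
})
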