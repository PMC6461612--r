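triangle <- function() {
  w <- matrix(1, 3, 3); diag(w) <- 0; w
}

test_that("efficiencies match closed forms on canonical graphs", {
  expect_equal(global_efficiency(triangle()), 1)
  expect_equal(local_efficiency(triangle()), 1)
  # 3-node path 1-2-3: (1 + 1 + 1/2)/3
  p <- matrix(0, 3, 3); p[1, 2] <- p[2, 1] <- 1; p[2, 3] <- p[3, 2] <- 1
  expect_equal(global_efficiency(p), 5 / 6)
  # star graph has no triangles: local efficiency 0
  s <- matrix(0, 5, 5); s[1, 2:5] <- s[2:5, 1] <- 1
  expect_equal(local_efficiency(s), 0)
  # empty network
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  expect_equal(local_efficiency(matrix(0, 4, 4)), 0)
})

test_that("efficiencies agree with an independent shortest-path oracle", {
  set.seed(100)
  for (i in 1:40) {
    n <- sample(8:15, 1)
    w <- random_weight_matrix(n, p_edge = runif(1, 0.2, 0.8))
    expect_equal(global_efficiency(w), oracle_global_efficiency(w),
                 tolerance = 1e-10)
    expect_equal(local_efficiency(w), oracle_local_efficiency(w),
                 tolerance = 1e-10)
  }
})

test_that("efficiency is permutation invariant, edge monotone and scale invariant", {
  set.seed(101)
  w <- random_weight_matrix(12, p_edge = 0.4)
  perm <- sample(12)
  expect_equal(global_efficiency(w[perm, perm]), global_efficiency(w))
  expect_equal(local_efficiency(w[perm, perm]), local_efficiency(w))
  # adding an edge cannot decrease global efficiency
  zero_pairs <- which(upper.tri(w) & w == 0, arr.ind = TRUE)
  ij <- zero_pairs[1, ]
  w2 <- w; w2[ij[1], ij[2]] <- w2[ij[2], ij[1]] <- max(w) / 2
  expect_gte(global_efficiency(w2, normalize_max = FALSE),
             global_efficiency(w, normalize_max = FALSE))
  # with max-normalization metrics are invariant to global rescaling
  expect_equal(global_efficiency(3.7 * w), global_efficiency(w))
  expect_equal(local_efficiency(3.7 * w), local_efficiency(w))
  # without it, scaling up weights cannot decrease efficiency
  expect_gte(global_efficiency(3.7 * w, normalize_max = FALSE),
             global_efficiency(w, normalize_max = FALSE))
})

test_that("null networks preserve every node's binary degree", {
  set.seed(102)
  w <- random_weight_matrix(20, p_edge = 0.25)
  deg <- rowSums(w > 0)
  wsort <- sort(w[upper.tri(w) & w > 0])
  for (i in 1:10) {
    nw <- hemiconn:::.null_network(w)
    expect_identical(rowSums(nw > 0), deg)
    expect_equal(sort(nw[upper.tri(nw) & nw > 0]), wsort)  # same weight multiset
  }
})

test_that("normalized efficiencies are seeded and flag unrewirable graphs", {
  set.seed(103)
  w <- random_weight_matrix(15, p_edge = 0.4)
  a <- normalized_efficiencies(w, n_nulls = 10, seed = 5)
  b <- normalized_efficiencies(w, n_nulls = 10, seed = 5)
  expect_identical(a, b)
  expect_warning(normalized_efficiencies(triangle(), n_nulls = 3, seed = 1),
                 "complete")
})

test_that("connection classes match an exhaustive pair loop", {
  atlas <- default_atlas()
  set.seed(104)
  w <- random_weight_matrix(90, p_edge = 0.2)
  sp <- split_hemispheres(w, atlas)
  cc <- classify_connections(sp$L, sp$R, sp$inter)
  # brute force over all 4005 unordered pairs
  hemi <- atlas$hemisphere; partner <- atlas_partner(atlas)
  sums <- c(intra_left = 0, intra_right = 0, homotopic = 0, heterotopic = 0)
  for (i in 1:89) for (j in (i + 1):90) {
    cls <- if (hemi[i] == hemi[j]) {
      if (hemi[i] == "L") "intra_left" else "intra_right"
    } else if (partner[i] == j) "homotopic" else "heterotopic"
    sums[cls] <- sums[cls] + w[i, j]
  }
  expect_equal(cc$intra_left, unname(sums["intra_left"]))
  expect_equal(cc$intra_right, unname(sums["intra_right"]))
  expect_equal(cc$homotopic, unname(sums["homotopic"]))
  expect_equal(cc$heterotopic, unname(sums["heterotopic"]))
  # totals conserved
  expect_equal(sum(unlist(cc[, 3:6])), sum(w[upper.tri(w)]))
  # zero matrix
  spz <- split_hemispheres(matrix(0, 90, 90), atlas)
  ccz <- classify_connections(spz$L, spz$R, spz$inter)
  expect_true(all(unlist(ccz[, 3:6]) == 0))
})

test_that("nodal degrees match combinatorics and an exhaustive loop", {
  atlas <- default_atlas()
  ones <- matrix(1, 90, 90); diag(ones) <- 0
  sp <- split_hemispheres(ones, atlas)
  nd <- nodal_degrees(sp$L, sp$R, sp$inter, atlas)
  expect_true(all(nd$intra_degree == 44))
  expect_true(all(nd$inter_degree == 45))
  # hemisphere intra-degree sum identity
  cc <- classify_connections(sp$L, sp$R, sp$inter)
  expect_equal(sum(nd$intra_degree[nd$hemisphere == "L"]), 2 * cc$intra_left)

  set.seed(105)
  w <- random_weight_matrix(90, p_edge = 0.15)
  sp <- split_hemispheres(w, atlas)
  nd <- nodal_degrees(sp$L, sp$R, sp$inter, atlas)
  hemi <- atlas$hemisphere
  for (r in sample(90, 8)) {
    same <- which(hemi == hemi[r]); other <- which(hemi != hemi[r])
    row <- nd[nd$region_id == r, ]
    expect_equal(row$intra_degree, sum(w[r, same]))
    expect_equal(row$inter_degree, sum(w[r, other]))
  }
  # zero inter field
  wz <- w
  wz[hemi == "L", hemi == "R"] <- 0
  wz[hemi == "R", hemi == "L"] <- 0
  spz <- split_hemispheres(wz, atlas)
  ndz <- nodal_degrees(spz$L, spz$R, spz$inter, atlas)
  expect_true(all(ndz$inter_degree == 0))
})

test_that("area under the density curve matches closed forms and an oracle", {
  grid <- seq(0.08, 0.15, by = 0.01)
  expect_equal(auc_over_densities(rep(3, 8), grid), 3 * 0.07)
  lin <- 2 * grid + 1
  expect_equal(auc_over_densities(lin, grid),
               0.07 * (min(lin) + max(lin)) / 2)
  set.seed(106)
  v <- runif(8)
  expect_equal(auc_over_densities(v, grid), pracma::trapz(grid, v))
  expect_error(auc_over_densities(v[1:5], grid), "one value per")
})
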