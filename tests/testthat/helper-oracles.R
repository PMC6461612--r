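# Shared fixtures and independent oracles.

# random symmetric non-negative weight matrix (sparse-ish)
random_weight_matrix <- function(n, p_edge = 0.5, wmin = 0.1, wmax = 1) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  sel <- ut & (matrix(stats::runif(n * n), n, n) < p_edge)
  w[sel] <- stats::runif(sum(sel), wmin, wmax)
  w + t(w)
}

# Independent efficiency oracle built on igraph's shortest paths (the
# package implementation uses its own Floyd-Warshall core).
oracle_global_efficiency <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(0)
  w <- w / mx
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(0)
  wn <- w / mx
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(wn[i, ] > 0)
    if (length(nb) < 2) next
    sub <- wn[nb, nb, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    inv <- 1 / d
    diag(inv) <- 0
    inv[is.infinite(d)] <- 0
    k <- length(nb)
    vals[i] <- sum(inv) / (k * (k - 1))
  }
  mean(vals)
}

# minimal 4-region atlas data.frame (2 homotopic pairs)
toy_atlas_df <- function() {
  data.frame(region_id = 1:4,
             name = c("A left", "A right", "B left", "B right"),
             abbreviation = c("A.L", "A.R", "B.L", "B.R"),
             hemisphere = c("L", "R", "L", "R"),
             homotopic_partner_id = c(2L, 1L, 4L, 3L),
             size_volume = c(10, 11, 20, 21),
             size_area = c(5, 6, 7, 8),
             stringsAsFactors = FALSE)
}

# minimal subject table for stats tests
toy_subjects <- function(n_per_group, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    data.frame(subject_id = sprintf("s%03d", seq_len(n)),
               group = rep(c("MDD", "HC"), each = n_per_group),
               age = round(stats::rnorm(n, 40, 10)),
               gender = sample(c("F", "M"), n, replace = TRUE),
               education = round(stats::rnorm(n, 12, 3)),
               mean_fd = exp(stats::rnorm(n, log(0.12), 0.3)),
               hamd = c(rep(20L, n_per_group), rep(2L, n_per_group)),
               duration = c(rep(24, n_per_group), rep(0, n_per_group)),
               stringsAsFactors = FALSE)
  })
}

# Watts-Strogatz-style fixture: ring lattice (k neighbors each side) with
# extra random shortcuts, mildly varied weights
ring_lattice_shortcuts <- function(n = 45, k = 3, shortcuts = 30, seed = 1) {
  withr::with_seed(seed, {
    w <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (s in seq_len(k)) {
        j <- ((i + s - 1) %% n) + 1
        w[i, j] <- w[j, i] <- stats::runif(1, 0.8, 1.2)
      }
    }
    for (r in seq_len(shortcuts)) {
      ij <- sample(n, 2)
      w[ij[1], ij[2]] <- w[ij[2], ij[1]] <- stats::runif(1, 0.8, 1.2)
    }
    w
  })
}

# independent oracle for the two-level mixed ANCOVA: car's repeated-measures
# general linear model with type-III tests
car_anova_oracle <- function(L, R, subjects, covariates) {
  dd <- data.frame(L = L, R = R,
                   group = factor(subjects$group, levels = c("HC", "MDD")))
  for (v in covariates) {
    x <- subjects[[v]]
    if (!is.numeric(x)) x <- as.numeric(factor(x)) - 1
    dd[[v]] <- x - mean(x)
  }
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  form <- stats::as.formula(paste("cbind(L, R) ~ group +",
                                  paste(covariates, collapse = " + ")))
  mod <- stats::lm(form, data = dd)
  av <- summary(car::Anova(mod, idata = data.frame(hemi = factor(c("L", "R"))),
                           idesign = ~hemi, type = 3),
                univariate = TRUE)$univariate.tests
  c(group = av["group", "F value"], hemi = av["hemi", "F value"],
    interaction = av["group:hemi", "F value"])
}
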