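# Inferential layer: demographics tests, the two-way mixed group x
# hemisphere ANCOVA, post hoc tests, Bonferroni-corrected region-wise
# tests, partial brain-clinical correlations and the regional-size
# validation.
#
# With exactly two within-subject levels (L, R) the mixed ANOVA with
# covariates factorizes exactly into two covariate-adjusted regressions:
#   * group main effect: subject mean (L + R)/2 ~ group + covariates;
#   * hemisphere main effect and group x hemisphere interaction:
#     difference (R - L) ~ 1 + group + covariates, where the intercept
#     carries the hemisphere effect and the group coefficient the
#     interaction.
# Covariates and the group indicator are mean-centered so the difference-
# model intercept is the grand hemisphere effect; each F is the squared t
# of the corresponding coefficient, with denominator df = n - 2 - k for k
# covariates. This reproduces the classical general-linear-model fit (see
# the test suite, which checks it against an independent GLM).

# centered design pieces: group indicator (MDD = 1) and covariate matrix
.design <- function(subjects, covariates) {
  # effect coding +/- 0.5: the difference-model intercept is then the
  # UNWEIGHTED grand hemisphere effect (classical type-III convention),
  # also under unbalanced groups
  g <- ifelse(subjects$group == "MDD", 0.5, -0.5)
  if (length(unique(g)) < 2) stop("both groups must be present")
  X <- NULL
  if (length(covariates) > 0) {
    cols <- lapply(covariates, function(v) {
      if (!v %in% names(subjects)) stop("missing covariate: ", v)
      x <- subjects[[v]]
      if (!is.numeric(x)) x <- as.numeric(factor(x)) - 1   # e.g. gender 0/1
      x
    })
    X <- do.call(cbind, cols)
    colnames(X) <- covariates
    X <- scale(X, center = TRUE, scale = FALSE)
    if (qr(cbind(1, X))$rank < ncol(X) + 1) {
      stop("covariates are rank-deficient")
    }
  }
  list(g = g, X = X, n = length(g))
}

# coefficient t statistics for (possibly multi-column) responses Y against
# a fixed design; returns list(t = p x q matrix, beta, df_res)
.fit_t <- function(Xm, Y) {
  if (nrow(Xm) - ncol(Xm) < 1) {
    stop("too few subjects (", nrow(Xm), ") for a model with ", ncol(Xm),
         " coefficients")
  }
  qr_x <- qr(Xm)
  beta <- qr.coef(qr_x, Y)
  res <- qr.resid(qr_x, Y)
  df_res <- nrow(Xm) - ncol(Xm)
  sigma2 <- colSums(as.matrix(res)^2) / df_res
  cjj <- diag(chol2inv(qr.R(qr_x)))
  se <- sqrt(outer(cjj, sigma2))
  tmat <- as.matrix(beta) / se
  tmat[se == 0 & as.matrix(beta) == 0] <- 0   # degenerate: no signal, no noise
  list(t = tmat, beta = as.matrix(beta), df_res = df_res)
}

# vectorized two-level mixed ANCOVA for q responses; M, D are n x q
# matrices of subject means and (R - L) differences
.mixed_anova_multi <- function(M, D, des) {
  Xm <- cbind(`(Intercept)` = 1, group = des$g, des$X)
  fm <- .fit_t(Xm, M)
  fd <- .fit_t(Xm, D)
  list(F_group = fm$t[2, ]^2, beta_group = fm$beta[2, ],
       F_hemi = fd$t[1, ]^2, beta_hemi = fd$beta[1, ],
       F_interaction = fd$t[2, ]^2, beta_interaction = fd$beta[2, ],
       df1 = 1, df2 = fm$df_res,
       p_group = stats::pf(fm$t[2, ]^2, 1, fm$df_res, lower.tail = FALSE),
       p_hemi = stats::pf(fd$t[1, ]^2, 1, fd$df_res, lower.tail = FALSE),
       p_interaction = stats::pf(fd$t[2, ]^2, 1, fd$df_res,
                                 lower.tail = FALSE))
}

# align a (subject_id, L, R) data.frame or n x 2 matrix with subjects
.two_level_values <- function(values, subjects) {
  if (is.data.frame(values)) {
    i <- match(subjects$subject_id, values$subject_id)
    if (anyNA(i)) stop("values missing for some subjects")
    cbind(L = values$L[i], R = values$R[i])
  } else {
    v <- as.matrix(values)
    if (nrow(v) != nrow(subjects) || ncol(v) != 2) {
      stop("values must be an n x 2 (L, R) matrix aligned with subjects")
    }
    colnames(v) <- c("L", "R")
    v
  }
}

#' Two-way mixed group x hemisphere ANCOVA
#'
#' Tests the group main effect, hemisphere main effect, and group x
#' hemisphere interaction of a per-subject two-hemisphere measure, adjusting
#' for covariates, via the exact two-regression factorization of the
#' two-level mixed design (see the package vignette).
#'
#' @param values data.frame with columns subject_id, L, R, or an n x 2
#'   matrix in subject order.
#' @param subjects a `subject_table` (needs `group` plus the covariates).
#' @param covariates character vector of covariate column names (non-numeric
#'   columns such as gender are coded 0/1; all covariates are centered).
#' @param measure label for reporting.
#' @return object of class `mixed_anova_result`: F, p and df per effect,
#'   effect directions, and the design summary.
#' @export
mixed_anova <- function(values, subjects,
                        covariates = c("age", "gender", "education"),
                        measure = "measure") {
  v <- .two_level_values(values, subjects)
  des <- .design(subjects, covariates)
  if (min(table(subjects$group)) < 3) stop("need at least 3 subjects per group")
  M <- cbind((v[, "L"] + v[, "R"]) / 2)
  D <- cbind(v[, "R"] - v[, "L"])
  fit <- .mixed_anova_multi(M, D, des)
  structure(list(
    measure = measure, n = des$n,
    df = c(1, fit$df2), covariates = covariates,
    F_group = unname(fit$F_group), p_group = unname(fit$p_group),
    F_hemi = unname(fit$F_hemi), p_hemi = unname(fit$p_hemi),
    F_interaction = unname(fit$F_interaction),
    p_interaction = unname(fit$p_interaction),
    direction_group = if (fit$beta_group < 0) "MDD < HCs" else "MDD > HCs",
    direction_hemi = if (fit$beta_hemi > 0) "RH > LH" else "LH > RH"),
    class = "mixed_anova_result")
}

#' @export
print.mixed_anova_result <- function(x, ...) {
  cat(sprintf("Two-way mixed ANCOVA: %s (n = %d, df = %d, %d)\n",
              x$measure, x$n, x$df[1], x$df[2]))
  cat(sprintf("  group        F = %8.3f  p = %.4g  (%s)\n",
              x$F_group, x$p_group, x$direction_group))
  cat(sprintf("  hemisphere   F = %8.3f  p = %.4g  (%s)\n",
              x$F_hemi, x$p_hemi, x$direction_hemi))
  cat(sprintf("  interaction  F = %8.3f  p = %.4g\n",
              x$F_interaction, x$p_interaction))
  invisible(x)
}

#' Post hoc tests for the mixed ANCOVA
#'
#' Hemisphere post hoc: paired t test on R - L, with no covariates (the one
#' comparison run unadjusted). Group post hoc: independent t test on
#' covariate-residualized values pooled across both hemispheres, with
#' denominator df = 2n - 2 - k.
#'
#' @inheritParams mixed_anova
#' @param which "hemisphere" or "group".
#' @return one-row data.frame: test, T, df, p, direction.
#' @export
posthoc_tests <- function(values, subjects,
                          covariates = c("age", "gender", "education"),
                          which = c("hemisphere", "group")) {
  which <- match.arg(which)
  v <- .two_level_values(values, subjects)
  n <- nrow(v)
  if (which == "hemisphere") {
    d <- v[, "R"] - v[, "L"]
    if (stats::sd(d) == 0) {
      return(data.frame(test = "paired t (R vs L)", T = 0, df = n - 1,
                        p = 1, direction = "none",
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(d)
    return(data.frame(test = "paired t (R vs L)",
                      T = unname(tt$statistic), df = unname(tt$parameter),
                      p = tt$p.value,
                      direction = if (mean(d) > 0) "RH > LH" else "LH > RH",
                      stringsAsFactors = FALSE))
  }
  des <- .design(subjects, covariates)
  y <- c(v[, "L"], v[, "R"])
  Xc <- if (is.null(des$X)) matrix(1, 2 * n, 1) else
    cbind(1, rbind(des$X, des$X))
  res <- stats::lm.fit(Xc, y)$residuals
  grp <- rep(subjects$group, 2)
  k <- if (is.null(des$X)) 0 else ncol(des$X)
  t_raw <- stats::t.test(res[grp == "MDD"], res[grp == "HC"],
                         var.equal = TRUE)
  df_adj <- 2 * n - 2 - k
  tval <- unname(t_raw$statistic)
  data.frame(test = "independent t (MDD vs HCs, pooled hemispheres)",
             T = tval, df = df_adj,
             p = 2 * stats::pt(-abs(tval), df_adj),
             direction = if (tval < 0) "MDD < HCs" else "MDD > HCs",
             stringsAsFactors = FALSE)
}

#' Covariate-adjusted two-sample group test
#'
#' Independent group comparison via the regression `y ~ group + covariates`
#' (the design used for inter-hemispheric measures, which have no
#' within-subject factor).
#'
#' @param y per-subject values (subject order).
#' @param subjects a `subject_table`.
#' @param covariates covariate column names.
#' @param measure label.
#' @return one-row data.frame: measure, T, df, p, direction, group means.
#' @export
group_ttest <- function(y, subjects,
                        covariates = c("age", "gender", "education"),
                        measure = "measure") {
  des <- .design(subjects, covariates)
  Xm <- cbind(1, des$g, des$X)
  fit <- .fit_t(Xm, cbind(y))
  tval <- fit$t[2, 1]
  data.frame(measure = measure, T = tval, df = fit$df_res,
             p = 2 * stats::pt(-abs(tval), fit$df_res),
             direction = if (tval < 0) "MDD < HCs" else "MDD > HCs",
             mean_mdd = mean(y[subjects$group == "MDD"]),
             mean_hc = mean(y[subjects$group == "HC"]),
             stringsAsFactors = FALSE)
}

#' Demographics tests
#'
#' Pooled-variance two-sample t tests for age, education and head motion,
#' and a Pearson chi-squared test (no continuity correction) for gender.
#'
#' @param subjects a `subject_table` with both groups.
#' @return data.frame: variable, test, statistic, df, p.
#' @export
demographics_tests <- function(subjects) {
  if (length(unique(subjects$group)) < 2) stop("both groups must be present")
  mdd <- subjects$group == "MDD"
  row_t <- function(v) {
    x <- subjects[[v]][mdd]; y <- subjects[[v]][!mdd]
    n1 <- length(x); n2 <- length(y); df <- n1 + n2 - 2
    s2p <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
    se <- sqrt(s2p * (1 / n1 + 1 / n2))
    diffm <- mean(x) - mean(y)
    tval <- if (se == 0) { if (diffm == 0) 0 else sign(diffm) * Inf }
            else diffm / se
    data.frame(variable = v, test = "two-sample t",
               statistic = tval, df = df,
               p = 2 * stats::pt(-abs(tval), df), stringsAsFactors = FALSE)
  }
  tab <- table(subjects$group, subjects$gender)
  cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  rbind(row_t("age"), row_t("education"), row_t("mean_fd"),
        data.frame(variable = "gender", test = "chi-squared",
                   statistic = unname(cs$statistic),
                   df = unname(cs$parameter), p = cs$p.value,
                   stringsAsFactors = FALSE))
}

#' Region-wise mixed ANCOVA with Bonferroni correction
#'
#' Runs the two-level mixed ANCOVA for each homotopic region pair on a nodal
#' degree table and flags effects surviving Bonferroni correction over the
#' region family (alpha / n_pairs, per measure per modality).
#'
#' @param nodal data.frame from [nodal_degrees()] stacked over subjects.
#' @param atlas the `atlas_table`.
#' @param subjects a `subject_table`.
#' @param covariates covariate column names.
#' @param measure "intra_degree" or "inter_degree".
#' @param alpha family-wise level (default 0.05).
#' @return data.frame of class `region_effect_table`: one row per homotopic
#'   pair with F, p, Bonferroni flag and direction per effect.
#' @export
regionwise_tests <- function(nodal, atlas, subjects,
                             covariates = c("age", "gender", "education"),
                             measure = c("intra_degree", "inter_degree"),
                             alpha = 0.05) {
  measure <- match.arg(measure)
  des <- .design(subjects, covariates)
  lid <- atlas_hemi_ids(atlas, "L")
  partner <- atlas_partner(atlas)
  np <- length(lid)
  n <- nrow(subjects)
  get_vals <- function(ids) {
    sub <- nodal[nodal$region_id %in% ids, c("subject_id", "region_id", measure)]
    m <- matrix(NA_real_, n, length(ids))
    i <- match(sub$subject_id, subjects$subject_id)
    j <- match(sub$region_id, ids)
    m[cbind(i, j)] <- sub[[measure]]
    if (anyNA(m)) stop("nodal table is missing region values for some subjects")
    m
  }
  L <- get_vals(lid)
  R <- get_vals(partner[lid])
  fit <- .mixed_anova_multi((L + R) / 2, R - L, des)
  thr <- alpha / np
  lab <- sub("\\.L$", "", atlas$abbreviation[lid])
  out <- data.frame(
    region = lab, measure = measure,
    F_group = fit$F_group, p_group = fit$p_group,
    sig_group = fit$p_group < thr,
    dir_group = ifelse(fit$beta_group < 0, "MDD < HCs", "MDD > HCs"),
    F_hemi = fit$F_hemi, p_hemi = fit$p_hemi,
    sig_hemi = fit$p_hemi < thr,
    dir_hemi = ifelse(fit$beta_hemi > 0, "RH > LH", "LH > RH"),
    F_interaction = fit$F_interaction, p_interaction = fit$p_interaction,
    sig_interaction = fit$p_interaction < thr,
    stringsAsFactors = FALSE)
  attr(out, "bonferroni_threshold") <- thr
  attr(out, "df") <- c(1, fit$df2)
  class(out) <- c("region_effect_table", "data.frame")
  out
}

#' Partial correlation
#'
#' Pearson correlation of the residuals of x and y after regressing each on
#' the covariates; with no covariates this reduces exactly to the plain
#' Pearson correlation. p from t with df = n - 2 - k.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data.frame of covariates (or `NULL`).
#' @return list of class `partial_correlation_result`: r, p, n, df,
#'   covariate count; `undefined = TRUE` attribute on r when a residual has
#'   zero variance.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  k <- 0
  if (!is.null(covariates)) {
    Z <- as.matrix(covariates)
    if (!is.numeric(Z)) stop("covariates must be numeric")
    k <- ncol(Z)
    if (n <= k + 2) stop("need n > number of covariates + 2")
    Xm <- cbind(1, Z)
    if (qr(Xm)$rank < ncol(Xm)) stop("covariates are rank-deficient")
    sx <- stats::sd(x); sy <- stats::sd(y)
    x <- stats::lm.fit(Xm, x)$residuals
    y <- stats::lm.fit(Xm, y)$residuals
    # a residual numerically at zero means the variable is spanned by the
    # covariates; the partial correlation is undefined
    if (stats::sd(x) < 1e-10 * max(sx, 1)) x <- rep(0, n)
    if (stats::sd(y) < 1e-10 * max(sy, 1)) y <- rep(0, n)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    r <- structure(NA_real_, undefined = TRUE)
    return(structure(list(r = r, p = NA_real_, n = n, df = n - 2 - k,
                          n_covariates = k),
                     class = "partial_correlation_result"))
  }
  r <- stats::cor(x, y)
  df <- n - 2 - k
  tval <- r * sqrt(df / (1 - r^2))
  structure(list(r = r, p = 2 * stats::pt(-abs(tval), df), n = n, df = df,
                 n_covariates = k),
            class = "partial_correlation_result")
}

#' Regional-size validation
#'
#' Per subject and hemisphere, correlates the regional sizes (volume for
#' functional networks, surface area for structural networks) with the nodal
#' degrees, Fisher-z transforms the correlations, and feeds them into the
#' mixed ANCOVA. When any effect is significant at `alpha`, the region-wise
#' tests are recomputed on size-normalized degree (degree / size).
#'
#' @param nodal stacked [nodal_degrees()] table for one modality.
#' @param atlas the `atlas_table`.
#' @param subjects a `subject_table`.
#' @param covariates covariate column names.
#' @param modality "functional" (volume) or "structural" (area).
#' @param alpha significance level for triggering the normalized re-analysis.
#' @return list with `size_anova` (per measure) and `normalized_regions`
#'   (per measure region tables, or `NULL` when not triggered).
#' @export
regional_size_validation <- function(nodal, atlas, subjects,
                                     covariates = c("age", "gender", "education"),
                                     modality = c("functional", "structural"),
                                     alpha = 0.05) {
  modality <- match.arg(modality)
  size <- if (modality == "functional") atlas$size_volume else atlas$size_area
  if (stats::sd(size) == 0) stop("regional sizes have zero variance")
  measures <- c("intra_degree", "inter_degree")
  size_anova <- list()
  triggered <- FALSE
  for (ms in measures) {
    vals <- matrix(NA_real_, nrow(subjects), 2,
                   dimnames = list(NULL, c("L", "R")))
    for (h in c("L", "R")) {
      ids <- atlas_hemi_ids(atlas, h)
      sub <- nodal[nodal$hemisphere == h, c("subject_id", "region_id", ms)]
      for (i in seq_len(nrow(subjects))) {
        rows <- sub[sub$subject_id == subjects$subject_id[i], ]
        deg <- rows[[ms]][match(ids, rows$region_id)]
        r <- if (stats::sd(deg) == 0) 0 else stats::cor(size[ids], deg)
        vals[i, h] <- fisher_z(r)
      }
    }
    res <- mixed_anova(vals, subjects, covariates,
                       measure = paste0("size_correlation_", ms))
    size_anova[[ms]] <- res
    if (min(res$p_group, res$p_hemi, res$p_interaction) < alpha) {
      triggered <- TRUE
    }
  }
  normalized <- NULL
  if (triggered) {
    nn <- nodal
    sz <- size[nn$region_id]
    nn$intra_degree <- nn$intra_degree / sz
    nn$inter_degree <- nn$inter_degree / sz
    normalized <- lapply(measures, function(ms) {
      regionwise_tests(nn, atlas, subjects, covariates, measure = ms,
                       alpha = alpha)
    })
    names(normalized) <- measures
  }
  list(size_anova = size_anova, normalized_regions = normalized)
}
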