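#' Build a covariate-adjusted design matrix for group comparison
#'
#' Columns: intercept, group indicator (1 = patient), then the requested
#' covariates. Sex is coded 0/1 by first appearance of its labels in the
#' manifest.
#'
#' @param manifest cohort manifest data.frame.
#' @param covariates character vector of manifest columns to adjust for
#'   (default age, sex, mean framewise displacement).
#' @param patient_label group label treated as the patient group; defaults to
#'   the first label appearing in the manifest.
#' @return Full-column-rank n x p numeric matrix with named columns.
#' @export
design_matrix <- function(manifest,
                          covariates = c("age", "sex", "mean_fd"),
                          patient_label = NULL) {
  if (is.null(patient_label)) patient_label <- manifest$group[1]
  X <- cbind(intercept = rep(1, nrow(manifest)),
             group = as.numeric(manifest$group == patient_label))
  for (cv in covariates) {
    v <- manifest[[cv]]
    if (is.null(v)) stop("covariate '", cv, "' not in manifest")
    if (!is.numeric(v)) v <- as.numeric(factor(v, levels = unique(v))) - 1
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  X
}

#' Covariate-adjusted Hotelling's T-squared group test
#'
#' Multivariate linear model of the (typically bivariate) response on the
#' design matrix; the group effect is tested with the Hotelling-Lawley trace
#' for the single-row contrast selecting the group coefficient,
#' \eqn{T^2 = \nu \,\mathrm{tr}(H E^{-1})} with \eqn{\nu = n - p}, converted
#' to an exact F statistic \eqn{F = T^2 (\nu - q + 1)/(q\nu)} on
#' \eqn{(q, \nu - q + 1)} degrees of freedom (q = number of responses).
#'
#' @param Y n x q numeric response matrix (q >= 1).
#' @param X design matrix from [design_matrix()] (must contain a `group`
#'   column).
#' @return list with `T2`, `F`, `p`, `df`, and `coef` (the group coefficient
#'   per response).
#' @export
hotelling_group_test <- function(Y, X) {
  Y <- as.matrix(Y)
  n <- nrow(Y); q <- ncol(Y); p <- ncol(X)
  if (n != nrow(X)) stop("Y and X row counts differ")
  if (n <= p + q) stop("too few observations for the model")
  g <- match("group", colnames(X))
  if (is.na(g)) stop("X has no 'group' column")
  qr_x <- qr(X)
  B <- qr.coef(qr_x, Y)
  E <- crossprod(qr.resid(qr_x, Y))
  nu <- n - p
  XtX_inv <- chol2inv(qr.R(qr_x))
  cvc <- XtX_inv[g, g]
  cb <- B[g, ]
  H <- tcrossprod(cb) / cvc
  E_inv <- tryCatch(solve(E), error = function(e)
    stop("singular residual cross-product matrix (degenerate responses)"))
  T2 <- nu * sum(diag(H %*% E_inv))
  Fstat <- T2 * (nu - q + 1) / (q * nu)
  pval <- stats::pf(Fstat, q, nu - q + 1, lower.tail = FALSE)
  list(T2 = T2, F = Fstat, p = pval, df = c(q, nu - q + 1), coef = cb)
}

#' Covariate-adjusted univariate group test
#'
#' Least-squares model of a single response on the design matrix; two-sided
#' t-test on the group coefficient.
#'
#' @param y numeric response vector.
#' @param X design matrix with a `group` column.
#' @return list with `t` (signed), `p`, `df`, `coef`.
#' @export
univariate_group_test <- function(y, X) {
  y <- as.numeric(y)
  n <- length(y); p <- ncol(X)
  g <- match("group", colnames(X))
  qr_x <- qr(X)
  b <- unname(qr.coef(qr_x, y)[g])
  rss <- sum(qr.resid(qr_x, y)^2)
  nu <- n - p
  se <- sqrt(rss / nu * chol2inv(qr.R(qr_x))[g, g])
  tstat <- b / se
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), nu), df = nu, coef = b)
}

#' Bonferroni adjustment
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param m family size.
#' @return `pmin(1, m * p)`.
#' @export
bonferroni <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= 1)
  pmin(1, m * p)
}

#' Regional (per-parcel) group tests on the first two gradients
#'
#' One covariate-adjusted Hotelling test per parcel, response = (G1, G2)
#' across subjects; Bonferroni family = number of parcels.
#'
#' @param fit a [fit_gradients()] result.
#' @param assign `network_assignment` (annotates each parcel's network).
#' @param covariates,patient_label passed to [design_matrix()].
#' @return data.frame: `parcel`, `network`, `T2`, `F`, `p`, `p_bonferroni`.
#' @export
regional_group_tests <- function(fit, assign,
                                 covariates = c("age", "sex", "mean_fd"),
                                 patient_label = NULL) {
  X <- design_matrix(fit$manifest, covariates, patient_label)
  P <- nrow(fit$template$components)
  G1 <- t(vapply(fit$embeddings, function(e) e$components[, 1], numeric(P)))
  G2 <- t(vapply(fit$embeddings, function(e) e$components[, 2], numeric(P)))
  res <- lapply(seq_len(P), function(j)
    hotelling_group_test(cbind(G1[, j], G2[, j]), X))
  out <- data.frame(parcel = seq_len(P),
                    network = as.character(assign$network),
                    T2 = vapply(res, `[[`, numeric(1), "T2"),
                    F = vapply(res, `[[`, numeric(1), "F"),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    stringsAsFactors = FALSE)
  out$p_bonferroni <- bonferroni(out$p, P)
  out
}

#' Network-level group tests
#'
#' (a) bivariate Hotelling test of the within-network (G1, G2) scores per
#' network (family 7); (b) univariate test of within-network dispersion per
#' network (family 7); (c) univariate test of between-network dispersion per
#' network pair (family 21); (d) univariate test of global gradient variation
#' per gradient (family 2). All models adjust for the given covariates.
#'
#' @param metrics a [network_metrics()] result.
#' @param covariates,patient_label passed to [design_matrix()].
#' @return list of data.frames `score`, `dispersion`, `between`, `variation`,
#'   each with statistic, `p` and `p_bonferroni` columns.
#' @export
network_group_tests <- function(metrics,
                                covariates = c("age", "sex", "mean_fd"),
                                patient_label = NULL) {
  stopifnot(inherits(metrics, "network_metrics"))
  X <- design_matrix(metrics$manifest, covariates, patient_label)
  lv <- metrics$networks

  score <- do.call(rbind, lapply(lv, function(k) {
    h <- hotelling_group_test(cbind(metrics$score_g1[, k], metrics$score_g2[, k]), X)
    data.frame(network = k, T2 = h$T2, F = h$F, p = h$p, stringsAsFactors = FALSE)
  }))
  score$p_bonferroni <- bonferroni(score$p, length(lv))

  dispersion <- do.call(rbind, lapply(lv, function(k) {
    u <- univariate_group_test(metrics$dispersion[, k], X)
    data.frame(network = k, t = u$t, coef = u$coef, p = u$p, stringsAsFactors = FALSE)
  }))
  dispersion$p_bonferroni <- bonferroni(dispersion$p, length(lv))

  pair_names <- colnames(metrics$between)
  between <- do.call(rbind, lapply(pair_names, function(pr) {
    u <- univariate_group_test(metrics$between[, pr], X)
    data.frame(pair = pr, t = u$t, coef = u$coef, p = u$p, stringsAsFactors = FALSE)
  }))
  between$p_bonferroni <- bonferroni(between$p, length(pair_names))

  variation <- do.call(rbind, lapply(c("G1", "G2"), function(gg) {
    u <- univariate_group_test(metrics$variation[, gg], X)
    data.frame(gradient = gg, t = u$t, coef = u$coef, p = u$p, stringsAsFactors = FALSE)
  }))
  variation$p_bonferroni <- bonferroni(variation$p, 2)

  list(score = score, dispersion = dispersion, between = between,
       variation = variation)
}

#' Spearman correlation with Fisher-transform confidence interval
#'
#' Spearman's rho as the Pearson correlation of average ranks, p-value from
#' the t approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}}, and a 95%
#' confidence interval via the Fisher transform
#' \eqn{\tanh(\mathrm{atanh}\,\rho \pm 1.96/\sqrt{n-3})}. Incomplete pairs are
#' dropped (pairwise deletion).
#'
#' @param x,y numeric vectors (may contain NA).
#' @param ci_inflation multiplier on the Fisher-z standard error
#'   (default 1.96 normal quantile; set `z = 1.03 * 1.96`-style inflation via
#'   this knob if a rank-based variance correction is wanted).
#' @return list with `rho`, `p`, `ci95`, `n`.
#' @export
spearman_with_ci <- function(x, y, ci_inflation = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero variance in ranks")
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p = p, ci95 = fisher_ci(rho, n, ci_inflation), n = n)
}

#' Fisher-transform confidence interval for a correlation
#'
#' \eqn{\tanh(\mathrm{atanh}\,\rho \pm 1.96\,c/\sqrt{n-3})} — the normal-theory
#' 95% interval on the z scale, back-transformed.
#'
#' @param rho correlation in [-1, 1].
#' @param n number of pairs (> 3).
#' @param ci_inflation multiplier `c` on the standard error (default 1;
#'   1.03 gives the rank-based variance-inflated variant).
#' @return length-2 numeric `c(low, high)`.
#' @export
fisher_ci <- function(rho, n, ci_inflation = 1) {
  stopifnot(n > 3, abs(rho) <= 1)
  zr <- atanh(min(1 - 1e-15, max(-1 + 1e-15, rho)))
  half <- ci_inflation * 1.96 / sqrt(n - 3)
  tanh(zr + c(-1, 1) * half)
}

#' Correlation screen of network gradient metrics against clinical scores
#'
#' Spearman correlations, restricted to the patient group, between each
#' within-network gradient score (7 networks x gradients 1-2 by default) and
#' each clinical variable, with Bonferroni correction over the whole screen.
#'
#' @param metrics a [network_metrics()] result.
#' @param variables manifest columns to correlate against (e.g. `"sdmt"`,
#'   `"edss"`, `"disease_duration"`, `"lesion_load"`, `"bpf"`).
#' @param patient_label patient group label (default: first label in the
#'   manifest).
#' @param family Bonferroni family size; defaults to
#'   `n_features * n_variables`.
#' @return data.frame: `feature`, `variable`, `n`, `rho`, `p`,
#'   `p_bonferroni`, `ci_low`, `ci_high`.
#' @export
correlation_screen <- function(metrics, variables = "sdmt",
                               patient_label = NULL, family = NULL) {
  stopifnot(inherits(metrics, "network_metrics"))
  man <- metrics$manifest
  if (is.null(patient_label)) patient_label <- man$group[1]
  pat <- man$group == patient_label
  feats <- cbind(`colnames<-`(metrics$score_g1, paste0("G1_", metrics$networks)),
                 `colnames<-`(metrics$score_g2, paste0("G2_", metrics$networks)))
  feats <- feats[pat, , drop = FALSE]
  if (is.null(family)) family <- ncol(feats) * length(variables)
  rows <- list()
  for (v in variables) {
    yv <- man[[v]][pat]
    for (f in colnames(feats)) {
      s <- spearman_with_ci(feats[, f], yv)
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, variable = v, n = s$n, rho = s$rho, p = s$p,
        ci_low = s$ci95[1], ci_high = s$ci95[2], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni(out$p, family)
  out
}

#' Cohort demographics comparison table
#'
#' Group-wise summaries with two-sample pooled-variance t-tests for
#' continuous variables and a continuity-corrected chi-squared test for
#' binary variables, in the style of a clinical Table 1.
#'
#' @param manifest cohort manifest.
#' @param continuous continuous manifest columns to compare (only those with
#'   data in both groups are tested; others are summarised with `NA`
#'   statistics).
#' @param binary binary (two-level) manifest columns, compared by 2x2
#'   chi-squared with continuity correction.
#' @return data.frame with one row per variable: per-group `mean ± sd` (or
#'   level counts), `statistic` name, `value`, `p`.
#' @export
demographics_table <- function(manifest,
                               continuous = c("age", "mean_fd", "sdmt", "bpf",
                                              "disease_duration", "lesion_load"),
                               binary = "sex") {
  gl <- unique(manifest$group)
  if (length(gl) != 2) stop("exactly two groups required")
  g1 <- manifest$group == gl[1]
  fmt <- function(v) if (all(is.na(v))) "N/A" else
    sprintf("%.2f ± %.2f", mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE))
  rows <- list()
  for (v in intersect(continuous, names(manifest))) {
    x1 <- manifest[[v]][g1]; x2 <- manifest[[v]][!g1]
    if (sum(is.finite(x1)) >= 2 && sum(is.finite(x2)) >= 2) {
      tt <- stats::t.test(x1, x2, var.equal = TRUE)
      stat <- unname(tt$statistic); pv <- tt$p.value
    } else {
      stat <- NA_real_; pv <- NA_real_
    }
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, group1 = fmt(x1), group2 = fmt(x2),
      statistic = "t", value = stat, p = pv, stringsAsFactors = FALSE)
  }
  for (v in intersect(binary, names(manifest))) {
    tab <- table(factor(manifest[[v]], levels = unique(manifest[[v]])),
                 factor(manifest$group, levels = gl))
    ct <- stats::chisq.test(tab, correct = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      variable = v,
      group1 = paste(tab[, 1], collapse = ":"),
      group2 = paste(tab[, 2], collapse = ":"),
      statistic = "chi_squared", value = unname(ct$statistic), p = ct$p.value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "groups") <- gl
  out
}
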