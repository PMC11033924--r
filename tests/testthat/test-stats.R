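fake_manifest <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("s%03d", 1:n),
             group = rep(c("MS", "HC"), length.out = n),
             age = rnorm(n, 40, 10),
             sex = sample(c("F", "M"), n, replace = TRUE),
             mean_fd = rlnorm(n, log(0.1), 0.3),
             stringsAsFactors = FALSE)
}

test_that("the covariate-adjusted Hotelling test reduces to the classical form", {
  set.seed(1)
  n <- 40
  g <- rep(c(1, 0), each = n / 2)
  Y <- matrix(rnorm(2 * n), n, 2) + 0.5 * g
  X <- cbind(intercept = 1, group = g)
  h <- hotelling_group_test(Y, X)
  # classical two-sample Hotelling T2
  m1 <- colMeans(Y[g == 1, ]); m2 <- colMeans(Y[g == 0, ])
  S_pool <- ((n / 2 - 1) * cov(Y[g == 1, ]) + (n / 2 - 1) * cov(Y[g == 0, ])) / (n - 2)
  T2_classic <- (n / 2) * (n / 2) / n *
    drop(t(m1 - m2) %*% solve(S_pool) %*% (m1 - m2))
  expect_equal(h$T2, T2_classic, tolerance = 1e-10)
  # exact F transform with q = 2
  expect_equal(h$F, h$T2 * (n - 2 - 1) / (2 * (n - 2)), tolerance = 1e-12)
})

test_that("identical group responses give a zero statistic and p = 1", {
  set.seed(2)
  Yhalf <- matrix(rnorm(30), 15, 2)
  Y <- rbind(Yhalf, Yhalf)
  X <- cbind(intercept = 1, group = rep(c(1, 0), each = 15))
  h <- hotelling_group_test(Y, X)
  expect_lt(h$T2, 1e-18)
  expect_equal(h$p, 1, tolerance = 1e-8)
})

test_that("a single-response Hotelling test equals the squared t statistic", {
  man <- fake_manifest(50, seed = 3)
  X <- design_matrix(man)
  set.seed(3)
  y <- rnorm(50) + 0.4 * X[, "group"] + 0.02 * X[, "age"]
  h <- hotelling_group_test(cbind(y), X)
  u <- univariate_group_test(y, X)
  expect_equal(h$T2, u$t^2, tolerance = 1e-10)
})

test_that("the Hotelling-Lawley trace agrees with R's multivariate anova", {
  man <- fake_manifest(50, seed = 9)
  X <- design_matrix(man)
  set.seed(90)
  Y <- matrix(rnorm(100), 50, 2)
  Y[, 1] <- Y[, 1] + 0.4 * X[, "group"]
  h <- hotelling_group_test(Y, X)
  dat <- data.frame(g = X[, "group"], age = X[, "age"],
                    sex = X[, "sex"], fd = X[, "mean_fd"])
  # sequential anova with the group term last tests the same marginal
  # hypothesis as the contrast formulation
  fit <- lm(Y ~ age + sex + fd + g, data = dat)
  av <- anova(fit, test = "Hotelling-Lawley")
  hl <- av["g", "Hotelling-Lawley"]
  expect_equal(h$T2, (50 - ncol(X)) * hl, tolerance = 1e-8)
  expect_equal(h$p, av["g", "Pr(>F)"], tolerance = 1e-8)
})

test_that("a univariate model without covariate effects matches the pooled t-test", {
  set.seed(4)
  n <- 60
  g <- rep(c(1, 0), each = n / 2)
  y <- rnorm(n) + 0.3 * g
  X <- cbind(intercept = 1, group = g)
  u <- univariate_group_test(y, X)
  tt <- t.test(y[g == 1], y[g == 0], var.equal = TRUE)
  expect_equal(u$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(u$p, tt$p.value, tolerance = 1e-10)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.4, 5), 1)
  expect_equal(bonferroni(c(0.2, 0.7), 1), c(0.2, 0.7))
})

test_that("Spearman correlation handles monotone, rank-formula and NA cases", {
  expect_equal(spearman_with_ci(1:10, (1:10)^3)$rho, 1)
  s <- spearman_with_ci(c(1, 2, 3, 4, 5), c(3, 1, 2, 5, 4))
  expect_equal(s$rho, cor(c(1, 2, 3, 4, 5), c(3, 1, 2, 5, 4), method = "spearman"),
               tolerance = 1e-12)
  # rank formula on the spec's 3-point case, padded to meet n >= 5
  expect_equal(cor(1:3, c(3, 1, 2), method = "spearman"), -0.5)
  # p agrees with R's t-approximation path
  set.seed(5)
  x <- rnorm(30); y <- 0.4 * x + rnorm(30)
  s2 <- spearman_with_ci(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(s2$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(s2$p, ct$p.value, tolerance = 1e-6)
  # pairwise deletion
  x[3] <- NA
  expect_equal(spearman_with_ci(x, y)$n, 29)
  expect_error(spearman_with_ci(rep(1, 10), 1:10), "zero variance")
  expect_error(spearman_with_ci(1:4, 1:4), "at least 5")
})

test_that("the Fisher-transform CI brackets rho and matches the closed form", {
  set.seed(6)
  x <- rnorm(50); y <- 0.5 * x + rnorm(50)
  s <- spearman_with_ci(x, y)
  expect_gte(s$rho, s$ci95[1]); expect_lte(s$rho, s$ci95[2])
  half <- 1.96 / sqrt(s$n - 3)
  expect_equal(s$ci95, tanh(atanh(s$rho) + c(-1, 1) * half), tolerance = 1e-12)
})

test_that("demographics table reproduces pooled t and chi-squared statistics", {
  man <- fake_manifest(80, seed = 7)
  man$sdmt <- ifelse(man$group == "MS", rnorm(80, 38, 13), NA)
  tab <- demographics_table(man)
  # pooled t for age matches the direct formula
  a1 <- man$age[man$group == "MS"]; a2 <- man$age[man$group == "HC"]
  sp <- sqrt(((length(a1) - 1) * var(a1) + (length(a2) - 1) * var(a2)) /
               (length(a1) + length(a2) - 2))
  t_direct <- (mean(a1) - mean(a2)) / (sp * sqrt(1 / length(a1) + 1 / length(a2)))
  expect_equal(tab$value[tab$variable == "age"], t_direct, tolerance = 1e-12)
  # one-group-only variables are summarized but not tested
  expect_true(is.na(tab$value[tab$variable == "sdmt"]))
  expect_identical(tab$group2[tab$variable == "sdmt"], "N/A")
  # chi-squared on sex matches stats::chisq.test with continuity correction
  ct <- chisq.test(table(man$sex, man$group)[, c("MS", "HC")], correct = TRUE)
  expect_equal(tab$value[tab$variable == "sex"], unname(ct$statistic),
               tolerance = 1e-12)
  # identical groups produce null statistics
  man2 <- rbind(man, man)
  man2$group <- rep(c("MS", "HC"), each = 80)
  man2$subject_id <- sprintf("d%03d", 1:160)
  tab2 <- demographics_table(man2)
  expect_equal(tab2$value[tab2$variable == "age"], 0, tolerance = 1e-12)
  expect_equal(tab2$value[tab2$variable == "sex"], 0, tolerance = 1e-12)
})

test_that("design matrices encode group and sex as documented", {
  man <- fake_manifest(20, seed = 8)
  X <- design_matrix(man)
  expect_identical(colnames(X), c("intercept", "group", "age", "sex", "mean_fd"))
  expect_equal(X[, "group"], as.numeric(man$group == "MS"))
  expect_equal(X[, "sex"], as.numeric(factor(man$sex, levels = unique(man$sex))) - 1)
  man$dup <- man$age
  expect_error(design_matrix(man, covariates = c("age", "dup")), "rank deficient")
})

test_that("network and regional tests produce coherent Bonferroni families", {
  coh <- small_cohort(n = c(MS = 8L, HC = 8L))
  fit <- fit_gradients(coh)
  met <- network_metrics(fit, coh$lookup)
  ng <- network_group_tests(met)
  expect_equal(nrow(ng$score), 7)
  expect_equal(nrow(ng$between), 21)
  expect_equal(ng$score$p_bonferroni, pmin(1, 7 * ng$score$p))
  expect_equal(ng$between$p_bonferroni, pmin(1, 21 * ng$between$p))
  expect_equal(ng$variation$p_bonferroni, pmin(1, 2 * ng$variation$p))
  reg <- regional_group_tests(fit, coh$lookup)
  expect_equal(nrow(reg), 200)
  expect_equal(reg$p_bonferroni, pmin(1, 200 * reg$p))
  expect_true(all(is.finite(reg$T2)))
})

test_that("the correlation screen restricts to patients and reports every pair", {
  coh <- small_cohort(seed = 21, n = c(MS = 25L, HC = 10L))
  fit <- fit_gradients(coh)
  met <- network_metrics(fit, coh$lookup)
  cs <- correlation_screen(met, variables = c("sdmt", "edss"))
  expect_equal(nrow(cs), 28)
  expect_true(all(cs$n <= 25))
  expect_equal(cs$p_bonferroni, pmin(1, 28 * cs$p))
  # a variable equal to a metric correlates perfectly
  met2 <- met
  met2$manifest$probe <- met$score_g1[, "DMN"]
  cs2 <- correlation_screen(met2, variables = "probe")
  expect_equal(cs2$rho[cs2$feature == "G1_DMN"], 1)
})
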