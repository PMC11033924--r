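# Small deterministic feature tables keep the boosted-tree tests quick.
toy_features <- function(n, seed = 1, p = 14) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("G", rep(1:2, each = p / 2), "_",
                                           rep(head(LETTERS, p / 2), 2))))
  list(x = x, y = rnorm(n), subject_id = sprintf("s%03d", 1:n))
}

fast_cfg <- function(...) {
  defaults <- list(
    grid = data.frame(max_depth = 3L, eta = 0.3, nrounds = 30L),
    perm_grid = data.frame(max_depth = 3L, eta = 0.3, nrounds = 30L),
    n_permutations = 20L, repetitions = 3L)
  do.call(prediction_config, utils::modifyList(defaults, list(...)))
}

test_that("the hold-out split is deterministic, exhaustive and ceiling-sized", {
  ft <- toy_features(116)
  sp1 <- split_holdout(ft, 0.20, seed = 4)
  sp2 <- split_holdout(ft, 0.20, seed = 4)
  expect_identical(sp1$holdout_idx, sp2$holdout_idx)
  expect_length(sp1$holdout$y, 24)   # ceiling(0.2 * 116)
  expect_length(sp1$train$y, 92)
  expect_setequal(c(sp1$train$subject_id, sp1$holdout$subject_id), ft$subject_id)
  expect_length(intersect(sp1$train$subject_id, sp1$holdout$subject_id), 0)
  expect_error(split_holdout(ft, 1.2), "fraction")
  expect_error(split_holdout(toy_features(10), 0.2), "at least 20")
})

test_that("a perfect predictor is ranked first and selected alone", {
  ft <- toy_features(60, seed = 2)
  ft$y <- ft$x[, "G2_D"] * 10
  fit <- nested_cv_fit(ft, fast_cfg(), rep_seed = 1)
  expect_identical(fit$ranking[1], "G2_D")
  expect_true("G2_D" %in% fit$selected)
  expect_lt(fit$validation_mae, 0.1 * sd(ft$y))
  expect_error(nested_cv_fit(list(x = ft$x, y = rep(1, 60)), fast_cfg(), 1),
               "constant")
})

test_that("selection never degrades the criterion it optimizes", {
  ft <- toy_features(50, seed = 3)
  ft$y <- 2 * ft$x[, 1] + ft$x[, 2] + rnorm(50, 0, 0.5)
  fit <- nested_cv_fit(ft, fast_cfg(), rep_seed = 2)
  expect_lte(fit$validation_mae, fit$mae_by_n[length(fit$mae_by_n)] + 1e-12)
  expect_equal(fit$validation_mae, min(fit$mae_by_n))
  # smallest n wins ties by construction
  expect_equal(fit$n_selected, which.min(fit$mae_by_n))
})

test_that("hold-out subjects never influence training artifacts", {
  ft <- toy_features(60, seed = 4)
  ft$y <- ft$x[, 3] + rnorm(60, 0, 0.3)
  cfg <- fast_cfg(seed = 11)
  sp <- split_holdout(ft, 0.2, seed = cfg$seed)
  fit1 <- nested_cv_fit(sp$train, cfg, rep_seed = 99)
  # mutate hold-out targets; the training path must not change
  ft2 <- ft
  ft2$y[sp$holdout_idx] <- ft2$y[sp$holdout_idx] + 100
  sp2 <- split_holdout(ft2, 0.2, seed = cfg$seed)
  expect_identical(sp2$holdout_idx, sp$holdout_idx)
  fit2 <- nested_cv_fit(sp2$train, cfg, rep_seed = 99)
  expect_identical(fit1$ranking, fit2$ranking)
  expect_identical(fit1$selected, fit2$selected)
  expect_equal(fit1$validation_mae, fit2$validation_mae, tolerance = 1e-12)
})

test_that("hold-out evaluation computes the mean absolute error", {
  ft <- toy_features(40, seed = 5)
  ft$y <- ft$x[, 1] * 5
  sp <- split_holdout(ft, 0.25, seed = 1)
  m <- gradmap:::xgb_fit(sp$train$x[, 1, drop = FALSE], sp$train$y,
                         data.frame(max_depth = 2L, eta = 0.3, nrounds = 100L))
  mae <- holdout_evaluate(m, colnames(ft$x)[1], sp$holdout)
  pred <- gradmap:::xgb_predict(m, sp$holdout$x[, 1, drop = FALSE])
  expect_equal(mae, mean(abs(pred - sp$holdout$y)), tolerance = 1e-12)
  expect_error(holdout_evaluate(m, "nope", sp$holdout), "nope")
})

test_that("permutation p-values are valid and hit the boundary correctly", {
  ft <- toy_features(40, seed = 6)
  ft$y <- ft$x[, 2] * 3 + rnorm(40, 0, 0.2)
  cfg <- fast_cfg()
  # an observed MAE better than every permutation gives the minimum p
  perm <- permutation_significance(ft, cfg, observed_mae = 0, seed = 123)
  expect_equal(perm$p, 1 / (cfg$n_permutations + 1))
  # an observed MAE worse than every permutation gives p = 1
  perm2 <- permutation_significance(ft, cfg, observed_mae = 1e6, seed = 123)
  expect_equal(perm2$p, 1)
  expect_length(perm$null_mae, 20)
})

test_that("direction of influence recovers planted monotone dependence", {
  set.seed(7)
  x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("up", "noise")))
  pred <- 2 * x[, "up"] + rnorm(100, 0, 0.1)
  rho <- direction_of_influence(c("up", "noise"), x, pred)
  expect_gt(rho["up"], 0.8)
  expect_lt(abs(rho["noise"]), 0.3)
})

test_that("the full prediction wrapper is reproducible with fixed seeds", {
  ft <- toy_features(45, seed = 8)
  ft$y <- ft$x[, 1] + rnorm(45, 0, 0.5)
  cfg <- fast_cfg(seed = 5, repetitions = 2L, n_permutations = 5L)
  p1 <- sdmt_prediction(ft, cfg)
  p2 <- sdmt_prediction(ft, cfg)
  expect_identical(p1$validation_mae, p2$validation_mae)
  expect_identical(p1$holdout_mae, p2$holdout_mae)
  expect_identical(p1$permutation_p, p2$permutation_p)
  expect_identical(lapply(p1$repetitions, `[[`, "selected"),
                   lapply(p2$repetitions, `[[`, "selected"))
  expect_s3_class(p1, "sdmt_prediction")
  expect_gte(p1$permutation_p, 0)
  expect_output(print(p1), "validation MAE")
})
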