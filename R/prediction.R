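#' Network gradient feature table for prediction
#'
#' Assembles the 14 within-network gradient scores (7 networks x gradients
#' 1-2) and the cognition-score target for the patient group; subjects with
#' a missing target are dropped.
#'
#' @param metrics a [network_metrics()] result.
#' @param target manifest column holding the score to predict (default
#'   `"sdmt"`).
#' @param patient_label patient group label (default: first label in the
#'   manifest).
#' @return list with `x` (n x 14 matrix, columns `G<g>_<network>`), `y`
#'   (targets) and `subject_id`.
#' @export
gradient_features <- function(metrics, target = "sdmt", patient_label = NULL) {
  stopifnot(inherits(metrics, "network_metrics"))
  man <- metrics$manifest
  if (is.null(patient_label)) patient_label <- man$group[1]
  keep <- man$group == patient_label & is.finite(man[[target]])
  x <- cbind(`colnames<-`(metrics$score_g1, paste0("G1_", metrics$networks)),
             `colnames<-`(metrics$score_g2, paste0("G2_", metrics$networks)))
  list(x = x[keep, , drop = FALSE], y = man[[target]][keep],
       subject_id = man$subject_id[keep])
}

#' Prediction configuration
#'
#' @param outer_folds,inner_folds cross-validation folds (defaults 5, 5).
#' @param repetitions number of repeated nested-CV runs with fresh fold
#'   splits (default 10).
#' @param holdout_fraction fraction of subjects set aside before any
#'   training (default 0.20; hold-out size is `ceiling(fraction * n)`).
#' @param n_permutations permutations for the significance test
#'   (default 1000).
#' @param grid data.frame hyperparameter grid with columns `max_depth`,
#'   `eta`, `nrounds` (default 3 x 3 x 3 spanning shallow/deep, slow/fast).
#' @param perm_grid reduced grid used inside permutation runs. The default
#'   `NULL` derives it from the data: the hyperparameter configuration most
#'   frequently selected across the observed repetitions' outer folds, so the
#'   null models mimic the complexity actually chosen on the real targets.
#'   Any explicit grid (including the full one, for exhaustive permutations)
#'   can be supplied instead.
#' @param subsample row subsampling for the boosted trees (default 1).
#' @param seed master seed.
#' @return A `prediction_config` list.
#' @export
prediction_config <- function(outer_folds = 5L, inner_folds = 5L,
                              repetitions = 10L, holdout_fraction = 0.20,
                              n_permutations = 1000L,
                              grid = expand.grid(max_depth = c(2L, 3L, 4L),
                                                 eta = c(0.05, 0.1, 0.3),
                                                 nrounds = c(50L, 100L, 200L)),
                              perm_grid = NULL,
                              subsample = 1, seed = 1L) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 1,
            outer_folds >= 2, inner_folds >= 2)
  structure(list(outer_folds = outer_folds, inner_folds = inner_folds,
                 repetitions = repetitions, holdout_fraction = holdout_fraction,
                 n_permutations = n_permutations, grid = grid,
                 perm_grid = perm_grid, subsample = subsample,
                 seed = as.integer(seed)),
            class = "prediction_config")
}

#' Hold-out split of a feature table
#'
#' Disjoint, exhaustive split into a training/validation set and a hold-out
#' test set of size `ceiling(fraction * n)`, drawn once by seed and fixed
#' across repetitions.
#'
#' @param ft feature table from [gradient_features()].
#' @param fraction hold-out fraction in (0, 1).
#' @param seed integer seed for the draw.
#' @return list with `train` and `holdout` feature tables and the index
#'   vectors used.
#' @export
split_holdout <- function(ft, fraction = 0.20, seed = 1L) {
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  n <- length(ft$y)
  if (n < 20) stop("need at least 20 subjects to split")
  set.seed(seed)
  n_hold <- ceiling(fraction * n)
  hold <- sort(sample.int(n, n_hold))
  subset_ft <- function(idx) list(x = ft$x[idx, , drop = FALSE], y = ft$y[idx],
                                  subject_id = ft$subject_id[idx])
  list(train = subset_ft(setdiff(seq_len(n), hold)),
       holdout = subset_ft(hold),
       holdout_idx = hold)
}

xgb_fit <- function(x, y, cfg_row, subsample = 1) {
  d <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(max_depth = cfg_row$max_depth, eta = cfg_row$eta,
                  subsample = subsample, objective = "reg:squarederror",
                  nthread = 1),
    data = d, nrounds = cfg_row$nrounds, verbose = 0)
}

xgb_predict <- function(model, x) {
  stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1))
}

xgb_gain <- function(model, feature_names) {
  imp <- xgboost::xgb.importance(model = model)
  gain <- stats::setNames(rep(0, length(feature_names)), feature_names)
  if (!is.null(imp) && nrow(imp)) gain[imp$Feature] <- imp$Gain
  gain
}

make_folds <- function(n, k) {
  f <- rep(seq_len(k), length.out = n)
  sample(f)
}

#' One repetition of nested cross-validation with importance-gain feature
#' selection
#'
#' For each outer fold, a grid search in the inner loop picks the boosted-tree
#' hyperparameters by mean inner-validation MAE; a model with all features is
#' fit on the outer-training portion and its importance gain extracted. The
#' feature ranking is the mean gain across outer folds. Models restricted to
#' the top-n features (n = 1..14) are then evaluated on the outer validation
#' folds, and the selected set is the n minimizing mean validation MAE
#' (smallest n on ties).
#'
#' @param train feature table (training/validation subjects only).
#' @param cfg a [prediction_config()].
#' @param rep_seed seed controlling this repetition's fold splits.
#' @param grid hyperparameter grid (defaults to `cfg$grid`; the permutation
#'   path passes `cfg$perm_grid`).
#' @return list with `ranking` (features by decreasing mean gain),
#'   `mean_gain`, `selected` (chosen feature subset), `validation_mae`,
#'   `mae_by_n`, `fold_configs`, `final_config` (modal fold config) and
#'   `oof_pred` (out-of-fold predictions of the selected models).
#' @export
nested_cv_fit <- function(train, cfg, rep_seed, grid = cfg$grid) {
  x <- train$x; y <- train$y
  if (stats::sd(y) == 0) stop("degenerate (constant) prediction target")
  n <- length(y); nf <- ncol(x)
  if (n < cfg$outer_folds * 2) stop("too few subjects for the outer folds")
  set.seed(rep_seed)
  outer <- make_folds(n, cfg$outer_folds)

  fold_configs <- vector("list", cfg$outer_folds)
  gains <- matrix(0, cfg$outer_folds, nf, dimnames = list(NULL, colnames(x)))
  for (f in seq_len(cfg$outer_folds)) {
    tr <- which(outer != f)
    if (nrow(grid) > 1) {
      inner <- make_folds(length(tr), cfg$inner_folds)
      mae_cfg <- vapply(seq_len(nrow(grid)), function(ci) {
        mean(vapply(seq_len(cfg$inner_folds), function(fi) {
          itr <- tr[inner != fi]; iva <- tr[inner == fi]
          m <- xgb_fit(x[itr, , drop = FALSE], y[itr], grid[ci, ], cfg$subsample)
          mean(abs(xgb_predict(m, x[iva, , drop = FALSE]) - y[iva]))
        }, numeric(1)))
      }, numeric(1))
      best <- which.min(mae_cfg)
    } else best <- 1L
    fold_configs[[f]] <- grid[best, , drop = FALSE]
    m_all <- xgb_fit(x[tr, , drop = FALSE], y[tr], grid[best, ], cfg$subsample)
    gains[f, ] <- xgb_gain(m_all, colnames(x))
  }
  mean_gain <- colMeans(gains)
  ranking <- colnames(x)[order(mean_gain, decreasing = TRUE)]

  mae_by_n <- numeric(nf)
  oof_by_n <- matrix(NA_real_, n, nf)
  for (nn in seq_len(nf)) {
    feats <- ranking[seq_len(nn)]
    for (f in seq_len(cfg$outer_folds)) {
      tr <- which(outer != f); va <- which(outer == f)
      m <- xgb_fit(x[tr, feats, drop = FALSE], y[tr], fold_configs[[f]],
                   cfg$subsample)
      oof_by_n[va, nn] <- xgb_predict(m, x[va, feats, drop = FALSE])
    }
    mae_by_n[nn] <- mean(abs(oof_by_n[, nn] - y))
  }
  n_sel <- which.min(mae_by_n)  # which.min takes the smallest index on ties
  modal <- table(vapply(fold_configs, function(g)
    paste(g$max_depth, g$eta, g$nrounds), ""))
  final_key <- names(modal)[which.max(modal)]
  final_config <- fold_configs[[match(final_key, vapply(fold_configs, function(g)
    paste(g$max_depth, g$eta, g$nrounds), ""))]]

  list(ranking = ranking, mean_gain = mean_gain,
       selected = ranking[seq_len(n_sel)], n_selected = n_sel,
       validation_mae = mae_by_n[n_sel], mae_by_n = mae_by_n,
       fold_configs = fold_configs, final_config = final_config,
       oof_pred = oof_by_n[, n_sel])
}

#' Permutation significance of the validation MAE
#'
#' Shuffles the training targets and reruns the full
#' ranking-plus-feature-selection procedure (with the reduced permutation
#' grid) to build a null MAE distribution;
#' `p = (1 + #(permuted MAE <= observed)) / (n_permutations + 1)`.
#'
#' @param train training feature table.
#' @param cfg a [prediction_config()].
#' @param observed_mae validation MAE obtained on the unshuffled targets by
#'   the identical procedure.
#' @param seed seed for the permutation draws.
#' @param grid hyperparameter grid for the permutation runs (defaults to
#'   `cfg$perm_grid`; must be supplied when that is `NULL`).
#' @return list with `p` and `null_mae` (the permuted MAE values).
#' @export
permutation_significance <- function(train, cfg, observed_mae,
                                     seed = cfg$seed + 10000L,
                                     grid = cfg$perm_grid) {
  if (is.null(grid)) stop("no permutation grid supplied")
  null_mae <- numeric(cfg$n_permutations)
  for (b in seq_len(cfg$n_permutations)) {
    set.seed(seed + b)
    perm <- train
    perm$y <- sample(train$y)
    fit <- nested_cv_fit(perm, cfg, rep_seed = seed + b, grid = grid)
    null_mae[b] <- fit$validation_mae
  }
  list(p = (1 + sum(null_mae <= observed_mae)) / (cfg$n_permutations + 1),
       null_mae = null_mae)
}

#' Hold-out evaluation of a final model
#'
#' @param model fitted boosted-tree model (trained on the full
#'   training/validation set with the selected features).
#' @param features the selected feature names the model was trained on.
#' @param holdout hold-out feature table.
#' @return mean absolute error on the hold-out subjects.
#' @export
holdout_evaluate <- function(model, features, holdout) {
  if (!all(features %in% colnames(holdout$x)))
    stop("hold-out table lacks feature(s): ",
         paste(setdiff(features, colnames(holdout$x)), collapse = ", "))
  mean(abs(xgb_predict(model, holdout$x[, features, drop = FALSE]) - holdout$y))
}

#' Direction of influence of top-ranked features
#'
#' Spearman correlation between each given feature's values and the
#' out-of-fold predicted targets of one repetition; the sign indicates
#' whether larger feature values push predictions up or down.
#'
#' @param features feature names to assess.
#' @param x feature matrix (training subjects).
#' @param predictions out-of-fold predictions for the same subjects.
#' @return named numeric vector of Spearman rho.
#' @export
direction_of_influence <- function(features, x, predictions) {
  vapply(features, function(f)
    spearman_with_ci(x[, f], predictions)$rho, numeric(1))
}

#' Predict a cognition score from network gradient features
#'
#' The full prediction framework: a fixed 80/20 hold-out split, repeated
#' fivefold nested cross-validation with grid-searched boosted trees and
#' iterative importance-gain feature selection, permutation significance of
#' the validation MAE, and per-repetition hold-out evaluation of the final
#' model.
#'
#' @param ft feature table from [gradient_features()].
#' @param cfg a [prediction_config()].
#' @param top_k number of top-ranked features whose direction of influence is
#'   reported (default 3).
#' @return An `sdmt_prediction` object: per-repetition results
#'   (`repetitions`), aggregate validation and hold-out MAE (mean, sd),
#'   consensus feature ranking, selection counts, permutation p, and
#'   direction-of-influence summaries.
#' @export
sdmt_prediction <- function(ft, cfg = prediction_config(), top_k = 3L) {
  split <- split_holdout(ft, cfg$holdout_fraction, seed = cfg$seed)
  reps <- vector("list", cfg$repetitions)
  val_mae <- hold_mae <- numeric(cfg$repetitions)
  rho_mat <- NULL
  for (r in seq_len(cfg$repetitions)) {
    fit <- nested_cv_fit(split$train, cfg, rep_seed = cfg$seed + 100L * r)
    val_mae[r] <- fit$validation_mae
    final <- xgb_fit(split$train$x[, fit$selected, drop = FALSE],
                     split$train$y, fit$final_config, cfg$subsample)
    hold_mae[r] <- holdout_evaluate(final, fit$selected, split$holdout)
    rho <- direction_of_influence(fit$ranking[seq_len(top_k)], split$train$x,
                                  fit$oof_pred)
    rho_mat <- rbind(rho_mat, rho)
    fit$holdout_mae <- hold_mae[r]
    fit$direction_rho <- rho
    reps[[r]] <- fit
  }
  sel_counts <- sort(table(unlist(lapply(reps, `[[`, "selected"))),
                     decreasing = TRUE)
  gain_mean <- colMeans(do.call(rbind, lapply(reps, `[[`, "mean_gain")))
  # permutation null: unless an explicit reduced grid was given, reuse the
  # hyperparameter configuration most often selected across the observed
  # outer folds, and compare against an observed MAE computed by the
  # identical (reduced) procedure
  perm_grid <- cfg$perm_grid
  if (is.null(perm_grid)) {
    all_cfgs <- do.call(rbind, unlist(lapply(reps, `[[`, "fold_configs"),
                                      recursive = FALSE))
    keys <- apply(all_cfgs, 1, paste, collapse = "|")
    perm_grid <- all_cfgs[match(names(which.max(table(keys))), keys), ,
                          drop = FALSE]
  }
  val_mae_reduced <- vapply(seq_len(cfg$repetitions), function(r)
    nested_cv_fit(split$train, cfg, rep_seed = cfg$seed + 100L * r,
                  grid = perm_grid)$validation_mae, numeric(1))
  perm <- permutation_significance(split$train, cfg, mean(val_mae_reduced),
                                   grid = perm_grid)
  structure(list(repetitions = reps, split = split,
                 validation_mae = c(mean = mean(val_mae), sd = stats::sd(val_mae)),
                 validation_mae_reduced = c(mean = mean(val_mae_reduced),
                                            sd = stats::sd(val_mae_reduced)),
                 holdout_mae = c(mean = mean(hold_mae), sd = stats::sd(hold_mae)),
                 selection_counts = sel_counts,
                 consensus_ranking = names(sort(gain_mean, decreasing = TRUE)),
                 mean_gain = gain_mean,
                 direction_rho = rho_mat,
                 permutation_p = perm$p, null_mae = perm$null_mae,
                 permutation_grid = perm_grid,
                 config = cfg),
            class = "sdmt_prediction")
}

#' @export
print.sdmt_prediction <- function(x, ...) {
  cat("Boosted-tree cognition-score prediction (",
      length(x$repetitions), " repetitions)\n", sep = "")
  cat(sprintf("  validation MAE: %.2f ± %.2f points\n",
              x$validation_mae["mean"], x$validation_mae["sd"]))
  cat(sprintf("  hold-out MAE:   %.2f ± %.2f points (n = %d)\n",
              x$holdout_mae["mean"], x$holdout_mae["sd"],
              length(x$split$holdout$y)))
  cat(sprintf("  permutation p:  %.4g (%d permutations)\n",
              x$permutation_p, x$config$n_permutations))
  cat("  top features:",
      paste(x$consensus_ranking[1:3], collapse = ", "), "\n")
  invisible(x)
}
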