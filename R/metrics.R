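#' Within-network gradient scores
#'
#' Mean gradient value per network, for each retained gradient.
#'
#' @param emb aligned `gradient_embedding` (or plain P x m matrix).
#' @param assign `network_assignment` for the same parcels.
#' @return K x m matrix of network means (rows = networks).
#' @export
within_network_score <- function(emb, assign) {
  g <- embedding_matrix(emb)
  check_networks(assign, nrow(g))
  out <- apply(g, 2, function(col) tapply(col, assign$network, mean))
  rownames(out) <- levels(assign$network)
  out
}

#' Within-network dispersion
#'
#' Sum of squared Euclidean distances of each network's parcels from the
#' network centroid, in the first-two-gradient plane.
#'
#' @inheritParams within_network_score
#' @return Named numeric vector of length K (squared gradient units).
#' @export
within_network_dispersion <- function(emb, assign) {
  g <- embedding_matrix(emb)[, 1:2, drop = FALSE]
  check_networks(assign, nrow(g))
  vapply(levels(assign$network), function(k) {
    x <- g[assign$network == k, , drop = FALSE]
    ctr <- colMeans(x)
    sum(sweep(x, 2, ctr)^2)
  }, numeric(1))
}

#' Between-network dispersion
#'
#' Euclidean distances between network centroids in the first-two-gradient
#' plane.
#'
#' @inheritParams within_network_score
#' @return K x K symmetric matrix of centroid distances (zero diagonal).
#' @export
between_network_dispersion <- function(emb, assign) {
  g <- embedding_matrix(emb)[, 1:2, drop = FALSE]
  check_networks(assign, nrow(g))
  ctr <- apply(g, 2, function(col) tapply(col, assign$network, mean))
  d <- as.matrix(stats::dist(ctr))
  dimnames(d) <- list(levels(assign$network), levels(assign$network))
  d
}

#' Global gradient variation
#'
#' Sample standard deviation (denominator P - 1) of each of the first two
#' gradients across all parcels; lower values indicate a compressed axis.
#'
#' @param emb aligned `gradient_embedding` (or plain P x m matrix).
#' @return Named numeric vector `c(G1 = ..., G2 = ...)`.
#' @export
global_variation <- function(emb) {
  g <- embedding_matrix(emb)[, 1:2, drop = FALSE]
  if (nrow(g) < 2) stop("need at least 2 parcels")
  stats::setNames(apply(g, 2, stats::sd), c("G1", "G2"))
}

#' Per-subject network gradient metrics for a fitted cohort
#'
#' Computes all network-level metrics (within-network scores for gradients 1
#' and 2, within-network dispersion, between-network dispersion, global
#' variation) for every subject of a [fit_gradients()] result.
#'
#' @param fit a `gradient_fit`.
#' @param assign `network_assignment`.
#' @return A `network_metrics` list with components:
#'   `score_g1`, `score_g2` (subjects x networks matrices),
#'   `dispersion` (subjects x networks), `between` (subjects x pairs, columns
#'   named `A|B`), `variation` (subjects x 2), and `manifest`.
#' @export
network_metrics <- function(fit, assign) {
  stopifnot(inherits(fit, "gradient_fit"))
  subj <- names(fit$embeddings)
  K <- nlevels(assign$network)
  lv <- levels(assign$network)
  pairs <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  pair_names <- paste(lv[pairs[, 1]], lv[pairs[, 2]], sep = "|")

  score_g1 <- score_g2 <- dispersion <- matrix(NA_real_, length(subj), K,
                                               dimnames = list(subj, lv))
  between <- matrix(NA_real_, length(subj), nrow(pairs),
                    dimnames = list(subj, pair_names))
  variation <- matrix(NA_real_, length(subj), 2,
                      dimnames = list(subj, c("G1", "G2")))
  for (i in seq_along(subj)) {
    emb <- fit$embeddings[[i]]
    sc <- within_network_score(emb, assign)
    score_g1[i, ] <- sc[, 1]
    score_g2[i, ] <- sc[, 2]
    dispersion[i, ] <- within_network_dispersion(emb, assign)
    bd <- between_network_dispersion(emb, assign)
    between[i, ] <- bd[pairs]
    variation[i, ] <- global_variation(emb)
  }
  structure(list(score_g1 = score_g1, score_g2 = score_g2,
                 dispersion = dispersion, between = between,
                 variation = variation, manifest = fit$manifest,
                 networks = lv),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat("Network gradient metrics:", nrow(x$score_g1), "subjects,",
      length(x$networks), "networks\n")
  invisible(x)
}

embedding_matrix <- function(emb) {
  if (inherits(emb, "gradient_embedding")) emb$components else as.matrix(emb)
}

check_networks <- function(assign, P) {
  if (nrow(assign) != P)
    stop("network assignment has ", nrow(assign), " parcels; embedding has ", P)
  counts <- table(assign$network)
  if (any(counts == 0))
    stop("empty network(s): ", paste(names(counts)[counts == 0], collapse = ", "))
  invisible(TRUE)
}
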