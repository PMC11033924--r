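#' Row-wise sparsification of a connectivity matrix
#'
#' In each row, keeps the `k = round(density * (P - 1))` largest off-diagonal
#' values by signed value and zeroes the rest (ties broken by parcel index:
#' earlier index wins). Retained values are unchanged; the result is generally
#' asymmetric.
#'
#' @param z Fisher-z connectivity matrix (zero diagonal).
#' @param density fraction of off-diagonal connections to keep per row,
#'   in (0, 1); default 0.10.
#' @return Row-sparse P x P matrix.
#' @export
sparsify_rows <- function(z, density = 0.10) {
  if (!(density > 0 && density < 1)) stop("density must be in (0, 1)")
  P <- nrow(z)
  k <- round(density * (P - 1))
  if (k < 1) stop("density ", density, " keeps 0 connections per row at P = ", P)
  out <- matrix(0, P, P)
  for (i in seq_len(P)) {
    row <- z[i, ]
    row[i] <- -Inf
    # order() is stable: among equal values the smaller index is selected
    keep <- order(row, decreasing = TRUE)[seq_len(k)]
    out[i, keep] <- z[i, keep]
  }
  dimnames(out) <- dimnames(z)
  out
}

#' Cosine affinity between connectivity profiles
#'
#' Cosine similarity between every pair of (sparsified) connectivity rows,
#' with negative similarities clipped to 0 so the kernel is a valid
#' nonnegative affinity. Diagonal is exactly 1.
#'
#' @param s row-sparse matrix from [sparsify_rows()] (or any matrix of
#'   connectivity profiles; rows must be nonzero).
#' @return P x P symmetric affinity matrix with entries in [0, 1], tagged
#'   `kernel = "cosine"`.
#' @export
cosine_affinity <- function(s) {
  norms <- sqrt(rowSums(s^2))
  if (any(norms == 0))
    stop("all-zero connectivity row for parcel ",
         paste(which(norms == 0), collapse = ", "))
  w <- tcrossprod(s / norms)
  w[w < 0] <- 0
  w[w > 1] <- 1
  w <- (w + t(w)) / 2
  diag(w) <- 1
  structure(w, kernel = "cosine")
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Computes the gradient components of a nonnegative affinity matrix via
#' diffusion maps: (i) anisotropic normalization
#' \eqn{W' = D^{-\alpha} W D^{-\alpha}} with \eqn{D} the diagonal of row sums
#' of \eqn{W}; (ii) Markov operator \eqn{M = D_{row}^{-1} W'}; (iii)
#' eigendecomposition of the symmetric conjugate
#' \eqn{S = D_{row}^{1/2} M D_{row}^{-1/2}} (numerically stable, real); (iv)
#' the trivial stationary eigenvector (eigenvalue 1) is discarded; (v) each
#' remaining eigenvector \eqn{\psi_c} is scaled by \eqn{\lambda_c^t}, or by
#' the multiscale factor \eqn{\lambda_c / (1 - \lambda_c)} when
#' `diffusion_time = 0`.
#'
#' Explained variance is reported as \eqn{\lambda_c / \sum \lambda} over the
#' retained non-trivial eigenvalues (a declared convention; diffusion-map
#' eigenvalues admit no unique variance decomposition).
#'
#' @param w symmetric nonnegative affinity matrix, connected under its
#'   nonzero entries.
#' @param n_components number of gradients to retain (default 10).
#' @param alpha anisotropic-diffusion parameter in [0, 1] (default 0.5).
#' @param diffusion_time scale parameter t >= 0; 0 selects multiscale
#'   scaling (default).
#' @return A `gradient_embedding`: list with `components` (P x m matrix),
#'   `lambdas` (retained eigenvalues, descending), `explained_variance`,
#'   `aligned` flag, and the parameters used.
#' @export
diffusion_embedding <- function(w, n_components = 10L, alpha = 0.5,
                                diffusion_time = 0) {
  P <- nrow(w)
  if (n_components >= P) stop("n_components must be < number of parcels")
  if (any(w < 0)) stop("affinity must be nonnegative")
  if (max(abs(w - t(w))) > 1e-10) stop("affinity must be symmetric")
  comp <- graph_components(w > 0)
  if (length(unique(comp)) > 1)
    stop("affinity graph is disconnected (component sizes: ",
         paste(sort(table(comp), decreasing = TRUE), collapse = ", "), ")")

  d <- rowSums(w)
  w_alpha <- w / outer(d^alpha, d^alpha)
  d_row <- rowSums(w_alpha)
  inv_sqrt <- 1 / sqrt(d_row)
  S <- w_alpha * tcrossprod(inv_sqrt)  # D^{-1/2} W' D^{-1/2}, symmetric
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  # eigenvalue 1 with eigenvector ~ sqrt(d_row) is the stationary mode
  lambdas <- e$values[-1]
  vecs <- e$vectors[, -1, drop = FALSE]
  idx <- seq_len(n_components)
  lambdas <- lambdas[idx]
  if (any(lambdas <= 0))
    stop("retained eigenvalue <= 0; affinity too close to disconnected/degenerate")
  if (any(lambdas >= 1))
    stop("non-trivial eigenvalue >= 1; affinity graph appears disconnected")
  psi <- inv_sqrt * vecs[, idx, drop = FALSE]  # back-transform to M's eigenvectors
  scale_fac <- if (diffusion_time == 0) lambdas / (1 - lambdas) else lambdas^diffusion_time
  components <- sweep(psi, 2, scale_fac, `*`)
  colnames(components) <- paste0("G", idx)
  structure(list(components = components,
                 lambdas = lambdas,
                 explained_variance = lambdas / sum(lambdas),
                 aligned = FALSE,
                 alpha = alpha, diffusion_time = diffusion_time),
            class = "gradient_embedding")
}

# connected components of an undirected adjacency (logical matrix), label per node
graph_components <- function(adj) {
  P <- nrow(adj)
  comp <- integer(P)
  cur <- 0L
  for (s in seq_len(P)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @export
print.gradient_embedding <- function(x, ...) {
  cat("Gradient embedding:", nrow(x$components), "parcels x",
      ncol(x$components), "components",
      if (isTRUE(x$aligned)) "(aligned)" else "(unaligned)", "\n")
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance[seq_len(min(3, length(x$explained_variance)))]),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Build the group gradient template
#'
#' Runs sparsify -> cosine affinity -> diffusion embedding on a group-mean
#' Fisher-z connectivity matrix and applies a deterministic sign convention
#' (each component's largest-magnitude entry is made positive).
#'
#' @param group_fc group-mean Fisher-z connectivity matrix.
#' @param density,n_components,alpha,diffusion_time embedding parameters,
#'   see [sparsify_rows()] and [diffusion_embedding()].
#' @return A `gradient_embedding` with attribute `template = TRUE`.
#' @export
build_template <- function(group_fc, density = 0.10, n_components = 10L,
                           alpha = 0.5, diffusion_time = 0) {
  emb <- diffusion_embedding(
    cosine_affinity(sparsify_rows(group_fc, density)),
    n_components = n_components, alpha = alpha, diffusion_time = diffusion_time)
  flip <- apply(emb$components, 2, function(v) sign(v[which.max(abs(v))]))
  emb$components <- sweep(emb$components, 2, flip, `*`)
  attr(emb, "template") <- TRUE
  emb
}

#' Procrustes alignment of an embedding to a template
#'
#' Finds the orthogonal matrix R (rotation + reflection; no scaling, no
#' translation) minimizing \eqn{\|XR - T\|_F} in closed form from the singular
#' value decomposition of \eqn{X^\top T}, and returns the rotated embedding.
#' All retained components are aligned jointly.
#'
#' @param emb `gradient_embedding` to align.
#' @param template reference `gradient_embedding` of identical dimensions.
#' @return The aligned `gradient_embedding` (`aligned = TRUE`), with the
#'   rotation stored in attribute `rotation`.
#' @export
align_to_template <- function(emb, template) {
  X <- emb$components; Tm <- template$components
  if (!all(dim(X) == dim(Tm)))
    stop("embedding (", paste(dim(X), collapse = "x"),
         ") and template (", paste(dim(Tm), collapse = "x"), ") dimensions differ")
  s <- svd(crossprod(X, Tm))
  R <- s$u %*% t(s$v)
  emb$components <- X %*% R
  colnames(emb$components) <- colnames(Tm)
  emb$aligned <- TRUE
  attr(emb, "rotation") <- R
  emb
}

#' Fit aligned functional gradients for a cohort
#'
#' The core pipeline: per-subject Pearson connectivity, Fisher z-transform,
#' group-mean template embedding, per-subject diffusion-map embeddings and
#' orthogonal Procrustes alignment to the template.
#'
#' @param cohort a `synthetic_cohort` or a list with elements `manifest`
#'   (data.frame) and `ts` (named list of [parcel_timeseries()]).
#' @param density,n_components,alpha,diffusion_time embedding parameters.
#' @param fd_threshold QC threshold in mm passed to [qc_filter()].
#' @param bandpass if `TRUE`, band-pass filter each series first (off by
#'   default: the synthetic generator produces temporally white signals with
#'   no frequency structure to remove; set `TRUE` for real recordings).
#' @param band length-2 band edges in Hz used when `bandpass = TRUE`.
#' @return A `gradient_fit`: list with `template`, `embeddings` (named list of
#'   aligned `gradient_embedding`s), `manifest` (post-QC), `exclusions` and
#'   the parameters used.
#' @export
fit_gradients <- function(cohort, density = 0.10, n_components = 10L,
                          alpha = 0.5, diffusion_time = 0,
                          fd_threshold = 0.5, bandpass = FALSE,
                          band = c(0.01, 0.1)) {
  qc <- qc_filter(cohort$manifest, cohort$ts, fd_threshold)
  ts <- qc$ts
  if (bandpass)
    ts <- lapply(ts, bandpass_filter, low = band[1], high = band[2])
  zs <- lapply(ts, function(x) fisher_z(pearson_fc(x)))
  template <- build_template(group_mean_fc(zs), density = density,
                             n_components = n_components, alpha = alpha,
                             diffusion_time = diffusion_time)
  embeddings <- lapply(zs, function(z)
    align_to_template(
      diffusion_embedding(cosine_affinity(sparsify_rows(z, density)),
                          n_components = n_components, alpha = alpha,
                          diffusion_time = diffusion_time),
      template))
  structure(list(template = template, embeddings = embeddings,
                 manifest = qc$manifest, exclusions = qc$exclusions,
                 density = density, n_components = n_components,
                 alpha = alpha, diffusion_time = diffusion_time),
            class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat("Gradient fit:", length(x$embeddings), "aligned subjects,",
      ncol(x$template$components), "components\n")
  cat("  template explained variance (G1, G2):",
      sprintf("%.1f%%, %.1f%%", 100 * x$template$explained_variance[1],
              100 * x$template$explained_variance[2]), "\n")
  if (nrow(x$exclusions))
    cat("  excluded:", nrow(x$exclusions), "subject(s)\n")
  invisible(x)
}

#' @export
summary.gradient_fit <- function(object, ...) {
  ev <- object$template$explained_variance
  cat("Template eigenvalue spectrum (", length(ev), " components):\n", sep = "")
  print(round(data.frame(lambda = object$template$lambdas,
                         explained_variance = ev), 4))
  invisible(object)
}

#' Scatterplot of the template gradient space
#'
#' Plots parcels in the first-two-gradient plane, coloured by network.
#'
#' @param x a `gradient_fit`.
#' @param lookup optional `network_assignment` used for colouring.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gradient_fit <- function(x, lookup = NULL, ...) {
  g <- x$template$components[, 1:2]
  col <- if (!is.null(lookup)) as.integer(lookup$network) else 1L
  graphics::plot(g[, 1], g[, 2], col = col, pch = 16,
                 xlab = "Gradient 1", ylab = "Gradient 2", ...)
  if (!is.null(lookup))
    graphics::legend("topleft", legend = levels(lookup$network),
                     col = seq_len(nlevels(lookup$network)), pch = 16, cex = 0.7)
  invisible(x)
}
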