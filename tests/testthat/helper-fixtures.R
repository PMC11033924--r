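# Small in-memory fixtures shared across test files.

# A tiny but pipeline-complete synthetic cohort (reduced subject count only;
# parcel/timepoint dimensions and all planted effects are the defaults).
small_cohort <- function(seed = 7L, n = c(MS = 12L, HC = 12L), ...) {
  simulate_cohort(simulation_spec(seed = seed, n_per_group = n, ...))
}

# Random symmetric nonnegative affinity with unit diagonal, strictly positive
# entries (hence connected).
rand_affinity <- function(P, seed = 1L) {
  set.seed(seed)
  m <- matrix(runif(P * P, 0.05, 1), P, P)
  w <- (m + t(m)) / 2
  diag(w) <- 1
  w
}

# Random orthogonal matrix via QR with a fixed sign convention.
rand_orthogonal <- function(m, seed = 1L) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(m * m), m, m))
  Q <- qr.Q(qr_d)
  Q %*% diag(sign(diag(qr.R(qr_d))), m)
}

# Independent brute-force diffusion-map embedding: literal transcription of
# the operator definitions using a dense nonsymmetric eigensolver.
brute_diffusion <- function(w, n_components, alpha = 0.5, t = 0) {
  d <- rowSums(w)
  w_a <- w / outer(d^alpha, d^alpha)
  m <- w_a / rowSums(w_a)
  e <- eigen(m)
  stopifnot(max(abs(Im(e$values))) < 1e-10)
  vals <- Re(e$values); vecs <- Re(e$vectors)
  o <- order(vals, decreasing = TRUE)
  vals <- vals[o]; vecs <- vecs[, o, drop = FALSE]
  vals <- vals[-1]; vecs <- vecs[, -1, drop = FALSE]  # drop trivial
  idx <- seq_len(n_components)
  sc <- if (t == 0) vals[idx] / (1 - vals[idx]) else vals[idx]^t
  # normalize eigenvectors to the same convention as the package
  # (psi = D^{-1/2} v with v unit-norm in the symmetrized space)
  d_row <- rowSums(w_a)
  vecs <- apply(vecs[, idx, drop = FALSE], 2, function(v) {
    u <- sqrt(d_row) * v
    v / sqrt(sum(u^2))
  })
  list(lambdas = vals[idx], components = sweep(vecs, 2, sc, `*`))
}

# Column-wise comparison up to sign.
expect_equal_upto_sign <- function(A, B, tol) {
  for (j in seq_len(ncol(A))) {
    d <- min(max(abs(A[, j] - B[, j])), max(abs(A[, j] + B[, j])))
    expect_lt(d, tol)
  }
}

# Mean silhouette of labelled points (Euclidean), hand-rolled.
mean_silhouette <- function(X, labels) {
  D <- as.matrix(dist(X))
  sil <- vapply(seq_len(nrow(X)), function(i) {
    own <- labels == labels[i]; own[i] <- FALSE
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}
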