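test_that("row sparsification keeps exactly the top-k signed values per row", {
  set.seed(1)
  z <- matrix(rnorm(21 * 21), 21, 21); z <- (z + t(z)) / 2; diag(z) <- 0
  s <- sparsify_rows(z, density = 0.1)  # k = round(0.1 * 20) = 2
  for (i in 1:21) {
    kept <- which(s[i, ] != 0)
    expect_length(kept, 2)
    expect_setequal(kept, order(replace(z[i, ], i, -Inf), decreasing = TRUE)[1:2])
    expect_equal(s[i, kept], z[i, kept])
  }
  # at P = 200 and 10% density, 20 connections survive per row
  z200 <- matrix(rnorm(200 * 200), 200); z200 <- (z200 + t(z200)) / 2; diag(z200) <- 0
  expect_true(all(rowSums(sparsify_rows(z200, 0.10) != 0) == 20))
  # ties broken by parcel index
  ztie <- matrix(1, 5, 5); diag(ztie) <- 0
  stie <- sparsify_rows(ztie, 0.4)  # k = round(0.4*4) = 2
  expect_equal(which(stie[3, ] != 0), c(1, 2))
  expect_error(sparsify_rows(ztie, 0.05), "0 connections")
})

test_that("cosine affinity matches hand-computed similarities and is clipped", {
  s <- rbind(c(1, 2, 0), c(2, 1, 0), c(0, 0, 1), c(1, 2, 0), c(-1, -2, 0))
  w <- cosine_affinity(s)
  expect_equal(w[1, 2], 0.8, tolerance = 1e-12)   # (1*2+2*1)/ (sqrt5*sqrt5)
  expect_equal(w[1, 4], 1, tolerance = 1e-12)     # identical rows
  expect_equal(w[1, 3], 0)                        # orthogonal rows
  expect_equal(w[1, 5], 0)                        # negative similarity clipped
  expect_equal(diag(w), rep(1, 5))
  expect_true(all(w >= 0 & w <= 1))
  expect_lt(max(abs(w - t(w))), 1e-12)
  expect_error(cosine_affinity(rbind(c(1, 0), c(0, 0))), "parcel 2")
})

test_that("diffusion embedding matches a dense brute-force eigendecomposition", {
  for (P in c(10, 16, 20)) {
    w <- rand_affinity(P, seed = P)
    emb <- diffusion_embedding(w, n_components = 5)
    ref <- brute_diffusion(w, n_components = 5)
    expect_equal(emb$lambdas, ref$lambdas, tolerance = 1e-8)
    expect_equal_upto_sign(emb$components, ref$components, 1e-8)
    expect_equal(emb$explained_variance, emb$lambdas / sum(emb$lambdas))
    expect_true(all(diff(emb$lambdas) <= 1e-12))
  }
})

test_that("diffusion embedding is invariant to uniform affinity scaling", {
  w <- rand_affinity(12, seed = 3)
  a <- diffusion_embedding(w, 4)
  b <- diffusion_embedding(3 * w, 4)
  expect_equal(a$lambdas, b$lambdas, tolerance = 1e-10)
  expect_equal_upto_sign(a$components, b$components, 1e-8)
})

test_that("the leading gradient separates two weakly-joined cliques", {
  P <- 12
  w <- matrix(0, P, P)
  w[1:6, 1:6] <- 0.9; w[7:12, 7:12] <- 0.9
  diag(w) <- 1
  w[6, 7] <- w[7, 6] <- 0.05
  emb <- diffusion_embedding(w, 3)
  g1 <- emb$components[, 1]
  expect_true(all(sign(g1[1:6]) == sign(g1[1])))
  expect_true(all(sign(g1[7:12]) == -sign(g1[1])))
  expect_lt(sd(g1[1:6]) / abs(mean(g1[1:6])), 0.2)
})

test_that("disconnected affinities are rejected with component sizes", {
  w <- matrix(0, 7, 7)
  w[1:3, 1:3] <- 0.8; w[4:7, 4:7] <- 0.8; diag(w) <- 1
  expect_error(diffusion_embedding(w, 2), "disconnected")
  expect_error(diffusion_embedding(w, 2), "4, 3")
})

test_that("template construction is deterministic with an anchored sign", {
  z <- local({
    set.seed(5)
    m <- matrix(rnorm(40 * 40, sd = 0.4), 40); m <- (m + t(m)) / 2; diag(m) <- 0
    structure(m, stage = "fisher_z")
  })
  t1 <- build_template(z, n_components = 5)
  t2 <- build_template(z, n_components = 5)
  expect_identical(t1$components, t2$components)
  for (j in 1:5) {
    v <- t1$components[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("gradient components are orthogonal under the Markov inner product", {
  w <- rand_affinity(15, seed = 8)
  emb <- diffusion_embedding(w, 5, alpha = 0.5)
  d <- rowSums(w)
  w_a <- w / outer(d^0.5, d^0.5)
  d_row <- rowSums(w_a)
  gram <- t(emb$components) %*% (d_row * emb$components)
  off <- gram - diag(diag(gram))
  expect_lt(max(abs(off)), 1e-8)
})

test_that("Procrustes alignment recovers planted orthogonal transforms", {
  set.seed(6)
  Tm <- list(components = matrix(rnorm(30 * 6), 30, 6), aligned = FALSE)
  class(Tm) <- "gradient_embedding"
  # fixed point
  self <- align_to_template(Tm, Tm)
  expect_lt(max(abs(self$components - Tm$components)), 1e-10)
  expect_lt(max(abs(attr(self, "rotation") - diag(6))), 1e-10)
  # planted rotation + reflection
  for (s in 1:3) {
    Q <- rand_orthogonal(6, seed = s)
    X <- Tm; X$components <- Tm$components %*% Q
    al <- align_to_template(X, Tm)
    expect_lt(norm(al$components - Tm$components, "F"), 1e-8)
    expect_true(al$aligned)
  }
  # pure sign flips are undone
  F1 <- Tm; F1$components <- Tm$components %*% diag(c(-1, 1, -1, 1, 1, -1))
  expect_lt(norm(align_to_template(F1, Tm)$components - Tm$components, "F"), 1e-8)
  # alignment preserves pairwise parcel distances
  X <- Tm; X$components <- Tm$components %*% rand_orthogonal(6, seed = 9)
  al <- align_to_template(X, Tm)
  expect_equal(as.vector(dist(al$components)), as.vector(dist(X$components)),
               tolerance = 1e-10)
  bad <- Tm; bad$components <- Tm$components[, 1:3]
  expect_error(align_to_template(bad, Tm), "dimensions differ")
})

test_that("small-instance pipeline agrees with an independent transcription", {
  set.seed(10)
  for (P in c(15, 20)) {
    m <- matrix(rnorm(P * P, sd = 0.3), P); m <- (m + t(m)) / 2; diag(m) <- 0
    s <- sparsify_rows(m, 0.3)
    # independent sparsify: full sort per row
    s_ref <- matrix(0, P, P)
    k <- round(0.3 * (P - 1))
    for (i in 1:P) {
      v <- m[i, ]; v[i] <- -Inf
      top <- order(v, decreasing = TRUE)[1:k]
      s_ref[i, top] <- m[i, top]
    }
    expect_equal(s, s_ref)
    norms <- sqrt(rowSums(s^2))
    w_ref <- tcrossprod(s / norms); w_ref[w_ref < 0] <- 0; diag(w_ref) <- 1
    w_ref <- (w_ref + t(w_ref)) / 2
    emb <- diffusion_embedding(cosine_affinity(s), 4)
    ref <- brute_diffusion(w_ref, 4)
    expect_equal(emb$lambdas, ref$lambdas, tolerance = 1e-8)
    expect_equal_upto_sign(emb$components, ref$components, 1e-8)
  }
})

test_that("the template recovers the planted network geometry", {
  # population-level connectivity of the default design, no sampling noise
  spec <- simulation_spec()
  S <- build_group_covariance(spec, "HC")
  z <- atanh(S * (1 - 1e-12)); diag(z) <- 0
  attr(z, "stage") <- "fisher_z"
  tmpl <- build_template(z)
  lk <- canonical_networks()
  sil <- mean_silhouette(tmpl$components[, 1:2], as.character(lk$network))
  expect_gt(sil, 0)
  set.seed(11)
  sil_perm <- replicate(20, mean_silhouette(tmpl$components[, 1:2],
                                            sample(as.character(lk$network))))
  expect_gt(sil, max(sil_perm))
})
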